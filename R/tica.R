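#' Time-lagged independent component analysis (tICA)
#'
#' Fits the slow linear subspace of a feature trajectory by solving the
#' generalized eigenproblem `C_tau v = lambda C_0 v`, where `C_0` is the
#' instantaneous covariance and `C_tau` the symmetrized time-lagged
#' covariance (reversible estimate). Components are ranked by kinetic
#' variance `lambda^2`. Lagged pairs are formed within each trajectory
#' only; trajectories are never concatenated across boundaries.
#'
#' Constant features (zero variance over the lagged-pair frames) carry no
#' kinetic information and are removed with a warning before solving. The
#' instantaneous covariance is ridge-regularized with
#' `epsilon = ridge * trace(C0)/dim` to keep nearly-degenerate binary
#' feature sets solvable.
#'
#' @param features a [feature_trajectory()], a list of them, a numeric
#'   matrix, or a list of matrices.
#' @param lag lag time in frames (integer >= 0). `lag = 0` reduces to pure
#'   whitening (all eigenvalues 1).
#' @param n_components number of components to keep (default 20).
#' @param ridge relative ridge strength on `C0` (default 1e-6).
#' @param dt_ns frame spacing when bare matrices are supplied.
#' @return Object of class `tica_model` with fields `mean`, `C0`, `Ct`,
#'   `eigenvalues` (ranked by kinetic variance), `vectors`
#'   (C0-orthonormal columns), `lag_frames`, `lag_ns`, `kept` (indices of
#'   retained input features), `n_components`.
#' @export
fit_tica <- function(features, lag, n_components = 20, ridge = 1e-6,
                     dt_ns = NULL) {
  trajs <- .as_feature_list(features, dt_ns)
  dt_ns <- trajs$dt_ns
  mats <- trajs$mats
  lag <- as.integer(lag)
  stopifnot(lag >= 0)
  if (any(vapply(mats, nrow, integer(1)) <= lag))
    stop("lag must be shorter than every trajectory")

  dim_in <- ncol(mats[[1]])
  labels <- colnames(mats[[1]]) %||% paste0("f", seq_len(dim_in))

  # accumulate moments over lagged pairs (both windows -> reversible)
  s1 <- numeric(dim_in)
  s2 <- matrix(0, dim_in, dim_in)
  sct <- matrix(0, dim_in, dim_in)
  npair <- 0
  for (m in mats) {
    n <- nrow(m)
    i0 <- seq_len(n - lag)
    x0 <- m[i0, , drop = FALSE]
    xt <- m[i0 + lag, , drop = FALSE]
    s1 <- s1 + colSums(x0) + colSums(xt)
    s2 <- s2 + crossprod(x0) + crossprod(xt)
    sct <- sct + crossprod(x0, xt) + crossprod(xt, x0)
    npair <- npair + length(i0)
  }
  mu <- s1 / (2 * npair)
  c0 <- s2 / (2 * npair) - tcrossprod(mu)
  ct <- sct / (2 * npair) - tcrossprod(mu)

  keep <- which(diag(c0) > 1e-12)
  if (length(keep) < dim_in) {
    warning(sprintf("removed %d constant feature(s) before tICA: %s",
                    dim_in - length(keep),
                    paste(labels[-keep], collapse = ", ")))
    c0 <- c0[keep, keep, drop = FALSE]
    ct <- ct[keep, keep, drop = FALSE]
  }
  if (length(keep) == 0) stop("all features are constant")
  mu <- mu[keep]

  eps <- ridge * sum(diag(c0)) / length(keep)
  c0r <- c0 + diag(eps, nrow(c0))
  ch <- chol(c0r)  # c0r = t(ch) %*% ch
  # M = ch^-T Ct ch^-1 is symmetric; solve the ordinary eigenproblem there
  z <- forwardsolve(t(ch), ct)
  m <- forwardsolve(t(ch), t(z))
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  ord <- order(es$values^2, decreasing = TRUE)
  lam <- es$values[ord]
  vec <- backsolve(ch, es$vectors[, ord, drop = FALSE])
  if (max(abs(lam)) > 1 + 1e-6)
    warning(sprintf("leading |eigenvalue| %.4f exceeds 1; estimate may be ill-conditioned",
                    max(abs(lam))))
  nc <- min(n_components, length(lam))
  structure(list(mean = mu, C0 = c0, Ct = ct,
                 eigenvalues = lam[seq_len(nc)],
                 vectors = vec[, seq_len(nc), drop = FALSE],
                 all_eigenvalues = lam,
                 lag_frames = lag, lag_ns = lag * (dt_ns %||% 1),
                 dt_ns = dt_ns %||% 1, ridge = eps,
                 kept = keep, dim_in = dim_in,
                 labels = labels, n_components = nc),
            class = "tica_model")
}

.as_feature_list <- function(features, dt_ns = NULL) {
  if (inherits(features, "feature_trajectory")) features <- list(features)
  if (is.matrix(features)) features <- list(features)
  stopifnot(is.list(features), length(features) >= 1)
  if (inherits(features[[1]], "feature_trajectory")) {
    dt <- features[[1]]$dt_ns
    mats <- lapply(features, function(f) f$mat)
  } else {
    dt <- dt_ns
    mats <- lapply(features, as.matrix)
  }
  dims <- vapply(mats, ncol, integer(1))
  if (length(unique(dims)) != 1) stop("feature dimensions differ across trajectories")
  list(mats = mats, dt_ns = dt)
}

#' Project features onto fitted tICA components
#'
#' Mean-subtracted projection onto the retained eigenvectors; columns of
#' the result are the independent components, deterministic given the
#' model.
#'
#' @param model a fitted `tica_model`.
#' @param features a [feature_trajectory()], matrix, or list thereof.
#' @return frames x n_components matrix (or list of matrices when a list
#'   was supplied).
#' @export
tica_transform <- function(model, features) {
  stopifnot(inherits(model, "tica_model"))
  one <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != model$dim_in)
      stop(sprintf("feature dimension %d does not match model (%d)",
                   ncol(m), model$dim_in))
    x <- m[, model$kept, drop = FALSE]
    sweep(x, 2, model$mean) %*% model$vectors
  }
  if (inherits(features, "feature_trajectory")) return(one(features$mat))
  if (is.matrix(features)) return(one(features))
  lapply(features, function(f)
    one(if (inherits(f, "feature_trajectory")) f$mat else f))
}

#' Kinetic variance of tICA components
#'
#' @param model a `tica_model`.
#' @return Numeric vector `lambda^2` for the retained components.
#' @export
kinetic_variance <- function(model) model$eigenvalues^2

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: %d -> %d components at lag %d frames (%.3g ns)\n",
              x$dim_in, x$n_components, x$lag_frames, x$lag_ns))
  cat("Leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n")
  invisible(x)
}
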