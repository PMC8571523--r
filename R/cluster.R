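#' k-means discretization of the tICA space into microstates
#'
#' Lloyd iterations from k-means++ seeding, run until the largest center
#' shift drops below `tol` or `max_iter` is reached. Deterministic for a
#' fixed seed. Clusters that empty out during an iteration are repaired by
#' reseeding the center to the point farthest from its current center, so
#' the number of microstates stays fixed.
#'
#' @param x frames x dims matrix (typically tICA projections), or a list
#'   of such matrices (concatenated; per-trajectory labels are returned).
#' @param k number of microstates (clusters).
#' @param seed integer RNG seed for the k-means++ initialization.
#' @param max_iter maximum Lloyd iterations (default 100).
#' @param tol convergence threshold on the maximum center displacement.
#' @return Object of class `discretization` with `centers` (k x dims),
#'   `labels` (integer vector, or list when `x` was a list), `inertia`,
#'   `k`, `seed`, `iter`, `converged`.
#' @export
kmeans_fit <- function(x, k, seed = 1L, max_iter = 100L, tol = 1e-8) {
  xs <- if (is.list(x) && !is.data.frame(x)) lapply(x, as.matrix) else list(as.matrix(x))
  lens <- vapply(xs, nrow, integer(1))
  xm <- do.call(rbind, xs)
  n <- nrow(xm)
  if (n < k) stop(sprintf("n_frames (%d) < k (%d): choose a smaller k", n, k))
  set.seed(seed)
  centers <- xm[.kmeanspp_init(xm, k), , drop = FALSE]
  xsq <- rowSums(xm^2)
  lab <- integer(n)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    d2 <- .sq_dists(xm, centers, xsq)
    lab <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      idx <- lab == j
      if (!any(idx)) {
        # empty-cluster repair: reseed to the globally worst-fit point
        far <- which.max(d2[cbind(seq_len(n), lab)])
        newc[j, ] <- xm[far, ]
        lab[far] <- j
      } else {
        newc[j, ] <- colMeans(xm[idx, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  d2 <- .sq_dists(xm, centers, xsq)
  lab <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), lab)])
  labels <- if (length(xs) > 1)
    unname(split(lab, rep(seq_along(xs), lens)))
  else lab
  structure(list(k = as.integer(k), centers = centers, labels = labels,
                 inertia = inertia, seed = as.integer(seed),
                 iter = iter, converged = converged),
            class = "discretization")
}

# squared distances frames x centers via the expansion |x|^2 - 2 x.c + |c|^2
.sq_dists <- function(x, centers, xsq = rowSums(x^2)) {
  d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j + 1], ])^2))
  }
  idx
}

#' Assign data to the nearest microstate center
#'
#' Euclidean nearest-center assignment; ties are broken by the lowest
#' center index.
#'
#' @param centers k x dims center matrix or a `discretization`.
#' @param x new data (frames x dims).
#' @return Integer labels in `1..k`.
#' @export
assign_microstates <- function(centers, x) {
  if (inherits(centers, "discretization")) centers <- centers$centers
  x <- as.matrix(x)
  if (ncol(x) != ncol(centers)) stop("dimension mismatch with centers")
  d2 <- .sq_dists(x, centers)
  max.col(-d2, ties.method = "first")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("k-means discretization: k = %d, inertia = %.4g, %s after %d iterations\n",
              x$k, x$inertia,
              if (x$converged) "converged" else "not converged", x$iter))
  invisible(x)
}
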