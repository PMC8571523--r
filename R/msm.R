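#' Count microstate transitions at a lag time
#'
#' Sliding-window counting: every frame is a window start, so a trajectory
#' of length L contributes L - lag transition counts. Counting never
#' crosses trajectory boundaries. The count matrix is then restricted to
#' its largest strongly connected component (by total counts), which is
#' required for a unique stationary distribution downstream.
#'
#' @param dtrajs integer vector of microstate labels, or a list of them.
#' @param lag_frames lag time in frames (>= 1).
#' @param n_states total number of microstates; inferred from the labels
#'   when omitted.
#' @param mode counting mode; only `"sliding"` is implemented.
#' @return Object of class `count_model` with `counts` (full matrix),
#'   `active` (microstate indices of the connected set),
#'   `counts_active`, `lag_frames`, `dropped` (indices outside the set).
#' @export
count_transitions <- function(dtrajs, lag_frames, n_states = NULL,
                              mode = "sliding") {
  mode <- match.arg(mode, "sliding")
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag_frames <- as.integer(lag_frames)
  stopifnot(lag_frames >= 1)
  if (all(vapply(dtrajs, length, integer(1)) <= lag_frames))
    stop("lag exceeds the length of every trajectory")
  n <- n_states %||% max(vapply(dtrajs, max, numeric(1)))
  cm <- matrix(0, n, n)
  for (d in dtrajs) {
    d <- as.integer(d)
    L <- length(d)
    if (L <= lag_frames) next
    from <- d[seq_len(L - lag_frames)]
    to <- d[seq_len(L - lag_frames) + lag_frames]
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    cm <- cm + unclass(tab)
  }
  dimnames(cm) <- NULL

  g <- igraph::graph_from_adjacency_matrix(cm > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # keep the component with the largest total counts
  wt <- tapply(rowSums(cm) + colSums(cm), comp$membership, sum)
  best <- as.integer(names(which.max(wt)))
  active <- which(comp$membership == best)
  dropped <- setdiff(which(rowSums(cm) + colSums(cm) > 0), active)
  if (length(dropped))
    warning(sprintf("%d microstate(s) outside the largest connected set dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")))
  structure(list(counts = cm, active = active,
                 counts_active = cm[active, active, drop = FALSE],
                 lag_frames = lag_frames, n_states = n, dropped = dropped),
            class = "count_model")
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximizing the likelihood of the
#' counts under detailed balance, by the standard fixed-point iteration on
#' unnormalized symmetric flows:
#' `x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)`.
#' The stationary distribution is `pi_i = x_i / sum(x)` and
#' `T = x / rowSums(x)`, so detailed balance holds exactly at every
#' iterate. Convergence is declared when the maximum relative change of
#' the flows drops below `tol`.
#'
#' @param counts a [count_transitions()] result (or a raw count matrix,
#'   assumed connected).
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param dt_ns physical time per frame (ns), used to report lag and
#'   timescales in ns.
#' @return Object of class `msm_model` with `T`, `pi`, `eigenvalues`
#'   (real, sorted decreasing, leading value 1), `lag_frames`, `lag_ns`,
#'   `active` (original microstate indices), `convergence`.
#' @export
estimate_reversible <- function(counts, tol = 1e-10, max_iter = 10000L,
                                dt_ns = 1) {
  if (inherits(counts, "count_model")) {
    cm <- counts$counts_active
    active <- counts$active
    lag_frames <- counts$lag_frames
  } else {
    cm <- as.matrix(counts)
    active <- seq_len(nrow(cm))
    lag_frames <- 1L
  }
  n <- nrow(cm)
  csym <- cm + t(cm)
  ci <- rowSums(cm)
  if (any(ci == 0)) stop("count matrix has an empty row; restrict to the connected set first")
  x <- csym
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    xnew <- csym / denom
    resid <- max(abs(xnew - x) / pmax(x, 1e-300))
    x <- xnew
    if (resid < tol) break
  }
  xi <- rowSums(x)
  tm <- x / xi
  pi <- xi / sum(xi)
  ev <- .reversible_spectrum(tm, pi)
  structure(list(T = tm, pi = pi, eigenvalues = ev,
                 lag_frames = lag_frames, lag_ns = lag_frames * dt_ns,
                 dt_ns = dt_ns, active = active, counts = cm,
                 convergence = list(iter = iter, resid = resid,
                                    converged = resid < tol)),
            class = "msm_model")
  }

# real spectrum of a reversible transition matrix via the symmetrized
# similarity transform D^{1/2} T D^{-1/2}
.reversible_spectrum <- function(tm, pi, vectors = FALSE) {
  s <- sqrt(pi)
  sym <- tm * outer(s, 1 / s)
  sym <- (sym + t(sym)) / 2
  es <- eigen(sym, symmetric = TRUE)
  if (!vectors) return(es$values)
  # right eigenvectors of T, pi-orthonormal: v = y / sqrt(pi)
  list(values = es$values, vectors = es$vectors / s)
}

#' Implied timescales over a grid of lag times
#'
#' Builds an MSM at each lag and reports
#' `t_i(tau) = -tau / ln(lambda_i(tau))` for the slowest processes.
#' Lag-independence ("plateau") of the implied timescales indicates
#' Markovianity and guides the lag-time choice. Eigenvalues that are not
#' in (0, 1) yield an undefined (NA) timescale at that lag.
#'
#' @param dtrajs discrete trajectory or list of trajectories.
#' @param lags integer vector of lag times in frames.
#' @param n_its number of processes to report (default 5).
#' @param dt_ns physical time per frame (ns).
#' @return Object of class `its_profile`: data.frame with columns
#'   `lag_frames`, `lag_ns`, `process` (2 = slowest), `its_ns`.
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 5, dt_ns = 1) {
  rows <- list()
  for (lag in sort(unique(as.integer(lags)))) {
    m <- estimate_reversible(suppressWarnings(
      count_transitions(dtrajs, lag)), dt_ns = dt_ns)
    lam <- m$eigenvalues
    k <- min(n_its, length(lam) - 1)
    li <- lam[seq_len(k) + 1]
    its <- ifelse(li > 0 & li < 1, -(lag * dt_ns) / log(li), NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      lag_frames = lag, lag_ns = lag * dt_ns,
      process = seq_len(k) + 1, its_ns = its)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("its_profile", class(out))
  out
}

#' Plateau verdict for an implied-timescale profile
#'
#' A process has plateaued at a lag when its implied timescale changes by
#' less than `rel_tol` relative to the previous grid point, over two
#' successive grid points. The profile verdict requires the slowest
#' `n_slow` processes to satisfy this simultaneously.
#'
#' @param its an `its_profile`.
#' @param n_slow number of slow processes that must plateau (default 3).
#' @param rel_tol relative-change threshold (default 0.1).
#' @return List with `plateaued` (logical), `lag_ns` (earliest plateau
#'   lag, NA if none), and the per-lag relative changes.
#' @export
its_plateau <- function(its, n_slow = 3, rel_tol = 0.1) {
  lags <- sort(unique(its$lag_ns))
  if (length(lags) < 3)
    return(list(plateaued = FALSE, lag_ns = NA_real_, rel_change = NULL))
  procs <- sort(unique(its$process))[seq_len(min(n_slow, length(unique(its$process))))]
  m <- sapply(procs, function(p) {
    v <- its$its_ns[its$process == p][order(its$lag_ns[its$process == p])]
    v
  })
  m <- as.matrix(m)
  rel <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]) /
    m[-nrow(m), , drop = FALSE]
  ok <- apply(rel < rel_tol, 1, function(r) all(r, na.rm = FALSE))
  ok[is.na(ok)] <- FALSE
  # two successive grid points below threshold
  run <- which(ok[-length(ok)] & ok[-1])
  lag_at <- if (length(run)) lags[min(run)] else NA_real_
  list(plateaued = length(run) > 0, lag_ns = lag_at, rel_change = rel)
}
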