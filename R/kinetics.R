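#' Forward committor probabilities
#'
#' Solves the committor linear system on the microstate MSM:
#' `q+_i = sum_j T_ij q+_j` for intermediates, with boundary conditions
#' `q+ = 0` on the source set A and `q+ = 1` on the sink set B. For a
#' reversible chain the backward committor is `q- = 1 - q+`.
#'
#' @param msm an `msm_model`.
#' @param A integer indices of the source (e.g. unbound) microstates.
#' @param B integer indices of the sink (e.g. bound) microstates.
#' @return Numeric vector `q+` over microstates, with attribute
#'   `q_minus`.
#' @export
committor <- function(msm, A, B) {
  stopifnot(inherits(msm, "msm_model"))
  n <- nrow(msm$T)
  A <- unique(as.integer(A)); B <- unique(as.integer(B))
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  if (!length(A) || !length(B)) stop("A and B must be non-empty")
  mid <- setdiff(seq_len(n), c(A, B))
  q <- numeric(n)
  q[B] <- 1
  if (length(mid)) {
    tm <- msm$T
    lhs <- diag(length(mid)) - tm[mid, mid, drop = FALSE]
    rhs <- rowSums(tm[mid, B, drop = FALSE])
    sol <- tryCatch(solve(lhs, rhs), error = function(e) {
      reach <- .reachable(tm, B)
      stranded <- mid[!mid %in% reach]
      stop(sprintf("singular committor system; stranded intermediates: %s",
                   paste(stranded, collapse = ", ")))
    })
    q[mid] <- sol
  }
  attr(q, "q_minus") <- 1 - q
  q
}

# states from which `targets` is reachable in the directed graph T > 0
.reachable <- function(tm, targets) {
  g <- igraph::graph_from_adjacency_matrix(t(tm) > 0, mode = "directed")
  unique(unlist(lapply(targets, function(b)
    as.integer(igraph::subcomponent(g, b, mode = "out")))))
}

#' Macrostate-aggregated committor
#'
#' Stationary-weighted mean of the member microstate committors, one value
#' per macrostate.
#'
#' @param q microstate committor vector.
#' @param pi stationary distribution.
#' @param crisp macrostate assignment per microstate.
#' @return Numeric vector over macrostates.
#' @export
committor_macro <- function(q, pi, crisp) {
  vapply(sort(unique(crisp)), function(j) {
    w <- pi[crisp == j]
    sum(w * q[crisp == j]) / sum(w)
  }, numeric(1))
}

#' Transition-path-theory reactive flux and pathway decomposition
#'
#' Gross reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j), net flux
#' `f+_ij = max(0, f_ij - f_ji)`, and total A->B flux
#' `F = sum_{i in A, j notin A} f_ij`. Pathways are extracted from the
#' net-flux digraph by iterative bottleneck (widest-path) removal: find
#' the A->B path with the largest minimum edge capacity, subtract that
#' bottleneck flux along it, and repeat until the remaining flux falls
#' below `residual_frac * F`.
#'
#' @param msm an `msm_model`.
#' @param A,B source and sink microstate index sets.
#' @param decompose extract pathways (default TRUE).
#' @param residual_frac stop decomposition when the undecomposed flux
#'   drops below this fraction of the total (default 0.01).
#' @param max_paths safety cap on the number of extracted paths.
#' @return Object of class `tpt_result` with `q_plus`, `q_minus`,
#'   `gross_flux`, `net_flux`, `total_flux` (per lag time of the MSM),
#'   `pathways` (list of `states`, `flux`, `fraction`), `residual_flux`.
#' @export
tpt_flux <- function(msm, A, B, decompose = TRUE, residual_frac = 0.01,
                     max_paths = 1000L) {
  q <- committor(msm, A, B)
  qm <- attr(q, "q_minus")
  n <- nrow(msm$T)
  f <- outer(msm$pi * qm, q) * msm$T
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  total <- sum(f[A, setdiff(seq_len(n), A), drop = FALSE])
  pathways <- list()
  residual <- total
  if (decompose && total > 0) {
    w <- fnet
    repeat {
      p <- .widest_path(w, A, B)
      if (is.null(p) || length(pathways) >= max_paths) break
      bott <- min(w[cbind(p[-length(p)], p[-1])])
      if (bott <= 0) break
      w[cbind(p[-length(p)], p[-1])] <-
        w[cbind(p[-length(p)], p[-1])] - bott
      pathways[[length(pathways) + 1]] <-
        list(states = p, flux = bott, fraction = bott / total)
      residual <- residual - bott
      if (residual < residual_frac * total) break
    }
  }
  structure(list(q_plus = as.numeric(q), q_minus = qm, gross_flux = f,
                 net_flux = fnet, total_flux = total, A = A, B = B,
                 pathways = pathways, residual_flux = max(residual, 0)),
            class = "tpt_result")
}

# maximin (widest) path from any source to any sink; O(n^2) Dijkstra variant
.widest_path <- function(w, sources, sinks) {
  n <- nrow(w)
  width <- rep(-Inf, n)
  parent <- rep(NA_integer_, n)
  width[sources] <- Inf
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > 0)
    if (!length(cand)) return(NULL)
    u <- cand[which.max(width[cand])]
    if (u %in% sinks) break
    visited[u] <- TRUE
    nb <- which(w[u, ] > 0 & !visited)
    for (v in nb) {
      cw <- min(width[u], w[u, v])
      if (cw > width[v]) { width[v] <- cw; parent[v] <- u }
    }
  }
  path <- u
  while (!is.na(parent[u])) { u <- parent[u]; path <- c(u, path) }
  if (!(path[1] %in% sources)) return(NULL)
  path
}

#' Coarse-grain a reactive flux onto macrostates
#'
#' @param tpt a `tpt_result`.
#' @param crisp macrostate assignment per microstate.
#' @return Macrostate x macrostate net flux matrix (within-state flux
#'   zeroed).
#' @export
coarse_grain_flux <- function(tpt, crisp) {
  m <- max(crisp)
  agg <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
    agg[a, b] <- sum(tpt$gross_flux[crisp == a, crisp == b, drop = FALSE])
  pmax(agg - t(agg), 0)
}

#' Mean first passage time between state sets
#'
#' Solves `m_i = tau_lag + sum_j T_ij m_j` with `m = 0` on the target set;
#' the set-level MFPT averages the source-state values with
#' stationary weights restricted to the source set. Includes both direct
#' transitions and all routes through intermediate states.
#'
#' @param msm an `msm_model`.
#' @param from,to source and target microstate index sets (disjoint).
#' @return MFPT in ns (per the MSM's `dt_ns`), with attribute
#'   `per_state` holding the per-microstate values.
#' @export
mfpt <- function(msm, from, to) {
  stopifnot(inherits(msm, "msm_model"))
  n <- nrow(msm$T)
  from <- unique(as.integer(from)); to <- unique(as.integer(to))
  if (length(intersect(from, to))) stop("from and to must be disjoint")
  rest <- setdiff(seq_len(n), to)
  reach <- .reachable(msm$T, to)
  if (!all(rest %in% reach))
    stop("target set unreachable from some states")
  lhs <- diag(length(rest)) - msm$T[rest, rest, drop = FALSE]
  m <- numeric(n)
  m[rest] <- solve(lhs, rep(msm$lag_ns, length(rest)))
  w <- msm$pi[from] / sum(msm$pi[from])
  out <- sum(w * m[from])
  attr(out, "per_state") <- m
  out
}

#' On/off rate constants from mean first passage times
#'
#' `k_on = 1 / (MFPT_on * C)` and `k_off = 1 / MFPT_off`, with `C` the
#' ligand concentration; the residence time is `1 / k_off = MFPT_off`.
#'
#' @param mfpt_on_s binding MFPT in seconds.
#' @param mfpt_off_s unbinding MFPT in seconds.
#' @param C ligand concentration (mol/L).
#' @return List with `k_on` (1/(M s)), `k_off` (1/s), `residence_s`.
#' @export
rate_constants <- function(mfpt_on_s, mfpt_off_s, C) {
  if (C <= 0) stop("ligand concentration must be positive")
  stopifnot(mfpt_on_s > 0, mfpt_off_s > 0)
  list(k_on = 1 / (mfpt_on_s * C), k_off = 1 / mfpt_off_s,
       residence_s = mfpt_off_s)
}

#' Binding free energy from stationary populations
#'
#' `dG = -RT ln(pi_bound / pi_unbound)` with R = 1.9872e-3 kcal/(mol K)
#' (natural logarithm). The standard-state value corrects to a 1 M
#' reference concentration:
#' `dG0 = -RT [ ln(pi_bound/pi_unbound) + ln(C0/C) ]`, where `C` is the
#' effective ligand concentration of the simulation volume.
#'
#' @param pi_bound,pi_unbound stationary populations in (0, 1).
#' @param temperature absolute temperature (K).
#' @param C effective ligand concentration (M); default 1 (no correction).
#' @param C0 standard-state concentration (M), default 1.
#' @return List with `dG` and `dG0` in kcal/mol.
#' @export
binding_free_energy <- function(pi_bound, pi_unbound, temperature,
                                C = 1, C0 = 1) {
  if (pi_bound <= 0 || pi_bound >= 1 || pi_unbound <= 0 || pi_unbound >= 1)
    stop("populations must lie strictly in (0, 1)")
  stopifnot(temperature > 0, C > 0, C0 > 0)
  rt <- .R_KCAL * temperature
  dg <- -rt * log(pi_bound / pi_unbound)
  dg0 <- -rt * (log(pi_bound / pi_unbound) + log(C0 / C))
  list(dG = dg, dG0 = dg0)
}

#' Assemble a kinetics/thermodynamics rate report
#'
#' Converts MFPTs (ns) into on/off rate constants, residence time and
#' binding free energies, carrying the concentration and temperature used.
#'
#' @param mfpt_on_ns,mfpt_off_ns binding/unbinding MFPT in ns.
#' @param pi_bound,pi_unbound bound/unbound stationary populations.
#' @param C ligand concentration (M).
#' @param temperature temperature (K).
#' @param C0 standard-state concentration (M).
#' @return Object of class `rate_report`.
#' @export
rate_report <- function(mfpt_on_ns, mfpt_off_ns, pi_bound, pi_unbound,
                        C, temperature, C0 = 1) {
  rates <- rate_constants(mfpt_on_ns * 1e-9, mfpt_off_ns * 1e-9, C)
  fe <- binding_free_energy(pi_bound, pi_unbound, temperature, C, C0)
  structure(c(list(mfpt_on_s = mfpt_on_ns * 1e-9,
                   mfpt_off_s = mfpt_off_ns * 1e-9,
                   concentration_M = C, temperature_K = temperature),
              rates, fe),
            class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat("Binding kinetics report\n")
  cat(sprintf("  MFPT(on)  = %.4g s   MFPT(off) = %.4g s\n",
              x$mfpt_on_s, x$mfpt_off_s))
  cat(sprintf("  k_on  = %.3g /M/s   k_off = %.3g /s   residence = %.4g s\n",
              x$k_on, x$k_off, x$residence_s))
  cat(sprintf("  dG = %.3f kcal/mol   dG0 = %.3f kcal/mol (C = %.3g M, T = %.2f K)\n",
              x$dG, x$dG0, x$concentration_M, x$temperature_K))
  invisible(x)
}

#' Trajectory bootstrap of a set-level MFPT
#'
#' Resamples whole trajectories with replacement, re-estimates the MSM and
#' recomputes the MFPT, giving a simple spread estimate. This is a
#' convenience utility; it makes no claim of matching any particular
#' published uncertainty estimator.
#'
#' @param dtrajs list of discrete trajectories.
#' @param lag_frames MSM lag in frames.
#' @param from,to microstate index sets (in the full state numbering).
#' @param n_boot bootstrap replicates (default 20).
#' @param dt_ns frame time (ns).
#' @param seed RNG seed.
#' @return Numeric vector of bootstrap MFPT values (ns); failed
#'   replicates (e.g. disconnected resamples) are NA.
#' @export
bootstrap_mfpt <- function(dtrajs, lag_frames, from, to, n_boot = 20,
                           dt_ns = 1, seed = 1L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    res <- dtrajs[sample.int(length(dtrajs), replace = TRUE)]
    tryCatch({
      m <- estimate_reversible(suppressWarnings(
        count_transitions(res, lag_frames)), dt_ns = dt_ns)
      fr <- match(from, m$active); tt <- match(to, m$active)
      if (anyNA(fr) || anyNA(tt)) return(NA_real_)
      as.numeric(mfpt(m, fr, tt))
    }, error = function(e) NA_real_)
  }, numeric(1))
}
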