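#' PCCA+ coarse-graining into metastable macrostates
#'
#' Robust Perron cluster analysis on the top right eigenvectors of a
#' reversible microstate MSM (pi-orthonormalized). The inner-simplex
#' variant is used: the rows of the eigenvector matrix that span the
#' largest simplex are located by orthogonal index search, and the linear
#' transform mapping those vertex rows to the unit simplex corners yields
#' fuzzy memberships. Small negative memberships from the linear transform
#' are clipped and rows renormalized; crisp assignment is by row argmax.
#'
#' @param msm an `msm_model` from [estimate_reversible()].
#' @param n_macro number of macrostates (2 <= n_macro <= n_micro).
#' @param degeneracy_tol minimum spectral gap between the `n_macro`-th and
#'   next eigenvalue; a smaller gap raises an error suggesting a different
#'   `n_macro`.
#' @return Object of class `macro_model` with `memberships` (chi,
#'   microstates x macrostates), `crisp` (argmax macrostate per
#'   microstate), `populations` (summed stationary weights),
#'   `n_macro`, `eigenvalues` (the ones used).
#' @export
pcca_plus <- function(msm, n_macro, degeneracy_tol = 1e-10) {
  stopifnot(inherits(msm, "msm_model"))
  n <- nrow(msm$T)
  m <- as.integer(n_macro)
  if (m < 2 || m > n) stop("need 2 <= n_macro <= n_micro")
  es <- .reversible_spectrum(msm$T, msm$pi, vectors = TRUE)
  if (m < n && abs(es$values[m] - es$values[m + 1]) < degeneracy_tol)
    stop(sprintf(paste0("eigenvalues %d and %d are degenerate (gap < %g); ",
                        "choose a different n_macro"), m, m + 1,
                 degeneracy_tol))
  x <- es$vectors[, seq_len(m), drop = FALSE]
  x[, 1] <- 1  # Perron eigenvector is constant; enforce exactly
  vert <- .simplex_vertices(x)
  a <- solve(x[vert, , drop = FALSE])
  chi <- x %*% a
  chi <- pmin(pmax(chi, 0), 1)
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  if (length(unique(crisp)) < m)
    stop("a macrostate received no crisp members; reduce n_macro")
  pops <- as.numeric(tapply(msm$pi, factor(crisp, levels = seq_len(m)), sum))
  structure(list(memberships = chi, crisp = crisp, populations = pops,
                 n_macro = m, eigenvalues = es$values[seq_len(m)],
                 pi = msm$pi),
            class = "macro_model")
}

# orthogonal index search for the rows spanning the largest simplex
.simplex_vertices <- function(x) {
  m <- ncol(x)
  n <- nrow(x)
  idx <- integer(m)
  ortho <- x
  norms <- rowSums(ortho^2)
  idx[1] <- which.max(norms)
  ortho <- sweep(ortho, 2, ortho[idx[1], ])
  for (j in seq_len(m - 1) + 1) {
    norms <- sqrt(rowSums(ortho^2))
    idx[j] <- which.max(norms)
    if (norms[idx[j]] < 1e-12)
      stop("degenerate eigenvector rows: cannot span the requested simplex")
    u <- ortho[idx[j], ] / norms[idx[j]]
    ortho <- ortho - outer(as.numeric(ortho %*% u), u)
  }
  idx
}

#' Choose the number of macrostates from timescale separation
#'
#' Gap heuristic: with implied timescales sorted from slow to fast, the
#' number of metastable states is one more than the position of the
#' largest ratio `t_i / t_{i+1}` among the slowest processes.
#'
#' @param its numeric vector of implied timescales (slowest first), or an
#'   `its_profile` (the largest available lag is used).
#' @param max_processes how many leading ratios to consider (default 6).
#' @return Integer `n_macro`, with attribute `gap_ratios`.
#' @export
choose_n_macro <- function(its, max_processes = 6) {
  if (inherits(its, "its_profile")) {
    last <- max(its$lag_ns)
    ts <- its$its_ns[its$lag_ns == last][order(its$process[its$lag_ns == last])]
  } else {
    ts <- as.numeric(its)
  }
  ts <- ts[is.finite(ts) & ts > 0]
  if (length(ts) < 2) stop("need at least two finite implied timescales")
  ts <- sort(ts, decreasing = TRUE)
  k <- min(max_processes, length(ts) - 1)
  ratios <- ts[seq_len(k)] / ts[seq_len(k) + 1]
  n_macro <- 1L + which.max(ratios)
  attr(n_macro, "gap_ratios") <- ratios
  n_macro
}

#' Assign semantic labels (U, I, B) to macrostates
#'
#' The bound macrostate is the one whose (stationary-weighted) members
#' score highest on a bound-likeness score (e.g. total pocket contacts, or
#' negative pocket distance); the unbound macrostate scores lowest; the
#' remaining states are intermediates `I1, I2, ...` ordered by decreasing
#' population.
#'
#' @param macro a `macro_model`.
#' @param bound_score numeric score per microstate (higher = more bound).
#' @return Character vector of labels, one per macrostate, plus attribute
#'   `micro_labels` giving the label of each microstate.
#' @export
label_macrostates <- function(macro, bound_score) {
  stopifnot(inherits(macro, "macro_model"),
            length(bound_score) == length(macro$crisp))
  m <- macro$n_macro
  sc <- vapply(seq_len(m), function(j) {
    w <- macro$pi[macro$crisp == j]
    sum(w * bound_score[macro$crisp == j]) / sum(w)
  }, numeric(1))
  labels <- rep(NA_character_, m)
  labels[which.max(sc)] <- "B"
  labels[which.min(sc)] <- "U"
  inter <- which(is.na(labels))
  inter <- inter[order(macro$populations[inter], decreasing = TRUE)]
  labels[inter] <- if (length(inter) == 1) "I" else
    paste0("I", seq_along(inter))
  attr(labels, "micro_labels") <- labels[macro$crisp]
  labels
}

#' Macrostate report (label, stationary population, committor)
#'
#' @param macro a `macro_model`.
#' @param labels optional semantic labels from [label_macrostates()].
#' @param committor optional per-macrostate committor values.
#' @return data.frame mirroring a macrostate characteristics table.
#' @export
macrostate_report <- function(macro, labels = NULL, committor = NULL) {
  out <- data.frame(macrostate = labels %||% paste0("M", seq_len(macro$n_macro)),
                    population_pct = 100 * macro$populations)
  if (!is.null(committor)) out$committor <- committor
  out[order(-out$population_pct), ]
}

#' @export
print.macro_model <- function(x, ...) {
  cat(sprintf("PCCA+ macro model: %d macrostates\n", x$n_macro))
  print(round(x$populations, 4))
  invisible(x)
}
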