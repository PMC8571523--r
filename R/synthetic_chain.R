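#' Specification of a discrete chain with planted metastable blocks
#'
#' Describes a reversible Markov chain whose microstates are grouped into
#' metastable blocks (e.g. unbound `U`, intermediates `I1`/`I2`, bound `B`)
#' with prescribed stationary block populations. Within-block hops are
#' frequent, between-block hops rare, so the chain has a controlled
#' timescale separation and serves as exact ground truth for estimator
#' recovery tests.
#'
#' @param n_micro integer, number of microstates.
#' @param blocks character or factor of length `n_micro` assigning each
#'   microstate to a block label.
#' @param target_populations named numeric, stationary probability of each
#'   block; must sum to 1 and carry one name per block label.
#' @param intra_rate per-step hop probability between two microstates of
#'   the same block (before the Metropolis acceptance factor).
#' @param inter_rate per-step hop probability scale between microstates of
#'   different blocks; must be positive and smaller than `intra_rate`.
#' @param seed integer seed recorded with the spec and used by samplers
#'   that are not given their own seed.
#' @return An object of class `planted_chain_spec`.
#' @seealso [build_reversible_chain()], [sample_chain()]
#' @export
planted_chain_spec <- function(n_micro, blocks, target_populations,
                               intra_rate, inter_rate, seed = 1L) {
  blocks <- as.character(blocks)
  stopifnot(length(blocks) == n_micro)
  labs <- unique(blocks)
  if (!all(labs %in% names(target_populations)))
    stop("target_populations must be named with every block label")
  target_populations <- target_populations[labs]
  if (abs(sum(target_populations) - 1) > 1e-12)
    stop("target_populations must sum to 1 (tolerance 1e-12)")
  if (any(target_populations <= 0)) stop("block populations must be positive")
  if (!(intra_rate > inter_rate && inter_rate > 0))
    stop("rates must satisfy intra_rate > inter_rate > 0")
  if (any(table(blocks) == 0)) stop("every block must be non-empty")
  structure(list(n_micro = as.integer(n_micro), blocks = blocks,
                 target_populations = target_populations,
                 intra_rate = intra_rate, inter_rate = inter_rate,
                 seed = as.integer(seed)),
            class = "planted_chain_spec")
}

#' Build a reversible transition matrix with planted block structure
#'
#' Constructs a row-stochastic transition matrix by Metropolis acceptance,
#' `T_ij = q_ij * min(1, pi_j / pi_i)`, on a block-connectivity graph with
#' symmetric proposal rates (`intra_rate` within blocks, `inter_rate`
#' between connected blocks). Detailed balance against the target
#' stationary distribution holds by construction; within each block the
#' stationary weight is spread uniformly over member microstates.
#'
#' @param spec a [planted_chain_spec()].
#' @param connectivity optional symmetric logical/numeric matrix (blocks x
#'   blocks, dimnames = block labels) scaling between-block proposal rates;
#'   defaults to all block pairs connected with weight 1. Entries of 0
#'   forbid direct exchange between two blocks.
#' @return A list of class `planted_chain` with elements `T` (transition
#'   matrix), `pi` (exact stationary distribution), `blocks`, and `spec`.
#' @export
build_reversible_chain <- function(spec, connectivity = NULL) {
  stopifnot(inherits(spec, "planted_chain_spec"))
  n <- spec$n_micro
  labs <- names(spec$target_populations)
  nb <- length(labs)
  if (is.null(connectivity)) {
    connectivity <- matrix(1, nb, nb, dimnames = list(labs, labs))
  } else {
    stopifnot(all(labs %in% rownames(connectivity)),
              all(labs %in% colnames(connectivity)))
    connectivity <- connectivity[labs, labs]
    if (any(connectivity != t(connectivity)))
      stop("connectivity must be symmetric")
  }
  bsize <- table(spec$blocks)[labs]
  pi <- spec$target_populations[spec$blocks] / as.numeric(bsize[spec$blocks])
  pi <- as.numeric(pi)

  bi <- match(spec$blocks, labs)
  q <- matrix(0, n, n)
  same <- outer(bi, bi, "==")
  q[same] <- spec$intra_rate
  q[!same] <- spec$inter_rate * connectivity[cbind(bi[row(q)[!same]],
                                                   bi[col(q)[!same]])]
  diag(q) <- 0
  accept <- pmin(1, outer(pi, pi, function(a, b) b / a))
  tm <- q * accept
  rs <- rowSums(tm)
  if (any(rs > 1))
    stop(sprintf(paste0("infeasible rates: row sum %.3f > 1 at microstate %d; ",
                        "reduce intra_rate or inter_rate"),
                 max(rs), which.max(rs)))
  diag(tm) <- 1 - rs
  structure(list(T = tm, pi = pi, blocks = spec$blocks, spec = spec),
            class = "planted_chain")
}

#' Sample a discrete trajectory from a Markov chain
#'
#' Draws a realization of the chain using inverse-CDF sampling in compiled
#' code. Bitwise reproducible for a fixed seed.
#'
#' @param T row-stochastic transition matrix (or a `planted_chain`).
#' @param n_steps trajectory length in steps (including the start state).
#' @param seed integer seed; `NULL` continues from the current RNG state.
#' @param start starting state (1-based). Default 1.
#' @return Integer vector of 1-based state labels, length `n_steps`.
#' @export
sample_chain <- function(T, n_steps, seed = NULL, start = 1L) {
  if (inherits(T, "planted_chain")) T <- T$T
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  if (max(abs(rowSums(T) - 1)) > 1e-8) stop("T must be row-stochastic")
  if (start < 1 || start > nrow(T)) stop("start out of range")
  if (!is.null(seed)) set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  cum[, ncol(cum)] <- 1  # guard against rounding
  cpp_sample_chain(cum, as.integer(n_steps), as.integer(start))
}

#' Sample first-passage times into a target set
#'
#' Monte Carlo first-passage sampling used as a stochastic oracle for the
#' mean-first-passage-time linear solve.
#'
#' @inheritParams sample_chain
#' @param target integer vector of 1-based target states.
#' @param n_rep number of independent passages to sample.
#' @param max_steps censoring horizon; passages longer than this are `NA`.
#' @return Numeric vector of first-passage times in steps.
#' @export
sample_first_passage <- function(T, start, target, n_rep, seed = NULL,
                                 max_steps = 1e7) {
  if (inherits(T, "planted_chain")) T <- T$T
  if (!is.null(seed)) set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  cum[, ncol(cum)] <- 1
  mask <- rep(FALSE, nrow(T))
  mask[target] <- TRUE
  if (mask[start]) stop("start must lie outside the target set")
  cpp_first_passage(cum, as.integer(start), mask, as.integer(n_rep),
                    max_steps)
}

#' Aggregate a stationary distribution over planted blocks
#'
#' @param chain a `planted_chain`.
#' @return Named numeric of block stationary populations.
#' @export
block_populations <- function(chain) {
  stopifnot(inherits(chain, "planted_chain"))
  p <- tapply(chain$pi, chain$blocks, sum)
  p[names(chain$spec$target_populations)]
}

#' @export
print.planted_chain <- function(x, ...) {
  cat(sprintf("Planted reversible chain: %d microstates, %d blocks\n",
              length(x$pi), length(unique(x$blocks))))
  print(round(block_populations(x), 4))
  invisible(x)
}
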