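#' Collective variable definitions for the metadynamics engine
#'
#' Three CV types are available on toy landscapes:
#' * `cv_position(dim)` — a bare coordinate (useful for 1-D landscapes);
#' * `cv_distance(ref)` — Euclidean distance to a reference point, the
#'   toy analogue of a pocket-ligand distance;
#' * `cv_contacts(sites, r0)` — smooth contact count
#'   `sum_i 1/(1 + (r_i/r0)^6)` over interaction sites, a differentiable
#'   stand-in for a discrete contact/hydrogen-bond count.
#'
#' @param dim coordinate index (1-based).
#' @return A `metad_cv` object.
#' @rdname metad_cv
#' @export
cv_position <- function(dim = 1L) {
  structure(list(type = 0L, dim = as.integer(dim)), class = "metad_cv")
}

#' @param ref reference point (nm).
#' @rdname metad_cv
#' @export
cv_distance <- function(ref) {
  structure(list(type = 1L, ref = as.numeric(ref)), class = "metad_cv")
}

#' @param sites matrix of interaction-site coordinates (sites x d, nm).
#' @param r0 switching distance (nm).
#' @rdname metad_cv
#' @export
cv_contacts <- function(sites, r0 = 0.5) {
  if (!is.matrix(sites)) sites <- matrix(sites, nrow = 1)
  structure(list(type = 2L, sites = sites, r0 = r0), class = "metad_cv")
}

#' Evaluate a collective variable and its gradient (reference path)
#'
#' R-level evaluation used for testing the compiled propagator's CV
#' handling (e.g. against finite differences).
#'
#' @param cv a `metad_cv`.
#' @param x position vector.
#' @return List with `value` and `gradient`.
#' @export
cv_eval <- function(cv, x) {
  x <- as.numeric(x)
  if (cv$type == 0L) {
    g <- numeric(length(x)); g[cv$dim] <- 1
    return(list(value = x[cv$dim], gradient = g))
  }
  if (cv$type == 1L) {
    dx <- x - cv$ref
    r <- sqrt(sum(dx^2))
    g <- if (r < 1e-12) numeric(length(x)) else dx / r
    return(list(value = r, gradient = g))
  }
  val <- 0; g <- numeric(length(x))
  for (i in seq_len(nrow(cv$sites))) {
    dx <- x - cv$sites[i, ]
    r <- sqrt(sum(dx^2))
    u <- r / cv$r0
    val <- val + 1 / (1 + u^6)
    if (r > 1e-12)  # df/dx = (df/dr) dx/r with df/dr = -6 u^6 / (r (1+u^6)^2)
      g <- g + (-6 * u^6 / (r^2 * (1 + u^6)^2)) * dx
  }
  list(value = val, gradient = g)
}

#' Well-tempered metadynamics bias protocol
#'
#' Gaussian hills are deposited along one or two CVs every `stride` steps
#' with effective height `h * exp(-V(s)/(kB dT))`, where
#' `dT = (bias_factor - 1) * temperature`, so that revisited regions
#' receive progressively smaller hills. The accumulated bias and its CV
#' gradient are kept on a fixed grid (Gaussian tails truncated at 6
#' widths) and interpolated during propagation.
#'
#' @param cvs list of 1 or 2 [`metad_cv`] objects.
#' @param height initial Gaussian hill height (kJ/mol, default 1.2).
#' @param widths Gaussian width per CV (default `c(0.00981, 0.227)`:
#'   distance in nm, contact count dimensionless).
#' @param stride deposition interval in steps (default 500).
#' @param bias_factor well-tempering factor `gamma_b > 1` (default 6).
#' @param temperature simulation temperature (K, default 300).
#' @param grid_min,grid_max,grid_n bias grid range and size per CV.
#' @return Object of class `metad_bias`.
#' @export
metad_bias <- function(cvs, height = 1.2, widths = c(0.00981, 0.227),
                       stride = 500L, bias_factor = 6, temperature = 300,
                       grid_min, grid_max, grid_n = 400L) {
  if (inherits(cvs, "metad_cv")) cvs <- list(cvs)
  ncv <- length(cvs)
  stopifnot(ncv %in% c(1L, 2L),
            all(vapply(cvs, inherits, logical(1), "metad_cv")))
  if (bias_factor <= 1) stop("bias_factor must exceed 1")
  if (stride < 1) stop("deposition stride must be >= 1")
  widths <- rep_len(widths, ncv)
  grid_n <- rep_len(as.integer(grid_n), ncv)
  stopifnot(length(grid_min) == ncv, length(grid_max) == ncv,
            all(grid_max > grid_min), all(widths > 0), height > 0)
  structure(list(cvs = cvs, height = height, widths = widths,
                 stride = as.integer(stride), bias_factor = bias_factor,
                 temperature = temperature,
                 delta_T = (bias_factor - 1) * temperature,
                 grid_min = grid_min, grid_max = grid_max, grid_n = grid_n),
            class = "metad_bias")
}

#' Run well-tempered metadynamics on a toy landscape
#'
#' Overdamped Langevin dynamics under the landscape potential plus the
#' history-dependent bias. Reproducible for a fixed seed (taken from
#' `params`).
#'
#' @param landscape a [toy_landscape()].
#' @param params a [langevin_params()].
#' @param bias a [metad_bias()].
#' @param x0 start position; defaults to the bound (deepest) basin center.
#' @param thin keep every `thin`-th frame.
#' @return Object of class `wtmetad_run` with `positions`, `cv` (frames x
#'   ncv), `hills` (deposition ledger: time ps, centers, widths,
#'   effective height, bias factor), `bias_grid`, plus the inputs.
#' @export
run_wtmetad <- function(landscape, params, bias, x0 = NULL, thin = 1L) {
  stopifnot(inherits(landscape, "toy_landscape"),
            inherits(params, "langevin_params"),
            inherits(bias, "metad_bias"))
  if (is.null(x0))
    x0 <- landscape$centers[landscape$bound_basin, ]
  cv_list <- lapply(bias$cvs, unclass)
  set.seed(params$seed)
  res <- cpp_wtmetad(landscape$centers, landscape$depths, landscape$widths,
                     if (landscape$shape == "gaussian") 0L else 1L,
                     landscape$half_box, params$dt, params$kT, params$gamma,
                     params$n_steps, as.numeric(x0), as.integer(thin),
                     cv_list, bias$height, bias$widths, bias$stride,
                     bias$bias_factor, bias$temperature,
                     as.numeric(bias$grid_min), as.numeric(bias$grid_max),
                     as.integer(bias$grid_n))
  hills <- as.data.frame(res$hills)
  structure(list(positions = res$positions, cv = res$cv, hills = hills,
                 bias_grid = res$bias_grid, bias = bias, params = params,
                 landscape = landscape, dt_ps = params$dt,
                 thin = as.integer(thin), seed = params$seed),
            class = "wtmetad_run")
}

#' Reconstruct the free energy surface from deposited hills
#'
#' Under well-tempered metadynamics the asymptotic bias satisfies
#' `V(s, t -> inf) = -dT/(T + dT) F(s) + const`, so the free energy is
#' recovered as `F(s) = -(T + dT)/dT * V(s)`, shifted so `min F = 0`.
#' The bias is summed over the hill ledger on the requested grid with
#' Gaussian tails truncated at 6 widths. The additive constant in the
#' deposited bias is irrelevant: any `bias_offset` leaves the shifted
#' surface unchanged.
#'
#' @param run a `wtmetad_run`, or a hills data.frame (then `temperature`
#'   and `bias_factor` must be supplied).
#' @param grid1,grid2 evaluation grids per CV; default to the bias grid.
#' @param bias_offset constant added to the deposited bias before the
#'   transform (exposed to make the invariance testable).
#' @param temperature,bias_factor needed when `run` is a bare hills table.
#' @param n_average number of late-stage checkpoints to average. With the
#'   default 1 the surface is read from the final bias only; larger values
#'   average the (min-shifted) estimates at `n_average` hill counts evenly
#'   spaced over the second half of the deposition history, damping the
#'   residual fluctuations of the instantaneous well-tempered estimate.
#' @return For one CV, a data.frame `s`, `F_kJmol`; for two CVs a list
#'   with `grid1`, `grid2` and matrix `F_kJmol`.
#' @export
reconstruct_free_energy <- function(run, grid1 = NULL, grid2 = NULL,
                                    bias_offset = 0,
                                    temperature = NULL, bias_factor = NULL,
                                    n_average = 1L) {
  if (inherits(run, "wtmetad_run")) {
    hills <- run$hills
    temperature <- run$bias$temperature
    bias_factor <- run$bias$bias_factor
    if (is.null(grid1))
      grid1 <- seq(run$bias$grid_min[1], run$bias$grid_max[1],
                   length.out = run$bias$grid_n[1])
    if (is.null(grid2) && length(run$bias$cvs) == 2)
      grid2 <- seq(run$bias$grid_min[2], run$bias$grid_max[2],
                   length.out = run$bias$grid_n[2])
  } else {
    hills <- run
    if (is.null(temperature) || is.null(bias_factor))
      stop("temperature and bias_factor are required with a bare hills table")
  }
  if (nrow(hills) < 1) stop("need at least one deposited hill")
  dT <- (bias_factor - 1) * temperature
  fac <- -(temperature + dT) / dT
  two_d <- !is.null(grid2) && !all(is.na(hills$center2))
  nh <- nrow(hills)
  n_average <- max(1L, as.integer(n_average))
  checkpoints <- if (n_average == 1) nh else
    unique(round(seq(ceiling(nh / 2), nh, length.out = n_average)))

  v <- if (two_d) matrix(bias_offset, length(grid1), length(grid2))
  else rep(bias_offset, length(grid1))
  fsum <- 0 * v
  done <- 0L
  for (cp in checkpoints) {
    for (i in seq(done + 1, cp)) {
      d1 <- grid1 - hills$center1[i]
      s1 <- abs(d1) <= 6 * hills$width1[i]
      if (!any(s1)) next
      g1 <- exp(-d1[s1]^2 / (2 * hills$width1[i]^2))
      if (!two_d) {
        v[s1] <- v[s1] + hills$height[i] * g1
      } else {
        d2 <- grid2 - hills$center2[i]
        s2 <- abs(d2) <= 6 * hills$width2[i]
        if (!any(s2)) next
        g2 <- exp(-d2[s2]^2 / (2 * hills$width2[i]^2))
        v[s1, s2] <- v[s1, s2] + hills$height[i] * outer(g1, g2)
      }
    }
    done <- cp
    f <- fac * v
    fsum <- fsum + (f - min(f))
  }
  f <- fsum / length(checkpoints)
  f <- f - min(f)
  if (!two_d) return(data.frame(s = grid1, F_kJmol = f))
  list(grid1 = grid1, grid2 = grid2, F_kJmol = f)
}

#' First ligand-egress time from a biased trajectory
#'
#' Scans a (distance-like) CV series for the first time it exceeds the
#' unbound threshold and stays beyond it continuously for a dwell window,
#' guarding against transient recrossings. If the CV never satisfies the
#' criterion within the trajectory, the event is reported as censored.
#'
#' @param cv numeric CV series (e.g. `run$cv[, 1]`), or a `wtmetad_run`
#'   (first CV used).
#' @param dt time per sample (ps for a `wtmetad_run`'s thinned series).
#' @param threshold unbound threshold on the CV.
#' @param dwell dwell window (same time unit as `dt`); default
#'   10 x 500 steps x dt for a run, else `100 * dt`.
#' @return List with `time` (first-exit time, `NA` when censored),
#'   `step` (sample index), `censored` (logical).
#' @export
egress_time <- function(cv, dt = NULL, threshold, dwell = NULL) {
  if (inherits(cv, "wtmetad_run")) {
    run <- cv
    dt <- dt %||% (run$dt_ps * run$thin)
    dwell <- dwell %||% (10 * run$bias$stride * run$dt_ps)
    cv <- run$cv[, 1]
  }
  stopifnot(!is.null(dt), dt > 0)
  dwell <- dwell %||% (100 * dt)
  out <- cv > threshold
  if (out[1]) warning("trajectory does not start inside the bound region")
  need <- max(1L, ceiling(dwell / dt))
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    return(list(time = NA_real_, step = NA_integer_, censored = TRUE))
  s <- starts[hit[1]]
  list(time = (s - 1) * dt, step = s, censored = FALSE)
}
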