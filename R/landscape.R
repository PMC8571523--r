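#' Toy ligand-binding energy landscape
#'
#' A low-dimensional stand-in for a protein-ligand binding landscape: a sum
#' of radial attractive basins (the deepest one playing the role of the
#' binding site, shallower ones of transient encounter intermediates)
#' inside a reflecting box representing the unbound bulk.
#'
#' @param centers numeric matrix (basins x dimensions, nm) of basin
#'   positions; a vector is treated as a single-basin landscape.
#' @param depths basin depths in kJ/mol (positive = attractive).
#' @param widths basin widths in nm.
#' @param half_box half-width of the reflecting box (nm).
#' @param shape `"gaussian"` for Gaussian wells
#'   `U = -sum_k D_k exp(-r_k^2 / 2 w_k^2)`, or `"harmonic"` for
#'   `U = sum_k (D_k / 2 w_k^2) r_k^2` (spring constant `D_k/w_k^2`).
#' @return Object of class `toy_landscape`; the deepest basin is recorded
#'   as the designated bound site (`$bound_basin`).
#' @export
toy_landscape <- function(centers, depths, widths, half_box,
                          shape = c("gaussian", "harmonic")) {
  shape <- match.arg(shape)
  if (!is.matrix(centers)) centers <- matrix(centers, nrow = 1)
  stopifnot(nrow(centers) == length(depths), length(depths) == length(widths))
  if (any(depths < 0)) stop("basin depths must be >= 0")
  if (any(widths <= 0)) stop("basin widths must be > 0")
  if (half_box <= 0) stop("half_box must be > 0")
  if (any(abs(centers) > half_box)) stop("basin centers must lie in the box")
  structure(list(centers = centers, depths = depths, widths = widths,
                 half_box = half_box, shape = shape,
                 dim = ncol(centers), bound_basin = which.max(depths)),
            class = "toy_landscape")
}

#' Langevin integration parameters
#'
#' @param dt time step (ps).
#' @param kT thermal energy (kJ/mol); 300 K corresponds to 2.494 kJ/mol.
#' @param gamma friction coefficient (amu/ps).
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(dt, kT, gamma, n_steps, seed = 1L) {
  stopifnot(dt > 0, kT > 0, gamma > 0, n_steps >= 1)
  structure(list(dt = dt, kT = kT, gamma = gamma,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "langevin_params")
}

#' Potential energy of a toy landscape
#'
#' Reference (R-level) evaluation used for testing and Boltzmann-weight
#' oracles; the propagators use an equivalent compiled kernel.
#'
#' @param landscape a [toy_landscape()].
#' @param x numeric matrix of positions (rows) or a single position vector.
#' @return Numeric vector of potential energies (kJ/mol).
#' @export
landscape_potential <- function(landscape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  u <- numeric(nrow(x))
  for (k in seq_along(landscape$depths)) {
    r2 <- rowSums(sweep(x, 2, landscape$centers[k, ])^2)
    w2 <- landscape$widths[k]^2
    u <- u + if (landscape$shape == "gaussian")
      -landscape$depths[k] * exp(-r2 / (2 * w2))
    else 0.5 * (landscape$depths[k] / w2) * r2
  }
  u
}

#' Gradient of a toy landscape potential
#'
#' @inheritParams landscape_potential
#' @return Matrix of gradients (same shape as `x`, kJ/mol/nm).
#' @export
landscape_gradient <- function(landscape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  g <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(landscape$depths)) {
    dx <- sweep(x, 2, landscape$centers[k, ])
    w2 <- landscape$widths[k]^2
    if (landscape$shape == "gaussian") {
      pref <- landscape$depths[k] * exp(-rowSums(dx^2) / (2 * w2)) / w2
      g <- g + dx * pref
    } else {
      g <- g + dx * (landscape$depths[k] / w2)
    }
  }
  g
}

#' Fixed pseudo-residue coordinates ringing each basin
#'
#' Places single-atom "residues" on a ring (2-D) or at symmetric points
#' (1-D/3-D) around every basin center so that binary contact featurization
#' can distinguish which basin the ligand occupies.
#'
#' @param landscape a [toy_landscape()].
#' @param n_per_basin residues per basin (default 6).
#' @param ring_radius distance from basin center to each residue (nm);
#'   default 0.35 nm so a ligand at the basin bottom is within the standard
#'   0.5 nm contact cutoff of that basin's residues only.
#' @return Named list of 1 x d coordinate matrices, one per pseudo-residue,
#'   with an attribute `basin` giving the parent basin index.
#' @export
pseudo_residues <- function(landscape, n_per_basin = 6, ring_radius = 0.35) {
  d <- landscape$dim
  out <- list()
  basin <- integer(0)
  for (k in seq_len(nrow(landscape$centers))) {
    ctr <- landscape$centers[k, ]
    if (d == 1) {
      offs <- matrix(ring_radius * c(-1, 1), ncol = 1)
    } else {
      ang <- 2 * pi * (seq_len(n_per_basin) - 1) / n_per_basin
      offs <- cbind(cos(ang), sin(ang)) * ring_radius
      if (d == 3) offs <- cbind(offs, 0)
    }
    for (i in seq_len(nrow(offs))) {
      out[[length(out) + 1]] <- matrix(ctr + offs[i, ], nrow = 1)
      basin <- c(basin, k)
    }
  }
  names(out) <- sprintf("res%02d", seq_along(out))
  attr(out, "basin") <- basin
  out
}

#' Overdamped Langevin simulation of ligand diffusion and binding
#'
#' Integrates `x <- x - (dt/gamma) grad U + sqrt(2 kT dt / gamma) xi` on a
#' toy landscape with reflecting box walls, and attaches fixed
#' pseudo-residue coordinates so the positional trajectory can be run
#' through contact featurization.
#'
#' @param landscape a [toy_landscape()].
#' @param params a [langevin_params()].
#' @param x0 starting position (defaults to the box center).
#' @param thin keep every `thin`-th frame (the initial frame is kept).
#' @param residues optional pre-built pseudo-residue list; defaults to
#'   [pseudo_residues()] of the landscape.
#' @return Object of class `binding_trajectory` with elements `positions`
#'   (frames x d, nm), `dt_ns` (time per saved frame), `residues`,
#'   `landscape`, `params`, `seed`.
#' @export
brownian_binding_sim <- function(landscape, params, x0 = NULL, thin = 1L,
                                 residues = NULL) {
  stopifnot(inherits(landscape, "toy_landscape"),
            inherits(params, "langevin_params"))
  noise_sd <- sqrt(2 * params$kT * params$dt / params$gamma)
  wmin <- min(landscape$widths)
  if (noise_sd > wmin)
    stop(sprintf(paste0("dt too large: per-step displacement %.3g nm exceeds ",
                        "the narrowest basin width %.3g nm"), noise_sd, wmin))
  if (is.null(x0)) x0 <- rep(0, landscape$dim)
  stopifnot(length(x0) == landscape$dim)
  set.seed(params$seed)
  pos <- cpp_langevin(landscape$centers, landscape$depths, landscape$widths,
                      if (landscape$shape == "gaussian") 0L else 1L,
                      landscape$half_box, params$dt, params$kT, params$gamma,
                      params$n_steps, as.numeric(x0), as.integer(thin))
  if (is.null(residues)) residues <- pseudo_residues(landscape)
  structure(list(positions = pos,
                 dt_ns = params$dt * thin / 1000,
                 residues = residues, landscape = landscape, params = params,
                 seed = params$seed, thin = as.integer(thin)),
            class = "binding_trajectory")
}

#' Boltzmann weights of landscape regions on a grid
#'
#' Numerically integrates `exp(-U/kT)` over a regular grid, as an
#' equilibrium oracle for the Langevin sampler. Regions are basin spheres
#' of given radius plus the remaining bulk.
#'
#' @param landscape a [toy_landscape()].
#' @param kT thermal energy (kJ/mol).
#' @param radius basin assignment radius (nm); grid points within `radius`
#'   of a basin center count toward that basin.
#' @param n_grid grid points per dimension.
#' @return Named numeric: equilibrium probability of each basin and of the
#'   bulk, plus attribute `per_volume` (probability density ratios).
#' @export
boltzmann_weights <- function(landscape, kT, radius, n_grid = 201) {
  d <- landscape$dim
  ax <- seq(-landscape$half_box, landscape$half_box, length.out = n_grid)
  grid <- as.matrix(do.call(expand.grid, rep(list(ax), d)))
  w <- exp(-landscape_potential(landscape, grid) / kT)
  nb <- nrow(landscape$centers)
  assign <- rep(0L, nrow(grid))
  for (k in seq_len(nb)) {
    r <- sqrt(rowSums(sweep(grid, 2, landscape$centers[k, ])^2))
    assign[assign == 0L & r < radius] <- k
  }
  tot <- sum(w)
  p <- vapply(0:nb, function(k) sum(w[assign == k]) / tot, numeric(1))
  vol <- vapply(0:nb, function(k) sum(assign == k), numeric(1))
  out <- p[c(2:(nb + 1), 1)]
  names(out) <- c(sprintf("basin%d", seq_len(nb)), "bulk")
  dens <- (p / vol)[c(2:(nb + 1), 1)]
  names(dens) <- names(out)
  attr(out, "per_volume") <- dens
  out
}
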