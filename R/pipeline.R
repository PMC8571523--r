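#' Pipeline configuration
#'
#' Collects and validates every stage parameter of the end-to-end MSM
#' pipeline on synthetic ligand-binding data: the toy landscape and
#' Langevin settings, contact featurization cutoff, tICA lag and
#' dimensionality, microstate count, MSM lag grid, macrostate override,
#' and the thermodynamic constants used in the rate report. The defaults
#' describe a "parent-ligand-like" system: a deep binding basin, two
#' shallow transient intermediates, and a large unbound bulk.
#'
#' @param landscape a [toy_landscape()]; default parent-like (see above).
#' @param n_traj number of independent Langevin trajectories.
#' @param n_steps integration steps per trajectory.
#' @param dt_ps,kT,gamma Langevin parameters ([langevin_params()]).
#' @param thin save every `thin`-th frame.
#' @param cutoff contact cutoff (nm).
#' @param tica_lag_frames,tica_components tICA settings.
#' @param k microstate count for k-means.
#' @param its_lags lag grid (frames) for the implied-timescale profile.
#' @param msm_lag_frames MSM estimation lag (frames).
#' @param n_macro macrostate count; `NULL` selects it by the timescale
#'   gap heuristic ([choose_n_macro()]).
#' @param concentration effective ligand concentration (M).
#' @param temperature temperature (K) for free energies.
#' @param seed master seed; per-trajectory seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = NULL,
                            n_traj = 8L, n_steps = 60000L,
                            dt_ps = 0.002, kT = 2.494, gamma = 1,
                            thin = 10L, cutoff = 0.5,
                            tica_lag_frames = 5L, tica_components = 5L,
                            k = 60L, its_lags = c(1L, 2L, 5L, 10L, 20L),
                            msm_lag_frames = 5L, n_macro = NULL,
                            concentration = 0.01, temperature = 300,
                            seed = 1L) {
  if (is.null(landscape))
    landscape <- toy_landscape(
      centers = rbind(c(1.5, 0), c(-1, 1.2), c(-1, -1.2)),
      depths = c(14, 6, 6), widths = c(0.3, 0.25, 0.25),
      half_box = 3, shape = "gaussian")
  stopifnot(inherits(landscape, "toy_landscape"),
            n_traj >= 1, n_steps > thin, cutoff > 0,
            tica_lag_frames >= 1, k >= 2, msm_lag_frames >= 1,
            concentration > 0, temperature > 0)
  if (!is.null(n_macro)) stopifnot(n_macro >= 2)
  structure(list(landscape = landscape, n_traj = as.integer(n_traj),
                 n_steps = as.integer(n_steps), dt_ps = dt_ps, kT = kT,
                 gamma = gamma, thin = as.integer(thin), cutoff = cutoff,
                 tica_lag_frames = as.integer(tica_lag_frames),
                 tica_components = as.integer(tica_components),
                 k = as.integer(k), its_lags = as.integer(its_lags),
                 msm_lag_frames = as.integer(msm_lag_frames),
                 n_macro = n_macro, concentration = concentration,
                 temperature = temperature, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips every scalar parameter plus the landscape definition.
#'
#' @param config a [pipeline_config()].
#' @param file YAML path.
#' @return `file` invisibly ([write_config()]); a `pipeline_config`
#'   ([read_config()]).
#' @export
write_config <- function(config, file) {
  l <- config$landscape
  out <- unclass(config)
  out$landscape <- list(centers = as.numeric(t(l$centers)),
                        dim = l$dim, depths = l$depths, widths = l$widths,
                        half_box = l$half_box, shape = l$shape)
  yaml::write_yaml(out, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  l <- raw$landscape
  landscape <- toy_landscape(
    centers = matrix(as.numeric(l$centers), ncol = l$dim, byrow = TRUE),
    depths = as.numeric(l$depths), widths = as.numeric(l$widths),
    half_box = l$half_box, shape = l$shape)
  raw$landscape <- NULL
  args <- c(list(landscape = landscape), raw)
  do.call(pipeline_config, args[names(args) %in% names(formals(pipeline_config))])
}

#' Run the full MSM ligand-binding pipeline on synthetic data
#'
#' Simulate -> featurize -> tICA -> k-means -> implied timescales ->
#' reversible MSM -> PCCA+ -> TPT/committors -> MFPT-derived rates and
#' binding free energy. Deterministic given the config seed. Macrostates
#' are labelled bound (B) / unbound (U) / intermediate (I*) from the
#' per-microstate mean distance to the binding basin.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress (default FALSE).
#' @return Object of class `msm_pipeline`: list with `config`, `tica`,
#'   `disc`, `its`, `msm`, `macro`, `labels`, `tpt`, `report`
#'   (macrostate table), `rates` (a `rate_report`).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("simulating %d trajectories", config$n_traj)
  sims <- stage("simulate", {
    lapply(seq_len(config$n_traj), function(i) {
      pars <- langevin_params(config$dt_ps, config$kT, config$gamma,
                              config$n_steps,
                              seed = config$seed * 1000L + i)
      brownian_binding_sim(config$landscape, pars, thin = config$thin)
    })
  })

  say("featurizing")
  feats <- stage("featurize", {
    spec <- contact_spec(cutoff = config$cutoff)
    lapply(sims, contact_features, spec = spec)
  })
  dt_ns <- feats[[1]]$dt_ns

  say("tICA")
  tica <- stage("tica", suppressWarnings(
    fit_tica(feats, lag = config$tica_lag_frames,
             n_components = config$tica_components)))
  proj <- tica_transform(tica, feats)

  say("clustering k = %d", config$k)
  disc <- stage("cluster",
                kmeans_fit(proj, k = config$k, seed = config$seed))
  dtrajs <- disc$labels
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)

  say("implied timescales")
  its <- stage("its", suppressWarnings(
    implied_timescales(dtrajs, config$its_lags, dt_ns = dt_ns)))

  say("MSM at lag %d frames", config$msm_lag_frames)
  msm <- stage("msm", suppressWarnings(estimate_reversible(
    count_transitions(dtrajs, config$msm_lag_frames), dt_ns = dt_ns)))

  n_macro <- config$n_macro %||% stage("choose_n_macro", {
    ts <- its$its_ns[its$lag_frames == config$msm_lag_frames]
    as.integer(choose_n_macro(ts))
  })
  say("PCCA+ with %d macrostates", n_macro)
  macro <- stage("pcca", pcca_plus(msm, n_macro))

  # bound-likeness: negative mean distance of member frames to the bound
  # basin center
  say("labelling macrostates")
  bound_ctr <- config$landscape$centers[config$landscape$bound_basin, ]
  allpos <- do.call(rbind, lapply(sims, function(s) s$positions))
  alllab <- unlist(dtrajs)
  dist_b <- sqrt(rowSums(sweep(allpos, 2, bound_ctr)^2))
  micro_dist <- tapply(dist_b, alllab, mean)
  score <- -as.numeric(micro_dist[as.character(msm$active)])
  score[is.na(score)] <- min(score, na.rm = TRUE)
  labels <- label_macrostates(macro, score)

  A <- which(macro$crisp == which(labels == "U"))
  B <- which(macro$crisp == which(labels == "B"))
  say("TPT and rates")
  tpt <- stage("tpt", tpt_flux(msm, A, B))
  qmac <- committor_macro(tpt$q_plus, msm$pi, macro$crisp)
  mf_on <- stage("mfpt", as.numeric(mfpt(msm, A, B)))
  mf_off <- stage("mfpt", as.numeric(mfpt(msm, B, A)))
  pops <- macro$populations
  rates <- rate_report(mf_on, mf_off,
                       pi_bound = pops[which(labels == "B")],
                       pi_unbound = pops[which(labels == "U")],
                       C = config$concentration,
                       temperature = config$temperature)
  report <- macrostate_report(macro, labels, qmac)

  structure(list(config = config, tica = tica, disc = disc, its = its,
                 msm = msm, macro = macro, labels = labels, tpt = tpt,
                 committor_macro = qmac, mfpt_on_ns = mf_on,
                 mfpt_off_ns = mf_off, report = report, rates = rates),
            class = "msm_pipeline")
}

#' @export
print.msm_pipeline <- function(x, ...) {
  cat("MSM ligand-binding pipeline\n")
  cat(sprintf("  %d microstates -> %d macrostates (MSM lag %.3g ns)\n",
              nrow(x$msm$T), x$macro$n_macro, x$msm$lag_ns))
  cat("Macrostate report:\n")
  print(x$report, row.names = FALSE, digits = 3)
  print(x$rates)
  invisible(x)
}
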