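# 1-D symmetric double well used in several tests: two Gaussian basins of
# ~5 kT depth whose saddle sits at essentially zero potential.
double_well <- function(depth = 12.5) {
  toy_landscape(matrix(c(-0.75, 0.75), ncol = 1), depths = c(depth, depth),
                widths = c(0.18, 0.18), half_box = 1.5)
}

test_that("CV values and gradients agree with finite differences", {
  cvs <- list(cv_position(2),
              cv_distance(c(0.3, -0.2)),
              cv_contacts(rbind(c(0.5, 0), c(-0.5, 0.2)), r0 = 0.4))
  x <- c(0.21, -0.37)
  h <- 1e-6
  for (cv in cvs) {
    ev <- cv_eval(cv, x)
    num <- vapply(1:2, function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (cv_eval(cv, xp)$value - cv_eval(cv, xm)$value) / (2 * h)
    }, numeric(1))
    expect_equal(ev$gradient, num, tolerance = 1e-5)
  }
})

test_that("propagator CV series matches the reference CV evaluation", {
  ls <- toy_landscape(matrix(c(0, 0), 1), depths = 8, widths = 0.3,
                      half_box = 2)
  sites <- rbind(c(0.4, 0), c(-0.4, 0), c(0, 0.4))
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 5000, seed = 2)
  b <- metad_bias(list(cv_distance(c(0, 0)), cv_contacts(sites, r0 = 0.5)),
                  height = 1.2, widths = c(0.05, 0.2), stride = 500,
                  grid_min = c(0, 0), grid_max = c(3, 3),
                  grid_n = c(201, 61))
  run <- run_wtmetad(ls, p, b, thin = 50)
  ref1 <- apply(run$positions, 1, function(x)
    cv_eval(cv_distance(c(0, 0)), x)$value)
  ref2 <- apply(run$positions, 1, function(x)
    cv_eval(cv_contacts(sites, r0 = 0.5), x)$value)
  expect_equal(run$cv[, 1], ref1, tolerance = 1e-12)
  expect_equal(run$cv[, 2], ref2, tolerance = 1e-12)
})

test_that("zero hills reduces to unbiased Langevin for the same seed", {
  ls <- double_well()
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 2000, seed = 3)
  b <- metad_bias(cv_position(1), stride = 5000,  # stride > n_steps: no hills
                  grid_min = -1.5, grid_max = 1.5, grid_n = 101)
  run <- run_wtmetad(ls, p, b, x0 = -0.75)
  ref <- brownian_binding_sim(ls, p, x0 = -0.75)
  expect_equal(nrow(run$hills), 0)
  expect_equal(run$positions, ref$positions, tolerance = 1e-12)
})

test_that("well-tempered heights decay at revisited CV points", {
  ls <- double_well()
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 2e5, seed = 5)
  b <- metad_bias(cv_position(1), height = 1.2, widths = 0.05, stride = 500,
                  bias_factor = 6, grid_min = -1.5, grid_max = 1.5,
                  grid_n = 301)
  run <- run_wtmetad(ls, p, b, x0 = -0.75)
  h <- run$hills
  expect_true(all(h$height <= 1.2 + 1e-12))
  expect_true(all(h$height > 0))
  # among hills deposited within half a width of each other, heights
  # strictly decrease with time
  for (i in seq_len(min(nrow(h), 200))) {
    later <- which(abs(h$center1 - h$center1[i]) < 0.025 &
                     h$time > h$time[i])
    if (length(later)) expect_lt(min(h$height[later]), h$height[i] + 1e-12)
  }
  # bias energy at deposition grows where revisited
  expect_gt(max(h$bias_at_center), 0)
})

test_that("flat landscape exploration covers the CV range", {
  ls <- toy_landscape(matrix(0, 1, 1), depths = 0, widths = 0.5,
                      half_box = 1.5)
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 2e5, seed = 7)
  b <- metad_bias(cv_position(1), height = 1.2, widths = 0.05, stride = 500,
                  grid_min = -1.5, grid_max = 1.5, grid_n = 61)
  run <- run_wtmetad(ls, p, b)
  bins <- cut(run$cv[, 1], seq(-1.5, 1.5, length.out = 61))
  expect_gt(mean(table(bins) > 0), 0.95)
})

test_that("a single hill reconstructs to a scaled negative Gaussian", {
  hills <- data.frame(time = 2.5, center1 = 0.2, center2 = NA,
                      width1 = 0.1, width2 = NA, height = 1.0,
                      bias_factor = 6)
  grid <- seq(-1, 1, length.out = 401)
  f <- reconstruct_free_energy(hills, grid1 = grid, temperature = 300,
                               bias_factor = 6)
  # F = -(T+dT)/dT * V, min-shifted: max at the hill center, zero far away
  dT <- 5 * 300
  fac <- (300 + dT) / dT
  expected <- fac * 1.0 * (1 - exp(-(grid - 0.2)^2 / (2 * 0.1^2)))
  # truncation at 6 widths leaves a tiny plateau offset; compare shape
  expect_equal(f$F_kJmol, expected - min(expected), tolerance = 1e-6)
  expect_equal(f$s[which.min(abs(f$F_kJmol - 0))], 0.2, tolerance = 0.01)
})

test_that("free-energy reconstruction is invariant to a bias offset", {
  ls <- double_well()
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 5e4, seed = 9)
  b <- metad_bias(cv_position(1), height = 1.2, widths = 0.05, stride = 500,
                  grid_min = -1.5, grid_max = 1.5, grid_n = 201)
  run <- run_wtmetad(ls, p, b, x0 = -0.75)
  f0 <- reconstruct_free_energy(run)
  f1 <- reconstruct_free_energy(run, bias_offset = 37.5)
  expect_equal(f0$F_kJmol, f1$F_kJmol, tolerance = 1e-10)
  # late-stage checkpoint averaging returns the same grid and a nearby,
  # min-shifted surface
  fa <- reconstruct_free_energy(run, n_average = 4)
  expect_equal(fa$s, f0$s)
  expect_equal(min(fa$F_kJmol), 0)
})

test_that("double-well barrier is recovered within 0.5 kT", {
  ls <- double_well()
  xg <- seq(-1.5, 1.5, length.out = 601)
  u <- landscape_potential(ls, matrix(xg, ncol = 1))
  barrier_true <- max(u[xg > -0.7 & xg < 0.7]) - min(u)
  # dt well below the relaxation time of hill-scale bias features
  # (k_hill ~ h/w^2) keeps the Euler-Maruyama sampling unbiased
  p <- langevin_params(dt = 0.001, kT = 2.494, gamma = 1,
                       n_steps = 1e7, seed = 11)
  b <- metad_bias(cv_position(1), height = 0.5, widths = 0.05, stride = 500,
                  bias_factor = 6, temperature = 300,
                  grid_min = -1.5, grid_max = 1.5, grid_n = 601)
  run <- run_wtmetad(ls, p, b, x0 = -0.75, thin = 1000)
  fes <- reconstruct_free_energy(run)
  fmin <- min(min(fes$F_kJmol[fes$s < 0]), min(fes$F_kJmol[fes$s > 0]))
  fbar <- max(fes$F_kJmol[fes$s > -0.55 & fes$s < 0.55])
  expect_lt(abs((fbar - fmin) - barrier_true), 0.5 * 2.494)
})

test_that("deepening the bound basin lowers the reconstructed basin depth", {
  fes_at_bound <- function(depth) {
    ls <- toy_landscape(matrix(c(-0.75, 0.75), ncol = 1),
                        depths = c(depth, 6), widths = c(0.18, 0.18),
                        half_box = 1.5)
    p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                         n_steps = 2e6, seed = 13)
    b <- metad_bias(cv_position(1), height = 1.2, widths = 0.05,
                    stride = 500, grid_min = -1.5, grid_max = 1.5,
                    grid_n = 301)
    run <- run_wtmetad(ls, p, b, x0 = -0.75, thin = 100)
    f <- reconstruct_free_energy(run)
    # depth of the bound well relative to the shallow reference well
    min(f$F_kJmol[f$s < 0]) - min(f$F_kJmol[f$s > 0])
  }
  vals <- vapply(c(8, 12, 16), fes_at_bound, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("egress detection scans threshold crossings with a dwell window", {
  cv <- c(rep(0.2, 999), rep(1.5, 600))
  e <- egress_time(cv, dt = 1, threshold = 1.0, dwell = 500)
  expect_false(e$censored)
  expect_equal(e$step, 1000)
  expect_equal(e$time, 999)
  # never leaves -> censored
  e2 <- egress_time(rep(0.2, 500), dt = 1, threshold = 1.0, dwell = 100)
  expect_true(e2$censored)
  # a brief recrossing spike shorter than the dwell does not count
  cv3 <- c(rep(0.2, 100), rep(1.5, 50), rep(0.2, 100), rep(1.5, 300))
  e3 <- egress_time(cv3, dt = 1, threshold = 1.0, dwell = 200)
  expect_equal(e3$step, 251)
})

test_that("deeper bound basins yield longer median egress across seeds", {
  egress_one <- function(depth, seed) {
    ls <- toy_landscape(matrix(c(0, 0), 1), depths = depth, widths = 0.25,
                        half_box = 2)
    p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                         n_steps = 4e5, seed = seed)
    b <- metad_bias(cv_distance(c(0, 0)), height = 1.2, widths = 0.05,
                    stride = 500, grid_min = 0, grid_max = 3, grid_n = 301)
    run <- run_wtmetad(ls, p, b, thin = 10)
    # dwell: one deposition interval; box-scale diffusion recrosses faster
    e <- egress_time(run, threshold = 1.0, dwell = 500 * 0.005)
    if (e$censored) Inf else e$time
  }
  shallow <- vapply(1:10, function(s) egress_one(10, s), numeric(1))
  deep <- vapply(1:10, function(s) egress_one(18, s), numeric(1))
  expect_gt(median(deep), median(shallow))
})
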