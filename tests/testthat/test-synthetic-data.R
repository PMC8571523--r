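test_that("planted chain spec validates its invariants", {
  expect_error(planted_chain_spec(4, c("a", "a", "b", "b"),
                                  c(a = 0.5, b = 0.6), 0.2, 0.01),
               "sum to 1")
  expect_error(planted_chain_spec(4, c("a", "a", "b", "b"),
                                  c(a = 0.5, b = 0.5), 0.01, 0.2),
               "intra_rate > inter_rate")
  expect_error(planted_chain_spec(4, c("a", "a", "b", "b"),
                                  c(a = 0.5, x = 0.5), 0.2, 0.01),
               "named")
})

test_that("symmetric two-block chain gives a symmetric matrix and uniform pi", {
  spec <- planted_chain_spec(6, rep(c("a", "b"), each = 3),
                             c(a = 0.5, b = 0.5), 0.2, 0.01)
  ch <- build_reversible_chain(spec)
  expect_equal(ch$T, t(ch$T), tolerance = 1e-14)
  expect_equal(ch$pi, rep(1 / 6, 6), tolerance = 1e-14)
})

test_that("four-block chain reproduces bound-dominant target populations", {
  ch <- build_reversible_chain(table_like_spec())
  expect_equal(as.numeric(block_populations(ch)),
               c(0.3527, 0.0037, 0.0044, 0.6392), tolerance = 1e-10)
  # exact stationarity against an eigendecomposition oracle
  expect_equal(ch$pi, stationary_eigen(ch$T), tolerance = 1e-10)
})

test_that("every generated matrix satisfies detailed balance", {
  for (seed in 1:5) {
    set.seed(seed)
    nb <- sample(2:4, 1)
    sizes <- sample(2:5, nb, replace = TRUE)
    pops <- as.numeric(runif_simplex(seed, nb))
    names(pops) <- paste0("b", seq_len(nb))
    spec <- planted_chain_spec(sum(sizes),
                               rep(names(pops), sizes), pops,
                               intra_rate = 0.1, inter_rate = 1e-3)
    ch <- build_reversible_chain(spec)
    flux <- ch$pi * ch$T
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    expect_equal(rowSums(ch$T), rep(1, sum(sizes)), tolerance = 1e-12)
  }
})

test_that("infeasible rates are rejected with a diagnostic", {
  spec <- planted_chain_spec(6, rep(c("a", "b"), each = 3),
                             c(a = 0.5, b = 0.5), 0.55, 0.1)
  expect_error(build_reversible_chain(spec), "infeasible rates")
})

test_that("forbidden block exchange via connectivity zeroes those transitions", {
  spec <- table_like_spec()
  conn <- matrix(1, 4, 4, dimnames = list(c("U", "I1", "I2", "B"),
                                          c("U", "I1", "I2", "B")))
  conn["U", "B"] <- conn["B", "U"] <- 0
  ch <- build_reversible_chain(spec, connectivity = conn)
  u <- which(ch$blocks == "U"); b <- which(ch$blocks == "B")
  expect_true(all(ch$T[u, b] == 0) && all(ch$T[b, u] == 0))
})

test_that("chain sampling is seeded, reproducible, and respects structure", {
  # identity matrix: constant trajectory from any start
  expect_equal(unique(sample_chain(diag(3), 100, seed = 1, start = 2)), 2L)
  # deterministic flip-flop alternates strictly
  flip <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sample_chain(flip, 6, seed = 1, start = 1),
               c(1L, 2L, 1L, 2L, 1L, 2L))
  ch <- three_state_chain()
  expect_identical(sample_chain(ch, 5000, seed = 99),
                   sample_chain(ch, 5000, seed = 99))
})

test_that("empirical state frequencies converge to the exact stationary law", {
  ch <- three_state_chain()
  n <- 1e6
  d <- sample_chain(ch, n, seed = 123)
  freq <- tabulate(d, 3) / n
  pi_exact <- stationary_eigen(ch$T)
  # 3 sigma with an effective sample size reduced by the autocorrelation time
  lam2 <- sort(abs(eigen(ch$T)$values), decreasing = TRUE)[2]
  tau_int <- (1 + lam2) / (1 - lam2)
  se <- sqrt(pi_exact * (1 - pi_exact) * tau_int / n)
  expect_true(all(abs(freq - pi_exact) < 3 * se))
})

test_that("harmonic well sampling matches Boltzmann variance", {
  # kT/k per dimension; dt far below the well relaxation time gamma/k
  ls <- toy_landscape(matrix(c(0, 0), 1), depths = 10, widths = 0.5,
                      half_box = 3, shape = "harmonic")
  p <- langevin_params(dt = 0.001, kT = 2.494, gamma = 1,
                       n_steps = 1e6, seed = 7)
  sim <- brownian_binding_sim(ls, p)
  k_spring <- 10 / 0.5^2
  ratio <- apply(sim$positions, 2, var) / (2.494 / k_spring)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("zero-depth landscape reduces to free diffusion", {
  ls <- toy_landscape(matrix(c(0, 0), 1), depths = 0, widths = 0.5,
                      half_box = 50)
  p <- langevin_params(dt = 0.01, kT = 2.0, gamma = 2,
                       n_steps = 2e5, seed = 3)
  sim <- brownian_binding_sim(ls, p)
  # MSD over increments of m frames: 2 d (kT/gamma) t
  for (m in c(1, 5, 20)) {
    x <- sim$positions
    inc <- x[-(1:m), ] - x[seq_len(nrow(x) - m), ]
    msd <- mean(rowSums(inc^2))
    expect_equal(msd, 2 * 2 * (2.0 / 2) * m * 0.01, tolerance = 0.05)
  }
})

test_that("visitation fractions follow numerically integrated Boltzmann weights", {
  ls <- toy_landscape(rbind(c(1, 0), c(-1, 0)), depths = c(10, 4),
                      widths = c(0.3, 0.3), half_box = 2)
  p <- langevin_params(dt = 0.005, kT = 2.494, gamma = 1,
                       n_steps = 1e6, seed = 21)
  sim <- brownian_binding_sim(ls, p)
  w <- boltzmann_weights(ls, kT = 2.494, radius = 0.5)
  dens <- attr(w, "per_volume")
  r1 <- sqrt(rowSums(sweep(sim$positions, 2, c(1, 0))^2))
  r2 <- sqrt(rowSums(sweep(sim$positions, 2, c(-1, 0))^2))
  obs <- c(basin1 = mean(r1 < 0.5), basin2 = mean(r2 < 0.5))
  obs <- c(obs, bulk = 1 - sum(obs))
  # probabilities agree with the grid oracle and order deep > bulk
  # (per area) > shallow intermediate as planted
  expect_equal(as.numeric(obs), as.numeric(w), tolerance = 0.12)
  expect_gt(dens["basin1"], dens["bulk"])
  expect_gt(obs["basin1"], obs["basin2"])
})

test_that("too-large Langevin steps are rejected", {
  ls <- toy_landscape(matrix(c(0, 0), 1), depths = 5, widths = 0.05,
                      half_box = 2)
  p <- langevin_params(dt = 0.1, kT = 2.494, gamma = 1, n_steps = 100)
  expect_error(brownian_binding_sim(ls, p), "dt too large")
})

test_that("pseudo-residues ring each basin and are contact-distinguishable", {
  ls <- toy_landscape(rbind(c(1.5, 0), c(-1.5, 0)), depths = c(10, 5),
                      widths = c(0.3, 0.3), half_box = 3)
  res <- pseudo_residues(ls)
  expect_length(res, 12)
  v_b1 <- contact_vector(matrix(c(1.5, 0), 1), res)
  v_b2 <- contact_vector(matrix(c(-1.5, 0), 1), res)
  basin <- attr(res, "basin")
  expect_equal(v_b1, as.integer(basin == 1))
  expect_equal(v_b2, as.integer(basin == 2))
})
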