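# MSM built from exact expected counts of a planted chain: the estimate
# equals the chain itself up to rounding.
exact_msm <- function(chain, scale = 1e9, lag_frames = 1, dt_ns = 1) {
  m <- estimate_reversible(round(chain$T * chain$pi * scale), dt_ns = dt_ns)
  m$lag_frames <- lag_frames
  m$lag_ns <- lag_frames * dt_ns
  m
}

test_that("committor boundary conditions hold exactly on any MSM", {
  ch <- build_reversible_chain(table_like_spec())
  m <- exact_msm(ch)
  A <- which(ch$blocks == "U"); B <- which(ch$blocks == "B")
  q <- committor(m, A, B)
  expect_identical(q[A], rep(0, length(A)))
  expect_identical(q[B], rep(1, length(B)))
  expect_true(all(q >= 0 & q <= 1))
  # macrostate aggregation keeps the source at 0 and the sink at 1
  crisp <- as.integer(factor(ch$blocks, levels = c("U", "I1", "I2", "B")))
  qm <- committor_macro(q, m$pi, crisp)
  expect_equal(qm[1], 0)
  expect_equal(qm[4], 1)
  # reversibility: q+ + q- = 1 everywhere
  expect_equal(as.numeric(q) + attr(q, "q_minus"), rep(1, 20),
               tolerance = 1e-8)
})

test_that("symmetric source-intermediate-sink chain has q+(I) = 0.5", {
  tm <- matrix(c(0.9, 0.1, 0,
                 0.1, 0.8, 0.1,
                 0, 0.1, 0.9), 3, byrow = TRUE)
  m <- estimate_reversible(round(tm * 1e8))
  q <- committor(m, 1, 3)
  expect_equal(q[2], 0.5, tolerance = 1e-8)
})

test_that("birth-death committor matches the closed-form product oracle", {
  p <- c(0.3, 0.25, 0.2, 0.15, 0)
  q <- c(0, 0.1, 0.2, 0.25, 0.3)
  tm <- birth_death_T(p, q)
  m <- estimate_reversible(round(stationary_eigen(tm) * tm * 1e10))
  got <- committor(m, 1, 5)
  expect_equal(as.numeric(got), bd_committor(p, q), tolerance = 1e-6)
})

test_that("TPT flux is conserved and decomposes into pathways", {
  ch <- build_reversible_chain(table_like_spec())
  m <- exact_msm(ch)
  A <- which(ch$blocks == "U"); B <- which(ch$blocks == "B")
  tp <- tpt_flux(m, A, B)
  n <- nrow(m$T)
  # net-flux divergence zero at every intermediate
  mid <- setdiff(seq_len(n), c(A, B))
  div <- rowSums(tp$net_flux) - colSums(tp$net_flux)
  expect_lt(max(abs(div[mid])), 1e-10 * tp$total_flux)
  # flux out of A equals flux into B equals F
  expect_equal(sum(tp$net_flux[A, ]) - sum(tp$net_flux[, A]),
               tp$total_flux, tolerance = 1e-8)
  expect_equal(sum(tp$net_flux[, B]) - sum(tp$net_flux[B, ]),
               tp$total_flux, tolerance = 1e-8)
  # path fractions sum to <= 1 with the remainder reported
  fr <- vapply(tp$pathways, `[[`, numeric(1), "fraction")
  expect_lte(sum(fr), 1 + 1e-12)
  expect_equal(sum(fr) + tp$residual_flux / tp$total_flux, 1,
               tolerance = 1e-8)
})

test_that("forbidden direct transitions route all flux via the intermediate", {
  tm <- matrix(c(0.9, 0.1, 0,
                 0.05, 0.9, 0.05,
                 0, 0.1, 0.9), 3, byrow = TRUE)
  m <- estimate_reversible(round(stationary_eigen(tm) * tm * 1e9))
  tp <- tpt_flux(m, 1, 3)
  expect_equal(length(tp$pathways), 1)
  expect_equal(tp$pathways[[1]]$states, c(1, 2, 3))
  expect_equal(tp$pathways[[1]]$fraction, 1, tolerance = 1e-6)
  # hand-computable: F = pi_1 T_12 q+(2), q+(2) = 0.5 by symmetry
  expect_equal(tp$total_flux, m$pi[1] * m$T[1, 2] * 0.5, tolerance = 1e-6)
})

test_that("strong direct coupling dominates; off-pathway intermediates carry none", {
  # U (1) <-> B (2) directly and strongly; I_on (3) weakly on-pathway;
  # I_off (4) connected to U only, so it cannot carry sink-ward net flux
  labs <- c("U", "B", "Ion", "Ioff")
  conn <- matrix(0, 4, 4, dimnames = list(labs, labs))
  conn["U", "B"] <- conn["B", "U"] <- 10
  conn["U", "Ion"] <- conn["Ion", "U"] <- 1
  conn["Ion", "B"] <- conn["B", "Ion"] <- 1
  conn["U", "Ioff"] <- conn["Ioff", "U"] <- 1
  spec <- planted_chain_spec(4, labs,
                             c(U = 0.35, B = 0.60, Ion = 0.03, Ioff = 0.02),
                             intra_rate = 0.5, inter_rate = 0.02)
  ch <- build_reversible_chain(spec, connectivity = conn)
  m <- exact_msm(ch)
  tp <- tpt_flux(m, 1, 2, residual_frac = 1e-6)
  paths <- lapply(tp$pathways, `[[`, "states")
  fracs <- vapply(tp$pathways, `[[`, numeric(1), "fraction")
  direct <- vapply(paths, identical, logical(1), c(1L, 2L))
  expect_gt(sum(fracs[direct]), 0.8)   # direct U->B dominates
  through_off <- vapply(paths, function(p) 4 %in% p, logical(1))
  expect_equal(sum(fracs[through_off]), 0)  # off-pathway state contributes 0
})

test_that("MFPT matches geometric waiting and birth-death closed forms", {
  # 2-state chain: MFPT = lag / p
  p <- 0.02
  tm <- matrix(c(1 - p, p, 0.5, 0.5), 2, byrow = TRUE)
  m <- estimate_reversible(round(stationary_eigen(tm) * tm * 1e9))
  expect_equal(as.numeric(mfpt(m, 1, 2)), 1 / p, tolerance = 1e-6)
  # 5-state birth-death chain vs nested-sum oracle
  pb <- c(0.3, 0.25, 0.2, 0.15, 0)
  qb <- c(0, 0.1, 0.2, 0.25, 0.3)
  tb <- birth_death_T(pb, qb)
  mb <- estimate_reversible(round(stationary_eigen(tb) * tb * 1e11))
  expect_equal(as.numeric(mfpt(mb, 1, 5)), bd_mfpt_1_to_n(pb, qb),
               tolerance = 1e-6)
})

test_that("linear-solve MFPT matches the empirical first-passage mean", {
  ch <- three_state_chain()
  m <- exact_msm(ch)
  solve_mfpt <- as.numeric(mfpt(m, 1, 3))
  fpt <- sample_first_passage(ch, start = 1, target = 3, n_rep = 1e5,
                              seed = 29)
  expect_true(all(is.finite(fpt)))
  se <- sd(fpt) / sqrt(length(fpt))
  expect_lt(abs(mean(fpt) - solve_mfpt), 3 * se)
})

test_that("unbinding from a strongly bound state is far slower than binding", {
  ch <- build_reversible_chain(table_like_spec())
  m <- exact_msm(ch)
  A <- which(ch$blocks == "U"); B <- which(ch$blocks == "B")
  expect_gt(as.numeric(mfpt(m, B, A)), as.numeric(mfpt(m, A, B)))
})

test_that("rate constants follow the MFPT definitions", {
  r <- rate_constants(10, 1, C = 0.1)
  expect_equal(r$k_on, 1)            # 1 / (10 s x 0.1 M)
  expect_equal(r$k_off, 1)
  r2 <- rate_constants(1e-6, 1e-6, C = 1)
  expect_equal(r2$k_off, 1e6)        # microsecond off-time -> 1e6 /s
  expect_equal(r2$residence_s, 1e-6)
  expect_error(rate_constants(1, 1, C = 0), "concentration")
  # off-rate ratio across two reported systems: 1e6 / 0.038e6 ~ 26.3
  koff_parent <- rate_constants(1, 1 / 1e6, C = 1)$k_off
  koff_deriv <- rate_constants(1, 1 / 0.038e6, C = 1)$k_off
  expect_equal(koff_parent / koff_deriv, 26.3, tolerance = 0.01)
  expect_gte(koff_parent / koff_deriv, 25)
})

test_that("binding free energy reproduces direct evaluation of the formula", {
  expect_equal(binding_free_energy(0.5, 0.5, 310.15)$dG0, 0)
  fe <- binding_free_energy(0.6392, 0.3527, 310.15)
  expect_equal(fe$dG, -0.367, tolerance = 0.002)
  # standard-state correction at C < C0 stabilizes binding
  fe2 <- binding_free_energy(0.6392, 0.3527, 310.15, C = 0.01)
  expect_lt(fe2$dG0, fe$dG)
  expect_equal(fe2$dG0 - fe$dG,
               -1.9872041e-3 * 310.15 * log(1 / 0.01), tolerance = 1e-9)
  expect_error(binding_free_energy(0, 0.5, 300), "strictly")
})

test_that("two-state reduction is consistent with detailed balance within 20%", {
  ch <- build_reversible_chain(table_like_spec())
  m <- exact_msm(ch, dt_ns = 1)
  A <- which(ch$blocks == "U"); B <- which(ch$blocks == "B")
  pi_u <- sum(m$pi[A]); pi_b <- sum(m$pi[B])
  conc <- 0.05
  r <- rate_constants(as.numeric(mfpt(m, A, B)) * 1e-9,
                      as.numeric(mfpt(m, B, A)) * 1e-9, C = conc)
  lhs <- r$k_on * conc * pi_u
  rhs <- r$k_off * pi_b
  expect_lt(abs(lhs - rhs) / rhs, 0.2)
})

test_that("rate report bundles units coherently and bootstrap runs", {
  rep <- rate_report(mfpt_on_ns = 100, mfpt_off_ns = 1000,
                     pi_bound = 0.6, pi_unbound = 0.3,
                     C = 0.01, temperature = 300)
  expect_equal(rep$mfpt_on_s, 1e-7)
  expect_equal(rep$k_off, 1 / (1000e-9))
  expect_equal(rep$residence_s, 1e-6)
  expect_lt(rep$dG0, rep$dG)  # dilute box stabilizes on standardization
  ch <- three_state_chain()
  dts <- lapply(1:4, function(i) sample_chain(ch, 2e4, seed = i))
  bs <- bootstrap_mfpt(dts, 1, from = 1, to = 3, n_boot = 10)
  expect_true(sum(is.finite(bs)) >= 8)
  expect_true(all(bs[is.finite(bs)] > 0))
})
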