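# tolerances used for the quicker property runs (the reference-value
# reproductions in the acceptance suite use the tight defaults)
quick <- list(rtol = 1e-10, atol = 1e-12, period_rtol = 1e-8)

test_that("the integrator reproduces closed-form decay and fixed points", {
  # pure exponential decay on a hand-built one-dimensional model
  lin <- structure(list(name = "linear_decay", m = 1L, pars = list(),
                        spec = NULL, rhs = function(s) -s,
                        jac = function(s) matrix(-1, 1, 1), nl = NULL,
                        constructor = NULL, args = NULL),
                   class = "cell_model")
  tr <- integrate_model(lin, 1, 5, dt = 0.05)
  expect_equal(tr$state[, 1], exp(-tr$time), tolerance = 1e-10)
  # an equilibrium initial condition stays put
  md <- single_cell_model(ht_spec, 0.7)
  eq <- solve_equilibrium(md)
  tr2 <- integrate_model(md, eq$state, 50, dt = 0.1)
  expect_lt(max(abs(sweep(tr2$state, 2, eq$state))), 1e-8)
  expect_error(integrate_model(md, c(-0.1, 0.1, 0.1), 1), "nonnegative")
  expect_error(integrate_model(md, rep(0.1, 4), 1), "dimension")
})

test_that("below the bifurcation value the equilibrium is a stable focus", {
  a0 <- single_cell_hb(ht_spec)$parameter_values$alpha
  md <- single_cell_model(ht_spec, a0 - 0.05)
  eq <- solve_equilibrium(md)
  tr <- integrate_model(md, eq$state * 1.2, 600, dt = 0.1,
                        rtol = 1e-10, atol = 1e-12)
  final_dev <- max(abs(tr$state[nrow(tr$state), ] - eq$state))
  expect_lt(final_dev, 1e-3)
  expect_error(
    do.call(extract_cycle, c(list(md, transient = 50, window = 50,
                                  max_time = 300), quick)),
    "no cycle|did not converge")
})

test_that("extracted cycles are self-consistent and reproducible across initial conditions", {
  md <- fixture_model("fig4")
  cs1 <- do.call(extract_cycle,
                 c(list(md, x0 = fixture_initial_state("fig4"), transient = 100), quick))
  expect_equal(cs1$frequency * cs1$period, 2 * pi, tolerance = 1e-14)
  expect_lte(cs1$convergence_metric, quick$period_rtol)
  expect_true(all(cs1$amplitude > 0))
  cs2 <- do.call(extract_cycle,
                 c(list(md, x0 = c(0.4, 0.2, 0.3), transient = 100), quick))
  expect_equal(cs1$period, cs2$period, tolerance = 1e-8)
})

test_that("near the bifurcation the cycle frequency approaches the eigenvalue prediction", {
  sd1 <- seeded_near_cycle(ht_spec, 1e-3)
  cs <- extract_cycle(sd1$model, x0 = sd1$x0, transient = 300, window = 60,
                      max_time = 3000, period_rtol = 1e-7,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(cs$frequency, sqrt(3), tolerance = 5e-3)
})

test_that("a timescale factor scales the cycle frequency exactly", {
  base <- single_cell_model(ht_spec, 0.60139)
  fast <- single_cell_model(ht_spec, 0.60139, sigma = 1.3)
  cs_b <- do.call(extract_cycle, c(list(base, transient = 100), quick))
  cs_f <- do.call(extract_cycle, c(list(fast, transient = 100), quick))
  expect_equal(cs_f$frequency, 1.3 * cs_b$frequency, tolerance = 1e-6)
})

test_that("frequency decreases and amplitude grows with the production rate", {
  md <- single_cell_model(ht_spec, 0.6)
  a0 <- single_cell_hb(ht_spec)$parameter_values$alpha
  sw <- frequency_sweep(md, "alpha", a0 + c(0.015, 0.06, 0.15, 0.3),
                        transient = 150, window = 50, max_time = 1500,
                        period_rtol = 1e-7, rtol = 1e-10, atol = 1e-12)
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$omega) < 0))
  expect_true(all(diff(sw$amplitude) > 0))
  expect_lt(sw$omega[1], sqrt(3))
  expect_equal(sw$omega[1], sqrt(3), tolerance = 0.02)
})

test_that("identical coupled cells synchronise; nonidentical cells phase-lock", {
  mdi <- coupled_identical_model(ht_spec, 0.475, 0.05, 20)
  csi <- do.call(extract_cycle, c(list(mdi, transient = 150, window = 50,
                                       max_time = 2000), quick))
  expect_lt(max(abs(csi$phase_differences)), 1e-6 * csi$period)
  # collective frequency near the example value at (0.05, 0.475)
  expect_equal(csi$frequency, 1.71999, tolerance = 1e-3)
  mdn <- coupled_nonidentical_model(ht_spec, 0.53, 0.05, 20, 1.05)
  csn <- extract_cycle(mdn, transient = 300, window = 60, max_time = 2500,
                       period_rtol = 1e-6, rtol = 1e-10, atol = 1e-12)
  # phase-locked with a clearly nonzero offset, near the reported peak-time
  # difference of ~0.31 for these cells
  expect_gt(abs(csn$phase_differences[["cell2_x1"]]), 0.2)
  expect_lt(abs(csn$phase_differences[["cell2_x1"]]), 0.4)
})

test_that("average frequency and average period are distinct summaries", {
  mk <- function(T) structure(list(period = T, frequency = 2 * pi / T,
                                   amplitude = 1, phase_differences = NULL,
                                   convergence_metric = 0),
                              class = "cycle_summary")
  av <- average_frequency(list(mk(2), mk(4)))
  expect_equal(av$T_ave, 3)
  expect_equal(2 * pi / av$omega_ave, 8 / 3)
  expect_equal(average_frequency(list(mk(3)))$omega_ave, 2 * pi / 3)
  expect_error(average_frequency(list()), "nonempty")
})

test_that("the two-cell average frequency at the waveform-matched drive is reproduced", {
  md <- single_cell_model(ht_spec, 0.60139)
  cs <- do.call(extract_cycle, c(list(md, transient = 100), quick))
  omega_ave <- mean(c(1, 1.05)) * cs$frequency
  expect_equal(omega_ave, 1.77086089, tolerance = 1e-3)
})

test_that("a coupling strength matching collective and average frequency exists", {
  md <- coupled_nonidentical_model(ps_spec, 0.56, 0.04, 20, 1.05)
  res <- find_matching_coupling(md, c(0.036, 0.046), tol = 2e-4,
                                transient = 300, window = 60, max_time = 2500,
                                period_rtol = 1e-6, rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(res$c_match - 0.04), 1e-3)
  expect_lt(abs(res$residual), 1e-3)
})
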