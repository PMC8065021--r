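test_that("characteristic coefficients match known forms and an eigen-product oracle", {
  # single-cell linearization: lambda^3 + 3 lambda^2 + 3 lambda + (alpha gamma + 1)
  md <- single_cell_model(ht_spec, 0.7)
  eq <- solve_equilibrium(md)
  g <- repression_gamma(ht_spec, eq$state[3])
  b <- char_coefficients(model_jacobian(md, eq$state))
  expect_equal(as.numeric(b), c(3, 3, 0.7 * g + 1), tolerance = 1e-12)
  # (lambda + 1)^3
  expect_equal(as.numeric(char_coefficients(-diag(3))), c(3, 3, 1),
               tolerance = 1e-14)
  # random 8x8 against expansion of prod(lambda - lambda_i)
  set.seed(5)
  for (k in 1:5) {
    J <- matrix(rnorm(64), 8, 8)
    b <- as.numeric(char_coefficients(J))
    oracle <- poly_from_roots(eigen(J, only.values = TRUE)$values)
    expect_equal(b, oracle, tolerance = 1e-9 * max(1, max(abs(oracle))))
  }
})

test_that("Hurwitz determinants encode the cubic bifurcation condition", {
  # for (3, 3, b3): D2 = 9 - b3, zero exactly when alpha gamma = 8
  hw <- hurwitz_determinants(c(3, 3, 9))
  expect_equal(hw$D[2], 0)
  expect_true(hw$D_m_minus_1_zero)
  expect_identical(hw$classification, "hopf_candidate")
  expect_equal(hurwitz_determinants(c(3, 3, 5))$D[2], 4)
  # identity D_m = b_m * D_(m-1)
  set.seed(8)
  for (k in 1:20) {
    b <- rnorm(6, sd = 2)
    hw <- hurwitz_determinants(b)
    expect_equal(hw$D[6], b[6] * hw$D[5], tolerance = 1e-9 * (1 + abs(hw$D[6])))
  }
})

test_that("Routh-Hurwitz classification agrees with a root-location oracle", {
  set.seed(123)
  n_stable <- 0
  for (k in 1:500) {
    m <- sample(4:8, 1)
    roots <- c()
    while (length(roots) < m) {
      if (m - length(roots) >= 2 && runif(1) < 0.6) {
        re <- runif(1, -2, if (runif(1) < 0.25) 0.8 else -0.02)
        im <- runif(1, 0.1, 2)
        roots <- c(roots, complex(real = re, imaginary = im),
                   complex(real = re, imaginary = -im))
      } else {
        roots <- c(roots, runif(1, -3, if (runif(1) < 0.2) 0.8 else -0.02))
      }
    }
    b <- poly_from_roots(roots)
    hw <- hurwitz_determinants(b, zero_tol = 1e-12)
    truly_stable <- all(Re(roots) < 0)
    if (truly_stable) n_stable <- n_stable + 1
    expect_identical(hw$classification == "stable", truly_stable,
                     label = sprintf("draw %d", k))
  }
  expect_gt(n_stable, 50)  # both outcomes well represented
})

test_that("single-cell bifurcation values match the reference examples", {
  hp <- single_cell_hb(ht_spec)
  expect_equal(hp$equilibrium$state[3], 0.148684, tolerance = 1e-5)
  expect_equal(hp$parameter_values$alpha, 0.545174, tolerance = 1e-5)
  expect_identical(hp$omega_star, sqrt(3))
  expect_lt(abs(hp$parameter_values$alpha *
                  repression_value(ht_spec, hp$equilibrium$state[3]) -
                  hp$equilibrium$state[3]), 1e-10)
  hp2 <- single_cell_hb(ps_spec)
  expect_equal(hp2$equilibrium$state[3], 0.058730, tolerance = 1e-5)
  expect_equal(hp2$parameter_values$alpha, 0.533809, tolerance = 1e-5)
  # the linearization at the bifurcation is the universal constant matrix
  J <- model_jacobian(single_cell_model(ht_spec, hp$parameter_values$alpha),
                      hp$equilibrium$state)
  expect_equal(J, matrix(c(-1, 0, -8, 1, -1, 0, 0, 1, -1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
  expect_true(any(abs(hp$eigenvalues - sqrt(3) * 1i) < 1e-7))
  expect_true(any(abs(hp$eigenvalues + 3) < 1e-7))
  # nonzero transversal crossing
  expect_lt(hp$crossing_derivative, 0)
  expect_lt(hp2$crossing_derivative, 0)
})

test_that("infeasible single-cell parameter regions are refused", {
  expect_error(single_cell_hb(hill_repression(8, 0.136)), "n > 8")
  expect_error(single_cell_hb(hill_repression(3, 0.136)), "n > 8")
  # A below the sequestration threshold (127 + 48 sqrt(7)) k_d
  expect_error(single_cell_hb(seq_repression(2e-3, 1e-5)), "infeasible")
})

test_that("identical-cell bifurcation matches the closed-form example values", {
  hp <- coupled_identical_hb(ht_spec, 0.05, 20)
  expect_equal(hp$parameter_values$alpha, 0.4742, tolerance = 1e-4)
  expect_equal(hp$omega_star, 1.721229, tolerance = 1e-5)
  expect_equal(repression_gamma(ht_spec, hp$equilibrium$state[3]), 15.05911,
               tolerance = 1e-4)
  hp2 <- coupled_identical_hb(ps_spec, 0.05, 20)
  expect_equal(hp2$parameter_values$alpha, 0.4766, tolerance = 1e-4)
  expect_equal(hp2$omega_star, 1.721278, tolerance = 1e-5)
  # closed-form frequency agrees with the 8x8 spectrum
  for (h in list(hp, hp2)) {
    imag_pair <- h$eigenvalues[abs(Re(h$eigenvalues)) < 1e-6 & Im(h$eigenvalues) > 0]
    expect_length(imag_pair, 1)
    expect_equal(Im(imag_pair), h$omega_star, tolerance = 1e-6)
  }
  expect_error(coupled_identical_hb(ht_spec, 0.05, 0.8), "s > 1")
})

test_that("the identical-cell bifurcation collapses to the single-cell one as c -> 0", {
  for (spec in list(ht_spec, ps_spec)) {
    hp0 <- single_cell_hb(spec)
    hp <- coupled_identical_hb(spec, 1e-8, 20)
    expect_equal(hp$parameter_values$alpha, hp0$parameter_values$alpha,
                 tolerance = 1e-6)
    expect_equal(hp$omega_star, sqrt(3), tolerance = 1e-6)
  }
})

test_that("the identical-pair polynomial factors through the synchronous quartic", {
  set.seed(21)
  for (k in 1:8) {
    spec <- if (k %% 2) hill_repression(sample(9:14, 1), runif(1, 0.05, 0.3))
      else seq_repression(runif(1, 0.03, 0.12), 10^runif(1, -6, -4.2))
    a <- runif(1, 0.3, 0.8); cc <- runif(1, 0.01, 0.1); s <- runif(1, 2, 25)
    md <- coupled_identical_model(spec, a, cc, s)
    eq <- solve_equilibrium(md)
    g <- repression_gamma(spec, eq$state[3])
    b8 <- as.numeric(char_coefficients(model_jacobian(md, eq$state)))
    bp <- synchronous_quartic(spec, a, cc, s, "+", gamma = g)
    bm <- synchronous_quartic(spec, a, cc, s, "-", gamma = g)
    expect_equal(bp, c(s + 3, 3 * (s + 1), a * g + 3 * s + 1,
                       s * (a * g + 1) + cc * s * g), tolerance = 1e-12)
    expect_equal(b8, poly_mult_monic(bp, bm),
                 tolerance = 1e-9 * max(1, max(abs(b8))))
    # the restricted synchronous 4-D system carries exactly the "+" factor
    J <- model_jacobian(md, eq$state)
    J4 <- J[1:4, 1:4] + J[1:4, 5:8]
    expect_equal(as.numeric(char_coefficients(J4)), bp,
                 tolerance = 1e-9 * max(1, max(abs(bp))))
  }
})

test_that("the anti-phase factor never produces the first bifurcation", {
  set.seed(33)
  found <- 0
  for (k in 1:20) {
    spec <- hill_repression(sample(9:14, 1), runif(1, 0.05, 0.3))
    cc <- runif(1, 0.02, 0.12); s <- runif(1, 2, 25)
    D3 <- function(branch) function(a) {
      b <- synchronous_quartic(spec, a, cc, s, branch)
      b[1] * b[2] * b[3] - b[3]^2 - b[1]^2 * b[4]
    }
    r <- tryCatch(stats::uniroot(D3("-"), c(0.05, 3), tol = 1e-10),
                  error = identity)
    if (inherits(r, "error")) next
    found <- found + 1
    expect_lt(D3("+")(r$root), 0)
  }
  expect_gt(found, 5)
})

test_that("the collective frequency decreases with gamma and with coupling", {
  s <- 20
  wc <- function(g, cc) sqrt(0.5 * (sqrt((s^2 + 3)^2 - 4 * s * cc * g) - (s^2 - 3)))
  expect_true(all(diff(vapply(seq(1, 16, by = 0.5), wc, 0, cc = 0.05)) < 0))
  expect_true(all(diff(vapply(seq(0.005, 0.2, by = 0.005), function(cc)
    wc(15, cc), 0)) < 0))
})

test_that("the numeric locator agrees with the closed form for identical cells", {
  md <- coupled_nonidentical_model(ht_spec, 0.5, 0.05, 20, sigma = 1)
  hp_num <- general_hb_locator(md, "alpha", c(0.42, 0.55))
  hp_cf <- coupled_identical_hb(ht_spec, 0.05, 20)
  expect_equal(hp_num$parameter_values$alpha, hp_cf$parameter_values$alpha,
               tolerance = 1e-6)
  expect_equal(hp_num$omega_star, hp_cf$omega_star, tolerance = 1e-6)
})

test_that("the numeric locator reproduces the nonidentical-pair examples", {
  md <- coupled_nonidentical_model(ht_spec, 0.5, 0.05, 20, 1.05)
  hp <- general_hb_locator(md, "alpha", c(0.45, 0.6))
  expect_equal(hp$parameter_values$alpha, 0.5165, tolerance = 1e-4)
  expect_equal(hp$omega_star, 1.801918, tolerance = 1e-4)
  # printed spectrum at the bifurcation value
  ev <- hp$eigenvalues
  expect_true(any(abs(ev - complex(real = -0.018114, imaginary = 1.706965)) < 1e-4))
  expect_true(any(abs(ev + 2.974896) < 1e-4))
  expect_true(any(abs(ev + 3.141083) < 1e-4))
  md2 <- coupled_nonidentical_model(ps_spec, 0.5, 0.038, 20, 1.05)
  hp2 <- general_hb_locator(md2, "alpha", c(0.45, 0.6))
  expect_equal(hp2$parameter_values$alpha, 0.5043, tolerance = 1e-4)
  expect_equal(hp2$omega_star, 1.806613, tolerance = 1e-4)
  # simple-Hopf spectra: exactly one near-imaginary pair, the rest stable
  for (h in list(hp, hp2)) {
    near <- abs(Re(h$eigenvalues)) < 1e-7
    expect_identical(sum(near), 2L)
    expect_true(all(Re(h$eigenvalues[!near]) < -1e-7))
    expect_true(abs(h$crossing_derivative) > 0)
  }
})

test_that("the locators refuse flat-tail and slope-bound-violating configurations", {
  # coupling strong enough that the slope bound 8(s+1)^3/(c s (s+3)^2)
  # falls below gamma at the self-consistent equilibrium: alpha* <= 0
  expect_error(coupled_identical_hb(ht_spec, 1.0, 20), "infeasible")
  # the numeric locator reports not-found (no sign change of D_(m-1))
  # rather than a spurious root when the bracket covers only flat-tail
  # equilibria (tiny gamma)
  flat <- hill_repression(11, 10)
  mdf <- coupled_nonidentical_model(flat, 0.5, 0.05, 20, 1.05)
  expect_error(general_hb_locator(mdf, "alpha", c(0.1, 3)), "not found")
})

test_that("the bifurcation curve stays below the single-cell value and tracks alpha + c ~ alpha0", {
  a0 <- single_cell_hb(ht_spec)$parameter_values$alpha
  curve <- trace_hb_curve(ht_spec, seq(0.005, 0.1, length.out = 20), s = 20)
  expect_true(all(curve$feasible))
  expect_true(all(curve$alpha_star < a0))
  # the quasi-steady approximation alpha + c = alpha0 holds to 2 percent
  # at weak coupling and degrades smoothly (to ~8 percent by c = 0.1)
  dev <- abs(curve$alpha_star + curve$coupling - a0) / a0
  expect_true(all(dev[curve$coupling <= 0.026] < 0.02))
  expect_true(all(dev < 0.08))
  expect_true(all(diff(dev) > 0))
  # passes through the worked example point
  i <- which.min(abs(curve$coupling - 0.05))
  expect_equal(curve$alpha_star[i], 0.4742, tolerance = 2e-3)
  expect_true(all(diff(curve$alpha_star) < 0))
})

test_that("the numeric locator finds the segmentation-clock bifurcation", {
  md <- segclock_example_model(nu1 = 0.2, nu_c = 0.1, sigma = 1.05)
  hp <- general_hb_locator(md, "nu1", c(0.2, 0.26), n_scan = 150,
                           guess = rep(0.05, 8))
  expect_gt(hp$parameter_values$nu1, 0.2)
  expect_lt(hp$parameter_values$nu1, 0.26)
  expect_gt(hp$omega_star, 0)
  near <- abs(Re(hp$eigenvalues)) < 1e-7
  expect_identical(sum(near), 2L)
  expect_true(all(Re(hp$eigenvalues[!near]) < 0))
})

test_that("the Hill slope peak location and gap follow the closed forms", {
  pg <- gamma_peak_gap(ht_spec)
  expect_equal(pg$x_M, 0.133764, tolerance = 1e-5)
  expect_gt(pg$gap, 0)  # equilibrium right of the peak for n < 17
  # gamma really is maximised at x_M
  xs <- seq(0.8, 1.2, by = 0.001) * pg$x_M
  expect_equal(xs[which.max(repression_gamma(ht_spec, xs))], pg$x_M,
               tolerance = 2e-3)
  expect_equal(gamma_peak_gap(hill_repression(17, 0.2))$gap, 0)
  expect_error(gamma_peak_gap(hill_repression(7, 0.2)), "n > 8")
  expect_error(gamma_peak_gap(ps_spec), "Hill")
})
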