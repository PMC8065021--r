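#' Characteristic polynomial coefficients
#'
#' Computes the coefficients `b1..bm` of the monic characteristic polynomial
#' `lambda^m + b1 lambda^(m-1) + ... + bm` of a real square matrix by the
#' Faddeev-LeVerrier recurrence. This keeps the coefficients exactly
#' polynomial in the matrix entries (no eigenvalue round-off), which matters
#' because the Hurwitz determinants built from them are differenced to
#' machine precision near a bifurcation.
#'
#' @param J Real square matrix.
#' @return Object of class `char_poly`: numeric vector `b` of length
#'   `m = nrow(J)`.
#' @export
char_coefficients <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), is.numeric(J))
  m <- nrow(J)
  M <- diag(m)
  b <- numeric(m)
  for (k in seq_len(m)) {
    MA <- J %*% M
    b[k] <- -sum(diag(MA)) / k
    M <- MA + b[k] * diag(m)
  }
  structure(b, class = "char_poly")
}

#' Hurwitz determinants and the degenerate Routh-Hurwitz test
#'
#' Builds the Hurwitz matrices `H_i` (entry `(r, c)` is `b_(2c - r)`, with
#' `b_0 = 1` and `b_j = 0` outside `0..m`) and their determinants
#' `D_i = det(H_i)`. The classification implements the degenerate
#' Routh-Hurwitz criterion: all roots in the open left half-plane iff all
#' `D_i > 0` (`stable`); exactly one purely imaginary conjugate pair with
#' all other roots strictly stable iff `b_m > 0`, `D_i > 0` for
#' `i <= m - 2` and `D_(m-1) = 0` (`hopf_candidate`); anything else is
#' `unstable`.
#'
#' @param p A `char_poly` or plain numeric coefficient vector `b1..bm`.
#' @param zero_tol Relative tolerance for declaring `D_(m-1)` zero.
#' @return Object of class `hurwitz_report`: list with `D` (vector of
#'   determinants), logical flags `b_m_positive`,
#'   `all_Di_positive_through_m_minus_2`, `D_m_minus_1_zero`, and
#'   `classification`.
#' @export
hurwitz_determinants <- function(p, zero_tol = 1e-9) {
  b <- as.numeric(p)
  m <- length(b)
  if (m < 2) stop("polynomial degree must be at least 2")
  bb <- c(1, b)  # bb[k + 1] = b_k
  D <- numeric(m)
  for (i in seq_len(m)) {
    H <- matrix(0, i, i)
    for (r in seq_len(i)) for (cl in seq_len(i)) {
      k <- 2L * cl - r
      if (k >= 0 && k <= m) H[r, cl] <- bb[k + 1L]
    }
    D[i] <- det(H)
  }
  dm1_zero <- abs(D[m - 1L]) <= zero_tol * (1 + abs(D[max(m - 2L, 1L)]))
  bm_pos <- b[m] > 0
  head_pos <- all(D[seq_len(max(m - 2L, 0L))] > 0)
  classification <- if (all(D > 0)) "stable"
    else if (bm_pos && head_pos && dm1_zero) "hopf_candidate"
    else "unstable"
  structure(list(D = D,
                 b_m_positive = bm_pos,
                 all_Di_positive_through_m_minus_2 = head_pos,
                 D_m_minus_1_zero = dm1_zero,
                 classification = classification),
            class = "hurwitz_report")
}

#' @export
print.hurwitz_report <- function(x, ...) {
  cat("<hurwitz_report>", x$classification, "\n  D:",
      paste(signif(x$D, 6), collapse = ", "), "\n")
  invisible(x)
}

new_hopf_point <- function(parameter_values, equilibrium, omega_star,
                           crossing_derivative, hurwitz, eigenvalues) {
  structure(list(parameter_values = parameter_values,
                 equilibrium = equilibrium,
                 omega_star = omega_star,
                 crossing_derivative = crossing_derivative,
                 hurwitz = hurwitz,
                 eigenvalues = eigenvalues),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat("<hopf_point>\n  parameters:",
      paste(names(x$parameter_values),
            vapply(x$parameter_values, function(v) format(v, digits = 8), ""),
            sep = "=", collapse = ", "),
      sprintf("\n  omega* = %.8f, crossing derivative = %.4g\n",
              x$omega_star, x$crossing_derivative))
  invisible(x)
}

# eigenvalue-side verification shared by all locators: exactly one
# near-imaginary conjugate pair, everything else strictly stable
.verify_hopf_spectrum <- function(J, re_tol = 1e-7) {
  ev <- eigen(J, only.values = TRUE)$values
  near <- abs(Re(ev)) <= re_tol
  n_imag <- sum(near & Im(ev) > 0)
  ok <- (n_imag == 1) && all(Re(ev[!near]) < -re_tol)
  list(ok = ok, eigenvalues = ev,
       omega = if (n_imag >= 1) max(Im(ev[near])) else NA_real_)
}

#' Single-cell Hopf bifurcation point (closed form)
#'
#' The single-cell system bifurcates at `alpha0 = 8 / gamma(xbar)`. For
#' Hill repression the equilibrium at the bifurcation is
#' `xbar = k_H (8 / (n - 8))^(1/n)`, feasible only for `n > 8` (a
#' necessary and sufficient condition). For protein sequestration,
#' `xbar = (64/63)(A - k_d) - (8/63) sqrt((A - k_d)^2 - 252 A k_d)` (the
#' smaller root, giving the smaller `alpha0`), feasible for
#' `A > (127 + 48 sqrt(7)) k_d`. In either case the Jacobian at the
#' bifurcation is a constant matrix with eigenvalues `+/- sqrt(3) i, -3`,
#' so `omega* = sqrt(3)` for every repression function.
#'
#' @param spec A [repression_spec][repression].
#' @param sigma Optional timescale factor; scales `omega*` and the spectrum.
#' @return A `hopf_point` with fields `parameter_values` (`alpha`),
#'   `equilibrium`, `omega_star`, `crossing_derivative`, `hurwitz`,
#'   `eigenvalues`.
#' @export
single_cell_hb <- function(spec, sigma = 1) {
  stopifnot(inherits(spec, "repression_spec"))
  if (spec$kind == "HT") {
    if (spec$n <= 8)
      stop("infeasible: the single-cell Hill model requires n > 8 for a Hopf bifurcation")
    xbar <- spec$k_H * (8 / (spec$n - 8))^(1 / spec$n)
  } else {
    thr <- (127 + 48 * sqrt(7)) * spec$k_d
    if (spec$A <= thr)
      stop(sprintf("infeasible: protein-sequestration Hopf requires A > (127 + 48*sqrt(7)) k_d = %.6g", thr))
    Am <- spec$A - spec$k_d
    xbar <- 64 / 63 * Am - 8 / 63 * sqrt(Am^2 - 252 * spec$A * spec$k_d)
  }
  g <- repression_gamma(spec, xbar)
  alpha0 <- 8 / g
  # self-consistency alpha0 * f(xbar) = xbar
  sc <- abs(alpha0 * repression_value(spec, xbar) - xbar)
  if (sc > 1e-10 * (1 + xbar))
    stop(sprintf("internal inconsistency: alpha0*f(xbar) - xbar = %.3e", sc))
  model <- single_cell_model(spec, alpha0, sigma)
  eq <- solve_equilibrium(model)
  J <- model_jacobian(model, eq$state)
  hw <- hurwitz_determinants(char_coefficients(J))
  cross <- .crossing_derivative(function(a) {
    md <- update_model(model, alpha = a)
    e <- solve_equilibrium(md)
    hurwitz_determinants(char_coefficients(model_jacobian(md, e$state)))$D[2]
  }, alpha0)
  chk <- .verify_hopf_spectrum(J)
  new_hopf_point(list(alpha = alpha0), eq, sqrt(3) * sigma, cross, hw,
                 chk$eigenvalues)
}

# central-difference derivative of D_(m-1) wrt the bifurcation parameter
.crossing_derivative <- function(Dfun, a, h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(1, abs(a))
  (Dfun(a + h) - Dfun(a - h)) / (2 * h)
}

#' Coupled identical-cell Hopf bifurcation point (closed form)
#'
#' For `N` identical mean-field-coupled cells the characteristic polynomial
#' factors through the synchronous quartic, whose degenerate Routh-Hurwitz
#' condition gives the bifurcation value
#' `alpha* = (1 / 2 gamma) [-(s-1)(s^2+4s+7) + (s+3) sqrt((s^2+3)^2 - 4 s c gamma)]`
#' (the "+" branch; only `s > 1` is supported) and frequency
#' `omega_c* = sqrt(((s^2+3)^2 - 4 s c gamma)^(1/2)/2 - (s^2-3)/2)`.
#' Because `gamma` depends on the equilibrium, `alpha*` is found
#' self-consistently with `(alpha* + c) f(xbar) = xbar` by scanning and
#' root-finding in `xbar`; when two roots exist (possible for protein
#' sequestration) the smaller is returned, giving the smaller `alpha*`.
#'
#' @param spec A [repression_spec][repression].
#' @param coupling Coupling strength `c > 0`.
#' @param s Coupling-signal timescale, must satisfy `s > 1`.
#' @param N Number of cells used for the verification Jacobian.
#' @return A `hopf_point`; `parameter_values` holds `alpha` and `coupling`,
#'   and the reported `omega_star` is the closed form, cross-checked
#'   against the Jacobian spectrum.
#' @export
coupled_identical_hb <- function(spec, coupling, s, N = 2L) {
  stopifnot(inherits(spec, "repression_spec"), coupling > 0)
  if (s <= 1) stop("unsupported parameter: the closed-form locator requires s > 1")
  disc <- function(g) (s^2 + 3)^2 - 4 * s * coupling * g
  astar_of_g <- function(g) {
    d <- disc(g)
    if (d < 0) return(NA_real_)
    (1 / (2 * g)) * (-(s - 1) * (s^2 + 4 * s + 7) + (s + 3) * sqrt(d))
  }
  resid <- function(x) {
    a <- astar_of_g(repression_gamma(spec, x))
    if (is.na(a)) return(NA_real_)
    (a + coupling) * repression_value(spec, x) - x
  }
  # bracket by scanning x; xbar <= alpha* + c is not a priori bounded, so
  # scan a generous multiple of the repression scale
  xmax <- if (spec$kind == "HT") 50 * spec$k_H else 5 * spec$A
  xs <- exp(seq(log(1e-8 * xmax), log(xmax), length.out = 4000))
  rs <- vapply(xs, resid, 0)
  ok <- !is.na(rs)
  sgn <- which(ok[-length(ok)] & ok[-1] &
                 rs[-length(rs)] * rs[-1] < 0)
  if (!length(sgn))
    stop("no self-consistent equilibrium found: no sign change of the fixed-point residual")
  roots <- vapply(sgn, function(i)
    stats::uniroot(resid, c(xs[i], xs[i + 1]), tol = 1e-14)$root, 0)
  xbar <- min(roots)  # smaller root -> smaller alpha*
  g <- repression_gamma(spec, xbar)
  if (g >= 8 * (s + 1)^3 / (coupling * s * (s + 3)^2))
    stop("infeasible: gamma exceeds 8(s+1)^3 / (c s (s+3)^2), so alpha* <= 0")
  astar <- astar_of_g(g)
  omega <- sqrt(0.5 * (sqrt(disc(g)) - (s^2 - 3)))
  model <- coupled_identical_model(spec, astar, coupling, s, N)
  eq <- solve_equilibrium(model)
  J <- model_jacobian(model, eq$state)
  hw <- hurwitz_determinants(char_coefficients(J))
  chk <- .verify_hopf_spectrum(J, re_tol = 1e-6)
  if (!is.na(chk$omega) && abs(chk$omega - omega) > 1e-6)
    warning(sprintf("closed-form omega %.8f vs spectral %.8f disagree",
                    omega, chk$omega))
  cross <- .crossing_derivative(function(a) {
    b <- synchronous_quartic(spec, a, coupling, s)
    b[1] * b[2] * b[3] - b[3]^2 - b[1]^2 * b[4]
  }, astar)
  new_hopf_point(list(alpha = astar, coupling = coupling), eq, omega,
                 cross, hw, chk$eigenvalues)
}

#' Synchronous-subsystem quartic coefficients
#'
#' Coefficients `(b1, b2, b3, b4)` of the quartic factor of the identical
#' coupled-cell characteristic polynomial carried by the synchronous
#' (diagonal) subspace: `b1 = s + 3`, `b2 = 3(s + 1)`,
#' `b3 = alpha gamma + 3 s + 1`, `b4 = s (alpha gamma + 1) + c s gamma`.
#' The complementary (anti-phase) factor has the same `b1..b3` and
#' `b4 = s (alpha gamma + 1)`; request it with `branch = "-"`.
#'
#' @param spec A [repression_spec][repression].
#' @param alpha,coupling,s Model parameters.
#' @param branch `"+"` (synchronous) or `"-"` (anti-phase).
#' @param gamma Optional slope magnitude; defaults to the value at the
#'   self-consistent equilibrium of `(alpha + c) f(x) = x`.
#' @return Numeric vector `b1..b4`.
#' @export
synchronous_quartic <- function(spec, alpha, coupling, s, branch = "+",
                                gamma = NULL) {
  if (is.null(gamma)) {
    x <- .scalar_eq_root(spec, alpha + coupling)
    gamma <- repression_gamma(spec, x)
  }
  b4 <- s * (alpha * gamma + 1)
  if (branch == "+") b4 <- b4 + coupling * s * gamma
  c(s + 3, 3 * (s + 1), alpha * gamma + 3 * s + 1, b4)
}

#' Numeric Hopf-bifurcation locator via the degenerate Routh-Hurwitz test
#'
#' For models without a closed-form bifurcation value (nonidentical cells,
#' segmentation clock), finds the value of a chosen parameter at which the
#' second-to-last Hurwitz determinant `D_(m-1)` of the equilibrium
#' linearization crosses zero from above. The equilibrium is re-solved at
#' every evaluation. After root-finding, the remaining degenerate
#' Routh-Hurwitz side conditions and a nonzero crossing derivative are
#' verified, and the frequency is read off the Jacobian's near-imaginary
#' eigenvalue pair.
#'
#' @param model A `cell_model` (any value of the bifurcation parameter).
#' @param param Name of the bifurcation parameter (e.g. `"alpha"`, `"nu1"`).
#' @param bracket Length-2 numeric search interval.
#' @param n_scan Grid points used to bracket the first sign change.
#' @param guess Optional equilibrium seed (passed to [solve_equilibrium()]).
#' @return A `hopf_point`.
#' @export
general_hb_locator <- function(model, param, bracket, n_scan = 40,
                               guess = NULL) {
  stopifnot(inherits(model, "cell_model"), length(bracket) == 2,
            bracket[1] < bracket[2])
  warm <- guess
  Dm1 <- function(a) {
    md <- do.call(update_model, stats::setNames(list(model, a), c("model", param)))
    eq <- solve_equilibrium(md, guess = warm)
    warm <<- eq$state
    b <- char_coefficients(model_jacobian(md, eq$state))
    hurwitz_determinants(b)$D[md$m - 1L]
  }
  grid <- seq(bracket[1], bracket[2], length.out = n_scan + 1)
  vals <- vapply(grid, Dm1, 0)
  # first crossing from positive to negative (D_(m-1) decreasing through 0)
  idx <- which(vals[-length(vals)] > 0 & vals[-1] < 0)
  if (!length(idx)) {
    idx <- which(vals[-length(vals)] * vals[-1] < 0)
    if (!length(idx))
      stop("not found: D_(m-1) has no sign change in the bracket")
  }
  i <- idx[1]
  astar <- stats::uniroot(Dm1, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  md <- do.call(update_model, stats::setNames(list(model, astar), c("model", param)))
  eq <- solve_equilibrium(md, guess = warm)
  J <- model_jacobian(md, eq$state)
  hw <- hurwitz_determinants(char_coefficients(J))
  if (!(hw$b_m_positive && hw$all_Di_positive_through_m_minus_2))
    stop("degenerate candidate: D_(m-1) vanishes but the remaining Routh-Hurwitz side conditions fail")
  cross <- .crossing_derivative(Dm1, astar)
  if (abs(cross) < 1e-12)
    stop("degenerate candidate: crossing derivative of D_(m-1) is zero")
  chk <- .verify_hopf_spectrum(J, re_tol = 1e-6)
  if (!chk$ok)
    stop("degenerate candidate: spectrum is not a simple Hopf configuration")
  pv <- stats::setNames(list(astar), param)
  pv$coupling <- model$pars$coupling %||% model$pars$nu_c
  new_hopf_point(pv, eq, chk$omega, cross, hw, chk$eigenvalues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trace a Hopf-bifurcation curve in the (coupling, alpha) plane
#'
#' Natural-parameter continuation over an increasing coupling grid: for
#' identical cells each point uses the closed-form locator; for other
#' families the numeric locator is used with a bracket seeded from the
#' previous solution. A grid point whose solve fails is retried once with a
#' bisected coupling step; if that also fails the point is skipped with a
#' warning (partial curve).
#'
#' @param spec A [repression_spec][repression] (identical-cell family), or a
#'   `cell_model` template for the numeric locator.
#' @param coupling_grid Increasing vector of coupling strengths.
#' @param s Coupling timescale (identical-cell family).
#' @param param Bifurcation parameter name for the numeric path.
#' @param bracket_width Half-width of the numeric locator's alpha bracket
#'   around the previous solution.
#' @return A data.frame with columns `coupling, alpha_star, x_bar, gamma,
#'   omega_star, crossing_derivative, feasible`.
#' @export
trace_hb_curve <- function(spec, coupling_grid, s = NULL, param = "alpha",
                           bracket_width = 0.08) {
  stopifnot(all(diff(coupling_grid) > 0))
  rows <- vector("list", length(coupling_grid))
  if (inherits(spec, "repression_spec")) {
    stopifnot(!is.null(s))
    for (k in seq_along(coupling_grid)) {
      cc <- coupling_grid[k]
      hp <- tryCatch(coupled_identical_hb(spec, cc, s), error = identity)
      if (inherits(hp, "error")) {
        warning(sprintf("coupling %.6g infeasible: %s", cc, conditionMessage(hp)))
        rows[[k]] <- data.frame(coupling = cc, alpha_star = NA, x_bar = NA,
                                gamma = NA, omega_star = NA,
                                crossing_derivative = NA, feasible = FALSE)
        next
      }
      xb <- hp$equilibrium$state[3]
      rows[[k]] <- data.frame(coupling = cc, alpha_star = hp$parameter_values$alpha,
                              x_bar = xb, gamma = repression_gamma(spec, xb),
                              omega_star = hp$omega_star,
                              crossing_derivative = hp$crossing_derivative,
                              feasible = TRUE)
    }
  } else if (inherits(spec, "cell_model")) {
    model <- spec
    prev <- model$pars[[param]]
    for (k in seq_along(coupling_grid)) {
      cc <- coupling_grid[k]
      solve_at <- function(cpl, center) {
        mdl <- update_model(model, coupling = cpl)
        general_hb_locator(mdl, param,
                           c(center - bracket_width, center + bracket_width))
      }
      hp <- tryCatch(solve_at(cc, prev), error = identity)
      if (inherits(hp, "error") && k > 1) {
        # bisect the coupling step once to re-seed, then retry
        mid <- (coupling_grid[k - 1] + cc) / 2
        hp_mid <- tryCatch(solve_at(mid, prev), error = identity)
        if (!inherits(hp_mid, "error"))
          hp <- tryCatch(solve_at(cc, hp_mid$parameter_values[[param]]),
                         error = identity)
      }
      if (inherits(hp, "error")) {
        warning(sprintf("coupling %.6g: branch lost (%s)", cc,
                        conditionMessage(hp)))
        rows[[k]] <- data.frame(coupling = cc, alpha_star = NA, x_bar = NA,
                                gamma = NA, omega_star = NA,
                                crossing_derivative = NA, feasible = FALSE)
        next
      }
      prev <- hp$parameter_values[[param]]
      xb <- hp$equilibrium$state[3]
      g <- if (!is.null(model$spec)) repression_gamma(model$spec, xb) else NA
      rows[[k]] <- data.frame(coupling = cc, alpha_star = prev, x_bar = xb,
                              gamma = g, omega_star = hp$omega_star,
                              crossing_derivative = hp$crossing_derivative,
                              feasible = TRUE)
    }
  } else stop("'spec' must be a repression_spec or a cell_model")
  do.call(rbind, rows)
}

#' Location and distance of the Hill slope maximum
#'
#' The Hill slope magnitude `gamma(x)` peaks at
#' `x_M = k_H ((n - 1) / (n + 1))^(1/n)`. The signed gap
#' `xbar^n - x_M^n = -k_H^n n (n - 17) / ((n - 8)(n + 1))` measures how far
#' the single-cell bifurcation equilibrium sits from that peak: positive
#' (equilibrium to the right) for `8 < n < 17`, zero at `n = 17`.
#'
#' @param spec A Hill-type [repression_spec][repression] with `n > 8`.
#' @return List with `x_M` and `gap` (`= xbar^n - x_M^n`).
#' @export
gamma_peak_gap <- function(spec) {
  stopifnot(inherits(spec, "repression_spec"))
  if (spec$kind != "HT") stop("gamma_peak_gap applies to Hill-type repression only")
  n <- spec$n; k <- spec$k_H
  if (n <= 8) stop("infeasible: requires n > 8")
  x_M <- k * ((n - 1) / (n + 1))^(1 / n)
  gap <- -k^n * n * (n - 17) / ((n - 8) * (n + 1))
  list(x_M = x_M, gap = gap)
}
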