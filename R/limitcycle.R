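#' Integrate a model with a high-accuracy adaptive solver
#'
#' Thin wrapper around [deSolve::ode()] (`lsoda`) at tight tolerances
#' (defaults `rtol = 1e-12`, `atol = 1e-14`), returning the trajectory
#' together with the time derivative at every output point so that event
#' times can later be refined by cubic Hermite interpolation.
#'
#' @param model A `cell_model`.
#' @param x0 Nonnegative initial state of length `model$m`.
#' @param t_end End time (nondimensional tau units).
#' @param dt Output sampling interval.
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `trajectory`: list with `time`, `state`
#'   (matrix, one column per component) and `deriv` (same shape).
#' @export
integrate_model <- function(model, x0, t_end, dt = 0.01,
                            rtol = 1e-12, atol = 1e-14) {
  stopifnot(inherits(model, "cell_model"), t_end > 0)
  if (length(x0) != model$m) stop("initial state dimension must be ", model$m)
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  f <- function(t, y, parms) list(model$rhs(y))
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y = as.numeric(x0), times = times, func = f,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integrator failure; last accepted time %.6g",
                 out[nrow(out), 1]))
  st <- unname(out[, -1, drop = FALSE])
  dv <- t(apply(st, 1, model$rhs))
  structure(list(time = out[, 1], state = st, deriv = dv),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points, t in [%g, %g], %d components\n",
              length(x$time), min(x$time), max(x$time), ncol(x$state)))
  invisible(x)
}

# upward crossing times of column `comp` through `level`, refined by cubic
# Hermite interpolation using the stored derivatives
.crossing_times <- function(traj, comp, level) {
  g <- traj$state[, comp] - level
  dg <- traj$deriv[, comp]
  tt <- traj$time
  idx <- which(g[-length(g)] < 0 & g[-1] >= 0)
  vapply(idx, function(i) {
    h <- tt[i + 1] - tt[i]
    p0 <- g[i]; p1 <- g[i + 1]; m0 <- dg[i] * h; m1 <- dg[i + 1] * h
    hermite <- function(u)
      (2 * u^3 - 3 * u^2 + 1) * p0 + (u^3 - 2 * u^2 + u) * m0 +
      (-2 * u^3 + 3 * u^2) * p1 + (u^3 - u^2) * m1
    tt[i] + h * stats::uniroot(hermite, c(0, 1), tol = 1e-15)$root
  }, 0)
}

# peak time of column `comp` within the final full cycle: locate the
# downward zero of the stored derivative and refine it on the cubic
# Hermite interpolant of the state (whose derivative is quadratic in the
# cell, solved in closed form via uniroot on the Hermite derivative)
.peak_time <- function(traj, comp, t_from, t_to) {
  sel <- which(traj$time >= t_from & traj$time <= t_to)
  x <- traj$state[sel, comp]
  d <- traj$deriv[sel, comp]
  tt <- traj$time[sel]
  i <- which.max(x)
  if (i == 1 || i == length(sel)) return(tt[i])
  # bracket the derivative sign change nearest the discrete maximum
  j <- if (d[i] >= 0) i else i - 1
  if (j < 1 || j >= length(sel) || !(d[j] >= 0 && d[j + 1] < 0)) return(tt[i])
  h <- tt[j + 1] - tt[j]
  p0 <- x[j]; p1 <- x[j + 1]; m0 <- d[j] * h; m1 <- d[j + 1] * h
  dH <- function(u)  # derivative of the cubic Hermite interpolant
    (6 * u^2 - 6 * u) * p0 + (3 * u^2 - 4 * u + 1) * m0 +
    (-6 * u^2 + 6 * u) * p1 + (3 * u^2 - 2 * u) * m1
  tt[j] + h * stats::uniroot(dH, c(0, 1), tol = 1e-15)$root
}

#' Detect a stable limit cycle and summarise it
#'
#' Integrates in windows until successive period estimates stabilise, then
#' reports period, frequency, per-component amplitude and (for multi-cell
#' models) the phase differences between corresponding components of
#' different cells.
#'
#' The Poincare section is the repressor component `x3` of the first cell
#' crossing its trailing-window mean upward; crossing times are refined by
#' cubic Hermite interpolation of the dense output (the integrator supplies
#' exact derivatives at the sample points). The period estimate of a window
#' is the last full return time; the cycle is accepted when the relative
#' change between the last two window estimates falls below
#' `period_rtol`.
#'
#' @param model A `cell_model` in its oscillatory regime.
#' @param x0 Initial state; defaults to the equilibrium with each component
#'   perturbed by +1 percent.
#' @param transient Time integrated and discarded before measuring.
#' @param window Window length per period-estimate round.
#' @param max_time Total time budget; exceeding it without convergence is
#'   an error (no stable cycle found at the requested tolerance).
#' @param period_rtol Relative tolerance on successive period estimates.
#' @param dt,rtol,atol Passed to [integrate_model()].
#' @return Object of class `cycle_summary`: `period`, `frequency`
#'   (`= 2 pi / period`), `amplitude` (per component, half peak-to-trough
#'   of the final cycle), `phase_differences` (per paired component, first
#'   cell minus later cell peak time, in time units), and
#'   `convergence_metric`.
#' @export
extract_cycle <- function(model, x0 = NULL, transient = 100, window = 50,
                          max_time = 5000, period_rtol = 1e-9, dt = 0.01,
                          rtol = 1e-12, atol = 1e-14) {
  stopifnot(inherits(model, "cell_model"))
  section_comp <- 3L  # repressor of the first cell, present in every model
  if (is.null(x0)) {
    eq <- solve_equilibrium(model)
    x0 <- eq$state * 1.01
  }
  if (transient > 0) {
    tr <- integrate_model(model, x0, transient, dt = dt, rtol = rtol, atol = atol)
    x0 <- tr$state[nrow(tr$state), ]
  }
  t_used <- transient
  level <- NA_real_   # section level fixed after the first window
  cross <- numeric(0) # global crossing times
  acc_prev <- NA_real_
  per <- NA_real_
  conv <- NA_real_
  traj <- NULL
  t_offset <- 0
  repeat {
    traj <- integrate_model(model, x0, window, dt = dt, rtol = rtol, atol = atol)
    x0 <- traj$state[nrow(traj$state), ]
    t_used <- t_used + window
    if (is.na(level)) level <- mean(traj$state[, section_comp])
    cr <- .crossing_times(traj, section_comp, level)
    cross <- c(cross, t_offset + cr)
    t_offset <- t_offset + window
    p <- diff(cross)
    if (length(p) >= 3) {
      nh <- length(p)
      # the approach to the cycle decays geometrically per return (single
      # dominant Floquet mode), so the limit is recovered by fitting the
      # tail of the return-time sequence to p_n = T + A r^n; skipped at
      # the round-off floor where the increments are pure noise
      per <- p[nh]
      d <- diff(p[max(1, nh - 12):nh])
      nd <- length(d)
      if (abs(d[nd]) > 1e-11 * per && nd >= 2) {
        rat <- d[-1] / d[-nd]
        rat <- rat[is.finite(rat) & rat > 0 & rat < 1]
        if (length(rat) >= 2) {
          r <- exp(mean(log(rat)))
          per <- p[nh] + d[nd] * r / (1 - r)
        } else {
          den <- p[nh] - 2 * p[nh - 1] + p[nh - 2]
          if (abs(den) > 4e-12 * per)
            per <- p[nh] - (p[nh] - p[nh - 1])^2 / den
        }
      }
      if (!is.na(acc_prev)) {
        conv <- abs(per - acc_prev) / per
        if (conv <= period_rtol) break
      }
      acc_prev <- per
    }
    if (t_used >= max_time) {
      if (is.na(per))
        stop("no cycle detected: no section crossings (stable equilibrium or wrong section)")
      stop(sprintf(paste0("period estimates did not converge within the time budget ",
                          "(last %.10g, relative change %.3g)"), per, conv))
    }
  }
  # a full cycle (not the very last, so that half-period-shifted peak
  # searches stay inside the window) for amplitudes and phases
  cr <- .crossing_times(traj, section_comp, level)
  nc <- length(cr)
  t1 <- cr[max(nc - 2, 1)]; t2 <- cr[max(nc - 1, 2)]
  Tloc <- t2 - t1
  sel <- traj$time >= t1 & traj$time <= t2
  amp <- apply(traj$state[sel, , drop = FALSE], 2,
               function(v) (max(v) - min(v)) / 2)
  phase <- NULL
  n_cells <- model$m %/% 4L
  if (model$m %% 4L == 0L && n_cells >= 2) {
    phase <- numeric(4L * (n_cells - 1L))
    nmv <- character(length(phase))
    k <- 0L
    for (cell in 2:n_cells) for (comp in 1:4) {
      k <- k + 1L
      p1 <- .peak_time(traj, comp, t1, t2)
      # nearest corresponding peak of the other cell, one local period
      # centred on p1: no modular wrap-around needed
      p2 <- .peak_time(traj, 4L * (cell - 1L) + comp,
                       p1 - Tloc / 2, p1 + Tloc / 2)
      phase[k] <- p2 - p1
      nmv[k] <- sprintf("cell%d_x%d", cell, comp)
    }
    names(phase) <- nmv
  }
  structure(list(period = per, frequency = 2 * pi / per, amplitude = amp,
                 phase_differences = phase, convergence_metric = conv,
                 time_used = t_used, final_state = x0),
            class = "cycle_summary")
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat(sprintf("<cycle_summary> T = %.10g, omega = %.8g (converged to %.2g)\n",
              x$period, x$frequency, x$convergence_metric))
  cat("  amplitude:", paste(signif(x$amplitude, 6), collapse = ", "), "\n")
  if (!is.null(x$phase_differences))
    cat("  phase differences:",
        paste(names(x$phase_differences),
              signif(x$phase_differences, 6), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sweep a parameter and record cycle frequency and amplitude
#'
#' One [extract_cycle()] call per grid value, warm-started from the final
#' state of the previous cycle. Grid points where no cycle is found are
#' kept in the table and flagged rather than dropped.
#'
#' @param model A `cell_model` template.
#' @param param Parameter name to sweep (e.g. `"alpha"` or `"coupling"`).
#' @param grid Parameter values (visited in order).
#' @param ... Passed to [extract_cycle()].
#' @return data.frame with columns `param` value, `omega`, `period`,
#'   amplitude of the first component, and `converged`.
#' @export
frequency_sweep <- function(model, param, grid, ...) {
  stopifnot(inherits(model, "cell_model"))
  x0 <- NULL
  rows <- lapply(grid, function(v) {
    md <- do.call(update_model, stats::setNames(list(model, v), c("model", param)))
    cs <- tryCatch(extract_cycle(md, x0 = x0, ...), error = identity)
    if (inherits(cs, "error"))
      return(data.frame(param = v, omega = NA_real_, period = NA_real_,
                        amplitude = NA_real_, converged = FALSE))
    x0 <<- cs$final_state
    data.frame(param = v, omega = cs$frequency, period = cs$period,
               amplitude = cs$amplitude[1], converged = TRUE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  out
}

#' Average frequency and average period of individual cells
#'
#' Arithmetic means `omega_Ave = mean(omega_i)` and `T_Ave = mean(T_i)`.
#' Both are returned because they are not equivalent: the period of the
#' average frequency is the harmonic, not arithmetic, mean of the periods.
#'
#' @param cycles List of `cycle_summary` objects (one per isolated cell).
#' @return List with `omega_ave` and `T_ave`.
#' @export
average_frequency <- function(cycles) {
  if (!length(cycles)) stop("'cycles' must be a nonempty list")
  stopifnot(all(vapply(cycles, inherits, TRUE, "cycle_summary")))
  list(omega_ave = mean(vapply(cycles, `[[`, 0, "frequency")),
       T_ave = mean(vapply(cycles, `[[`, 0, "period")))
}

#' Coupling strength at which collective equals average frequency
#'
#' Finds the root of `c -> omega_c(c) - omega_Ave` by bracketed
#' root-finding over [extract_cycle()] evaluations of the coupled model,
#' with `omega_Ave` computed once from the isolated cells at the same
#' `alpha`.
#'
#' @param model A coupled `cell_model` (its `alpha` is held fixed).
#' @param c_bracket Length-2 coupling interval with a sign change.
#' @param omega_ave Average frequency of the isolated cells; computed from
#'   the decoupled single-cell models when omitted.
#' @param tol Root tolerance on the coupling strength.
#' @param ... Passed to [extract_cycle()].
#' @return List with `c_match`, `omega_ave` and the residual at the root.
#' @export
find_matching_coupling <- function(model, c_bracket, omega_ave = NULL,
                                   tol = 1e-4, ...) {
  stopifnot(inherits(model, "cell_model"), length(c_bracket) == 2)
  if (is.null(omega_ave)) {
    sig <- model$pars$sigma %||% 1
    w1 <- extract_cycle(single_cell_model(model$spec, model$pars$alpha), ...)$frequency
    # a sigma-scaled cell oscillates at sigma times the base frequency
    omega_ave <- mean(c(w1, sig * w1))
  }
  x0 <- NULL
  fres <- function(cc) {
    cs <- extract_cycle(update_model(model, coupling = cc), x0 = x0, ...)
    x0 <<- cs$final_state
    cs$frequency - omega_ave
  }
  lo <- fres(c_bracket[1]); hi <- fres(c_bracket[2])
  if (lo * hi > 0)
    stop(sprintf("not found: omega_c - omega_Ave has the same sign at both ends (%.6g, %.6g)",
                 lo, hi))
  r <- stats::uniroot(fres, c_bracket, f.lower = lo, f.upper = hi, tol = tol)
  list(c_match = r$root, omega_ave = omega_ave, residual = r$f.root)
}
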