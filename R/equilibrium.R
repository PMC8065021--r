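#' Solve for the positive equilibrium of a model
#'
#' Equilibrium location is model-specific:
#'
#' * `single_cell`: the unique positive root of `alpha f(x) = x`, found by
#'   Brent's method on the bracket `(0, alpha]` (guaranteed because
#'   `f <= 1`), then polished by Newton steps.
#' * `coupled_identical`: the unique positive root of
#'   `(alpha + c) f(x) = x`; the full state is assembled per cell as
#'   `(x, x, x, f(x))`.
#' * `coupled_nonidentical`: a damped Newton iteration on the two coupled
#'   scalar conditions in `(x3, y3)` (the remaining components follow from
#'   `x1 = x2 = x3`, `x4 = f(x3)` and likewise for `y`), initialised from
#'   the decoupled equilibria at the same `alpha`.
#' * `segclock_pair`: a damped 8-dimensional Newton iteration from a
#'   user-supplied seed.
#'
#' @param model A `cell_model`.
#' @param guess Optional starting state (required strategy only for the
#'   segmentation-clock pair, where no closed-form reduction exists;
#'   default `rep(0.5, 8)`).
#' @param tol Root tolerance passed to the scalar solver.
#' @return An object of class `equilibrium`: list with `state` (length
#'   `model$m`), `residual` (max-norm of the rhs at the state) and `pars`.
#' @export
solve_equilibrium <- function(model, guess = NULL, tol = 1e-13) {
  stopifnot(inherits(model, "cell_model"))
  state <- switch(model$name,
    single_cell = {
      x <- .scalar_eq_root(model$spec, model$pars$alpha, tol)
      rep(x, 3)
    },
    coupled_identical = {
      ac <- model$pars$alpha + model$pars$coupling
      x <- .scalar_eq_root(model$spec, ac, tol)
      rep(c(x, x, x, repression_value(model$spec, x)), model$pars$N)
    },
    coupled_nonidentical = .nonidentical_eq(model, tol),
    segclock_pair = .newton_eq(model, if (is.null(guess)) rep(0.5, 8) else guess),
    # other (user-supplied) families: plain damped Newton, no positivity
    .newton_eq(model, if (is.null(guess)) rep(0.5, model$m) else guess,
               positive = FALSE)
  )
  res <- max(abs(model_rhs(model, state)))
  if (res > 1e-10 * (1 + max(abs(state))))
    stop(sprintf("equilibrium solver did not converge: residual %.3e", res))
  structure(list(state = state, residual = res, pars = model$pars),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium> state:", paste(signif(x$state, 8), collapse = ", "),
      sprintf("\n  residual %.2e\n", x$residual))
  invisible(x)
}

# unique positive root of a*f(x) = x on (0, a]; f <= 1 guarantees the bracket
.scalar_eq_root <- function(spec, a, tol = 1e-13) {
  h <- function(x) a * repression_value(spec, x) - x
  x <- stats::uniroot(h, c(1e-14, a * (1 + 1e-12)), tol = tol)$root
  # Newton polish (gamma = -f')
  for (i in 1:3) {
    d <- -a * repression_gamma(spec, x) - 1
    x <- x - h(x) / d
  }
  x
}

# two-cell heterogeneous equilibrium: damped Newton on the (x3, y3) system
.nonidentical_eq <- function(model, tol = 1e-13) {
  spec <- model$spec; p <- model$pars
  a <- p$alpha; cc <- p$coupling; sig <- p$sigma
  F <- function(v) {
    fx <- repression_value(spec, v[1]); fy <- repression_value(spec, v[2])
    c(a * fx - v[1] + cc / 2 * (fx + fy),
      sig * (a * fy - v[2]) + cc / 2 * (fx + fy))
  }
  Jf <- function(v) {
    gx <- -repression_gamma(spec, v[1]); gy <- -repression_gamma(spec, v[2])
    matrix(c((a + cc / 2) * gx - 1, cc / 2 * gy,
             cc / 2 * gx, sig * (a * gy - 1) + cc / 2 * gy),
           2, 2, byrow = TRUE)
  }
  x0 <- .scalar_eq_root(spec, a, tol)
  v <- c(x0, x0)
  for (it in 1:200) {
    fv <- F(v)
    if (max(abs(fv)) < 1e-14 * (1 + max(abs(v)))) break
    dv <- solve(Jf(v), -fv)
    lam <- 1
    while (any(v + lam * dv <= 0) && lam > 1e-8) lam <- lam / 2
    v <- v + lam * dv
    if (max(abs(dv)) < 1e-15) break
  }
  c(v[1], v[1], v[1], repression_value(spec, v[1]),
    v[2], v[2], v[2], repression_value(spec, v[2]))
}

# generic damped Newton using the analytic Jacobian
.newton_eq <- function(model, x0, maxit = 300, positive = TRUE) {
  x <- as.numeric(x0)
  for (it in seq_len(maxit)) {
    fx <- model_rhs(model, x)
    nf <- max(abs(fx))
    if (nf < 1e-13 * (1 + max(abs(x)))) break
    dx <- solve(model_jacobian(model, x), -fx)
    lam <- 1
    repeat {
      xn <- x + lam * dx
      if ((!positive || all(xn > 0)) &&
          max(abs(model_rhs(model, xn))) <= nf * (1 - 0.25 * lam) + 1e-15)
        break
      lam <- lam / 2
      if (lam < 1e-10) { xn <- x + lam * dx; break }
    }
    x <- xn
  }
  x
}
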