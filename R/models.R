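#' ODE model systems for genetic negative-feedback oscillators
#'
#' Constructors for the four autonomous systems analysed by the package, all
#' in nondimensional time tau (equal degradation rates scaled to 1):
#'
#' * [single_cell_model()] -- the 3-variable mRNA/protein/repressor loop
#'   `x1' = alpha f(x3) - x1, x2' = x1 - x2, x3' = x2 - x3`, optionally
#'   multiplied through by a timescale factor `sigma` (a cell running
#'   `sigma` times faster).
#' * [coupled_identical_model()] -- `N` identical 4-variable cells
#'   (states `x1..x4` per cell, `x4` the released coupling signal) coupled
#'   through the mean field `(c/N) sum x4_j` with strength `c` and signal
#'   timescale `s`.
#' * [coupled_nonidentical_model()] -- two cells, the second scaled by
#'   `sigma`, coupled the same way (an 8-variable system).
#' * [segclock_model()] -- a pair of 4-variable zebrafish segmentation-clock
#'   cells with Michaelis-Menten degradation, Hill repression and
#'   signal-mediated coupling of strength `nu_c`.
#'
#' Each model carries its right-hand side and a hand-coded analytic Jacobian;
#' the two are cross-validated against finite differences in the test suite.
#'
#' @param spec A [repression_spec][repression] (Hill-type or
#'   protein-sequestration).
#' @param alpha Ratio of production to degradation rates; the bifurcation
#'   parameter.
#' @param sigma Timescale scaling of (the second) cell; `sigma = 1` gives
#'   identical cells.
#' @param coupling Mean-field coupling strength `c >= 0`.
#' @param s Timescale of the intercellular coupling signal (`s > 0`).
#' @param N Number of identical cells (default 2).
#' @return An object of class `cell_model` with fields `name`, `m`
#'   (dimension), `pars`, `spec`, and functions `rhs(state)`, `jac(state)`.
#' @name models
NULL

new_cell_model <- function(name, m, pars, spec, rhs, jac,
                           constructor, args, nl = NULL) {
  structure(list(name = name, m = m, pars = pars, spec = spec,
                 rhs = rhs, jac = jac, nl = nl,
                 constructor = constructor, args = args),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model '%s'> dimension %d\n", x$name, x$m))
  cat("  parameters:", paste(names(x$pars),
                             vapply(x$pars, format, ""), sep = "=",
                             collapse = ", "), "\n")
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}

#' @rdname models
#' @export
single_cell_model <- function(spec, alpha, sigma = 1) {
  stopifnot(inherits(spec, "repression_spec"), alpha > 0, sigma > 0)
  rhs <- function(state) {
    sigma * c(alpha * repression_value(spec, state[3]) - state[1],
              state[1] - state[2],
              state[2] - state[3])
  }
  jac <- function(state) {
    g <- repression_gamma(spec, state[3])
    sigma * matrix(c(-1, 0, -alpha * g,
                     1, -1, 0,
                     0, 1, -1), 3, 3, byrow = TRUE)
  }
  # nonlinearity enters only through f(x3) in row 1
  nl <- list(list(j = 3L, w = c(sigma * alpha, 0, 0)))
  new_cell_model("single_cell", 3L,
                 list(alpha = alpha, sigma = sigma), spec, rhs, jac,
                 "single_cell_model",
                 list(spec = spec, alpha = alpha, sigma = sigma), nl)
}

#' @rdname models
#' @export
coupled_identical_model <- function(spec, alpha, coupling, s, N = 2L) {
  stopifnot(inherits(spec, "repression_spec"), alpha > 0, coupling >= 0,
            s > 0, N >= 1)
  N <- as.integer(N)
  m <- 4L * N
  i4 <- function(i) 4L * (i - 1L)
  rhs <- function(state) {
    if (length(state) != m) stop("state dimension must be ", m)
    vbar <- mean(state[i4(seq_len(N)) + 4L])
    out <- numeric(m)
    for (i in seq_len(N)) {
      o <- i4(i)
      fx <- repression_value(spec, state[o + 3L])
      out[o + 1L] <- alpha * fx - state[o + 1L] + coupling * vbar
      out[o + 2L] <- state[o + 1L] - state[o + 2L]
      out[o + 3L] <- state[o + 2L] - state[o + 3L]
      out[o + 4L] <- s * (fx - state[o + 4L])
    }
    out
  }
  jac <- function(state) {
    if (length(state) != m) stop("state dimension must be ", m)
    J <- matrix(0, m, m)
    for (i in seq_len(N)) {
      o <- i4(i)
      g <- repression_gamma(spec, state[o + 3L])
      J[o + 1L, o + 1L] <- -1
      J[o + 1L, o + 3L] <- -alpha * g
      J[o + 2L, o + 1L] <- 1; J[o + 2L, o + 2L] <- -1
      J[o + 3L, o + 2L] <- 1; J[o + 3L, o + 3L] <- -1
      J[o + 4L, o + 3L] <- -s * g
      J[o + 4L, o + 4L] <- -s
      for (j in seq_len(N))
        J[o + 1L, i4(j) + 4L] <- J[o + 1L, i4(j) + 4L] + coupling / N
    }
    J
  }
  nl <- lapply(seq_len(N), function(i) {
    w <- numeric(m)
    w[i4(i) + 1L] <- alpha
    w[i4(i) + 4L] <- s
    list(j = i4(i) + 3L, w = w)
  })
  new_cell_model("coupled_identical", m,
                 list(alpha = alpha, coupling = coupling, s = s, N = N),
                 spec, rhs, jac, "coupled_identical_model",
                 list(spec = spec, alpha = alpha, coupling = coupling,
                      s = s, N = N), nl)
}

#' @rdname models
#' @export
coupled_nonidentical_model <- function(spec, alpha, coupling, s, sigma) {
  stopifnot(inherits(spec, "repression_spec"), alpha > 0, coupling >= 0,
            s > 0, sigma > 0)
  rhs <- function(state) {
    if (length(state) != 8L) stop("state dimension must be 8")
    fx <- repression_value(spec, state[3]); fy <- repression_value(spec, state[7])
    cpl <- coupling / 2 * (state[4] + state[8])
    c(alpha * fx - state[1] + cpl,
      state[1] - state[2],
      state[2] - state[3],
      s * (fx - state[4]),
      sigma * (alpha * fy - state[5]) + cpl,
      sigma * (state[5] - state[6]),
      sigma * (state[6] - state[7]),
      s * (fy - state[8]))
  }
  jac <- function(state) {
    if (length(state) != 8L) stop("state dimension must be 8")
    g <- repression_gamma(spec, state[3])
    gt <- repression_gamma(spec, state[7])
    J <- matrix(0, 8, 8)
    J[1, 1] <- -1; J[1, 3] <- -alpha * g
    J[1, 4] <- coupling / 2; J[1, 8] <- coupling / 2
    J[2, 1] <- 1; J[2, 2] <- -1
    J[3, 2] <- 1; J[3, 3] <- -1
    J[4, 3] <- -s * g; J[4, 4] <- -s
    J[5, 5] <- -sigma; J[5, 7] <- -sigma * alpha * gt
    J[5, 4] <- coupling / 2; J[5, 8] <- coupling / 2
    J[6, 5] <- sigma; J[6, 6] <- -sigma
    J[7, 6] <- sigma; J[7, 7] <- -sigma
    J[8, 7] <- -s * gt; J[8, 8] <- -s
    J
  }
  nl <- list(list(j = 3L, w = c(alpha, 0, 0, s, 0, 0, 0, 0)),
             list(j = 7L, w = c(0, 0, 0, 0, sigma * alpha, 0, 0, s)))
  new_cell_model("coupled_nonidentical", 8L,
                 list(alpha = alpha, coupling = coupling, s = s,
                      sigma = sigma),
                 spec, rhs, jac, "coupled_nonidentical_model",
                 list(spec = spec, alpha = alpha, coupling = coupling,
                      s = s, sigma = sigma), nl)
}

#' @rdname models
#' @param nu1,nu2,nu3,nu4,nu5,nu6,nu7,nu8 Rate constants of the
#'   segmentation-clock cell (transcription, degradation and signal rates).
#' @param k1,k2,k4,k6,k7,k8 Michaelis / repression threshold constants.
#' @param n,h Hill coefficients of gene and signal repression.
#' @param nu_c Coupling strength through the signal variable.
#' @export
segclock_model <- function(nu1, nu2, nu3, nu4, nu5, nu6, nu7, nu8,
                           k1, k2, k4, k6, k7, k8, n, h,
                           nu_c = 0, sigma = 1) {
  pars <- list(nu1 = nu1, nu2 = nu2, nu3 = nu3, nu4 = nu4, nu5 = nu5,
               nu6 = nu6, nu7 = nu7, nu8 = nu8, k1 = k1, k2 = k2,
               k4 = k4, k6 = k6, k7 = k7, k8 = k8, n = n, h = h,
               nu_c = nu_c, sigma = sigma)
  if (any(vapply(pars[setdiff(names(pars), c("nu_c"))], `<=`, TRUE, 0)))
    stop("all segmentation-clock parameters except 'nu_c' must be positive")
  hill <- function(x, k, e) k^e / (k^e + x^e)          # decreasing Hill term
  dhill <- function(x, k, e) -k^e * e * x^(e - 1) / (k^e + x^e)^2
  mm <- function(x, v, k) v * x / (k + x)              # Michaelis-Menten
  dmm <- function(x, v, k) v * k / (k + x)^2
  cell <- function(u, drive) {
    c(hill(u[3], k1, n) * (nu1 + drive) - mm(u[1], nu2, k2),
      nu3 * u[1] - mm(u[2], nu4, k4) - nu5 * u[2],
      nu5 * u[2] - mm(u[3], nu6, k6),
      nu7 * hill(u[3], k7, h) - mm(u[4], nu8, k8))
  }
  rhs <- function(state) {
    if (length(state) != 8L) stop("state dimension must be 8")
    x <- state[1:4]; y <- state[5:8]
    c(cell(x, nu_c * y[4]),
      sigma * cell(y, (nu_c / sigma) * x[4]))
  }
  jac_cell <- function(u, drive) {
    J <- matrix(0, 4, 4)
    J[1, 1] <- -dmm(u[1], nu2, k2)
    J[1, 3] <- dhill(u[3], k1, n) * (nu1 + drive)
    J[2, 1] <- nu3
    J[2, 2] <- -dmm(u[2], nu4, k4) - nu5
    J[3, 2] <- nu5
    J[3, 3] <- -dmm(u[3], nu6, k6)
    J[4, 3] <- nu7 * dhill(u[3], k7, h)
    J[4, 4] <- -dmm(u[4], nu8, k8)
    J
  }
  jac <- function(state) {
    if (length(state) != 8L) stop("state dimension must be 8")
    x <- state[1:4]; y <- state[5:8]
    J <- matrix(0, 8, 8)
    J[1:4, 1:4] <- jac_cell(x, nu_c * y[4])
    J[5:8, 5:8] <- sigma * jac_cell(y, (nu_c / sigma) * x[4])
    J[1, 8] <- hill(x[3], k1, n) * nu_c          # d x1' / d y4
    J[5, 4] <- hill(y[3], k1, n) * nu_c          # d y1' / d x4 (sigma cancels)
    J
  }
  args <- pars
  new_cell_model("segclock_pair", 8L, pars, NULL, rhs, jac,
                 "segclock_model", args, nl = NULL)
}

#' Update model parameters
#'
#' Rebuilds a model with some parameters replaced, e.g.
#' `update_model(mod, alpha = 0.5)`. Used by the bifurcation locators to
#' sweep the bifurcation parameter.
#'
#' @param model A `cell_model`.
#' @param ... Named scalar parameters to replace.
#' @return A new `cell_model`.
#' @export
update_model <- function(model, ...) {
  stopifnot(inherits(model, "cell_model"))
  repl <- list(...)
  args <- model$args
  bad <- setdiff(names(repl), names(args))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  args[names(repl)] <- repl
  do.call(model$constructor, args)
}

#' Evaluate the right-hand side or Jacobian of a model
#'
#' @param model A `cell_model`.
#' @param state Numeric state vector of length `model$m`.
#' @return `model_rhs`: the time derivative; `model_jacobian`: the
#'   `m x m` analytic Jacobian.
#' @export
model_rhs <- function(model, state) {
  stopifnot(inherits(model, "cell_model"))
  if (length(state) != model$m)
    stop("state dimension must be ", model$m)
  model$rhs(state)
}

#' @rdname model_rhs
#' @export
model_jacobian <- function(model, state) {
  stopifnot(inherits(model, "cell_model"))
  if (length(state) != model$m)
    stop("state dimension must be ", model$m)
  model$jac(state)
}
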