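#' Transcription-repression functions
#'
#' A repression spec describes a smooth, strictly decreasing transcription
#' rate function f on `[0, Inf)` with `f(0) = 1` and `f(x) -> 0` as
#' `x -> Inf`. Two mechanisms are supported:
#'
#' * **Hill-type (HT)**: `f(x) = 1 / (1 + (x / k_H)^n)`, cooperative binding
#'   of the repressor to the gene promoter with Hill coefficient `n` and
#'   half-saturation constant `k_H`.
#' * **Protein sequestration (PS)**: the unsequestered fraction of a free
#'   activator pool `A` when the repressor binds it with dissociation
#'   constant `k_d`,
#'   `f(x) = (A - x - k_d + sqrt((A - x - k_d)^2 + 4 A k_d)) / (2 A)`.
#'
#' The slope magnitude `gamma(x) = -f'(x)` at the equilibrium controls both
#' the Hopf bifurcation value (`alpha0 = 8 / gamma` for the single cell) and
#' the collective frequency of coupled cells, so it is exposed directly.
#'
#' @param n Hill coefficient (positive integer-valued scalar).
#' @param k_H Half-saturation constant (positive scalar).
#' @param A Total activator concentration (positive scalar).
#' @param k_d Activator-repressor dissociation constant (positive scalar).
#' @return An object of class `repression_spec` with fields `kind`
#'   (`"HT"` or `"PS"`) and the mechanism parameters.
#' @examples
#' ht <- hill_repression(n = 11, k_H = 0.136)
#' repression_value(ht, 0.136)   # 0.5 at half-saturation
#' ps <- seq_repression(A = 0.0659, k_d = 1e-5)
#' repression_value(ps, 0)       # exactly 1
#' @name repression
NULL

#' @rdname repression
#' @export
hill_repression <- function(n, k_H) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(k_H), length(k_H) == 1L)
  if (n <= 0 || abs(n - round(n)) > 1e-8)
    stop("Hill coefficient 'n' must be a positive integer")
  if (k_H <= 0) stop("half-saturation constant 'k_H' must be positive")
  structure(list(kind = "HT", n = as.numeric(round(n)), k_H = k_H),
            class = "repression_spec")
}

#' @rdname repression
#' @export
seq_repression <- function(A, k_d) {
  stopifnot(is.numeric(A), length(A) == 1L, is.numeric(k_d), length(k_d) == 1L)
  if (A <= 0) stop("activator concentration 'A' must be positive")
  if (k_d <= 0) stop("dissociation constant 'k_d' must be positive")
  structure(list(kind = "PS", A = A, k_d = k_d), class = "repression_spec")
}

#' @export
print.repression_spec <- function(x, ...) {
  if (x$kind == "HT")
    cat(sprintf("Hill-type repression: n = %g, k_H = %g\n", x$n, x$k_H))
  else
    cat(sprintf("Protein-sequestration repression: A = %g, k_d = %g\n",
                x$A, x$k_d))
  invisible(x)
}

# discriminant of the sequestration quadratic; written as
# (A - x + k_d)^2 + 4 k_d x (algebraically identical) to avoid the
# cancellation in (A - x - k_d)^2 + 4 A k_d and make f(0) = 1 exact
.ps_root <- function(spec, x)
  sqrt((spec$A - x + spec$k_d)^2 + 4 * spec$k_d * x)

#' Evaluate a repression function
#'
#' @param spec A [repression_spec][repression] object.
#' @param x Nonnegative repressor concentration(s).
#' @return `f(x)`, in `(0, 1]`. Vectorised over `x`.
#' @export
repression_value <- function(spec, x) {
  stopifnot(inherits(spec, "repression_spec"), is.numeric(x))
  if (any(x < 0)) stop("'x' must be nonnegative")
  if (spec$kind == "HT") {
    1 / (1 + (x / spec$k_H)^spec$n)
  } else {
    b <- spec$A - x - spec$k_d
    (b + .ps_root(spec, x)) / (2 * spec$A)
  }
}

#' Repression slope magnitude gamma(x) = -f'(x)
#'
#' Closed forms: for the Hill mechanism
#' `gamma = k_H^n n x^(n-1) / (k_H^n + x^n)^2`; for protein sequestration
#' `gamma = (A - x - k_d + S) / (2 A S)` with
#' `S = sqrt((A - x - k_d)^2 + 4 A k_d)`. Always positive for `x > 0`.
#'
#' @inheritParams repression_value
#' @param x Positive repressor concentration(s).
#' @return `-f'(x) > 0`. Vectorised over `x`.
#' @export
repression_gamma <- function(spec, x) {
  stopifnot(inherits(spec, "repression_spec"), is.numeric(x))
  if (any(x <= 0)) stop("'x' must be positive")
  if (spec$kind == "HT") {
    n <- spec$n; k <- spec$k_H
    k^n * n * x^(n - 1) / (k^n + x^n)^2
  } else {
    b <- spec$A - x - spec$k_d
    s <- .ps_root(spec, x)
    (b + s) / (2 * spec$A * s)
  }
}

# second derivative f''(x); used by the normal-form reduction
repression_d2 <- function(spec, x) {
  if (spec$kind == "HT") {
    n <- spec$n; k <- spec$k_H
    D <- k^n + x^n
    -k^n * n * x^(n - 2) * ((n - 1) * k^n - (n + 1) * x^n) / D^3
  } else {
    s <- .ps_root(spec, x)
    2 * spec$k_d / s^3
  }
}

# third derivative f'''(x)
repression_d3 <- function(spec, x) {
  if (spec$kind == "HT") {
    n <- spec$n; k <- spec$k_H
    D <- k^n + x^n
    num <- (n - 1) * ((n - 2) * k^n - 2 * (n + 1) * x^n) * D -
      3 * n * x^n * ((n - 1) * k^n - (n + 1) * x^n)
    -k^n * n * x^(n - 3) * num / D^4
  } else {
    b <- spec$A - x - spec$k_d
    s <- .ps_root(spec, x)
    6 * spec$k_d * b / s^5
  }
}
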