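#' Hopf normal-form coefficients and bifurcation classification
#'
#' Projects the system onto the centre eigenspace at a verified Hopf point
#' and computes the standard normal-form quantities: the quadratic and
#' cubic projection coefficients `g20, g11, g02, g21`, the curvature
#' coefficient
#' `C1 = i/(2 omega) (g20 g11 - 2 |g11|^2 - |g02|^2 / 3) + g21 / 2`,
#' and from it
#'
#' * `p2 = -Re C1 / Re lambda'(alpha*)` -- the bifurcation direction: the
#'   cycle exists for `alpha > alpha*` when `p2 > 0` (supercritical side);
#' * `zeta2 = 2 Re C1` -- orbital stability: stable cycle when `zeta2 < 0`;
#' * `T2 = -(Im C1 + p2 Im lambda'(alpha*)) / omega*` -- leading period
#'   trend: `T = (2 pi / omega*) (1 + T2 eps^2 + O(eps^4))` with
#'   `eps^2 = (alpha - alpha*) / p2`.
#'
#' The quadratic/cubic directional derivatives `B(u, v)` and `C(u, v, w)`
#' are evaluated from analytic second and third derivatives of the
#' repression function where the model declares its nonlinear structure
#' (the gene-circuit models: the only nonlinearity is `f(x3)` per cell, so
#' the tensors have one nonzero direction per cell), and by central finite
#' differences of the rhs otherwise. The centre-manifold corrections use
#' `h11 = -A^{-1} B(q, qbar)` and `h20 = (2 i omega I - A)^{-1} B(q, q)`,
#' and `lambda'(alpha*)` is a central difference over re-solved equilibria.
#'
#' @param model The `cell_model` at the bifurcation parameter value.
#' @param hp A `hopf_point` for `model` (from one of the locators).
#' @param param Name of the bifurcation parameter (default `"alpha"`).
#' @param h_lambda Step for the eigenvalue-derivative central difference.
#' @return Object of class `normal_form`: `g20, g11, g02, g21, C1`
#'   (complex), `p2, zeta2, T2, lambda_prime`, and `classification`
#'   (`"supercritical_stable"`, `"subcritical_unstable"` or
#'   `"degenerate"`).
#' @export
hopf_coefficients <- function(model, hp, param = "alpha", h_lambda = 1e-4) {
  stopifnot(inherits(model, "cell_model"), inherits(hp, "hopf_point"))
  x0 <- hp$equilibrium$state
  A <- model_jacobian(model, x0)
  m <- model$m
  w <- hp$omega_star
  es <- eigen(A)
  i_q <- which.min(abs(es$values - 1i * w))
  lam <- es$values[i_q]
  if (abs(Re(lam)) > 1e-6 || abs(Im(lam) - w) > 1e-5)
    stop("refusing: the supplied hopf_point does not match the Jacobian spectrum")
  q <- es$vectors[, i_q]
  q <- q / sqrt(sum(Conj(q) * q))
  # fixed phase convention: largest-magnitude component real positive
  j <- which.max(abs(q))
  q <- q * Conj(q[j]) / abs(q[j])
  # left eigenvector: A^T p = conj(lam) p, normalised <p, q> = 1
  et <- eigen(t(A))
  i_p <- which.min(abs(et$values - Conj(lam)))
  p <- et$vectors[, i_p]
  p <- p / Conj(sum(Conj(p) * q))
  Bf <- .bilinear_form(model, x0)
  Cf <- .trilinear_form(model, x0)
  ip <- function(a, b) sum(Conj(a) * b)   # <a, b> = conj(a) . b
  Bqq <- Bf(q, q); Bqqb <- Bf(q, Conj(q)); Bqbqb <- Bf(Conj(q), Conj(q))
  g20 <- ip(p, Bqq)
  g11 <- ip(p, Bqqb)
  g02 <- ip(p, Bqbqb)
  # centre-manifold quadratic coefficients: the centre components (along q
  # and conj(q)) are removed before inverting, so that the 2-D reduced-form
  # combination below does not double-count the quadratic interactions
  H20 <- Bqq - g20 * q - Conj(g02) * Conj(q)
  H11 <- Bqqb - g11 * q - Conj(g11) * Conj(q)
  h20 <- solve(2i * w * diag(m) - A, H20)
  h11 <- solve(A, -H11)
  g21 <- ip(p, Cf(q, q, Conj(q))) + ip(p, Bf(Conj(q), h20)) +
    2 * ip(p, Bf(q, h11))
  C1 <- (1i / (2 * w)) * (g20 * g11 - 2 * abs(g11)^2 - abs(g02)^2 / 3) +
    g21 / 2
  lp <- .lambda_prime(model, param, hp$parameter_values[[param]], w, h_lambda)
  if (abs(Re(lp)) < 1e-12)
    stop("refusing: crossing derivative of the eigenvalue is numerically zero")
  p2 <- -Re(C1) / Re(lp)
  zeta2 <- 2 * Re(C1)
  T2 <- -(Im(C1) + p2 * Im(lp)) / w
  classification <- if (abs(Re(C1)) < 1e-10) "degenerate"
    else if (p2 > 0 && zeta2 < 0) "supercritical_stable"
    else "subcritical_unstable"
  structure(list(g20 = g20, g11 = g11, g02 = g02, g21 = g21, C1 = C1,
                 p2 = p2, zeta2 = zeta2, T2 = T2, lambda_prime = lp,
                 classification = classification),
            class = "normal_form")
}

#' @export
print.normal_form <- function(x, ...) {
  cat("<normal_form>", x$classification, "\n")
  cat(sprintf("  C1 = %.6g%+.6gi,  p2 = %.6g,  zeta2 = %.6g,  T2 = %.6g\n",
              Re(x$C1), Im(x$C1), x$p2, x$zeta2, x$T2))
  invisible(x)
}

# quadratic directional derivative B(u, v) of the rhs at x0
.bilinear_form <- function(model, x0) {
  if (!is.null(model$nl)) {
    terms <- lapply(model$nl, function(tm)
      list(j = tm$j, w = tm$w, d2 = repression_d2(model$spec, x0[tm$j])))
    function(u, v)
      Reduce(`+`, lapply(terms, function(tm) tm$w * (tm$d2 * u[tm$j] * v[tm$j])))
  } else {
    h <- 1e-4 * max(1, max(abs(x0)))
    f <- model$rhs
    Qh <- function(z, hh) (f(x0 + hh * z) - 2 * f(x0) + f(x0 - hh * z)) / hh^2
    # Richardson-extrapolated second directional derivative (O(h^4))
    Q <- function(z) (4 * Qh(z, h) - Qh(z, 2 * h)) / 3
    Br <- function(a, b) (Q(a + b) - Q(a - b)) / 4  # real bilinear form
    # extend to complex arguments by multilinearity over Re/Im parts
    function(u, v) {
      ur <- Re(u); ui <- Im(u); vr <- Re(v); vi <- Im(v)
      Br(ur, vr) - Br(ui, vi) + 1i * (Br(ur, vi) + Br(ui, vr))
    }
  }
}

# cubic directional derivative C(u, v, w) of the rhs at x0
.trilinear_form <- function(model, x0) {
  if (!is.null(model$nl)) {
    terms <- lapply(model$nl, function(tm)
      list(j = tm$j, w = tm$w, d3 = repression_d3(model$spec, x0[tm$j])))
    function(u, v, w)
      Reduce(`+`, lapply(terms, function(tm)
        tm$w * (tm$d3 * u[tm$j] * v[tm$j] * w[tm$j])))
  } else {
    h <- 2e-4 * max(1, max(abs(x0)))
    f <- model$rhs
    Th <- function(z, hh)
      (f(x0 + 2 * hh * z) - 2 * f(x0 + hh * z) + 2 * f(x0 - hh * z) -
         f(x0 - 2 * hh * z)) / (2 * hh^3)
    # Richardson-extrapolated third directional derivative (O(h^4))
    Tr <- function(z) (4 * Th(z, h) - Th(z, 2 * h)) / 3
    Cr <- function(a, b, cc)  # real symmetric trilinear form by polarisation
      (Tr(a + b + cc) - Tr(a + b - cc) - Tr(a - b + cc) + Tr(a - b - cc) -
         Tr(-a + b + cc) + Tr(-a + b - cc) + Tr(-a - b + cc) -
         Tr(-a - b - cc)) / 48
    # extend to complex arguments by multilinearity over Re/Im parts
    function(u, v, w) {
      ur <- Re(u); ui <- Im(u); vr <- Re(v); vi <- Im(v)
      wr <- Re(w); wi <- Im(w)
      Cr(ur, vr, wr) - Cr(ui, vi, wr) - Cr(ui, vr, wi) - Cr(ur, vi, wi) +
        1i * (Cr(ui, vr, wr) + Cr(ur, vi, wr) + Cr(ur, vr, wi) -
                Cr(ui, vi, wi))
    }
  }
}

# d lambda / d param at the Hopf point, by central difference with the
# equilibrium re-solved at each evaluation
.lambda_prime <- function(model, param, a_star, w, h = 1e-4) {
  eig_near <- function(a, target) {
    md <- do.call(update_model, stats::setNames(list(model, a), c("model", param)))
    eq <- solve_equilibrium(md)
    ev <- eigen(model_jacobian(md, eq$state), only.values = TRUE)$values
    ev[which.min(abs(ev - target))]
  }
  hh <- h * max(1, abs(a_star))
  (eig_near(a_star + hh, 1i * w) - eig_near(a_star - hh, 1i * w)) / (2 * hh)
}
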