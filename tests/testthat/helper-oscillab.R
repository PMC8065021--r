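# shared fixtures and small oracles for the test suite

ht_spec <- hill_repression(11, 0.136)
ps_spec <- seq_repression(0.0659, 1e-5)

# central-difference Jacobian oracle
num_jacobian <- function(model, x, h = 1e-7) {
  m <- model$m
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    e <- rep(0, m)
    e[j] <- h * max(1, abs(x[j]))
    J[, j] <- (model_rhs(model, x + e) - model_rhs(model, x - e)) / (2 * e[j])
  }
  J
}

# random positive state in a sensible range for a given model
random_state <- function(model, lo = 0.02, hi = 0.6) {
  stats::runif(model$m, lo, hi)
}

# planar supercritical normal form z' = (mu + i) z - z |z|^2, embedded in
# the reals; exact values: C1 = -2, p2 = 2, zeta2 = -4, T2 = 0 under the
# package's eigenvector normalisation
toy_hopf_model <- function(mu = 0) {
  rhs <- function(s) {
    r2 <- s[1]^2 + s[2]^2
    c(mu * s[1] - s[2] - s[1] * r2,
      s[1] + mu * s[2] - s[2] * r2)
  }
  jac <- function(s) {
    matrix(c(mu - (s[1]^2 + s[2]^2) - 2 * s[1]^2, -1 - 2 * s[1] * s[2],
             1 - 2 * s[1] * s[2], mu - (s[1]^2 + s[2]^2) - 2 * s[2]^2),
           2, 2, byrow = TRUE)
  }
  structure(list(name = "toy_hopf", m = 2L, pars = list(mu = mu),
                 spec = NULL, rhs = rhs, jac = jac, nl = NULL,
                 constructor = toy_hopf_model, args = list(mu = mu)),
            class = "cell_model")
}

# seed an initial state near the small-amplitude cycle predicted by the
# normal form, to shorten near-bifurcation transients
seeded_near_cycle <- function(spec, delta, nf = NULL) {
  hp <- single_cell_hb(spec)
  a0 <- hp$parameter_values$alpha
  base <- single_cell_model(spec, a0)
  if (is.null(nf)) nf <- hopf_coefficients(base, hp)
  md <- update_model(base, alpha = a0 + delta)
  eq <- solve_equilibrium(md)
  es <- eigen(model_jacobian(base, hp$equilibrium$state))
  q <- es$vectors[, which.min(abs(es$values - sqrt(3) * 1i))]
  q <- q / sqrt(sum(Conj(q) * q))
  eps <- sqrt(delta / nf$p2)
  list(model = md, x0 = pmax(eq$state + 2 * eps * Re(q), 1e-6),
       hp = hp, nf = nf, eps = eps)
}

# polynomial multiplication oracle (coefficient convolution, monic inputs
# given as b-vectors: x^n + b1 x^(n-1) + ...)
poly_mult_monic <- function(b1, b2) {
  p1 <- c(1, b1)
  p2 <- c(1, b2)
  out <- rep(0, length(p1) + length(p2) - 1)
  for (i in seq_along(p1)) out[i:(i + length(p2) - 1)] <-
      out[i:(i + length(p2) - 1)] + p1[i] * p2
  out[-1]  # drop the leading 1
}

# monic coefficients from prescribed roots (real oracle for char poly /
# Routh-Hurwitz tests)
poly_from_roots <- function(roots) {
  cf <- 1
  for (r in roots) cf <- c(cf, 0) - c(0, r * cf)
  Re(cf[-1])
}
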