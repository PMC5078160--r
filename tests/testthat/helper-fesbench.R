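# Shared helpers: path-level EA/TI estimators assembled from a harmonic
# reduced_potential_set, used to test endpoint recovery. Windows' forward
# samples are disjoint across stages, so quadrature SEs are valid for EA;
# TI handles the shared-state correlation through per-state trapezoid
# weights.

ea_path <- function(rps) {
  K <- nrow(rps$u)
  tot <- 0; v <- 0
  for (k in seq_len(K - 1L)) {
    lo <- rps$origin == k
    e <- ea_estimate(rps$u[k + 1L, lo] - rps$u[k, lo], rps$temperature)
    tot <- tot + e$value; v <- v + e$se^2
  }
  list(value = tot, se = sqrt(v))
}

# dU/dlambda of the linear-force-constant harmonic path: (k1-k0) x^2 / 2,
# with x^2 recovered from the diagonal potential u_kk = k(lambda_k) x^2 / 2.
ti_path_harmonic <- function(rps, k0, k1) {
  lam <- rps$lambdas
  kfun <- k0 + lam * (k1 - k0)
  K <- length(lam)
  m <- s <- numeric(K)
  for (k in seq_len(K)) {
    x2 <- 2 * rps$u[k, rps$origin == k] / kfun[k]
    d <- (k1 - k0) * x2 / 2
    m[k] <- mean(d); s[k] <- sd(d) / sqrt(length(d))
  }
  ti_estimate(lam, m, s)
}

# forward/backward window of adjacent states (exported package utility)
adjacent_window <- function(rps, k) extract_window(rps, k)
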