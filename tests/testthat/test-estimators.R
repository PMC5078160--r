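kt300 <- kT(300)

test_that("exponential averaging matches hand-evaluated and closed-form values", {
  # constant samples: the average collapses to the constant
  expect_equal(ea_estimate(c(2, 2, 2), 300)$value, 2)
  expect_equal(ea_estimate(5.5, 500)$value, 5.5)

  # two samples {0, 1} in kT units: -ln((1 + e^-1)/2) = 0.3798855
  expect_equal(ea_estimate(c(0, 1) * kt300, 300)$value / kt300,
               -log((1 + exp(-1)) / 2), tolerance = 1e-12)

  # Gaussian closed form: dG = mu - sigma^2/(2 kT)
  set.seed(41)
  mu <- 3; sigma <- 1
  dU <- rnorm(2e4, mu, sigma)
  est <- ea_estimate(dU, 300)
  expect_lt(abs(est$value - (mu - sigma^2 / (2 * kt300))), 3 * est$se)

  expect_error(ea_estimate(numeric(0)), "at least one")
  expect_error(ea_estimate(c(1, NA)), "finite")
})

test_that("EA is overflow-safe for very large energies", {
  expect_equal(ea_estimate(c(1e5, 1e5), 300)$value, 1e5)
  expect_true(is.finite(ea_estimate(c(-5e4, -5e4 + 1), 300)$value))
})

test_that("BAR solves the Bennett equation with the sample-size term", {
  # mirror symmetry: forward all c, backward all -c
  w <- window_samples(0, 1, c(3, 3, 3), c(-3, -3, -3))
  expect_equal(bar_estimate(w, 300)$value, 3, tolerance = 1e-6)

  # {0,1}/{0,-1} at kT = 1 is symmetric about 0.5; cross-check the package
  # root against an independent uniroot solve of the implicit equation
  w2 <- window_samples(0, 1, c(0, 1) * kt300, c(0, -1) * kt300)
  got <- bar_estimate(w2, 300)$value / kt300
  resid <- function(dF) {
    sum(1 / (1 + exp(c(0, 1) - dF))) - sum(1 / (1 + exp(c(0, -1) + dF)))
  }
  oracle <- uniroot(resid, c(-5, 5), tol = 1e-12)$root
  expect_equal(got, oracle, tolerance = 1e-5)
  expect_equal(got, 0.5, tolerance = 1e-5)
})

test_that("BAR is antisymmetric under exchanging the window directions", {
  for (s in 1:5) {
    set.seed(s)
    fwd <- rnorm(80, 2, 3); bwd <- rnorm(120, -1, 3)
    a <- bar_estimate(window_samples(0, 1, fwd, bwd), 300)$value
    b <- bar_estimate(window_samples(0, 1, bwd, fwd), 300)$value
    expect_equal(a, -b, tolerance = 1e-5)
  }
})

test_that("BAR reports convergence diagnostics on failure", {
  w <- window_samples(0, 1, c(0, 1), c(0, -1))
  expect_error(bar_estimate(w, 300, tol = 1e-12, max_iter = 3L),
               "did not converge")
})

test_that("TI integrates the trapezoid rule exactly where it should", {
  # constant derivative
  expect_equal(ti_estimate(c(0, 1), c(4, 4))$value, 4)
  # hand trapezoid: {0, 0.5, 1} x {0, 1, 2} -> 1
  expect_equal(ti_estimate(c(0, 0.5, 1), c(0, 1, 2))$value, 1)

  # derivative 3*lambda^2 on the 13-point schedule: for a quadratic the
  # composite trapezoid error is exactly sum(h^3) * f''/12 = sum(h^3)/2
  lam <- default_lambda_schedule()
  got <- ti_estimate(lam, 3 * lam^2)$value
  expect_equal(got, 1 + sum(diff(lam)^3) / 2, tolerance = 1e-12)
  expect_lt(abs(got - 1), 0.01)

  expect_error(ti_estimate(c(0.5, 0.2), c(1, 1)), "increasing")
  expect_error(ti_estimate(0.5, 1), "at least two")
})

test_that("MBAR reproduces degenerate and two-state limits", {
  # two identical states: dG = 0 within noise
  set.seed(7)
  u <- matrix(rnorm(2 * 200, 10, 2), nrow = 2, byrow = FALSE)
  u[2, ] <- u[1, ]
  rps <- reduced_potential_set(c(0, 1), u, rep(1:2, each = 100), 300)
  expect_lt(abs(mbar_estimate(rps)$estimate$value), 0.3)

  # two-state MBAR reduces exactly to BAR
  rps2 <- sample_harmonic_alchemy(1, 4, lambda_schedule = c(0, 1),
                                  n_per_state = 150, seed = 11)
  mb <- mbar_estimate(rps2, tol = 1e-10)$estimate$value
  bb <- bar_estimate(adjacent_window(rps2, 1L), 300, tol = 1e-10)$value
  expect_equal(mb, bb, tolerance = 1e-6)
})

test_that("MBAR recovers the analytic harmonic free-energy difference", {
  rps <- sample_harmonic_alchemy(1, 4, n_per_state = 100, seed = 3)
  fit <- mbar_estimate(rps)
  se <- mbar_bootstrap_se(rps, n_boot = 40, seed = 5)
  expect_lt(abs(fit$estimate$value - attr(rps, "exact_dg")), 3 * as.numeric(se))
  # first state pinned at zero
  expect_identical(fit$f[1L], 0)
})

test_that("self-consistent MBAR agrees with direct minimisation of its objective", {
  rps <- sample_harmonic_alchemy(1, 3, lambda_schedule = c(0, 0.5, 1),
                                 n_per_state = 120, seed = 9)
  fit <- mbar_estimate(rps, tol = 1e-11)
  kt <- kT(rps$temperature)
  u_red <- rps$u / kt
  N_k <- tabulate(rps$origin, nbins = 3)
  op <- optim(c(0, 0), function(f) fesbench:::mbar_objective(f, u_red, N_k),
              method = "BFGS", control = list(reltol = 1e-15, maxit = 500))
  expect_equal(op$par[2L] * kt, fit$estimate$value, tolerance = 1e-6)
})

test_that("MBAR endpoint telescopes into adjacent-window BAR sums", {
  rps <- sample_harmonic_alchemy(1, 2.5, lambda_schedule = c(0, 0.25, 0.5, 0.75, 1),
                                 n_per_state = 150, seed = 21)
  mb <- mbar_estimate(rps)$estimate$value
  bp <- bar_path_estimate(rps, n_boot = 40, seed = 22)
  mb_se <- mbar_bootstrap_se(rps, n_boot = 40, seed = 23)
  expect_lt(abs(mb - bp$value), 3 * sqrt(bp$se^2 + as.numeric(mb_se)^2))
})

test_that("MBAR rejects invalid input", {
  expect_error(reduced_potential_set(c(0, 1), matrix(0, 2, 2), c(1, 1), 300),
               "empty state")
  expect_error(reduced_potential_set(c(0, 0.5), matrix(0, 2, 2), c(1, 2), 300),
               "ending at 1")
  rps <- sample_harmonic_alchemy(1, 2, lambda_schedule = c(0, 1),
                                 n_per_state = 10, seed = 1)
  expect_error(mbar_estimate(rps, tol = -1), "positive")
})

test_that("MBAR bootstrap SE behaves like a sampling standard error", {
  # zero-variance samples: SE is exactly 0
  u <- rbind(rep(1, 20), rep(2, 20))
  rps0 <- reduced_potential_set(c(0, 1), u, rep(1:2, each = 10), 300)
  expect_equal(as.numeric(mbar_bootstrap_se(rps0, n_boot = 10, seed = 1)), 0)

  # determinism under a fixed seed
  rps <- sample_harmonic_alchemy(1, 4, lambda_schedule = c(0, 0.5, 1),
                                 n_per_state = 80, seed = 2)
  s1 <- mbar_bootstrap_se(rps, n_boot = 30, seed = 42)
  s2 <- mbar_bootstrap_se(rps, n_boot = 30, seed = 42)
  expect_identical(as.numeric(s1), as.numeric(s2))

  # doubling the sample size shrinks the SE by about 1/sqrt(2)
  rps_n <- sample_harmonic_alchemy(1, 4, lambda_schedule = c(0, 0.5, 1),
                                   n_per_state = 100, seed = 13)
  rps_2n <- sample_harmonic_alchemy(1, 4, lambda_schedule = c(0, 0.5, 1),
                                    n_per_state = 200, seed = 13)
  r <- as.numeric(mbar_bootstrap_se(rps_2n, n_boot = 80, seed = 7)) /
       as.numeric(mbar_bootstrap_se(rps_n, n_boot = 80, seed = 7))
  expect_lt(abs(r - 1 / sqrt(2)), 0.3 / sqrt(2))
})

test_that("EA forward and negated EA backward bracket BAR on Gaussian work", {
  # the standard one-sided bias ordering, E[EA_fwd] >= E[BAR] >= E[EA_bwd],
  # checked on the mean estimates over seeds (per-seed estimates are too
  # noisy for the ordering to hold deterministically)
  kt <- kt300
  m <- vapply(1:60, function(s) {
    w <- sample_gaussian_work(2, 2 * kt, n_f = 100, n_r = 100,
                              temperature = 300, seed = s)
    c(ea_f = ea_estimate(w$dU_forward, 300)$value,
      bar = bar_estimate(w, 300)$value,
      ea_b = -ea_estimate(w$dU_backward, 300)$value)
  }, numeric(3))
  means <- rowMeans(m)
  expect_gt(means[["ea_f"]], means[["bar"]])
  expect_gt(means[["bar"]], means[["ea_b"]])
  # and BAR sits on the implied answer while both EA estimates are biased
  expect_lt(abs(means[["bar"]] - (2 - (2 * kt)^2 / (2 * kt))), 0.15)
})
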