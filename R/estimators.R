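## Free-energy estimators: exponential averaging (Zwanzig), Bennett
## acceptance ratio, thermodynamic integration, and multistate BAR.
## All exponential averages use max-shifted log-sum-exp.

#' Exponential-averaging (Zwanzig) free-energy estimate
#'
#' One-sided perturbation estimate \eqn{\Delta G = -kT \ln\langle e^{-\Delta
#' U/kT}\rangle} from perturbation-energy samples.
#'
#' @param dU Numeric vector of perturbation energies U(target) - U(reference),
#'   kJ/mol, sampled in the reference ensemble.
#' @param temperature Temperature in kelvin.
#' @return A `free_energy_estimate` (method "EA"). The standard error is the
#'   delta-method propagation of the sample variance of the exponential
#'   weights.
#' @examples
#' ea_estimate(c(2, 2, 2), 300)$value  # exactly 2
#' @export
ea_estimate <- function(dU, temperature = 300) {
  if (length(dU) < 1L) stop("`dU` must contain at least one sample", call. = FALSE)
  dU <- as.numeric(dU)
  if (!all(is.finite(dU))) stop("`dU` has non-finite values", call. = FALSE)
  beta <- 1 / kT(temperature)
  value <- -log_mean_exp(-beta * dU) / beta
  se <- NA_real_
  n <- length(dU)
  if (n >= 2L) {
    # var(-kT log xbar) ~ kT^2 var(x)/(n xbar^2); computed on shifted weights
    w <- exp(-beta * dU - max(-beta * dU))
    se <- (1 / beta) * sd(w) / (mean(w) * sqrt(n))
  }
  free_energy_estimate(value, se, "EA")
}

## Bennett implicit equation residual at trial dF (all in kT units):
##   sum_F fermi(M + wF - dF) - sum_R fermi(-M + wR + dF)
## with M = log(nF/nR); monotonically increasing in dF.
bar_residual <- function(dF, wF, wR, M) {
  fermi <- function(x) 1 / (1 + exp(x))
  sum(fermi(M + wF - dF)) - sum(fermi(-M + wR + dF))
}

#' Bennett acceptance ratio (BAR) estimate for one window
#'
#' Solves the self-consistent Bennett equation in its Fermi-function form,
#' including the sample-size ratio term, by bisection on the monotone
#' residual. The initial bracket comes from the forward and (negated)
#' backward exponential-averaging estimates, expanded if needed.
#'
#' @param window A [window_samples()] object with both `dU_forward` and
#'   `dU_backward` populated.
#' @param temperature Temperature in kelvin.
#' @param tol Convergence tolerance on the free energy, kJ/mol.
#' @param max_iter Iteration cap for the bisection.
#' @return A `free_energy_estimate` (method "BAR") with the asymptotic
#'   standard error (`se_kind = "asymptotic"`).
#' @export
bar_estimate <- function(window, temperature = 300, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(window, "window_samples"))
  if (is.null(window$dU_forward) || is.null(window$dU_backward)) {
    stop("BAR needs both forward and backward samples", call. = FALSE)
  }
  kt <- kT(temperature)
  beta <- 1 / kt
  wF <- beta * window$dU_forward    # forward work, kT
  wR <- beta * window$dU_backward   # reverse work, kT
  nF <- length(wF); nR <- length(wR)
  M <- log(nF / nR)

  # bracket from the two one-sided EA estimates
  ea_f <- -log_mean_exp(-wF)
  ea_r <- log_mean_exp(-wR)  # negated backward estimate of the same dF
  lo <- min(ea_f, ea_r) - 1
  hi <- max(ea_f, ea_r) + 1
  expand <- 0L
  while (bar_residual(lo, wF, wR, M) > 0 && expand < 60L) {
    lo <- lo - 2^expand; expand <- expand + 1L
  }
  expand <- 0L
  while (bar_residual(hi, wF, wR, M) < 0 && expand < 60L) {
    hi <- hi + 2^expand; expand <- expand + 1L
  }
  if (bar_residual(lo, wF, wR, M) > 0 || bar_residual(hi, wF, wR, M) < 0) {
    stop("BAR bracket expansion failed; samples may be degenerate", call. = FALSE)
  }
  iter <- 0L
  btol <- beta * tol
  while ((hi - lo) > btol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf(
        "BAR did not converge in %d iterations (bracket width %.3g kT)",
        max_iter, hi - lo), call. = FALSE)
    }
    mid <- (lo + hi) / 2
    if (bar_residual(mid, wF, wR, M) < 0) lo <- mid else hi <- mid
  }
  dF <- (lo + hi) / 2

  # Bennett asymptotic variance from the Fermi weights at the solution
  fF <- 1 / (1 + exp(M + wF - dF))
  fR <- 1 / (1 + exp(-M + wR + dF))
  var_kt2 <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
             (mean(fR^2) / mean(fR)^2 - 1) / nR
  se <- kt * sqrt(max(var_kt2, 0))
  free_energy_estimate(dF * kt, se, "BAR",
                       extra = list(se_kind = "asymptotic", iterations = iter))
}

#' Thermodynamic-integration estimate
#'
#' Trapezoidal integration of the mean dU/dlambda over the lambda grid. The
#' quadrature rule is recorded in the result metadata.
#'
#' @param lambdas Increasing coupling values.
#' @param mean_dudl Mean dU/dlambda at each lambda, kJ/mol.
#' @param se_dudl Optional standard errors of the means, propagated through
#'   the trapezoid weights.
#' @return A `free_energy_estimate` (method "TI").
#' @export
ti_estimate <- function(lambdas, mean_dudl, se_dudl = NULL) {
  lambdas <- as.numeric(lambdas); mean_dudl <- as.numeric(mean_dudl)
  if (length(lambdas) < 2L) stop("TI needs at least two lambda points", call. = FALSE)
  if (length(lambdas) != length(mean_dudl)) {
    stop("`lambdas` and `mean_dudl` lengths differ", call. = FALSE)
  }
  if (any(diff(lambdas) <= 0)) stop("`lambdas` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(mean_dudl))) stop("non-finite dU/dlambda means", call. = FALSE)
  h <- diff(lambdas)
  n <- length(lambdas)
  value <- sum(h * (mean_dudl[-1] + mean_dudl[-n]) / 2)
  se <- NA_real_
  if (!is.null(se_dudl)) {
    w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid weight of each grid point
    se <- sqrt(sum((w * as.numeric(se_dudl))^2))
  }
  free_energy_estimate(value, se, "TI", extra = list(quadrature = "trapezoid"))
}

## Self-consistent MBAR update in kT units.
## u_red: K x N reduced potentials; N_k: snapshot counts; f: current estimate.
mbar_iterate <- function(u_red, N_k, f) {
  K <- nrow(u_red)
  # log denominator per snapshot: log sum_k N_k exp(f_k - u_kn)
  a <- f + log(N_k) - u_red          # K x N
  amax <- apply(a, 2L, max)
  log_den <- amax + log(colSums(exp(sweep(a, 2L, amax))))
  b <- -u_red - rep(log_den, each = K)  # K x N
  bmax <- apply(b, 1L, max)
  fnew <- -(bmax + log(rowSums(exp(b - bmax))))
  fnew - fnew[1L]
}

## Negative log-likelihood form of the MBAR objective (convex in f), used by
## the tests as an independent second route to the same solution.
mbar_objective <- function(f, u_red, N_k) {
  f <- c(0, f)
  K <- nrow(u_red); N <- ncol(u_red)
  a <- f + log(N_k) - u_red
  amax <- apply(a, 2L, max)
  log_den <- amax + log(colSums(exp(sweep(a, 2L, amax))))
  sum(log_den) / N - sum(N_k * f) / N
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Self-consistent MBAR free energies for all states of a
#' [reduced_potential_set()], seeded by stagewise BAR along adjacent states
#' and iterated until the largest per-state change falls below `tol`.
#'
#' @param rps A `reduced_potential_set`.
#' @param tol Convergence tolerance, kJ/mol, on the per-state free energies.
#' @param max_iter Iteration cap for the self-consistent loop.
#' @return A list of class `mbar_result`: `f` (per-state free energies,
#'   kJ/mol, first state pinned at 0), `estimate` (endpoint
#'   `free_energy_estimate`, method "MBAR"), `iterations`.
#' @export
mbar_estimate <- function(rps, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(rps, "reduced_potential_set"))
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  kt <- kT(rps$temperature)
  u_red <- rps$u / kt
  K <- nrow(u_red)
  N_k <- tabulate(rps$origin, nbins = K)

  # stagewise BAR seed over adjacent states
  f <- numeric(K)
  for (k in seq_len(K - 1L)) {
    idx_lo <- rps$origin == k
    idx_hi <- rps$origin == k + 1L
    wF <- u_red[k + 1L, idx_lo] - u_red[k, idx_lo]
    wR <- u_red[k, idx_hi] - u_red[k + 1L, idx_hi]
    dfk <- tryCatch({
      win <- window_samples(rps$lambdas[k], rps$lambdas[k + 1L],
                            wF * kt, wR * kt)
      bar_estimate(win, rps$temperature)$value / kt
    }, error = function(e) {
      # degenerate window (e.g. single sample): fall back to forward EA
      -log_mean_exp(-wF)
    })
    f[k + 1L] <- f[k] + dfk
  }

  btol <- tol / kt
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fnew <- mbar_iterate(u_red, N_k, f)
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < btol) break
    if (iter >= max_iter) {
      stop(sprintf("MBAR did not converge in %d iterations (max |df| = %.3g kT)",
                   max_iter, delta), call. = FALSE)
    }
  }
  f_kj <- f * kt
  endpoint <- free_energy_estimate(
    f_kj[K] - f_kj[1L], NA_real_, "MBAR",
    extra = list(iterations = iter))
  structure(list(f = f_kj, estimate = endpoint, iterations = iter,
                 lambdas = rps$lambdas, temperature = rps$temperature),
            class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> %d states, endpoint dG = %.4f kJ/mol (%d iterations)\n",
              length(x$f), x$estimate$value, x$iterations))
  invisible(x)
}

## Telescoped BAR total over adjacent states of a reduced_potential_set.
bar_path_value <- function(rps, tol = 1e-6) {
  K <- nrow(rps$u)
  total <- 0
  for (k in seq_len(K - 1L)) {
    total <- total +
      bar_estimate(extract_window(rps, k), rps$temperature, tol = tol)$value
  }
  total
}

#' Telescoped BAR estimate along a lambda path
#'
#' Sums adjacent-window BAR estimates over all states of a
#' [reduced_potential_set()]. Because adjacent windows share each state's
#' samples, their errors are correlated and a quadrature sum of per-window
#' asymptotic SEs understates the uncertainty of the total; the standard
#' error is therefore computed by bootstrap resampling of snapshots within
#' each state.
#'
#' @param rps A `reduced_potential_set`.
#' @param n_boot Bootstrap replicates for the SE (default 100); 0 skips the
#'   bootstrap and returns `NA` SE.
#' @param seed Integer seed for the resampling.
#' @param tol Per-window BAR tolerance, kJ/mol.
#' @return A `free_energy_estimate` (method "BAR").
#' @export
bar_path_estimate <- function(rps, n_boot = 100L, seed = 1L, tol = 1e-6) {
  stopifnot(inherits(rps, "reduced_potential_set"))
  value <- bar_path_value(rps, tol)
  se <- NA_real_
  if (n_boot >= 2L) {
    by_state <- split(seq_along(rps$origin), rps$origin)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(by_state,
                           function(i) sample(i, length(i), replace = TRUE)),
                    use.names = FALSE)
      rb <- reduced_potential_set(rps$lambdas, rps$u[, idx, drop = FALSE],
                                  rps$origin[idx], rps$temperature)
      tryCatch(bar_path_value(rb, tol), error = function(e) NA_real_)
    }, numeric(1))
    se <- sd(reps[!is.na(reps)])
  }
  free_energy_estimate(value, se, "BAR",
                       extra = list(se_kind = "bootstrap", n_boot = n_boot))
}

#' Nonparametric bootstrap standard error of the MBAR endpoint
#'
#' Resamples snapshots with replacement within each state, re-runs
#' [mbar_estimate()], and reports the standard deviation of the endpoint free
#' energy over replicates. Failed replicates are dropped and counted.
#'
#' @param rps A `reduced_potential_set`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the same seed reproduces the same resampling.
#' @param tol Convergence tolerance passed to [mbar_estimate()].
#' @return Numeric standard error (kJ/mol) with attributes `n_failed` and
#'   `replicates`.
#' @export
mbar_bootstrap_se <- function(rps, n_boot = 100L, seed = 1L, tol = 1e-8) {
  stopifnot(inherits(rps, "reduced_potential_set"))
  if (n_boot < 2L) stop("`n_boot` must be at least 2", call. = FALSE)
  K <- nrow(rps$u)
  by_state <- split(seq_along(rps$origin), rps$origin)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_state, function(i) sample(i, length(i), replace = TRUE)),
                  use.names = FALSE)
    reps[b] <- tryCatch({
      rb <- reduced_potential_set(rps$lambdas, rps$u[, idx, drop = FALSE],
                                  rps$origin[idx], rps$temperature)
      mbar_estimate(rb, tol = tol)$estimate$value
    }, error = function(e) NA_real_)
  }
  ok <- reps[!is.na(reps)]
  if (length(ok) < 2L) stop("too few successful bootstrap replicates", call. = FALSE)
  se <- sd(ok)
  attr(se, "n_failed") <- sum(is.na(reps))
  attr(se, "replicates") <- length(ok)
  se
}

## Save/restore the RNG state so seeded helpers do not disturb the caller's
## random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
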