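## Domain containers for per-lambda samples: reduced_potential_set holds the
## full u[k, n] matrix for MBAR; window_samples holds the forward/backward
## perturbation energies (and optional dU/dlambda) of one adjacent window.

#' Per-state reduced-potential samples
#'
#' Container for the input of [mbar_estimate()]: potential energies of every
#' snapshot evaluated at every coupling state, together with the state each
#' snapshot was sampled from.
#'
#' @param lambdas Strictly increasing coupling values in \[0, 1\], first 0 and
#'   last 1.
#' @param u Numeric matrix, `u[k, n]` = potential energy (kJ/mol) of snapshot
#'   `n` evaluated at state `k`. The "reduced" (dimensionless) potential used
#'   internally is `u / kT`.
#' @param origin Integer vector of length `ncol(u)`; state index each snapshot
#'   was sampled from. Every state must contribute at least one snapshot.
#' @param temperature Temperature in kelvin (default 300).
#' @return An object of class `reduced_potential_set`.
#' @seealso [sample_harmonic_alchemy()] for a generator with exact ground
#'   truth.
#' @export
reduced_potential_set <- function(lambdas, u, origin, temperature = 300) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2L || any(diff(lambdas) <= 0) ||
      lambdas[1L] != 0 || lambdas[length(lambdas)] != 1) {
    stop("`lambdas` must be strictly increasing, starting at 0 and ending at 1",
         call. = FALSE)
  }
  u <- as.matrix(u)
  if (nrow(u) != length(lambdas)) {
    stop("`u` must have one row per lambda state", call. = FALSE)
  }
  if (!all(is.finite(u))) stop("all entries of `u` must be finite", call. = FALSE)
  origin <- as.integer(origin)
  if (length(origin) != ncol(u)) {
    stop("`origin` must have one entry per snapshot (column of `u`)", call. = FALSE)
  }
  if (any(origin < 1L) || any(origin > length(lambdas))) {
    stop("`origin` contains invalid state indices", call. = FALSE)
  }
  counts <- tabulate(origin, nbins = length(lambdas))
  if (any(counts == 0L)) {
    stop("every state must have at least one snapshot; empty state(s): ",
         paste(which(counts == 0L), collapse = ", "), call. = FALSE)
  }
  kT(temperature)
  structure(
    list(lambdas = lambdas, u = u, origin = origin, temperature = temperature),
    class = "reduced_potential_set"
  )
}

#' @export
print.reduced_potential_set <- function(x, ...) {
  cat(sprintf("<reduced_potential_set> %d states, %d snapshots, T = %g K\n",
              length(x$lambdas), ncol(x$u), x$temperature))
  invisible(x)
}

#' Forward/backward samples of one perturbation window
#'
#' @param lambda_low,lambda_high Coupling values bounding the window,
#'   `lambda_low < lambda_high`.
#' @param dU_forward Samples of U(high) - U(low), kJ/mol, drawn in the low
#'   ensemble.
#' @param dU_backward Samples of U(low) - U(high), kJ/mol, drawn in the high
#'   ensemble.
#' @param dudl_low,dudl_high Optional dU/dlambda samples (kJ/mol) in the two
#'   ensembles, used by [ti_estimate()] and [bar_ti_discrepancy()].
#' @return An object of class `window_samples`.
#' @export
window_samples <- function(lambda_low, lambda_high, dU_forward, dU_backward,
                           dudl_low = NULL, dudl_high = NULL) {
  if (!is.numeric(lambda_low) || !is.numeric(lambda_high) ||
      lambda_low >= lambda_high) {
    stop("`lambda_low` must be < `lambda_high`", call. = FALSE)
  }
  chk <- function(x, nm, min_n = 2L) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) < min_n) {
      stop(sprintf("`%s` needs at least %d samples", nm, min_n), call. = FALSE)
    }
    if (!all(is.finite(x))) stop(sprintf("`%s` has non-finite values", nm), call. = FALSE)
    x
  }
  structure(
    list(lambda_low = lambda_low, lambda_high = lambda_high,
         dU_forward = chk(dU_forward, "dU_forward"),
         dU_backward = chk(dU_backward, "dU_backward"),
         dudl_low = chk(dudl_low, "dudl_low"),
         dudl_high = chk(dudl_high, "dudl_high")),
    class = "window_samples"
  )
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf("<window_samples> [%g, %g]: %d fwd, %d bwd%s\n",
              x$lambda_low, x$lambda_high,
              length(x$dU_forward), length(x$dU_backward),
              if (!is.null(x$dudl_low)) ", with dU/dl" else ""))
  invisible(x)
}

#' Extract one adjacent-state window from a reduced-potential set
#'
#' Builds the forward/backward [window_samples()] of the window between
#' states `k` and `k + 1`: forward perturbation energies are evaluated on
#' the snapshots of state `k`, backward ones on those of state `k + 1`.
#'
#' @param rps A [reduced_potential_set()].
#' @param k Lower state index (1-based), `k <` number of states.
#' @return A `window_samples` object.
#' @export
extract_window <- function(rps, k) {
  stopifnot(inherits(rps, "reduced_potential_set"))
  k <- as.integer(k)
  if (k < 1L || k >= nrow(rps$u)) stop("`k` out of range", call. = FALSE)
  lo <- rps$origin == k
  hi <- rps$origin == k + 1L
  window_samples(rps$lambdas[k], rps$lambdas[k + 1L],
                 rps$u[k + 1L, lo] - rps$u[k, lo],
                 rps$u[k, hi] - rps$u[k + 1L, hi])
}

## Constructor for estimator results.
free_energy_estimate <- function(value, se = NA_real_, method, direction = NULL,
                                 extra = list()) {
  stopifnot(is.finite(value))
  if (!is.na(se) && se < 0) stop("standard error must be >= 0", call. = FALSE)
  structure(
    c(list(value = value, se = se, method = method, direction = direction),
      extra),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  se_txt <- if (is.na(x$se)) "" else sprintf(" +/- %.3f", x$se)
  cat(sprintf("<%s> %.4f%s kJ/mol\n", x$method, x$value, se_txt))
  invisible(x)
}
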