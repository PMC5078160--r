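## Per-window overlap and convergence diagnostics. Six measures are computed
## for each perturbation window: the Bhattacharyya coefficient Omega of the
## forward and (negated) backward perturbation-energy distributions, the
## Wu-Kofke-style overlap K_AB and bias metric Pi, the maximum
## exponential-average weight w_max, the EA hysteresis, and the |BAR - TI|
## discrepancy. Windows failing two measures (or any window with negative Pi)
## are flagged for refinement at the window midpoint.

#' Default diagnostic thresholds
#'
#' Pass/fail thresholds for the six overlap measures: Omega and K_AB are
#' acceptable above 0.7, Pi is alarming below 0.5 (and negative Pi alone
#' forces refinement), w_max above 0.3 indicates that a single snapshot
#' dominates the exponential average, and EA-hysteresis or |BAR - TI|
#' differences above 4 kJ/mol indicate poor convergence.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(omega = 0.7, kab = 0.7, pi = 0.5, wmax = 0.3, ddg_ea = 4, ddg_ti = 4)
}

## Shared-support equal-width histogram masses for two sample vectors.
## Returns list(p, q) of per-bin probability masses.
shared_histogram <- function(a, b, bins) {
  rng <- range(c(a, b))
  if (rng[1L] == rng[2L]) {
    # all samples identical across both sets: single degenerate bin
    return(list(p = 1, q = 1))
  }
  brk <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  cut_idx <- function(x) pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE), 1L), bins)
  p <- tabulate(cut_idx(a), nbins = bins) / length(a)
  q <- tabulate(cut_idx(b), nbins = bins) / length(b)
  list(p = p, q = q)
}

#' Bhattacharyya overlap of forward and backward energy distributions
#'
#' Computes \eqn{\Omega = \sum_b \sqrt{p_b q_b}} over shared equal-width
#' histogram bins, where p is the forward dU distribution and q the negated
#' backward dU distribution (both describe U(high) - U(low), so perfect
#' phase-space overlap gives identical distributions and Omega = 1).
#'
#' @param window A [window_samples()] object.
#' @param bins Number of equal-width bins over the union range (default 50).
#' @return Omega in \[0, 1\].
#' @export
bhattacharyya_overlap <- function(window, bins = 50L) {
  stopifnot(inherits(window, "window_samples"))
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  a <- window$dU_forward
  b <- -window$dU_backward
  if (is.null(a) || is.null(b)) {
    stop("both forward and backward samples are required", call. = FALSE)
  }
  h <- shared_histogram(a, b, as.integer(bins))
  sum(sqrt(h$p * h$q))
}

#' Overlap and bias measures in the spirit of Wu & Kofke
#'
#' `kab` quantifies how the forward dU distribution sits relative to the
#' negated-backward one, on the scale used for phase-space overlap
#' diagnostics: 0 for disjoint distributions, about 1 for coincident ones,
#' approaching 2 when the first (forward) distribution lies entirely inside
#' the second. It is computed from shared-bin histogram masses as
#' `max(0, 2*C_A - C_B)`, where `C_A` is the forward mass falling in bins
#' occupied by the backward distribution and `C_B` the converse.
#'
#' `pi` is a sample-size-versus-dissipation bias metric: for each sampled
#' direction, `sqrt(2 log n) - sqrt(2 d)` with `d` the dissipated work of
#' that direction in kT (forward mean work minus the BAR free energy, and
#' its mirror for the backward direction); the reported Pi is the smaller of
#' the two. Pi is large and positive when the available samples comfortably
#' cover the dissipation, and goes negative when the sample size is too
#' small for a reliable estimate.
#'
#' These closed forms are this package's constructions, chosen to satisfy
#' the limiting behaviours quoted for the original Wu & Kofke measures.
#'
#' @param window A [window_samples()] object.
#' @param temperature Temperature in kelvin.
#' @param bins Histogram bins for `kab` (default 50).
#' @return List with elements `kab`, `pi`, and logical `low_n` (fewer than 10
#'   samples in either direction).
#' @export
wu_kofke_measures <- function(window, temperature = 300, bins = 50L) {
  stopifnot(inherits(window, "window_samples"))
  a <- window$dU_forward
  b <- -window$dU_backward
  if (is.null(a) || is.null(b)) {
    stop("both forward and backward samples are required", call. = FALSE)
  }
  low_n <- length(a) < 10L || length(b) < 10L

  h <- shared_histogram(a, b, as.integer(bins))
  occ_p <- h$p > 0; occ_q <- h$q > 0
  C_A <- sum(h$p[occ_q])  # forward mass where backward has support
  C_B <- sum(h$q[occ_p])  # backward mass where forward has support
  kab <- max(0, 2 * C_A - C_B)

  kt <- kT(temperature)
  dF <- bar_estimate(window, temperature)$value
  # dissipated work per direction, kT; magnitudes so that unphysical
  # orderings (apparent negative dissipation) also count against the window
  d_fwd <- abs(mean(window$dU_forward) - dF) / kt
  d_bwd <- abs(dF - mean(-window$dU_backward)) / kt
  pi_fwd <- sqrt(2 * log(length(a))) - sqrt(2 * d_fwd)
  pi_bwd <- sqrt(2 * log(length(b))) - sqrt(2 * d_bwd)
  list(kab = kab, pi = min(pi_fwd, pi_bwd), low_n = low_n)
}

#' Maximum exponential-average weight
#'
#' The largest normalized Boltzmann weight in the exponential average,
#' \eqn{w_{max} = \max_i e^{-\Delta U_i/kT} / \sum_j e^{-\Delta U_j/kT}}.
#' Values above 0.3 mean a single snapshot dominates the estimate.
#'
#' @param dU Perturbation-energy samples, kJ/mol.
#' @param temperature Temperature in kelvin.
#' @return w_max in \[1/n, 1\].
#' @export
max_weight <- function(dU, temperature = 300) {
  if (length(dU) < 1L) stop("`dU` must contain at least one sample", call. = FALSE)
  dU <- as.numeric(dU)
  if (!all(is.finite(dU))) stop("`dU` has non-finite values", call. = FALSE)
  x <- -dU / kT(temperature)
  exp(max(x) - log_sum_exp(x))
}

#' Exponential-averaging hysteresis
#'
#' Magnitude of the cycle closure of the two one-sided estimates,
#' \eqn{|\Delta G_{EA,fwd} + \Delta G_{EA,bwd}|}, where the forward term
#' estimates dG(low to high) from `dU_forward` and the backward term
#' estimates dG(high to low) from `dU_backward`. Exact estimates cancel;
#' finite samples under poor overlap do not.
#'
#' @param window A [window_samples()] object.
#' @param temperature Temperature in kelvin.
#' @return Non-negative hysteresis, kJ/mol.
#' @export
ea_hysteresis <- function(window, temperature = 300) {
  stopifnot(inherits(window, "window_samples"))
  if (is.null(window$dU_forward) || is.null(window$dU_backward)) {
    stop("both forward and backward samples are required", call. = FALSE)
  }
  g_fwd <- ea_estimate(window$dU_forward, temperature)$value
  g_bwd <- ea_estimate(window$dU_backward, temperature)$value
  abs(g_fwd + g_bwd)
}

#' |BAR - TI| discrepancy for one window
#'
#' The BAR estimate from the forward/backward samples compared with the
#' two-point trapezoid TI estimate from the window's dU/dlambda samples.
#'
#' @param window A [window_samples()] object carrying `dudl_low` and
#'   `dudl_high`.
#' @param temperature Temperature in kelvin.
#' @return Non-negative discrepancy, kJ/mol.
#' @export
bar_ti_discrepancy <- function(window, temperature = 300) {
  stopifnot(inherits(window, "window_samples"))
  if (is.null(window$dudl_low) || is.null(window$dudl_high)) {
    stop("window carries no dU/dlambda samples", call. = FALSE)
  }
  bar <- bar_estimate(window, temperature)$value
  ti <- ti_estimate(c(window$lambda_low, window$lambda_high),
                    c(mean(window$dudl_low), mean(window$dudl_high)))$value
  abs(bar - ti)
}

#' Full overlap report for one window
#'
#' Computes all six measures for a window and applies the thresholds.
#'
#' @param window A [window_samples()] object. dU/dlambda samples are optional;
#'   without them `ddg_ti` is `NA` and its flag passes.
#' @param temperature Temperature in kelvin.
#' @param bins Histogram bins for Omega and K_AB.
#' @param thresholds Threshold list as from [default_thresholds()].
#' @return An `overlap_report`: the six measures, per-measure logical `flags`
#'   (`TRUE` = fail), and `low_n`.
#' @export
overlap_report <- function(window, temperature = 300, bins = 50L,
                           thresholds = default_thresholds()) {
  stopifnot(inherits(window, "window_samples"))
  omega <- bhattacharyya_overlap(window, bins)
  wk <- wu_kofke_measures(window, temperature, bins)
  wmax <- max(max_weight(window$dU_forward, temperature),
              max_weight(window$dU_backward, temperature))
  ddg_ea <- ea_hysteresis(window, temperature)
  ddg_ti <- if (!is.null(window$dudl_low) && !is.null(window$dudl_high)) {
    bar_ti_discrepancy(window, temperature)
  } else NA_real_
  flags <- c(
    omega = omega < thresholds$omega,
    kab = wk$kab < thresholds$kab,
    pi = wk$pi < thresholds$pi,
    wmax = wmax > thresholds$wmax,
    ddg_ea = ddg_ea > thresholds$ddg_ea,
    ddg_ti = !is.na(ddg_ti) && ddg_ti > thresholds$ddg_ti
  )
  structure(
    list(lambda_low = window$lambda_low, lambda_high = window$lambda_high,
         omega = omega, kab = wk$kab, pi = wk$pi, wmax = wmax,
         ddg_ea = ddg_ea, ddg_ti = ddg_ti, flags = flags, low_n = wk$low_n),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> [%g, %g] omega=%.3f kab=%.3f pi=%.2f wmax=%.3f ddg_ea=%.2f ddg_ti=%s; %d flag(s)\n",
    x$lambda_low, x$lambda_high, x$omega, x$kab, x$pi, x$wmax, x$ddg_ea,
    if (is.na(x$ddg_ti)) "NA" else sprintf("%.2f", x$ddg_ti), sum(x$flags)))
  invisible(x)
}

#' Build an overlap report from precomputed measures
#'
#' Applies the thresholds to measures computed elsewhere (e.g. read from a
#' report file) so they can be fed to [assess_window()].
#'
#' @param omega,kab,pi,wmax,ddg_ea,ddg_ti The six measures; `ddg_ti` may be
#'   `NA`.
#' @param lambda_low,lambda_high Window bounds.
#' @param thresholds Threshold list as from [default_thresholds()].
#' @return An `overlap_report`.
#' @export
overlap_report_from_measures <- function(omega, kab, pi, wmax, ddg_ea,
                                         ddg_ti = NA_real_,
                                         lambda_low = 0, lambda_high = 1,
                                         thresholds = default_thresholds()) {
  flags <- c(
    omega = omega < thresholds$omega,
    kab = kab < thresholds$kab,
    pi = pi < thresholds$pi,
    wmax = wmax > thresholds$wmax,
    ddg_ea = ddg_ea > thresholds$ddg_ea,
    ddg_ti = !is.na(ddg_ti) && ddg_ti > thresholds$ddg_ti
  )
  structure(
    list(lambda_low = lambda_low, lambda_high = lambda_high,
         omega = omega, kab = kab, pi = pi, wmax = wmax,
         ddg_ea = ddg_ea, ddg_ti = ddg_ti, flags = flags, low_n = FALSE),
    class = "overlap_report"
  )
}

#' Lambda-refinement decision for one window
#'
#' A window is refined when at least two of the six measures fail their
#' thresholds, or whenever Pi is negative. The proposed new lambda is the
#' window midpoint.
#'
#' @param report An `overlap_report` (or a [window_samples()] object, which
#'   is diagnosed first).
#' @param thresholds Threshold list; only used when `report` is a window.
#' @param temperature Temperature in kelvin; only used when `report` is a
#'   window.
#' @return List with `refine` (logical), `proposed_lambda` (midpoint or
#'   `NA`), and `reasons` (names of failing measures; includes
#'   `"pi_negative"` when negativity alone triggers).
#' @export
assess_window <- function(report, thresholds = default_thresholds(),
                          temperature = 300) {
  if (inherits(report, "window_samples")) {
    report <- overlap_report(report, temperature = temperature,
                             thresholds = thresholds)
  }
  stopifnot(inherits(report, "overlap_report"))
  reasons <- names(report$flags)[report$flags]
  pi_neg <- is.finite(report$pi) && report$pi < 0
  refine <- sum(report$flags) >= 2L || pi_neg
  if (pi_neg && !("pi_negative" %in% reasons)) {
    reasons <- c(reasons, "pi_negative")
  }
  list(
    refine = refine,
    proposed_lambda = if (refine) (report$lambda_low + report$lambda_high) / 2 else NA_real_,
    reasons = if (refine) reasons else character(0)
  )
}
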