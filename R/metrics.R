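## Quality metrics comparing calculated with experimental affinities:
## MAD, MADtr (systematic error removed), maximum error, Pearson R (plain or
## antisymmetrized over both perturbation directions), regression slope,
## Kendall tau-b, IC50 conversion, and the parametric bootstrap machinery.

#' Paired calculated/experimental affinities
#'
#' @param calculated Calculated affinities (dG or pairwise ddG), kJ/mol.
#' @param experimental Experimental affinities, kJ/mol.
#' @param labels Optional point labels.
#' @param calc_se,exp_se Optional per-point standard errors, kJ/mol.
#' @param relative Logical; `TRUE` when the values are pairwise relative
#'   affinities (ddG), in which case the antisymmetrized Pearson mode is
#'   meaningful.
#' @return An object of class `affinity_pairs`.
#' @export
affinity_pairs <- function(calculated, experimental, labels = NULL,
                           calc_se = NA_real_, exp_se = NA_real_,
                           relative = FALSE) {
  calculated <- as.numeric(calculated)
  experimental <- as.numeric(experimental)
  n <- length(calculated)
  if (n < 2L || length(experimental) != n) {
    stop("`calculated` and `experimental` must have equal length >= 2",
         call. = FALSE)
  }
  if (!all(is.finite(calculated)) || !all(is.finite(experimental))) {
    stop("affinities must be finite", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(
    list(labels = as.character(labels),
         calculated = calculated, experimental = experimental,
         calc_se = rep_len(as.numeric(calc_se), n),
         exp_se = rep_len(as.numeric(exp_se), n),
         relative = isTRUE(relative)),
    class = "affinity_pairs"
  )
}

#' @export
print.affinity_pairs <- function(x, ...) {
  cat(sprintf("<affinity_pairs> %d %s points\n", length(x$calculated),
              if (x$relative) "relative (ddG)" else "absolute (dG)"))
  invisible(x)
}

as_pairs <- function(pairs) {
  if (inherits(pairs, "affinity_pairs")) return(pairs)
  stop("expected an `affinity_pairs` object", call. = FALSE)
}

#' Mean absolute deviation
#'
#' @param pairs An [affinity_pairs()] object.
#' @return MAD = mean |calc - exp|, kJ/mol.
#' @export
mad_error <- function(pairs) {
  p <- as_pairs(pairs)
  mean(abs(p$calculated - p$experimental))
}

#' Maximum absolute error
#'
#' @param pairs An [affinity_pairs()] object.
#' @return max |calc - exp|, kJ/mol.
#' @export
max_error <- function(pairs) {
  p <- as_pairs(pairs)
  max(abs(p$calculated - p$experimental))
}

#' MAD after removal of the systematic error
#'
#' Subtracts the mean signed error from the calculated values before taking
#' the mean absolute deviation, so a constant offset scores zero.
#'
#' @param pairs An [affinity_pairs()] object.
#' @return MADtr, kJ/mol.
#' @export
madtr <- function(pairs) {
  p <- as_pairs(pairs)
  err <- p$calculated - p$experimental
  mean(abs(err - mean(err)))
}

#' Pearson correlation, plain or antisymmetrized
#'
#' In plain mode this is the centred Pearson correlation and the regression
#' slope of calculated on experimental. For relative (ddG) data the result
#' depends on the arbitrary direction chosen for each perturbation; the
#' antisymmetrized mode removes that dependence by augmenting every pair
#' (x, y) with its mirror (-x, -y) before the centred computation (the mean
#' is then exactly zero).
#'
#' @param pairs An [affinity_pairs()] object.
#' @param antisymmetrize Augment with the sign-flipped points first?
#' @return List with `r`, `r_squared`, `slope`.
#' @export
pearson <- function(pairs, antisymmetrize = FALSE) {
  p <- as_pairs(pairs)
  x <- p$experimental; y <- p$calculated
  n_min <- if (antisymmetrize) 2L else 3L
  if (length(x) < n_min) {
    stop(sprintf("need at least %d points", n_min), call. = FALSE)
  }
  if (antisymmetrize) {
    x <- c(x, -x); y <- c(y, -y)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined: zero variance in one series", call. = FALSE)
  }
  r <- cor(x, y)
  slope <- cov(x, y) / var(x)
  list(r = r, r_squared = r^2, slope = slope)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau; ties in either series reduce the denominator.
#'
#' @param pairs An [affinity_pairs()] object.
#' @return tau-b in \[-1, 1\].
#' @export
kendall_tau <- function(pairs) {
  p <- as_pairs(pairs)
  x <- p$experimental; y <- p$calculated
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("tau undefined: a series is constant", call. = FALSE)
  }
  cor(x, y, method = "kendall")
}

#' Convert IC50 to a binding free energy
#'
#' dG = RT ln(IC50 / C0) with the standard-state concentration C0 = 1 M.
#'
#' @param ic50 IC50 in mol/L; must be positive.
#' @param temperature Temperature in kelvin (default 300).
#' @return dG in kJ/mol.
#' @examples
#' ic50_to_dg(50e-6)  # ~ -24.7 kJ/mol at 300 K
#' @export
ic50_to_dg <- function(ic50, temperature = 300) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("`ic50` must be positive", call. = FALSE)
  }
  GAS_CONSTANT * temperature * log(ic50)
}

#' Full metric report
#'
#' @param pairs An [affinity_pairs()] object.
#' @param antisymmetrize Pearson mode (see [pearson()]).
#' @return List of class `metric_report` with `mad`, `madtr`, `max_error`,
#'   `pearson_r`, `r_squared`, `slope`, `kendall_tau`.
#' @export
metric_report <- function(pairs, antisymmetrize = FALSE) {
  p <- as_pairs(pairs)
  pr <- pearson(p, antisymmetrize)
  structure(
    list(mad = mad_error(p), madtr = madtr(p), max_error = max_error(p),
         pearson_r = pr$r, r_squared = pr$r_squared, slope = pr$slope,
         kendall_tau = kendall_tau(p), antisymmetrize = antisymmetrize,
         n = length(p$calculated)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d: MAD %.2f, MADtr %.2f, max %.2f, R %.2f%s, slope %.2f, tau %.2f\n",
    x$n, x$mad, x$madtr, x$max_error, x$pearson_r,
    if (x$antisymmetrize) " (antisym.)" else "", x$slope, x$kendall_tau))
  invisible(x)
}

#' Parametric bootstrap configuration
#'
#' @param n_samples Bootstrap replicates (default 500).
#' @param exp_sigma Assumed experimental uncertainty, kJ/mol (default 1.7),
#'   used where `exp_se` is missing.
#' @param seed Integer seed.
#' @return List of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_samples = 500L, exp_sigma = 1.7, seed = 1L) {
  if (n_samples < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  if (exp_sigma < 0) stop("`exp_sigma` must be >= 0", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), exp_sigma = exp_sigma,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Parametric bootstrap of the quality metrics
#'
#' For each replicate, independent Gaussian noise is added to both series
#' (per-point `calc_se` for the calculated values, `exp_se` or the
#' configured `exp_sigma` for the experimental ones) and the metrics are
#' recomputed. Replicates where a metric is undefined (e.g. a constant
#' series for tau) are dropped per metric and counted.
#'
#' @param pairs An [affinity_pairs()] object; `calc_se` entries that are
#'   `NA` are treated as 0.
#' @param cfg A [bootstrap_config()].
#' @param metrics Character vector from `c("mad", "madtr", "max_error",
#'   "pearson_r", "slope", "kendall_tau")`.
#' @param antisymmetrize Pearson mode.
#' @return List of class `bootstrap_report`: per metric the point `estimate`,
#'   bootstrap `mean`, `se`, and `n_dropped`.
#' @export
bootstrap_metrics <- function(pairs, cfg = bootstrap_config(),
                              metrics = c("mad", "madtr", "max_error",
                                          "pearson_r", "slope", "kendall_tau"),
                              antisymmetrize = FALSE) {
  p <- as_pairs(pairs)
  stopifnot(inherits(cfg, "bootstrap_config"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  n <- length(p$calculated)
  csd <- ifelse(is.na(p$calc_se), 0, p$calc_se)
  esd <- ifelse(is.na(p$exp_se), cfg$exp_sigma, p$exp_se)

  eval_metrics <- function(calc, expv) {
    pp <- affinity_pairs(calc, expv, relative = p$relative)
    out <- setNames(rep(NA_real_, length(metrics)), metrics)
    for (m in metrics) {
      out[m] <- tryCatch(switch(m,
        mad = mad_error(pp), madtr = madtr(pp), max_error = max_error(pp),
        pearson_r = pearson(pp, antisymmetrize)$r,
        slope = pearson(pp, antisymmetrize)$slope,
        kendall_tau = kendall_tau(pp)),
        error = function(e) NA_real_)
    }
    out
  }

  point <- eval_metrics(p$calculated, p$experimental)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  draws <- matrix(NA_real_, nrow = cfg$n_samples, ncol = length(metrics),
                  dimnames = list(NULL, metrics))
  for (b in seq_len(cfg$n_samples)) {
    calc_b <- p$calculated + rnorm(n, 0, csd)
    exp_b <- p$experimental + rnorm(n, 0, esd)
    draws[b, ] <- eval_metrics(calc_b, exp_b)
  }
  res <- lapply(metrics, function(m) {
    v <- draws[, m]
    ok <- v[!is.na(v)]
    list(estimate = unname(point[m]),
         mean = if (length(ok)) mean(ok) else NA_real_,
         se = if (length(ok) >= 2L) sd(ok) else 0,
         n_dropped = sum(is.na(v)))
  })
  structure(setNames(res, metrics), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("  %-12s %8.3f  (boot %8.3f +/- %.3f, %d dropped)\n",
                m, x[[m]]$estimate, x[[m]]$mean, x[[m]]$se, x[[m]]$n_dropped))
  }
  invisible(x)
}
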