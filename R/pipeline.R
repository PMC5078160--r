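## Umbrella configuration and pipeline driver tying the stages together:
## estimate -> diagnose (per-window inputs), network -> evaluate (edge
## tables), and score (component tables). Randomness fans out from a single
## seed via a stage counter so each stage is independently reproducible.

#' Pipeline run configuration
#'
#' Validated container of all stage settings. Defaults reproduce the
#' benchmark study conditions: T = 300 K, overlap thresholds
#' 0.7/0.7/0.5/0.3/4/4, parametric metric bootstrap with 500 replicates and
#' 1.7 kJ/mol experimental sigma, and a 100-replicate MBAR bootstrap.
#'
#' @param windows_file,dudl_file Optional per-window sample TSVs (see
#'   [read_window_file()]).
#' @param ukn_file Optional u_kn CSV for MBAR (see [read_ukn_file()]).
#' @param edges_file,ligands_file Optional network CSVs.
#' @param components_file Optional component-table CSV for scoring.
#' @param temperature Kelvin.
#' @param thresholds Diagnostic thresholds, as [default_thresholds()].
#' @param scheme Network comparison scheme for [all_pairs_table()].
#' @param reference Reference ligand id for the `fixed_reference` scheme.
#' @param variant Composite-score variant.
#' @param n_boot Metric bootstrap replicates.
#' @param exp_sigma Experimental sigma for the metric bootstrap, kJ/mol.
#' @param mbar_boot MBAR bootstrap replicates.
#' @param antisymmetrize Pearson mode for relative data.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @return List of class `run_config`.
#' @export
run_config <- function(windows_file = NULL, dudl_file = NULL, ukn_file = NULL,
                       edges_file = NULL, ligands_file = NULL,
                       components_file = NULL,
                       temperature = 300, thresholds = default_thresholds(),
                       scheme = "all_pairs", reference = NULL,
                       variant = "corrected", n_boot = 500L, exp_sigma = 1.7,
                       mbar_boot = 100L, antisymmetrize = FALSE,
                       seed = 1L, out_dir = NULL) {
  kT(temperature)
  need_names <- c("omega", "kab", "pi", "wmax", "ddg_ea", "ddg_ti")
  if (!all(need_names %in% names(thresholds))) {
    stop("`thresholds` must contain: ", paste(need_names, collapse = ", "),
         call. = FALSE)
  }
  if (n_boot < 2L || mbar_boot < 2L) stop("bootstrap counts must be >= 2", call. = FALSE)
  if (exp_sigma < 0) stop("`exp_sigma` must be >= 0", call. = FALSE)
  for (f in c(windows_file, dudl_file, ukn_file, edges_file, ligands_file,
              components_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  structure(
    list(windows_file = windows_file, dudl_file = dudl_file,
         ukn_file = ukn_file, edges_file = edges_file,
         ligands_file = ligands_file, components_file = components_file,
         temperature = temperature, thresholds = thresholds,
         scheme = scheme, reference = reference, variant = variant,
         n_boot = as.integer(n_boot), exp_sigma = exp_sigma,
         mbar_boot = as.integer(mbar_boot),
         antisymmetrize = isTRUE(antisymmetrize),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `thresholds` may
#' be partially specified and is merged over the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) {
    y$thresholds <- utils::modifyList(default_thresholds(), y$thresholds)
  }
  do.call(run_config, y)
}

## stage sub-seed: deterministic fan-out from the master seed
stage_seed <- function(cfg, stage_index) {
  (cfg$seed * 1000L + stage_index) %% .Machine$integer.max
}

#' Run the configured pipeline
#'
#' Executes every stage whose inputs are configured, in order: window
#' estimation + diagnostics, MBAR on a u_kn matrix (with bootstrap SE),
#' network composition + metric evaluation, and component-table scoring.
#' Writes a JSON summary and CSV tables into `out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result` with one element per executed
#'   stage plus `timings` (seconds) and `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  result <- list(seed = cfg$seed)
  timings <- c()
  tick <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  if (!is.null(cfg$windows_file)) {
    result$windows <- tick({
      windows <- read_window_file(cfg$windows_file, cfg$dudl_file)
      per_window <- lapply(windows, function(w) {
        rep <- overlap_report(w, cfg$temperature, thresholds = cfg$thresholds)
        dec <- assess_window(rep)
        bar <- bar_estimate(w, cfg$temperature)
        list(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
             bar = bar$value, bar_se = bar$se,
             ea_fwd = ea_estimate(w$dU_forward, cfg$temperature)$value,
             omega = rep$omega, kab = rep$kab, pi = rep$pi,
             wmax = rep$wmax, ddg_ea = rep$ddg_ea, ddg_ti = rep$ddg_ti,
             refine = dec$refine, proposed_lambda = dec$proposed_lambda,
             reasons = dec$reasons)
      })
      list(per_window = per_window,
           total_bar = sum(vapply(per_window, `[[`, numeric(1), "bar")),
           total_bar_se = sqrt(sum(vapply(per_window, `[[`, numeric(1),
                                          "bar_se")^2)),
           n_refine = sum(vapply(per_window, `[[`, logical(1), "refine")))
    }, "windows")
  }

  if (!is.null(cfg$ukn_file)) {
    result$mbar <- tick({
      rps <- read_ukn_file(cfg$ukn_file)
      fit <- mbar_estimate(rps)
      se <- mbar_bootstrap_se(rps, n_boot = cfg$mbar_boot,
                              seed = stage_seed(cfg, 2L))
      list(f = fit$f, endpoint = fit$estimate$value, endpoint_se = as.numeric(se),
           boot_failed = attr(se, "n_failed"))
    }, "mbar")
  }

  if (!is.null(cfg$edges_file) && !is.null(cfg$ligands_file)) {
    result$network <- tick({
      net <- read_network_files(cfg$edges_file, cfg$ligands_file)
      tab <- all_pairs_table(net, scheme = cfg$scheme,
                             reference = cfg$reference)
      out <- list(table = tab)
      with_exp <- tab[!is.na(tab$exp), ]
      if (nrow(with_exp) >= 2L) {
        pairs <- affinity_pairs(with_exp$calc, with_exp$exp,
                                labels = paste(with_exp$from, with_exp$to, sep = "->"),
                                calc_se = with_exp$se, relative = TRUE)
        out$metrics <- metric_report(pairs, antisymmetrize = cfg$antisymmetrize)
        out$bootstrap <- bootstrap_metrics(
          pairs, bootstrap_config(cfg$n_boot, cfg$exp_sigma,
                                  stage_seed(cfg, 3L)),
          antisymmetrize = cfg$antisymmetrize)
      }
      out
    }, "network")
  }

  if (!is.null(cfg$components_file)) {
    result$scores <- tick({
      tab <- read.csv(cfg$components_file, stringsAsFactors = FALSE)
      score_component_table(tab, variant = cfg$variant)
    }, "scores")
  }

  result$timings <- timings
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(result$network)) {
      write.csv(result$network$table,
                file.path(cfg$out_dir, "relative_affinities.csv"),
                row.names = FALSE)
    }
    if (!is.null(result$scores)) {
      write.csv(result$scores, file.path(cfg$out_dir, "binding_scores.csv"),
                row.names = FALSE)
    }
    # timings vary between runs and stay out of the summary so that seeded
    # reruns are byte-identical
    jsonlite::write_json(
      strip_for_json(result[setdiff(names(result), "timings")]),
      file.path(cfg$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  structure(result, class = "pipeline_result")
}

## drop non-serialisable bits (class attrs survive fine, tables get verbose)
strip_for_json <- function(x) {
  if (inherits(x, "metric_report") || inherits(x, "bootstrap_report")) {
    return(unclass(x))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, strip_for_json))
  x
}

#' @export
print.pipeline_result <- function(x, ...) {
  stages <- setdiff(names(x), c("seed", "timings"))
  cat(sprintf("<pipeline_result> stages: %s (seed %d)\n",
              paste(stages, collapse = ", "), x$seed))
  invisible(x)
}
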