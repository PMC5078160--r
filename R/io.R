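## Readers and writers for the package's tabular interchange formats:
## per-window perturbation-energy TSVs, u_kn reduced-potential CSVs with a
## structured sidecar header, and edge/ligand tables.

#' Read a window file
#'
#' The format is TSV with header columns `lambda_low`, `lambda_high`,
#' `direction` (`fwd` = sample of U(high)-U(low) in the low ensemble,
#' `rev` = sample of U(low)-U(high) in the high ensemble) and `dU` (kJ/mol),
#' one sample per row. An optional dU/dlambda file (TSV: `lambda`, `dudl`)
#' attaches derivative samples to the windows whose bounds match.
#'
#' @param path Window TSV path.
#' @param dudl_path Optional derivative TSV path.
#' @return List of [window_samples()], ordered by `lambda_low`.
#' @export
read_window_file <- function(path, dudl_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("window file is empty: ", path, call. = FALSE)
  need <- c("lambda_low", "lambda_high", "direction", "dU")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("window file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_dir <- which(!raw$direction %in% c("fwd", "rev"))
  if (length(bad_dir) > 0) {
    stop("invalid direction at line(s): ",
         paste(bad_dir + 1L, collapse = ", "), call. = FALSE)
  }
  num_bad <- which(!is.finite(suppressWarnings(as.numeric(raw$dU))) |
                   !is.finite(suppressWarnings(as.numeric(raw$lambda_low))) |
                   !is.finite(suppressWarnings(as.numeric(raw$lambda_high))))
  if (length(num_bad) > 0) {
    stop("non-numeric or non-finite value at line(s): ",
         paste(num_bad + 1L, collapse = ", "), call. = FALSE)
  }
  raw$dU <- as.numeric(raw$dU)

  dudl <- NULL
  if (!is.null(dudl_path)) {
    dudl <- read.delim(dudl_path, stringsAsFactors = FALSE)
    if (!all(c("lambda", "dudl") %in% names(dudl))) {
      stop("dudl file needs columns `lambda`, `dudl`", call. = FALSE)
    }
  }
  key <- paste(raw$lambda_low, raw$lambda_high)
  out <- lapply(unique(key), function(k) {
    d <- raw[key == k, ]
    lo <- d$lambda_low[1L]; hi <- d$lambda_high[1L]
    dl_lo <- dl_hi <- NULL
    if (!is.null(dudl)) {
      dl_lo <- dudl$dudl[dudl$lambda == lo]
      dl_hi <- dudl$dudl[dudl$lambda == hi]
      if (length(dl_lo) < 2L) dl_lo <- NULL
      if (length(dl_hi) < 2L) dl_hi <- NULL
    }
    window_samples(lo, hi,
                   dU_forward = d$dU[d$direction == "fwd"],
                   dU_backward = d$dU[d$direction == "rev"],
                   dudl_low = dl_lo, dudl_high = dl_hi)
  })
  out[order(vapply(out, function(w) w$lambda_low, numeric(1)))]
}

#' Write a window file
#'
#' @param windows List of [window_samples()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_file <- function(windows, path) {
  rows <- lapply(windows, function(w) {
    rbind(
      data.frame(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
                 direction = "fwd", dU = w$dU_forward),
      data.frame(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
                 direction = "rev", dU = w$dU_backward))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a u_kn reduced-potential file
#'
#' CSV matrix with the snapshot origin-state index in the first column and
#' the potential evaluated at every state in the remaining columns; the
#' lambda schedule and temperature live in `#`-prefixed header lines
#' (`# lambdas: 0,0.05,...` and `# temperature: 300`).
#'
#' @param path File path.
#' @return A [reduced_potential_set()].
#' @export
read_ukn_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(name) {
    ln <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("u_kn header missing field: ", name, call. = FALSE)
    sub(paste0("^#\\s*", name, ":\\s*"), "", ln)
  }
  lambdas <- as.numeric(strsplit(get_field("lambdas"), ",")[[1L]])
  temperature <- as.numeric(get_field("temperature"))
  d <- read.csv(path, comment.char = "#", header = FALSE)
  reduced_potential_set(lambdas, t(as.matrix(d[, -1L])), d[[1L]], temperature)
}

#' Write a u_kn reduced-potential file
#'
#' @param rps A [reduced_potential_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ukn_file <- function(rps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# lambdas: ", paste(rps$lambdas, collapse = ",")),
    paste0("# temperature: ", rps$temperature)), con)
  write.table(cbind(rps$origin, t(rps$u)), con, sep = ",",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a perturbation network from edge and ligand CSVs
#'
#' Edge CSV columns: `from`, `to`, `value`, `se`, `conformer` (optional,
#' multiple rows per from/to pair become conformer candidates), `selected`
#' (optional logical marking the chosen candidate). Ligand CSV columns:
#' `id`, `set`, `exp_dg`, `is_reference`, `non_binder` (optional).
#'
#' @param edges_path,ligands_path CSV paths.
#' @return A [perturbation_network()].
#' @export
read_network_files <- function(edges_path, ligands_path) {
  ed <- read.csv(edges_path, stringsAsFactors = FALSE)
  li <- read.csv(ligands_path, stringsAsFactors = FALSE)
  need_e <- c("from", "to", "value")
  if (!all(need_e %in% names(ed))) {
    stop("edge file needs columns: ", paste(need_e, collapse = ", "), call. = FALSE)
  }
  if (!all(c("id", "set") %in% names(li))) {
    stop("ligand file needs columns: id, set", call. = FALSE)
  }
  if (is.null(ed$se)) ed$se <- NA_real_
  if (is.null(ed$conformer)) ed$conformer <- "conf1"
  lig <- ligand_table(
    li$id, li$set,
    exp_dg = if (is.null(li$exp_dg)) NA_real_ else li$exp_dg,
    is_reference = if (is.null(li$is_reference)) FALSE else li$is_reference,
    non_binder = if (is.null(li$non_binder)) FALSE else li$non_binder)
  key <- paste(ed$from, ed$to, sep = "->")
  edges <- lapply(unique(key), function(k) {
    d <- ed[key == k, ]
    sel <- NA_integer_
    if (!is.null(d$selected) && any(as.logical(d$selected), na.rm = TRUE)) {
      sel <- which(as.logical(d$selected))[1L]
    }
    perturbation_edge(d$from[1L], d$to[1L], d$value, d$se, d$conformer,
                      selected = sel)
  })
  perturbation_network(lig, edges,
                       set_id = if (length(unique(li$set)) == 1L) li$set[1L] else NA_integer_)
}
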