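## Packaged benchmark tables for the HSP90 congeneric-series study (D3R
## Grand Challenge 2015 data set): docking/MM-GBSA scores with experimental
## affinities, the QM/MM energy-component table, and the alchemical
## perturbation edges with conformer candidates. Values are stored at the
## 0.1 kJ/mol precision of the published tables.

FIXTURE_MD5 <- c(
  hsp90_table3_scores.csv = "40e18ff581bb6f818c0038c26c5dc9cc",
  hsp90_table5_components.csv = "0e3e979b5fc24fb35e5df4f0e61ed3e4",
  hsp90_table7_edges.csv = "2f2bfe42033a3713f82b5be453f642b6",
  hsp90_table7_set2.csv = "1622addd3c254fcf1120da860af382e6"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "fesbench")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}

read_fixture_csv <- function(file) {
  p <- fixture_path(file)
  got <- unname(tools::md5sum(p))
  if (!identical(got, unname(FIXTURE_MD5[[file]]))) {
    stop(sprintf("fixture %s is corrupted (md5 %s, expected %s)",
                 file, got, FIXTURE_MD5[[file]]), call. = FALSE)
  }
  read.csv(p, stringsAsFactors = FALSE, colClasses = NA)
}

#' Load the packaged HSP90 benchmark tables
#'
#' Returns the published tables used as inputs throughout the package:
#' \describe{
#'   \item{`table3`}{absolute binding-affinity scores (GScore, Emodel,
#'     IFDScore, MM/GBSA) with experimental dG for the 19 ligands; set 2
#'     appears in two blocks (3VHA- and 2WI7-based calculations).}
#'   \item{`table5`}{the QM/MM (free-)energy components per ligand, plus the
#'     printed composite dG_bind and dG'_bind columns for verification.}
#'   \item{`table7`}{relative binding free energies of the studied
#'     perturbations for sets 1 and 3, with both conformer candidates and
#'     the published selection.}
#'   \item{`table7_set2`}{the direct set-2 perturbations (101 to 100, 105,
#'     106) per crystal structure and water treatment, with experimental
#'     relative affinities.}
#'   \item{`lambda_schedule`}{the 13-point coupling schedule.}
#' }
#' File checksums are verified on every load.
#'
#' @return Named list of data.frames (and the schedule vector).
#' @export
load_fixtures <- function() {
  list(
    table3 = read_fixture_csv("hsp90_table3_scores.csv"),
    table5 = read_fixture_csv("hsp90_table5_components.csv"),
    table7 = read_fixture_csv("hsp90_table7_edges.csv"),
    table7_set2 = read_fixture_csv("hsp90_table7_set2.csv"),
    lambda_schedule = default_lambda_schedule()
  )
}

#' Build the perturbation network of benchmark set 1 or 3
#'
#' Assembles a [perturbation_network()] from the packaged edge table,
#' honouring the published conformer selections. Set 1 has five ligands and
#' one reference; set 3 has ten ligands (including the two stereoisomers of
#' the non-binder) and three references.
#'
#' @param set_id 1 or 3.
#' @param use_recorded_selection Keep the published (bold-face) conformer
#'   choices (default); otherwise edges touching a reference are re-selected
#'   by the rule in [select_conformer()].
#' @return A `perturbation_network`.
#' @export
hsp90_network <- function(set_id, use_recorded_selection = TRUE) {
  if (!set_id %in% c(1L, 3L)) stop("`set_id` must be 1 or 3", call. = FALSE)
  fx <- load_fixtures()
  ed <- fx$table7[fx$table7$set_id == set_id, ]
  t3 <- fx$table3[fx$table3$block %in% c("set1", "set3"), ]

  ids <- unique(c(ed$from, ed$to))
  refs <- grep("^ref", ids, value = TRUE)
  exp_dg <- rep(NA_real_, length(ids))
  nb <- rep(FALSE, length(ids))
  for (i in seq_along(ids)) {
    base_id <- sub("^(61)[SR]$", "\\1", ids[i])
    j <- match(base_id, t3$ligand)
    if (!is.na(j) && !(ids[i] %in% refs)) {
      nb[i] <- t3$non_binder[j]
      # non-binders keep only their assigned bound, used when opted in
      exp_dg[i] <- t3$exp_dg[j]
      if (nb[i]) exp_dg[i] <- NA_real_
    }
  }
  lig <- ligand_table(ids, set_id = set_id, exp_dg = exp_dg,
                      is_reference = ids %in% refs, non_binder = nb)
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    r <- ed[i, ]
    has2 <- !is.na(r$value2)
    perturbation_edge(
      r$from, r$to,
      values = if (has2) c(r$value1, r$value2) else r$value1,
      ses = if (has2) c(r$se1, r$se2) else r$se1,
      conformers = if (has2) c(r$label1, r$label2) else r$label1,
      selected = if (use_recorded_selection) r$selected else NA_integer_)
  })
  perturbation_network(lig, edges, set_id = set_id)
}

#' Set-2 affinity pairs for one crystal structure and water treatment
#'
#' The three direct perturbations of benchmark set 2 as an
#' [affinity_pairs()] object (relative ddG data).
#'
#' @param structure "2WI7", "3FT5", or "2WI7_3FT5".
#' @param water "without_wat" or "with_wat".
#' @return An `affinity_pairs` object with `relative = TRUE`.
#' @export
hsp90_set2_pairs <- function(structure = c("2WI7", "3FT5", "2WI7_3FT5"),
                             water = c("without_wat", "with_wat")) {
  structure <- match.arg(structure)
  water <- match.arg(water)
  t7 <- load_fixtures()$table7_set2
  d <- t7[t7$block == water & t7$structure == structure, ]
  if (nrow(d) == 0L) {
    stop(sprintf("no set-2 data for %s / %s", structure, water), call. = FALSE)
  }
  affinity_pairs(d$value, d$exp_ddg,
                 labels = paste(d$from, d$to, sep = "->"),
                 calc_se = d$se, relative = TRUE)
}
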