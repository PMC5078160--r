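## Perturbation-network composition. Each alchemical edge carries a relative
## binding free energy ddG = dG_bind(to) - dG_bind(from) (thermodynamic-cycle
## convention), possibly with several conformer candidates from independent
## perturbations. Relative affinities between any two ligands are signed sums
## of selected edge values along the fewest-edge path; standard errors add in
## quadrature (correlations between shared path segments are ignored).

#' Ligand table constructor
#'
#' @param id Character ligand labels (e.g. "80", "ref2", "61S").
#' @param set_id Integer series id (1, 2, or 3).
#' @param exp_dg Experimental binding free energies, kJ/mol; `NA` for
#'   reference ligands and unknowns.
#' @param is_reference Logical; reference ligands are auxiliary molecules
#'   without experimental data, inserted to keep perturbations small.
#' @param non_binder Logical; experimentally a non-binder (affinity weaker
#'   than the assay ceiling).
#' @return A data.frame of ligands.
#' @export
ligand_table <- function(id, set_id, exp_dg = NA_real_, is_reference = FALSE,
                         non_binder = FALSE) {
  d <- data.frame(id = as.character(id), set_id = as.integer(set_id),
                  exp_dg = as.numeric(exp_dg),
                  is_reference = as.logical(is_reference),
                  non_binder = as.logical(non_binder),
                  stringsAsFactors = FALSE)
  if (any(d$is_reference & !is.na(d$exp_dg))) {
    stop("reference ligands must not carry experimental affinities", call. = FALSE)
  }
  if (anyDuplicated(d$id)) stop("duplicate ligand ids", call. = FALSE)
  d
}

#' Perturbation edge with conformer candidates
#'
#' @param from,to Ligand ids; the edge value is
#'   `dG_bind(to) - dG_bind(from)`.
#' @param values Candidate ddG values (kJ/mol), one per independent
#'   perturbation (e.g. the two ring conformations).
#' @param ses Candidate standard errors, kJ/mol.
#' @param conformers Candidate labels (e.g. "conf1"/"conf2" or "S"/"R").
#' @param selected Optional index of a pre-selected candidate (e.g. recorded
#'   from an upstream analysis); when `NA` the selection rule of
#'   [pn_select_conformers()] applies.
#' @return A one-row list of class `perturbation_edge`.
#' @export
perturbation_edge <- function(from, to, values, ses = NA_real_,
                              conformers = NULL, selected = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("an edge needs at least one candidate", call. = FALSE)
  ses <- rep_len(as.numeric(ses), length(values))
  if (any(!is.na(ses) & ses < 0)) stop("standard errors must be >= 0", call. = FALSE)
  if (is.null(conformers)) conformers <- paste0("conf", seq_along(values))
  if (!is.na(selected) && (selected < 1L || selected > length(values))) {
    stop("`selected` is not a valid candidate index", call. = FALSE)
  }
  structure(
    list(from = as.character(from), to = as.character(to),
         values = values, ses = ses, conformers = as.character(conformers),
         selected = as.integer(selected)),
    class = "perturbation_edge"
  )
}

#' Perturbation network
#'
#' @param ligands A [ligand_table()].
#' @param edges List of [perturbation_edge()] objects.
#' @param set_id Optional series id tag.
#' @return An object of class `perturbation_network`.
#' @export
perturbation_network <- function(ligands, edges, set_id = NA_integer_) {
  stopifnot(is.data.frame(ligands))
  if (!all(vapply(edges, inherits, logical(1), "perturbation_edge"))) {
    stop("`edges` must be a list of perturbation_edge objects", call. = FALSE)
  }
  ends <- vapply(edges, function(e) c(e$from, e$to), character(2))
  if (!all(ends %in% ligands$id)) {
    stop("edge endpoint(s) missing from the ligand table: ",
         paste(setdiff(as.vector(ends), ligands$id), collapse = ", "),
         call. = FALSE)
  }
  keys <- apply(ends, 2L, paste, collapse = "->")
  if (anyDuplicated(keys)) stop("duplicate directed edge(s)", call. = FALSE)
  structure(list(ligands = ligands, edges = edges, set_id = set_id),
            class = "perturbation_network")
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat(sprintf("<perturbation_network> set %s: %d ligands (%d reference), %d edges\n",
              ifelse(is.na(x$set_id), "?", x$set_id), nrow(x$ligands),
              sum(x$ligands$is_reference), length(x$edges)))
  invisible(x)
}

#' Select the conformer candidate of one edge
#'
#' For edges that touch a reference ligand, the retained perturbation is the
#' one giving the most favourable binding of the non-reference ligand
#' relative to the reference: for an edge X -> ref the candidate with the
#' largest ddG, for ref -> X the smallest. Ties keep the first-listed
#' candidate. A pre-recorded `selected` index always wins. An edge between
#' two non-reference ligands with several candidates and no recorded
#' selection is a configuration error (no rule is defined for it).
#'
#' @param edge A [perturbation_edge()].
#' @param ligands A [ligand_table()] identifying the reference ligands.
#' @return List with `value`, `se`, `conformer`, `index`.
#' @export
select_conformer <- function(edge, ligands) {
  stopifnot(inherits(edge, "perturbation_edge"))
  if (!is.na(edge$selected)) {
    i <- edge$selected
  } else if (length(edge$values) == 1L) {
    i <- 1L
  } else {
    ref_from <- ligands$is_reference[match(edge$from, ligands$id)]
    ref_to <- ligands$is_reference[match(edge$to, ligands$id)]
    if (isTRUE(ref_to)) {
      i <- which.max(edge$values)   # X -> ref: max ddG = lowest dG_bind(X)
    } else if (isTRUE(ref_from)) {
      i <- which.min(edge$values)   # ref -> X: min ddG = lowest dG_bind(X)
    } else {
      stop(sprintf(
        "edge %s->%s joins two non-reference ligands with %d candidates and no recorded selection",
        edge$from, edge$to, length(edge$values)), call. = FALSE)
    }
  }
  list(value = edge$values[i], se = edge$ses[i],
       conformer = edge$conformers[i], index = i)
}

## Resolve every edge to its selected candidate; returns a data.frame
## from,to,value,se,conformer.
pn_select_conformers <- function(net) {
  stopifnot(inherits(net, "perturbation_network"))
  rows <- lapply(net$edges, function(e) {
    s <- select_conformer(e, net$ligands)
    data.frame(from = e$from, to = e$to, value = s$value, se = s$se,
               conformer = s$conformer, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## igraph over the selected edges (undirected; sign handled per traversal).
pn_graph <- function(net) {
  sel <- pn_select_conformers(net)
  g <- igraph::graph_from_data_frame(
    sel[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$ligands$id, stringsAsFactors = FALSE))
  igraph::E(g)$value <- sel$value
  igraph::E(g)$se <- sel$se
  igraph::E(g)$from_id <- sel$from
  igraph::E(g)$to_id <- sel$to
  g
}

#' Relative binding free energy between two ligands
#'
#' Composes ddG(a -> b) = dG_bind(b) - dG_bind(a) as the signed sum of
#' selected edge values along the fewest-edge path from `a` to `b`; the
#' standard error is the quadrature sum of the traversed edge SEs.
#'
#' @param net A [perturbation_network()].
#' @param ligand_a,ligand_b Ligand ids.
#' @param max_edges Maximum number of edges allowed in the path; `Inf` for
#'   unlimited.
#' @return A `free_energy_estimate` (method "network") with the edge count in
#'   `$n_edges`.
#' @export
relative_affinity <- function(net, ligand_a, ligand_b, max_edges = Inf) {
  stopifnot(inherits(net, "perturbation_network"))
  ligand_a <- as.character(ligand_a); ligand_b <- as.character(ligand_b)
  if (!all(c(ligand_a, ligand_b) %in% net$ligands$id)) {
    stop("unknown ligand id", call. = FALSE)
  }
  if (ligand_a == ligand_b) {
    return(free_energy_estimate(0, 0, "network",
                                direction = c(ligand_a, ligand_b),
                                extra = list(n_edges = 0L)))
  }
  g <- pn_graph(net)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = ligand_a, to = ligand_b, output = "epath"))
  ep <- sp$epath[[1L]]
  if (length(ep) == 0L) {
    stop(sprintf("no path between %s and %s", ligand_a, ligand_b), call. = FALSE)
  }
  if (length(ep) > max_edges) {
    stop(sprintf("path from %s to %s needs %d edges, more than the %s allowed",
                 ligand_a, ligand_b, length(ep), format(max_edges)),
         call. = FALSE)
  }
  # walk the vertex path and apply each edge with the traversal sign
  vp <- suppressWarnings(
    igraph::shortest_paths(g, from = ligand_a, to = ligand_b, output = "vpath"))$vpath[[1L]]
  vnames <- igraph::V(g)$name[vp]
  total <- 0; var_sum <- 0
  for (k in seq_along(ep)) {
    e <- ep[k]
    v_from <- igraph::E(g)$from_id[as.integer(e)]
    val <- igraph::E(g)$value[as.integer(e)]
    se <- igraph::E(g)$se[as.integer(e)]
    sgn <- if (vnames[k] == v_from) 1 else -1
    total <- total + sgn * val
    if (!is.na(se)) var_sum <- var_sum + se^2
  }
  free_energy_estimate(total, sqrt(var_sum), "network",
                       direction = c(ligand_a, ligand_b),
                       extra = list(n_edges = length(ep)))
}

#' Relative-affinity table under a comparison scheme
#'
#' Enumerates ligand pairs under one of three schemes and tabulates
#' calculated versus experimental relative affinities:
#' \describe{
#'   \item{`fixed_reference`}{every non-reference ligand against one chosen
#'     ligand (which must have an experimental value).}
#'   \item{`max_two_edges`}{all unordered pairs reachable within two edges.}
#'   \item{`all_pairs`}{all unordered pairs of non-reference ligands.}
#' }
#' Non-binder ligands are excluded unless `include_non_binders` is set, in
#' which case their assigned bound enters as the experimental value.
#'
#' @param net A [perturbation_network()].
#' @param scheme One of "fixed_reference", "max_two_edges", "all_pairs".
#' @param reference Ligand id for `fixed_reference`.
#' @param include_non_binders Include non-binder ligands as data points?
#' @return Data.frame: from, to, calc, se, exp (experimental ddG where both
#'   ligands have experimental values), n_edges.
#' @export
all_pairs_table <- function(net, scheme = c("all_pairs", "max_two_edges",
                                            "fixed_reference"),
                            reference = NULL, include_non_binders = FALSE) {
  scheme <- match.arg(scheme)
  lig <- net$ligands
  pool <- lig$id[!lig$is_reference & (include_non_binders | !lig$non_binder)]
  if (scheme == "fixed_reference") {
    if (is.null(reference) || !(reference %in% lig$id)) {
      stop("`reference` must name a ligand in the network", call. = FALSE)
    }
    if (is.na(lig$exp_dg[match(reference, lig$id)])) {
      stop("fixed reference has no experimental affinity", call. = FALSE)
    }
    pairs <- cbind(reference, setdiff(pool, reference))
    max_edges <- Inf
  } else {
    cmb <- utils::combn(pool, 2L)
    pairs <- t(cmb)
    max_edges <- if (scheme == "max_two_edges") 2L else Inf
  }
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    est <- tryCatch(relative_affinity(net, a, b, max_edges = max_edges),
                    error = function(e) NULL)
    if (is.null(est)) next
    ea <- lig$exp_dg[match(a, lig$id)]
    eb <- lig$exp_dg[match(b, lig$id)]
    rows[[length(rows) + 1L]] <- data.frame(
      from = a, to = b, calc = est$value, se = est$se,
      exp = if (!is.na(ea) && !is.na(eb)) eb - ea else NA_real_,
      n_edges = est$n_edges, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("scheme produced no feasible pairs on this network", call. = FALSE)
  }
  out
}
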