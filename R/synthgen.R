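## Synthetic inputs with exact ground truth: harmonic alchemical states
## (analytic partition function), Crooks-consistent Gaussian work pairs, and
## perturbation networks generated from known node free energies.

#' Sample a harmonic alchemical transformation
#'
#' One-dimensional harmonic states U_lambda(x) = k(lambda) x^2 / 2 with the
#' force constant interpolated linearly from `k0` to `k1`. Independent
#' Gaussian configurations are drawn from each state and the potential of
#' every snapshot is evaluated at all states, giving a full
#' [reduced_potential_set()] whose exact endpoint free-energy difference is
#' known in closed form, dA = (kT/2) ln(k1/k0).
#'
#' @param k0,k1 Endpoint force constants (energy/length^2), > 0.
#' @param lambda_schedule Coupling schedule (default the 13-point schedule).
#' @param n_per_state Snapshots per state (default 100, mirroring 1 ns
#'   sampled every 10 ps).
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return A `reduced_potential_set` with attribute `exact_dg` (kJ/mol).
#' @export
sample_harmonic_alchemy <- function(k0, k1,
                                    lambda_schedule = default_lambda_schedule(),
                                    n_per_state = 100L, temperature = 300,
                                    seed = 1L) {
  if (k0 <= 0 || k1 <= 0) stop("force constants must be positive", call. = FALSE)
  kt <- kT(temperature)
  lam <- as.numeric(lambda_schedule)
  kfun <- k0 + lam * (k1 - k0)
  K <- length(lam)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  x <- unlist(lapply(seq_len(K), function(k) {
    rnorm(n_per_state, 0, sqrt(kt / kfun[k]))
  }))
  origin <- rep(seq_len(K), each = n_per_state)
  u <- outer(kfun / 2, x^2)  # K x N potential energies, kJ/mol
  rps <- reduced_potential_set(lam, u, origin, temperature)
  attr(rps, "exact_dg") <- (kt / 2) * log(k1 / k0)
  rps
}

#' Sample a Crooks-consistent Gaussian work pair
#'
#' Forward perturbation energies are drawn from N(mu_f, sigma^2); backward
#' ones from the Crooks-consistent mirror, so the negated-backward
#' distribution is N(mu_f - sigma^2/kT, sigma^2) and the implied free-energy
#' difference is dG = mu_f - sigma^2 / (2 kT), halfway between the two
#' means.
#'
#' @param mu_f Forward mean, kJ/mol.
#' @param sigma Common standard deviation, kJ/mol, > 0.
#' @param n_f,n_r Forward/backward sample counts (default 100 each).
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @param lambda_low,lambda_high Window bounds for the returned object.
#' @param with_dudl Attach linear-path dU/dlambda samples consistent with
#'   the window (so TI on the window equals the same dG in expectation)?
#' @return A [window_samples()] object with attribute `implied_dg` (kJ/mol).
#' @export
sample_gaussian_work <- function(mu_f, sigma, n_f = 100L, n_r = 100L,
                                 temperature = 300, seed = 1L,
                                 lambda_low = 0, lambda_high = 1,
                                 with_dudl = FALSE) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  kt <- kT(temperature)
  implied <- mu_f - sigma^2 / (2 * kt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  dU_f <- rnorm(n_f, mu_f, sigma)
  dU_b <- rnorm(n_r, -mu_f + sigma^2 / kt, sigma)  # U(low)-U(high) in high state
  dl <- lambda_high - lambda_low
  win <- window_samples(
    lambda_low, lambda_high, dU_f, dU_b,
    dudl_low = if (with_dudl) rnorm(n_f, mu_f / dl, sigma / dl) else NULL,
    dudl_high = if (with_dudl) rnorm(n_r, (mu_f - sigma^2 / kt) / dl, sigma / dl) else NULL)
  attr(win, "implied_dg") <- implied
  win
}

#' Generate a perturbation network from known node free energies
#'
#' Edge values are node free-energy differences plus Gaussian noise. When
#' `conformer_offset > 0`, every edge that touches a reference ligand gets a
#' second, unfavourable conformer candidate offset by that amount (so the
#' selection rule should always recover the planted favourable one).
#'
#' @param node_dg Named numeric vector of true binding free energies,
#'   kJ/mol; names are ligand ids.
#' @param edge_list Two-column matrix or data.frame of (from, to) ligand
#'   ids; must connect all nodes.
#' @param reference_ids Character ids treated as reference ligands (no
#'   experimental values).
#' @param noise_sd Gaussian edge noise SD, kJ/mol (>= 0).
#' @param conformer_offset Offset of the planted unfavourable candidate,
#'   kJ/mol (0 = single candidate per edge).
#' @param seed Integer seed.
#' @param set_id Series tag.
#' @return A [perturbation_network()] with attribute `true_dg` (the input
#'   node free energies). Non-reference ligands carry their true dG as the
#'   experimental value.
#' @export
generate_network <- function(node_dg, edge_list, reference_ids = character(0),
                             noise_sd = 0, conformer_offset = 0, seed = 1L,
                             set_id = NA_integer_) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ids <- names(node_dg)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("`node_dg` must be uniquely named", call. = FALSE)
  }
  el <- as.matrix(edge_list)[, 1:2, drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing_nodes <- setdiff(ids, igraph::V(g)$name)
  if (length(missing_nodes) > 0) g <- igraph::add_vertices(g, length(missing_nodes), name = missing_nodes)
  if (!igraph::is_connected(g)) stop("edge list does not connect all nodes", call. = FALSE)

  is_ref <- ids %in% reference_ids
  lig <- ligand_table(ids, set_id = ifelse(is.na(set_id), 1L, set_id),
                      exp_dg = ifelse(is_ref, NA_real_, unname(node_dg)),
                      is_reference = is_ref)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  edges <- lapply(seq_len(nrow(el)), function(i) {
    from <- el[i, 1L]; to <- el[i, 2L]
    true_val <- node_dg[[to]] - node_dg[[from]]
    val <- true_val + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    touches_ref <- from %in% reference_ids || to %in% reference_ids
    if (conformer_offset > 0 && touches_ref) {
      # the unfavourable candidate makes the non-reference ligand bind worse
      bad <- if (to %in% reference_ids) val - conformer_offset else val + conformer_offset
      perturbation_edge(from, to, c(val, bad), ses = noise_sd,
                        conformers = c("planted", "offset"))
    } else {
      perturbation_edge(from, to, val, ses = noise_sd)
    }
  })
  net <- perturbation_network(lig, edges, set_id = set_id)
  attr(net, "true_dg") <- node_dg
  net
}
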