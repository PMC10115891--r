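#' Synthesize a matched apo/effector/heated three-state study
#'
#' Builds one toy topology and three conformational ensembles emulating the
#' study design in which an allosteric effector and plain heating are
#' compared on the same protein:
#' \describe{
#'   \item{apo_cold}{reference state: the residue-residue coupling runs
#'     through a chain of buried (low solvent accessibility) relay
#'     residues connecting a source residue on chain `f` to a destination
#'     residue on chain `h`.}
#'   \item{holo_cold}{effector-bound analogue: the coupling is re-routed
#'     through a chain of solvent-exposed relay residues (the buried chain
#'     is weakened, the exposed chain strengthened) and two effector-site
#'     residue pairs are pulled into atomic contact.}
#'   \item{apo_warm}{heated apo state: identical coupling re-routing and
#'     contact changes as `holo_cold`, plus a global variance scale
#'     `temperature_scale_warm` — heating mimics the effector.}
#' }
#' Every planted difference is recorded in `ground_truth`, so downstream
#' centrality, pathway, contact-perturbation and PCA analyses can be
#' checked against the construction.
#'
#' A matching synthetic amide-shift temperature series is generated for all
#' residues; the exposed relay residues are planted with a curved
#' (quadratic) temperature response, the rest are linear at -4 ppb/K.
#'
#' @param n_residues residues in the toy protein (>= 12).
#' @param n_frames frames per ensemble.
#' @param seed master seed; every derived draw is seeded from it.
#' @param temperature_scale_warm covariance scale of the heated state.
#' @param rho_strong,rho_weak per-axis correlations of the strong and weak
#'   coupling chains.
#' @return Object of class `state_triple`: `topology` (apo reference),
#'   `topology_active` (contact-shifted reference shared by `holo_cold`
#'   and `apo_warm`), ensembles `apo_cold`, `holo_cold`, `apo_warm`,
#'   `shifts` (temperature-series shift table), and `ground_truth` (list:
#'   `source`, `dest`, `relays_internal`, `relays_external`, `coupling`,
#'   `contacts`, `curved_residues`, `exposure_threshold`,
#'   `temperature_scale_warm`).
#' @export
synthesize_state_triple <- function(n_residues = 36L, n_frames = 4000L,
                                    seed = 1L,
                                    temperature_scale_warm = 1.5,
                                    rho_strong = 0.45, rho_weak = 0.15) {
  stopifnot(n_residues >= 12, rho_strong > rho_weak, rho_weak >= 0,
            2 * rho_strong < 1)  # keeps the planted cycle covariance PSD
  topo <- make_toy_topology(n_residues, split = 0.5, seed = seed)
  labels <- topo$residues$label
  n <- n_residues

  src <- 2L
  dst <- n - 1L
  rel <- topology_rel_sasa(topo)
  cand <- setdiff(seq_len(n), c(src - 1L, src, src + 1L,
                                dst - 1L, dst, dst + 1L))
  buried <- cand[order(rel[cand])][1:2]
  exposed <- cand[order(-rel[cand])][1:2]
  # threshold separating the two relay groups on this structure
  thr <- (max(rel[buried]) + min(rel[exposed])) / 2

  chain_pairs <- function(relays, rho) {
    data.frame(i = c(src, relays[1], relays[2]),
               j = c(relays[1], relays[2], dst),
               rho = rho)
  }
  pairs_apo <- rbind(chain_pairs(buried, rho_strong),
                     chain_pairs(exposed, rho_weak))
  pairs_active <- rbind(chain_pairs(buried, rho_weak),
                        chain_pairs(exposed, rho_strong))

  # effector-site contact formation: two residue pairs pulled to 4 A in the
  # active reference geometry, picked far apart in the apo reference and
  # disjoint from source/dest/relays
  used <- c(src, dst, buried, exposed)
  free_f <- setdiff(which(topo$residues$chain == "f"), used)
  free_h <- setdiff(which(topo$residues$chain == "h"), used)
  ca <- ca_indices(topo)
  dmat <- as.matrix(stats::dist(topo$xyz[ca, , drop = FALSE]))
  pick <- function(pool_i, pool_j, taken) {
    sub <- dmat[pool_i, pool_j, drop = FALSE]
    sub[, colnames(sub) %in% as.character(taken)] <- -Inf
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    c(pool_i[ij[1]], pool_j[ij[2]])
  }
  p1 <- pick(free_f, free_h, integer())
  p2 <- pick(setdiff(free_f, p1), setdiff(free_h, p1), p1)
  contacts <- data.frame(i = c(p1[1], p2[1]), j = c(p1[2], p2[2]),
                         distance = 4.0)

  topo_active <- topo
  for (r in seq_len(nrow(contacts))) {
    topo_active <- shift_residue_contact(topo_active, contacts$i[r],
                                         contacts$j[r],
                                         contacts$distance[r])
  }

  spec_of <- function(pairs, scale, sub_seed) {
    ensemble_spec(n_frames, covariance = "block", planted_pairs = pairs,
                  base_variance = 1, temperature_scale = scale,
                  seed = seed * 1000L + sub_seed)
  }
  apo_cold <- sample_gaussian_ensemble(topo, spec_of(pairs_apo, 1, 1L),
                                       state = "apo_cold", temperature = 303)
  holo_cold <- sample_gaussian_ensemble(topo_active,
                                        spec_of(pairs_active, 1, 2L),
                                        state = "holo_cold",
                                        temperature = 303)
  apo_warm <- sample_gaussian_ensemble(
    topo_active, spec_of(pairs_active, temperature_scale_warm, 3L),
    state = "apo_warm", temperature = 323)

  temps <- c(292.92, 295.0, 297.5, 300.0, 302.73,
             307.62, 312.0, 317.0, 322.41)
  curved <- labels[exposed]
  intercepts <- with_seed(seed + 7L,
                          stats::runif(n_residues, 7.8, 8.6))
  sspec <- shift_spec(
    residues = labels, temperatures = temps, intercept = intercepts,
    slope = ifelse(labels %in% curved, -2, -4),
    quad = ifelse(labels %in% curved, 0.1, 0),
    noise_sd = 0.002, seed = seed + 11L)
  shifts <- make_shift_table(sspec, source = "experimental")

  coupling <- data.frame(
    i = pairs_apo$i, j = pairs_apo$j,
    rho_apo = pairs_apo$rho, rho_active = pairs_active$rho)
  structure(list(
    topology = topo, topology_active = topo_active,
    apo_cold = apo_cold, holo_cold = holo_cold, apo_warm = apo_warm,
    shifts = shifts,
    ground_truth = list(
      source = labels[src], dest = labels[dst],
      relays_internal = labels[buried], relays_external = labels[exposed],
      coupling = coupling,
      contacts = data.frame(node_i = labels[contacts$i],
                            node_j = labels[contacts$j],
                            i = contacts$i, j = contacts$j,
                            distance = contacts$distance),
      curved_residues = curved,
      exposure_threshold = unname(thr),
      temperature_scale_warm = temperature_scale_warm)),
    class = "state_triple")
}

#' @export
print.state_triple <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(paste0(
    "state_triple: %d residues, %d frames/state\n",
    "  coupling %s -> %s re-routed %s (buried) => %s (exposed)\n",
    "  contacts formed: %s\n"),
    nrow(x$topology$residues), n_frames(x$apo_cold),
    gt$source, gt$dest,
    paste(gt$relays_internal, collapse = "-"),
    paste(gt$relays_external, collapse = "-"),
    paste(paste0(gt$contacts$node_i, ":", gt$contacts$node_j),
          collapse = ", ")))
  invisible(x)
}

# Relative solvent accessibility of every residue on the reference
# coordinates of a topology (Shrake-Rupley over heavy atoms / max area).
topology_rel_sasa <- function(topology, probe = 1.4, n_points = 192L) {
  heavy <- topology$atoms$heavy
  sasa_atom <- shrake_rupley(topology$xyz[heavy, , drop = FALSE],
                             radii = vdw_radius(topology$atoms$element[heavy]),
                             probe = probe, n_points = n_points)
  res_of <- topology$atoms$residue[heavy]
  sasa_res <- tapply(sasa_atom, res_of, sum)
  sasa <- setNames(numeric(nrow(topology$residues)),
                   topology$residues$label)
  sasa[as.integer(names(sasa_res))] <- sasa_res
  suppressWarnings(sasa / max_sasa(topology$residues$resname))
}

# Translate all atoms of residue j along the i->j CA axis so the CA-CA
# distance equals `distance` (A); returns the modified topology.
shift_residue_contact <- function(topology, i, j, distance) {
  ca <- ca_indices(topology)
  v <- topology$xyz[ca[j], ] - topology$xyz[ca[i], ]
  d0 <- sqrt(sum(v^2))
  shift <- v / d0 * (distance - d0)
  sel <- topology$atoms$residue == j
  topology$xyz[sel, ] <- sweep(topology$xyz[sel, , drop = FALSE], 2,
                               shift, "+")
  topology
}
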