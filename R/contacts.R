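#' Ensemble-averaged residue-residue atomic contact network
#'
#' For every residue pair, counts atom pairs closer than `cutoff` in each
#' frame and averages over frames: w_ij is the mean atomic contact count
#' per frame, so thresholds are frame-count independent. Two modes:
#' \describe{
#'   \item{symmetric}{all heavy atoms of residue i vs all heavy atoms of
#'     residue j (hydrogens excluded).}
#'   \item{nh}{asymmetric: the backbone amide (NH) group of residue i — its
#'     N plus the amide H when present — vs all heavy atoms of every other
#'     residue; rows are the NH-carrying residue.}
#' }
#'
#' @param ensemble an [new_ensemble()].
#' @param cutoff contact distance cutoff (A), default 5.
#' @param mode `"symmetric"` or `"nh"`.
#' @param min_seq_sep minimum |i - j| within a chain for a pair to be
#'   counted (1 excludes only self-pairs).
#' @return Object of class `contact_network`: `nodes`, `w` (mean contacts
#'   per frame; symmetric or directional), `mode`, `cutoff`, `n_frames`.
#' @export
count_contacts <- function(ensemble, cutoff = 5, mode = c("symmetric", "nh"),
                           min_seq_sep = 1L) {
  mode <- match.arg(mode)
  topo <- ensemble$topology
  if (!any(topo$atoms$heavy)) stop("topology has no heavy atoms",
                                   call. = FALSE)
  n <- nrow(topo$residues)
  nf <- n_frames(ensemble)
  co <- ensemble$coords
  w <- matrix(0, n, n, dimnames = list(topo$residues$label,
                                       topo$residues$label))

  sep_ok <- function(i, j) {
    if (topo$residues$chain[i] != topo$residues$chain[j]) return(TRUE)
    abs(topo$residues$resno[i] - topo$residues$resno[j]) >= min_seq_sep
  }

  # candidate residue pairs pre-filtered on reference-geometry CA distance:
  # pairs further apart than cutoff + 2 * max displacement cannot touch
  atoms_of <- split(seq_len(nrow(topo$atoms)), topo$atoms$residue)
  heavy_of <- lapply(atoms_of, function(ix) ix[topo$atoms$heavy[ix]])
  nh_of <- lapply(seq_len(n), function(i) {
    ix <- atoms_of[[i]]
    ix[topo$atoms$role[ix] == "N" | topo$atoms$name[ix] == "H"]
  })

  pair_count <- function(ix_a, ix_b) {
    # mean number of sub-cutoff atom pairs per frame, vectorized over frames
    tot <- numeric(nf)
    for (a in ix_a) {
      xa <- co[, a, , drop = TRUE]
      if (is.null(dim(xa))) xa <- matrix(xa, ncol = 3)
      for (b in ix_b) {
        xb <- co[, b, , drop = TRUE]
        if (is.null(dim(xb))) xb <- matrix(xb, ncol = 3)
        d2 <- (xa[, 1] - xb[, 1])^2 + (xa[, 2] - xb[, 2])^2 +
          (xa[, 3] - xb[, 3])^2
        tot <- tot + (d2 < cutoff^2)
      }
    }
    mean(tot)
  }

  # reach pre-filter on per-atom maximum excursion from residue reference
  ca <- ca_indices(topo)
  ref_ca <- topo$xyz[ca, , drop = FALSE]
  max_disp <- vapply(seq_len(n), function(i) {
    tr <- co[, ca[i], , drop = TRUE]
    if (is.null(dim(tr))) tr <- matrix(tr, ncol = 3)
    sqrt(max(rowSums(sweep(tr, 2, ref_ca[i, ])^2)))
  }, 0)
  span <- vapply(seq_len(n), function(i) {
    at <- atoms_of[[i]]
    sqrt(max(rowSums(sweep(topo$xyz[at, , drop = FALSE], 2,
                           ref_ca[i, ])^2)))
  }, 0)
  reach <- max_disp + span

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mode == "symmetric" && j <= i) next
      if (mode == "nh" && j == i) next
      if (!sep_ok(i, j)) next
      dref <- sqrt(sum((ref_ca[i, ] - ref_ca[j, ])^2))
      if (dref > cutoff + reach[i] + reach[j]) next
      if (mode == "symmetric") {
        w[i, j] <- w[j, i] <- pair_count(heavy_of[[i]], heavy_of[[j]])
      } else {
        w[i, j] <- pair_count(nh_of[[i]], heavy_of[[j]])
      }
    }
  }
  structure(list(nodes = topo$residues$label, w = w, mode = mode,
                 cutoff = cutoff, min_seq_sep = min_seq_sep,
                 n_frames = nf),
            class = "contact_network")
}

#' Dynamical perturbation contact network between two states
#'
#' Delta-w_ij = w_ij(B) - w_ij(A): contacts gained (positive) or lost
#' (negative) when going from state A to state B. The thresholded view
#' keeps only |Delta-w| > w_t (default 6 contacts); per-residue totals of
#' gained/lost contact weight support induced-perturbation-network reports
#' centered on single residues.
#'
#' @param net_a,net_b [count_contacts()] results with identical nodes,
#'   mode and cutoff.
#' @param w_t edge weight threshold.
#' @return Object of class `perturbation_network`: `nodes`, `delta_w`,
#'   `w_t`, `edges` (thresholded data.frame with `node_i`, `node_j`,
#'   `delta_w`, `sign`), `node_gain`, `node_loss`.
#' @export
perturbation_network <- function(net_a, net_b, w_t = 6) {
  stopifnot(inherits(net_a, "contact_network"),
            inherits(net_b, "contact_network"))
  if (!identical(net_a$nodes, net_b$nodes) ||
      net_a$mode != net_b$mode || net_a$cutoff != net_b$cutoff) {
    stop("contact networks differ in nodes, mode or cutoff", call. = FALSE)
  }
  d <- net_b$w - net_a$w
  sym <- net_a$mode == "symmetric"
  sel <- if (sym) upper.tri(d) & abs(d) > w_t else
    abs(d) > w_t & row(d) != col(d)
  ij <- which(sel, arr.ind = TRUE)
  edges <- data.frame(node_i = net_a$nodes[ij[, 1]],
                      node_j = net_a$nodes[ij[, 2]],
                      delta_w = d[ij],
                      sign = ifelse(d[ij] > 0, "gain", "loss"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$delta_w)), , drop = FALSE]
  pos <- pmax(d, 0); neg <- pmin(d, 0)
  structure(list(nodes = net_a$nodes, delta_w = d, w_t = w_t,
                 mode = net_a$mode, edges = edges,
                 node_gain = setNames(rowSums(pos), net_a$nodes),
                 node_loss = setNames(rowSums(neg), net_a$nodes)),
            class = "perturbation_network")
}

#' Spearman similarity of two perturbation networks
#'
#' Rank correlation of Delta-w over the union of residue pairs whose
#' |Delta-w| passes the floor in either network — the statistic used to
#' quantify how similar two activations (e.g. effector binding vs heating)
#' are at the contact level.
#'
#' @param pn_1,pn_2 [perturbation_network()]s over the same pair universe.
#' @param weight_floor minimum |Delta-w| (in either network) for a pair to
#'   enter the comparison.
#' @return list: `rho` (Spearman), `n_pairs` compared.
#' @export
network_similarity <- function(pn_1, pn_2, weight_floor = 6) {
  stopifnot(inherits(pn_1, "perturbation_network"),
            inherits(pn_2, "perturbation_network"))
  if (!identical(pn_1$nodes, pn_2$nodes)) {
    stop("perturbation networks have different node sets", call. = FALSE)
  }
  sym <- pn_1$mode == "symmetric"
  sel0 <- if (sym) upper.tri(pn_1$delta_w) else
    row(pn_1$delta_w) != col(pn_1$delta_w)
  keep <- sel0 & (abs(pn_1$delta_w) >= weight_floor |
                    abs(pn_2$delta_w) >= weight_floor)
  v1 <- pn_1$delta_w[keep]; v2 <- pn_2$delta_w[keep]
  if (length(v1) < 3L) {
    stop("fewer than 3 residue pairs pass the weight floor", call. = FALSE)
  }
  list(rho = stats::cor(v1, v2, method = "spearman"),
       n_pairs = length(v1))
}
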