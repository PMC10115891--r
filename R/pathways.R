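#' Convert a correlation network into signalling-path edge weights
#'
#' Edge cost w_ij = -ln(r_MI): minimizing the total cost of a path
#' maximizes the product of generalized correlations along it, so the
#' cheapest path is the most correlated communication channel. r_MI is
#' clamped to \[1e-8, 1 - 1e-12\] before the logarithm so zero- and
#' unit-correlation edges stay finite; clamped edges are recorded.
#'
#' @param network a `correlation_network`.
#' @param floor,ceiling clamp bounds applied to A_ij.
#' @return Object of class `weighted_graph`: `nodes`, `w` (symmetric,
#'   >= 0), `clamped` (logical matrix).
#' @export
edge_weights <- function(network, floor = 1e-8, ceiling = 1 - 1e-12) {
  a <- if (is.matrix(network)) network else network$A
  nodes <- if (is.matrix(network)) {
    rownames(network) %||% as.character(seq_len(nrow(a)))
  } else network$nodes
  stopifnot(all(is.finite(a)), all(a >= 0), all(a <= 1))
  clamped <- a < floor | a > ceiling
  diag(clamped) <- FALSE
  w <- -log(pmin(pmax(a, floor), ceiling))
  diag(w) <- 0
  dimnames(w) <- list(nodes, nodes)
  structure(list(nodes = nodes, w = w, clamped = clamped,
                 floor = floor, ceiling = ceiling),
            class = "weighted_graph")
}

as_igraph <- function(graph) {
  w <- graph$w
  g <- igraph::graph_from_adjacency_matrix(
    (w + t(w)) / 2, mode = "undirected", weighted = TRUE, diag = FALSE)
  g
}

# Attach a zero-weight virtual super-source connected to all source nodes;
# returns the augmented igraph and the super-source vertex name.
with_super_source <- function(g, sources) {
  g2 <- igraph::add_vertices(g, 1, name = ".super.")
  edges <- as.vector(rbind(".super.", sources))
  # igraph treats weight 0 fine for Dijkstra (non-negative)
  igraph::add_edges(g2, edges, weight = 0)
}

#' Minimum-cost communication path between residue sets
#'
#' Dijkstra shortest path on -ln(r_MI) edge weights from the best of the
#' source residues to the destination. Multiple sources are handled with a
#' virtual zero-weight super-source, so the returned path is the global
#' optimum over all sources.
#'
#' @param graph a [edge_weights()] result.
#' @param sources character vector of source residue labels.
#' @param dest destination residue label.
#' @return list: `path` (node sequence), `weight` (total cost; exp(-weight)
#'   is the product of r_MI along the path).
#' @export
shortest_path <- function(graph, sources, dest) {
  stopifnot(inherits(graph, "weighted_graph"))
  miss <- setdiff(c(sources, dest), graph$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  g <- with_super_source(as_igraph(graph), sources)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = ".super.", to = dest,
                           weights = igraph::E(g)$weight, output = "both"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0L) {
    stop("destination ", dest, " unreachable from source(s) ",
         paste(sources, collapse = ", "), call. = FALSE)
  }
  nodes <- igraph::V(g)$name[as.integer(vp)]
  nodes <- nodes[nodes != ".super."]
  list(path = nodes, weight = path_weight(graph, nodes))
}

path_weight <- function(graph, nodes) {
  if (length(nodes) < 2L) return(0)
  idx <- match(nodes, graph$nodes)
  sum(graph$w[cbind(idx[-length(idx)], idx[-1])])
}

#' Optimal and k-suboptimal communication pathways
#'
#' Yen-style loopless k-shortest paths on -ln(r_MI) weights, globally
#' ranked across all sources (virtual super-source). The merged node
#' multiset counts, for every residue, in how many of the k paths it
#' appears — the "merged suboptimal pathways" picture used to map the most
#' likely routes of motion transmission.
#'
#' @inheritParams shortest_path
#' @param k number of ranked paths to return (fewer if fewer exist).
#' @return Object of class `path_set`: `paths` (list of node sequences),
#'   `weights` (non-decreasing), `sources`, `dest`, `membership` (named
#'   count per residue), `exposure` (NULL until [classify_exposure()]).
#' @export
k_suboptimal_paths <- function(graph, sources, dest, k = 50L) {
  stopifnot(inherits(graph, "weighted_graph"), k >= 1)
  miss <- setdiff(c(sources, dest), graph$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  g <- with_super_source(as_igraph(graph), sources)
  ks <- suppressWarnings(
    igraph::k_shortest_paths(g, from = ".super.", to = dest, k = k,
                             weights = igraph::E(g)$weight))
  if (length(ks$vpaths) == 0L) {
    stop("destination ", dest, " unreachable from source(s) ",
         paste(sources, collapse = ", "), call. = FALSE)
  }
  paths <- lapply(ks$vpaths, function(vp) {
    nodes <- igraph::V(g)$name[as.integer(vp)]
    nodes[nodes != ".super."]
  })
  wts <- vapply(paths, function(p) path_weight(graph, p), 0)
  ord <- order(wts)
  paths <- paths[ord]; wts <- wts[ord]
  membership <- table(factor(unlist(paths), levels = graph$nodes))
  structure(list(paths = paths, weights = wts, sources = sources,
                 dest = dest,
                 membership = setNames(as.integer(membership),
                                       names(membership)),
                 exposure = NULL),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set: %d path(s) %s -> %s; best weight %.4f\n",
              length(x$paths), paste(x$sources, collapse = "+"), x$dest,
              x$weights[1]))
  invisible(x)
}

#' Label pathway residues as solvent-exposed (external) or buried (internal)
#'
#' Computes per-residue relative solvent accessibility on the ensemble-mean
#' structure with a rolling-probe (Shrake-Rupley sphere-sampling) area
#' method, probe radius 1.4 A, divides by a per-residue-type maximum
#' accessible area, and labels residues at or above the threshold
#' `external` (so a threshold of 0 labels every residue external).
#' Reports the external fraction of the merged pathway node multiset — the
#' quantity that distinguishes a surface communication channel from one
#' buried in the protein matrix.
#'
#' @param ensemble the ensemble the paths were computed on.
#' @param path_set a [k_suboptimal_paths()] result.
#' @param rel_sasa_threshold relative accessibility above which a residue
#'   counts as external.
#' @param n_points sphere sample points per atom.
#' @return The `path_set` with `exposure` (named factor per network
#'   residue), `rel_sasa` (named numeric) and `external_fraction` (of the
#'   merged path multiset) filled in.
#' @export
classify_exposure <- function(ensemble, path_set,
                              rel_sasa_threshold = 0.2, n_points = 192L) {
  topo <- ensemble$topology
  mean_xyz <- apply(ensemble$coords, c(2, 3), mean)
  heavy <- topo$atoms$heavy
  sasa_atom <- shrake_rupley(mean_xyz[heavy, , drop = FALSE],
                             radii = vdw_radius(topo$atoms$element[heavy]),
                             probe = 1.4, n_points = n_points)
  res_of <- topo$atoms$residue[heavy]
  sasa_res <- tapply(sasa_atom, res_of, sum)
  sasa <- setNames(numeric(nrow(topo$residues)), topo$residues$label)
  sasa[as.integer(names(sasa_res))] <- sasa_res

  max_area <- max_sasa(topo$residues$resname)
  rel <- setNames(as.numeric(sasa) / max_area, topo$residues$label)
  exposure <- setNames(factor(ifelse(rel >= rel_sasa_threshold,
                                     "external", "internal"),
                              levels = c("internal", "external")),
                       topo$residues$label)
  member <- path_set$membership
  merged_nodes <- names(member)[member > 0]
  counts <- member[member > 0]
  ext_frac <- sum(counts[exposure[merged_nodes] == "external"]) / sum(counts)
  path_set$exposure <- exposure
  path_set$rel_sasa <- rel
  path_set$external_fraction <- ext_frac
  path_set$rel_sasa_threshold <- rel_sasa_threshold
  path_set
}

# Maximum accessible surface area per residue type (A^2), tripeptide-based
# reference values; unknown types fall back to Gly with a warning.
MAX_SASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

max_sasa <- function(resnames) {
  out <- MAX_SASA[resnames]
  if (anyNA(out)) {
    warning("residue type(s) without a max-SASA entry; using Gly reference: ",
            paste(unique(resnames[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- MAX_SASA[["G"]]
  }
  unname(out)
}

vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  out <- r[element]
  out[is.na(out)] <- 1.70
  unname(out)
}

# Shrake-Rupley solvent-accessible surface area: sample `n_points`
# near-uniform sphere points per atom (golden-spiral lattice) at radius
# r_vdw + probe and count points not inside any neighbour's expanded
# sphere.
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 192L) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_points) - 0.5
  z <- 1 - 2 * i / n_points
  rho <- sqrt(pmax(1 - z^2, 0))
  theta <- golden * (seq_len(n_points) - 1)
  unit <- cbind(rho * cos(theta), rho * sin(theta), z)
  rad <- radii + probe
  out <- numeric(n)
  for (a in seq_len(n)) {
    pts <- sweep(unit * rad[a], 2, xyz[a, ], "+")
    nb <- which(rowSums(sweep(xyz, 2, xyz[a, ])^2) <
                  (rad + rad[a])^2 & seq_len(n) != a)
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      d2 <- rowSums(sweep(pts, 2, xyz[b, ])^2)
      acc <- acc & d2 > rad[b]^2
      if (!any(acc)) break
    }
    out[a] <- 4 * pi * rad[a]^2 * sum(acc) / n_points
  }
  out
}
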