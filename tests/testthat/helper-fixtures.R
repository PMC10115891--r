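# Shared fixture builders and brute-force oracles for the test suite.
# Everything here is constructed in code; no binary fixtures.

# Build a toy_topology from hand-placed atoms: `atoms_by_residue` is a list
# with one entry per residue, each an (atoms x 3) matrix whose rownames are
# atom names (must include "CA"). Chains must be contiguous.
manual_topology <- function(atoms_by_residue, chain = NULL, resname = "A") {
  n <- length(atoms_by_residue)
  if (is.null(chain)) chain <- rep("f", n)
  resname <- rep_len(resname, n)
  resno <- stats::ave(seq_len(n), chain, FUN = seq_along)
  residues <- data.frame(
    chain = chain, resno = resno, resname = resname,
    label = format_residue_label(chain, resno, resname),
    stringsAsFactors = FALSE)
  atoms <- list()
  for (i in seq_len(n)) {
    m <- atoms_by_residue[[i]]
    nm <- rownames(m)
    atoms[[i]] <- data.frame(
      name = nm,
      role = ifelse(nm %in% c("N", "CA", "C", "O"), nm, "sidechain"),
      residue = i,
      heavy = !grepl("^H", nm),
      element = ifelse(grepl("^H", nm), "H",
                       substr(sub("^SC", "C", nm), 1, 1)),
      stringsAsFactors = FALSE)
  }
  topo <- structure(
    list(residues = residues,
         atoms = do.call(rbind, c(atoms, make.row.names = FALSE)),
         xyz = do.call(rbind, atoms_by_residue)),
    class = "toy_topology")
  rownames(topo$xyz) <- NULL
  topo
}

# CA-only topology from an (n x 3) coordinate matrix.
ca_only_topology <- function(ca_xyz, chain = NULL, resname = "A") {
  manual_topology(
    lapply(seq_len(nrow(ca_xyz)),
           function(i) matrix(ca_xyz[i, ], 1, 3,
                              dimnames = list("CA", NULL))),
    chain = chain, resname = resname)
}

# Ensemble whose every frame equals the topology reference coordinates.
static_ensemble <- function(topology, n_frames = 2L, aligned = TRUE) {
  na <- nrow(topology$atoms)
  coords <- array(0, c(n_frames, na, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- topology$xyz
  new_ensemble(topology, coords, aligned = aligned)
}

# Ensemble from an explicit list of (atoms x 3) frames.
frames_ensemble <- function(topology, frames, aligned = TRUE) {
  coords <- array(0, c(length(frames), nrow(topology$atoms), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_ensemble(topology, coords, aligned = aligned)
}

# Brute-force oracle: all simple paths from any node in `sources` to `dest`
# on the graph whose edges are the positive entries of the r_MI adjacency
# `A` (dimnames required), using the same -log clamp as edge_weights().
# Returns paths sorted by total weight.
enumerate_simple_paths <- function(A, sources, dest,
                                   floor = 1e-8, ceiling = 1 - 1e-12) {
  nodes <- rownames(A)
  w <- -log(pmin(pmax(A, floor), ceiling))
  paths <- list(); wts <- numeric(0)
  dfs <- function(path, cost) {
    cur <- path[length(path)]
    if (cur == dest) {
      paths[[length(paths) + 1L]] <<- path
      wts[[length(wts) + 1L]] <<- cost
      return(invisible())
    }
    for (nb in nodes[A[cur, ] > 0]) {
      if (!(nb %in% path)) dfs(c(path, nb), cost + w[cur, nb])
    }
  }
  for (s in sources) dfs(s, 0)
  ord <- order(wts)
  list(paths = paths[ord], weights = wts[ord])
}

# Random connected r_MI adjacency fixture with values in (0.1, 0.9).
random_rmi_graph <- function(n, p = 0.5, seed = 1L) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- stats::runif(1, 0.1, 0.9)
    }
    dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
    # accept only connected graphs so every node is reachable
    reached <- 1L
    repeat {
      nxt <- unique(c(reached, which(colSums(A[reached, , drop = FALSE] > 0) > 0)))
      if (length(nxt) == length(reached)) break
      reached <- nxt
    }
    if (length(reached) == n) return(A)
  }
}

# Hand-rolled Spearman rank correlation (mean ranks for ties).
spearman_manual <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Rotation matrices for rigid-invariance tests.
rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
rotation_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

# Apply one rigid motion to every frame of an ensemble.
transform_ensemble <- function(ensemble, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    fr <- ensemble$coords[f, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    out$coords[f, , ] <- sweep(fr %*% t(rotation), 2, translation, "+")
  }
  out
}

# Sparse "isolated pair" geometry for clean contact-perturbation tests:
# residues sit on a line 60 A apart (no cross-residue contacts possible),
# each with a CA plus three satellite heavy atoms within 0.9 A, so a
# planted 4-A approach of two residues creates >> 6 atomic contacts.
contact_line_topology <- function(n_residues = 6L, spacing = 60) {
  sat <- rbind(SC1 = c(0.9, 0, 0), SC2 = c(0, 0.9, 0), SC3 = c(0, 0, 0.9))
  manual_topology(lapply(seq_len(n_residues), function(i) {
    base <- c((i - 1) * spacing, 0, 0)
    m <- rbind(CA = base, sweep(sat, 2, base, "+"))
    m
  }), chain = rep(c("f", "h"), each = ceiling(n_residues / 2))[1:n_residues])
}
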