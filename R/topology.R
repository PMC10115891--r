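#' Toy all-atom topology with a self-avoiding C-alpha trace
#'
#' Builds a coarse two-chain protein stand-in: a self-avoiding random walk of
#' C-alpha atoms with ~3.8 A between consecutive residues, a full backbone
#' (N, CA, C, O) per residue and 0-4 sidechain heavy atoms placed within
#' 2.5 A of the C-alpha. Chains are tagged `f` and `h`, emulating the
#' two-subunit residue naming convention. Hydrogens are not generated; the
#' amide H needed by the secondary-structure assigner is reconstructed
#' geometrically downstream.
#'
#' @param n_residues total number of residues (>= 2).
#' @param split fraction of residues assigned to chain `f` (the remainder go
#'   to chain `h`); the chain-f count is `round(n_residues * split)`.
#' @param seed integer seed; the same call always returns identical
#'   coordinates.
#' @param max_sidechain maximum number of sidechain heavy atoms per residue
#'   (drawn uniformly from `0:max_sidechain`).
#' @return An object of class `toy_topology` with elements
#'   \describe{
#'     \item{residues}{data.frame: `chain`, `resno` (1-based within chain),
#'       `resname` (one-letter), `label`.}
#'     \item{atoms}{data.frame: `name` (N/CA/C/O/SC1..), `role`,
#'       `residue` (row index into `residues`), `heavy` (logical),
#'       `element`.}
#'     \item{xyz}{reference coordinates, atoms x 3, in Angstrom.}
#'   }
#' @export
make_toy_topology <- function(n_residues, split = 0.5, seed = 1L,
                              max_sidechain = 4L) {
  if (!is.numeric(n_residues) || n_residues < 2) {
    stop("n_residues must be >= 2", call. = FALSE)
  }
  n_residues <- as.integer(n_residues)
  stopifnot(split >= 0, split <= 1)
  with_seed(seed, {
    ca <- sample_self_avoiding_trace(n_residues, step = 3.8, min_sep = 4.0)
    n_f <- as.integer(round(n_residues * split))
    chain <- c(rep("f", n_f), rep("h", n_residues - n_f))
    resno <- c(seq_len(n_f), seq_len(n_residues - n_f))
    resname <- sample(c("A", "G", "L", "V", "S", "T", "K", "D", "E", "R"),
                      n_residues, replace = TRUE)
    residues <- data.frame(chain = chain, resno = resno, resname = resname,
                           label = format_residue_label(chain, resno, resname),
                           stringsAsFactors = FALSE)

    atoms <- list(); xyz <- list()
    for (i in seq_len(n_residues)) {
      # backbone frame: local orthonormal axes from the chain direction
      dir_next <- if (i < n_residues) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
      e1 <- dir_next / sqrt(sum(dir_next^2))
      ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      pos <- rbind(
        N  = ca[i, ] - 1.46 * e1 + 0.30 * e2,
        CA = ca[i, ],
        C  = ca[i, ] + 1.52 * e1 + 0.30 * e2,
        O  = ca[i, ] + 1.52 * e1 + 0.30 * e2 + 1.23 * e3
      )
      n_sc <- sample(0:max_sidechain, 1L)
      if (n_sc > 0) {
        sc <- matrix(rnorm(3 * n_sc), ncol = 3)
        sc <- sc / sqrt(rowSums(sc^2)) * runif(n_sc, 1.5, 2.4)
        sc <- sweep(sc, 2, ca[i, ], "+")
        rownames(sc) <- paste0("SC", seq_len(n_sc))
        pos <- rbind(pos, sc)
      }
      atoms[[i]] <- data.frame(
        name = rownames(pos),
        role = ifelse(rownames(pos) %in% c("N", "CA", "C", "O"),
                      rownames(pos), "sidechain"),
        residue = i,
        heavy = TRUE,
        element = substr(ifelse(grepl("^SC", rownames(pos)), "C",
                                rownames(pos)), 1, 1),
        stringsAsFactors = FALSE
      )
      xyz[[i]] <- pos
    }
    topo <- structure(
      list(residues = residues,
           atoms = do.call(rbind, c(atoms, make.row.names = FALSE)),
           xyz = do.call(rbind, xyz)),
      class = "toy_topology")
    rownames(topo$xyz) <- NULL
    validate_topology(topo)
    topo
  })
}

# Self-avoiding random walk: fixed step, resample any step that brings the
# new point within `min_sep` of a non-adjacent previous point.
sample_self_avoiding_trace <- function(n, step = 3.8, min_sep = 4.0,
                                       max_tries = 200L) {
  pts <- matrix(0, nrow = n, ncol = 3)
  for (i in 2:n) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      # bias gently forward to avoid dead ends on long chains
      if (i > 2) {
        prev_dir <- pts[i - 1, ] - pts[i - 2, ]
        prev_dir <- prev_dir / sqrt(sum(prev_dir^2))
        u <- u + 0.8 * prev_dir; u <- u / sqrt(sum(u^2))
      }
      cand <- pts[i - 1, ] + step * u
      if (i <= 2) { ok <- TRUE } else {
        d2 <- rowSums(sweep(pts[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
        ok <- all(d2 >= min_sep^2)
      }
      if (ok) { pts[i, ] <- cand; break }
    }
    if (!ok) stop("self-avoiding walk failed; retry with another seed",
                  call. = FALSE)
  }
  pts
}

validate_topology <- function(topo) {
  stopifnot(inherits(topo, "toy_topology"))
  n_ca <- tapply(topo$atoms$role == "CA", topo$atoms$residue, sum)
  if (!all(n_ca == 1L)) stop("every residue needs exactly one CA", call. = FALSE)
  stopifnot(nrow(topo$xyz) == nrow(topo$atoms),
            all(topo$atoms$residue %in% seq_len(nrow(topo$residues))))
  for (ch in unique(topo$residues$chain)) {
    r <- topo$residues$resno[topo$residues$chain == ch]
    if (any(diff(r) <= 0)) stop("residue ids must increase within a chain",
                                call. = FALSE)
  }
  invisible(topo)
}

#' @export
print.toy_topology <- function(x, ...) {
  cat(sprintf("toy_topology: %d residues (%s), %d atoms\n",
              nrow(x$residues),
              paste(sprintf("%s:%d", names(table(x$residues$chain)),
                            table(x$residues$chain)), collapse = ", "),
              nrow(x$atoms)))
  invisible(x)
}

# Row indices of the CA atoms, ordered by residue.
ca_indices <- function(topology) {
  which(topology$atoms$role == "CA")[order(topology$atoms$residue[topology$atoms$role == "CA"])]
}

# Atom row index for a (residue index, atom name) pair.
atom_index <- function(topology, residue, name) {
  hit <- which(topology$atoms$residue == residue & topology$atoms$name == name)
  if (length(hit) != 1L) {
    stop(sprintf("atom %s not found in residue %s", name,
                 topology$residues$label[residue]), call. = FALSE)
  }
  hit
}
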