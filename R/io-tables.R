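#' Write an ensemble as a compact binary array container with a JSON sidecar
#'
#' Coordinates are stored as little-endian doubles (`<stem>.bin`,
#' frame-major); the sidecar (`<stem>.json`) records array dimensions, the
#' topology, labels, and an optional ground-truth block so that planted
#' perturbations always travel with the data they describe.
#'
#' @param ensemble an [new_ensemble()].
#' @param stem output path without extension.
#' @param ground_truth optional data.frame stored verbatim in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_ensemble_bin <- function(ensemble, stem, ground_truth = NULL) {
  bin <- paste0(stem, ".bin"); side <- paste0(stem, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(ensemble$coords), con, size = 8, endian = "little")
  meta <- list(dims = dim(ensemble$coords),
               state = ensemble$state, temperature = ensemble$temperature,
               aligned = ensemble$aligned,
               residues = ensemble$topology$residues,
               atoms = ensemble$topology$atoms,
               xyz = ensemble$topology$xyz,
               ground_truth = ground_truth)
  jsonlite::write_json(meta, side, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(side)
}

#' @rdname write_ensemble_bin
#' @param stem path stem used at write time.
#' @return `read_ensemble_bin()`: a list with `ensemble` and `ground_truth`.
#' @export
read_ensemble_bin <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  co <- readBin(con, "numeric", n = prod(dims), size = 8, endian = "little")
  topo <- structure(list(residues = as.data.frame(meta$residues),
                         atoms = as.data.frame(meta$atoms),
                         xyz = matrix(unlist(meta$xyz), ncol = 3)),
                    class = "toy_topology")
  ens <- new_ensemble(topo, array(co, dims), state = meta$state,
                      temperature = meta$temperature,
                      aligned = isTRUE(meta$aligned))
  gt <- if (!is.null(meta$ground_truth)) as.data.frame(meta$ground_truth)
  list(ensemble = ens, ground_truth = gt)
}

#' Write a residue-pair network as a thresholded TSV edge list
#'
#' Works for both correlation networks (rMI adjacency) and perturbation
#' networks (delta-w): emits one row per unordered pair with
#' `|weight| > threshold`, sorted by decreasing `|weight|` then lexically by
#' node labels — a stable, diff-friendly export.
#'
#' @param network a `correlation_network` or `perturbation_network` (any
#'   object with `nodes` and a square `weights`-like matrix), or a square
#'   matrix with dimnames.
#' @param path output TSV.
#' @param threshold minimum `|weight|` for a row to be emitted.
#' @return Number of data rows written, invisibly.
#' @export
write_edge_list <- function(network, path, threshold = 0) {
  if (is.matrix(network)) {
    w <- network; nodes <- rownames(network) %||% as.character(seq_len(nrow(w)))
  } else {
    w <- network$A %||% network$delta_w
    nodes <- network$nodes
  }
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(is.finite(w)))
  ij <- which(upper.tri(w) & abs(w) > threshold, arr.ind = TRUE)
  df <- data.frame(node_i = nodes[ij[, 1]], node_j = nodes[ij[, 2]],
                   weight = w[ij],
                   sign = ifelse(w[ij] >= 0, "+", "-"),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$weight), df$node_i, df$node_j), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}

#' Read / write chemical-shift tables as TSV
#'
#' Columns: `residue`, `nucleus`, `temperature_K`, `shift_ppm` and
#' (optionally) `source`.
#'
#' @param table a shift table data.frame.
#' @param path TSV path.
#' @export
write_shift_table <- function(table, path) {
  stopifnot(all(c("residue", "nucleus", "temperature_K", "shift_ppm")
                %in% names(table)))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "nucleus", "temperature_K", "shift_ppm")
                %in% names(tab)))
  tab
}
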