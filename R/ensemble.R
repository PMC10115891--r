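#' Conformational ensemble container
#'
#' The universal input of every analysis stage: a topology plus a
#' frames x atoms x 3 coordinate array in Angstrom, with optional state and
#' temperature labels (e.g. an "apo30 analog" at 303 K).
#'
#' @param topology a `toy_topology` (or compatible list with `residues`,
#'   `atoms`, `xyz`).
#' @param coords numeric array `[frames, atoms, 3]`; all values finite.
#' @param state optional state label.
#' @param temperature optional temperature label (K).
#' @param aligned logical; set by [superpose()] once frames share a common
#'   rigid-body frame.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(topology, coords, state = NULL, temperature = NULL,
                         aligned = FALSE) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != nrow(topology$atoms)) {
    stop("coordinate array does not match topology atom count", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates in ensemble", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords,
                 state = state, temperature = temperature,
                 aligned = isTRUE(aligned)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d atoms (%d residues)%s%s\n",
              n_frames(x), dim(x$coords)[2], nrow(x$topology$residues),
              if (!is.null(x$state)) paste0(", state ", x$state) else "",
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' @rdname new_ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

# frames x (3 n_ca) matrix of CA coordinates, per-residue xyz triples
ca_matrix <- function(ensemble) {
  ca <- ca_indices(ensemble$topology)
  co <- ensemble$coords[, ca, , drop = FALSE]
  n <- dim(co)[1]
  out <- matrix(0, n, length(ca) * 3L)
  for (a in seq_len(3L)) out[, seq(a, by = 3L, length.out = length(ca))] <- co[, , a]
  out
}

# frames x 3 coordinate track of one atom
atom_track <- function(ensemble, atom) ensemble$coords[, atom, , drop = TRUE]
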