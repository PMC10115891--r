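#' Interdomain hinge (breathing) angle series
#'
#' Per-frame angle (degrees) at the C-alpha of the middle residue of an
#' ordered triple, between the vectors vertex -> first and vertex -> third.
#' Used for hinge/breathing motions measured between two domains, e.g. the
#' angle at hW123 between arms to hG52 and fF120.
#'
#' @param ensemble an [new_ensemble()].
#' @param triple character vector of three residue labels; the middle one
#'   is the vertex.
#' @return Object of class `angle_series`: `angle` (per frame, deg),
#'   `mean`, `sd`, `triple`.
#' @export
hinge_angle <- function(ensemble, triple) {
  stopifnot(length(triple) == 3L)
  idx <- resolve_residues(ensemble$topology, triple)
  ca <- ca_indices(ensemble$topology)[idx]
  p1 <- atom_track(ensemble, ca[1]); pv <- atom_track(ensemble, ca[2])
  p3 <- atom_track(ensemble, ca[3])
  if (is.null(dim(p1))) { p1 <- matrix(p1, ncol = 3); pv <- matrix(pv, ncol = 3); p3 <- matrix(p3, ncol = 3) }
  u <- p1 - pv; v <- p3 - pv
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-9 | nv < 1e-9)) {
    stop("coincident C-alpha positions make the angle undefined",
         call. = FALSE)
  }
  cosang <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
  ang <- acos(cosang) * 180 / pi
  structure(list(angle = ang, mean = mean(ang), sd = stats::sd(ang),
                 triple = triple),
            class = "angle_series")
}

# Parse an atom label of the form "<residue label>-<atom name>",
# e.g. "fL63-N" or "fR59-O".
parse_atom_label <- function(text) {
  m <- regexec("^([fh][A-Z]?[0-9]+)-([A-Z0-9']+)$", text)
  p <- regmatches(text, m)[[1]]
  if (length(p) != 3L) stop("malformed atom label: ", text, call. = FALSE)
  list(residue = p[2], atom = p[3])
}

#' Backbone hydrogen-bond distance series and occupancy
#'
#' Per-frame donor-acceptor distance for a named backbone atom pair (the
#' distance-based H-bond definition, e.g. fL63-N to fR59-O), with
#' occupancy = fraction of frames below the cutoff and mean +/- sd of the
#' distance.
#'
#' @param ensemble an [new_ensemble()].
#' @param donor,acceptor atom labels `"<residue>-<atom>"`, e.g. `"fL63-N"`.
#' @param cutoff H-bond distance cutoff (A), default 3.5.
#' @return Object of class `hbond_series`: `distance` (per frame, A),
#'   `occupancy`, `mean`, `sd`, `cutoff`, `donor`, `acceptor`.
#' @export
hbond_series <- function(ensemble, donor, acceptor, cutoff = 3.5) {
  d <- parse_atom_label(donor); a <- parse_atom_label(acceptor)
  di <- resolve_residues(ensemble$topology, d$residue)
  ai <- resolve_residues(ensemble$topology, a$residue)
  d_at <- atom_index(ensemble$topology, di, d$atom)
  a_at <- atom_index(ensemble$topology, ai, a$atom)
  pd <- atom_track(ensemble, d_at); pa <- atom_track(ensemble, a_at)
  if (is.null(dim(pd))) { pd <- matrix(pd, ncol = 3); pa <- matrix(pa, ncol = 3) }
  dist <- sqrt(rowSums((pd - pa)^2))
  structure(list(distance = dist, occupancy = mean(dist < cutoff),
                 mean = mean(dist), sd = stats::sd(dist), cutoff = cutoff,
                 donor = donor, acceptor = acceptor),
            class = "hbond_series")
}
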