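PEPTIDE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8)

# Natural-extension-reference-frame placement: position D given A-B-C with
# bond |CD|, angle B-C-D (deg) and dihedral A-B-C-D (deg).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal backbone from repeated (phi, psi) dihedrals
#'
#' Chain-extension construction with standard peptide bond lengths and
#' angles (trans peptide, omega = 180 deg): phi = psi = (-57, -47) gives an
#' ideal alpha-helix, (-139, 135) an extended beta strand. Returns a
#' one-frame topology with N, CA, C, O per residue — the geometric fixture
#' for the secondary-structure assigner.
#'
#' @param n_residues chain length.
#' @param phi,psi backbone dihedrals in degrees (recycled).
#' @param chain chain tag.
#' @return A `toy_topology` whose `xyz` holds the constructed conformation.
#' @export
make_ideal_backbone <- function(n_residues, phi = -57, psi = -47,
                                chain = "f") {
  stopifnot(n_residues >= 2)
  phi <- rep_len(phi, n_residues); psi <- rep_len(psi, n_residues)
  g <- PEPTIDE_GEOM
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(g$b_n_ca, 0, 0)
  a0 <- g$a_n_ca_c * pi / 180
  pos[["C1"]] <- pos[["CA1"]] + g$b_ca_c * c(-cos(a0), sin(a0), 0)
  for (i in seq_len(n_residues)) {
    ni <- pos[[paste0("N", i)]]; cai <- pos[[paste0("CA", i)]]
    ci <- pos[[paste0("C", i)]]
    pos[[paste0("O", i)]] <- nerf_place(ni, cai, ci, g$b_c_o, g$a_ca_c_o,
                                        psi[i] + 180)
    if (i == n_residues) break
    nn <- nerf_place(ni, cai, ci, g$b_c_n, g$a_ca_c_n, psi[i])
    pos[[paste0("N", i + 1)]] <- nn
    can <- nerf_place(cai, ci, nn, g$b_n_ca, g$a_c_n_ca, 180)
    pos[[paste0("CA", i + 1)]] <- can
    pos[[paste0("C", i + 1)]] <- nerf_place(ci, nn, can, g$b_ca_c,
                                            g$a_n_ca_c, phi[i + 1])
  }
  names_per <- c("N", "CA", "C", "O")
  atoms <- data.frame(
    name = rep(names_per, n_residues),
    role = rep(names_per, n_residues),
    residue = rep(seq_len(n_residues), each = 4),
    heavy = TRUE,
    element = rep(c("N", "C", "C", "O"), n_residues),
    stringsAsFactors = FALSE)
  xyz <- t(vapply(paste0(atoms$name, atoms$residue), function(k) pos[[k]],
                  numeric(3)))
  rownames(xyz) <- NULL
  residues <- data.frame(chain = chain, resno = seq_len(n_residues),
                         resname = "A",
                         label = format_residue_label(chain,
                                                      seq_len(n_residues),
                                                      "A"),
                         stringsAsFactors = FALSE)
  structure(list(residues = residues, atoms = atoms, xyz = xyz),
            class = "toy_topology")
}

# Backbone amide H reconstruction (DSSP convention): H sits 1.0 A from N
# along the direction of the preceding carbonyl C -> O reversed, i.e.
# h = n + (c_prev - o_prev)/|c_prev - o_prev|. Chain-initial residues get
# no H and cannot donate.
reconstruct_amide_h <- function(n_xyz, c_prev, o_prev) {
  v <- c_prev - o_prev
  n_xyz + v / sqrt(sum(v^2))
}

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between the CO of
# the acceptor and the NH of the donor; bond when E < -0.5.
ks_energy <- function(o, c, n, h) {
  r <- function(p, q) sqrt(sum((p - q)^2))
  27.888 * (1 / r(o, n) + 1 / r(c, h) - 1 / r(o, h) - 1 / r(c, n))
}

#' Simplified 3-class secondary-structure assignment
#'
#' Per-frame Kabsch-Sander-style assignment mapped to the three classes
#' used in persistency analysis: backbone H-bonds are detected with the
#' electrostatic criterion E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)
#' < -0.5 kcal/mol (amide H reconstructed geometrically when absent);
#' helix (3-, 4- or 5-turn patterns: two consecutive i -> i+n turns),
#' sheet (parallel/antiparallel bridge patterns), otherwise coil. Helix
#' takes priority over sheet.
#'
#' @param ensemble an [new_ensemble()] whose residues carry backbone
#'   N, CA, C, O atoms.
#' @return Object of class `sse_record`: `classes` (frames x residues
#'   character matrix with values `"helix"`, `"sheet"`, `"coil"`) and
#'   `nodes`.
#' @export
assign_sse <- function(ensemble) {
  topo <- ensemble$topology
  n <- nrow(topo$residues)
  nf <- n_frames(ensemble)
  idx <- lapply(c("N", "CA", "C", "O"), function(role) {
    vapply(seq_len(n), function(i) {
      hit <- which(topo$atoms$residue == i & topo$atoms$role == role)
      if (length(hit) == 1L) hit else NA_integer_
    }, 1L)
  })
  names(idx) <- c("N", "CA", "C", "O")
  missing_bb <- which(is.na(idx$N) | is.na(idx$CA) | is.na(idx$C) |
                        is.na(idx$O))
  if (length(missing_bb)) {
    warning("residue(s) missing backbone atoms forced to coil: ",
            paste(topo$residues$label[missing_bb], collapse = ", "))
  }
  same_chain_prev <- c(FALSE, topo$residues$chain[-1] ==
                         topo$residues$chain[-n])

  classes <- matrix("coil", nf, n)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    # reconstructed amide H per residue (NA for chain-initial / missing)
    h <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      if (!same_chain_prev[i] || i %in% missing_bb ||
          (i - 1) %in% missing_bb) next
      h[i, ] <- reconstruct_amide_h(xyz[idx$N[i], ], xyz[idx$C[i - 1], ],
                                    xyz[idx$O[i - 1], ])
    }
    # hb[i, j]: CO of residue i accepts the NH of residue j
    hb <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      if (i %in% missing_bb) next
      for (j in seq_len(n)) {
        if (abs(i - j) < 2 || j %in% missing_bb || anyNA(h[j, ])) next
        # cheap distance gate before the energy evaluation
        if (sum((xyz[idx$O[i], ] - xyz[idx$N[j], ])^2) > 25) next
        e <- ks_energy(xyz[idx$O[i], ], xyz[idx$C[i], ],
                       xyz[idx$N[j], ], h[j, ])
        hb[i, j] <- e < -0.5
      }
    }
    turn <- lapply(3:5, function(nn) {
      v <- rep(FALSE, n)
      ok <- seq_len(max(n - nn, 0))
      v[ok] <- hb[cbind(ok, ok + nn)]
      v
    })
    is_helix <- rep(FALSE, n)
    for (ti in seq_along(turn)) {
      nn <- (3:5)[ti]; tv <- turn[[ti]]
      for (i in seq_len(max(n - nn - 1, 0))) {
        if (tv[i] && tv[i + 1]) is_helix[(i + 1):(i + nn)] <- TRUE
      }
    }
    is_sheet <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      # parallel: hb(i-1, j) & hb(j, i+1); antiparallel: hb(i, j) & hb(j, i)
      # or hb(i-1, j+1) & hb(j-1, i+1)
      par <- (i > 1 && i < n && hb[i - 1, j] && hb[j, i + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i > 1 && i < n && j > 1 && j < n &&
           hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) { is_sheet[i] <- TRUE; is_sheet[j] <- TRUE }
    }
    cl <- ifelse(is_helix, "helix", ifelse(is_sheet, "sheet", "coil"))
    cl[missing_bb] <- "coil"
    classes[f, ] <- cl
  }
  colnames(classes) <- topo$residues$label
  structure(list(classes = classes, nodes = topo$residues$label),
            class = "sse_record")
}

#' Per-residue secondary-structure persistency
#'
#' Fraction of frames in which each residue retains its reference
#' secondary-structure class; the difference of two states' persistencies
#' is a plain subtraction (bounded in \[-1, 1\]).
#'
#' @param record an `sse_record` (from [assign_sse()] or an external
#'   per-frame assignment table coerced to a frames x residues character
#'   matrix).
#' @param reference named character vector: reference class per residue
#'   (must cover all residues of the record).
#' @return Named numeric vector of persistencies in \[0, 1\].
#' @export
sse_persistency <- function(record, reference) {
  classes <- if (inherits(record, "sse_record")) record$classes else
    as.matrix(record)
  nodes <- colnames(classes)
  if (!all(nodes %in% names(reference))) {
    stop("reference assignment does not cover all residues", call. = FALSE)
  }
  ref <- reference[nodes]
  match_ref <- t(t(classes) == as.character(ref))
  setNames(colMeans(match_ref), nodes)
}

#' Build an ideal two-stranded antiparallel beta sheet
#'
#' Two extended strands (phi = -139, psi = 135) in the canonical strand
#' frame (strand axis x, sheet plane xy), the second rotated 180 deg about
#' the sheet normal and offset so that inter-strand backbone hydrogen
#' bonds form — the geometric fixture for bridge-pattern detection.
#'
#' @param n_residues residues per strand.
#' @return A `toy_topology` with chains `f` and `h`, one strand each.
#' @export
make_antiparallel_sheet <- function(n_residues = 8L) {
  s_a <- make_ideal_backbone(n_residues, -139, 135, chain = "f")
  ca <- s_a$xyz[s_a$atoms$role == "CA", , drop = FALSE]
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  xyz_a <- sweep(s_a$xyz, 2, cen) %*% sv$v
  rz <- diag(c(-1, -1, 1))
  # registry offsets tuned once on the Kabsch-Sander energy so the two
  # strands pair with antiparallel bridges
  xyz_b <- sweep(xyz_a %*% t(rz), 2, c(-3.5, 4, -0.5), "+")
  atoms_b <- s_a$atoms; atoms_b$residue <- atoms_b$residue + n_residues
  res_b <- s_a$residues; res_b$chain <- "h"
  res_b$label <- format_residue_label("h", res_b$resno, res_b$resname)
  structure(list(residues = rbind(s_a$residues, res_b),
                 atoms = rbind(s_a$atoms, atoms_b),
                 xyz = rbind(xyz_a, xyz_b)),
            class = "toy_topology")
}
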