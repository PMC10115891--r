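AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
AA1 <- setNames(names(AA3), AA3)

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; chain tag `f` is written as chain ID
#' `A` and `h` as `B` (first/second chain in file order). Coordinates are
#' rendered with PDB's fixed 3-decimal precision.
#'
#' @param ensemble an [new_ensemble()].
#' @param path output file path.
#' @param chain_ids two chain-ID characters for the `f` and `h` tags.
#' @return `path`, invisibly.
#' @export
write_multi_model_pdb <- function(ensemble, path, chain_ids = c("A", "B")) {
  topo <- ensemble$topology
  chain_of <- setNames(chain_ids, c("f", "h"))
  res <- topo$residues[topo$atoms$residue, ]
  resname3 <- unname(AA3[ifelse(res$resname %in% names(AA3), res$resname, "X")])
  lines <- character(0)
  for (fr in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[fr, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    rec <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(topo$atoms)),
      ifelse(nchar(topo$atoms$name) < 4, paste0(" ", topo$atoms$name),
             topo$atoms$name),
      resname3, chain_of[res$chain], res$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, topo$atoms$element)
    lines <- c(lines, sprintf("MODEL     %4d", fr), rec, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file into an ensemble
#'
#' One frame per MODEL (a single-structure file yields a one-frame
#' ensemble). Hydrogens are kept but flagged non-heavy; insertion codes are
#' preserved in the residue table; the first chain ID in file order maps to
#' tag `f`, the second to `h` (override with `chain_map`).
#'
#' @param path PDB file.
#' @param chain_map optional named character vector mapping chain IDs to
#'   tags, e.g. `c(A = "f", B = "h")`.
#' @return An [new_ensemble()].
#' @export
read_multi_model_pdb <- function(path, chain_map = NULL) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_no <- cumsum(grepl("^MODEL", lines))
  if (max(model_no) == 0L) model_no <- rep(1L, length(lines))
  at <- lines[is_atom]
  if (!length(at)) stop("no ATOM records in ", path, call. = FALSE)
  amodel <- model_no[is_atom]
  models <- split(seq_along(at), amodel)
  n_per <- lengths(models)
  if (length(unique(n_per)) != 1L) {
    off <- names(n_per)[n_per != n_per[1]][1]
    stop(sprintf("MODEL %s has %d atoms; expected %d", off,
                 n_per[[off]], n_per[[1]]), call. = FALSE)
  }

  first <- at[models[[1]]]
  fld <- function(x, a, b) substr(x, a, b)
  name <- trimws(fld(first, 13, 16))
  resname3 <- trimws(fld(first, 18, 20))
  chain_id <- fld(first, 22, 22)
  resseq <- as.integer(fld(first, 23, 26))
  icode <- fld(first, 27, 27)
  element <- trimws(fld(first, 77, 78))
  no_el <- element == ""
  if (any(no_el)) {
    warning("atom(s) without element field; heavy flag inferred from name")
    element[no_el] <- substr(sub("^[0-9]*", "", name[no_el]), 1, 1)
  }

  if (is.null(chain_map)) {
    ids <- unique(chain_id)
    chain_map <- setNames(c("f", "h")[seq_along(ids)], ids)
  }
  res_key <- paste(chain_id, resseq, icode, sep = "|")
  res_idx <- match(res_key, unique(res_key))
  ures <- !duplicated(res_key)
  residues <- data.frame(
    chain = unname(chain_map[chain_id[ures]]),
    resno = resseq[ures],
    resname = unname(ifelse(resname3[ures] %in% names(AA1),
                            AA1[resname3[ures]], "X")),
    icode = icode[ures],
    stringsAsFactors = FALSE)
  residues$label <- format_residue_label(residues$chain, residues$resno,
                                         residues$resname)
  atoms <- data.frame(
    name = name,
    role = ifelse(name %in% c("N", "CA", "C", "O"), name, "sidechain"),
    residue = res_idx,
    heavy = !grepl("^H", element) & element != "D",
    element = element,
    stringsAsFactors = FALSE)

  coords <- array(0, c(length(models), length(first), 3))
  for (m in seq_along(models)) {
    rows <- at[models[[m]]]
    coords[m, , 1] <- as.numeric(fld(rows, 31, 38))
    coords[m, , 2] <- as.numeric(fld(rows, 39, 46))
    coords[m, , 3] <- as.numeric(fld(rows, 47, 54))
  }
  topo <- structure(list(residues = residues, atoms = atoms,
                         xyz = coords[1, , , drop = TRUE]),
                    class = "toy_topology")
  if (is.null(dim(topo$xyz))) topo$xyz <- matrix(topo$xyz, ncol = 3)
  new_ensemble(topo, coords)
}
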