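#' Parse a residue label of the form "fL63" or "hG50"
#'
#' Residues are addressed with the two-subunit convention used for
#' heterodimeric enzymes such as IGPS: a chain tag (`f` for the cyclase
#' subunit, `h` for the glutaminase subunit), an optional one-letter residue
#' code, and the residue number within that chain. `format_residue_label()`
#' is the exact inverse.
#'
#' @param text character vector of labels matching `[fh][A-Z]?[0-9]+`.
#' @return A data.frame with columns `chain`, `resname` (`NA` when the label
#'   carries no one-letter code) and `resno` (integer), one row per label.
#' @examples
#' parse_residue_label("fL63")
#' parse_residue_label(c("hG50", "f104"))
#' @export
parse_residue_label <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  m <- regmatches(text, regexec("^([fh])([A-Z]?)([0-9]+)$", text))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed residue label(s): ", paste(text[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    chain   = vapply(m, `[`, "", 2L),
    resname = ifelse(vapply(m, `[`, "", 3L) == "", NA_character_,
                     vapply(m, `[`, "", 3L)),
    resno   = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_residue_label
#' @param chain chain tag (`"f"` or `"h"`).
#' @param resno residue number within the chain.
#' @param resname optional one-letter residue code.
#' @export
format_residue_label <- function(chain, resno, resname = NA_character_) {
  paste0(chain, ifelse(is.na(resname), "", resname), resno)
}

# Resolve user-supplied residue labels to row indices of a topology's residue
# table. Accepts labels with or without the one-letter code.
resolve_residues <- function(topology, labels) {
  parsed <- parse_residue_label(labels)
  idx <- mapply(function(ch, no) {
    hit <- which(topology$residues$chain == ch & topology$residues$resno == no)
    if (length(hit) != 1L) NA_integer_ else hit
  }, parsed$chain, parsed$resno)
  if (anyNA(idx)) {
    stop("residue(s) not in topology: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  unname(idx)
}
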