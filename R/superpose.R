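#' Least-squares rigid superposition of an ensemble
#'
#' Fits every frame onto a reference by the optimal rotation + translation
#' (Kabsch construction via SVD, with the determinant guard that forbids
#' reflections), minimizing C-alpha RMSD. With `reference = "mean"` the
#' reference is the ensemble mean structure and the fit is iterated until the
#' mean stops moving (each pass recomputes the mean and re-fits), which
#' converges quickly and is the standard way to remove rigid-body motion
#' before correlation or covariance analysis.
#'
#' @param ensemble an [new_ensemble()].
#' @param reference `"mean"`, or a frame index, or an atoms x 3 matrix.
#' @param iterate number of mean-refit passes when `reference = "mean"`.
#' @return list: `ensemble` (aligned, flagged), `rmsd` (per-frame C-alpha
#'   RMSD to the reference, Angstrom).
#' @export
superpose <- function(ensemble, reference = "mean", iterate = 20L) {
  ca <- ca_indices(ensemble$topology)
  if (length(ca) < 3L) stop("need >= 3 C-alpha atoms to superpose",
                            call. = FALSE)
  co <- ensemble$coords
  nf <- dim(co)[1]

  fit_all <- function(co, ref_ca) {
    check_degenerate(ref_ca)
    rmsd <- numeric(nf)
    for (f in seq_len(nf)) {
      fr <- co[f, , , drop = TRUE]
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
      fit <- kabsch(fr[ca, , drop = FALSE], ref_ca)
      co[f, , ] <- sweep(fr, 2, fit$center_x) %*% fit$rotation
      co[f, , ] <- sweep(co[f, , , drop = TRUE], 2, fit$center_y, "+")
      moved <- co[f, ca, , drop = TRUE]
      rmsd[f] <- sqrt(mean(rowSums((moved - ref_ca)^2)))
    }
    list(co = co, rmsd = rmsd)
  }

  if (identical(reference, "mean")) {
    # iterate fit-to-mean to convergence (the mean moves after each pass);
    # convergence makes the operation idempotent to numerical precision
    for (pass in seq_len(max(iterate, 1L))) {
      ref_ca <- apply(co[, ca, , drop = FALSE], c(2, 3), mean)
      res <- fit_all(co, ref_ca)
      delta <- max(abs(res$co - co))
      co <- res$co
      if (delta < 1e-10) break
    }
  } else {
    ref <- if (is.matrix(reference)) reference else
      co[as.integer(reference), , , drop = TRUE]
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
    ref_ca <- if (nrow(ref) == length(ca)) ref else ref[ca, , drop = FALSE]
    res <- fit_all(co, ref_ca)
    co <- res$co
  }
  out <- ensemble
  out$coords <- co
  out$aligned <- TRUE
  list(ensemble = out, rmsd = res$rmsd)
}

# Optimal rotation mapping x onto y (both m x 3, same atoms), centered.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, center_x = cx, center_y = cy)
}

check_degenerate <- function(pts) {
  cen <- sweep(pts, 2, colMeans(pts))
  sv <- svd(cen, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate (collinear) C-alpha set; rigid fit is ill-defined",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-residue C-alpha root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2) in Angstrom; the ensemble must
#' be superposed first so that rigid-body drift does not inflate the
#' fluctuations.
#'
#' @param ensemble an aligned [new_ensemble()].
#' @return named numeric vector, one value per residue.
#' @export
rmsf <- function(ensemble) {
  if (!ensemble$aligned) stop("superpose the ensemble before RMSF",
                              call. = FALSE)
  ca <- ca_indices(ensemble$topology)
  co <- ensemble$coords[, ca, , drop = FALSE]
  if (dim(co)[1] == 1L) {
    warning("single-frame ensemble: RMSF is identically zero")
    return(setNames(numeric(length(ca)), ensemble$topology$residues$label))
  }
  mu <- apply(co, c(2, 3), mean)
  dev <- sweep(co, c(2, 3), mu)
  msf <- apply(dev^2, 2, function(m) mean(rowSums(matrix(m, ncol = 3))))
  setNames(sqrt(msf), ensemble$topology$residues$label)
}
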