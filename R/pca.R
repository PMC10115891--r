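#' Essential-dynamics PCA of an aligned ensemble
#'
#' Diagonalizes the covariance matrix of the flattened selected coordinates
#' (C-alpha by default, or the full N/CA/C/O backbone), giving the
#' collective modes of motion sorted by decreasing eigenvalue (A^2). The
#' ensemble must be superposed first: without removing rigid-body motion
#' the leading modes are rotations, not internal dynamics.
#'
#' @param ensemble an aligned [new_ensemble()] with >= 2 frames.
#' @param selection `"ca"` or `"backbone"`.
#' @return Object of class `pca_model`: `mean` (flattened mean
#'   coordinates), `modes` (columns = eigenvectors, orthonormal),
#'   `eigenvalues` (non-negative, non-increasing), `selection`, `basis`
#'   (`"single"`), `atom_idx`.
#' @export
fit_pca <- function(ensemble, selection = c("ca", "backbone")) {
  selection <- match.arg(selection)
  if (!ensemble$aligned) {
    stop("ensemble must be superposed before PCA (run superpose())",
         call. = FALSE)
  }
  if (n_frames(ensemble) < 2L) stop("need >= 2 frames", call. = FALSE)
  x <- selection_matrix(ensemble, selection)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / nrow(xc)  # population covariance: concatenation-consistent
  e <- eigen(cv, symmetric = TRUE)
  structure(list(mean = mu, modes = e$vectors,
                 eigenvalues = pmax(e$values, 0),
                 selection = selection, basis = "single",
                 atom_idx = attr(x, "atom_idx")),
            class = "pca_model")
}

selection_matrix <- function(ensemble, selection) {
  topo <- ensemble$topology
  idx <- if (selection == "ca") ca_indices(topo) else
    which(topo$atoms$role %in% c("N", "CA", "C", "O"))
  co <- ensemble$coords[, idx, , drop = FALSE]
  nf <- dim(co)[1]
  out <- matrix(0, nf, length(idx) * 3L)
  for (a in 1:3) out[, seq(a, by = 3L, length.out = length(idx))] <- co[, , a]
  attr(out, "atom_idx") <- idx
  out
}

#' Project frames onto principal components
#'
#' @param ensemble an ensemble with the same topology/selection as the
#'   model.
#' @param model a [fit_pca()] or [joint_basis()] model.
#' @param n_components number of leading components to keep.
#' @return frames x n_components matrix of projections (A).
#' @export
project <- function(ensemble, model, n_components = 3L) {
  x <- selection_matrix(ensemble, model$selection)
  if (ncol(x) != length(model$mean)) {
    stop("ensemble selection does not match the PCA model", call. = FALSE)
  }
  k <- min(n_components, ncol(model$modes))
  sweep(x, 2, model$mean) %*% model$modes[, seq_len(k), drop = FALSE]
}

#' Variance metrics of a PCA model
#'
#' Reports, for the first `k` modes, both the standard variance explained
#' (lambda_m / sum lambda and its cumulative sum) and a squared-eigenvalue
#' metric (cumulative sum of lambda_m^2 normalized by sum lambda^2) that
#' weights the top modes more strongly; the two are labelled distinctly
#' and never interchangeable.
#'
#' @param model a `pca_model`.
#' @param k number of leading components to report.
#' @return data.frame: `component`, `eigenvalue`, `var_explained`,
#'   `cum_var_explained`, `cum_sq_eigenvalue`.
#' @export
variance_metrics <- function(model, k = 10L) {
  lam <- model$eigenvalues
  k <- min(k, length(lam))
  if (sum(lam) <= 0) stop("model has zero total variance", call. = FALSE)
  ve <- lam / sum(lam)
  sq <- lam^2 / sum(lam^2)
  data.frame(component = seq_len(k),
             eigenvalue = lam[seq_len(k)],
             var_explained = ve[seq_len(k)],
             cum_var_explained = cumsum(ve)[seq_len(k)],
             cum_sq_eigenvalue = cumsum(sq)[seq_len(k)])
}

#' Joint (concatenated) PCA basis over several ensembles
#'
#' Fits one PCA on the frame-concatenated coordinates of all ensembles
#' (identical topologies, aligned to a common reference), so the states
#' can be compared in a single low-dimensional space: projections of each
#' state use the shared mean and shared modes.
#'
#' @param ensembles list of aligned ensembles with identical topologies.
#' @param selection `"ca"` or `"backbone"`.
#' @return A `pca_model` with `basis = "joint"`.
#' @export
joint_basis <- function(ensembles, selection = c("ca", "backbone")) {
  selection <- match.arg(selection)
  stopifnot(length(ensembles) >= 1L)
  mats <- lapply(ensembles, function(e) {
    if (!e$aligned) stop("all ensembles must be superposed", call. = FALSE)
    selection_matrix(e, selection)
  })
  p <- unique(vapply(mats, ncol, 1L))
  if (length(p) != 1L) stop("ensemble topologies differ", call. = FALSE)
  x <- do.call(rbind, mats)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  structure(list(mean = mu, modes = e$vectors,
                 eigenvalues = pmax(e$values, 0),
                 selection = selection, basis = "joint",
                 atom_idx = attr(mats[[1]], "atom_idx")),
            class = "pca_model")
}

#' Overlap of two states' 1-D projections (Bhattacharyya coefficient)
#'
#' Histogram-based Bhattacharyya coefficient of two projection vectors on
#' a shared basis: 1 = identical distributions, 0 = disjoint. Used to test
#' that two planted states separate on the component that carries their
#' difference and overlap on the others.
#'
#' @param proj_a,proj_b numeric vectors (projections of two states on one
#'   component of a joint basis).
#' @param n_bins histogram bins over the pooled range.
#' @return Bhattacharyya coefficient in \[0, 1\].
#' @export
projection_overlap <- function(proj_a, proj_b, n_bins = 50L) {
  rng <- range(c(proj_a, proj_b))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pa <- hist(proj_a, breaks = br, plot = FALSE)$counts / length(proj_a)
  pb <- hist(proj_b, breaks = br, plot = FALSE)$counts / length(proj_b)
  sum(sqrt(pa * pb))
}
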