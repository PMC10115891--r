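#' Specification of a planted-covariance Gaussian ensemble
#'
#' Describes the generating distribution of a synthetic conformational
#' ensemble: C-alpha displacements are drawn from a 3n-dimensional
#' multivariate Gaussian whose covariance is either a block design with
#' planted per-axis residue-pair correlations, an elastic-network covariance
#' (pseudo-inverse of a Kirchhoff matrix), or a user-supplied matrix.
#' `temperature_scale` multiplies the whole covariance, emulating the larger
#' thermal fluctuations of a heated state.
#'
#' @param n_frames number of frames to draw (>= 2).
#' @param covariance one of `"block"`, `"elastic_network"`, `"custom"`.
#' @param planted_pairs data.frame with columns `i`, `j` (residue indices)
#'   and `rho` (per-axis correlation, |rho| < 1); block covariance only.
#' @param base_variance per-axis displacement variance (A^2).
#' @param temperature_scale scalar multiplying the covariance (1 = reference
#'   temperature; 2 emulates a variance-doubling heating).
#' @param sigma custom 3n x 3n covariance (covariance = "custom").
#' @param en_cutoff elastic-network contact cutoff (A).
#' @param seed integer seed for the draw.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames,
                          covariance = c("block", "elastic_network", "custom"),
                          planted_pairs = NULL, base_variance = 1,
                          temperature_scale = 1, sigma = NULL,
                          en_cutoff = 7, seed = 1L) {
  covariance <- match.arg(covariance)
  stopifnot(n_frames >= 2, base_variance > 0, temperature_scale > 0)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("i", "j", "rho") %in% names(planted_pairs)),
              all(abs(planted_pairs$rho) < 1))
  }
  if (covariance == "custom" && is.null(sigma)) {
    stop("covariance = 'custom' requires sigma", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), covariance = covariance,
                 planted_pairs = planted_pairs, base_variance = base_variance,
                 temperature_scale = temperature_scale, sigma = sigma,
                 en_cutoff = en_cutoff, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Build the 3n x 3n displacement covariance a spec describes.
spec_covariance <- function(topology, spec) {
  n <- nrow(topology$residues)
  sig <- switch(spec$covariance,
    block = {
      s <- diag(spec$base_variance, 3 * n)
      pp <- spec$planted_pairs
      if (!is.null(pp)) {
        for (r in seq_len(nrow(pp))) {
          i <- pp$i[r]; j <- pp$j[r]
          if (i < 1 || j < 1 || i > n || j > n || i == j) {
            stop("planted pair addresses unknown residue pair (", i, ",", j,
                 ")", call. = FALSE)
          }
          for (a in 0:2) {
            s[3 * (i - 1) + 1 + a, 3 * (j - 1) + 1 + a] <-
              s[3 * (j - 1) + 1 + a, 3 * (i - 1) + 1 + a] <-
              pp$rho[r] * spec$base_variance
          }
        }
      }
      s
    },
    elastic_network = {
      ca <- topology$xyz[ca_indices(topology), , drop = FALSE]
      d <- as.matrix(stats::dist(ca))
      k <- -(d > 0 & d <= spec$en_cutoff) * 1
      diag(k) <- -rowSums(k)
      cres <- pseudo_inverse(k)
      # rescale so the mean per-residue variance equals base_variance
      cres <- cres * spec$base_variance / mean(diag(cres))
      kronecker(cres, diag(3))
    },
    custom = {
      if (!is.matrix(spec$sigma) || any(dim(spec$sigma) != 3 * n)) {
        stop("custom sigma must be 3*n_residues square", call. = FALSE)
      }
      spec$sigma
    })
  sig * spec$temperature_scale
}

pseudo_inverse <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Symmetric PSD square root; errors naming the offending eigenvalue.
psd_sqrt <- function(sigma) {
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol) {
    stop(sprintf("covariance is not positive semi-definite (eigenvalue %.6g)",
                 min(e$values)), call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(vals))
}

#' Draw a correlated Gaussian conformational ensemble
#'
#' Each frame is the topology's reference structure plus a C-alpha
#' displacement drawn from the spec's multivariate Gaussian; all atoms of a
#' residue move rigidly with its C-alpha, so C-alpha-level correlations and
#' heavy-atom contact statistics share one planted ground truth.
#'
#' @param topology a `toy_topology`.
#' @param spec an [ensemble_spec()].
#' @param state,temperature optional labels stored on the ensemble.
#' @return An [new_ensemble()] with `spec$n_frames` frames.
#' @export
sample_gaussian_ensemble <- function(topology, spec, state = NULL,
                                     temperature = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- nrow(topology$residues)
  sigma <- spec_covariance(topology, spec)
  root <- psd_sqrt(sigma)
  disp <- with_seed(spec$seed, {
    z <- matrix(rnorm(spec$n_frames * 3 * n), spec$n_frames, 3 * n)
    z %*% t(root)
  })
  coords <- array(0, c(spec$n_frames, nrow(topology$atoms), 3))
  res_of_atom <- topology$atoms$residue
  for (a in 1:3) {
    axis_disp <- disp[, 3 * (seq_len(n) - 1) + a, drop = FALSE]
    coords[, , a] <- axis_disp[, res_of_atom, drop = FALSE] +
      rep(topology$xyz[, a], each = spec$n_frames)
  }
  # frames are drawn in the generator's fixed laboratory frame: no
  # rigid-body motion is introduced, so the ensemble is born aligned
  new_ensemble(topology, coords, state = state, temperature = temperature,
               aligned = TRUE)
}

#' Generate a matched two-state ensemble pair with planted perturbations
#'
#' Emulates an apo/holo (or cold/heated) comparison: state A is drawn from
#' `base_spec`; state B differs only by the planted perturbations — changed
#' per-axis coupling on named residue pairs (driving the downstream
#' eigenvector-centrality difference) and/or changed C-alpha distances on
#' named residue pairs (driving the contact-perturbation network). A
#' ground-truth table of every planted change and its expected downstream
#' sign is returned alongside.
#'
#' @param topology a `toy_topology`.
#' @param base_spec [ensemble_spec()] for state A (block covariance).
#' @param delta_rho data.frame(`i`, `j`, `delta`): additive change to the
#'   planted per-axis correlation of pair (i, j) in state B.
#' @param contact_shift data.frame(`i`, `j`, `distance`): in state B's
#'   reference geometry residue `j` (all its atoms) is translated along the
#'   i->j axis so the CA-CA distance equals `distance` (A).
#' @param temperature_scale_B covariance scale for state B (defaults to A's).
#' @return list with `A`, `B` (ensembles) and `ground_truth` (data.frame:
#'   `kind`, `i`, `j`, `value`, `expected_sign` for the downstream
#'   delta-EC / delta-w).
#' @export
make_two_state_pair <- function(topology, base_spec, delta_rho = NULL,
                                contact_shift = NULL,
                                temperature_scale_B = NULL) {
  stopifnot(inherits(base_spec, "ensemble_spec"),
            base_spec$covariance == "block")
  n <- nrow(topology$residues)
  truth <- list()

  spec_b <- base_spec
  spec_b$seed <- base_spec$seed + 1L
  if (!is.null(temperature_scale_B)) spec_b$temperature_scale <- temperature_scale_B

  if (!is.null(delta_rho)) {
    stopifnot(all(c("i", "j", "delta") %in% names(delta_rho)))
    pp <- base_spec$planted_pairs %||%
      data.frame(i = integer(), j = integer(), rho = numeric())
    for (r in seq_len(nrow(delta_rho))) {
      i <- delta_rho$i[r]; j <- delta_rho$j[r]
      if (i < 1 || j < 1 || i > n || j > n) {
        stop("delta_rho addresses unknown residue pair (", i, ",", j, ")",
             call. = FALSE)
      }
      hit <- which((pp$i == i & pp$j == j) | (pp$i == j & pp$j == i))
      old <- if (length(hit)) pp$rho[hit[1]] else 0
      new <- old + delta_rho$delta[r]
      if (abs(new) >= 1) stop("perturbed rho leaves (-1, 1)", call. = FALSE)
      if (length(hit)) pp$rho[hit[1]] <- new
      else pp <- rbind(pp, data.frame(i = i, j = j, rho = new))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "coupling", i = i, j = j, value = delta_rho$delta[r],
        expected_sign = sign(delta_rho$delta[r]))
    }
    spec_b$planted_pairs <- pp
  }

  topo_b <- topology
  if (!is.null(contact_shift)) {
    stopifnot(all(c("i", "j", "distance") %in% names(contact_shift)))
    ca <- ca_indices(topology)
    for (r in seq_len(nrow(contact_shift))) {
      i <- contact_shift$i[r]; j <- contact_shift$j[r]
      if (i < 1 || j < 1 || i > n || j > n || i == j) {
        stop("contact_shift addresses unknown residue pair (", i, ",", j, ")",
             call. = FALSE)
      }
      v <- topo_b$xyz[ca[j], ] - topo_b$xyz[ca[i], ]
      d0 <- sqrt(sum(v^2))
      shift <- v / d0 * (contact_shift$distance[r] - d0)
      sel <- topo_b$atoms$residue == j
      topo_b$xyz[sel, ] <- sweep(topo_b$xyz[sel, , drop = FALSE], 2, shift, "+")
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "contact", i = i, j = j,
        value = contact_shift$distance[r] - d0,
        expected_sign = ifelse(contact_shift$distance[r] < d0, 1, -1))
    }
  }

  list(A = sample_gaussian_ensemble(topology, base_spec, state = "A"),
       B = sample_gaussian_ensemble(topo_b, spec_b, state = "B"),
       ground_truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(kind = character(), i = integer(), j = integer(),
                    value = numeric(), expected_sign = numeric()))
}
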