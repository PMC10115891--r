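#' Build the generalized-correlation residue network of an ensemble
#'
#' Each node is one residue's C-alpha; the edge weight A_ij is the
#' generalized correlation r_MI of the two residues' displacement vectors,
#' estimated after superposing every frame onto the ensemble mean (Kabsch
#' fit, iterated to convergence) so rigid-body motion does not masquerade as
#' correlation; ensembles already flagged aligned (e.g. synthetic draws
#' born in a common frame) are used as-is. The diagonal is set to zero
#' (no self-edges).
#'
#' @param ensemble an [new_ensemble()] with >= 100 frames.
#' @param estimator `"gaussian"` (closed-form, default) or `"knn"`.
#' @param k neighbour count for the knn estimator.
#' @return Object of class `correlation_network`: `nodes` (residue labels),
#'   `A` (symmetric r_MI matrix, zero diagonal), `estimator`, `n_frames`.
#' @export
build_network <- function(ensemble, estimator = c("gaussian", "knn"), k = 6L) {
  estimator <- match.arg(estimator)
  if (n_frames(ensemble) < 100L) {
    stop("need >= 100 frames to estimate a correlation network",
         call. = FALSE)
  }
  aligned <- if (ensemble$aligned) ensemble else
    superpose(ensemble, reference = "mean", iterate = 20L)$ensemble
  x <- ca_matrix(aligned)
  x <- sweep(x, 2, colMeans(x))
  n <- nrow(ensemble$topology$residues)
  a <- matrix(0, n, n)

  if (estimator == "gaussian") {
    sig <- stats::cov(x)
    ld3 <- vapply(seq_len(n), function(i) {
      idx <- 3 * (i - 1) + 1:3
      determinant(sig[idx, idx])$modulus[1]
    }, 0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      idx <- c(3 * (i - 1) + 1:3, 3 * (j - 1) + 1:3)
      dt <- determinant(sig[idx, idx])
      mi <- if (dt$sign[1] <= 0) MI_CAP else {
        0.5 * (ld3[i] + ld3[j] - dt$modulus[1])
      }
      a[i, j] <- a[j, i] <- generalized_correlation(min(max(mi, 0), MI_CAP))
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      mi <- estimate_mi(x[, 3 * (i - 1) + 1:3], x[, 3 * (j - 1) + 1:3],
                        estimator = "knn", k = k)
      a[i, j] <- a[j, i] <- generalized_correlation(mi$I)
    }
  }
  nodes <- ensemble$topology$residues$label
  dimnames(a) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = a, estimator = estimator,
                 n_frames = n_frames(ensemble)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %s estimator, %d frames\n",
              length(x$nodes), x$estimator, x$n_frames))
  invisible(x)
}

#' Eigenvector centrality of a residue correlation network
#'
#' The centrality c_i of residue i is the i-th entry of the leading
#' eigenvector of the adjacency matrix: c_i = (1/eps) * sum_j A_ij c_j,
#' eps the leading eigenvalue. By Perron-Frobenius the leading eigenvector
#' of a connected non-negative network can be chosen entrywise
#' non-negative; the profile is normalized to unit L2 norm so centralities
#' of different states are directly comparable. On a disconnected network
#' the profile is computed on the largest connected component and other
#' nodes get 0, with a warning.
#'
#' @param network a `correlation_network` (or any symmetric non-negative
#'   matrix with dimnames).
#' @param method `"dense"` (full symmetric eigendecomposition, default) or
#'   `"power"` (power iteration).
#' @param tol convergence tolerance for power iteration.
#' @return Object of class `centrality_profile`: `nodes`, `c` (unit L2,
#'   entries >= 0), `eigenvalue`, `normalization = "L2"`.
#' @export
eigenvector_centrality <- function(network, method = c("dense", "power"),
                                   tol = 1e-12) {
  method <- match.arg(method)
  a <- if (is.matrix(network)) network else network$A
  nodes <- if (is.matrix(network)) {
    rownames(network) %||% as.character(seq_len(nrow(network)))
  } else network$nodes
  stopifnot(isSymmetric(unname(a), tol = 1e-10), all(a >= 0))
  if (all(a == 0)) stop("degenerate network: all edge weights are zero",
                        call. = FALSE)

  comp <- connected_components(a > 0)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  if (length(sizes) > 1L) {
    warning("network is disconnected; centrality computed on the largest ",
            "component (", sizes[main], "/", length(comp), " nodes)")
  }
  keep <- which(comp == main)
  sub <- a[keep, keep, drop = FALSE]

  if (method == "dense") {
    e <- eigen(sub, symmetric = TRUE)
    eps <- e$values[1]
    v <- e$vectors[, 1]
  } else {
    v <- rep(1 / sqrt(nrow(sub)), nrow(sub))
    eps <- 0
    for (it in seq_len(100000L)) {
      w <- sub %*% v
      eps_new <- sqrt(sum(w^2))
      w <- as.vector(w) / eps_new
      if (max(abs(w - v)) < tol) { v <- w; eps <- eps_new; break }
      v <- w; eps <- eps_new
    }
  }
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  if (any(v < 0)) v <- pmax(v, 0)  # numerical dust on the Perron vector
  full <- numeric(length(comp))
  full[keep] <- v
  full <- full / sqrt(sum(full^2))
  resid <- sqrt(sum((a %*% full - eps * full)^2))
  if (resid > 1e-6) {
    warning(sprintf("eigen residual %.2e above 1e-6", resid))
  }
  structure(list(nodes = nodes, c = setNames(full, nodes),
                 eigenvalue = eps, normalization = "L2"),
            class = "centrality_profile")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Per-residue eigenvector-centrality difference between two states
#'
#' Delta-EC_i = c_i(B) - c_i(A) on the unit-L2 profiles; positive values
#' mark residues whose relative contribution to the correlated dynamics
#' grows in state B (e.g. upon effector binding or heating). The summed
#' positive and negative parts support side-level aggregation of
#' centrality gain vs depletion.
#'
#' @param profile_a,profile_b `centrality_profile`s over the same node set.
#' @return Object of class `centrality_difference`: `nodes`, `delta`
#'   (named), `gain` (sum of positive parts), `loss` (sum of negative
#'   parts).
#' @export
centrality_difference <- function(profile_a, profile_b) {
  if (!identical(profile_a$nodes, profile_b$nodes)) {
    extra <- union(setdiff(profile_a$nodes, profile_b$nodes),
                   setdiff(profile_b$nodes, profile_a$nodes))
    stop("node sets differ: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  d <- profile_b$c - profile_a$c
  structure(list(nodes = profile_a$nodes, delta = d,
                 gain = sum(d[d > 0]), loss = sum(d[d < 0])),
            class = "centrality_difference")
}
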