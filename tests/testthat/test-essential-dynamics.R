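# Helper: ensemble with displacements drawn along explicit CA-space modes.
# `modes` is a 3n x m orthonormal matrix, `sds` the per-mode sd (A).
planted_mode_ensemble <- function(topo, modes, sds, n_frames, seed) {
  sigma <- modes %*% (t(modes) * sds^2)
  sample_gaussian_ensemble(
    topo, ensemble_spec(n_frames, covariance = "custom",
                        sigma = sigma, seed = seed))
}

unit_mode <- function(n3, seed) {
  set.seed(seed)
  v <- rnorm(n3)
  v / sqrt(sum(v^2))
}

test_that("rank-1 covariance is recovered as a single dominant mode", {
  topo <- make_toy_topology(8, seed = 41)
  v <- unit_mode(24, seed = 1)
  ens <- planted_mode_ensemble(topo, matrix(v, ncol = 1), 2, 20000, seed = 2)
  m <- fit_pca(ens)
  vm <- variance_metrics(m, k = 3)
  expect_gt(vm$var_explained[1], 0.99)
  expect_gt(abs(sum(m$modes[, 1] * v)), 0.99)
  # spectral identities
  x <- matrix(0, 20000, 24)
  ca <- which(topo$atoms$role == "CA")
  for (a in 1:3) x[, seq(a, 24, by = 3)] <- ens$coords[, ca, a]
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / nrow(xc)
  expect_equal(sum(m$eigenvalues), sum(diag(cv)), tolerance = 1e-8)
  expect_equal(crossprod(m$modes), diag(24), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
})

test_that("planted 4:1 eigenvalue ratio is recovered within 5%", {
  topo <- make_toy_topology(8, seed = 41)
  v1 <- unit_mode(24, seed = 3)
  v2 <- unit_mode(24, seed = 4)
  v2 <- v2 - sum(v1 * v2) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  ens <- planted_mode_ensemble(topo, cbind(v1, v2), c(2, 1), 20000, seed = 5)
  m <- fit_pca(ens)
  expect_lt(abs(m$eigenvalues[1] / m$eigenvalues[2] - 4), 0.2)
  expect_gt(abs(sum(m$modes[, 1] * v1)), 0.99)
  expect_gt(abs(sum(m$modes[, 2] * v2)), 0.99)
})

test_that("PCA refuses unaligned input and short ensembles", {
  topo <- make_toy_topology(5, seed = 2)
  ens <- sample_gaussian_ensemble(
    topo, ensemble_spec(200, covariance = "block", seed = 1))
  un <- ens; un$aligned <- FALSE
  expect_error(fit_pca(un), "superpose")
  one <- static_ensemble(topo, 1)
  expect_error(fit_pca(one), "frames")
})

test_that("projections vanish at the mean and reconstruct completely", {
  topo <- make_toy_topology(6, seed = 7)
  ens <- sample_gaussian_ensemble(
    topo, ensemble_spec(300, covariance = "block", seed = 9))
  m <- fit_pca(ens)
  # projecting the training mean gives 0: build a one-frame ensemble at the
  # mean CA positions (all atoms at their mean)
  mean_xyz <- apply(ens$coords, c(2, 3), mean)
  at_mean <- frames_ensemble(topo, list(mean_xyz, mean_xyz))
  pr <- project(at_mean, m, n_components = 5)
  expect_lt(max(abs(pr)), 1e-10)

  # full reconstruction of centered coordinates
  full <- project(ens, m, n_components = length(m$eigenvalues))
  ca <- which(topo$atoms$role == "CA")
  x <- matrix(0, 300, 18)
  for (a in 1:3) x[, seq(a, 18, by = 3)] <- ens$coords[, ca, a]
  xc <- sweep(x, 2, m$mean)
  expect_lt(max(abs(full %*% t(m$modes) - xc)), 1e-8)

  small <- make_toy_topology(4, seed = 8)
  ens2 <- static_ensemble(small, 3)
  expect_error(project(ens2, m), "selection")
})

test_that("variance metrics report both definitions distinctly", {
  m <- structure(list(mean = numeric(4), modes = diag(4),
                      eigenvalues = c(4, 1, 0, 0), selection = "ca",
                      basis = "single", atom_idx = 1:4),
                 class = "pca_model")
  vm <- variance_metrics(m, k = 2)
  expect_equal(vm$cum_var_explained[1], 0.8)
  expect_equal(vm$cum_sq_eigenvalue[1], 16 / 17)
  expect_equal(vm$cum_var_explained[2], 1)
  expect_equal(vm$cum_sq_eigenvalue[2], 1)

  iso <- m; iso$eigenvalues <- rep(2, 4)
  expect_equal(variance_metrics(iso, 4)$var_explained, rep(0.25, 4))
})

test_that("joint basis equals single-state basis on duplicated input", {
  topo <- make_toy_topology(6, seed = 11)
  ens <- sample_gaussian_ensemble(
    topo, ensemble_spec(500, covariance = "block", seed = 12))
  single <- fit_pca(ens)
  joint <- joint_basis(list(ens, ens))
  expect_equal(joint$eigenvalues, single$eigenvalues, tolerance = 1e-8)
  # joint projections equal projections of centered coordinates by definition
  pr1 <- project(ens, joint, 3)
  ca <- which(topo$atoms$role == "CA")
  x <- matrix(0, 500, 18)
  for (a in 1:3) x[, seq(a, 18, by = 3)] <- ens$coords[, ca, a]
  manual <- sweep(x, 2, joint$mean) %*% joint$modes[, 1:3]
  expect_equal(pr1, manual, tolerance = 1e-12)

  other <- make_toy_topology(7, seed = 13)
  ens_o <- static_ensemble(other, 5)
  expect_error(joint_basis(list(ens, ens_o)), "topolog")
})

test_that("disjoint planted modes both surface in the top-2 joint PCs", {
  topo <- make_toy_topology(8, seed = 21)
  v1 <- unit_mode(24, seed = 31)
  v2 <- unit_mode(24, seed = 32)
  v2 <- v2 - sum(v1 * v2) * v1; v2 <- v2 / sqrt(sum(v2^2))
  e1 <- planted_mode_ensemble(topo, matrix(v1, ncol = 1), 2, 4000, seed = 33)
  e2 <- planted_mode_ensemble(topo, matrix(v2, ncol = 1), 2, 4000, seed = 34)
  joint <- joint_basis(list(e1, e2))
  span <- joint$modes[, 1:2]
  # both planted directions lie in the span of the top-2 joint PCs
  expect_gt(sqrt(sum((t(span) %*% v1)^2)), 0.99)
  expect_gt(sqrt(sum((t(span) %*% v2)^2)), 0.99)
})

test_that("joint projections separate planted states as in the study design", {
  topo <- make_toy_topology(8, seed = 21)
  v1 <- unit_mode(24, seed = 41)
  # two states displaced along v1 by +/- 2 A around a shared background
  base <- diag(0.25, 24)
  mk <- function(shift, seed) {
    ens <- sample_gaussian_ensemble(
      topo, ensemble_spec(3000, covariance = "custom", sigma = base,
                          seed = seed))
    ca <- which(topo$atoms$role == "CA")
    res_disp <- matrix(shift * v1, ncol = 3, byrow = TRUE)
    for (a in 1:3) {
      ens$coords[, , a] <- ens$coords[, , a] +
        rep(res_disp[topo$atoms$residue, a], each = 3000)
    }
    ens
  }
  ens_a <- mk(2, 42); ens_b <- mk(-2, 43)
  joint <- joint_basis(list(ens_a, ens_b))
  pa <- project(ens_a, joint, 3); pb <- project(ens_b, joint, 3)
  pooled_sd <- sqrt((stats::var(pa[, 1]) + stats::var(pb[, 1])) / 2)
  expect_gt(abs(mean(pa[, 1]) - mean(pb[, 1])), 3 * pooled_sd)
  # separation on PC1, overlap on PC2/PC3 (Bhattacharyya)
  o1 <- projection_overlap(pa[, 1], pb[, 1])
  o2 <- projection_overlap(pa[, 2], pb[, 2])
  o3 <- projection_overlap(pa[, 3], pb[, 3])
  expect_lt(o1, 0.2)
  expect_gt(o2, o1)
  expect_gt(o3, o1)
  expect_true(all(c(o1, o2, o3) >= 0 & c(o1, o2, o3) <= 1))
})
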