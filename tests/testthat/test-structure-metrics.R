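test_that("superposition is exact for rigid motions and reports RMSD 0", {
  topo <- make_toy_topology(10, seed = 17)
  ref <- topo$xyz
  moved <- sweep(ref %*% t(rotation_z(pi / 2)), 2, c(5, -3, 2), "+")
  ens <- frames_ensemble(topo, list(ref, moved), aligned = FALSE)
  fit <- superpose(ens, reference = 1)
  expect_equal(fit$rmsd[1], 0, tolerance = 1e-10)
  expect_lt(fit$rmsd[2], 1e-6)
  expect_true(fit$ensemble$aligned)
})

test_that("RMSD has its closed form on a symmetric fixture", {
  # 10 CA: 8 cube vertices + 2 on the x axis; displacing the two axial
  # atoms by +/- 0.5 A keeps centroid and optimal rotation at identity,
  # so RMSD = sqrt((0.5^2 + 0.5^2)/10) = sqrt(1/20)
  cube <- as.matrix(expand.grid(c(-4, 4), c(-4, 4), c(-4, 4)))
  colnames(cube) <- NULL
  ca <- rbind(cube, c(8, 0, 0), c(-8, 0, 0))
  topo <- ca_only_topology(ca)
  disp <- ca
  disp[9, 1] <- disp[9, 1] + 0.5
  disp[10, 1] <- disp[10, 1] - 0.5
  ens <- frames_ensemble(topo, list(ca, disp), aligned = FALSE)
  fit <- superpose(ens, reference = 1)
  expect_equal(fit$rmsd[2], sqrt(1 / 20), tolerance = 1e-10)
})

test_that("superposing to the mean is idempotent and matches bio3d", {
  topo <- make_toy_topology(12, seed = 23)
  ens <- sample_gaussian_ensemble(
    topo, ensemble_spec(40, covariance = "block", base_variance = 0.5,
                        seed = 4))
  # scramble with per-frame rigid motions
  set.seed(8)
  for (f in 1:40) {
    ens$coords[f, , ] <- sweep(
      ens$coords[f, , ] %*% t(rotation_x(runif(1, 0, 2 * pi))),
      2, rnorm(3, sd = 4), "+")
  }
  ens$aligned <- FALSE
  fit1 <- superpose(ens)
  fit2 <- superpose(fit1$ensemble)
  expect_lt(max(abs(fit2$ensemble$coords - fit1$ensemble$coords)), 1e-9)

  # cross-check the per-frame optimal RMSD against bio3d's Kabsch fit
  ca <- which(topo$atoms$role == "CA")
  ref <- apply(fit1$ensemble$coords[, ca, , drop = FALSE], c(2, 3), mean)
  for (f in c(1, 20, 40)) {
    inds <- seq_len(3 * length(ca))
    theirs <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                             mobile = as.vector(t(ens$coords[f, ca, ])),
                             fixed.inds = inds, mobile.inds = inds)
    d <- matrix(theirs, ncol = 3, byrow = TRUE) - ref
    rmsd_bio3d <- sqrt(mean(rowSums(d^2)))
    mine <- sqrt(mean(rowSums(
      (fit1$ensemble$coords[f, ca, ] - ref)^2)))
    expect_equal(mine, rmsd_bio3d, tolerance = 1e-6)
  }
})

test_that("degenerate collinear CA sets are refused", {
  ca <- cbind(seq(0, 36, by = 4), 0, 0)
  topo <- ca_only_topology(ca)
  ens <- static_ensemble(topo, 2, aligned = FALSE)
  expect_error(superpose(ens), "collinear")
})

test_that("RMSF matches analytic moments and is rotation invariant", {
  topo <- make_toy_topology(6, seed = 19)
  ens <- static_ensemble(topo, n_frames = 5)
  expect_true(all(rmsf(ens) == 0))

  sigma <- 0.7
  ens2 <- sample_gaussian_ensemble(
    topo, ensemble_spec(20000, covariance = "block",
                        base_variance = sigma^2, seed = 5))
  r <- rmsf(ens2)
  expect_true(all(abs(r - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.02))

  rot <- transform_ensemble(ens2, rotation_z(1.1), c(3, 1, -2))
  expect_equal(rmsf(rot), r, tolerance = 1e-10)

  # planted mobile segment rises above a rigid background
  sig <- diag(0.04, 18)
  sig[13:18, 13:18] <- diag(1, 6)  # residues 5-6 mobile
  ens3 <- sample_gaussian_ensemble(
    topo, ensemble_spec(5000, covariance = "custom", sigma = sig, seed = 6))
  r3 <- rmsf(ens3)
  expect_true(all(r3[5:6] > 3 * max(r3[1:4])))

  one <- static_ensemble(topo, n_frames = 1)
  expect_warning(r1 <- rmsf(one), "single")
  expect_true(all(r1 == 0))
  un <- ens2; un$aligned <- FALSE
  expect_error(rmsf(un), "superpose")
})

test_that("ideal helix, antiparallel sheet and random coil classify correctly", {
  helix <- make_ideal_backbone(20, phi = -57, psi = -47)
  ens_h <- static_ensemble(helix, 2)
  sse_h <- assign_sse(ens_h)
  interior <- 3:18
  expect_gt(mean(sse_h$classes[1, interior] == "helix"), 0.85)

  sheet <- make_antiparallel_sheet(8)
  ens_s <- static_ensemble(sheet, 2)
  sse_s <- assign_sse(ens_s)
  expect_gte(sum(sse_s$classes[1, ] == "sheet"), 8)
  expect_identical(sum(sse_s$classes[1, ] == "helix"), 0L)

  coil <- make_toy_topology(24, seed = 29)
  sse_c <- assign_sse(static_ensemble(coil, 2))
  expect_gte(mean(sse_c$classes[1, ] == "coil"), 0.8)
})

test_that("persistency is the per-residue match fraction", {
  classes <- matrix("coil", nrow = 10, ncol = 3)
  classes[1:5, 2] <- "helix"
  colnames(classes) <- paste0("fA", 1:3)
  ref <- c(fA1 = "coil", fA2 = "helix", fA3 = "sheet")
  p <- sse_persistency(classes, ref)
  expect_equal(unname(p), c(1, 0.5, 0))
  expect_true(all(p >= 0 & p <= 1))
  # difference-persistency bounded in [-1, 1]
  p2 <- sse_persistency(classes[c(1, 1, 1), ], ref)
  expect_true(all(abs(p - p2) <= 1))
})

test_that("hinge angles match analytic values and rigid invariance", {
  ca <- rbind(c(-5, 0, 0), c(0, 0, 0), c(5, 0, 0))
  topo <- ca_only_topology(ca)
  labs <- topo$residues$label
  ens <- static_ensemble(topo, 2)
  a <- hinge_angle(ens, labs)
  expect_equal(a$angle, c(180, 180), tolerance = 1e-8)

  ca2 <- rbind(c(5, 0, 0), c(0, 0, 0), c(0, 5, 0))
  ens2 <- static_ensemble(ca_only_topology(ca2), 2)
  expect_equal(hinge_angle(ens2, labs)$angle[1], 90, tolerance = 1e-8)

  ca3 <- rbind(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0))
  ens3 <- static_ensemble(ca_only_topology(ca3), 2)
  expect_equal(hinge_angle(ens3, labs)$angle[1], 45, tolerance = 1e-8)

  moved <- transform_ensemble(ens3, rotation_x(0.7), c(2, -1, 9))
  expect_equal(hinge_angle(moved, labs)$angle,
               hinge_angle(ens3, labs)$angle, tolerance = 1e-8)
})

test_that("hydrogen-bond series report distances and occupancy", {
  r1 <- rbind(N = c(0, 0, 0), CA = c(1.5, 0, 0))
  r2 <- rbind(CA = c(10, 0, 0), O = c(2.9, 0, 0))
  topo <- manual_topology(list(r1, r2))
  labs <- topo$residues$label
  donor <- paste0(labs[1], "-N"); acceptor <- paste0(labs[2], "-O")
  ens <- static_ensemble(topo, 4)
  hb <- hbond_series(ens, donor, acceptor)
  expect_equal(hb$distance, rep(2.9, 4), tolerance = 1e-12)
  expect_equal(hb$occupancy, 1)

  # 30% of frames below cutoff by construction
  frames <- lapply(1:10, function(f) {
    m <- topo$xyz
    m[4, 1] <- if (f <= 3) 2.9 else 6
    m
  })
  ens2 <- frames_ensemble(topo, frames)
  hb2 <- hbond_series(ens2, donor, acceptor, cutoff = 3.5)
  expect_equal(hb2$occupancy, 0.3)

  # hand-computed Euclidean norms on 3 frames
  f3 <- list(topo$xyz,
             { m <- topo$xyz; m[4, ] <- c(1, 2, 2); m },
             { m <- topo$xyz; m[4, ] <- c(3, 4, 0); m })
  hb3 <- hbond_series(frames_ensemble(topo, f3), donor, acceptor)
  expect_equal(hb3$distance, c(2.9, 3, 5), tolerance = 1e-12)

  expect_error(hbond_series(ens, paste0(labs[1], "-ZZ"), acceptor), "ZZ")
})
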