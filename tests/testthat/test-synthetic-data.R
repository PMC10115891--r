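test_that("make_toy_topology splits chains and is seed-deterministic", {
  topo <- make_toy_topology(10, split = 0.5, seed = 7)
  expect_identical(as.integer(table(topo$residues$chain)[c("f", "h")]),
                   c(5L, 5L))
  topo2 <- make_toy_topology(10, split = 0.5, seed = 7)
  expect_identical(topo$xyz, topo2$xyz)
  expect_identical(topo$residues, topo2$residues)
  expect_error(make_toy_topology(1), "n_residues")
})

test_that("toy topology honours its own geometric contract", {
  topo <- make_toy_topology(40, seed = 3)
  ca <- topo$xyz[which(topo$atoms$role == "CA"), , drop = FALSE]
  steps <- sqrt(rowSums(diff(ca)^2))
  # consecutive residues-in-file are consecutive along the walk
  expect_true(all(abs(steps - 3.8) <= 0.1 + 1e-9))
  # sidechain atoms within 2.5 A of their residue's CA
  sc <- which(topo$atoms$role == "sidechain")
  ca_of <- ca[topo$atoms$residue[sc], , drop = FALSE]
  expect_true(all(sqrt(rowSums((topo$xyz[sc, , drop = FALSE] - ca_of)^2))
                  <= 2.5 + 1e-9))
  # every residue has exactly one CA
  expect_true(all(tapply(topo$atoms$role == "CA", topo$atoms$residue, sum) == 1))
})

test_that("identity covariance draw matches its moments at n = 20,000", {
  topo <- make_toy_topology(6, seed = 2)
  spec <- ensemble_spec(20000, covariance = "block", seed = 5)
  ens <- sample_gaussian_ensemble(topo, spec)
  x <- ens$coords[, which(topo$atoms$role == "CA"), , drop = FALSE]
  v <- apply(x, c(2, 3), stats::var)
  expect_true(all(abs(v - 1) < 0.03))
  # Frobenius relative error of the empirical CA covariance vs planted
  flat <- matrix(0, 20000, 18)
  for (a in 1:3) flat[, seq(a, 18, by = 3)] <- x[, , a]
  emp <- stats::cov(flat)
  expect_lt(norm(emp - diag(18), "F") / norm(diag(18), "F"), 0.05)
})

test_that("planted per-axis correlation and temperature scaling are recovered", {
  topo <- make_toy_topology(5, seed = 2)
  spec <- ensemble_spec(20000, covariance = "block",
                        planted_pairs = data.frame(i = 1, j = 4, rho = 0.8),
                        seed = 9)
  ens <- sample_gaussian_ensemble(topo, spec)
  ca <- which(topo$atoms$role == "CA")
  for (a in 1:3) {
    r <- stats::cor(ens$coords[, ca[1], a], ens$coords[, ca[4], a])
    expect_lt(abs(r - 0.8), 0.02)
  }
  spec2 <- ensemble_spec(20000, covariance = "block", temperature_scale = 2,
                         seed = 9)
  ens2 <- sample_gaussian_ensemble(topo, spec2)
  v1 <- stats::var(sample_gaussian_ensemble(
    topo, ensemble_spec(20000, seed = 9))$coords[, ca[1], 1])
  v2 <- stats::var(ens2$coords[, ca[1], 1])
  expect_lt(abs(v2 / v1 - 2), 0.1)
})

test_that("elastic-network covariance is PSD and distance-structured", {
  topo <- make_toy_topology(12, seed = 4)
  spec <- ensemble_spec(500, covariance = "elastic_network", seed = 1)
  ens <- sample_gaussian_ensemble(topo, spec)
  expect_identical(dim(ens$coords), c(500L, nrow(topo$atoms), 3L))
  expect_true(all(is.finite(ens$coords)))
})

test_that("non-PSD custom covariance is rejected naming the eigenvalue", {
  topo <- make_toy_topology(2, seed = 1)
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 2  # eigenvalue -1
  expect_error(
    sample_gaussian_ensemble(topo, ensemble_spec(100, covariance = "custom",
                                                 sigma = bad)),
    "positive semi-definite.*-1", ignore.case = TRUE)
})

test_that("two-state pair: empty perturbation shares the distribution", {
  topo <- make_toy_topology(6, seed = 3)
  base <- ensemble_spec(300, covariance = "block", seed = 11)
  pair <- make_two_state_pair(topo, base)
  expect_identical(nrow(pair$ground_truth), 0L)
  expect_identical(pair$A$topology$xyz, pair$B$topology$xyz)
  # same generating distribution, different seeds: matching variances
  va <- stats::var(as.vector(pair$A$coords - rep(topo$xyz,
                                                 each = 300)))
  vb <- stats::var(as.vector(pair$B$coords - rep(topo$xyz, each = 300)))
  expect_lt(abs(va - vb), 0.15)
})

test_that("two-state pair: every planted perturbation gets one truth record", {
  topo <- make_toy_topology(10, seed = 6)
  base <- ensemble_spec(200, covariance = "block", seed = 2)
  pair <- make_two_state_pair(
    topo, base,
    delta_rho = data.frame(i = c(3, 2), j = c(9, 7), delta = c(0.5, 0.3)),
    contact_shift = data.frame(i = 4, j = 8, distance = 4.5))
  gt <- pair$ground_truth
  expect_identical(nrow(gt), 3L)
  expect_identical(sum(gt$kind == "coupling"), 2L)
  expect_identical(sum(gt$kind == "contact"), 1L)
  expect_error(
    make_two_state_pair(topo, base,
                        delta_rho = data.frame(i = 3, j = 99, delta = 0.2)),
    "unknown residue pair")
})

test_that("planted coupling increase drives positive downstream dEC", {
  topo <- make_toy_topology(10, seed = 6)
  base <- ensemble_spec(20000, covariance = "block", seed = 2)
  pair <- make_two_state_pair(
    topo, base, delta_rho = data.frame(i = 3, j = 9, delta = 0.5))
  ec_a <- eigenvector_centrality(build_network(pair$A))
  ec_b <- eigenvector_centrality(build_network(pair$B))
  d <- centrality_difference(ec_a, ec_b)$delta
  expect_gt(d[[3]], 0)
  expect_gt(d[[9]], 0)
  # the perturbed residues rank first in dEC
  expect_setequal(order(-d)[1:2], c(3L, 9L))
})

test_that("planted contact shift drives positive downstream dw", {
  topo <- contact_line_topology(6)
  base <- ensemble_spec(2000, covariance = "block", base_variance = 0.25,
                        seed = 8)
  pair <- make_two_state_pair(
    topo, base, contact_shift = data.frame(i = 2, j = 5, distance = 4.0))
  w_a <- count_contacts(pair$A)$w
  w_b <- count_contacts(pair$B)$w
  expect_equal(w_a[2, 5], 0, ignore_attr = TRUE)
  expect_gt(w_b[2, 5] - w_a[2, 5], 6)
})

test_that("shift tables realize their planted temperature profiles", {
  temps <- seq(293, 323, by = 6)
  sp <- shift_spec("fA1", temps, intercept = 8.2, slope = -4, quad = 0,
                   noise_sd = 0)
  tab <- make_shift_table(sp)
  fit <- stats::lm(shift_ppm ~ temperature_K, data = tab)
  expect_equal(unname(stats::coef(fit)[2]) * 1000, -4, tolerance = 1e-10)

  spq <- shift_spec("fA1", temps, slope = -4, quad = 0.2, noise_sd = 0)
  tq <- make_shift_table(spq)
  tc <- tq$temperature_K - mean(tq$temperature_K)
  rss_lin <- sum(resid(stats::lm(tq$shift_ppm ~ tc))^2)
  rss_quad <- sum(resid(stats::lm(tq$shift_ppm ~ tc + I(tc^2)))^2)
  expect_lt(rss_quad, rss_lin)

  spn <- shift_spec("fA1", temps, noise_sd = 0.002, seed = 42)
  expect_identical(make_shift_table(spn), make_shift_table(spn))
  expect_error(shift_spec("fA1", c(293, 293, 300)), "duplicate temperature")
})
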