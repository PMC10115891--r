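test_that("temperature coefficient matches the printed two-point example", {
  tab <- data.frame(residue = "fL63", nucleus = "HN",
                    temperature_K = c(292.92, 302.73),
                    shift_ppm = c(8.1000, 8.0608),
                    source = "experimental")
  tc <- temperature_coefficient(tab, "fL63", window = c(292.92, 302.73))
  expect_equal(tc, (8.0608 - 8.1000) / (302.73 - 292.92) * 1000,
               tolerance = 1e-12)
  expect_equal(round(tc, 3), -3.996)
})

test_that("slopes are exact on planted lines and zero on constants", {
  temps <- c(293, 298, 303, 308)
  tab <- make_shift_table(shift_spec("fA1", temps, slope = -4, noise_sd = 0))
  expect_equal(temperature_coefficient(tab, "fA1"), -4, tolerance = 1e-10)

  flat <- make_shift_table(shift_spec("fA1", temps, slope = 0, noise_sd = 0))
  expect_equal(temperature_coefficient(flat, "fA1"), 0, tolerance = 1e-12)

  # two-point and least-squares slope coincide at n = 2
  two <- tab[tab$temperature_K %in% temps[1:2], ]
  expect_equal(temperature_coefficient(two, "fA1"),
               temperature_coefficient(tab, "fA1", window = c(293, 298)),
               tolerance = 1e-10)
  expect_error(temperature_coefficient(two[1, ], "fA1"), "fewer than 2")
})

test_that("slope estimates are offset- and unit-equivariant", {
  temps <- seq(293, 323, by = 5)
  tab <- make_shift_table(shift_spec("fA1", temps, slope = -4.7,
                                     quad = 0.03, noise_sd = 0.001,
                                     seed = 5))
  base <- temperature_coefficient(tab, "fA1")
  shifted <- tab; shifted$shift_ppm <- shifted$shift_ppm + 2.5
  expect_equal(temperature_coefficient(shifted, "fA1"), base,
               tolerance = 1e-10)
  celsius <- tab; celsius$temperature_K <- celsius$temperature_K - 273.15
  expect_equal(
    temperature_coefficient(celsius, "fA1", window = c(-Inf, Inf)), base,
    tolerance = 1e-8)
})

test_that("curvature F-test flags exact quadratics and respects df limits", {
  temps <- seq(293, 323, length.out = 6)
  quad_tab <- make_shift_table(shift_spec("fA1", temps, slope = -4,
                                          quad = 0.05, noise_sd = 0))
  res <- curvature_test(quad_tab, "fA1")
  expect_lt(res$p, 1e-10)
  expect_true(res$curvature)

  lin_tab <- make_shift_table(shift_spec("fA1", temps, slope = -4,
                                         noise_sd = 0))
  res_l <- curvature_test(lin_tab, "fA1")
  expect_equal(res_l$p, 1)
  expect_false(res_l$curvature)

  three <- make_shift_table(shift_spec("fA1", temps[1:3], noise_sd = 0))
  expect_error(curvature_test(three, "fA1"), ">= 4")
})

test_that("F statistic agrees with R's own nested-model anova", {
  temps <- seq(292.92, 322.41, length.out = 8)
  tab <- make_shift_table(shift_spec("fA1", temps, slope = -4, quad = 0.01,
                                     noise_sd = 0.005, seed = 31))
  res <- curvature_test(tab, "fA1")
  tc <- tab$temperature_K - mean(tab$temperature_K)
  a <- stats::anova(stats::lm(tab$shift_ppm ~ tc),
                    stats::lm(tab$shift_ppm ~ tc + I(tc^2)))
  expect_equal(res$F, a$F[2], tolerance = 1e-10)
  expect_equal(res$p, a$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$n, 8L, ignore_attr = TRUE)
})

test_that("window slopes populate the 30C/50C comparison fields", {
  temps <- c(292.92, 297.5, 302.73, 307.62, 315, 322.41)
  tab <- make_shift_table(shift_spec("fA1", temps, slope = -3, quad = 0.08,
                                     noise_sd = 0))
  res <- curvature_test(tab, "fA1")
  expect_false(is.na(res$slope_30))
  expect_false(is.na(res$slope_50))
  # convex profile: later window has the larger (more positive) slope
  expect_gt(res$slope_50, res$slope_30)
  expect_equal(res$delta_slope, abs(res$slope_50 - res$slope_30),
               tolerance = 1e-12)
})

test_that("shift agreement recovers trivial and planted correlations", {
  set.seed(77)
  res_labels <- paste0("f", LETTERS[1:6], 1:6)
  mk_tab <- function(vals, src) {
    data.frame(residue = res_labels, nucleus = "CA",
               temperature_K = 303, shift_ppm = vals, source = src)
  }
  vals <- rnorm(6, 58, 2)
  expect_equal(shift_agreement(mk_tab(vals, "computed"),
                               mk_tab(vals, "experimental"))$r, 1)
  centered <- vals - mean(vals)
  expect_equal(shift_agreement(mk_tab(centered, "computed"),
                               mk_tab(-centered, "experimental"))$r, -1)

  # attenuation oracle: computed = experimental + noise tuned for rho = 0.9
  set.seed(78)
  n <- 150
  labs <- paste0("f", rep(LETTERS[1:25], 6), 1:150)
  exp_v <- rnorm(n, 58, 2)
  sd_noise <- 2 * sqrt(1 / 0.81 - 1)
  comp_v <- exp_v + rnorm(n, sd = sd_noise)
  big <- shift_agreement(
    data.frame(residue = labs, nucleus = "CA", temperature_K = 303,
               shift_ppm = comp_v, source = "computed"),
    data.frame(residue = labs, nucleus = "CA", temperature_K = 303,
               shift_ppm = exp_v, source = "experimental"))
  expect_lt(abs(big$r - 0.9), 0.05)
  expect_identical(big$n, 150L)

  # unmatched residues are listed, not silently dropped
  partial <- shift_agreement(mk_tab(vals, "computed")[1:5, ],
                             mk_tab(vals, "experimental")[2:6, ])
  expect_setequal(partial$unmatched, c(res_labels[1], res_labels[6]))
  expect_error(
    shift_agreement(mk_tab(vals, "computed")[1:2, ],
                    mk_tab(vals, "experimental")[1:2, ]),
    "fewer than 3")
})

test_that("ensemble averaging matches arithmetic and planted spread", {
  f1 <- data.frame(residue = "fA1", nucleus = "CA", temperature_K = NA,
                   shift_ppm = 8.0, source = "computed")
  f2 <- f1; f2$shift_ppm <- 8.2
  avg <- ensemble_average_shifts(list(f1, f2))
  expect_equal(avg$shift_ppm, 8.1)
  expect_identical(avg$n_frames, 2L)

  same <- ensemble_average_shifts(list(f1, f1, f1))
  expect_equal(same$shift_ppm, 8.0)
  expect_equal(same$sd_ppm, 0)

  set.seed(99)
  spread <- rnorm(10000, 120, 0.4)
  frames <- lapply(spread, function(v) {
    data.frame(residue = "hG2", nucleus = "N", temperature_K = NA,
               shift_ppm = v, source = "computed")
  })
  big <- ensemble_average_shifts(frames)
  expect_lt(abs(big$sd_ppm - 0.4) / 0.4, 0.05)
  expect_error(ensemble_average_shifts(list()), "no per-frame")
})
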