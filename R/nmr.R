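#' Amide temperature coefficient over a temperature window
#'
#' Slope of the chemical shift vs temperature in ppb/K within an inclusive
#' window: with exactly two in-window points the two-point difference
#' quotient (delta_T2 - delta_T1)/(T2 - T1); with more, the least-squares
#' slope (the two coincide at n = 2). Negative values mean the shift moves
#' upfield on heating, the typical behaviour; a positive coefficient
#' flags a protected, hydrogen-bonded amide.
#'
#' @param table a shift table (see [make_shift_table()]).
#' @param residue residue label.
#' @param nucleus nucleus (default `"HN"`).
#' @param window `c(T_low, T_high)` in K, endpoints included.
#' @return slope in ppb/K.
#' @export
temperature_coefficient <- function(table, residue, nucleus = "HN",
                                    window = c(-Inf, Inf)) {
  rows <- table$residue == residue & table$nucleus == nucleus &
    table$temperature_K >= window[1] & table$temperature_K <= window[2]
  tt <- table$temperature_K[rows]; dd <- table$shift_ppm[rows]
  if (length(tt) < 2L) {
    stop("fewer than 2 in-window points for ", residue, call. = FALSE)
  }
  o <- order(tt); tt <- tt[o]; dd <- dd[o]
  slope_ppm <- if (length(tt) == 2L) diff(dd) / diff(tt) else
    stats::cov(tt, dd) / stats::var(tt)
  slope_ppm * 1000
}

# The two printed windows flanking 30 C and 50 C used for coefficient
# comparison (K).
TEMPCO_WINDOW_30 <- c(292.92, 302.73)
TEMPCO_WINDOW_50 <- c(307.62, 322.41)

#' Curvature classification of a shift-vs-temperature profile
#'
#' Extra-sum-of-squares F-test comparing a linear fit (null) against a
#' quadratic fit of shift vs temperature:
#' F = ((RSS_lin - RSS_quad)/1) / (RSS_quad/(n - 3)), p from F(1, n - 3);
#' residues with p below `alpha` are flagged as displaying curvature
#' (non-linear temperature response, an indicator of conformational
#' change). Temperatures are centered before the quadratic fit for
#' conditioning. Also reports the temperature coefficients in the windows
#' around 30 C and 50 C and their absolute difference.
#'
#' @param table a shift table.
#' @param residue residue label.
#' @param nucleus nucleus.
#' @param alpha significance level.
#' @param window_low,window_high temperature windows (K) for the two local
#'   coefficients; set to `NULL` to skip.
#' @return Object of class `tempco_result`: `residue`, `slope_30`,
#'   `slope_50`, `delta_slope` (absolute), `F`, `p`, `curvature`, `n`.
#' @export
curvature_test <- function(table, residue, nucleus = "HN", alpha = 0.05,
                           window_low = TEMPCO_WINDOW_30,
                           window_high = TEMPCO_WINDOW_50) {
  rows <- table$residue == residue & table$nucleus == nucleus
  tt <- table$temperature_K[rows]; dd <- table$shift_ppm[rows]
  n <- length(tt)
  if (n < 4L) {
    stop("need >= 4 temperatures for the curvature F-test", call. = FALSE)
  }
  tc <- tt - mean(tt)
  fit_lin <- stats::lm(dd ~ tc)
  fit_quad <- stats::lm(dd ~ tc + I(tc^2))
  rss_lin <- sum(resid(fit_lin)^2)
  rss_quad <- sum(resid(fit_quad)^2)
  if (rss_quad <= .Machine$double.eps * sum(dd^2)) {
    if (rss_lin <= .Machine$double.eps * sum(dd^2)) {
      f <- 0; p <- 1  # both fits perfect: no evidence of curvature
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (rss_lin - rss_quad) / (rss_quad / (n - 3))
    p <- stats::pf(f, 1, n - 3, lower.tail = FALSE)
  }
  slope_l <- if (!is.null(window_low) &&
                 sum(tt >= window_low[1] & tt <= window_low[2]) >= 2)
    temperature_coefficient(table, residue, nucleus, window_low) else NA_real_
  slope_h <- if (!is.null(window_high) &&
                 sum(tt >= window_high[1] & tt <= window_high[2]) >= 2)
    temperature_coefficient(table, residue, nucleus, window_high) else NA_real_
  structure(list(residue = residue, nucleus = nucleus,
                 slope_30 = slope_l, slope_50 = slope_h,
                 delta_slope = abs(slope_h - slope_l),
                 F = f, p = p, curvature = p < alpha, alpha = alpha, n = n),
            class = "tempco_result")
}

#' @export
print.tempco_result <- function(x, ...) {
  cat(sprintf(
    "%s (%s): slope30 = %.2f, slope50 = %.2f ppb/K, F = %.3g, p = %.3g%s\n",
    x$residue, x$nucleus, x$slope_30, x$slope_50, x$F, x$p,
    if (isTRUE(x$curvature)) " [curvature]" else ""))
  invisible(x)
}

#' Agreement between computed and experimental chemical shifts
#'
#' Pearson correlation over residues matched by (residue, nucleus) between
#' a computed (ensemble-averaged) and an experimental shift table at the
#' same nominal condition; residues present in only one table are listed
#' as unmatched (e.g. resonances that are hard to assign experimentally).
#'
#' @param computed,experimental shift tables.
#' @param nucleus nucleus to compare.
#' @return list: `r` (Pearson), `n` matched, `residuals` (named
#'   computed - experimental), `unmatched`.
#' @export
shift_agreement <- function(computed, experimental, nucleus = "CA") {
  cc <- computed[computed$nucleus == nucleus, ]
  ee <- experimental[experimental$nucleus == nucleus, ]
  cm <- tapply(cc$shift_ppm, cc$residue, mean)
  em <- tapply(ee$shift_ppm, ee$residue, mean)
  shared <- intersect(names(cm), names(em))
  if (length(shared) < 3L) {
    stop("fewer than 3 matched residues for ", nucleus, call. = FALSE)
  }
  r <- stats::cor(cm[shared], em[shared])
  list(r = unname(r), n = length(shared),
       residuals = setNames(as.numeric(cm[shared] - em[shared]), shared),
       unmatched = setdiff(union(names(cm), names(em)), shared))
}

#' Ensemble-average per-frame predicted shifts
#'
#' Arithmetic mean per (residue, nucleus) over per-frame shift tables (the
#' output of a per-structure shift predictor applied to every frame), with
#' the frame count and between-frame sd recorded.
#'
#' @param frame_tables list of shift tables, one per frame, sharing the
#'   same (residue, nucleus) universe.
#' @return A computed shift table with extra columns `sd_ppm`, `n_frames`.
#' @export
ensemble_average_shifts <- function(frame_tables) {
  if (!length(frame_tables)) stop("no per-frame tables given", call. = FALSE)
  all <- do.call(rbind, frame_tables)
  key <- paste(all$residue, all$nucleus, sep = "|")
  mu <- tapply(all$shift_ppm, key, mean)
  s <- tapply(all$shift_ppm, key, stats::sd)
  n <- tapply(all$shift_ppm, key, length)
  parts <- strsplit(names(mu), "|", fixed = TRUE)
  out <- data.frame(
    residue = vapply(parts, `[`, "", 1L),
    nucleus = vapply(parts, `[`, "", 2L),
    temperature_K = NA_real_,
    shift_ppm = as.numeric(mu),
    source = "computed",
    sd_ppm = as.numeric(s),
    n_frames = as.integer(n),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
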