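#' Specification of a planted temperature-series chemical-shift table
#'
#' Emulates an HSQC temperature series: per residue, the amide shift follows
#' delta(T) = intercept + slope * (T - T_ref)/1000 + quad * (T - T_ref)^2/1000
#' + noise, with `slope` in ppb/K and `quad` in ppb/K^2 (T_ref is the lowest
#' temperature of the series).
#'
#' @param residues character vector of residue labels (e.g. `"fL63"`).
#' @param temperatures strictly increasing temperatures in K (>= 2 values;
#'   a realistic series spans ~293-323 K at >= 4 points).
#' @param intercept per-residue intercept (ppm); recycled.
#' @param slope per-residue linear coefficient (ppb/K); recycled.
#' @param quad per-residue quadratic coefficient (ppb/K^2); recycled.
#' @param noise_sd Gaussian noise sd (ppm).
#' @param nucleus nucleus label for all rows.
#' @param seed integer seed.
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(residues, temperatures, intercept = 8.2, slope = -4,
                       quad = 0, noise_sd = 0, nucleus = "HN", seed = 1L) {
  if (anyDuplicated(temperatures)) {
    stop("duplicate temperature in series", call. = FALSE)
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(temperatures) >= 2, noise_sd >= 0, all(temperatures > 0))
  structure(list(residues = residues, temperatures = temperatures,
                 intercept = rep_len(intercept, length(residues)),
                 slope = rep_len(slope, length(residues)),
                 quad = rep_len(quad, length(residues)),
                 noise_sd = noise_sd, nucleus = nucleus,
                 seed = as.integer(seed)),
            class = "shift_spec")
}

#' Generate a chemical-shift table with planted temperature profiles
#'
#' @param spec a [shift_spec()].
#' @param source value for the `source` column (`"experimental"` or
#'   `"computed"`).
#' @return A shift table: data.frame with columns `residue`, `nucleus`,
#'   `temperature_K`, `shift_ppm`, `source`; deterministic under the spec's
#'   seed.
#' @export
make_shift_table <- function(spec, source = "experimental") {
  stopifnot(inherits(spec, "shift_spec"))
  t_ref <- min(spec$temperatures)
  grid <- expand.grid(ri = seq_along(spec$residues),
                      ti = seq_along(spec$temperatures))
  dt <- spec$temperatures[grid$ti] - t_ref
  shift <- spec$intercept[grid$ri] +
    spec$slope[grid$ri] * dt / 1000 +
    spec$quad[grid$ri] * dt^2 / 1000
  noise <- with_seed(spec$seed,
                     rnorm(nrow(grid), sd = spec$noise_sd))
  data.frame(residue = spec$residues[grid$ri],
             nucleus = spec$nucleus,
             temperature_K = spec$temperatures[grid$ti],
             shift_ppm = shift + noise,
             source = source,
             stringsAsFactors = FALSE)
}
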