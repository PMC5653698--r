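#' Refractive-index / buoyant-density conversion constants
#'
#' The buoyant density \eqn{\rho} of a CsCl gradient fraction is obtained from
#' its refractive index \eqn{\eta} by the linear calibration
#' \eqn{\rho = a \eta - b}. The default constants (a = 10.9276, b = 13.593)
#' are the standard CsCl calibration at 20 degrees C; they are temperature
#' specific, so the temperature is carried along and callers working at other
#' temperatures must supply their own constants.
#'
#' @param a Unitless multiplier; must be positive.
#' @param b Unitless offset.
#' @param temperature_C Temperature (degrees C) at which the constants are
#'   valid. Default 20.
#' @return An object of class `conversion_constants`.
#' @examples
#' conversion_constants()
#' @export
conversion_constants <- function(a = 10.9276, b = 13.593, temperature_C = 20) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) {
    abort("`a` must be a positive finite number.", class = "siptrflp_error_input")
  }
  structure(
    list(a = a, b = b, temperature_C = temperature_C),
    class = "conversion_constants"
  )
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat(sprintf(
    "<conversion_constants> rho = %.4f * eta - %.3f (valid at %g degC)\n",
    x$a, x$b, x$temperature_C
  ))
  invisible(x)
}

#' Convert refractive index to buoyant density
#'
#' Applies \eqn{\rho = a \eta - b}. Refractive indices of CsCl SIP gradients
#' fall in a narrow window around 1.40; values outside `[1.20, 1.50]` are
#' rejected as readout errors.
#'
#' @param eta Numeric vector of refractive indices (unitless).
#' @param constants A [conversion_constants()] object.
#' @return Numeric vector of buoyant densities (g/cm^3).
#' @examples
#' density_from_ri(1.4)
#' @seealso [ri_from_density()] for the exact inverse.
#' @export
density_from_ri <- function(eta, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"), is.numeric(eta))
  bad <- eta[!is.na(eta) & (eta < 1.20 | eta > 1.50)]
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Refractive index out of range [1.20, 1.50]: %s",
        paste(format(bad[seq_len(min(5, length(bad)))]), collapse = ", ")
      ),
      class = "siptrflp_error_range"
    )
  }
  constants$a * eta - constants$b
}

#' Convert buoyant density to refractive index
#'
#' Exact inverse of [density_from_ri()]; used as the forward model by the
#' gradient simulator. Densities are restricted to the plausible CsCl DNA
#' window `[1.60, 1.85]` g/cm^3.
#'
#' @param rho Numeric vector of buoyant densities (g/cm^3).
#' @inheritParams density_from_ri
#' @return Numeric vector of refractive indices.
#' @examples
#' ri_from_density(1.70564)
#' @export
ri_from_density <- function(rho, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"), is.numeric(rho))
  bad <- rho[!is.na(rho) & (rho < 1.60 | rho > 1.85)]
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Buoyant density out of range [1.60, 1.85] g/cm^3: %s",
        paste(format(bad[seq_len(min(5, length(bad)))]), collapse = ", ")
      ),
      class = "siptrflp_error_range"
    )
  }
  (rho + constants$b) / constants$a
}

#' Validate a table of gradient fractions
#'
#' Checks a fraction table (one or more conditions) for structural validity,
#' computes buoyant densities from refractive indices where the density column
#' is absent or `NA`, and orders fractions heaviest first within each
#' condition. Fraction index 1 is the heaviest fraction (collected first from
#' the tube bottom), so density is expected to be non-increasing in index;
#' violations are reported as a warning, not an error, because real gradients
#' carry refractometer noise.
#'
#' @param fractions A data frame with columns `condition`, `fraction_index`,
#'   `refractive_index` and/or `buoyant_density`, and optionally
#'   `total_16S_copies` (copies/mL, non-negative).
#' @inheritParams density_from_ri
#' @return A tibble with `buoyant_density` filled in, sorted by condition and
#'   descending density.
#' @examples
#' f <- tibble::tibble(
#'   condition = "U", fraction_index = 1:3,
#'   refractive_index = c(1.404, 1.402, 1.400),
#'   total_16S_copies = c(1e5, 5e6, 2e6)
#' )
#' validate_fractions(f)
#' @export
validate_fractions <- function(fractions, constants = conversion_constants()) {
  fractions <- as_tibble(fractions)
  need <- c("condition", "fraction_index")
  missing_cols <- setdiff(need, names(fractions))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Fraction table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "siptrflp_error_schema"
    )
  }
  if (!("refractive_index" %in% names(fractions)) &&
      !("buoyant_density" %in% names(fractions))) {
    abort(
      "Fraction table needs `refractive_index` and/or `buoyant_density`.",
      class = "siptrflp_error_schema"
    )
  }
  if (!("buoyant_density" %in% names(fractions))) {
    fractions$buoyant_density <- NA_real_
  }
  dup <- fractions |>
    dplyr::count(.data$condition, .data$fraction_index) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      sprintf(
        "Duplicate fraction indices within condition(s): %s",
        paste(unique(dup$condition), collapse = ", ")
      ),
      class = "siptrflp_error_validation"
    )
  }
  n_per <- fractions |> dplyr::count(.data$condition)
  if (any(n_per$n < 3)) {
    abort("Each condition needs at least 3 fractions.", class = "siptrflp_error_validation")
  }
  fill <- is.na(fractions$buoyant_density)
  if (any(fill)) {
    fractions$buoyant_density[fill] <-
      density_from_ri(fractions$refractive_index[fill], constants)
  }
  out_of_range <- !is.na(fractions$buoyant_density) &
    (fractions$buoyant_density < 1.60 | fractions$buoyant_density > 1.85)
  if (any(out_of_range)) {
    abort(
      sprintf(
        "Buoyant density out of range [1.60, 1.85]: %s",
        paste(format(fractions$buoyant_density[out_of_range]), collapse = ", ")
      ),
      class = "siptrflp_error_range"
    )
  }
  if ("total_16S_copies" %in% names(fractions)) {
    if (any(fractions$total_16S_copies < 0, na.rm = TRUE)) {
      abort("`total_16S_copies` must be non-negative.", class = "siptrflp_error_validation")
    }
  }
  # density should fall with fraction index (index 1 = bottom = heaviest)
  non_mono <- fractions |>
    group_by(.data$condition) |>
    arrange(.data$fraction_index, .by_group = TRUE) |>
    summarise(bad = any(diff(.data$buoyant_density) > 1e-12), .groups = "drop") |>
    filter(.data$bad)
  if (nrow(non_mono) > 0) {
    warn(
      sprintf(
        "Non-monotone buoyant density vs fraction index in condition(s): %s (kept; re-sorted by density)",
        paste(non_mono$condition, collapse = ", ")
      ),
      class = "siptrflp_warning_nonmonotone"
    )
  }
  fractions |>
    arrange(.data$condition, desc(.data$buoyant_density), .data$fraction_index)
}
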