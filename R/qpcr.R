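#' Fit a qPCR calibration (standard) curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 template
#' copies over a serial dilution series, as used to quantify total bacterial
#' 16S rRNA gene copies per gradient fraction. Amplification efficiency is
#' derived from the slope as \eqn{E = 10^{-1/slope} - 1} (a slope of -3.3219
#' corresponds to perfect doubling, E = 1).
#'
#' @param dilutions Data frame with columns `copies` (> 0) and `cq`; at least
#'   3 distinct dilution levels are required. Replicate wells at the same
#'   copy number are allowed and enter the fit individually.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `n_levels`, and the fitted data.
#' @examples
#' d <- tibble::tibble(copies = 10^(3:5), cq = c(30, 26.68, 23.36))
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(dilutions) {
  dilutions <- as_tibble(dilutions)
  stopifnot(all(c("copies", "cq") %in% names(dilutions)))
  if (any(!is.finite(dilutions$cq)) || any(!is.finite(dilutions$copies)) ||
      any(dilutions$copies <= 0)) {
    abort("`copies` must be positive and `cq` finite.",
          class = "siptrflp_error_input")
  }
  if (length(unique(dilutions$copies)) < 3) {
    abort("At least 3 distinct dilution levels are required.",
          class = "siptrflp_error_input")
  }
  fit <- lm(cq ~ log10(copies), data = dilutions)
  slope <- unname(coef(fit)[2])
  # suppressWarnings: summary.lm warns on exactly collinear (perfect) fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope >= 0) {
    abort("Calibration slope must be negative (Cq falls with template).",
          class = "siptrflp_error_invalid_curve")
  }
  if (r2 < 0.98) {
    warn(sprintf("Calibration r^2 = %.4f < 0.98; curve quality is poor.", r2),
         class = "siptrflp_warning_curve_quality")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      efficiency = 10^(-1 / slope) - 1,
      r_squared = r2,
      n_levels = length(unique(dilutions$copies)),
      data = dilutions
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.4f + %.4f * log10(copies)\n  efficiency %.3f, r^2 %.4f, %d dilution levels\n",
    x$intercept, x$slope, x$efficiency, x$r_squared, x$n_levels
  ))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    efficiency = x$efficiency, r.squared = x$r_squared,
    n_levels = x$n_levels
  )
}

#' Absolute copy number from a Cq value
#'
#' Inverts the calibration line: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param cq Numeric vector of quantification cycles.
#' @param curve A [fit_standard_curve()] object, or any list with `slope` and
#'   `intercept`.
#' @return Numeric vector of template copies.
#' @examples
#' curve <- fit_standard_curve(
#'   tibble::tibble(copies = 10^(3:5), cq = c(30, 26.68, 23.36))
#' )
#' copies_from_cq(26.68, curve)
#' @export
copies_from_cq <- function(cq, curve) {
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    abort("Invalid calibration curve: slope must be negative.",
          class = "siptrflp_error_invalid_curve")
  }
  if (any(!is.finite(cq))) {
    abort("`cq` must be finite.", class = "siptrflp_error_input")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Autoplot a qPCR standard curve
#'
#' @param object A `standard_curve` object.
#' @param ... Unused.
#' @return A ggplot: Cq against log10 copies with the fitted line.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10(.data$copies), y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(
      x = "log10(16S copies)", y = "Cq",
      title = sprintf("Standard curve: slope %.3f, efficiency %.2f",
                      object$slope, object$efficiency)
    ) +
    ggplot2::theme_minimal()
}
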