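#' Default VOC degradation kinetics
#'
#' Lag-plus-first-order kinetics for the three co-injected VOCs, each
#' starting at 30 mg/L: concentration stays at the initial value until
#' `lag_days`, then decays as `initial * exp(-k * (t - lag))`. The default
#' lags are sequential (DCM, then benzene, then toluene) and the rates are
#' chosen so that, sampled daily, each compound reaches the 50-80% degraded
#' window on the day the corresponding culture would be harvested (days 4, 6
#' and 7).
#'
#' @param compound Compound names.
#' @param initial_mg_L Initial concentrations (mg/L).
#' @param lag_days Lag before first-order decay starts (days).
#' @param rate_per_day First-order rate constants k (1/day) after the lag.
#' @return Tibble `compound`, `initial_mg_L`, `lag_days`, `rate_per_day`.
#' @export
degradation_kinetics <- function(compound = c("DCM", "benzene", "toluene"),
                                 initial_mg_L = 30,
                                 lag_days = c(2.5, 4.5, 6.0),
                                 rate_per_day = c(0.95, 0.95, 0.72)) {
  out <- tibble(compound = compound,
                initial_mg_L = initial_mg_L,
                lag_days = lag_days,
                rate_per_day = rate_per_day)
  if (any(out$initial_mg_L < 0) || any(out$lag_days < 0) ||
      any(out$rate_per_day < 0)) {
    abort("Kinetic parameters must be non-negative.", class = "siptrflp_error_input")
  }
  out
}

#' Simulate VOC degradation time series
#'
#' Deterministic lag + first-order decay per compound (see
#' [degradation_kinetics()]).
#'
#' @param kinetics Kinetics tibble.
#' @param times Sampling times in days, ascending, starting at 0.
#' @return Tibble `compound`, `day`, `concentration` (mg/L).
#' @examples
#' simulate_degradation(times = 0:11)
#' @export
simulate_degradation <- function(kinetics = degradation_kinetics(),
                                 times = 0:11) {
  if (any(times < 0)) {
    abort("`times` must be non-negative.", class = "siptrflp_error_input")
  }
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0) {
    abort("`times` must be strictly ascending and start at 0.",
          class = "siptrflp_error_input")
  }
  tidyr::expand_grid(kinetics, day = times) |>
    mutate(concentration = dplyr::if_else(
      .data$day < .data$lag_days,
      .data$initial_mg_L,
      .data$initial_mg_L * exp(-.data$rate_per_day * (.data$day - .data$lag_days))
    )) |>
    select("compound", "day", "concentration")
}

#' Maximum interval degradation rate
#'
#' Maximum, over consecutive sampling points, of
#' `(C(t_i) - C(t_{i+1})) / (t_{i+1} - t_i)` -- the reporting convention for
#' "maximum rate of degradation" between two sampling days. For a series
#' that only increases, the (negative) maximum is returned with a warning.
#'
#' @param series Tibble `day`, `concentration`, optionally `compound` (rates
#'   are computed per compound).
#' @return Tibble (`compound`,) `max_rate_mg_L_day`, `interval_start`,
#'   `interval_end`.
#' @examples
#' s <- tibble::tibble(day = 0:4, concentration = c(30, 30, 30, 30, 18.1))
#' max_interval_rate(s) # 11.9 between days 3 and 4
#' @export
max_interval_rate <- function(series) {
  series <- as_tibble(series)
  if (!("compound" %in% names(series))) series$compound <- "compound"
  one <- function(df) {
    df <- df |> arrange(.data$day)
    if (nrow(df) < 2) {
      abort("At least two time points are required.", class = "siptrflp_error_input")
    }
    rate <- -diff(df$concentration) / diff(df$day)
    i <- which.max(rate)
    if (rate[i] < 0) {
      warn("Concentrations only increase; maximum interval rate is negative.",
           class = "siptrflp_warning_degenerate")
    }
    tibble(max_rate_mg_L_day = rate[i],
           interval_start = df$day[i], interval_end = df$day[i + 1])
  }
  series |>
    group_by(.data$compound) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' First sampling day within a target degraded-fraction window
#'
#' Finds, per compound, the first sampled time (after the initial point) at
#' which the degraded fraction `1 - C/C0` lies inside
#' `[target[1], target[2]]` -- the harvesting rule "sample when 50-80%
#' degraded". If degradation jumps over the window between two samples, the
#' first day beyond it is returned with a warning; if the lower bound is
#' never reached, an error is raised.
#'
#' @param series Tibble `day`, `concentration`, optionally `compound`.
#' @param target Two-element degraded-fraction window (default `c(0.5, 0.8)`).
#' @return Tibble (`compound`,) `sampling_day`, `degraded_fraction`.
#' @export
sampling_day <- function(series, target = c(0.5, 0.8)) {
  stopifnot(length(target) == 2, target[1] < target[2])
  series <- as_tibble(series)
  if (!("compound" %in% names(series))) series$compound <- "compound"
  one <- function(df) {
    df <- df |> arrange(.data$day)
    f <- 1 - df$concentration / df$concentration[1]
    cand <- setdiff(which(f >= target[1]), 1L)  # the t0 point never qualifies
    if (length(cand) == 0) {
      abort("Degradation never reaches the lower target bound.",
            class = "siptrflp_error_not_reached")
    }
    i <- cand[1]
    if (f[i] > target[2]) {
      warn(sprintf("Degradation skipped the %.0f-%.0f%% window between days %g and %g; reporting the first day beyond it.",
                   100 * target[1], 100 * target[2], df$day[i - 1], df$day[i]),
           class = "siptrflp_warning_window_skipped")
    }
    tibble(sampling_day = df$day[i], degraded_fraction = f[i])
  }
  series |>
    group_by(.data$compound) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Plot VOC degradation time series
#'
#' @param series Tibble from [simulate_degradation()] (or measured data with
#'   the same columns).
#' @param relative Plot `C/C0` instead of absolute concentration.
#' @return A ggplot.
#' @export
plot_degradation <- function(series, relative = TRUE) {
  series <- as_tibble(series)
  if (!("compound" %in% names(series))) series$compound <- "compound"
  if (relative) {
    series <- series |>
      group_by(.data$compound) |>
      arrange(.data$day, .by_group = TRUE) |>
      mutate(y = .data$concentration / first(.data$concentration)) |>
      ungroup()
    ylab <- "Relative concentration C/C0"
  } else {
    series$y <- series$concentration
    ylab <- "Concentration (mg/L)"
  }
  ggplot2::ggplot(series, ggplot2::aes(x = .data$day, y = .data$y,
                                       colour = .data$compound)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Day", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}
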