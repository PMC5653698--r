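#' Per-T-RF absolute copy numbers in one fraction
#'
#' Scales T-RF fluorescence proportions by the fraction's total bacterial 16S
#' copy number: each fragment's copies = proportion x total.
#'
#' @param proportions Tibble from [peak_proportions()] (`length_bp`,
#'   `proportion`, summing to 1 within 1e-6).
#' @param total_copies Total 16S copies/mL in the fraction (>= 0).
#' @return Tibble `length_bp`, `copies`.
#' @examples
#' trf_copy_numbers(
#'   tibble::tibble(length_bp = c(337, 398), proportion = c(0.3, 0.7)), 2e6
#' )
#' @export
trf_copy_numbers <- function(proportions, total_copies) {
  proportions <- as_tibble(proportions)
  stopifnot(all(c("length_bp", "proportion") %in% names(proportions)))
  if (!is.finite(total_copies) || total_copies < 0) {
    abort("`total_copies` must be non-negative.", class = "siptrflp_error_input")
  }
  if (abs(sum(proportions$proportion) - 1) > 1e-6) {
    abort("Proportions must sum to 1 (within 1e-6).", class = "siptrflp_error_input")
  }
  proportions |>
    mutate(copies = .data$proportion * total_copies) |>
    select("length_bp", "copies")
}

#' Normalize a copy-number series by its maximum
#'
#' Divides every value by the series maximum so the largest value is exactly
#' 1, the normalisation used to draw per-fragment buoyant-density
#' distributions.
#'
#' @param x Non-negative numeric vector.
#' @return `x / max(x)`.
#' @examples
#' normalize_by_max(c(2, 4, 8))
#' @export
normalize_by_max <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("Values must be finite and non-negative.", class = "siptrflp_error_input")
  }
  m <- max(x)
  if (m <= 0) {
    abort("All values are zero; a max-normalized distribution is undefined.",
          class = "siptrflp_error_degenerate")
  }
  x / m
}

# Internal constructor for a per-T-RF buoyant-density distribution.
new_trf_distribution <- function(buoyant_density, copies, condition, enzyme,
                                 representative_length_bp,
                                 member_lengths = representative_length_bp) {
  ord <- order(buoyant_density)
  rho_sorted <- buoyant_density[ord]
  copies_sorted <- copies[ord]
  out <- tibble(
    buoyant_density = rho_sorted,
    copies = copies_sorted,
    normalized = normalize_by_max(copies_sorted)
  )
  structure(out,
            class = c("trf_distribution", class(out)),
            condition = condition, enzyme = enzyme,
            representative_length_bp = representative_length_bp,
            member_lengths = member_lengths)
}

#' Construct a T-RF buoyant-density distribution directly
#'
#' Builds a `trf_distribution` from raw per-fraction copy numbers, e.g. when
#' the proportions-times-qPCR arithmetic has been done elsewhere. Points are
#' sorted by density ascending and max-normalized.
#'
#' @param buoyant_density Densities (g/cm^3) of the fractions.
#' @param copies Per-fraction copy numbers (>= 0, not all zero).
#' @param condition Condition label (e.g. "AE/AE-13N").
#' @param enzyme Enzyme name.
#' @param representative_length_bp Representative fragment length of the bin.
#' @param member_lengths Integer vector of member lengths (defaults to the
#'   representative).
#' @return A `trf_distribution` tibble (`buoyant_density`, `copies`,
#'   `normalized`).
#' @export
trf_distribution <- function(buoyant_density, copies, condition = "sample",
                             enzyme = NA_character_,
                             representative_length_bp = NA_integer_,
                             member_lengths = representative_length_bp) {
  stopifnot(length(buoyant_density) == length(copies))
  new_trf_distribution(buoyant_density, copies, condition, enzyme,
                       representative_length_bp, member_lengths)
}

#' Build the buoyant-density distribution of one T-RF bin
#'
#' For every fraction of one condition: sum the fluorescence of peaks whose
#' lengths fall in the bin, convert to a proportion of the fraction's total
#' fluorescence (small peaks removed at the relative floor), multiply by the
#' fraction's qPCR 16S copy number, and finally max-normalize across
#' fractions. Fractions without a matching peak contribute zero.
#'
#' @param fractions Validated fraction table ([validate_fractions()]) for one
#'   condition, with `buoyant_density` and `total_16S_copies`.
#' @param peaks Peak table for the same condition: `fraction_index`, `enzyme`,
#'   `length_bp`, `fluorescence`.
#' @param bin Integer vector of member lengths of the bin (e.g. one bin from
#'   [bin_lengths()]).
#' @param enzyme Enzyme name the bin belongs to.
#' @param floor Relative-fluorescence floor passed to [peak_proportions()].
#' @return A `trf_distribution` tibble.
#' @export
build_distribution <- function(fractions, peaks, bin, enzyme, floor = 0.005) {
  fractions <- as_tibble(fractions)
  peaks <- as_tibble(peaks)
  stopifnot(all(c("fraction_index", "buoyant_density", "total_16S_copies") %in%
                  names(fractions)),
            all(c("fraction_index", "enzyme", "length_bp", "fluorescence") %in%
                  names(peaks)))
  if (length(unique(fractions$condition %||% "x")) > 1) {
    abort("`fractions` must contain a single condition.",
          class = "siptrflp_error_config")
  }
  epeaks <- peaks[peaks$enzyme == enzyme, , drop = FALSE]
  if (nrow(epeaks) == 0) {
    abort(sprintf("No peaks for enzyme '%s' in the peak table.", enzyme),
          class = "siptrflp_error_config")
  }
  bin <- round_lengths(bin)
  lens <- round_lengths(epeaks$length_bp)
  sp <- split(seq_len(nrow(epeaks)), epeaks$fraction_index)
  copies <- vapply(seq_len(nrow(fractions)), function(i) {
    rows <- sp[[as.character(fractions$fraction_index[i])]]
    if (is.null(rows)) return(0)
    # merge co-migrating peaks, apply the relative floor, renormalize
    flu <- rowsum(epeaks$fluorescence[rows], lens[rows])
    len <- as.integer(rownames(flu))
    tot <- sum(flu)
    if (tot <= 0) return(0)
    keep <- flu[, 1] >= floor * tot
    p <- sum(flu[keep & len %in% bin, 1]) / sum(flu[keep, 1])
    p * fractions$total_16S_copies[i]
  }, numeric(1))
  new_trf_distribution(
    fractions$buoyant_density, copies,
    condition = as.character(fractions$condition[1] %||% "sample"),
    enzyme = enzyme,
    representative_length_bp = min(bin),
    member_lengths = sort(unique(bin))
  )
}

#' Copy-weighted mean buoyant density of a distribution
#'
#' Continuous one-number summary of a T-RF's density distribution:
#' \eqn{\sum \rho_i c_i / \sum c_i} over fractions, using raw (unnormalized)
#' copy numbers.
#'
#' @param dist A `trf_distribution`.
#' @return Weighted mean density (g/cm^3).
#' @export
weighted_mean_density <- function(dist) {
  stopifnot(inherits(dist, "trf_distribution"))
  tot <- sum(dist$copies)
  if (tot <= 0) {
    abort("Distribution has no mass.", class = "siptrflp_error_degenerate")
  }
  sum(dist$buoyant_density * dist$copies) / tot
}

#' Modal (peak) fraction density of a distribution
#'
#' Density of the fraction with the maximal normalized copy number; exact
#' ties are broken toward the heavier fraction.
#'
#' @param dist A `trf_distribution`.
#' @return Peak density (g/cm^3).
#' @export
peak_fraction_density <- function(dist) {
  stopifnot(inherits(dist, "trf_distribution"))
  if (max(dist$copies) <= 0) {
    abort("Distribution has no mass.", class = "siptrflp_error_degenerate")
  }
  mx <- max(dist$normalized)
  max(dist$buoyant_density[dist$normalized >= mx - 1e-12])
}

#' Shift-detection parameters
#'
#' @param heavy_threshold Density (g/cm^3) at and above which fractions count
#'   as "heavy" (default 1.732).
#' @param min_peak_shift Minimal labeled-minus-unlabeled peak-density
#'   difference (g/cm^3) to call a shift; default 0.004, about one fraction
#'   spacing.
#' @param pair_tolerance Maximal density difference (g/cm^3) when pairing the
#'   two conditions' fractions by nearest density (default 0.002).
#' @return A list of class `shift_params`.
#' @export
shift_params <- function(heavy_threshold = 1.732, min_peak_shift = 0.004,
                         pair_tolerance = 0.002) {
  stopifnot(heavy_threshold > 1.60, heavy_threshold < 1.85,
            min_peak_shift >= 0, pair_tolerance > 0)
  structure(list(heavy_threshold = heavy_threshold,
                 min_peak_shift = min_peak_shift,
                 pair_tolerance = pair_tolerance),
            class = "shift_params")
}

#' Detect a labeled-vs-unlabeled buoyant-density shift for one T-RF
#'
#' Pairs the two distributions' fractions by nearest density (within
#' `pair_tolerance`; unpairable points are dropped with a warning), then
#' computes: the peak (modal-fraction) densities, the weighted-mean density
#' shift, and the heavy-fraction ratio -- the summed normalized copy number
#' at densities at or above `heavy_threshold` in the labeled distribution
#' divided by the same sum in the unlabeled one (`Inf` when only the labeled
#' distribution carries heavy mass; 1 when neither does). The fragment is
#' called shifted when the peak-density difference is at least
#' `min_peak_shift` and the heavy ratio exceeds 1 (or is `Inf`).
#'
#' @param labeled,unlabeled `trf_distribution` objects for the labeled and
#'   the unlabeled (reference) condition.
#' @param params A [shift_params()] object.
#' @return One-row tibble: `enzyme`, `representative_length_bp`,
#'   `peak_density_labeled`, `peak_density_unlabeled`, `peak_shift`,
#'   `weighted_mean_shift`, `heavy_ratio`, `shifted`.
#' @export
detect_shift <- function(labeled, unlabeled, params = shift_params()) {
  stopifnot(inherits(labeled, "trf_distribution"),
            inherits(unlabeled, "trf_distribution"),
            inherits(params, "shift_params"))
  # pair labeled points with nearest unlabeled density
  idx <- map_int(labeled$buoyant_density, function(d) {
    j <- which.min(abs(unlabeled$buoyant_density - d))
    if (abs(unlabeled$buoyant_density[j] - d) > params$pair_tolerance) NA_integer_
    else j
  })
  if (all(is.na(idx))) {
    abort("Density grids of the two conditions do not overlap within the pairing tolerance.",
          class = "siptrflp_error_pairing")
  }
  if (any(is.na(idx))) {
    warn(sprintf("%d fraction(s) had no density match within %.4f g/cm^3 and were dropped from pairing.",
                 sum(is.na(idx)), params$pair_tolerance),
         class = "siptrflp_warning_pairing")
  }
  keep <- !is.na(idx)
  lab <- labeled[keep, ]
  unl <- unlabeled[idx[keep], ]
  heavy_l <- sum(lab$normalized[lab$buoyant_density >= params$heavy_threshold])
  heavy_u <- sum(unl$normalized[unl$buoyant_density >= params$heavy_threshold])
  heavy_ratio <- if (heavy_u > 0) heavy_l / heavy_u
                 else if (heavy_l > 0) Inf else 1
  pk_l <- peak_fraction_density(labeled)
  pk_u <- peak_fraction_density(unlabeled)
  tibble(
    enzyme = attr(labeled, "enzyme") %||% NA_character_,
    representative_length_bp = attr(labeled, "representative_length_bp") %||% NA_integer_,
    peak_density_labeled = pk_l,
    peak_density_unlabeled = pk_u,
    peak_shift = pk_l - pk_u,
    weighted_mean_shift = weighted_mean_density(labeled) - weighted_mean_density(unlabeled),
    heavy_ratio = heavy_ratio,
    shifted = (pk_l - pk_u >= params$min_peak_shift) && (heavy_ratio > 1)
  )
}

#' Shift report across all T-RF bins of an experiment
#'
#' Pools observed fragment lengths from the labeled and unlabeled condition
#' per enzyme, bins them ([bin_lengths()]), builds each bin's density
#' distribution in both conditions, and runs [detect_shift()]. Bins with no
#' copy mass in one of the two conditions cannot be compared (their
#' max-normalized distribution is undefined) and are reported with
#' `shifted = NA`.
#'
#' @param fractions Validated fraction table containing both conditions.
#' @param peaks Peak table containing both conditions.
#' @param labeled,unlabeled Condition labels to compare.
#' @param enzymes Enzyme registry tibble.
#' @param tolerance_bp Binning tolerance (bp).
#' @param params A [shift_params()] object.
#' @param floor Relative-fluorescence floor for [peak_proportions()].
#' @return Tibble with one row per enzyme x bin; the columns of
#'   [detect_shift()] plus `member_lengths` (comma-separated) and `n_members`.
#' @export
shift_report <- function(fractions, peaks, labeled, unlabeled,
                         enzymes = sip_enzymes(), tolerance_bp = 5,
                         params = shift_params(), floor = 0.005) {
  fractions <- as_tibble(fractions)
  peaks <- as_tibble(peaks)
  conds <- unique(fractions$condition)
  if (!all(c(labeled, unlabeled) %in% conds)) {
    abort(sprintf("Conditions '%s' and '%s' must both be present (found: %s).",
                  labeled, unlabeled, paste(conds, collapse = ", ")),
          class = "siptrflp_error_config")
  }
  unknown <- setdiff(unique(peaks$enzyme), enzymes$enzyme)
  if (length(unknown) > 0) {
    abort(sprintf("Peak table references unknown enzyme(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "siptrflp_error_config")
  }
  frac_l <- fractions |> filter(.data$condition == labeled)
  frac_u <- fractions |> filter(.data$condition == unlabeled)
  pk2 <- peaks |> filter(.data$condition %in% c(labeled, unlabeled))
  out <- map(unique(pk2$enzyme), function(enz) {
    ep <- pk2 |> filter(.data$enzyme == enz)
    bins <- bin_lengths(ep$length_bp, tolerance_bp = tolerance_bp)
    map(unique(bins$representative_length_bp), function(rep_len) {
      members <- bins$length_bp[bins$representative_length_bp == rep_len]
      dist_of <- function(fr, cond) {
        tryCatch(
          build_distribution(fr, pk2 |> filter(.data$condition == cond),
                             members, enz, floor = floor),
          siptrflp_error_degenerate = function(e) NULL
        )
      }
      dl <- dist_of(frac_l, labeled)
      du <- dist_of(frac_u, unlabeled)
      base <- tibble(
        enzyme = enz, representative_length_bp = as.integer(rep_len),
        member_lengths = paste(members, collapse = ","),
        n_members = length(members)
      )
      if (is.null(dl) || is.null(du)) {
        return(base |> mutate(
          peak_density_labeled = NA_real_, peak_density_unlabeled = NA_real_,
          peak_shift = NA_real_, weighted_mean_shift = NA_real_,
          heavy_ratio = NA_real_, shifted = NA
        ))
      }
      res <- detect_shift(dl, du, params)
      dplyr::bind_cols(base, res |> select(-"enzyme", -"representative_length_bp"))
    }) |> list_rbind()
  }) |> list_rbind()
  out |> arrange(.data$enzyme, .data$representative_length_bp)
}
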