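#' Simulator parameters
#'
#' Assumptions of the forward model that generates SIP/T-RFLP-like data. The
#' density model is the standard linear CsCl relationship: an unlabeled
#' genome bands at `rho_base + rho_gc_slope * GC` (1.660 + 0.098 x GC
#' g/cm^3), and full \eqn{^{13}}C labeling adds `rho_label_max` (0.036
#' g/cm^3), scaled by the atom-fraction excess actually assimilated. These
#' constants are simulator assumptions (configuration), not measurements.
#'
#' @param rho_base Density of a GC = 0 unlabeled genome (g/cm^3).
#' @param rho_gc_slope Density increase per unit GC fraction (g/cm^3).
#' @param rho_label_max Density increase at full 13C labeling (g/cm^3).
#' @param band_sigma Gaussian banding width of one taxon across the gradient
#'   (g/cm^3); 0 puts all mass in the nearest fraction.
#' @param n_fractions Number of fractions the gradient is divided into
#'   (default 18).
#' @param density_min,density_max Range spanned by the equally spaced
#'   fraction centers (g/cm^3).
#' @param eta_noise_sd Refractometer noise (refractive-index units).
#' @param len_error_sd Capillary sizing error of a fragment (bp, before
#'   clipping).
#' @param len_error_max Hard clip of the sizing error (bp); the default 4
#'   keeps simulated errors inside the 5-bp affiliation tolerance by
#'   construction. Set to `Inf` for untruncated robustness testing.
#' @param peak_jitter_sd Additional iid per-peak sizing jitter (bp); default
#'   0 (the sizing error of a given fragment is reproducible across lanes).
#' @param qpcr_lognormal_sd Lognormal sd of per-fraction qPCR totals.
#' @param total_copies Total community 16S copies/mL before fractionation.
#' @param cq_slope,cq_intercept,cq_noise_sd Calibration line and Cq noise for
#'   the simulated dilution series.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(rho_base = 1.660, rho_gc_slope = 0.098,
                       rho_label_max = 0.036, band_sigma = 0.005,
                       n_fractions = 18, density_min = 1.690,
                       density_max = 1.775, eta_noise_sd = 1e-4,
                       len_error_sd = 1.5, len_error_max = 4,
                       peak_jitter_sd = 0,
                       qpcr_lognormal_sd = 0.1, total_copies = 1e8,
                       cq_slope = -3.3219, cq_intercept = 40,
                       cq_noise_sd = 0.1) {
  if (density_min >= density_max) {
    abort("`density_min` must be below `density_max`.", class = "siptrflp_error_input")
  }
  if (n_fractions < 3) {
    abort("`n_fractions` must be >= 3.", class = "siptrflp_error_input")
  }
  structure(
    list(rho_base = rho_base, rho_gc_slope = rho_gc_slope,
         rho_label_max = rho_label_max, band_sigma = band_sigma,
         n_fractions = as.integer(n_fractions), density_min = density_min,
         density_max = density_max, eta_noise_sd = eta_noise_sd,
         len_error_sd = len_error_sd, len_error_max = len_error_max,
         peak_jitter_sd = peak_jitter_sd,
         qpcr_lognormal_sd = qpcr_lognormal_sd, total_copies = total_copies,
         cq_slope = cq_slope, cq_intercept = cq_intercept,
         cq_noise_sd = cq_noise_sd),
    class = "sim_params"
  )
}

#' Buoyant-density band center of a taxon
#'
#' `rho_base + rho_gc_slope * gc + rho_label_max * atom_frac`.
#'
#' @param gc_fraction GC content in `[0, 1]`.
#' @param atom_frac_13C Atom-fraction excess 13C assimilated, in `[0, 1]`.
#' @param params A [sim_params()] object.
#' @return Band center density (g/cm^3); vectorized.
#' @examples
#' taxon_band_center(0.684, 0)    # ~1.727
#' taxon_band_center(0.684, 0.61) # ~1.749
#' @export
taxon_band_center <- function(gc_fraction, atom_frac_13C, params = sim_params()) {
  if (any(gc_fraction < 0 | gc_fraction > 1) ||
      any(atom_frac_13C < 0 | atom_frac_13C > 1)) {
    abort("`gc_fraction` and `atom_frac_13C` must lie in [0, 1].",
          class = "siptrflp_error_input")
  }
  params$rho_base + params$rho_gc_slope * gc_fraction +
    params$rho_label_max * atom_frac_13C
}

# Validate a community tibble; derive gc from sequence if absent.
check_community <- function(community) {
  community <- as_tibble(community)
  need <- c("taxon_id", "relative_abundance")
  missing_cols <- setdiff(need, names(community))
  if (length(missing_cols) > 0) {
    abort(sprintf("Community lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "siptrflp_error_schema")
  }
  if (!("atom_frac_13C" %in% names(community))) community$atom_frac_13C <- 0
  if (!("gc_fraction" %in% names(community)) ||
      any(is.na(community$gc_fraction))) {
    if (!("sequence" %in% names(community))) {
      abort("Community needs `gc_fraction` or `sequence`.",
            class = "siptrflp_error_schema")
    }
    gc <- map_dbl(community$sequence, function(s) {
      s <- toupper(s)
      sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    })
    if (!("gc_fraction" %in% names(community))) community$gc_fraction <- gc
    else community$gc_fraction <- dplyr::coalesce(community$gc_fraction, gc)
  }
  if (abs(sum(community$relative_abundance) - 1) > 1e-6) {
    abort("Community relative abundances must sum to 1.",
          class = "siptrflp_error_validation")
  }
  community
}

#' Simulate a CsCl density gradient of a community
#'
#' Fraction centers are equally spaced on `[density_min, density_max]`
#' (heaviest fraction has index 1, as collected from the tube bottom). Each
#' taxon's DNA mass is apportioned over fractions proportionally to a
#' Gaussian band centered at [taxon_band_center()] with sd `band_sigma`,
#' evaluated at the fraction centers and renormalized so mass is conserved.
#' The stored `buoyant_density` is the true fraction-center value; the
#' measurement noise lives in `refractive_index` (inverse conversion plus
#' Gaussian noise), and per-fraction qPCR totals are perturbed lognormally.
#'
#' @param community Tibble with `taxon_id`, `relative_abundance` (summing to
#'   1), `gc_fraction` (or `sequence`), and optionally `atom_frac_13C`
#'   (default 0).
#' @param params A [sim_params()] object.
#' @param condition_label Condition name stored in the output.
#' @param seed Optional integer seed (local to this call).
#' @return Fraction tibble (`condition`, `fraction_index`,
#'   `refractive_index`, `buoyant_density`, `total_16S_copies`) with the
#'   noise-free per-taxon masses in attribute `taxon_masses`.
#' @export
simulate_gradient <- function(community, params = sim_params(),
                              condition_label = "labeled", seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  community <- check_community(community)
  centers <- seq(params$density_min, params$density_max,
                 length.out = params$n_fractions)
  band <- taxon_band_center(community$gc_fraction, community$atom_frac_13C, params)
  outside <- band < params$density_min - 3 * params$band_sigma |
    band > params$density_max + 3 * params$band_sigma
  if (any(outside)) {
    warn(sprintf("Band center(s) of taxa %s fall > 3 sigma outside the density grid; their mass is truncated.",
                 paste(community$taxon_id[outside], collapse = ", ")),
         class = "siptrflp_warning_truncation")
  }
  W <- vapply(seq_along(band), function(t) {
    if (params$band_sigma <= 0) {
      w <- numeric(length(centers))
      w[which.min(abs(centers - band[t]))] <- 1
      w
    } else {
      w <- dnorm(centers, mean = band[t], sd = params$band_sigma)
      if (sum(w) <= 0) {  # band far outside grid: collapse to nearest fraction
        w <- numeric(length(centers))
        w[which.min(abs(centers - band[t]))] <- 1
      }
      w / sum(w)
    }
  }, numeric(length(centers)))
  masses <- W %*% diag(community$relative_abundance, nrow = length(band))
  frac_mass <- rowSums(masses)
  noise <- exp(rnorm(length(centers), 0, params$qpcr_lognormal_sd))
  eta <- ri_from_density(centers) + rnorm(length(centers), 0, params$eta_noise_sd)
  out <- tibble(
    condition = condition_label,
    fraction_index = rev(seq_len(params$n_fractions)),  # index 1 = heaviest
    refractive_index = eta,
    buoyant_density = centers,
    total_16S_copies = frac_mass * params$total_copies * noise
  ) |> arrange(.data$fraction_index)
  tm <- as_tibble(as.data.frame(masses)) |>
    setNames(community$taxon_id) |>
    mutate(fraction_index = rev(seq_len(params$n_fractions))) |>
    pivot_longer(-"fraction_index", names_to = "taxon_id", values_to = "mass")
  attr(out, "taxon_masses") <- tm
  attr(out, "band_centers") <- setNames(band, community$taxon_id)
  out
}

# Draw per-fragment capillary sizing errors (systematic per taxon x enzyme).
draw_length_errors <- function(truth, params) {
  err <- rnorm(nrow(truth), 0, params$len_error_sd)
  if (is.finite(params$len_error_max)) {
    err <- pmin(pmax(err, -params$len_error_max), params$len_error_max)
  }
  truth |> mutate(error_bp = err)
}

#' Simulate T-RFLP peak tables for a simulated gradient
#'
#' Per fraction and enzyme, each taxon contributes one peak with fluorescence
#' proportional to its DNA mass in the fraction. The observed length is the
#' true terminal fragment length plus a capillary sizing error that is
#' systematic per fragment (drawn once per taxon x enzyme, reproduced across
#' lanes): Gaussian with sd `len_error_sd`, hard-clipped at
#' `+/- len_error_max` bp and rounded to integer bp. Optional iid per-peak
#' jitter can be added via `peak_jitter_sd`. Co-migrating taxa (identical
#' observed length) merge their fluorescence.
#'
#' @param gradient Output of [simulate_gradient()] (carries the per-taxon
#'   masses).
#' @param community The community tibble used for the gradient; must carry
#'   `sequence` or be covered by `true_trfs`.
#' @param enzymes Enzyme registry tibble.
#' @param params A [sim_params()] object.
#' @param true_trfs Optional tibble `taxon_id`, `enzyme`, `true_length_bp`;
#'   derived from sequences when absent.
#' @param length_errors Optional pre-drawn error table (`taxon_id`, `enzyme`,
#'   `true_length_bp`, `error_bp`) so several conditions share the same
#'   sizing bias; drawn here when `NULL`.
#' @param seed Optional integer seed (local to this call).
#' @param min_mass Taxon mass below which no peak is emitted (default 1e-9 of
#'   the community).
#' @return Peak tibble `condition`, `fraction_index`, `enzyme`, `length_bp`,
#'   `fluorescence`, with the error table in attribute `length_errors`.
#' @export
simulate_trflp <- function(gradient, community, enzymes = sip_enzymes(),
                           params = sim_params(), true_trfs = NULL,
                           length_errors = NULL, seed = NULL,
                           min_mass = 1e-9) {
  if (!is.null(seed)) withr::local_seed(seed)
  community <- check_community(community)
  masses <- attr(gradient, "taxon_masses")
  if (is.null(masses)) {
    abort("`gradient` lacks the `taxon_masses` attribute; use simulate_gradient().",
          class = "siptrflp_error_config")
  }
  if (is.null(true_trfs)) {
    if (!("sequence" %in% names(community)) || any(is.na(community$sequence))) {
      abort("Supply `true_trfs` or give every taxon a sequence.",
            class = "siptrflp_error_config")
    }
    pred <- predict_trf_table(setNames(community$sequence, community$taxon_id),
                              enzymes = enzymes)
    true_trfs <- pred |>
      rename(taxon_id = "sequence_id", true_length_bp = "expected_length_bp") |>
      select("taxon_id", "enzyme", "true_length_bp")
  }
  covered <- tidyr::expand_grid(taxon_id = community$taxon_id,
                                enzyme = enzymes$enzyme) |>
    dplyr::anti_join(true_trfs, by = c("taxon_id", "enzyme"))
  if (nrow(covered) > 0 || any(is.na(true_trfs$true_length_bp))) {
    abort("Every taxon needs a true T-RF for every enzyme (an enzyme that does not cut cannot be simulated).",
          class = "siptrflp_error_config")
  }
  if (is.null(length_errors)) {
    length_errors <- draw_length_errors(true_trfs, params)
  }
  obs <- length_errors |>
    mutate(observed_length_bp = as.integer(floor(.data$true_length_bp +
                                                   .data$error_bp + 0.5)))
  cond <- as.character(gradient$condition[1])
  peaks <- masses |>
    filter(.data$mass > min_mass) |>
    dplyr::inner_join(obs, by = "taxon_id", relationship = "many-to-many") |>
    mutate(
      length_bp = .data$observed_length_bp +
        if (params$peak_jitter_sd > 0)
          as.integer(round(rnorm(dplyr::n(), 0, params$peak_jitter_sd)))
        else 0L,
      fluorescence = .data$mass * 1e4
    ) |>
    group_by(.data$fraction_index, .data$enzyme, .data$length_bp) |>
    summarise(fluorescence = sum(.data$fluorescence), .groups = "drop") |>
    mutate(condition = cond) |>
    select("condition", "fraction_index", "enzyme", "length_bp", "fluorescence") |>
    arrange(.data$fraction_index, .data$enzyme, .data$length_bp)
  attr(peaks, "length_errors") <- length_errors
  peaks
}

#' Simulate a complete labeled/unlabeled SIP experiment
#'
#' Simulates the labeled condition (community as supplied, with its
#' `atom_frac_13C` values) and an unlabeled reference (same community with
#' atom fraction forced to 0) in one run. The capillary sizing errors are
#' drawn once per fragment and shared by both conditions, as the two samples
#' are sized in the same T-RFLP analysis.
#'
#' @inheritParams simulate_trflp
#' @param community Community tibble (see [simulate_gradient()]).
#' @param labels Length-2 character vector naming the labeled and unlabeled
#'   condition.
#' @param seed Optional integer seed governing all randomness of the run.
#' @return A list of class `sip_experiment`: `fractions`, `peaks` (both
#'   conditions), `true_trfs`, `length_errors`, `community`, `params`.
#' @examples
#' ex <- simulate_sip_experiment(example_community(), seed = 1)
#' head(ex$fractions)
#' @export
simulate_sip_experiment <- function(community, params = sim_params(),
                                    enzymes = sip_enzymes(), true_trfs = NULL,
                                    labels = c("labeled", "unlabeled"),
                                    seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  community <- check_community(community)
  if (is.null(true_trfs) && "true_trfs" %in% names(attributes(community))) {
    true_trfs <- attr(community, "true_trfs")
  }
  if (is.null(true_trfs) && !("sequence" %in% names(community))) {
    abort("Supply `true_trfs` or sequences for the community.",
          class = "siptrflp_error_config")
  }
  if (is.null(true_trfs)) {
    pred <- predict_trf_table(setNames(community$sequence, community$taxon_id),
                              enzymes = enzymes)
    true_trfs <- pred |>
      rename(taxon_id = "sequence_id", true_length_bp = "expected_length_bp") |>
      select("taxon_id", "enzyme", "true_length_bp")
  }
  errs <- draw_length_errors(true_trfs, params)
  unlabeled_comm <- community |> mutate(atom_frac_13C = 0)
  grad_l <- simulate_gradient(community, params, condition_label = labels[1])
  grad_u <- simulate_gradient(unlabeled_comm, params, condition_label = labels[2])
  pk_l <- simulate_trflp(grad_l, community, enzymes, params,
                         true_trfs = true_trfs, length_errors = errs)
  pk_u <- simulate_trflp(grad_u, unlabeled_comm, enzymes, params,
                         true_trfs = true_trfs, length_errors = errs)
  structure(
    list(
      fractions = bind_rows(grad_l, grad_u),
      peaks = bind_rows(pk_l, pk_u),
      true_trfs = true_trfs,
      length_errors = errs,
      community = community,
      params = params,
      labels = labels
    ),
    class = "sip_experiment"
  )
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat(sprintf(
    "<sip_experiment> %d taxa, %d fractions/condition, conditions: %s\n",
    nrow(x$community), x$params$n_fractions, paste(x$labels, collapse = " vs ")
  ))
  invisible(x)
}

#' Example four-taxon community
#'
#' A small synthetic consortium loosely inspired by VOC-degrading enrichment
#' cultures: one dominant taxon plus three minor ones, with exactly one taxon
#' (a Hyphomicrobium-like DCM assimilator) carrying 13C label at atom
#' fraction `atom_frac`. GC fractions are chosen so the unlabeled band
#' centers coincide with fraction-grid centers (1.700-1.730 g/cm^3), which
#' keeps each taxon's modal fraction stable under the default measurement
#' noise; true T-RFs are well separated between taxa for both enzymes.
#'
#' @param atom_frac Atom-fraction excess 13C of the labeled taxon (default
#'   0.61).
#' @return Community tibble with attribute `true_trfs`.
#' @examples
#' example_community()
#' @export
example_community <- function(atom_frac = 0.61) {
  comm <- tibble(
    taxon_id = c("Rhodanobacter_like", "Rhizobium_like",
                 "Bradyrhizobium_like", "Hyphomicrobium_like"),
    gc_fraction = c(0.71429, 0.40816, 0.51020, 0.66327),
    relative_abundance = c(0.50, 0.20, 0.15, 0.15),
    atom_frac_13C = c(0, 0, 0, atom_frac)
  )
  attr(comm, "true_trfs") <- tibble(
    taxon_id = rep(comm$taxon_id, each = 2),
    enzyme = rep(c("HhaI", "MspI"), times = 4),
    true_length_bp = c(204L, 491L, 438L, 236L, 566L, 120L, 341L, 403L)
  )
  comm
}

#' Simulate a qPCR serial-dilution series
#'
#' Ten-fold dilutions from `true_copies_top` downward, with Cq generated from
#' the configured calibration line plus Gaussian noise.
#'
#' @param true_copies_top Copies at the top (most concentrated) level.
#' @param n_levels Number of 10-fold dilution levels (>= 3).
#' @param params A [sim_params()] object (`cq_slope`, `cq_intercept`,
#'   `cq_noise_sd`).
#' @param seed Optional integer seed.
#' @return Tibble `copies`, `cq`, ready for [fit_standard_curve()].
#' @export
simulate_qpcr_dilution_series <- function(true_copies_top = 1e8, n_levels = 6,
                                          params = sim_params(), seed = NULL) {
  if (n_levels < 3) {
    abort("`n_levels` must be >= 3.", class = "siptrflp_error_input")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  copies <- true_copies_top / 10^(seq_len(n_levels) - 1)
  tibble(
    copies = copies,
    cq = params$cq_intercept + params$cq_slope * log10(copies) +
      rnorm(n_levels, 0, params$cq_noise_sd)
  )
}

#' Generate a synthetic 16S-like sequence with planted terminal fragments
#'
#' Produces a random DNA sequence of the requested GC content whose first
#' recognition site for each enzyme sits exactly where it yields the desired
#' terminal fragment length. Useful for exercising the in-silico digestion
#' path end to end.
#'
#' @param trf Named integer vector: desired T-RF length per enzyme name.
#' @param enzymes Enzyme registry covering the names of `trf`.
#' @param length Sequence length (default 900, a typical 27F-907R amplicon).
#' @param gc Target GC fraction of the background sequence.
#' @param seed Optional integer seed.
#' @param max_iter Repair iterations for accidental upstream sites.
#' @return A DNA string.
#' @examples
#' s <- simulate_taxon_sequence(c(HhaI = 341, MspI = 403), seed = 1)
#' terminal_fragment_length(s, "HhaI")
#' @export
simulate_taxon_sequence <- function(trf, enzymes = sip_enzymes(), length = 900,
                                    gc = 0.6, seed = NULL, max_iter = 200) {
  if (!is.null(seed)) withr::local_seed(seed)
  enz <- enzymes |> filter(.data$enzyme %in% names(trf))
  if (nrow(enz) != length(trf)) {
    abort("Every name of `trf` must be a registered enzyme.",
          class = "siptrflp_error_config")
  }
  starts <- map_int(seq_len(nrow(enz)), function(i) {
    as.integer(trf[[enz$enzyme[i]]]) - enz$cut_offset[i] + 1L
  })
  if (any(starts < 1) || any(starts + nchar(enz$site) - 1L > length)) {
    abort("Requested T-RFs do not fit in the sequence length.",
          class = "siptrflp_error_input")
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  protected <- unlist(map(seq_len(nrow(enz)), function(i) {
    seq.int(starts[i], starts[i] + nchar(enz$site[i]) - 1L)
  }))
  if (anyDuplicated(protected)) {
    abort("Planted recognition sites overlap; choose more separated T-RFs.",
          class = "siptrflp_error_input")
  }
  bases <- sample(names(probs), length, replace = TRUE, prob = probs)
  for (i in seq_len(nrow(enz))) {
    bases[seq.int(starts[i], starts[i] + nchar(enz$site[i]) - 1L)] <-
      strsplit(enz$site[i], "")[[1]]
  }
  for (iter in seq_len(max_iter)) {
    s <- paste(bases, collapse = "")
    ok <- TRUE
    for (i in seq_len(nrow(enz))) {
      pos <- as.integer(regexpr(enz$site[i], s, fixed = TRUE))
      if (pos != starts[i]) {
        ok <- FALSE
        # break the spurious upstream site at its first mutable base
        w <- seq.int(pos, pos + nchar(enz$site[i]) - 1L)
        mutable <- setdiff(w, protected)
        if (length(mutable) == 0) {
          abort("Cannot repair a site overlapping a planted window; choose other T-RFs.",
                class = "siptrflp_error_input")
        }
        j <- mutable[1]
        bases[j] <- sample(setdiff(c("A", "T"), bases[j]), 1)
      }
    }
    if (ok) return(s)
  }
  abort("Failed to generate a clean sequence; try another seed or length.",
        class = "siptrflp_error_input")
}
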