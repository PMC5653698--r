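IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Define a restriction enzyme
#'
#' A T-RFLP digest enzyme is described by its recognition site on the labeled
#' (top) strand and the cut offset: the number of bases of the site that
#' remain attached to the 5' terminal fragment. For HhaI (GCG^C) the offset is
#' 3; for MspI (C^CGG) it is 1.
#'
#' @param name Enzyme name.
#' @param site Recognition site, a DNA string over A/C/G/T.
#' @param cut_offset Integer in `(0, nchar(site)]`: bases after the site start
#'   at which the top strand is cut.
#' @return A one-row tibble with columns `enzyme`, `site`, `cut_offset`.
#' @examples
#' restriction_enzyme("HhaI", "GCGC", 3)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (grepl("[^ACGT]", site)) {
    abort("Recognition site must be over A/C/G/T.", class = "siptrflp_error_input")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset <= 0L || cut_offset > nchar(site)) {
    abort("`cut_offset` must be in (0, nchar(site)].", class = "siptrflp_error_input")
  }
  tibble(enzyme = name, site = site, cut_offset = cut_offset)
}

#' Built-in T-RFLP enzyme registry
#'
#' The two 4-cutters used for independent digests of carboxyfluorescein
#' end-labeled 16S amplicons: HhaI (GCG^C) and MspI (C^CGG).
#'
#' @return A tibble with one row per enzyme (`enzyme`, `site`, `cut_offset`).
#' @examples
#' sip_enzymes()
#' @export
sip_enzymes <- function() {
  bind_rows(
    restriction_enzyme("HhaI", "GCGC", 3),
    restriction_enzyme("MspI", "CCGG", 1)
  )
}

# Resolve an enzyme argument (name, one-row tibble, or registry subset row).
as_enzyme <- function(enzyme, registry = sip_enzymes()) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    row <- registry[registry$enzyme == enzyme, ]
    if (nrow(row) == 0) {
      abort(sprintf("Unknown enzyme '%s' (registry has: %s).", enzyme,
                    paste(registry$enzyme, collapse = ", ")),
            class = "siptrflp_error_config")
    }
    return(row[1, ])
  }
  if (is.data.frame(enzyme) && all(c("enzyme", "site", "cut_offset") %in% names(enzyme))) {
    if (nrow(enzyme) != 1L) {
      abort("Supply a single enzyme (one row).", class = "siptrflp_error_input")
    }
    return(as_tibble(enzyme))
  }
  abort("`enzyme` must be an enzyme name or a one-row enzyme tibble.",
        class = "siptrflp_error_input")
}

#' Terminal restriction fragment length of a sequence
#'
#' Scans the sequence 5' to 3' (base 1 carries the fluorescent label) for the
#' first exact occurrence of the enzyme's recognition site and returns the
#' length of the labeled terminal fragment, i.e. the cut position. IUPAC
#' ambiguity codes are legal in the query but never match a site (a window
#' containing an ambiguous base cannot produce a cut); the number of such
#' skipped windows is reported via a message when any occur. `NA` means the
#' enzyme does not cut the sequence.
#'
#' @param seq Character vector of DNA sequences (5'->3', labeled strand).
#' @param enzyme Enzyme name (looked up in `registry`) or a one-row enzyme
#'   tibble from [restriction_enzyme()].
#' @param registry Enzyme registry used to resolve names.
#' @param quiet Suppress the ambiguous-window message.
#' @return Integer vector: fragment length in bp, `NA` where the enzyme does
#'   not cut.
#' @examples
#' terminal_fragment_length("AAAAGCGCTT", "HhaI") # 7
#' terminal_fragment_length("TTCCGGAA", "MspI")   # 3
#' @export
terminal_fragment_length <- function(seq, enzyme, registry = sip_enzymes(),
                                     quiet = FALSE) {
  enz <- as_enzyme(enzyme, registry)
  seq <- toupper(as.character(seq))
  bad_chr <- grepl(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")), seq)
  if (any(bad_chr)) {
    abort("Sequences contain non-IUPAC characters.", class = "siptrflp_error_parse")
  }
  if (any(nchar(seq) < nchar(enz$site))) {
    abort("Sequences must be at least as long as the recognition site.",
          class = "siptrflp_error_input")
  }
  pos <- regexpr(enz$site, seq, fixed = TRUE)
  out <- ifelse(pos > 0, as.integer(pos) + enz$cut_offset - 1L, NA_integer_)
  has_amb <- grepl("[^ACGT]", seq)
  if (any(has_amb) && !quiet) {
    n_skip <- sum(map_int(which(has_amb), function(i) {
      end <- if (pos[i] > 0) pos[i] + nchar(enz$site) - 1L else nchar(seq[i])
      s <- substr(seq[i], 1L, end)
      amb <- gregexpr("[^ACGT]", s)[[1]]
      if (amb[1] == -1) return(0L)
      # windows of site length overlapping an ambiguous base
      w <- unique(unlist(lapply(amb, function(a) {
        seq.int(max(1L, a - nchar(enz$site) + 1L), min(a, nchar(s) - nchar(enz$site) + 1L))
      })))
      length(w[w >= 1])
    }))
    inform(sprintf("%d window(s) containing IUPAC ambiguity codes skipped (never match a site).",
                   n_skip))
  }
  as.integer(out)
}

#' Predict expected terminal fragments for a set of sequences
#'
#' In-silico digestion of clone or taxon 16S sequences: one prediction per
#' sequence x enzyme pair. Sequences where an enzyme does not cut are
#' reported with `expected_length_bp = NA`, never dropped.
#'
#' @param sequences A named character vector of DNA sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param enzymes Enzyme registry tibble (default both built-ins).
#' @param annotations Optional named character vector (names = sequence ids)
#'   with free-text annotation, e.g. the closest organism.
#' @return A tibble `sequence_id`, `enzyme`, `expected_length_bp`,
#'   `annotation`.
#' @examples
#' predict_trf_table(c(cloneA = "AAAAGCGCTTCCGGAA"))
#' @export
predict_trf_table <- function(sequences, enzymes = sip_enzymes(),
                              annotations = NULL) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  } else if (is.character(sequences) && length(sequences) == 1L &&
             is.null(names(sequences)) && file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- setNames(as.character(ss), names(ss))
  }
  if (length(sequences) == 0) {
    abort("No sequences supplied.", class = "siptrflp_error_input")
  }
  if (nrow(enzymes) == 0) {
    abort("No enzymes supplied.", class = "siptrflp_error_input")
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  ids <- names(sequences)
  out <- purrr::map(seq_len(nrow(enzymes)), function(i) {
    tibble(
      sequence_id = ids,
      enzyme = enzymes$enzyme[i],
      expected_length_bp = terminal_fragment_length(
        sequences, enzymes[i, ], registry = enzymes, quiet = TRUE
      )
    )
  }) |> list_rbind()
  out$annotation <- if (is.null(annotations)) NA_character_ else
    unname(annotations[out$sequence_id])
  out |> arrange(.data$sequence_id, .data$enzyme)
}

# Round fragment lengths half-up to integers, warning when fractional.
round_lengths <- function(x) {
  frac <- !is.na(x) & abs(x - round(x)) > 1e-9
  if (any(frac)) {
    warn(sprintf("%d fractional fragment length(s) rounded half-up to integer bp.",
                 sum(frac)),
         class = "siptrflp_warning_rounding")
  }
  as.integer(floor(x + 0.5))
}

#' Relative T-RF peak proportions from fluorescence
#'
#' Converts an electropherogram peak table for one sample into per-length
#' proportions of total fluorescence. Peaks below the relative-fluorescence
#' floor (default 0.5% of the sample total; a peak at exactly the floor is
#' retained) are removed before renormalisation, mirroring the usual
#' small-peak filtering of capillary profiles.
#'
#' @param peaks Data frame with columns `length_bp`, `fluorescence` (>= 0).
#' @param floor Relative-fluorescence floor as a fraction of total (default
#'   0.005).
#' @return Tibble `length_bp`, `proportion`; proportions sum to 1.
#' @examples
#' peak_proportions(tibble::tibble(length_bp = c(337, 398),
#'                                 fluorescence = c(300, 700)))
#' @export
peak_proportions <- function(peaks, floor = 0.005) {
  peaks <- as_tibble(peaks)
  stopifnot(all(c("length_bp", "fluorescence") %in% names(peaks)))
  if (any(peaks$fluorescence < 0, na.rm = TRUE)) {
    abort("Fluorescence must be non-negative.", class = "siptrflp_error_input")
  }
  peaks <- peaks |>
    mutate(length_bp = round_lengths(.data$length_bp)) |>
    group_by(.data$length_bp) |>
    summarise(fluorescence = sum(.data$fluorescence), .groups = "drop")
  total <- sum(peaks$fluorescence)
  if (!is.finite(total) || total <= 0) {
    abort("All peaks have zero fluorescence; proportions are undefined.",
          class = "siptrflp_error_degenerate")
  }
  kept <- peaks |> filter(.data$fluorescence >= floor * total)
  if (nrow(kept) == 0) {
    abort("All peaks fall below the fluorescence floor.",
          class = "siptrflp_error_degenerate")
  }
  kept |>
    mutate(proportion = .data$fluorescence / sum(.data$fluorescence)) |>
    select("length_bp", "proportion") |>
    arrange(.data$length_bp)
}

#' Bin observed fragment lengths across samples
#'
#' Capillary sizing of the same fragment varies by a few bp between runs, so
#' observed lengths are grouped before cross-sample comparison. Binning is
#' greedy and anchored at the smallest member: unique lengths are sorted
#' ascending and a new bin opens whenever a length exceeds the current bin's
#' smallest member by more than `tolerance_bp`. The result is deterministic
#' and independent of input order. Chains wider than the tolerance are split
#' (documented limitation of the greedy rule).
#'
#' @param lengths Integer vector of observed fragment lengths (bp); fractional
#'   values are rounded half-up with a warning.
#' @param tolerance_bp Maximum within-bin spread from the smallest member
#'   (default 5, the conventional maximum T-RFLP sizing error).
#' @return Tibble `length_bp`, `representative_length_bp` (the bin's smallest
#'   member), one row per unique observed length.
#' @examples
#' bin_lengths(c(337, 341, 500), tolerance_bp = 5)
#' @export
bin_lengths <- function(lengths, tolerance_bp = 5) {
  stopifnot(tolerance_bp >= 0)
  if (tolerance_bp > 10) {
    abort("`tolerance_bp` must be <= 10.", class = "siptrflp_error_input")
  }
  lengths <- round_lengths(lengths)
  u <- sort(unique(lengths[!is.na(lengths)]))
  if (length(u) == 0) {
    return(tibble(length_bp = integer(), representative_length_bp = integer()))
  }
  rep_len <- integer(length(u))
  anchor <- u[1]
  for (i in seq_along(u)) {
    if (u[i] - anchor > tolerance_bp) anchor <- u[i]
    rep_len[i] <- anchor
  }
  tibble(length_bp = u, representative_length_bp = rep_len)
}

#' Affiliation parameters
#'
#' @param tolerance_bp Inclusive length tolerance in bp (default 5). The
#'   conventional maximum T-RFLP sizing error is 5 bp and observed/expected
#'   pairs differing by exactly 5 bp are classified together, so the
#'   comparison is `<=`.
#' @param require_both_enzymes If `TRUE` (default) a candidate must match on
#'   every enzyme present in the observation; if `FALSE`, on at least one.
#' @return A list of class `affiliation_params`.
#' @export
affiliation_params <- function(tolerance_bp = 5, require_both_enzymes = TRUE) {
  tolerance_bp <- as.integer(tolerance_bp)
  if (tolerance_bp < 0 || tolerance_bp > 10) {
    abort("`tolerance_bp` must be in [0, 10].", class = "siptrflp_error_input")
  }
  structure(list(tolerance_bp = tolerance_bp,
                 require_both_enzymes = isTRUE(require_both_enzymes)),
            class = "affiliation_params")
}

#' Affiliate observed T-RFs with predicted clone fragments
#'
#' Compares observed T-RF lengths (one per enzyme) against in-silico
#' predictions for candidate clone sequences. A candidate matches when
#' `|observed - expected| <= tolerance_bp` for every enzyme present in the
#' observation (or any enzyme, with `require_both_enzymes = FALSE`).
#' Candidates are ranked by total absolute difference; exact ties share a
#' rank and are flagged `ambiguous`. An empty result means the observation is
#' unaffiliated.
#'
#' @param observed Named numeric vector (names = enzyme) or a data frame with
#'   columns `enzyme`, `length_bp`.
#' @param predictions Prediction table from [predict_trf_table()].
#' @param params An [affiliation_params()] object.
#' @return A tibble with one row per matching candidate x enzyme:
#'   `sequence_id`, `annotation`, `enzyme`, `observed_length_bp`,
#'   `expected_length_bp`, `abs_diff_bp`, `total_abs_diff_bp`, `rank`,
#'   `ambiguous`.
#' @examples
#' pred <- tibble::tibble(
#'   sequence_id = "cl1", enzyme = c("HhaI", "MspI"),
#'   expected_length_bp = c(341L, 403L), annotation = "Hyphomicrobium sp."
#' )
#' affiliate(c(HhaI = 337, MspI = 398), pred)
#' @export
affiliate <- function(observed, predictions, params = affiliation_params()) {
  stopifnot(inherits(params, "affiliation_params"))
  if (!is.data.frame(observed)) {
    observed <- tibble(enzyme = names(observed), length_bp = as.numeric(observed))
  }
  observed <- as_tibble(observed)
  stopifnot(all(c("enzyme", "length_bp") %in% names(observed)))
  if (nrow(observed) == 0) {
    abort("`observed` needs at least one enzyme.", class = "siptrflp_error_input")
  }
  observed$length_bp <- round_lengths(observed$length_bp)
  predictions <- as_tibble(predictions)
  predictions$expected_length_bp <- round_lengths(predictions$expected_length_bp)
  missing_enz <- setdiff(observed$enzyme, unique(predictions$enzyme))
  if (length(missing_enz) > 0) {
    abort(sprintf("Enzyme(s) absent from predictions: %s",
                  paste(missing_enz, collapse = ", ")),
          class = "siptrflp_error_config")
  }
  cmp <- predictions |>
    filter(.data$enzyme %in% observed$enzyme) |>
    left_join(observed, by = "enzyme") |>
    rename(observed_length_bp = "length_bp") |>
    mutate(abs_diff_bp = abs(.data$observed_length_bp - .data$expected_length_bp),
           hit = !is.na(.data$abs_diff_bp) & .data$abs_diff_bp <= params$tolerance_bp)
  per_seq <- cmp |>
    group_by(.data$sequence_id) |>
    summarise(
      n_hit = sum(.data$hit),
      n_enz = dplyr::n(),
      total_abs_diff_bp = sum(.data$abs_diff_bp[.data$hit]),
      .groups = "drop"
    ) |>
    filter(if (params$require_both_enzymes) .data$n_hit == .data$n_enz
           else .data$n_hit >= 1)
  if (nrow(per_seq) == 0) {
    return(tibble(
      sequence_id = character(), annotation = character(), enzyme = character(),
      observed_length_bp = integer(), expected_length_bp = integer(),
      abs_diff_bp = integer(), total_abs_diff_bp = integer(),
      rank = integer(), ambiguous = logical()
    ))
  }
  per_seq <- per_seq |>
    arrange(.data$total_abs_diff_bp) |>
    mutate(rank = dplyr::min_rank(.data$total_abs_diff_bp),
           ambiguous = duplicated(.data$total_abs_diff_bp) |
             duplicated(.data$total_abs_diff_bp, fromLast = TRUE))
  cmp |>
    filter(.data$sequence_id %in% per_seq$sequence_id, .data$hit) |>
    left_join(per_seq |> select("sequence_id", "total_abs_diff_bp", "rank", "ambiguous"),
              by = "sequence_id") |>
    select("sequence_id", "annotation", "enzyme", "observed_length_bp",
           "expected_length_bp", "abs_diff_bp", "total_abs_diff_bp",
           "rank", "ambiguous") |>
    arrange(.data$rank, .data$sequence_id, .data$enzyme)
}
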