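#' Read an OTU community-profile CSV
#'
#' Reads a wide community table (one row per OTU, one abundance column per
#' condition) such as the 16S amplicon summaries of enrichment cultures.
#' Censored cells written as `<0.1` (below the reporting floor) are parsed as
#' half the floor (0.05) for arithmetic and flagged `censored`; they are
#' never silently treated as zero.
#'
#' @param path CSV path with columns `otu_id`, `organism`, `accession`,
#'   `similarity`, then one percent-abundance column per condition.
#' @return A long tibble: `otu_id`, `organism`, `accession`, `similarity`,
#'   `condition`, `abundance` (percent), `censored`.
#' @export
read_community_profile <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  as_community_profile(wide)
}

#' Convert a wide community table to a long community profile
#'
#' @param wide Data frame with `otu_id`, `organism`, `accession`,
#'   `similarity` and condition columns; abundance cells may be numbers or
#'   censored strings like `<0.1`.
#' @return See [read_community_profile()].
#' @export
as_community_profile <- function(wide) {
  wide <- as_tibble(wide)
  meta <- c("otu_id", "organism", "accession", "similarity")
  missing_cols <- setdiff(c("otu_id"), names(wide))
  if (length(missing_cols) > 0) {
    abort("Community table needs an `otu_id` column.", class = "siptrflp_error_schema")
  }
  cond_cols <- setdiff(names(wide), meta)
  if (length(cond_cols) == 0) {
    abort("Community table has no condition columns.", class = "siptrflp_error_schema")
  }
  long <- wide |>
    pivot_longer(all_of(cond_cols), names_to = "condition", values_to = "raw") |>
    mutate(
      raw = str_trim(as.character(.data$raw)),
      censored = str_detect(.data$raw, "^<"),
      abundance = dplyr::if_else(
        .data$censored,
        suppressWarnings(as.numeric(sub("^<\\s*", "", .data$raw))) / 2,
        suppressWarnings(as.numeric(.data$raw))
      )
    )
  if (any(is.na(long$abundance))) {
    bad <- long |> filter(is.na(.data$abundance))
    abort(sprintf("Unparseable abundance cell(s), e.g. otu '%s' condition '%s'.",
                  bad$otu_id[1], bad$condition[1]),
          class = "siptrflp_error_schema")
  }
  if (any(long$abundance < 0)) {
    abort("Abundances must be non-negative.", class = "siptrflp_error_validation")
  }
  tot <- long |> group_by(.data$condition) |>
    summarise(s = sum(.data$abundance), .groups = "drop")
  if (any(tot$s > 100 + 1e-6)) {
    abort("Per-condition abundances exceed 100%.", class = "siptrflp_error_validation")
  }
  for (m in setdiff(meta, names(long))) long[[m]] <- NA_character_
  long |> select(all_of(meta), "condition", "abundance", "censored")
}

#' Filter OTUs by a minimum abundance floor
#'
#' Keeps OTUs whose (non-censored) abundance strictly exceeds `floor_percent`
#' in at least one condition -- the "any condition" rule, matching tables
#' that print censored `<floor` cells for OTUs retained because they exceed
#' the floor elsewhere. Idempotent at a fixed floor.
#'
#' @param profile Long community profile ([read_community_profile()]).
#' @param floor_percent Abundance floor in percent (default 0.1).
#' @return Filtered community profile (all conditions kept for retained
#'   OTUs).
#' @export
filter_min_abundance <- function(profile, floor_percent = 0.1) {
  stopifnot(floor_percent >= 0)
  keep <- profile |>
    group_by(.data$otu_id) |>
    summarise(keep = any(.data$abundance > floor_percent & !.data$censored),
              .groups = "drop") |>
    filter(.data$keep)
  profile |> filter(.data$otu_id %in% keep$otu_id)
}

#' Summed abundance of the k most abundant OTUs per condition
#'
#' @param profile Long community profile.
#' @param k Number of top OTUs (>= 1). If a condition has fewer OTUs, all are
#'   summed.
#' @return Tibble `condition`, `top_k_sum` (percent).
#' @examples
#' \dontrun{top_k_sum(profile, k = 4)}
#' @export
top_k_sum <- function(profile, k = 4) {
  if (k < 1) {
    abort("`k` must be >= 1.", class = "siptrflp_error_input")
  }
  profile |>
    group_by(.data$condition) |>
    arrange(desc(.data$abundance), .by_group = TRUE) |>
    slice(seq_len(min(k, dplyr::n()))) |>
    summarise(top_k_sum = sum(.data$abundance), .groups = "drop")
}

#' Across-condition abundance range of one OTU
#'
#' @param profile Long community profile covering all conditions of
#'   interest.
#' @param otu_id OTU identifier; must be present in every condition.
#' @return One-row tibble `otu_id`, `min_percent`, `max_percent`.
#' @export
dominant_abundance_range <- function(profile, otu_id) {
  rows <- profile |> filter(.data$otu_id == !!otu_id)
  conds <- unique(profile$condition)
  if (!all(conds %in% rows$condition)) {
    abort(sprintf("OTU '%s' is missing from condition(s): %s", otu_id,
                  paste(setdiff(conds, rows$condition), collapse = ", ")),
          class = "siptrflp_error_key")
  }
  tibble(otu_id = otu_id,
         min_percent = min(rows$abundance),
         max_percent = max(rows$abundance))
}
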