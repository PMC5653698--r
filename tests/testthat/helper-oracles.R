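# Independent oracles and small fixture builders used across tests.

# Brute-force terminal-fragment oracle: check every window against the site.
oracle_trf <- function(seq, site, cut_offset) {
  seq <- toupper(seq)
  n <- nchar(seq)
  L <- nchar(site)
  if (n < L) return(NA_integer_)
  for (s in seq_len(n - L + 1)) {
    if (substr(seq, s, s + L - 1) == site) return(as.integer(s + cut_offset - 1))
  }
  NA_integer_
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Minimal valid fraction table: three fractions, densities descending in index.
toy_fractions <- function(condition = "U",
                          densities = c(1.76, 1.75, 1.74),
                          copies = c(1e5, 4e5, 2e5)) {
  tibble::tibble(
    condition = condition,
    fraction_index = seq_along(densities),
    refractive_index = ri_from_density(densities),
    buoyant_density = densities,
    total_16S_copies = copies
  )
}

toy_peaks <- function(condition = "U", fraction_index, enzyme = "HhaI",
                      length_bp, fluorescence) {
  tibble::tibble(condition = condition, fraction_index = fraction_index,
                 enzyme = enzyme, length_bp = length_bp,
                 fluorescence = fluorescence)
}

table1_path <- function() {
  system.file("extdata", "voc_consortium_otus.csv", package = "siptrflp")
}

table2_path <- function() {
  system.file("extdata", "observed_expected_trfs.csv", package = "siptrflp")
}

# Prediction table for the example community's true fragments.
example_predictions <- function() {
  tt <- attr(example_community(), "true_trfs")
  tibble::tibble(
    sequence_id = tt$taxon_id, enzyme = tt$enzyme,
    expected_length_bp = tt$true_length_bp, annotation = tt$taxon_id
  )
}
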