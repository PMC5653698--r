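test_that("terminal fragment length is the first-site cut position", {
  expect_identical(terminal_fragment_length("AAAAGCGCTT", "HhaI"), 7L)
  expect_identical(terminal_fragment_length("TTCCGGAA", "MspI"), 3L)
  expect_identical(terminal_fragment_length("AAAATTTT", "HhaI"), NA_integer_)
  expect_identical(terminal_fragment_length("GCGC", "HhaI"), 3L)  # site at pos 1
  expect_error(terminal_fragment_length("ACGU", "HhaI"),
               class = "siptrflp_error_parse")
  expect_error(terminal_fragment_length("ACG", "HhaI"),
               class = "siptrflp_error_input")
})

test_that("ambiguity codes never produce a cut and are reported", {
  # GCGN does not match GCGC; the first exact site downstream wins
  expect_message(
    out <- terminal_fragment_length("AAGCGNAAGCGCAA", "HhaI"),
    "ambiguity"
  )
  expect_identical(out, 11L)
  expect_identical(terminal_fragment_length("NNNN", "HhaI", quiet = TRUE),
                   NA_integer_)
})

test_that("digestion agrees with a brute-force window oracle on random sequences", {
  set.seed(42)
  enz <- sip_enzymes()
  for (i in 1:500) {
    s <- random_dna(sample(50:1500, 1))
    e <- enz[sample(1:2, 1), ]
    expect_identical(terminal_fragment_length(s, e),
                     oracle_trf(s, e$site, e$cut_offset))
  }
})

test_that("appending bases past the first cut never changes the fragment", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste0(random_dna(60), "GCGC", random_dna(10))
    before <- terminal_fragment_length(s, "HhaI")
    after <- terminal_fragment_length(paste0(s, random_dna(200)), "HhaI")
    expect_identical(before, after)
  }
})

test_that("prediction tables cover every sequence x enzyme pair, keeping non-cutters", {
  p <- predict_trf_table(c(a = "AAAAGCGCTTCCGGAA"))
  expect_identical(nrow(p), 2L)
  expect_identical(p$expected_length_bp[p$enzyme == "HhaI"], 7L)
  expect_identical(p$expected_length_bp[p$enzyme == "MspI"], 11L)

  p2 <- predict_trf_table(c(x = "AAGCGCAA"))  # no MspI site
  expect_identical(p2$expected_length_bp[p2$enzyme == "MspI"], NA_integer_)
  expect_error(predict_trf_table(character(0)), class = "siptrflp_error_input")
})

test_that("prediction reads FASTA files and agrees with the oracle", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  set.seed(3)
  seqs <- replicate(5, random_dna(300))
  writeLines(c(rbind(paste0(">clone", 1:5), seqs)), fa)
  p <- predict_trf_table(fa)
  expect_identical(nrow(p), 10L)
  enz <- sip_enzymes()
  for (i in seq_len(nrow(p))) {
    e <- enz[enz$enzyme == p$enzyme[i], ]
    expect_identical(p$expected_length_bp[i],
                     oracle_trf(seqs[match(p$sequence_id[i], paste0("clone", 1:5))],
                                e$site, e$cut_offset))
  }
})

test_that("peak proportions normalize fluorescence with a relative floor", {
  expect_equal(
    peak_proportions(toy_peaks("U", 1, "HhaI", 337, 1000))$proportion, 1
  )
  p <- peak_proportions(
    tibble::tibble(length_bp = c(337, 398), fluorescence = c(300, 700))
  )
  expect_equal(p$proportion, c(0.3, 0.7))
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)

  # a peak at exactly the 0.5% floor is retained
  pb <- peak_proportions(
    tibble::tibble(length_bp = c(337, 500), fluorescence = c(995, 5))
  )
  expect_equal(pb$proportion, c(0.995, 0.005))
  # just below the floor it is removed before renormalisation
  pc <- peak_proportions(
    tibble::tibble(length_bp = c(337, 500), fluorescence = c(996, 4))
  )
  expect_equal(pc$proportion, 1)
  expect_error(
    peak_proportions(tibble::tibble(length_bp = 1, fluorescence = 0)),
    class = "siptrflp_error_degenerate"
  )
})

test_that("greedy binning anchors at the smallest member and splits wide chains", {
  b <- bin_lengths(c(337, 341), tolerance_bp = 5)
  expect_identical(unique(b$representative_length_bp), 337L)
  expect_identical(nrow(bin_lengths(100)), 1L)
  b2 <- bin_lengths(c(100, 105, 110), tolerance_bp = 5)
  expect_identical(b2$representative_length_bp, c(100L, 100L, 110L))
  expect_identical(nrow(bin_lengths(integer(0))), 0L)
})

test_that("binning is order-invariant and members stay within tolerance of the anchor", {
  set.seed(9)
  for (i in 1:20) {
    lens <- sample(50:900, 40, replace = TRUE)
    tol <- sample(0:5, 1)
    b1 <- bin_lengths(lens, tol)
    b2 <- bin_lengths(sample(lens), tol)
    expect_identical(b1, b2)
    expect_true(all(b1$length_bp - b1$representative_length_bp <= tol))
    expect_true(all(b1$length_bp >= b1$representative_length_bp))
  }
})

test_that("fractional capillary lengths are rounded half-up with a warning", {
  expect_warning(b <- bin_lengths(c(336.5, 341.2)),
                 class = "siptrflp_warning_rounding")
  expect_identical(b$length_bp, c(337L, 341L))
})

test_that("affiliation reproduces the observed/expected clone pairs", {
  pairs <- readr::read_csv(table2_path(), show_col_types = FALSE)
  hypho <- pairs[pairs$culture == "AE/AE-13D", ]
  prop <- pairs[pairs$culture == "AE/AE-13B", ]
  pred_h <- tibble::tibble(sequence_id = hypho$clone_id, enzyme = hypho$enzyme,
                           expected_length_bp = hypho$expected_length_bp,
                           annotation = hypho$annotation)
  pred_p <- tibble::tibble(sequence_id = prop$clone_id, enzyme = prop$enzyme,
                           expected_length_bp = prop$expected_length_bp,
                           annotation = prop$annotation)
  # Hyphomicrobium clone: observed 337/398 vs expected 341/403 at tol 5
  hit <- affiliate(c(HhaI = 337, MspI = 398), pred_h)
  expect_identical(unique(hit$sequence_id), "AE/AE-13D-05-001")
  expect_identical(sort(hit$abs_diff_bp), c(4L, 5L))
  # Propioniferax clone: observed 352/154 vs expected 355/158
  hit2 <- affiliate(c(HhaI = 352, MspI = 154), pred_p)
  expect_identical(unique(hit2$sequence_id), "AE/AE-13B-07-011")
  # far-off observation matches neither clone
  none <- affiliate(c(HhaI = 200, MspI = 300), dplyr::bind_rows(pred_h, pred_p))
  expect_identical(nrow(none), 0L)
  expect_error(affiliate(c(BstUI = 100), pred_h), class = "siptrflp_error_config")
})

test_that("affiliation is symmetric in enzymes and monotone in tolerance", {
  pred <- tibble::tibble(
    sequence_id = "cl", enzyme = c("HhaI", "MspI"),
    expected_length_bp = c(341L, 403L), annotation = NA_character_
  )
  a1 <- affiliate(c(HhaI = 337, MspI = 398), pred)
  a2 <- affiliate(c(MspI = 398, HhaI = 337), pred)
  expect_identical(a1, a2)
  for (tol in 0:10) {
    hit_t <- nrow(affiliate(c(HhaI = 337, MspI = 398), pred,
                            affiliation_params(tolerance_bp = tol))) > 0
    if (tol >= 5) expect_true(hit_t) else expect_false(hit_t)
  }
})

test_that("tied candidates are reported as ambiguous, not broken", {
  pred <- tibble::tibble(
    sequence_id = c("a", "a", "b", "b"),
    enzyme = rep(c("HhaI", "MspI"), 2),
    expected_length_bp = c(340L, 400L, 340L, 400L),
    annotation = NA_character_
  )
  hits <- affiliate(c(HhaI = 338, MspI = 399), pred)
  expect_true(all(hits$ambiguous))
  expect_identical(unique(hits$rank), 1L)
})
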