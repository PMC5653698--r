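test_that("T-RF copy numbers scale proportions by the fraction total", {
  p <- tibble::tibble(length_bp = c(337L, 398L), proportion = c(0.5, 0.5))
  expect_equal(trf_copy_numbers(p, 1e6)$copies, c(5e5, 5e5))
  p2 <- tibble::tibble(length_bp = c(337L, 398L), proportion = c(0.3, 0.7))
  expect_equal(trf_copy_numbers(p2, 2e6)$copies, c(6e5, 1.4e6))
  expect_equal(trf_copy_numbers(p, 0)$copies, c(0, 0))
  expect_error(trf_copy_numbers(p, -1), class = "siptrflp_error_input")
  expect_error(trf_copy_numbers(tibble::tibble(length_bp = 1, proportion = 0.5), 1),
               class = "siptrflp_error_input")
})

test_that("max-normalisation makes the largest value exactly 1", {
  expect_equal(normalize_by_max(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  expect_identical(max(normalize_by_max(c(2, 4, 8))), 1)
  expect_equal(normalize_by_max(7), 1)
  expect_error(normalize_by_max(c(0, 0)), class = "siptrflp_error_degenerate")
  expect_error(normalize_by_max(c(-1, 1)), class = "siptrflp_error_input")
})

test_that("distributions assemble proportions, qPCR totals and normalisation per fraction", {
  fr <- toy_fractions()  # densities 1.76, 1.75, 1.74; copies 1e5, 4e5, 2e5
  pk <- toy_peaks("U", fraction_index = 1:3, length_bp = 341,
                  fluorescence = c(500, 500, 500))
  d <- build_distribution(fr, pk, 341L, "HhaI")
  expect_equal(d$normalized, c(0.5, 1.0, 0.25))  # sorted by density ascending
  expect_equal(d$buoyant_density, c(1.74, 1.75, 1.76))
  expect_s3_class(d, "trf_distribution")

  # a fraction without the bin contributes zero
  pk2 <- toy_peaks("U", fraction_index = c(1, 2), length_bp = 341,
                   fluorescence = c(500, 500))
  d2 <- build_distribution(fr, pk2, 341L, "HhaI")
  expect_equal(d2$copies[d2$buoyant_density == 1.74], 0)

  # single-fraction support: 1 there, 0 elsewhere
  pk3 <- toy_peaks("U", fraction_index = 2, length_bp = 341, fluorescence = 10)
  d3 <- build_distribution(fr, pk3, 341L, "HhaI")
  expect_equal(d3$normalized, c(0, 1, 0))

  # bin absent everywhere: degenerate via normalisation
  expect_error(build_distribution(fr, pk, 999L, "HhaI"),
               class = "siptrflp_error_degenerate")
  expect_error(build_distribution(fr, pk, 341L, "MspI"),
               class = "siptrflp_error_config")
})

test_that("per-fraction copies across all bins conserve the qPCR total", {
  set.seed(21)
  fr <- toy_fractions(copies = c(2e5, 8e5, 3e5))
  pk <- toy_peaks("U", fraction_index = rep(1:3, each = 3),
                  length_bp = rep(c(120L, 341L, 560L), 3),
                  fluorescence = runif(9, 100, 1000))
  dists <- lapply(c(120L, 341L, 560L), function(b)
    build_distribution(fr, pk, b, "HhaI", floor = 0))  # no floor filtering
  total_by_fraction <- Reduce(`+`, lapply(dists, function(d) d$copies))
  # distributions are density-ascending; fractions are density-descending
  expect_equal(total_by_fraction, rev(fr$total_16S_copies), tolerance = 1e-6)
})

test_that("weighted mean density averages raw copies over fractions", {
  d <- trf_distribution(c(1.747, 1.75, 1.76), c(10, 0, 0))
  expect_equal(weighted_mean_density(d), 1.747)
  d2 <- trf_distribution(c(1.72, 1.76), c(5, 5))
  expect_equal(weighted_mean_density(d2), 1.74)
  d3 <- trf_distribution(c(1.72, 1.76), c(1, 3))
  expect_equal(weighted_mean_density(d3), 1.75)
})

test_that("peak density is the modal fraction, ties broken toward heavier", {
  d <- trf_distribution(c(1.727, 1.738, 1.749), c(1, 2, 8))
  expect_equal(peak_fraction_density(d), 1.749)
  tie <- trf_distribution(c(1.727, 1.749), c(5, 5))
  expect_equal(peak_fraction_density(tie), 1.749)
  fr <- toy_fractions()
  pk <- toy_peaks("U", 1:3, length_bp = 341, fluorescence = c(1, 1, 1))
  expect_equal(peak_fraction_density(build_distribution(fr, pk, 341L, "HhaI")),
               1.75)  # middle fraction holds the max copies
})

test_that("shift detection compares peak densities and heavy-fraction mass", {
  rho <- seq(1.705, 1.771, by = 0.011)  # grid holds 1.727 and 1.749 exactly
  shape <- function(center) dnorm(rho, center, 0.006)
  unl <- trf_distribution(rho, shape(1.727), condition = "U", enzyme = "HhaI",
                          representative_length_bp = 352L)
  lab <- trf_distribution(rho, shape(1.749), condition = "L", enzyme = "HhaI",
                          representative_length_bp = 352L)

  same <- detect_shift(unl, unl)
  expect_false(same$shifted)
  expect_equal(same$heavy_ratio, 1, tolerance = 1e-9)

  res <- detect_shift(lab, unl)
  expect_true(res$shifted)
  expect_equal(res$peak_shift, 0.022, tolerance = 1e-9)
  expect_gt(res$heavy_ratio, 1)

  # all labeled mass heavy, all unlabeled light -> infinite heavy ratio
  lab2 <- trf_distribution(c(1.70, 1.75), c(0, 1))
  unl2 <- trf_distribution(c(1.70, 1.75), c(1, 0))
  res2 <- detect_shift(lab2, unl2)
  expect_identical(res2$heavy_ratio, Inf)
  expect_true(res2$shifted)

  # non-overlapping grids cannot be paired
  far <- trf_distribution(c(1.80, 1.81, 1.82), c(1, 2, 1))
  expect_error(detect_shift(far, unl), class = "siptrflp_error_pairing")
})

test_that("detect_shift(x, x) never fires across random distributions", {
  set.seed(33)
  rho <- seq(1.69, 1.775, by = 0.005)
  for (i in 1:25) {
    x <- trf_distribution(rho, runif(length(rho)))
    r <- detect_shift(x, x)
    expect_false(r$shifted)
    expect_equal(r$peak_shift, 0)
  }
})

test_that("distributions are invariant to overall copy-number scale", {
  set.seed(5)
  fr <- toy_fractions()
  pk <- toy_peaks("U", 1:3, length_bp = 341, fluorescence = runif(3, 10, 100))
  d1 <- build_distribution(fr, pk, 341L, "HhaI")
  fr2 <- fr
  fr2$total_16S_copies <- fr2$total_16S_copies * 37.5
  d2 <- build_distribution(fr2, pk, 341L, "HhaI")
  expect_equal(d1$normalized, d2$normalized, tolerance = 1e-12)
  expect_equal(peak_fraction_density(d1), peak_fraction_density(d2))
  expect_equal(weighted_mean_density(d1), weighted_mean_density(d2),
               tolerance = 1e-12)
})
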