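test_that("band centers follow the GC and labeling density model", {
  expect_equal(taxon_band_center(0.5, 0), 1.709)
  expect_equal(taxon_band_center(0.684, 0), 1.727032, tolerance = 1e-9)
  expect_equal(taxon_band_center(0.684, 0.61), 1.748992, tolerance = 1e-9)
  expect_error(taxon_band_center(1.2, 0), class = "siptrflp_error_input")
  expect_error(taxon_band_center(0.5, -0.1), class = "siptrflp_error_input")
})

test_that("gradient simulation conserves mass and is reproducible", {
  comm <- example_community()
  g1 <- simulate_gradient(comm, seed = 4)
  g2 <- simulate_gradient(comm, seed = 4)
  expect_identical(g1, g2)
  g3 <- simulate_gradient(comm, seed = 5)
  expect_false(identical(g1$total_16S_copies, g3$total_16S_copies))

  # noise-free per-taxon masses sum to the taxon's abundance
  tm <- attr(g1, "taxon_masses")
  sums <- tapply(tm$mass, tm$taxon_id, sum)
  expect_equal(as.vector(sums[comm$taxon_id]), comm$relative_abundance,
               tolerance = 1e-9)
  # fraction index 1 is the heaviest fraction
  expect_equal(g1$buoyant_density[g1$fraction_index == 1],
               max(g1$buoyant_density))
})

test_that("a vanishing band width puts all mass in the nearest fraction", {
  comm <- tibble::tibble(taxon_id = "t", gc_fraction = 0.684,
                         relative_abundance = 1, atom_frac_13C = 0)
  g <- simulate_gradient(comm, sim_params(band_sigma = 0), seed = 1)
  tm <- attr(g, "taxon_masses")
  expect_identical(sum(tm$mass > 0), 1L)
  hit <- g$buoyant_density[g$fraction_index == tm$fraction_index[tm$mass > 0]]
  expect_equal(hit, 1.725, tolerance = 1e-9)  # nearest grid center to 1.727
})

test_that("a band center far outside the grid triggers a truncation warning", {
  comm <- tibble::tibble(taxon_id = "t", gc_fraction = 0.05,
                         relative_abundance = 1, atom_frac_13C = 0)
  expect_warning(simulate_gradient(comm, seed = 1),
                 class = "siptrflp_warning_truncation")
})

test_that("simulated peaks track taxon masses with bounded sizing error", {
  comm <- example_community()
  ex <- simulate_sip_experiment(comm, seed = 2)
  truth <- ex$true_trfs
  errs <- ex$length_errors
  expect_true(all(abs(errs$error_bp) <= sim_params()$len_error_max))
  # every observed peak length is within 4 bp of some true fragment
  obs <- unique(ex$peaks$length_bp)
  expect_true(all(vapply(obs, function(l)
    min(abs(l - truth$true_length_bp)) <= 4, logical(1))))
  # sizing error is shared between conditions: identical length sets
  l_lab <- sort(unique(ex$peaks$length_bp[ex$peaks$condition == "labeled"]))
  l_unl <- sort(unique(ex$peaks$length_bp[ex$peaks$condition == "unlabeled"]))
  expect_identical(l_lab, l_unl)

  # zero sizing error reproduces the true lengths exactly
  ex0 <- simulate_sip_experiment(comm, sim_params(len_error_sd = 0), seed = 2)
  expect_identical(sort(unique(ex0$peaks$length_bp)),
                   sort(unique(truth$true_length_bp)))
})

test_that("co-migrating fragments merge their fluorescence", {
  comm <- tibble::tibble(
    taxon_id = c("a", "b"), gc_fraction = c(0.5, 0.5),
    relative_abundance = c(0.5, 0.5), atom_frac_13C = 0
  )
  trfs <- tibble::tibble(taxon_id = rep(c("a", "b"), each = 2),
                         enzyme = rep(c("HhaI", "MspI"), 2),
                         true_length_bp = c(341L, 200L, 343L, 300L))
  g <- simulate_gradient(comm, sim_params(len_error_sd = 0), seed = 3)
  # force the two HhaI fragments onto the same observed length
  errs <- tibble::tibble(taxon_id = rep(c("a", "b"), each = 2),
                         enzyme = rep(c("HhaI", "MspI"), 2),
                         true_length_bp = c(341L, 200L, 343L, 300L),
                         error_bp = c(1, 0, -1, 0))
  pk <- simulate_trflp(g, comm, params = sim_params(), true_trfs = trfs,
                       length_errors = errs)
  h <- pk[pk$enzyme == "HhaI", ]
  expect_identical(unique(h$length_bp), 342L)
  m <- pk[pk$enzyme == "MspI", ]
  # merged fluorescence equals the sum of the separate fragments
  f1 <- sum(h$fluorescence[h$fraction_index == 10])
  f2 <- sum(m$fluorescence[m$fraction_index == 10])
  expect_equal(f1, f2, tolerance = 1e-9)
  # a missing true fragment is a configuration error
  expect_error(simulate_trflp(g, comm, true_trfs = trfs[-1, ]),
               class = "siptrflp_error_config")
})

test_that("planted-site sequences digest to the requested fragments", {
  set.seed(14)
  for (i in 1:10) {
    trf <- c(HhaI = sample(60:500, 1), MspI = sample(60:500, 1))
    if (abs(trf[1] - trf[2]) < 10) next
    s <- simulate_taxon_sequence(trf, gc = runif(1, 0.4, 0.7))
    expect_identical(terminal_fragment_length(s, "HhaI"), unname(as.integer(trf["HhaI"])))
    expect_identical(terminal_fragment_length(s, "MspI"), unname(as.integer(trf["MspI"])))
  }
})

test_that("sequence-bearing communities flow through the experiment", {
  seqs <- c(
    simulate_taxon_sequence(c(HhaI = 341, MspI = 403), gc = 0.66, seed = 21),
    simulate_taxon_sequence(c(HhaI = 204, MspI = 491), gc = 0.71, seed = 22)
  )
  comm <- tibble::tibble(
    taxon_id = c("lab", "ref"), sequence = seqs,
    relative_abundance = c(0.5, 0.5), atom_frac_13C = c(0.6, 0)
  )
  ex <- simulate_sip_experiment(comm, sim_params(len_error_sd = 0), seed = 9)
  expect_setequal(unique(ex$peaks$length_bp), c(341L, 403L, 204L, 491L))
})

test_that("degradation follows lag-then-first-order kinetics", {
  s <- simulate_degradation(times = 0:11)
  expect_equal(s$concentration[s$day == 0], rep(30, 3))  # 30 mg/L at t = 0
  k0 <- degradation_kinetics(compound = "x", lag_days = 2, rate_per_day = 0)
  expect_equal(simulate_degradation(k0, 0:5)$concentration, rep(30, 6))
  k <- degradation_kinetics(compound = "x", lag_days = 2, rate_per_day = 0.5)
  s2 <- simulate_degradation(k, 0:4)
  expect_equal(s2$concentration[s2$day == 4], 30 * exp(-1), tolerance = 1e-9)
  expect_error(simulate_degradation(k, c(-1, 0, 1)), class = "siptrflp_error_input")
  expect_error(degradation_kinetics(rate_per_day = -1), class = "siptrflp_error_input")
})

test_that("maximum interval rate finds the steepest drop between samples", {
  s <- tibble::tibble(day = 0:4, concentration = c(30, 30, 30, 30, 18.1))
  r <- max_interval_rate(s)
  expect_equal(r$max_rate_mg_L_day, 11.9, tolerance = 1e-9)
  expect_equal(c(r$interval_start, r$interval_end), c(3, 4))
  flat <- tibble::tibble(day = 0:3, concentration = rep(30, 4))
  expect_equal(max_interval_rate(flat)$max_rate_mg_L_day, 0)
  up <- tibble::tibble(day = 0:2, concentration = c(10, 20, 30))
  expect_warning(r2 <- max_interval_rate(up),
                 class = "siptrflp_warning_degenerate")
  expect_lt(r2$max_rate_mg_L_day, 0)
  expect_error(max_interval_rate(tibble::tibble(day = 1, concentration = 1)),
               class = "siptrflp_error_input")
})

test_that("sampling day is the first within the degraded-fraction window", {
  s <- tibble::tibble(day = 0:5, concentration = c(30, 30, 28, 20, 7.5, 2))
  expect_equal(sampling_day(s)$sampling_day, 4)  # 75% degraded on day 4
  expect_equal(sampling_day(s, c(0, 1))$sampling_day, 1)  # first day after t0
  skip <- tibble::tibble(day = 0:2, concentration = c(30, 18, 4.5))
  expect_warning(r <- sampling_day(skip),
                 class = "siptrflp_warning_window_skipped")
  expect_equal(r$sampling_day, 2)
  never <- tibble::tibble(day = 0:3, concentration = c(30, 29, 28, 27))
  expect_error(sampling_day(never), class = "siptrflp_error_not_reached")
})

test_that("default kinetics reach the harvest window on the expected days", {
  s <- simulate_degradation(times = 0:11)
  d <- sampling_day(s)
  expect_equal(d$sampling_day[d$compound == "DCM"], 4)
  expect_equal(d$sampling_day[d$compound == "benzene"], 6)
  expect_equal(d$sampling_day[d$compound == "toluene"], 7)
  # degraded fractions at harvest sit mid-window
  expect_true(all(d$degraded_fraction >= 0.5 & d$degraded_fraction <= 0.8))
  r <- max_interval_rate(s)
  expect_equal(r$interval_start[r$compound == "DCM"], 3)
  expect_equal(r$interval_end[r$compound == "DCM"], 4)
})
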