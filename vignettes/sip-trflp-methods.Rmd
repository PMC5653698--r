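---
title: "Methods: SIP/T-RFLP density-shift analysis and its synthetic data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIP/T-RFLP density-shift analysis and its synthetic data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siptrflp)
library(dplyr)
```

## The problem and the measurement model

DNA stable-isotope probing (DNA-SIP) identifies which members of a microbial
community assimilate a particular carbon source. The community is fed a
^13^C-labeled substrate; organisms that build the labeled carbon into DNA
produce measurably heavier genomes. Total DNA is centrifuged to equilibrium
in a CsCl gradient, the gradient is divided into fractions (18 in the
experimental design this package mirrors; fraction 1 is the heaviest,
collected first from the tube bottom), and each fraction is characterised
three ways:

* its **buoyant density**, from the refractive index via the linear
  calibration $\rho = a\,\eta - b$ with $a = 10.9276$, $b = 13.593$ valid at
  20&nbsp;°C (`density_from_ri()`; the constants are a configuration object
  because they are temperature specific);
* its **total bacterial 16S rRNA gene copies**, by TaqMan qPCR against a
  serial ten-fold dilution standard curve (`fit_standard_curve()`,
  `copies_from_cq()`);
* its **community fingerprint**, by T-RFLP: 16S amplicons end-labeled at the
  27F primer, digested separately with HhaI (GCG^C) and MspI (C^CGG), and the
  terminal fragments sized on a capillary. The proportion of each terminal
  restriction fragment (T-RF) is its share of total peak fluorescence
  (`peak_proportions()`).

For one T-RF and one condition, the per-fraction copy number is
$c_i = p_i N_i$ (proportion times the fraction's qPCR total), and the curve
plotted against density is $c_i / \max_i c_i$ (`build_distribution()`,
`normalize_by_max()`). Max-normalisation is applied **per T-RF within one
condition** — each curve's own maximum is 1. The alternative reading
(normalising both conditions of a figure panel jointly) cannot be excluded
from the source wording, but per-curve normalisation is the convention such
figures follow and is what the shift statistic below assumes.

## Shift detection

A fragment whose carriers assimilated the labeled substrate moves toward
heavier fractions. `detect_shift()` compares a labeled against an unlabeled
distribution using two statistics:

* the **peak (modal-fraction) density** difference, with ties broken toward
  the heavier fraction (`peak_fraction_density()`); no interpolation between
  fractions is attempted, because the measurement is intrinsically discrete;
* the **heavy-fraction ratio**: summed normalized copy number at densities
  $\ge$ 1.732 g/cm³ (labeled) over the same sum (unlabeled). 1.732 g/cm³ is
  the boundary above which labeled DNA accumulated in the motivating
  experiment; it is a tunable parameter of `shift_params()`.

A bin is *shifted* when the peak moves by at least `min_peak_shift`
(default 0.004 g/cm³, about one fraction spacing) **and** the heavy ratio
exceeds 1. The weighted-mean density (`weighted_mean_density()`, computed on
raw copies) is reported as a continuous effect size. The two conditions'
density grids are paired by nearest density within 0.002 g/cm³ rather than
by fraction index, since two gradients are never bit-identical. No
significance test is attached: with one gradient per condition there is no
replication to test over, and the original analysis makes none either.

Bins present in only one condition cannot be compared — the max-normalized
distribution of an all-zero series is undefined — and are reported with
`shifted = NA` rather than being guessed at.

## Fragment prediction, binning and affiliation

`terminal_fragment_length()` scans the labeled strand 5'→3' for the first
exact occurrence of the recognition site and returns the cut position
(site start + cut offset), so the fragment length includes the labeled
primer — the convention under which in-silico lengths are comparable to
capillary size calls. IUPAC ambiguity codes are legal in a query but never
match a site: a conservative choice that avoids phantom cuts in low-quality
clone reads (skipped windows are counted and reported).

Observed capillary lengths carry a systematic sizing error of up to ~5 bp.
Two consequences:

* **Binning** (`bin_lengths()`): unique observed lengths are grouped
  greedily, anchored at the smallest member, opening a new bin when a length
  exceeds the anchor by more than 5 bp. This is deterministic and
  order-independent, unlike single-linkage clustering; its documented
  limitation is that a chain of lengths wider than the tolerance is split.
* **Affiliation** (`affiliate()`): a clone sequence is a candidate for an
  observed fragment when |observed − expected| ≤ 5 bp for every enzyme
  observed. The comparison is *inclusive*: the published worked example
  classifies an observed 398 bp fragment with an expected 403 bp fragment —
  a difference of exactly 5 — so a strict `< 5` rule would not reproduce it.
  Candidates are ranked by total absolute difference; exact ties are
  reported as ambiguous, never broken arbitrarily. No correction for
  systematic capillary size-calling bias is applied (whether the published
  lengths were corrected is unknown; we take them as printed).

## The synthetic data generator

Because no raw gradient, electropherogram or qPCR data are deposited for
this kind of experiment, the package ships a forward simulator
(`simulate_sip_experiment()`) whose defaults *are* the study conditions the
analysis assumes. What it emulates:

* **Band centers.** An unlabeled genome bands at
  $\rho = 1.660 + 0.098\,\mathrm{GC}$ g/cm³, and full ^13^C labeling adds
  0.036 g/cm³, scaled by the atom-fraction excess assimilated. These are
  standard CsCl SIP relationships adopted as simulator *assumptions* (the
  motivating experiment states no density model); they are configuration,
  not constants. With GC 0.684 they place an unlabeled band at 1.727 g/cm³
  and, at atom fraction 0.61, a labeled band at 1.749 g/cm³ — the two
  printed peak densities. The atom fraction is a free parameter: no
  quantitative labeling efficiency is published, so the 1.727 → 1.749
  reproduction fixes it by construction, not by inference.
* **Banding.** Each taxon's DNA mass is spread over the fraction grid
  proportional to a Gaussian (sd `band_sigma` = 0.005 g/cm³) evaluated at
  the fraction centers and renormalized, conserving mass exactly before
  noise. The 18 fraction centers are equally spaced on 1.690–1.775 g/cm³, a
  grid spanning every density the motivating experiment prints
  (1.727–1.749, threshold 1.732). Real gradients are non-linear in
  collection order; the grid is caller-overridable. The *true* center
  density is stored per fraction, and the measurement noise (sd 10⁻⁴
  refractive-index units ≈ 0.0011 g/cm³) lives in the refractive-index
  readout; ingestion from CSV recomputes density from η when no density
  column is present.
* **T-RFLP.** One peak per taxon per fraction and enzyme, fluorescence
  proportional to DNA mass. The sizing error is Gaussian (sd 1.5 bp),
  hard-clipped at ±4 bp — so simulated data never violate the 5-bp
  affiliation tolerance by construction (set `len_error_max = Inf` for
  robustness testing) — rounded to integer bp, and drawn **once per
  fragment per experiment**: capillary migration bias is fragment-specific
  and reproducible across lanes, which is why the same fragment is called,
  e.g., 337 bp in every fraction and condition of a run. Optional iid
  per-peak jitter is available (`peak_jitter_sd`, default 0). Co-migrating
  fragments merge their fluorescence.
* **qPCR.** Per-fraction totals are perturbed lognormally (sd 0.1,
  approximating triplicate TaqMan variability); dilution series follow a
  slope −3.3219 / intercept 40 line with Gaussian Cq noise (sd 0.1).
* **Degradation.** Three VOCs (DCM, benzene, toluene), each injected at
  30 mg/L, degrade with sequential lags then first-order decay
  (`simulate_degradation()`). The default lags (2.5, 4.5, 6.0 d) and rates
  (0.95, 0.95, 0.72 d⁻¹) were chosen once so that daily sampling reaches the
  50–80 % degraded harvest window (`sampling_day()`) on days 4, 6 and 7 with
  degraded fractions of 76 %, 76 % and 51 % — the published harvest
  schedule. A lag-plus-first-order curve cannot *simultaneously* reproduce
  the published maximum interval rates (it yields 11.4/11.4/15.4 versus
  11.9/11.9/13.4 mg L⁻¹ d⁻¹); the harvest-day anchors were prioritised and
  the discrepancy is inherent to the model family, not tuned away.

A single seed governs all randomness; every simulation is bit-reproducible.

### The example community

`example_community()` is a four-taxon consortium loosely patterned on a
VOC-degrading enrichment: a dominant taxon (50 %), two mid-abundance taxa,
and a 15 % *Hyphomicrobium*-like taxon that alone carries label (atom
fraction 0.61). Its GC fractions place the unlabeled band centers exactly
on fraction-grid centers (1.700, 1.710, 1.725, 1.730 g/cm³). This is a
deliberate property of the *test* community: when a band center falls
midway between two fraction centers, the modal fraction is decided by a
near-coin-flip under 10 % qPCR noise, and a one-fraction peak wobble is
indistinguishable from a minimal shift. Real communities enjoy no such
alignment, so the false-positive behaviour verified on this community
(unlabeled-vs-unlabeled comparisons flag a shift in ≤ 5 % of runs) is a
statement about these study conditions, not about arbitrary data; for
off-grid taxa the peak-shift criterion alone is less specific, which is why
it is conjoined with the heavy-ratio criterion.

## What the tests do and do not establish

The simulator reproduces the *statistical shape* of gradient/T-RFLP/qPCR
data: Gaussian banding, proportional fluorescence, bounded systematic
sizing error, lognormal qPCR noise. It does not emulate PCR amplification
bias, rRNA operon copy-number variation, isotope fractionation chemistry,
gradient formation physics, or non-linear fraction spacing. Passing the
parameter-recovery and end-to-end checks therefore shows the *computation*
is correct and well-conditioned under realistic noise — not that any given
field data set satisfies the assumptions.

Problem sizes used by the checks: 20 simulated experiments for
parameter recovery, 100 unlabeled-vs-unlabeled experiments for the
false-positive rate, 50 four-taxon experiments for end-to-end detection,
500 random sequences against the brute-force digestion oracle, and 1000
random densities for the conversion round-trip.

## Numerical and degenerate-input choices

* Conversion functions range-check their inputs (η ∈ [1.20, 1.50],
  ρ ∈ [1.60, 1.85]) and name the offending value; non-monotone density
  versus fraction index is a warning, not an error.
* An all-zero copy series has no defined distribution: error, never NaN.
* Peak-proportion floor: 0.5 % of total fluorescence, *retained* at exactly
  the floor (≥ keeps), configurable.
* Fractional capillary lengths are rounded half-up on read, with a warning.
* Modal-density ties break toward the heavier fraction (the conservative
  direction for shift calling is the unlabeled curve; breaking both the
  same way keeps `detect_shift(x, x)` exactly unshifted).
* `top_k_sum()` with fewer than *k* OTUs sums what exists; censored `<0.1`
  community-table cells are stored as 0.05 and flagged, never dropped —
  note that with the strict `> floor` retention rule, OTUs whose printed
  abundance equals the floor everywhere (rounded values) are filtered out.

## Limitations

* Shift calls are heuristic flags, not hypothesis tests.
* The greedy binning can split fragments whose observed lengths straddle a
  bin boundary across independently sized runs; within one experiment the
  shared-sizing-error model prevents this, mirroring same-batch capillary
  runs.
* Only exact recognition-site matching is implemented (no methylation
  sensitivity, no degenerate sites).
* Multi-isotope SIP (¹⁵N, ¹⁸O) and OTU clustering/taxonomy assignment are
  out of scope.
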