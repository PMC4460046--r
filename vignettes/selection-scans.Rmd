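---
title: "Element-partitioned selection scans: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element-partitioned selection scans: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Different classes of genomic elements — coding sequence, UTRs, introns,
small and long noncoding RNAs, pseudogenes, conserved noncoding
sequence, intergenic DNA — experience different selective regimes.
`ncsel` implements the standard battery of scans that make those
regimes visible in phased population polymorphism data, organised
around a partition of the genome into labelled element intervals and a
genome-wide background:

* **Site-frequency-spectrum (SFS) neutrality tests** per element class,
  in sliding windows over concatenated element sequence, with bootstrap
  means and permutation tests against the genome-wide background.
  Purifying selection skews the SFS toward rare alleles (negative
  Tajima's *D*, excess DAF ≤ 0.05); recent positive selection produces
  an excess of high-frequency derived alleles (negative Fay & Wu's
  *H*).
* **Allele-frequency differentiation**: per-SNP Weir–Cockerham
  F<sub>ST</sub> over populations, globally and pairwise over pooled
  groups.
* **Conservation classes**: per-base constraint scores thresholded at
  ≥ 2 and ≥ 3 partition sites into conserved/non-conserved, crossed
  with the rare-DAF fraction.
* **Haplotype structure**: EHH, integrated EHH, and standardized iHS
  per core SNP; |iHS| > 2 flags sweep-like local haplotype
  homozygosity.
* **A composite caller**: a site is called positively selected when at
  least two of DAF > 0.5, F<sub>ST</sub> > 0.3, |iHS| > 2 hold, and is
  annotated with genes overlapping or within 5 kb.

Everything runs end-to-end on a built-in coalescent generator, so the
whole pipeline is testable without any external download.

# Statistical machinery

## SFS statistics and their variance constants

For `n` haplotypes with `S` segregating sites, `pi_total` (mean
pairwise differences), Watterson's `theta_W = S/a1`, and the unfolded
spectrum `xi_i` (sites with derived count `i`):

* Tajima's `D = (pi_total − S/a1) / sqrt(e1*S + e2*S(S−1))` with the
  classical `e1`, `e2` constants.
* Fu & Li's star statistics use **minor-allele singletons** `eta_s`
  (derived count 1 or `n−1`), so they need no outgroup:
  `D* = ((n/(n−1))S − a1·eta_s)/sqrt(V)` and
  `F* = (pi_total − ((n−1)/n)·eta_s)/sqrt(V)`.
* Fay & Wu's `H = pi_total − theta_H`,
  `theta_H = Σ 2 i² xi_i / (n(n−1))`, computed over polarized sites
  only and reported **unnormalized**.

The variance constants of the starred statistics are a known source of
transcription errors (the originally printed constants contain typos,
corrected later in the literature). `ncsel` therefore does not
transcribe printed constants at all: any numerator of the form
`Σ c_i xi_i` with zero expectation has exact neutral-coalescent
variance `alpha·theta + beta·theta²`, where `alpha = Σ c_i²/i` and
`beta` follows from the second moments of the unfolded SFS (Fu 1995).
`sfs_constants(n)` evaluates these exactly and the test suite verifies
that the same machinery reproduces Tajima's published `e1`/`e2` to
1e-12, which validates the covariance code that the D*/F* constants
share. Estimated variances use `theta_hat = S/a1` and the unbiased
`theta2_hat = S(S−1)/(a1²+a2)`, the same convention Tajima's `D` uses.

Undefined statistics (`S = 0`; `n < 4` for the starred tests; no
polarized sites for `H`) are flagged `NA`, never coerced to zero, and
excluded from window means — zero-filling empty windows would bias
bootstrap means toward 0.

## Windows, bootstrap, permutation

Element sequence is concatenated in genomic order onto a gapless axis;
windows are `[k·5000, k·5000 + 10000)` and terminal partial windows
are **dropped** rather than rescaled, keeping the length denominator
constant across windows. Bootstrap means resample windows with
replacement (1000 reps). The permutation test pools element and
background window values, reshuffles labels preserving group sizes
(default 10,000 reps), and reports the two-sided
`P = (1 + #{|Δperm| ≥ |Δobs|}) / (n_perm + 1)`; the +1 correction keeps
P strictly positive, and a one-sided variant is available behind a
flag. Window-level (rather than site-level) resampling is an
interpretation choice: windows are the exchangeable units whose means
the comparison is about.

## Weir–Cockerham F<sub>ST</sub>

Inputs are phased haplotypes, so the estimator is the haploid reduction
of the 1984 variance-components form (haplotypes as sampling units; the
within-individual component vanishes). Per-site components `a`
(among-population) and `b` (within) give `theta = a/(a+b)`; negative
per-site estimates are retained unclamped so threshold counts (e.g.
F<sub>ST</sub> < 0.05) stay well defined. Two multi-locus aggregates
are always reported — the mean of per-site ratios and the ratio of sums
`Σa/Σ(a+b)` — because the field uses both and they differ under
heterogeneous allele frequencies. On two-deme island simulations the
ratio-of-sums form agrees with Hudson's `1 − pi_within/pi_between` to
machine precision at equal sample sizes.

## EHH, iHH, iHS

`EHH(x)` among carriers of a core allele is the probability that two
random carriers are identical at every polymorphic site from the core
through `x`; it starts at 1 and is non-increasing. `iHH` is the
trapezoidal integral of EHH over physical distance (bp), truncated
where EHH crosses 0.05 (integrated to the interpolated crossing
point); truncation by chromosome edge or by an inter-marker gap over
200 kb sets a QC flag instead of silently extending. Unstandardized
`iHS = ln(iHH_A/iHH_D)` is standardized within derived-frequency bins
of width 0.05 — subtract the bin mean, divide by the bin SD — against
either the scan's own scores or an explicit reference
(`ihs_bin_stats()`), since allele age makes the raw score strongly
frequency-dependent. Physical distance is used throughout (no genetic
map), matching the common default when no map is supplied. Cores with
MAF < 0.05, unknown ancestral state, or fewer than two carriers of
either allele are skipped with flags.

A practical note on the standardization reference: neutral iHS scores
are correlated along a locus (shared genealogy), so bin moments
estimated from few loci are lumpy. The packaged calibration runs use
40 independent 1 Mb loci (n = 100, θ = 40), which stabilises the tail
fraction; per-bin SDs of ~0.3–0.6 remain and are genuine
between-genealogy variance, not estimation error.

## Enrichment and the composite caller

Element-versus-background 2×2 tables are tested with Pearson's χ²
(1 d.f., no continuity correction; Yates behind a flag), replaced by
Fisher's exact test whenever any expected cell is below 5 — the
standard operationalisation of "small sample size". The enrichment
ratio is observed/expected proportion (`P_O/P_E`). No multiple-testing
correction is applied across element classes (raw P at 0.05), but a
Benjamini–Hochberg helper is provided. The caller uses strict
inequalities (DAF > 0.5, F<sub>ST</sub> > 0.3, |iHS| > 2; a value
exactly at a threshold does not fire), requires ≥ 2 of 3 criteria, and
treats an undefined statistic as criterion-not-met. "Top 1%" style
thresholds are the empirical 99th percentile with ties included above
the cut. Gene annotation attaches every gene whose
`[start − 5000, end + 5000)` flank (half-open) contains the call,
sorted by distance then name. Whether the F<sub>ST</sub> criterion uses
the global or a pairwise value, and which population's iHS enters, are
configuration choices; the pipeline default is global F<sub>ST</sub>
plus the focal population's DAF and iHS, with population labels kept in
the output.

# The synthetic-data generator

The generator produces data with the statistical structure the scans
assume, not a calibrated model of any real genome:

* `simulate_neutral()`: Kingman coalescent (no intra-locus
  recombination) with infinite-sites mutation at rate θ/2 per branch
  unit; positions uniform; derived = mutant lineage. Windows here are
  short relative to recombination scales, and none of the SFS
  statistics require linkage variation, so omitting recombination
  trades realism for an exactly checkable null (`E[S] = θ·a1`,
  `E[pi] = θ`).
* `simulate_island()`: structured coalescent with per-lineage migration
  M/2 over `d` demes; with `M = 0` a split-time mode merges isolated
  demes at a stated divergence time.
* `simulate_sweep()`: founder-copy construction — carriers of a planted
  derived core allele copy one founder's flanking sequence out to
  per-haplotype geometric breakpoints (per-bp rate `crossover`,
  default 2e-6, i.e. mean ~500 kb tracts per side on the 1 Mb default
  locus). This is the regime of a strong, recent sweep whose derived
  haplotypes are essentially unbroken across the window — the signal
  iHS is designed to flag. The default was calibrated so the
  generator fulfils that role robustly: neutral within-bin iHS spread
  is ~0.5, so weaker copying (tracts ≲ 100 kb at this marker density)
  leaves the core z-score hovering at the threshold.
* `skew_sfs()`: inside designated constrained elements, each site's
  allele column is replaced by one drawn from the constrained pool by
  rejection (acceptance `(1/i)^(β−1)`), making the derived-count
  distribution ∝ `1/i^β` while preserving the number of sites; β = 1
  is a distributional no-op. This is an exact spectrum dial, not a
  model of selection dynamics — it deliberately destroys LD within the
  element.
* `simulate_study()`: one chromosome of consecutive island-model loci
  (defaults: 18 loci × 25 kb, 3 populations × 32 haplotypes, M = 2,
  θ = 25 per locus) with intron background, skewed CDS/CNC (β = 2), a
  lincRNA locus carrying a pop1-private sweep at frequency 0.8, a
  conservation track high over the constrained classes with
  probability 0.9, and genes planted at distances 0, < 5 kb, and
  > 5 kb from the sweep core.

All generators are pure functions of `(config, seed)`; replicate seeds
derive from a master seed by the documented counter scheme
`derive_seed(master, i) = (master + i·1000003) mod (2³¹−1)`.

**What passing tests do and do not show.** The simulated data are
phased, error-free, gap-free, biallelic, and (outside the sweep
construction) recombination-free, with known ancestral states and
uniform marker density. Real data violate all of these; in particular,
iHS behaviour under marker sparsity, phasing error, and ancestral
mispolarization is untested here, and the skew_sfs alternative is a
clean caricature of purifying selection. Passing calibration means the
statistics and machinery are implemented correctly, not that the
pipeline's error rates transfer to any real cohort.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; VCF
  positions convert at the boundary. Strand is ignored.
* AA-tag polarization is case-insensitive and reads only the first
  field of extended `aa|ref|alt` encodings; sites whose AA matches
  neither allele keep ALT-coding with `ancestral_known = FALSE`.
* Unphased genotypes are an error (not silently phased); multiallelic
  and indel records are skipped with a count.
* Missing conservation score = non-conserved at every threshold;
  conserved is inclusive (`score ≥ threshold`), non-conserved its
  strict complement.
* Frequency-bin assignment adds 1e-9 before flooring so exact
  multiples of the bin width land in their own bin regardless of
  floating-point representation.
* Monomorphic sites are undefined for F<sub>ST</sub> (flagged, not
  zero); spectrum bins are left-closed with the last bin right-closed;
  NA values excluded and counted.
* The permutation and bootstrap engines consume explicit seeds;
  identical seeds give identical outputs.
* The intergenic derivation rule ("at least 10 kb from any element")
  is ambiguous about tiling; both behaviours exist behind a `tile`
  flag (default: untiled stretches), and stretches > 10 kb without a
  variant are dropped only when a haplotype block is supplied.

# Problem sizes in the packaged checks

The calibration suite simulates at desk scale, chosen once: 8000
neutral replicates (n = 50, θ = 10) for the neutrality-statistic means
— Fay & Wu's *H* is unnormalized with SD ≈ 6.8 at θ = 10, so smaller
runs would leave the mean estimate dominated by Monte-Carlo noise; 500
two-deme loci for the F<sub>ST</sub> estimator comparison; 500 null and
100 alternative permutation trials; 40 reference loci plus 200 sweep
replicates for iHS; 30 replicates of ≥ 2000 sites for the low-DAF
enrichment; and one full study genome for the end-to-end run. The
same computations, re-seeded from the command line, are what
`scripts/acceptance.R` reports.

# Known limitations

* No intra-locus recombination outside the sweep construction; no
  genetic map for iHS.
* No missing-genotype handling in the haplotype scan (synthetic data
  are complete); real-data use would need imputation or masking
  upstream.
* The bootstrap is window-level i.i.d.; overlapping windows are
  correlated, so bootstrap SEs are mildly optimistic (the permutation
  test, which compares group means, is unaffected under its null).
* Fu & Li's D*/F* constants are exact under the standard neutral
  coalescent; under strong demography their null distribution shifts,
  as for all SFS tests — the background comparison is the intended
  control for this.
* The composite caller reports raw criteria without multiple-testing
  control, as is conventional for descriptive genome scans.
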