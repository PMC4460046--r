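# ncsel

Element-partitioned natural-selection scans on phased polymorphism
data, with a built-in coalescent simulator so the entire pipeline runs
and is tested without any external download.

## The scientific problem

Coding sequence, UTRs, introns, noncoding RNAs, pseudogenes, conserved
noncoding sequence, and intergenic DNA experience different selective
regimes, and those regimes leave distinct footprints in population
polymorphism data. `ncsel` computes the standard battery of scans over
a partition of the genome into labelled element classes, each compared
to the genome-wide background:

- **SFS neutrality tests** on concatenated element sequence in 10 kb /
  5 kb sliding windows: segregating sites *S*, nucleotide diversity π,
  Watterson's θ, Tajima's *D*, Fu & Li's *D*\* and *F*\*, Fay & Wu's
  *H* (unnormalized, polarized), and observed heterozygosity
  H<sub>o</sub> — with 1000-replicate bootstrap means and
  permutation tests (default 10,000 label reshuffles, two-sided,
  +1-corrected) against genome-wide windows.
- **Allele-frequency differentiation**: per-SNP Weir–Cockerham
  θ̂ = a/(a+b) on haplotypes (haploid reduction of the 1984
  variance-components estimator), globally over a population set and
  pairwise over pooled groups; both the mean of per-site values and
  the ratio of sums Σa/Σ(a+b) are reported.
- **MAF/DAF spectra** with half-open binning and χ²/Fisher enrichment
  of rare variants (DAF ≤ 0.05) per element class, with the
  P<sub>O</sub>/P<sub>E</sub> ratio.
- **Conservation classes**: per-base scores thresholded at ≥ 2 / ≥ 3
  (inclusive), percentage of element length conserved, and rare-DAF
  fractions within conserved/non-conserved site sets.
- **EHH / iHH / iHS**: extended haplotype homozygosity around each
  core SNP, trapezoid-integrated over physical distance with a 0.05
  cutoff, iHS = ln(iHH<sub>A</sub>/iHH<sub>D</sub>) standardized in
  derived-frequency bins of 0.05.
- **Composite caller**: a variant is called under positive selection
  when at least two of DAF > 0.5, F<sub>ST</sub> > 0.3, |iHS| > 2 hold
  (strict inequalities), then annotated with genes overlapping or
  within 5 kb.

The simulator provides the matching study conditions: a neutral
Kingman coalescent (E[S] = θ·a₁, E[π] = θ), an island model with
migration for differentiated populations, a founder-copy selective
sweep producing the long derived-background homozygosity iHS detects,
a rejection-resampling SFS skew (∝ 1/i^β) emulating purifying
selection inside constrained elements, and track generators for
elements, conservation scores, and genes.

## Worked example

The analysis workflow under `analysis/` is a sequence of numbered
drivers over the package functions; each writes its tables under
`results/`. Step 1 simulates the study genome (18 island-model loci,
3 populations × 32 haplotypes; CDS and CNC classes SFS-skewed at
β = 2; one lincRNA locus carrying a pop1-private sweep at derived
frequency 0.8):

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_window_neutrality.R
Rscript analysis/03_frequency_differentiation.R
Rscript analysis/04_haplotype_scan.R
Rscript analysis/05_selection_calls.R
```

Output of the run packaged here (seed 42):

```
Simulated 7611 sites over 450 kb in 96 haplotypes (3 populations).
Sweep core planted at position 62500 (pop1, derived freq 0.8).

Genome-wide background: 88 windows, mean D = -0.627
  CDS      mean D = -1.797 (background -0.627), perm P = 0.0015
  CNC      mean D = -1.945 (background -0.627), perm P = 0.0003
  intron   mean D = +0.002 (background -0.627), perm P = 0.0021
  lincRNA  mean D = -2.243 (background -0.627), perm P = 0.0156

Global F_ST: mean of per-site = 0.1087, ratio-of-sums = 0.2319
 element_class frac_low_daf            p     ratio direction
           CDS    0.8605619 2.165383e-95 1.6959443  enriched
           CNC    0.8149742 1.023766e-85 1.6061027  enriched
        intron    0.3851796 7.352172e-36 0.7590890  depleted
       lincRNA    0.3976608 7.140841e-05 0.7836863  depleted

Scored 3284 of 7611 sites; fraction |iHS| > 2: 0.054
Sweep core at 62500: iHS = -3.21 (unstandardized -1.76)

315 of 7611 sites called (>= 2 of 3 criteria).
Sweep core: called = TRUE, criteria met = 3, genes = coreGene,nearGene
```

Reading this: the two constrained classes show the rare-allele excess
of purifying selection (strongly negative window-mean Tajima's *D*,
significant against the background by permutation; > 80% of their
variants at DAF ≤ 0.05, 1.6–1.7× enriched over the background), while
the neutral intron class does not. The planted sweep core is
recovered by the composite caller with all three criteria firing
(pop1 DAF 0.81, elevated global F<sub>ST</sub>, standardized
iHS −3.2) and is annotated with the gene it overlaps and the gene
within 5 kb, but not the gene beyond 5 kb.

The same computation is available as a single call from files to
tables:

```r
library(ncsel)
st <- simulate_study(seed = 42, out_prefix = "study")
run_selection_scan(st$files$vcf, st$files$elements,
                   st$files$conservation, st$files$genes,
                   st$files$panel, out_dir = "out", focal_pop = "pop1",
                   seed = 1)
```

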