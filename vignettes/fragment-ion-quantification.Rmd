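---
title: "Fragment-ion peak-area quantification of phosphopeptides"
author: "phosquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-ion peak-area quantification of phosphopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosquant)
```

## The measurement problem

Relative quantification of protein phosphorylation by LC-MS/MS must solve
three coupled problems: (i) measure each phosphopeptide's signal
specifically, even when the precursor co-elutes with interferences; (ii)
correct for how much protein was loaded in each sample; and (iii) decide
which acceptor residue actually carries the phosphate when several
serines/threonines sit close together.

`phosquant` implements a pseudo-SRM answer used for label-free studies on
hybrid trap instruments, where accurate mass is available at the MS1 level
(FT, ~ppm) but fragment spectra come from an ion trap (~0.1-0.5 Da):

* **Phosphopeptides** are quantified from *MS2 fragment-ion* extracted ion
  chromatograms (XICs): for each of a small list of quantifier b/y ions
  unique to the phosphopeptide, the intensity within ±0.5 Da of the ion is
  summed in every MS2 scan whose isolation window covers the peptide's
  precursor, and the resulting RT trace is integrated. Fragment-level
  extraction keeps the measurement specific even at ion-trap precursor
  accuracy.
* **Internal standards** — unphosphorylated peptides of the *same protein*
  — are quantified from MS1 precursor XICs at ±10 ppm, at their listed
  charge states. Their mean area per run measures the amount of the
  protein loaded, so dividing each phosphopeptide area by it cancels
  loading and injection differences (an *endogenous* loading control;
  it also makes the statistics invariant to any global rescaling of a
  run's intensities, which the test suite asserts exactly).
* **Per-site statistics** are computed on a paired design: each site's
  normalized areas are divided by the mean of its control samples, so
  control ratios average to 1 by construction; the treated-ratio mean is
  the fold change, reported ± SEM (sample SD / sqrt(n)); significance
  comes from a two-sided paired *t*-test on the normalized areas (by
  scale invariance, identical on the ratios).

## Mass model

Monoisotopic residue masses with I/L equivalent; water 18.01056 Da;
proton 1.00728 Da; phosphorylation +79.96633 Da; Met oxidation
+15.99491 Da; neutral losses H3PO4 97.97690 Da and H2O 18.01056 Da.
Cysteine is unmodified by default (the shipped panel's published product
ions only reproduce without carbamidomethylation); fixed modifications
are configurable per peptide. `b_i` sums residues 1..i plus their
modification deltas plus charge protons; `y_j` additionally carries the
C-terminal water; neutral losses subtract from the fragment's neutral
mass before dividing by charge. `b_i(+1) + y_{n-i}(+1)` equals the
neutral mass + 2 protons, an invariant the tests enforce to 1e-4 Da.

A peptide whose spectra cannot discriminate two adjacent acceptors is
modeled with a single phosphate *floating* over an ambiguity group
(e.g. the `STQGVTLTDLQEAER` peptide, positions 1-2). Fragments covering
all or none of the group have well-defined masses; a fragment straddling
the group is an error unless an explicit site is supplied. This is what
makes such a peptide quantifiable as one unit — its quantifier ions are
exactly the ambiguity-safe ones.

```{r masses}
p <- modifiedPeptide("GSLTEQEPAER", "phospho@2")
c(neutral = neutralMass(p), mh = protonatedMz(p, 1),
  y8 = fragmentMz(p, "y", 8))
```

## XIC integration

A chromatogram has one point per contributing scan; scans with no peak
inside the tolerance window contribute zero, so a missing signal is an
*observed zero*, never a missing value (zeros propagate into means and
tests). Integration is trapezoidal over a deterministic peak region: the
apex is the most intense point (or the local maximum nearest an expected
RT); the region extends until intensity falls below 1% of the apex, a
local minimum drops below 5% of the apex, or the width reaches 2 min
(all configurable). On a noiseless Gaussian trace this recovers the
analytic area A·sigma·sqrt(2*pi) to well within 2%, which the acceptance
tests check against the closed form. Multiple quantifier ions are
combined by **summing** their areas: a sum preserves linearity in
abundance and matches SRM practice; per-ion areas are retained for audit.

## Site localization

Localization follows the Ascore idea: for each single-site isoform of
the peptide, count how many of its theoretical b/y ions match the
spectrum (±0.5 Da) when the spectrum is thinned to its *d* most intense
peaks per 100 m/z window, and convert the count into
−10·log10 of a cumulative binomial tail probability with per-trial
success probability d/100. The depth d in 1..10 that best separates the
two top isoforms is selected, and the reported Ascore is the score
difference computed on the **site-determining ions** only — fragments
whose m/z differs between the two isoforms. Scores ≥ 13 (about
P ≤ 0.05) are called confident. Neutral-loss peaks are matched but never
counted as localization evidence (a conservative choice: loss peaks are
abundant for phosphopeptides but not site-specific in an ion trap).
Deterministic tie-breaks: within a window, equal intensities rank by
lower m/z; equal isoform scores rank by lower position; the smallest
depth attaining the maximal separation wins; an exact tie yields
Ascore 0 and an ambiguous call. A brute-force re-enumeration of windows,
depths and binomial sums (in the test helpers) must agree exactly.

## The simulator

`simConfig()` / `simulateExperiment()` generate paired control/treated
runs with known ground truth, emulating the study design the package
targets: `nPairs = 4` paired biological replicates; per-site true folds
3.0, 11.7 and 2.3 at the three regulated sites and 1.0 elsewhere;
Gaussian elution (sigma 0.1 min) on a 0.05-min MS1 duty cycle;
DDA top-3 triggering above an intensity threshold; m/z jitter within the
extraction tolerances (truncated Gaussian, sd 2 ppm at MS1, 0.1 Da at
MS2); and multiplicative lognormal noise — a per-run loading factor
(sigma 0.15) shared by all peptides, cancelled by normalization, and a
per-run-per-peptide factor (sigma 0.2) that constitutes the replicate
scatter. Lognormal noise is the natural choice for strictly positive,
right-skewed peak areas. Where the emulated study fixes a value (pairs,
folds, tolerances) the default is that value; the noise magnitudes are
not knowable from printed tables and were chosen once as typical
label-free replicate variability such that the configured effect sizes
are recoverable at n = 4.

Two deliberate deviations from instrument realism:

* **Monoisotopic-only peaks** — no isotope envelopes, because the
  quantification contract reads only the monoisotopic trace.
* **No dynamic exclusion by default.** With 0.1-min peaks, a classic
  30-s exclusion would leave 1-2 MS2 scans per elution peak and make
  fragment-XIC integration degenerate; re-sampling every duty cycle
  gives the dense MS2 coverage that fragment-level quantification needs
  (the parameter is exposed for anyone wanting sparse sampling).

The simulator also does **not** model chimeric spectra, co-elution
interference, charge-state envelopes or missed cleavages. Passing the
end-to-end tests therefore shows that the pipeline's arithmetic and
contracts are right — recovery of configured folds through simulated
spectra — not that it is robust to every pathology of real data.
For the ambiguity-group peptide the simulator emits only ambiguity-safe
fragments, mirroring data in which the discriminating ions were not
detectable; its localization must therefore come out ambiguous, which
the tests assert.

Problem sizes used by the shipped tests and acceptance script: 14-peptide
panel, ~350 MS1 + ~300 MS2 scans per run, 8 runs per experiment, and 20
seeded replications for the parameter-recovery and null-behavior
summaries — small enough to re-run anywhere, dense enough that
integration error stays below the effects being measured.

```{r recovery, eval = FALSE}
## end-to-end parameter recovery (about a minute)
folds <- sapply(1:20, function(s) {
  res <- runQuantify(simulateExperiment(simConfig(seed = s))$runs)
  setNames(res$results$foldChange, res$results$site)
})
apply(folds, 1, median)
```

## Statistics: choices where the design was open

* **Two-sided** paired t-test: the conservative default; the regulated
  sites in the shipped reference table remain significant two-sided.
* **SEM** uses the n−1 sample standard deviation.
* **No multiple-testing correction** across the six sites; p-values are
  reported per site and flagged as such in the output log.
* **No automatic outlier removal**: replicate exclusion is only possible
  via the explicit `exclude` argument and is recorded in the run log.
* A site whose control mean is zero is flagged `unquantifiable` rather
  than failing the run; a sample whose internal standards are all zero
  is a hard error ("failed loading control"), since nothing downstream
  is interpretable.

## Re-analysis mode

`table4Fixture()` ships the published 6-site × 4-experiment ×
2-condition normalized peak-area table; `reanalyzeTable()` reproduces
its ratio columns, fold changes, SEMs and significance calls from those
areas alone, so the statistics layer is testable without spectra. Note
one wrinkle of printed data: summary rows recomputed from areas printed
at 3 significant figures can differ in the last printed digit from
summaries computed on already-rounded ratio columns; the package always
computes from the areas (unrounded ratios) and the tests compare at
tolerances reflecting the input rounding.

## Known limitations

* One floating phosphate per ambiguity group; multi-phospho joint
  localization is out of scope.
* No RT alignment or match-between-runs: pairing is by design, and each
  run is integrated independently.
* mzML is the only on-disk spectrum format (plus a delimited fallback
  for fixtures); vendor formats and mzXML are not read.
* The mass engine treats I/L as identical and ignores isotope envelopes;
  a-, c-, x- and z-ions are not modeled.
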