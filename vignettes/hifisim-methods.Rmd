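---
title: "Simulating multi-sample HiFi amplicon datasets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-sample HiFi amplicon datasets: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifisim)
```

This vignette is the package's account of the models it implements, the
parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The simulation model

A run is determined by a community (genomes with embedded rRNA operons),
a primer pair, a barcode table and a `run_config()`. Five stages follow.

### 1. Abundance

A single community molarity vector is drawn (`uniform`, `lognormal`,
`powerlaw` = rank$^{-\alpha}$, or a user `empirical` profile) and shared
across samples: the samples are replicates of one community, which is the
design of mock-community sequencing experiments. Biological variability
enters through a squared coefficient of variation (CV²) per feature and
sample, predicted from intensity by

$$\mathrm{CV}^2(i) \;=\; \beta_0 + \beta_1 \log_{10} i \;+\; \varepsilon,
\qquad \varepsilon \sim \mathcal{N}\!\big(0,\; \mu^2/\text{nb\_size}\big),$$

clamped at zero. Two aspects deserve emphasis:

* **The clamp is a modeled behaviour, not a numerical fix.** Count-matrix
  parameter-estimation procedures routinely return unavailable (NA)
  dispersions for sparse features and downstream tools convert them to 0,
  which means *no biological variability*: all replicates get identical
  expected abundances before technical sampling. `predict_variability()`
  reproduces exactly that: any draw (or mean prediction) at or below zero
  returns CV² = 0, and `simulate_sample_counts()` then uses the intensity
  as-is in the biological stage.
* **The default coefficients are a documented stand-in.** The canonical
  overdispersion shape — CV² decreasing with intensity — is encoded with
  defaults $\beta_0 = 0.013$, $\beta_1 = -0.12$ (CV² ≈ 0.05 at intensity
  0.5, ≈ 0.5 at 10⁻⁴) and `nb_size = 25`. The exact coefficients a
  particular real preset would give are not hard-coded anywhere; all three
  parameters are user-settable and `fit_variability_model()` estimates
  them from any (intensity, CV²) table by least squares plus a moment
  estimate for `nb_size`.

Counts are realized in two stages: a Gamma draw per feature with mean
equal to the intensity and CV² equal to the predicted variability
(biological), then a multinomial draw of the sample's full depth over the
renormalized stage-1 intensities (technical). The multinomial was chosen
over a multivariate hypergeometric because sequencing depth is far below
library complexity in amplicon settings; the function boundary makes this
a swap-in point. Column sums equal the configured depth by construction.

Genome intensities expand to ASV level by operon copy number: an ASV's
weight is its genome's intensity times its multiplicity, renormalized over
all ASVs. Whether variability is drawn once per feature or per
feature × sample is not observable from a single mock community; the
package draws per cell by default with `variability_per = "feature"` as
the switch.

### 2. In-silico PCR

Primer sites are found by IUPAC set matching with a per-primer mismatch
budget (default 2): genome base $b$ matches primer base $p$ iff
$b \in \text{set}(p)$; an N in the genome matches only a primer N. Every
forward site pairs with every downstream reverse-complemented reverse
site on both strands; nested and spanning candidates are all reported, and
the product length window (primer-inclusive) decides what survives. The
window is deliberately a run-level parameter (e.g. 1000–2000 for 16S,
2000–3500 for longer 16S–ITS–23S amplicons) rather than a hard-coded
filter, and extraction-time filtering is off by default.

Two conventions are recorded per amplicon because the field uses both:
the primer-inclusive `product_seq` (used for length filtering) and the
primer-exclusive `insert_seq` (used for template building, so primer
bases are not double-counted in the template formula below). A
3'-terminal primer mismatch is not specially penalized — no polymerase
extension model is attempted; this is a documented limitation.

### 3. Templates

Each sample × ASV with a positive count yields one template,

`A + FwdBarcode + FwdPrimer + ASV + RC(RevPrimer) + RC(RevBarcode) + A`,

carried with the count as its molecule multiplicity. The single flanking
`A` bases are literal. Degenerate primer positions must be concrete in a
real molecule; the package defaults to *oligo mode* (a random concrete
disambiguation of the primer oligo per template), which is biologically
truer for the 5' primer region of a PCR product, with *genomic mode*
(bases found at the binding site) as the alternative. Error-free
templates demultiplex to their sample with zero mismatches; since
simulated errors hit barcodes and insert alike, the reads support
realistic demultiplexing benchmarks.

### 4. Subreads

The pass number np per molecule comes from an empirical histogram (rows
outside [np_min, np_max] dropped, rest renormalized) or a lognormal
(draw, round to nearest integer, reject outside the range — simple and
unbiased within the support). Defaults: range 2–59, meanlog 2.3,
sdlog 0.5 (mode around 8–10 passes, right-skewed, matching the shape of
real HiFi pass-number distributions). `fit_np_lognormal()` uses the
population convention (divisor n) for sdlog — the MLE of the untruncated
lognormal — and the tests pin that convention.

Each pass walks the template base by base: with probability `accuracy`
(default 0.65) the base is emitted; otherwise the error type is chosen by
the substitution:insertion:deletion weights (default 6:55:39). An
insertion emits a uniform base and re-processes the same template base,
so insertion run lengths are geometric; a deletion skips the base. Passes
alternate strand, the minus-strand walk operating on the reverse
complement so errors accrue in read orientation. A homopolymer
multiplier (default 1 = off) can scale the indel mass inside runs of ≥ 3
identical bases, renormalized per position, as a hook for
sequence-context effects.

One arithmetic consequence worth spelling out: every walk event is one
column of the generating alignment, so the *identity per alignment
column* equals `accuracy` exactly, while matches per *template base* equal
$a/(1 - (1-a)w_{ins})$ (≈ 0.80 at defaults) because insertion columns add
to the alignment without consuming template. Realized identity and
error-type composition are asserted against the configured values at 10⁶
bases in the test suite, using the walk's exact edit counts rather than a
re-alignment: a minimum-edit-distance re-alignment of such noisy reads
systematically compresses the true edit script and would bias identity
upward.

### 5. Consensus and output

Subreads of a ZMW are oriented to the plus strand; the backbone is the
edit-distance medoid of up to five evenly spaced subreads (computing the
medoid over all pairs would be quadratic in np at no measurable accuracy
benefit); every subread is globally aligned to the backbone with unit
costs; and each column is called by plurality over {A, C, G, T, gap}.
Insertion columns between backbone positions are included only when
observed in at least half the subreads. Ties prefer a base in backbone
columns (the template has a base there) and the gap in insertion columns
(the template has none), then alphabetical order — all deterministic.
Per-base quality is $q = \min(93, \mathrm{round}(-10\log_{10}\max(\varepsilon,
1-k/n)))$ with $\varepsilon = 10^{-10}$, $k$ votes for the winner among
$n$ subreads; a single-subread ZMW gets a fixed Q20, since agreement is
undefined at n = 1.

This is backbone-based plurality voting, not the vendor's partial-order
HMM consensus: it is exact at accuracy 1, strictly improves with np (the
suite verifies the improvement from np = 3 to np = 15 by a paired sign
test), but leaves a higher residual error at accuracy 0.65 than vendor
CCS achieves on real data. Partial-order alignment is the recorded
upgrade path. No minimum-pass or predicted-accuracy post-filter is
applied; np is recorded per read so users can filter themselves.

Reads are named `<movie>/<zmw>/ccs` with the movie derived from the run
seed, and provenance (sample, genome, ASV, np, template) is carried in
the FASTQ header comment *and* a sidecar TSV, because header comments are
routinely stripped by downstream tools.

## Evaluation and calibration

`edit_distance_profile()` computes each read's minimum global
(unit-cost Levenshtein) distance over the reference ASVs, after applying
a read-length window — metrics impose minimum and maximum lengths so that
library artifacts outside the expected amplicon size do not dominate.
Ties break to the lexicographically smallest ASV id;
`misassignment_rate()` counts a tie that includes the true source as
correct (with identical references, the truth is genuinely ambiguous).
Histograms use unit-width bins on [0, d_max] plus an overflow bin.

`calibrate_accuracy()` reruns the simulator across an accuracy grid,
bins each run identically to the target histogram, and minimizes
$KL(p_{target} \| q_{sim})$ in nats with the simulated histogram smoothed
by an add-mass of 10⁻⁹ (the divergence is undefined on unsmoothed zero
bins, and the package refuses to compute it rather than silently
dropping them). Ties go to the lower accuracy. Against real data this
calibrates the simulator to a sequencing run; in this repository the
self-recovery property is what is testable: a target simulated at 0.65 is
recovered from the grid {0.55, 0.60, 0.65, 0.70, 0.75} at 2 000 reads.

`abundance_r2()` computes squared Pearson correlation on raw values by
default with a log10 option, since either scale is defensible and
published R² values rarely state which was used.
`positional_error_profile()` aligns reads to their true sources and
classifies every alignment column; under the package's
position-independent error model the profile is flat up to binomial
noise, which the suite checks by regression — sequence-position effects
(e.g. insertion pile-ups near amplicon ends seen in long amplicons) are
exactly what this metric is designed to expose when the model gains
context dependence.

## What the fixtures do and do not show

`generate_mock_community()` builds genomes as random spacer interleaved
with primer-flanked operons: a realized forward primer, a random core,
and the reverse-complemented realized reverse primer, with copies 2..k
substituted at the configured divergence rate (core only, so the truth
table always matches extraction exactly; primer realizations are drawn
once per genome so that zero divergence means identical copies).
Coordinates are 0-based half-open with strand, and slicing the genome at
the recorded coordinates reproduces the recorded amplicons — that
invariant is what makes every later stage testable.

The fixtures deliberately do *not* model rRNA secondary structure,
taxonomic sequence composition, GC skew, or conserved/variable region
architecture. Passing tests therefore demonstrate that the machinery is
correct (extraction finds what was embedded, abundances are conserved,
error rates match their dials), not that simulated reads are
indistinguishable from any particular instrument run; the latter claim
requires calibration against real data, which is what
`calibrate_accuracy()` and the empirical np tables are for.

## Randomness and determinism

Every stage derives its stream from the run seed through a hash
(`run seed → stage → unit`), so adding samples or molecules never
perturbs earlier draws, and per-ZMW work parallelizes with results
byte-identical for any worker count. The test suite pins this:
two runs with the same seed and different `workers` produce identical
FASTQ bytes.

## Problem sizes used in the tests

The suite exercises the statistical assertions at the smallest sizes at
which they are sharp: error composition and identity at 10⁶ template
bases (4σ binomial bands), misassignment on 2 000 reads from five
well-separated single-copy genomes (minimum inter-ASV distance ≥ 20,
pass numbers ≥ 5), calibration self-recovery at 2 000 reads per grid
point with a 60 bp core, consensus monotonicity on 100 paired ZMWs of a
500 bp template, and abundance recovery (R² > 0.95) on a 20-genome
staggered community at 13 000 reads per sample across 8 replicates.

## Known limitations

* PCR bias, chimera formation and adapter-dimer artifacts are not
  modeled; the length windows applied by the evaluation metrics are the
  standing mitigation.
* The consensus caller is plurality voting on a backbone, not a
  partial-order HMM; residual consensus error at low accuracy is higher
  than vendor tooling would produce.
* Pass-number distributions do not depend on insert length; per-length
  stratification (multiple histograms) is the recorded extension point.
* The variability model's default coefficients encode a shape, not a fit
  to any particular dataset — refit with `fit_variability_model()` when a
  real (intensity, CV²) table is available.
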