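---
title: "Models and methods behind ciberscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ciberscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciberscreen)
```

# The measurement and its model

A barcoded CRISPRi expression-reporter screen couples each guide to
expressed RNA barcodes. Comparing a barcode's abundance before and after
guide induction, relative to a normalizer, estimates how the knockdown
changes reporter transcription. Two normalizers are in play:

* **RNA-to-DNA** — reporter RNA barcodes over DNA barcodes. Corrects for
  cell abundance and copy number, but any knockdown that changes bulk
  transcription (polymerase, mediator, chromatin machinery) changes the
  RNA/DNA ratio of *its own* barcodes and appears as a hit regardless of
  the queried phenotype.
* **Matched-promoter RNA-to-RNA** — reporter RNA over a second RNA
  barcode expressed from a closely matched promoter on the same construct.
  Systemic effects hit both barcodes equally and cancel in the ratio;
  only reporter-specific regulation survives.

`ciber_fit()` treats the pre/post samples of each replicate as a pair,
because both are drawn from the same culture: the per-guide statistic is
the mean across replicates of the paired change in log2 ratio. An
unpaired two-group mode exists for count deposits whose pairing is
unrecorded, and the benchmark harness runs both.

## Library-size normalization, pseudocount, and centering

Each log ratio uses counts-per-million within its channel, with a 0.5
pseudocount for stability at low counts. Scaling cancels within the
paired difference only when depths match, so it is kept explicit.

Sequencing at fixed depth makes counts compositional: if the induced
library's total reporter output changes, every guide's raw ratio change
shifts by a shared sample-level constant. `ciber_fit()` therefore
subtracts each sample's median log ratio (median-of-ratios centering, as
in standard count-based differential analysis) before differencing, under
the assumption that most guides are phenotypically null. With balanced or
sparse effects the correction is near zero; it matters when planted
effects are one-sided. `center = "none"` disables it.

## Variance moderation

With two biological replicates each guide's variance estimate has a
single degree of freedom and is useless on its own. The per-guide
variances are modelled as draws from a scaled-F distribution around a
prior variance `s0^2` with prior degrees of freedom `d0`, estimated by
moment-matching the log variances (mean and variance of `log s_g^2`,
corrected by digamma/trigamma terms; `d0` solves a trigamma equation by
Newton iteration). The moderated variance is the df-weighted combination
`(d0*s0^2 + d_g*s_g^2)/(d0 + d_g)`; `d0 = 0` recovers the classical
paired t-test, which the tests verify to 12 digits, and the estimator is
cross-checked against an independent empirical-Bayes implementation.
When the observed spread of log variances does not exceed what sampling
noise alone implies, the moment equation has no positive solution; the
fit then uses an infinite-df prior at the mean observed variance. A
variance floor of 1e-8 guards exact zeros (identical counts across
replicates). Mean–variance precision weights are deliberately not
fitted: with guide-level aggregated counts and two replicates, weight
estimation is fragile, and the moderated constant-variance model is the
robust default.

## Calling and rolling up

Benjamini–Hochberg q-values are computed across guides within one screen
only. A guide is significant iff `q < 0.01` and `|log2fc|` exceeds the
screen's fold-change cutoff (1 for the background-comparison and
stabilization screens, 2 for the reporter-specific screen); q below
1e-50 is floored for display only — the raw value is preserved. Gene
roll-ups count significant guides per gene by direction; enrichment uses
one-sided Fisher's exact p (exact hypergeometric tail summation,
verified against exhaustive enumeration for all margins with universe
size ≤ 12) with Bonferroni correction at 0.05. The default universe is
the set of genes targeted by the guide library, since the library defines
the sampling frame; a genome-wide universe can be passed explicitly.

# The simulator

`simulate_screen()` draws, per guide: log-normal cell abundance
(`abundance_sd`, natural-log SD 0.5 by default — a moderate library
skew); a copy number (exactly 1 in `integrated` mode, log-normal in
`plasmid` mode); and four log2 effects scaled by knockdown efficiency —
phenotype (reporter only), systemic (both RNA channels), fitness (all
channels, abundance over the induction window), and DNA copy (DNA and,
proportionally, both RNA channels). The three channels of a sample derive
from one shared latent population: channel masses are gamma-perturbed
(shape 100, i.e. ~10% CV of technical noise per channel measurement) and
a multinomial draw at the configured depth produces integer counts.
Defaults encode the optimized screen conditions: 2 replicates, a pre/post
contrast with the pre-induction sample as baseline, depth 1e6 per sample
at desk scale (the real screens sequence upwards of 14 million reads per
sample — a documented setting, not the default), integrated single-copy
constructs, 5% phenotype hits of uniform ±[1,3] log2 and 5% systemic
guides of ±2 log2.

In plasmid mode, co-transformation (cells carrying two library plasmids)
is modelled as re-assigning a fraction `phi` (default 0.05) of each
guide's mass to one random other guide's barcodes — the simplest
one-parameter rendering of barcode–guide decoupling. The copy number is
drawn once per guide and shared across channels and samples, so it
cancels algebraically in every ratio; plasmid-mode noise instead enters
through count-level sampling (mass skew concentrates reads on few guides,
starving the rest) and through the co-transformation term. The tests
assert the resulting variance inflation relative to integrated mode over
500 null guides. The real distribution of episomal copy number and the
co-transformation rate are not well quantified for these libraries; both
defaults are order-of-magnitude choices exposed in the config.

What the simulator does **not** emulate: PCR jackpotting (subsumed into
the gamma term), guide-efficacy sequence features, growth dynamics under
constant-density culture, hormone dose kinetics, and RNA/DNA isolation
batch effects beyond the independent gamma noise. Passing tests on
simulated screens therefore demonstrate the statistical machinery and the
normalization algebra, not robustness to every real-data artifact.

DNA barcodes are represented as a third barcode set per guide. In the
real assay, DNA reads sequence the same physical barcodes as the RNA
channels from a different template; a distinct synthetic barcode per
channel keeps the barcode-to-(guide, channel) map one-to-one without
changing any ratio.

# Reads and counting

`emit_fastq()` writes `prefix + barcode + suffix` reads with independent
per-base substitution errors and constant qualities; `count_fastq()`
inverts it. Matching uses Hamming distance on an anchored, fixed-length
window: indels are not handled because the barcode position is fixed by
the amplicon layout. Exact matches are resolved by hash lookup; one
mismatch by a precomputed distance-1 neighbourhood index whose collisions
mark ambiguity; two mismatches (opt-in) by brute-force scan of the
remaining reads. A window at equal minimal distance from two library
barcodes is deliberately left unassigned. The library generator enforces
pairwise barcode distance ≥ 3 — two sequences within distance 2 always
share a distance-1 neighbour, which gives a hash-based screen — so
one-mismatch assignment is unambiguous on generated libraries. Quality
scores are ignored; substitution tolerance covers base-call noise at the
modelled error rates.

# Filtering

Barcodes with fewer than 5 reads in the pre-induction sample are
discarded before analysis. With replicates, the default requires the
minimum in **every** replicate's pre sample: replicates are independent
transformations analysed pairwise downstream, so a barcode absent from
one replicate's pre sample cannot contribute a valid pair. An `any` mode
is provided for pooled-style filtering; the choice is recorded in the
fit's inputs. The filter keys on the barcode's own channel, since
channels are sequenced as separate amplicons, and guides that survive in
only one channel are dropped entirely rather than imputed.

# Dose-response fit

`fit_isotherm()` fits `YFP = A_max*[H]/(k_1/2+[H])` by nonlinear least
squares with deterministic initialization (`A_max` at the maximum
signal, `k_1/2` at the median concentration), which makes the fit
order-invariant. The convergence test uses a scale offset so that
noiseless (zero-residual) data converge cleanly. No basal-fluorescence
term is fitted by default, exactly as the printed model; `offset = TRUE`
adds one. Replicate curves are fitted on pooled points; per-replicate
fitting is a caller-side loop.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
at desk scale: 2,000-guide screens at depth 1e6 for the
background-elimination and FDR experiments, 20 null repeats, 200–500
guide screens elsewhere, and 25–100 guide libraries for the FASTQ path.
Every stochastic stage takes an explicit integer seed and is
bit-reproducible; configs without a seed are rejected rather than
silently seeded from the clock.

# Known limitations

* Barcode-level random effects are out of scope; guides are the testing
  unit, with counts summed across a guide's independent barcodes.
* No shrinkage of the fold-change estimate itself, and no gene-level
  p-value combination — gene tables only count significant guides.
* The unpaired mode shares the moderation machinery but cannot recover
  the pairing information lost in a deposit; both modes are reported by
  the benchmark harness when pairing is unknown.
* Hamming-only matching misassigns reads containing indels inside the
  barcode window; at the modelled substitution rates these reads are
  simply lost to the unmatched tally.
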