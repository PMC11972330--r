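---
title: "Screening two-condition time courses for divergent temporal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening two-condition time courses for divergent temporal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempodiff)
```

## The problem and the model

Per-timepoint differential-expression tests ask whether a gene's level
differs between two conditions *at* a time point. In developmental time
courses the more informative question is often whether the gene's
*trajectory* differs — whether activation is delayed, attenuated,
suppressed, or ectopic in the perturbed arm. `tempodiff` screens for such
genes by treating each gene as a pair of short expression series (one per
condition, here labelled WT and KO) and measuring the dissimilarity of the
pair under twelve complementary time-series measures.

The method makes few distributional assumptions. Its pieces are:

**Expression scale.** Counts are normalized to TPM (reads per kilobase per
million mapped) and compressed with `log2(tpm + 1)`. TPM makes samples of
different depth comparable; the log keeps high expressors from dominating
every distance.

**One series per condition.** Replicates are collapsed by the arithmetic
mean of `log2(tpm+1)` per condition and time point (`aggregate = "median"`
is available). The mean is the minimal-assumption reduction when replicate
numbers are small and unbalanced (the default design is 4 WT vs 2 KO
replicates); nothing downstream depends on the replicate structure after
this step.

**Variance filter.** A gene enters the screen only if the sample variance
(denominator `2T - 1`) of its `2T` pooled, aggregated values is *strictly*
greater than 0.1. The threshold is on the `log2(tpm+1)` scale: genes below
it are essentially flat in both arms and could only contribute noise
rankings. A population-variance option (`var_type = "population"`) is
provided since "variance" alone does not pin down the estimator; the
default and the threshold interpretation are recorded here deliberately.

**Joint minmax scaling.** Each retained pair is rescaled with shared
extrema, `E' = (E - E_min) / (E_max - E_min)` over the pooled `2T` values,
so the pooled scaled values span exactly `[0, 1]`. Scaling the two arms
*together* is what preserves their relationship: a gene expressed at half
the WT plateau in KO stays at half after scaling. A consequence worth
stating is that every downstream distance is invariant to jointly positive
affine transforms of the raw pair — the screen ranks *shapes relative to
the pair's own range*, not absolute levels. Constant pairs
(`E_max = E_min`) cannot be scaled; they are zeroed, flagged degenerate,
and excluded from distance computation (they cannot pass the variance
filter anyway; the flag matters only for filter-free runs).

**Twelve dissimilarities.** The measures are deliberately heterogeneous:
pointwise (Euclidean; complexity-invariant CID; Pearson-correlation
`sqrt(2(1 - rho))`), shape/derivative (short-time-series distance in slope
space, using the true, possibly irregular time grid), elastic (dynamic time
warping; the time-alignment measurement TAM derived from the optimal DTW
path; discrete Fréchet), spectral (leading DFT coefficients; periodogram;
integrated periodogram; autocorrelation vectors), and information-based
(compression-based dissimilarity CDM over a quantized alphabet). A gene
whose pair is flagged by many of these at once diverges robustly, not just
under one notion of distance.

**Empirical 1% tail and consensus.** For each metric the observed distances
over the `N` screened genes are their own null model: the self-inclusive
tail probability `p(g) = #{g' : d(g') >= d(g)} / N` is the rank-based
equivalent of deriving the distance density empirically and cutting its
upper tail, and genes with `p <= alpha` (default 0.01) are "the 1% most
divergent" under that metric. We use the rank form rather than a kernel
density because a KDE bandwidth would be a free parameter sitting directly
in the decision path. Ties share one p-value, so a tie group at the cutoff
is selected or rejected as a whole. The compiled result keeps every gene
selected by at least one metric, sorted by the number of significant
metrics (descending), mean p (ascending), then gene id — a deterministic
total order.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `variance_threshold` | 0.1 | strict lower bound on pooled profile variance, `log2(tpm+1)` scale |
| `alpha` | 0.01 | per-metric empirical tail level |
| `aggregate` | mean | replicate collapse per condition x timepoint |
| `acf_max_lag` | `T - 2` | autocorrelation lags compared (5 at `T = 7`; lag `T - 1` rests on a single product and is discarded) |
| `fourier_n_coef` | `floor(T/2) + 1` | DFT coefficients compared, DC included (the non-redundant half-spectrum) |
| `per_n_freq` | `floor(T/2)` | nonzero Fourier frequencies in the periodogram measures |
| `cdm_alphabet_size` | 8 | uniform quantization bins over `[0, 1]` |
| `cdm_compressor` | lzma | `memCompress` backend (xz preset 9; `deflate` = gzip level 9) |
| `cid_epsilon` | 1e-12 | regularizer in the complexity ratio, guards the flat-series limit |
| `frechet_embedding` | value_only | ground cost on values alone; `time_value` embeds curves in the (day, value) plane |

Fréchet defaults to values only because the scaled values span `[0, 1]`
while the time axis spans days; in a 2-D embedding the time separation
would dominate the cost and the measure would degenerate toward index
alignment. TAM depends on *which* optimal DTW path is taken, so the
backtracking tie-break is fixed and documented: diagonal preferred, then
horizontal, then vertical.

## The synthetic-data generator

`simulate_timecourse()` emulates the structure the screen assumes: two
arms (default 4 and 2 replicates) over 7 time points at days
0, 2, 4, 6, 9, 11, 14 — a two-week differentiation window; the exact day
values are configurable since only their order and spacing enter the
slope-based metric. Latent trajectories on the linear TPM scale come from
four templates (flat, ramp, pulse, and the switch-like sigmoid
`baseline + plateau / (1 + exp(-k (t - t0)))` with `k = 1`/day and plateau
log-uniform in 10–1000 TPM, mimicking sequential developmental activation
without asserting any particular biology). Null genes share one latent
trajectory between arms; planted genes perturb the KO arm by delaying the
sigmoid midpoint, multiplying the plateau by a factor in (0, 1),
flattening to baseline, or activating a gene that is flat in WT.

Two emission modes separate concerns in testing: `"counts"` draws
negative-binomial reads (dispersion 0.05) around TPM-proportional means
under lognormal library sizes (mean 5e6, CV 0.2), exercising the
normalization path and TPM's depth invariance; `"expression"` adds
Gaussian noise (sd 0.1 by default) directly on the `log2(tpm+1)` scale,
exercising the screen in isolation — with the noise at zero, null genes
sit at exactly zero distance under every pointwise metric, a sharp
end-to-end identity the tests rely on.

What the generator does *not* emulate: clone-to-clone batch structure,
splice isoforms, count overdispersion that varies with expression,
correlated noise across time points, and the compositional coupling of
real transcriptomes beyond what TPM renormalization induces. Passing tests
therefore demonstrate the algorithmic contracts and the screen's behaviour
under idealized noise, not performance on any particular real data set.

## Numerical choices

* **Empirical p ranks** are computed as `(N - rank_min(d) + 1) / N`, which
  is exact integer arithmetic — no tolerance is involved in selection.
* **Zero-power series** in the integrated periodogram are detected up to
  the DFT's rounding noise (total power `<= T^2 * eps`); such series get
  the uniform ramp `F(k) = k/K`, so two constant series are at distance 0.
* **Constant series** get autocorrelation 0 at all lags and Pearson
  `rho := 0` (hence `d_cor = sqrt(2)`), by declared convention.
* **Degenerate pairs** are flagged, never scaled to NaN; no metric returns
  NaN on any pair that passes the variance filter (property-tested).
* **CDM quantization** maps a scaled value `v` to bin
  `min(floor(8 v), 7)`, one byte per point, and symmetrizes over the two
  concatenation orders; compression levels are whatever `memCompress`
  fixes (xz 9 / gzip 9) and are recorded in the distance-table metadata.
* The DTW, TAM and Fréchet recursions are compiled (Rcpp); all twelve
  kernels are verified against independently written oracles — exhaustive
  path/coupling enumeration for the elastic distances, direct-formula
  loops for the rest — to 1e-12, and a from-scratch plain-R implementation
  of the entire screen reproduces the packaged pipeline's distance table
  and consensus counts on simulated cohorts.

## Behaviour of the selection rule, and known limitations

The rank-based 1% rule has a hard combinatorial consequence: with tie-free
distances each metric selects exactly `floor(alpha N)` genes, so at most
`12 floor(alpha N) / k` genes can be significant in `>= k` metrics. Two
practical corollaries, both visible in the test suite:

* **Recall is capped by `alpha`.** If more than `~ 12 floor(alpha N)`
  genes are truly divergent, no consensus threshold can recover them all:
  the screen is a *top-slice* ranking, not a calibrated hypothesis test.
  In a 2,000-gene cohort with 50 planted delayed genes (about 930 pass the
  variance filter, so ~9 selections per metric), measured consensus recall
  over ten simulations is about 0.59 at `>= 1` metric and 0.06 at `>= 6`
  — the cap binding, not a defect of the distances. On a paper-scale
  cohort (62,710 profiles, 600 planted) the same rule recovers roughly
  three quarters of planted genes at `>= 1` metric
  (`scripts/acceptance.R` recomputes this).
* **Not every metric is continuous.** TAM takes ratios of small integer
  step counts, CDM takes ratios of compressed byte lengths (at `T = 7` the
  7-byte messages compress to essentially constant sizes, so CDM ties
  globally and selects nothing — it is retained for completeness of the
  metric family but contributes no discrimination at this series length),
  and the Fréchet distance on jointly scaled pairs has an atom at exactly
  1.0, the scaling ceiling. Tie groups at the cutoff are handled by the
  all-or-none rule; the exact-cardinality property holds for the nine
  continuous metrics.

Other limitations: the screen compares exactly two conditions over a
shared time grid (no multi-arm designs, no missing time points); it has no
notion of replicate-level uncertainty after aggregation, so a gene with
wildly inconsistent replicates and a gene with tight ones are treated
alike; and the empirical null is global, so a strong planted contingent
slightly inflates the tail threshold for everything else.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at 62,710 genes once (the
paper-scale rehearsal), the null calibration at 5,000, the selection
cardinality check at 10,000, and the recovery experiment at 10 x 2,000;
oracle comparisons for the elastic distances use series of length 2–5,
where exhaustive path enumeration is cheap. These sizes were chosen so the
whole suite documents the method's behaviour from unit identities up to
realistic scale on a single CPU.
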