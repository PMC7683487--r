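---
title: "Modelling competing number-format effects in speeded digit comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competing number-format effects in speeded digit comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitsim)
```

## The task and the model

digitsim models a speeded relative-quantity task: on every trial a single
numeral (the *probe*) appears and the participant judges, under a 1,500 ms
deadline, whether it denotes a quantity greater or less than five (the
*standard*). The probes are the digits 1–4 and 6–9, shown either as Arabic
digits or as Mandarin numerals (一 … 九) in separate condition blocks. Three
trial-level predictors compete to explain response time:

* **W** — the Welford numerical-distance term, `log(L / (L − S))` with `L`
  and `S` the larger and smaller of probe and standard. It captures both the
  distance effect (comparisons get faster as the probe moves away from the
  standard) and the size effect (at equal distance, larger quantities are
  harder: 6-vs-5 yields a larger term than 4-vs-5).
* **PSM** — the physical similarity of the probe to the standard with both
  rendered in Mandarin.
* **PSA** — the same similarity with both rendered as seven-segment Arabic
  digits.

Physical similarity between two glyphs is `P = O / D`: the number of line
segments the two glyphs share divided by the number of segments in exactly
one of them. Identical glyphs have `D = 0`; the package treats that as a
degenerate input rather than a score, which never arises in the task because
the standard is never shown as a probe.

The analysis model is a mixed-effects regression of natural-log RT on the
standardized predictors with participant as a random variable:

```
log RT_ij = (β0 + u0_j) + (βW + uW_j) W_z + (βPSM + uPSM_j) PSM_z
            + (βPSA + uPSA_j) PSA_z + ε_ij
```

The scientific interest is in the fixed slopes, in the per-participant
slopes (fixed effect plus predicted participant deviation), and in how the
PSM and PSA slopes covary across participants: a negative within-condition
correlation between them is the signature of two format-specific encodings
competing for the same comparison process, and a positive cross-condition
correlation of the PSM slope indicates a stable translation into the
Mandarin format regardless of the presented format.

## Glyph encodings

Encodings are curated data, not computation. Arabic digits live on the
"digital figure 8" seven-segment grid. Three digits have genuine display
variants (6 with or without the top bar, 7 with or without a top-left serif,
9 with or without the closing bottom bar); all variants ship as data. The
default variant set is the one whose similarity-to-5 profile correlates most
strongly with the Welford term (r = 0.64), the combination that best
reproduces the published correlation structure for this family of encodings;
the chosen set is stamped into every output's metadata.

The Mandarin numerals were transcribed onto a shared unit grid so that
strokes occupying the same position in two glyphs carry the same segment id.
Graphical stroke decompositions leave real ambiguities — whether 五's left
stroke is slanted (so that 四's vertical frame does not share it), whether
九's bending stroke shares the right vertical of 五, whether the legs of 六
and 八 coincide. We resolved them by rendering each candidate
(`plot_glyph()`) and preferring the reading that keeps the predictor
correlation structure in the qualitative regime expected of these measures:
PSA–Welford strongly positive, PSM–Welford weakly negative, PSM–PSA small:

```{r}
tab <- build_predictor_table()
round(predictor_correlations(tab), 3)
```

Because the digit set is fixed and exhaustive, predictors are standardized
with the population (n-denominator) variance over the eight probe digits.
Under the equal-frequency design, trial-level standardization differs only
by a constant factor, which the z-scoring absorbs — as it absorbs the
Welford constants `a`, `k` and the choice of log base, which is why the
defaults return the bare natural-log term.

## The synthetic cohort

The generator is the generative counterpart of the analysis model. Per
participant it draws the eight coefficients (intercept and three slopes, per
condition) from a multivariate normal whose means are the canonical
condition values (Arabic: intercept 6.16 log-ms, slopes 0.04, 0.01, −0.01
for W, PSM, PSA; Mandarin: 6.19 and 0.05, 0.01, −0.014) and whose
correlation structure carries the individual-differences signature
(within-condition corr(PSM, PSA) slopes −.43 Arabic / −.58 Mandarin;
cross-condition +.42 for PSM, +.26 for PSA). Trial RTs are
`exp(linear predictor + N(0, σ))`; responses are wrong with a
participant-specific Beta-distributed probability; RTs at or past the
1,500 ms deadline become timeouts with no response.

Values the analysis literature does not pin down are package defaults,
chosen once: random-effect SDs of 0.10 (intercept) and 0.02 (slopes),
residual SD 0.15 on the log scale — sized so that essentially all correct
RTs fall inside the deadline at the default intercepts — and error-rate
dispersion matched to between-participant SDs of .026/.025 via the Beta
parameterization. Errors are independent of the predictors by default
because the analysis treats accuracy only as an overall rate.

What the generator does *not* emulate: sequential effects (practice,
fatigue, post-error slowing), right-skewed residuals beyond lognormality,
digit-dependent error rates, and RT–accuracy tradeoffs. Passing
parameter-recovery tests therefore shows the pipeline is consistent with its
own generative assumptions — not that real data meet them.

## Preprocessing and numerical choices

Preprocessing drops timeouts, excludes any participant-by-condition cell
with an error rate above 0.5 (the response-key-reversal signature produces
rates above 0.96 and is always caught), keeps correct trials, trims the
fastest and slowest 0.5% of RTs pooled within condition (rank-based: exactly
`floor(n × .005)` trials per tail; a per-participant trim is available via
`clean_config(trim_scope = "participant")`), and takes natural logs.
Already-cleaned data pass through unchanged, making the step idempotent.
Note that re-trimming data simulated at post-trim slope values attenuates
the recovered Welford slope by about 5%; this is a property of the trim
itself, visible in any recovery study that applies it.

The mixed fit defaults to trial-level data with a fully parameterized
random-effect covariance, estimated by REML. Singular or non-converging fits
fall back to uncorrelated random effects, then to a random intercept only —
always flagged in the result and logged by `run_analyze()`. Slope tests are
reported as F = t² on `(1, n_obs − n_participants − 3)` denominator degrees
of freedom. That convention mirrors printed F statistics whose denominators
match participant-by-digit *cell* counts (63 participants × 8 digits gives
7 × 63 − 3 = 438), which hints the original analyses may have been fit to
cell means; `fit_condition(mode = "cells")` provides exactly that
granularity, and a large-sample normal p-value accompanies every test so
the df convention is never load-bearing. Whether the published r² of ~.3
was computed at trial or cell level is likewise unstated; we report the
squared correlation of fitted and observed log RT at the granularity the
model was fit to.

Per-participant slopes default to fixed effect plus BLUP deviation, which
shrinks noisy individual estimates toward the population mean and slightly
attenuates between-participant correlations; `slopes = "ols"` gives the
unshrunken per-participant least-squares fits instead. Cohen's d for paired
contrasts is `t/√n`, which is algebraically `mean(diff)/sd(diff)`.

## Parameter recovery

`recovery_experiment()` closes the loop: simulate with known values, analyze
with the pipeline, summarize bias, spread and the Monte-Carlo standard error
of each mean estimate, plus the rate at which the four slope correlations
reproduce their generating signs. The package's acceptance checks run 20
replicates of the full design (63 participants × 480 trials per condition);
at that scale one replicate costs a few seconds, and the mean recovered
Welford and PSA slopes land within a few percent of the generating values,
with all four correlation signs reproduced in well over 80% of replicates.

```{r recovery, eval = FALSE}
rec <- recovery_experiment(n_participants = 63, n_reps = 20, seed = 1)
tidy(rec)
glance(rec)
```

A small run (fewer participants, 2 replicates) exercises every stage in
seconds and is what the examples and the quick tests use.

## Known limitations

* Similarity is segment-set overlap only; stroke order, curvature and
  pixel-level overlap are out of scope, and the Mandarin transcription is
  one defensible reading of a graphical decomposition, shipped as editable
  CSV data rather than asserted as ground truth.
* The generator's lognormal, sequentially independent RTs are a convenience,
  not a claim about human RT distributions.
* The per-slope F-test df convention is a reporting choice among defensible
  ones; the normal-reference p-values are the stable companion.
* Real-data quantities that depend on the original trial files (exact mean
  RTs, F statistics, r² values) are outside what synthetic data can certify.
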