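---
title: "Synthesizing kinome array data with known ground truth"
author: "kinosynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing kinome array data with known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why synthesize kinome arrays

Kinome peptide microarrays measure the phosphorylation activity of a few
hundred kinase-substrate peptides, each printed as `l` within-array
replicate spots (typically 9). Benchmarking any step of the analysis
pipeline — background correction, variance stabilization, detection of
differential phosphorylation — requires data for which the correct answer
is known, and no public kinome dataset with known ground truth exists.

`kinosynth` provides that ground truth by construction, with two
complementary generators:

1. **Template simulation** from an explicit measurement-error model, used
   when no real arrays are at hand.
2. **Resampling synthesis**: given any repository of comparable arrays
   (real or simulated), build an *inter-array technical replicate* of a
   template array, and then *seed* a chosen set of peptides with genuine
   differential phosphorylation. Crucially, every spot value in a
   synthesized array is copied verbatim from a measured replicate set, so
   the subtle distributional quirks of the source data (skewness,
   heteroscedasticity, negative background-corrected values) are preserved
   rather than assumed away.

On top sits an evaluation loop that scores normalization methods by what
actually matters: their effect on the classification of peptides into
differentially and non-differentially phosphorylated.

## Data model

An array is a long tibble with columns `array_id`, `peptide_id`,
`replicate_index`, `foreground`, `background`. The background-corrected
intensity of a spot is `foreground - background` and **may be negative**:
at low signal-to-noise the local background estimate routinely exceeds
the foreground. The per-peptide summary `abc` is the mean
background-corrected intensity over the `l` replicate spots. Two arrays
are *comparable* when they carry the same peptides in the same order with
the same `l`; replicate spots are paired across arrays by their index,
a convention that physical arrays do not dictate but that all paired
statistics in this package use consistently.

## The measurement-error model

Template simulation uses the two-component (additive plus multiplicative)
error model for a background-corrected intensity,

    Y = alpha + mu * exp(gamma) + epsilon,
    gamma ~ N(0, sigma_mult^2),  epsilon ~ N(0, sigma_add^2),

with `alpha` the mean intensity of unphosphorylated probes and `mu` the
noise-free intensity. Its signature mean–variance relationship,
`Var(Y) = mu^2 e^{sigma_mult^2}(e^{sigma_mult^2}-1) + sigma_add^2`, is the
heteroscedasticity that variance stabilization is meant to remove. The
simulator adds an explicit raw background channel (`B ~ N(bg_mean,
bg_sd^2)` clamped at 0, `F = Y + B` clamped at 0) so that output files
carry raw foreground/background pairs like scanner exports do.

Per-peptide `mu` values are drawn from a two-part distribution: a point
mass at zero (unphosphorylated probes, `zero_fraction`) plus a lognormal
mixture. Across arrays of a repository, each peptide keeps a shared
anchor intensity re-drawn per array with a lognormal factor
(`between_array_sd`), so the same peptide is similar but not identical
from array to array.

### Default parameters and how they were chosen

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha_offset` | 50 | a.u. | small positive floor for unphosphorylated probes |
| `sigma_additive` | 45 | a.u. | sets the low-intensity noise floor; with `alpha_offset` it produces a small but nonzero fraction of negative corrected spots |
| `sigma_multiplicative` | 0.15 | — | ~15% replicate CV at high intensity, the mid-range of what kinome arrays show |
| `background_mean`, `background_sd` | 100, 20 | a.u. | typical scanner background scale |
| mixture | logN(log 800, 0.7) + logN(log 4500, 0.45), weights 0.75/0.25 | a.u. | right-skewed, clearly non-normal peptide means |
| `zero_fraction` | 0.03 | — | a few control/unreactive probes per array |
| `between_array_sd` | 0.12 | log units | cross-array 2-fold changes are rare, so the replicate-synthesis search almost always succeeds |

The defaults were fixed once, against the qualitative behaviour expected
of real kinome data and of the synthesis algorithms operating on it:
per-array peptide means reject Shapiro–Wilk normality; spot variance
increases with the mean; negative corrected intensities exist; the
replicate synthesizer routes its perturbation branch at the nominal rate
and its unseeded output is detected against the template at roughly the
nominal false-positive level of the paired t-test; and
Kolmogorov–Smirnov comparisons of template and replicate peptide-mean
distributions are non-significant in the vast majority of pairs. They are
study conditions, not tuning knobs: the test suite asserts these
properties at these defaults.

A second bundled condition, `low_signal_conditions()`, emulates arrays
dominated by weak signal with *overcorrected* background
(`alpha_offset = -120`, `zero_fraction = 0.3`): unphosphorylated probes
read below their local background, so roughly half of all spots — and
many whole peptides — are nonpositive after correction. This is the
regime in which the Log2 transform's zero-mapping destroys information,
and it is the condition under which the sensitivity contrast between
normalization methods is evaluated. With a positive offset the contrast
actually inverts: when a seeded change crosses zero, Log2 collapses one
side to a constant and the paired t-test detects the constant shift
easily, so Log2 can look spuriously sensitive. Only when both the
template and the seeded replicate sit wholly at or below zero does Log2
become blind, and that population only exists when unphosphorylated
probes centre below zero.

## Replicate synthesis

`synthesize_replicate()` builds, for a template `X` and a repository `R`
of all peptide replicate sets from `n` comparable arrays, an array `Y`
with no differentially phosphorylated peptides relative to `X`. Per
peptide `t`:

* with probability `theta` (the *noisy fraction*), compute the
  fold-change bounds around the template mean `abc_t` — `v = T*abc_t`,
  `w = abc_t/T` for positive means, `v = abc_t/T`, `w = abc_t*T`
  otherwise — and accept the first scanned candidate whose mean is
  neither statistically bigger than `v` nor statistically less than `w`
  (one-sided one-sample t-tests at level `alpha`);
* otherwise accept the first candidate whose mean is not significantly
  different from `abc_t` (two-sided one-sample t-test);
* if no candidate qualifies, copy the template's own spots.

`seed_phosphorylation()` then replaces requested peptides of `Y` with
candidates that are *statistically beyond* the bound (`> v` to
phosphorylate, `< w` to dephosphorylate). Requests that cannot be
satisfied — typically attempts to push an already extreme peptide
further — are reported as failed and excluded from the ground-truth
positive set, so the realized number of seeded peptides can be smaller
than the number requested.

Design choices where the procedure leaves room:

* **Scan order.** "An arbitrary candidate" is implemented as a fresh
  seeded random permutation of the repository per peptide, taking the
  first qualifier: reproducible, unbiased among qualifiers, and linear
  in `|R|` in the worst case. Entries are sampled with replacement and
  the template's own entries are eligible.
* **Zero-variance replicate sets.** The t-statistic degenerates; the
  predicates fall back to exact mean comparisons, the limit of the
  t-test as the standard deviation goes to zero.
* **`abc_t` exactly 0.** The bound branch is ill-posed (`v = w = 0`);
  the peptide falls back to the equivalence criterion against 0.
* **Sign-crossing fold changes.** The ratio definition of fold change
  covers only same-sign pairs; `generalized_fold_change()` returns `NA`
  as a sign-crossing marker. The algorithms never need a fold-change
  value there because all their decisions go through the `v`/`w`
  t-tests, which are defined for any signs.
* **One-sided versus two-sided.** "Not statistically bigger than `v`"
  and "statistically bigger than `v`" are one-sided tests; "not
  significantly different" is two-sided. No multiple-testing correction
  is applied anywhere in synthesis; the procedure is defined at raw
  `alpha`.
* **Branch assignment.** The noisy branch is a per-peptide Bernoulli
  draw with probability `theta`, not an exact quota.

## Normalization methods under comparison

**Log2** maps positive background-corrected values through `log2` and
everything else to 0. It is simple and fold-change interpretable, but it
collapses all nonpositive values onto one point (information loss) and
inflates variance just above zero.

**Generalized-log (glog/arcsinh)** applies
`h_i(x) = asinh((x - a_i)/b_i)` with per-array calibration `(a_i, b_i)`:
logarithmic for large `x`, linear near the offset, finite for negative
inputs, injective everywhere. Calibration is two-stage:

1. The pooled mean–variance relationship `Var ~ sigma_mult^2 (mean -
   alpha)^2 + sigma_add^2` is fitted to the per-peptide replicate
   statistics by maximum likelihood under a scaled chi-square model for
   sample variances (`estimate_error_model()`); this anchors the first
   array at `a_1 = alpha_hat`, `b_1 = sigma_add_hat / sigma_mult_hat`,
   the intensity at which the two noise components balance.
2. The remaining arrays are first aligned to the anchor by trimmed
   least squares on peptide means (so that a minority of genuinely
   differential peptides cannot drag the calibration), then refined by
   coordinate descent on a trimmed profile objective: the log of the
   pooled within-peptide variance of transformed values **plus the mean
   log-Jacobian penalty** `-2 log h'(x)`, evaluated on the fraction
   `lts_quantile` (default 0.9) of peptides with the smallest variances.
   The Jacobian term is essential: minimizing transformed variance alone
   is degenerate — any flattening of the transform reduces it — and in
   practice drags every non-anchor array toward a common wrong
   calibration. With the penalty the optimum sits at the
   variance-stabilizing calibration, which is the standard profile
   construction for this model family.

Numerical settings: coordinate descent with Nelder–Mead inner steps
(80 evaluations per array per sweep), at most `max_iter = 100` sweeps,
stopping when the relative objective decrease falls below `tol = 1e-8`;
non-convergence is flagged in the returned parameters and warned about,
with results still returned. Degenerate inputs (all values identical)
are rejected. Bit-exact agreement with any released VSN implementation
is explicitly not a goal; the contract is the variance-stabilization
property itself, which the test suite measures as the max/min ratio of
mean within-peptide variance across intensity deciles (< 2 after the
transform, > 10 before, on simulated data with known parameters).

## Detection and scoring

For a normalized (or raw) pair, each peptide's spots are paired by
replicate index and tested with a two-sided paired t-test; `p < alpha`
calls the peptide differential. All-zero difference vectors are never
detected (`p = 1`); constant nonzero differences always are (`p = 0`).
Against the seeded truth `P`, detection `F` and peptide universe `N`
yield the confusion partition `TP = P ∩ F`, `FP = (N−P) ∩ F`,
`TN = (N−P) ∩ (N−F)`, `FN = P ∩ (N−F)` and the four measures

    specificity = |TN| / (|TN| + |FP|)     sensitivity = |TP| / (|TP| + |FN|)
    precision   = |TP| / (|TP| + |FP|)     accuracy    = (|TP| + |TN|) / |N|

Undefined ratios are resolved and flagged so that averages over pairs
stay total: precision with no positive calls is 0, sensitivity with no
seeded positives is vacuously 1.

`run_performance_evaluation()` drives the whole loop (synthesize → seed
a uniform random subset with Bernoulli(0.5) directions → normalize →
detect → score) for each of `n_pairs` templates, deriving all child
seeds from one master seed. `compare_methods()` then reports, per
measure, a median-centred (Brown–Forsythe) Levene test and a paired
t-test on per-pair differences with `n' - 1` degrees of freedom. The
classical workflow chooses between equal- and unequal-variance t-tests
from the Levene result, but a *paired* design has a single difference
variance, so that switch has no effect on a paired test; we therefore
always run the standard paired t-test, report Levene alongside for
workflow fidelity, and add a Welch two-sample t-test as a sensitivity
check. Exactly constant per-pair differences (zero difference variance)
are reported as a deterministic difference rather than a t-statistic.

## What the generator does and does not emulate

Emulated: right-skewed non-normal peptide intensity distributions,
mean-dependent variance, negative background-corrected values,
within-array replicate structure, between-array similarity of the same
peptide, and (via resampling) the empirical replicate distribution of
whatever source data the repository holds.

Not emulated: spatial artifacts, print-tip and slide effects, scanner
saturation, and biological pathway dependence between peptides (real
kinome peptides are functionally related; here they are independent).
Passing tests on simulated repositories therefore demonstrate the
algorithms' statistical behaviour, not robustness to spatially
structured artifacts.

## Problem sizes used by the test suite

The suite works at the reference study shape — 48 comparable arrays of
297 peptides × 9 replicates — with 10 template/replicate pairs for the
synthesis self-consistency and seeding checks, 200 synthesis runs for the
branch-rate check, 50 pairs for distribution preservation, 20 pairs for
the null detection rate and for the normalization sensitivity contrast
(the latter at the low-signal condition), and 1000 random small instances
for each statistic-versus-oracle comparison. These sizes give stable
Monte-Carlo estimates for every property asserted while keeping a full
run in the low minutes on one core.

## Known limitations

* Candidate scanning is governed by observed summary statistics; with
  tiny repositories the equivalence search can fail often, silently
  degrading replicates toward exact copies of the template (the
  provenance attribute records this).
* The glog calibration assumes the two-component error model is at least
  approximately right; grossly different noise (e.g. saturated scanners)
  will mis-set `b_i`.
* Seeding against a bound derived from a noisy template mean inherits
  that mean's sampling error; for peptides near zero the realized fold
  change of a seeded peptide can be modest even though it clears the
  statistical bound.
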