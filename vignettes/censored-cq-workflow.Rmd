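---
title: "Censored-normal analysis of serum miRNA Cq profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored-normal analysis of serum miRNA Cq profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

High-throughput RT-qPCR panels report a quantification cycle Cq per (target,
sample) well. Cq is inherently a log2-scale abundance measure: one cycle is a
two-fold difference, and *lower* Cq means *higher* abundance. Serum is a
sparse matrix for miRNA: most of a 754-target panel never amplifies, and even
well-expressed targets drop out in some samples. A reaction that has not
crossed threshold by the last cycle is a *non-detect*. The central modelling
commitment of this package is that a non-detect is not a missing value in the
usual sense: the molecule's Cq exists but is only known to exceed the
detection limit \(L\) (here \(L = 40\)). Formally, per target \(i\) and group
\(g\),

\[ y_{is} \sim N(\mu_{ig}, \sigma_i^2), \qquad
   y_{is} \text{ observed iff } y_{is} \le L, \]

i.e. the data are **right-censored**, and every fit in the package maximizes
the censored-normal likelihood

\[ \ell(\mu, \sigma) = \sum_{\text{obs}} \log
   \frac{\phi\{(y_i - \mu)/\sigma\}}{\sigma}
   + n_{\text{cens}} \log\{1 - \Phi((L - \mu)/\sigma)\}. \]

Treating non-detects instead as absent (complete-case analysis) or as
pseudo-values at \(L\) biases group means toward the limit asymmetrically
when censoring rates differ between groups — exactly the situation a
differential-expression analysis is looking for. The two-group *tobit*
extension \(y^*_s = \beta_0 + \beta_1 g_s + \varepsilon\) gives the group
effect \(\beta_1\) directly on the Cq scale; after reference normalization
\(\beta_1\) is the \(\Delta\Delta Ct\) and the fold change is
\(2^{-\beta_1}\). p-values are two-sided Wald tests from the observed
information (a likelihood-ratio alternative would behave almost identically
at \(n \approx 127\); Wald is the standard tobit output and keeps per-target
cost at one fit).

A note on the fold-change convention: the combined output table reports
\(FC = 2^{-\Delta\Delta Ct}\), the standard relative-quantification
transform. Definitions of FC as a ratio of log-quantities that occasionally
appear in print are scale-ill-defined (the ratio changes under any rescaling
of the log base) and cannot produce fold changes spanning 0.05–16 from
Cq-scale effects; we treat them as typesetting shorthand for the same
\(2^{-\Delta\Delta Ct}\).

## Pipeline order and its rationale

1. **Well QC.** A well is kept only with amplification score \(> 1\), Cq
   confidence \(> 0.8\) and Cq \(\ge 6\); the comparators are deliberately
   literal (strict vs inclusive) and surfaced as arguments. A failed well is
   *excluded*, not censored: a loading or chemistry artifact says nothing
   about abundance, so it contributes neither a density nor a tail term to
   any likelihood, and counts as undetected (numerator only) in detection
   fractions whose denominator is the group's sample count.
2. **Hemolysis screen.** Red blood cells are rich in miR-451a, so serum
   hemolysis shows up as a small Cq(miR-451a) relative to the
   hemolysis-insensitive miR-23a-3p. Samples with
   \(\Delta Cq = Cq_{23a} - Cq_{451a} \ge 8\) are excluded; samples where a
   marker is missing are flagged indeterminate and kept by default (the
   alternative is configurable).
3. **Detection filter.** A target enters an analysis only if detected in at
   least 75% (inclusive) of the samples of *either* group of the comparison
   at hand; the filter is applied per comparison pair.
4. **Reference selection.** See below.
5. **Differential expression** on the reference-normalized, *un-imputed*
   matrix, with per-sample censoring limits \(L - f_s\) (the normalization
   factor \(f_s\) shifts each sample's limit along with its values).

## Reference selection

Stability algorithms need complete data, so non-detects among the candidate
pool are first imputed: per target and per arm (all endometriosis vs
controls, so that imputation cannot manufacture spurious between-arm
homogeneity), \((\hat\mu, \hat\sigma)\) are fitted by censored ML and each
censored cell is drawn from \(N(\hat\mu, \hat\sigma^2)\) truncated to
\([L, \infty)\). QC-excluded wells are drawn from the *untruncated* fitted
normal — they are technical dropouts, not evidence that the value exceeded
the limit. The inverse-CDF sampler works in log-probability space, so there
is no rejection loop and it remains exact arbitrarily far into the tail.
Imputed values exist only for stability scoring; the differential-expression
stage always returns to the post-QC missingness pattern (a test asserts the
masks are identical).

Four algorithms vote, implemented as genuinely distinct voters:

* **geNorm** \(M_i\): mean across-sample SD of the pairwise differences
  \(Cq_i - Cq_j\), with classic iterative worst-gene elimination (final pair
  tied at rank 1.5). Computed from the covariance matrix via
  \(\mathrm{Var}(x_i - x_j) = V_{ii} + V_{jj} - 2V_{ij}\), which makes the
  elimination loop cheap at panel scale.
* **Comparative \(\Delta Ct\)**: the same score, single pass, no
  elimination (identical to geNorm's first iteration — pinned by an exact
  test).
* **BestKeeper**: per-candidate Cq SD (its primary criterion, used for the
  rank), CV, and Pearson correlation with the per-sample mean index.
* **NormFinder**: per-group two-way decomposition on the Cq scale. The raw
  per-gene residual mean square \(t_{ig}\) is bias-corrected for the
  contamination introduced by estimating the sample effect from \(k\) genes,
  \(\hat\sigma^2_{ig} = (t_{ig} - \bar t_g/(k-1))/(1 - 2/k)\); the
  gene-by-group interaction \(d_{ig}\) is shrunk by its sampling variance,
  \(\tilde d = d\,\hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2/n_g)\) with the
  method-of-moments
  \(\hat\gamma^2 = \max\{0, \sum d^2/((k-1)(G-1)) - \overline{\sigma^2/n}\}\)
  — note the \((k-1)(G-1)\) degrees of freedom of the doubly-centered
  interactions — and the stability value is
  \(\mathrm{mean}_g |\tilde d_{ig}| + \mathrm{mean}_g \sqrt{\hat\sigma^2_{ig}/n_g}\).

The consensus score is the geometric mean of the four ranks (ties averaged);
lower is better, ties broken by geNorm M.

**Order of the screens.** The equivalence screen runs *before* the stability
algorithms, which see only the TOST-equivalent candidates. This was a
genuinely open design point, and the implementation decided it: NormFinder's
bias term centers the group means across the candidate genes, so regulated
candidates shift every other candidate's apparent inter-group bias by the
(signed) average of their effects. With regulated genes in the pool this
shared artifact is of the same order as the quantities separating the most
stable candidates, and consensus ranks among them become a lottery; the
original NormFinder guidance likewise asks for an unregulated input set.
TOST (two one-sided Welch tests at margin \(\delta\), equivalent iff
\(\max(p_{\text{lower}}, p_{\text{upper}}) < \alpha\)) is the screen. The
margin is not stated anywhere authoritative; the default \(\delta = 0.5\)
Cq (\(\approx\) 1.4-fold) is a conventional negligible-effect bound and is a
first-class argument. Note that TOST on raw Cq is also a *selection* on the
shared per-sample loading offset: if loading variability is large, genes
whose own noise happens to cancel the arms' offset difference pass
preferentially, and normalizing by them re-introduces a global group shift.
This argues for tight input equalization upstream (as qPCR protocols that
quantify RNA input do) and is a known limitation of raw-scale equivalence
screening.

Finally, candidates detected in \(\ge 95\%\) of samples are eligible, the
top \(k = 3\) by consensus rank become the reference set, and the per-sample
normalization factor is the arithmetic mean of their observed Cq values. A
sample missing a reference after QC is dropped with a warning rather than
normalized by a 2-of-3 mean, which would shift its factor by a
reference-specific offset; mean-of-available is available as an explicit
choice.

## The synthetic cohort

The generator (`sim_config()`, `simulate_cohort()`) reproduces the design of
the study this package models: 754 targets, 60 control samples and 67
endometriosis samples split 40 endometrioma / 27 deep-infiltrating, detection
limit Cq 40, and — matching the observed sparsity of serum panels — about
130 targets detectable in at least 75% of either group. That last condition
is imposed through a two-tier abundance model (`n_expressed = 130` targets
with baseline means in Cq 22–34; the rest at Cq 40–46, i.e. at or beyond the
limit), because a single uniform mean range either floods the detection
filter or starves it. Per-target SDs are uniform on 0.5–2.5 Cq; a shared
per-sample loading offset (SD 0.5 Cq, the residual variability after RNA
input equalization) motivates reference normalization; planted references
have group-invariant means with SD 0.15–0.35 Cq; planted effects use random
signs with \(|\Delta Ct| \in [0.5, 4]\) by default (recovery experiments use
\([1.5, 4]\)), spanning fold changes of roughly 0.06–16; 2% of amplified
wells carry failing QC covariates; 3% of samples are hemolysed, implemented
by shifting miR-451a *down* (the red-blood-cell miRNA is in excess — the
insensitive marker is left alone).

What the generator does *not* emulate: plate/position effects, probe-specific
amplification efficiencies, heavy-tailed or multimodal Cq noise,
correlation between targets beyond the shared loading offset, covariate
structure (age, BMI, menstrual phase), and any real miRNA biology in the
annotation (`simulate_annotation()` is a synthetic-id generator). Passing
recovery tests therefore demonstrate that the estimators and the pipeline
logic are correct under the stated model, not that the model captures
every failure mode of real serum data.

## Numerical choices

* All likelihood optimizations run in \((\text{location}, \log\sigma)\) with
  analytic gradients, deterministic initialization at uncensored sample
  moments, BFGS, and a Newton polish until the gradient norm is below
  \(10^{-9}\) (so the uncensored special cases agree with closed forms to
  \(\le 10^{-6}\)). Tobit fits restart from two fixed alternative starts if
  the first fit has not converged; non-convergence is flagged, never hidden,
  and per-target failures become `NA` rows rather than dropped rows.
* Truncated-normal sampling is inverse-CDF in log space; there is no
  rejection loop to hang in deep tails.
* Degenerate inputs error loudly: all-censored targets (non-identifiable),
  \(\hat\sigma \to 0\), a completely censored arm in a tobit fit, zero
  variance in both TOST arms with unequal means.
* Geometric-mean rank aggregation is computed in log space; zero-variance
  BestKeeper candidates get \(r = 1\) by convention with a message.
* Randomness is seeded per stage (a fixed offset from the pipeline seed), so
  adding a stage never perturbs earlier draws and a manifest (config + seed)
  replays a run byte-identically.

## Problem sizes used in validation

The test-suite and the acceptance script validate at the design scale of the
study: censored-ML calibration uses 200 replicates at \(n = 127\); tobit
type-I error uses 1000 null replicates at \(n = 60 + 67\) with \(\sim 20\%\)
censoring; TOST size uses 1000 replicates at 500 per group on the
equivalence boundary; end-to-end recovery uses 100 (tests) or 30
(acceptance script) full cohorts of 754 × 127 with 3 planted references and
20 planted effects of \(|\Delta Ct| \ge 1.5\). These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands while keeping a full
validation run in the low minutes on one core.

## Known limitations

* Tobit fits are per-target; there is no information sharing across targets
  (no empirical-Bayes variance moderation) and no covariate adjustment.
* The equivalence margin, like every threshold in the pipeline, is a
  judgment call surfaced as an argument; results for border-stable
  references can depend on it.
* With \(k = 3\) references fixed, the geNorm pairwise-variation criterion
  for choosing the number of references is intentionally out of scope.
* Raw-scale TOST screening under large loading variability can bias
  reference selection (see above); the package assumes input-equalized
  material.
```{r, eval = FALSE}
# A minimal end-to-end run:
library(mircq)
sim <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(sim$ct, sim$samples, seed = 1)
head(res$combined)
```
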