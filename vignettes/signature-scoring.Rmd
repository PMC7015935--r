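---
title: "Stroma and proliferation signature scoring for checkpoint-blockade response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroma and proliferation signature scoring for checkpoint-blockade response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Motivation and model

Durable responses to PD-1 blockade are associated with two transcriptional
changes visible early on treatment: remodeling of the tumor stroma, read
out as up-regulation of cancer-associated-fibroblast (CAF) marker genes,
and a slow-down of tumor cell division, read out as down-regulation of
G2M-checkpoint and E2F-target genes. `icbscore` operationalizes both as
gene-signature scores on bulk RNA-seq and combines them into a single
response classifier. This vignette explains the model behind each stage,
the parameters that matter, the numerical choices, and what the synthetic
benchmark can and cannot show.

The pipeline assumes a two-group design — durable responders (DR) versus
nonresponders (NR) — with raw gene-level counts, and that the signal of
interest is a mean shift in expression between groups. It does not model
covariates, batch, or cellular composition; a stroma score rising because
fibroblast content rises is exactly the intended reading, not a confounder
to remove.

## Differential expression stage

Counts for gene $g$ in sample $s$ are modeled as negative binomial with
mean $\mu_{gs} = q_g \, f_s$ and dispersion $\alpha_g$
($\mathrm{Var} = \mu + \alpha\mu^2$), where $f_s$ is a sample size factor.

* **Size factors** use the median-of-ratios estimator: the median, over
  genes with positive counts in every sample, of each sample's count
  divided by the gene's geometric mean across samples. Factors are
  rescaled to geometric mean exactly 1 so normalized counts remain on the
  raw scale. A matrix with no all-positive gene row is an error that
  advises filtering first; `filter_low_expression()` (keep genes with at
  least 1 read in at least 3 samples) is the intended preceding step, and
  library sizes for FPKM are computed on the filtered matrix.

* **Dispersion** is estimated per gene by pooled method of moments across
  the two groups and floored at $10^{-8}$; genes whose moment estimate is
  sub-Poisson are thus treated as Poisson. No shrinkage across genes is
  attempted: with the small group sizes this design targets, moment
  estimates are noisy, and we compensate in the reference distribution
  rather than in the estimator (below).

* **The Wald test** contrasts group means of size-factor-normalized
  counts on the log scale, with the standard error propagated from the
  negative-binomial variance through the delta method. The statistic is
  referred to a $t$ distribution with $n_1 + n_2 - 2$ degrees of freedom
  rather than the normal: with $n$ of 6–8 per group the plug-in dispersion
  adds real variance to the statistic, and the normal reference is
  measurably anticonservative there. The test suite checks the resulting
  type-I error on null simulations (target $0.05 \pm 0.02$ at nominal
  0.05) and near-uniformity of null p-values.

* **Fold changes** are $\log_2((m_1 + c)/(m_2 + c))$ with pseudocount
  $c = 0.5$ normalized counts, which bounds fold changes when a group mean
  is zero. All-zero genes are flagged and assigned $p = 1$,
  $\log_2\mathrm{FC} = 0$.

* **Multiple testing** uses Benjamini–Hochberg step-up FDR; the DEG rule
  is strict on both axes ($q < 0.05$, $|\log_2\mathrm{FC}| > 1$,
  i.e. fold change > 2).

This stage is intentionally a plain, documented negative-binomial Wald
test, not a re-implementation of DESeq2 (no dispersion shrinkage, Cook's
filtering, or independent filtering): the package's contribution is the
downstream scoring, and the plain test keeps the statistical behavior
auditable. A concordance test against DESeq2's fold changes on a simulated
cohort guards against gross disagreement.

## Signature derivation

* **Stroma**: among a user-supplied CAF marker panel, candidates are the
  genes with $\log_2\mathrm{FC} > 0$ and unadjusted $p < \alpha$
  (default 0.05); the top $k = 10$ by p-value form the signature.
  Unadjusted p is deliberate — the panel is small and pre-specified, so
  genome-wide FDR control would be miscalibrated for this selection. Ties
  are broken by larger $|\log_2\mathrm{FC}|$, then lexicographic gene id,
  making the selection deterministic. Fewer than $k$ qualifying markers
  returns them all with a warning.

* **Proliferation**: the union of the G2M-checkpoint and E2F-targets sets
  (duplicates removed) filtered to $\log_2\mathrm{FC} \le -1$. Note the
  threshold is *inclusive* here while the DEG rule is strict; the two
  rules are kept distinct on purpose, matching the two selection
  procedures they implement. There is no top-$k$: every qualifying gene
  enters.

The package never hard-codes published signature gene lists; signatures
are always derived from data or supplied by the user (as GMT plus a
provenance side-car of per-member fold change and p-value).

## Scoring and classification

FPKM values are normalized per gene to the arithmetic mean over the
scoring cohort after adding $\epsilon = 0.01$ FPKM, a value well below
meaningful expression whose only role is to keep logarithms finite at
zero. The cohort is always the sample set scored together — a new cohort
is normalized to its own mean, which is what makes scores comparable
across independently processed cohorts; pre- and on-treatment samples
intended for a paired comparison should be scored jointly. A signature
score is the geometric mean of the signature genes' normalized values, so
it is invariant to any per-gene rescaling (probe efficiency, length bias)
and gives each gene equal leverage on the log scale.

The **combination score** is $\ln(\text{stroma}) -
\ln(\text{proliferation})$. The two panels move in opposite directions in
responders, so the log-ratio is monotone in both and reduces the 2-D
stroma-vs-proliferation separation to one threshold; any slope-1
half-plane in log space is exactly representable. The decision threshold
is either supplied or trained by maximizing Youden's J. Candidate
thresholds are the midpoints between adjacent distinct training scores
(plus the minimum score): placing the boundary between training points
rather than on one generalizes better to held-out cohorts, because
derived signatures carry a winner's-curse inflation of training-cohort
scores that a boundary anchored on a training point inherits. Ties in J
resolve to the smaller threshold (favoring sensitivity). An alternative
two-threshold rule (responder iff stroma $\ge t_1$ **and** proliferation
$\le t_2$) is available via `rule = "two_threshold"` for users who want
independent axis cutoffs.

## Evaluation utilities

Sensitivity and specificity are reported as exact percentages plus a
one-decimal rounding (half away from zero). Undefined metrics (no
positives in truth) are `NA`, never 0. The Mann–Whitney and Wilcoxon
signed-rank tests use exact enumeration for small tie-free inputs and the
tie-corrected normal approximation otherwise; zero paired differences are
dropped (Pratt's treatment of zeros is not offered), and an all-zero
difference vector reports $p = 1$ with a warning. The Kaplan–Meier median
is the smallest time at which the product-limit curve reaches 0.5 or
below — no interpolation when it hits 0.5 exactly — and the log-rank test
is restricted to two groups.

## The synthetic cohort generator

`generate_expression_cohort()` emulates the statistical structure the
analysis assumes, with defaults fixed at the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_dr`, `n_nr` | 6, 8 | samples per response group |
| `n_genes` | 2000 | gene universe |
| `n_caf_markers` / `n_planted_stroma` | 50 / 10 | CAF panel and planted up-regulated subset |
| `delta_up` | 1.5 | planted log2 effect in DR (stroma genes) |
| G2M / E2F / overlap | 70 / 70 / 20 | cell-cycle sets, union 120 |
| `n_planted_prolif` / `delta_down` | 7 / 1.5 | planted down-regulated subset and log2 effect |
| `base_meanlog`, `base_sdlog` | 4, 1.5 | log-normal base means, typical bulk RNA-seq shape |
| `dispersion` | 0.2 | NB dispersion $\alpha$ |
| `libsize_sdlog` | 0.25 | log-normal library-size spread |
| `length_range` | 300–10000 bp | gene lengths for FPKM (typical mammalian transcript span) |
| `pair_sdlog` | 0.1 | shared pre/on pair random effect (log mean) |

Counts are drawn as
$K_{gs} \sim \mathrm{NB}(\mu = q_g f_s 2^{\delta_g I[s \in DR]}, \alpha)$.
All randomness flows from one seed through per-component derived streams
(base means, lengths, library sizes, pair effects, counts), so regenerating
any component is reproducible and two cohorts from the same config and seed
are bit-identical. The growth simulator produces piecewise-exponential
volume trajectories from three archetypes (durable regression, transient
regression with relapse, sustained growth, with treated-arm frequencies
matching the observed 13/6/34 category counts), converts volumes to
isotropic caliper dimensions, and labels the *observed* trajectory by
explicit rules: DR if volume never exceeds 1.2× baseline after day 14 and
ends at or below baseline; SR if it shrinks ≥ 30% below baseline and later
exceeds baseline; NR otherwise. Survival is evented on the first
measurement day the 1500 mm³ burden limit is reached, censored at study
end or on independent sacrifice. These labeling rules are synthetic
operationalizations for testing, not claims about the mouse data, which
reported the categories qualitatively.

### What the benchmark shows — and what it does not

The test suite and `scripts/acceptance.R` verify, on this generator, that
the pipeline recovers at least 7 of 10 planted stroma genes and 5 of 7
planted proliferation genes in at least 80% of seeds, that a combination
classifier trained on one cohort reaches at least 80% held-out sensitivity
and specificity on an independent cohort, and that the DE stage's type-I
error is within $0.05 \pm 0.02$ on null cohorts. Problem sizes were chosen
as the smallest that make these rates stable: 25 seeds for recovery, 20
train/test seed pairs for held-out performance, 10 null cohorts of 2000
genes for calibration.

The generator emulates mean shifts with gene-wise independent NB noise.
Real cohorts additionally have correlated genes (co-regulation, cellular
composition), batch and processing effects, outlier samples, varying
sequencing depth by orders of magnitude, and signatures whose member genes
do not share one common effect size. Passing these benchmarks therefore
demonstrates correctness of the computations and sane statistical behavior
under the assumed model — not clinical performance on patient data.

## Known limitations

* The DE stage has no covariates, no multi-factor designs, and no
  dispersion shrinkage; very small or very dispersed cohorts will favor a
  dedicated DE package.
* The combination rule is a stand-in formalization (log-ratio with a
  trained threshold); other monotone combinations are possible and the
  two-threshold variant is provided for comparison.
* Whether FPKM should use effective or annotated transcript length is
  left to the caller, who supplies the length table.
* Affinity prediction for neo-antigen candidates is an external input;
  the package only enumerates windows and applies the < 500 nM filter to
  a supplied table.
* Ortholog mapping between species is the caller's responsibility; gene
  identifiers are matched case-sensitively after whitespace stripping.
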