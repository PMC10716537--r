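---
title: "Methods: ensemble attribute weighting for calorie-restriction signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble attribute weighting for calorie-restriction signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsig)
```

## The problem and the model

A calorie-restriction (CR) experiment yields a gene × sample count matrix
spanning several tissues, with each sample labelled control or CR. The
goal is a small gene signature that separates the two treatment states
*regardless of tissue*. `crsig` approaches this as a mixed-type feature
scoring problem: every gene becomes one numeric feature, the tissue of
origin becomes one categorical feature, and all features compete on the
same footing against the binary treatment label. If the experiment truly
carries a tissue-independent treatment signal, responsive genes will
out-score the tissue attribute; if tissue identity dominates the data,
the tissue feature will surface near the top of the ranking and the
"tissue-independent signature" claim fails transparently.

Seven attribute-weighting algorithms score each feature. Five of them
(information gain, gain ratio, symmetric uncertainty, chi-squared, Gini
index decrease) operate on the contingency table of discretized feature
values against the label; one (Rule) is the training accuracy of the best
single-feature decision rule; one (Relief) contrasts feature differences
to nearest same-class and opposite-class neighbors in the full joint
feature space, so it is the only member sensitive to feature
interactions. The ensemble defends against the idiosyncrasies of any
single criterion: entropy measures favour many-valued features, χ² is
sample-size dependent, Relief is noise-sensitive at small n, and the
plain sum of min-max-normalized weights W(f) = Σ_a w̃_a(f) requires a
feature to do well under most criteria to rank highly. No algorithm is
weighted above another; the sum is the published aggregation convention
for this family of workflows and the printed weight tables are consistent
with row sums on a 0–1 per-algorithm scale.

### Assumptions

* The label is binary and both levels are present (checked everywhere).
* Expression features enter the weighters as **log2 CPM**,
  `log2(1e6·count/library_size + 1)`. The upstream workflows this package
  emulates do not document the unit fed to their weighting models, so the
  unit is a design choice here: log2 CPM removes library-size artifacts
  (which would otherwise be a spurious "feature" correlated with batch)
  and compresses the dynamic range that would otherwise let a handful of
  extreme counts dominate equal-frequency binning. Raw counts
  (`transform = "none"`) and size-factor-normalized log counts
  (`"vst_log"`) are available alternatives.
* Samples are exchangeable within tissue × treatment cells; no covariates
  beyond tissue are modelled.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `bins` (equal-frequency discretization) | 5 | with n = 40 samples, 5 bins keep ≈8 samples per bin — enough to estimate per-bin class proportions; the legacy tools in this niche used similar unpublished defaults. Configurable; ties merge bins automatically. |
| `relief_k` (neighbors) | 10 | standard ReliefF practice; capped at min(class size) − 1 so small designs degrade gracefully. The pass is deterministic (m = n, ties broken by sample index), so a seed only matters if random tie-breaking were enabled. |
| `k_signature` | 20 | the signature size used in the emulated workflow. |
| DE dispersion | gene-wise method of moments, floor 1e-8 | no shrinkage: with 10 samples per tissue contrast the MoM estimate is noisy but unbiased enough to calibrate the Wald test (the null-simulation acceptance test measures type-I error directly); a shrinkage estimator could replace it behind the same interface. |
| HDI mass | 0.95 | reporting convention. |
| ROPE bounds | ±0.1·sd(y) | the emulated analyses name a ROPE but never its bounds; ±0.1 standardized units is the conventional "negligible effect" default, and both bounds are user-settable. |
| high-confidence threshold | s ≥ 3 sentences | the source text is internally inconsistent (">3" in one place, "3 … high" plus worked examples of 3–6 sentences elsewhere); s ≥ 3 matches every worked example. `confidence_class(s, high_threshold = 4)` gives the stricter reading. |
| `max_drugs` | 4 | combination-size cap for greedy repurposing; purely a reporting bound. |

## The synthetic world

`simulate_counts()` draws counts from NB(mean = L_j · 2^(b_g + t_{tissue(j),g}
+ δ_g·I(CR_j)), dispersion α_g), Var = μ + αμ². Defaults state the
emulated design: 1000 genes; 4 tissues × (5 control + 5 CR) = 40 samples
(the "n = 5 per region per group" design); baseline log2-means
Normal(6, 2); dispersions logNormal(log 0.05, 0.3), the moderate
overdispersion typical of laboratory-rodent bulk RNA-seq; 10 spiked
responder genes at |log2FC| = 2 split evenly up/down (published CR
signatures contain both directions); per-gene tissue offsets
Normal(0, 0.5) so tissue structure is present but does not drown the
treatment signal; library-size factors Uniform(0.7, 1.4), the ≈2-fold
depth variation of a routine sequencing run.

What a green test on this world establishes: the pipeline recovers known
responders through the full weighting → ranking path, ranks the tissue
attribute below them, calibrates the Wald test under a correctly
specified NB null, and separates labels on PC1 of a real signature. What
it does **not** establish: behavior under gene–gene correlation (genes
are simulated independently given tissue), outlier samples, batch
effects confounded with treatment, count structures far from NB, or the
gene identities of any real CR experiment — the published gene lists and
variance percentages require the original raw reads, which the package
deliberately does not download.

`simulate_relations()` generates a toy mined-literature corpus: random
typed edges with per-edge sentence counts 1 + Poisson(λ) and one
designated hub gene wired to every concept, so hub recovery and the
confidence-class mix are testable against closed-form Poisson tails.

## Numerical choices

* **Wald fit.** The two-group NB model is fit by per-group Newton
  iteration on the score equation Σ(y − μ)/(1 + αμ) = 0 (the MLE of each
  group mean at fixed α and offsets), giving β̂₁ = log(m̂₁/m̂₀);
  Var(β̂₁) = 1/A₀ + 1/A₁ with A_g = Σ μ/(1 + αμ) is the closed-form
  inverse Fisher information for the log-link group model. Convergence
  tolerance 1e-12 relative; non-convergence flags the gene and yields NA
  p. A group of all-zero counts triggers a +0.5 pseudo-count refit,
  flagged `pseudo`; an all-zero gene is `untestable`, carries NA, and is
  excluded from the BH denominator.
* **Discretization ties.** Equal-frequency edges are interior quantiles;
  duplicated edges are merged, so the effective bin count can drop (a
  constant feature collapses to one bin with a warning, weighting 0).
* **Tie-breaks.** Ensemble ranking: descending W, then lexicographic
  feature id. Rule thresholds: lower threshold wins. Relief neighbors:
  sample order. Greedy cover: coverage gain, then total sentence support,
  then lexicographic drug id. Every path is deterministic given inputs.
* **PCA.** Eigendecomposition of the Pearson correlation matrix of
  signature genes; zero-variance genes are dropped with a warning rather
  than failing the run (they carry no separation information); sign
  convention: the largest-magnitude loading of each component is
  positive.
* **HDI.** Sliding-window shortest interval over the sorted draws
  containing ⌈mass·S⌉ of them; exact for the reported draw vectors, no
  density smoothing.
* **Sampler.** (μ, δ) are drawn from their exact bivariate normal
  conditional; log σ by random-walk Metropolis (step 0.5) under a
  half-Cauchy(sd(y)) prior; 4 chains, half warm-up, pooled. Split-R̂ is
  logged and warned above 1.05 but never gates output — with a
  conjugate-dominated posterior the sampler mixes in a handful of
  iterations and a hard gate would only mask configuration errors.

## Open design choices made here

* **"Rule" weighting** is named but never defined in the source
  workflows; it is operationalized as best single-feature split accuracy
  (per-level majority vote for categorical features, exhaustive threshold
  search both directions for numeric ones). This is the classic OneR
  criterion and is validated against an independent exhaustive-search
  oracle in the tests.
* **Drug-combination selection** is formalized as greedy weighted set
  cover over the drug → signature-gene coverage sets. Greedy is within
  H(n) of optimal in general and equals the optimum on the designed test
  fixtures; the test suite also brute-forces all ≤10-drug instances it
  generates to verify coverage exactness and the H(n) bound, because
  instances where greedy is strictly suboptimal do exist.
* **Weighting on all genes** by default (no DE prefilter): whether the
  emulated workflow prefiltered is unstated; `prefilter_fdr` in the run
  config enables `fdr < t` prefiltering when wanted.
* **Pooled feature table** (all tissues in one table with tissue as a
  feature) is the primary analysis mode, since tissue independence is
  the question being asked; per-tissue tables are reachable by
  subsetting the sample table.

## Known limitations

* MoM dispersion without shrinkage loses power at n = 5 per group
  relative to empirical-Bayes approaches; the package trades power for
  transparency and replaceability.
* Relief materializes per-feature pairwise difference matrices (O(n²)
  per feature); fine at 10³–10⁴ features × ≤10² samples, not intended
  for single-cell-scale sample counts.
* The normal-likelihood posterior model treats proportional outcomes on
  the raw scale; strongly bounded or skewed outcomes would warrant a
  different likelihood family.
* The relation layer consumes already-extracted records; it performs no
  text mining and trusts entity typing in its input.
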