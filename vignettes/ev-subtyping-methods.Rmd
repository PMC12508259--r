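---
title: "Methods: subtyping extracellular-vesicle proteomes"
author: "evsubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtyping extracellular-vesicle proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsubtype)
```

## The problem

Extracellular vesicles (EVs) carry proteins from their cells of origin, so
the proteome of EVs shed by prostate cancer cells encodes the tumour's
molecular subtype: androgen-receptor-driven adenocarcinoma (AR+),
neuroendocrine (AR-/NE+) and double negative (AR-/NE-). Label-free
quantitative (LFQ) mass spectrometry of EV isolates yields peptide x sample
intensity tables with heavy left-censoring; turning those tables into
subtype calls requires a chain of steps - imputation, protein aggregation,
variance-stabilising normalisation, clustering, signature activity scoring,
differential enrichment, gene set enrichment, and projection of derived
signatures onto patient plasma cohorts. `evsubtype` implements that chain
end to end, together with a synthetic-data generator whose ground truth
makes every stage testable by recovery.

## The synthetic cohort generator

`simulate_cellline_cohort()` emulates the study layout: 9 cell lines
(4 AR+, 3 AR-/NE+, 2 AR-/NE-) x 2 biological EV isolations. Peptide
intensities follow the additive-multiplicative error model

$$x_{ji} = a_i + b_i\, e^{\eta}\, \mu_{j} + \epsilon, \qquad
\eta \sim N(0, \sigma_{mult}^2),\ \epsilon \sim N(0, \sigma_{add}^2),$$

with $\mu_j$ the product of a log2-normal protein abundance, a log-normal
peptide ionisation efficiency, and a $2^{\delta}$ subtype shift for
signature proteins in samples of their subtype. Detection is
missing-not-at-random: a cell is observed with probability
$\mathrm{logit}^{-1}((\log_2 x - m_0)/k)$, so censoring concentrates at low
intensity - the regime the 1%-quantile imputation is built for.

Defaults are fixed once as the study conditions and are not data-fitted:

| parameter | default | rationale |
|---|---|---|
| proteins / signature size | 2000 / 150 per subtype | desk-scale, stable enrichment statistics |
| peptides per protein | Poisson(4) + 1 | typical LFQ support |
| $\delta$ | 1.5 log2 | clear but not trivial subtype effect |
| abundance | $\log_2\mu \sim N(13, 2^2)$ | ~4 orders of magnitude dynamic range |
| $\sigma_{mult}$ | 0.2 | ~20% CV, typical LFQ replicate noise |
| $\sigma_{add}$ | 50 intensity units | detection-limit-scale additive noise |
| $m_0$, $k$ | 10 (log2), 1 | ~8-12% censored cells |

`simulate_patient_cohort()` builds patient profiles as simplex mixtures of
the three subtype mean profiles plus a shared plasma background; the
background proteins are on the generated healthy-plasma list by
construction, and a fraction of cell-line proteins is marked
ubiquitous-in-plasma so the healthy filter removes part of every derived
signature, as it does with real cohorts.

What the generator does *not* emulate: correlated peptide-level errors
within a sample, protein-inference ambiguity (each peptide maps to exactly
one protein), contaminant co-isolates, batch and acquisition-order effects,
and per-cell-line biology beyond an optional log-normal effect
(`sigma_line`, default 0). Recovery tests therefore show that the
implementation is correct under the stated model, not that the model
captures everything about real EV data.

## Preprocessing

The order is fixed - impute, then aggregate, then normalise - and
`aggregate_proteins()` refuses tables that still contain missing cells.

**Imputation** (`impute_missing()`): undetected cells are drawn from
$N(q, s^2)$ on the log2 scale, where $q$ is the 1% quantile of all detected
log2 intensities and $s$ the median over peptides (with at least two
detected values) of the per-peptide SD. The quantile is global by default;
a per-sample variant is exposed (`impute_scope = "sample"`) because the
convention is ambiguous in the field. Draws are back-transformed to the
linear scale; the detection mask is preserved so downstream steps can
distinguish measured from imputed values.

**Aggregation**: protein value = arithmetic mean of its peptides' linear
intensities; proteins with fewer than `min_peptides = 2` peptides are
dropped as unreliable single-peptide quantifications.

**Detection calls** (`detection_call()`) use the pre-imputation mask: a
protein is detected in a sample iff at least `min_peptides` of its peptides
were observed there.

## Variance-stabilising normalisation

`vsn_normalize()` fits the calibrated glog model
$t_{pi} = \operatorname{arcsinh}((x_{pi} - a_i)/b_i)$ by minimising the
negative profile log-likelihood

$$\frac{N}{2}\log \mathrm{SSR}(t) - \sum_{p,i}
  \log \frac{\partial\,\operatorname{arcsinh}((x-a_i)/b_i)}{\partial x},$$

with SSR the pooled within-protein sum of squares over the proteins kept in
the fit. Numerical choices:

* **Gauge.** The model is invariant to a common affine change, so the first
  sample is fixed at $a = 0, b = 1$; all calibration is relative to it.
* **Positivity.** Scale factors are optimised as $\log b$, so $b > 0$ is
  structural and never an error path.
* **Optimisation.** BFGS with analytic gradients; outer iterations
  re-select the trimmed set and stop when the relative objective change
  falls below `1e-8` (or after 100 iterations). On noise-free distorted
  data the fit inverts the distortion to numerical precision.
* **Robust trimming.** Differentially regulated proteins violate the
  calibration model. The fit trims the 10% of proteins with the largest
  within-protein residual sums *and* extends the trim to every protein
  whose residual sum is a robust outlier (beyond median + 5 MAD), capped at
  half the proteome. The extension matters: under the study conditions
  22.5% of proteins carry subtype shifts, and with a fixed 10% trim the
  calibration absorbs part of the regulation *asymmetrically* (the subtype
  groups have 8, 6 and 4 samples), which shifts null proteins between
  groups and inflates the differential false discovery rate several-fold.
  With the adaptive trim the regulated proteins leave the fit and the
  empirical FDR returns to its nominal level.

**Identifiability of the offsets.** The offsets $a_i$ are informed only by
measurements near the additive-noise scale; with abundances centred
$\sim 2^{13}$ and $\sigma_{add} = 50$, only a few percent of proteins carry
that information, so $\hat a_i$ has a sampling error of tens of intensity
units even at the converged maximum-likelihood fit. The scale ratios
$b_i/b_{ref}$ - which drive everything downstream - recover to within 1-2%.
This is an information limit of the design, not an optimiser artefact, and
the corresponding recovery check in the test suite documents it by failing
at its stated strength.

Because the pipeline imputes before normalising (the upstream convention
for this workflow), imputation-dominated low-abundance proteins enter the
calibration; this perturbs fitted offsets slightly but not the scale ratios
or any downstream result.

## Structure: clustering and PCA

Samples (or proteins) are clustered by UPGMA/average linkage on
$d = 1 - r$ with $r$ the Pearson correlation of profiles - distances lie in
$[0, 2]$. Items are sorted lexicographically before agglomeration so merge
ties resolve deterministically; zero-variance items get $d = 1$ to
everything and are flagged rather than erroring. PCA projects samples on
the principal axes of the row-centred matrix; explained-variance fractions
are non-increasing by construction.

`overlap_counts()` reproduces the subtype-core logic: a protein belongs to
a subtype set iff detected in *every* isolation of that subtype; the seven
Venn regions and the all-subtype core (with its percentage of all quantified
proteins - the denominator choice is documented in the function help) are
reported.

## Signature activity scores

* **Summative z-score** (`zscore_signature_score()`): per found gene,
  z-score across samples; per sample, sum over genes; min-max rescale to
  [0, 1] across the cohort. The score is cohort-relative and invariant to
  per-gene affine rescaling. If all raw scores tie, the score is reported
  as 0.5 with a `degenerate` flag rather than NaN, keeping report tables
  rectangular while staying honest. Replicates can be averaged on the raw
  scale before rescaling (`replicate_policy = "mean_of_replicates"`),
  matching how cohort scores are usually displayed.
* **NE correlation score** (`correlation_ne_score()`): per sample, the
  correlation between the sample's gene-wise z-scored values and a
  user-supplied neuroendocrine reference profile over the shared genes
  (at least 3 required). Pearson by default; Spearman via config, since
  the correlation flavour of the published integrated NEPC score is not
  fixed by convention.

## Differential enrichment and signatures

Per protein, a Welch two-sample t-test on glog values compares subtype
groups (AR+ vs AR-, and each AR- subtype vs rest). Welch is the default
because subtype groups have unequal sizes and no variance homogeneity can
be assumed; moderated-t approaches are deliberately out of scope.
Constant proteins get $p = 1$. Benjamini-Hochberg q-values are computed
over all tested proteins (Storey's $\pi_0$-corrected variant via
`qvalue_method = "storey"`); significance is $q < 0.05$.

`ternary_fractions()` expresses each protein's mean linear signal per
subtype as percentages summing to 100 - always on the linear matrix, since
percentages of signal require non-negativity - and bins the simplex into a
6-subdivision triangular density grid. Corner and edge points are assigned
deterministically to the adjacent upright bin.

`derive_subtype_signatures()` applies three auditable filters per subtype:
(1) significantly enriched proteins, ordered by q then |mean difference|;
(2) intersection with the patient-detected universe (a protein counts as
patient-detected iff it is a row of the patient matrix, whose upstream
detection filtering is that cohort's responsibility); (3) removal of
healthy-plasma EV proteins. The counts $n_1 \ge n_2 \ge n_{final}$ are all
reported. `patient_subtype_score()` averages the per-protein z-scores
(across patients) over each final signature; raw-level averaging is a
config option.

## Gene set enrichment

The ranking metric is signal-to-noise
$(\mu_A - \mu_B)/(s_A + s_B)$ with each group SD floored at
$\max(0.2\,|\mu|,\, 0.2)$ - the minimum-SD convention of the canonical
desktop implementation, adopted here as convention. The enrichment score
walks the ranked list, adding $|r|^p / \sum_{hits} |r|^p$ at hits and
subtracting $1/(N - N_H)$ at misses; with the default weight $p = 1$ this
is the weighted statistic, and at $p = 0$ it reduces exactly to the
classical KS statistic on hit positions (asserted against an independent
oracle in the tests). The running sum starts and ends at zero.

The null distribution uses *gene_set* permutation - random sets of
identical size drawn from the ranked universe - which is the appropriate
choice when there are too few samples for phenotype permutation. Each
(set, permutation) pair consumes an independent substream keyed by the set
name, so results do not depend on collection order and duplicated sets
score identically. Nominal p is $(1 + k)/(1 + n_{same sign})$, NES is the
ES over the mean |null ES| of the same sign, and FDR q follows the
sign-stratified NES-pooling of the original method (BH on nominal p as the
config alternative, since published FDR flavours vary).

## Reproducibility

A single master seed drives everything. Every stochastic stage derives a
named substream via `substream_seed(seed, label, ...)` (a 31-bit string
hash), so inserting or removing a stage never shifts the randomness
consumed elsewhere, and two runs with the same config produce byte-identical
report JSON.

```{r, eval = FALSE}
cfg <- run_config(seed = 7)
res <- run_pipeline(cfg, out_dir = "evsubtype_out")
str(res$report$structure)
```

## Problem sizes used in the checks

The packaged checks run the full study conditions (2000 proteins, 18
samples) for clustering, scoring, differential and GSEA recovery; the
imputation distribution check uses ~1.2 x 10^4 censored cells; null FDR
control averages 20 replicate cohorts of 500 proteins; oracle equivalence
checks cover up to 10^4 p-values and 12-leaf trees. These sizes are the
package's choice of a desk-scale experiment that keeps every statistic
stable.

## Known limitations

* The generator's independence assumptions (peptides, samples) make
  recovery easier than on real data with correlated structure.
* Offsets $a_i$ are weakly identified at realistic abundance scales (see
  above); downstream results depend on the well-identified scale ratios.
* The NE score requires a user-supplied reference profile; the package does
  not ship one.
* Patient mixtures are linear in linear-scale profiles; real plasma EV
  cohorts mix non-linearly and carry matrix proteins (albumin,
  immunoglobulins) that are only represented here as a generic background.
* GSEA FDR with 100 permutations is coarse (p floor 1/101); increase
  `n_permutations` for fine-grained q-values.
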