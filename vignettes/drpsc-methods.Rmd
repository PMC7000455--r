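---
title: "Methods: pharmacogene-weighted signature-reversal scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogene-weighted signature-reversal scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpsc)
```

## The model

Signature-reversal repositioning rests on one premise: a drug that helps
against a disease tends to push transcript and protein abundances in the
direction opposite to the disease's perturbation. `drpsc` quantifies that
premise as a single score per drug, weighted by pharmacogenomic knowledge.

Every input is reduced to a *perturbation signature*: a map from gene (or
protein) identifiers to log2 fold changes,

$$F_k^{\mathrm{drug}} = \log_2 \frac{E_k^{\mathrm{treated}}}{E_k^{\mathrm{control}}},
\qquad
F_k^{\mathrm{disease}} = \log_2 \frac{E_k^{\mathrm{case}}}{E_k^{\mathrm{normal}}}.$$

Drug signatures are computed per experimental condition — the tuple
(compound CID, cell line, dose, time) — after replicates sharing the full
tuple are collapsed by per-gene arithmetic means; vehicle controls are
averaged within cell line, because vehicle wells are shared across doses
and times on typical perturbation platforms. Disease signatures retain only
genes that pass a differential-expression filter (below).

A gene $k$ shared by a drug signature and a disease signature is
*inversely perturbed* when the two fold changes have strictly opposite
signs; a zero fold change is never inverse. Each inverse gene contributes a
perturbation score

$$\mathrm{PS}_k = |F_k^{\mathrm{disease}}| - |F_k^{\mathrm{drug}}|,$$

which is largest when a strong disease shift is opposed by a mild drug
shift, zero for an exact equal-magnitude reversal, and negative when the
drug overshoots. Over the full gene intersection of size $n$ (non-inverse
genes contribute zero), and over its pharmacogene subset of size $m$
(genes annotated as drug targets, enzymes, transporters or carriers), the
drug's score under one condition is

$$\Big[\tfrac{1}{n}\sum_{k=1}^{n} \mathrm{PS}_{g_k}\Big]
  \times
  \Big[\tfrac{1}{m}\sum_{i=1}^{m} \mathrm{PS}_{pg_i}\Big],$$

and the Drug Repositioning Perturbation Score (DRPS) of the drug is the
**maximum** of this product over all of its conditions. Drugs ranked by
DRPS are then cut into three contiguous classes (`high`, `intermediate`,
`low`) of sizes differing by at most one — the Drug Repositioning
Perturbation Class (DRPC). Validation asks, within each class, whether
drugs actually prescribed for the disease (the gold standard) score above
the rest, summarised as a Mann–Whitney AUC. Finally, multi-omics
candidates are the drugs classed `high` against at least one
transcriptomic *and* at least one proteomic disease signature, and never
`low` anywhere.

## Interpretation choices the formula leaves open

Several details of the score are underdetermined by its verbal definition;
`drpsc` fixes them as follows, each behind an explicit argument where a
user could defensibly want the alternative.

**Denominators $n$ and $m$.** "Total number of genes" is read as the size
of the gene intersection between the drug and disease signatures ($m$: its
pharmacogene subset). The intersection is the only set on which both fold
changes exist; using a union or a full platform gene count would make
scores depend on platform size rather than on reversal. Non-inverse genes
sit in the denominator with a zero numerator contribution, so a drug that
inverts only a sliver of the disease signature is diluted accordingly.

**Negative means and the product.** Both component means can be negative
(a drug that systematically overshoots). The product of two negative means
would be positive, rewarding exactly the wrong behaviour, so by default
each mean is floored at zero before multiplying (`floor_negative_means =
TRUE`). Disabling the floor reproduces the raw product.

**No pharmacogene overlap.** When $m = 0$ the pharmacogene mean is defined
as zero and the product vanishes: the method's premise is
pharmacogene-weighted evidence, so absence of overlap yields no score
rather than an undefined one.

**Strictness and ties.** Sign opposition is strict ($F = 0$ is never
inverse). Ties in the condition maximum are broken by the
lexicographically smallest condition key; ties in drug ranking are broken
by ascending CID, and when the cohort size is not divisible by three the
extra class slots go to the higher classes first. All three rules exist
purely so that reruns are byte-identical.

**Candidate quantifier.** Whether a candidate must be `high` in *every*
transcriptomic signature or in *at least one* is genuinely ambiguous when
more than one transcriptomic layer is supplied; `select_candidates()`
defaults to "at least one" and exposes `transcriptomic_quantifier = "all"`.

## Differential testing

Disease signatures come from a per-gene two-sided Welch (unequal-variance)
t-test with Benjamini–Hochberg FDR control, run on log2-transformed
intensities when `method = "log_welch_t"`. The reported effect is always
`log2((mean_case + pc)/(mean_normal + pc))` on the intensity scale. This is
a deliberate simplification: the scoring method consumes only
(gene, log2 fold change) pairs, so a count-model GLM with dispersion
estimation or variance-stabilising normalisation would change which genes
pass the filter at the margin, not the scoring machinery itself. The test
suite cross-checks the Welch ranking against limma's moderated t on
simulated data; for proteomics a per-sample median-centring of log2
intensities is available (`normalize = "median_center"`), and the
unadjusted `p ≤ 0.05` convention sometimes used for small proteomic
designs is reachable via `use_fdr = FALSE` (note it is non-strict, whereas
the q-value cut `q < threshold` is strict).

Two numerical conventions matter. A gene with zero variance in both groups
carries no within-group evidence, so its p-value is 1 regardless of the
mean difference (its fold change is still reported — such genes can still
enter a signature through `use_fdr = FALSE` only if p ≤ threshold fails,
i.e. effectively never at usual thresholds). And fold changes are
protected by a configurable pseudocount; the default is 0 because the
package's simulated intensities are bounded away from zero, while
count-like data should use 1. Genes whose drug fold change is undefined at
pseudocount 0 are dropped from the signature with a warning rather than
poisoning it with infinities.

## The synthetic study

All tests and the acceptance script run on synthetic data with planted
structure; `sim_config()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | gene universe |
| `n_degs` | 100 | planted disease genes |
| `effect_size` | 2 | planted \|log2 FC\| in cases |
| `noise_sd` | 0.2 | Gaussian noise SD, log2 scale |
| `n_case`, `n_normal` | 10, 10 | transcript-layer samples |
| `n_drugs`, `n_reversers` | 50, 10 | compounds / true reversers |
| `reversal_fraction` | 0.9 | share of disease genes a reverser inverts |
| `n_conditions_per_drug` | 3 | conditions per compound |
| `reversal_magnitude` | 0.25 | drug/disease magnitude ratio, best condition |
| `offtarget_magnitude` | 0.75 | magnitude ratio, remaining conditions |
| `pgl_fraction` | 0.1 | pharmacogene list size / universe |
| `pgl_enrichment_in_reversers` | 0.3 | share of the list drawn from disease genes |
| `n_case_protein`, `n_normal_protein` | 9, 8 | protein-layer samples |
| `protein_fraction` | 0.4 | share of the universe measured as protein |

Expression is generated on the log2 scale (baseline 7, i.e. intensities
around 128) and exponentiated, so intensities are always positive and the
noiseless limit reproduces planted fold changes exactly. Sample sizes,
effect size and noise describe a comfortably powered two-group design —
deliberately so, since the simulations exist to test the scoring
machinery, not the limits of the t-test; the protein layer's 9 vs 8
samples mirror the small cohorts typical of brain proteomics.

One generator choice deserves emphasis. Because
$\mathrm{PS} = |F^{\mathrm{disease}}| - |F^{\mathrm{drug}}|$, an *exact*
equal-magnitude reversal scores zero, and shrinking a drug's fold changes
*raises* its score. Planted reversers therefore oppose the disease at a
quarter of its magnitude (`reversal_magnitude = 0.25`) at their designated
best condition — a mild opposing perturbation, which is also the
biologically plausible regime for a short cell-line exposure versus a
chronic tissue contrast — and at three quarters of the disease magnitude
(nearer the zero-scoring full negation) at their other conditions. The
designated best condition then genuinely attains the condition maximum,
which lets the tests distinguish max- from mean-aggregation across
conditions. Non-reversers are pure noise signatures.

What passing tests do and do not show: the simulation plants clean
monotone structure with homoscedastic Gaussian noise and no batch effects,
no correlated genes, no dose–response ordering, and no platform
differences between the drug-database layers. Recovery of planted
reversers (mean high-class AUC ≥ 0.95 at reversal fraction 0.9, chance
AUC within 0.5 ± 0.1 under the null) demonstrates that the implementation
scores, ranks and classifies correctly — not that the method will achieve
any particular AUC on real archives, where signal-to-noise, signature
sizes and gold-standard quality are all less favourable.

## Problem sizes and runtime

The default test suite and the acceptance script use the study conditions
above: 20 simulation seeds for recovery and null calibration, 20 for
differential-stage calibration, 100 random instances (≤ 25 genes, ≤ 4
conditions, ≤ 6 pharmacogenes) for brute-force score equivalence, and a
reduced 200-gene/12-drug configuration for the byte-identity pipeline
reruns. These sizes were chosen so the entire verification cycle completes
in well under a minute on one core while keeping every Monte-Carlo margin
wide relative to its threshold.

## Known limitations

- Gene identifiers are opaque strings; cross-platform harmonisation
  (probe sets, Ensembl/symbol mapping) must happen upstream.
- Compound-name standardisation is an offline table lookup; there is no
  live PubChem querying, and unmapped compounds are silently excluded
  (with a message) rather than fuzzily matched.
- The differential stage offers no paired designs, covariates, or
  count-model dispersion estimation.
- Drug signatures from different platforms are pooled as-is; no
  cross-platform rescaling is attempted before the condition maximum.
- The score is asymmetric by construction: it rewards mild reversal over
  exact reversal. Users comparing drugs with very different perturbation
  magnitudes should keep this in mind when reading raw DRPS values; the
  class labels and within-class AUCs are rank-based and unaffected by
  monotone rescalings.

## A minimal worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, sim = sim_config(n_genes = 300, n_drugs = 15,
                                             n_reversers = 3))
res <- run_pipeline(cfg, "demo_run")
res$auc
head(res$scores_rna)
res$candidates
```

The same artifacts are produced by the command-line wrapper,
`system.file("cli", "drpsc.R", package = "drpsc")`, whose subcommands
(`build-db`, `disease-sig`, `score`, `candidates`, `evaluate`,
`similarity`, `simulate`, `pipeline`) are thin shells over the exported
functions.
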