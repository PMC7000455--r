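# drpsc

Signature-reversal drug repositioning with pharmacogene-weighted
perturbation scores.

`drpsc` is for computational pharmacologists and bioinformaticians who
want to rank a library of compounds by how strongly each compound's
induced expression perturbation *inverts* a disease's perturbation, with
the evidence weighted toward pharmacogenes (annotated drug targets,
enzymes, transporters and carriers). It covers the whole workflow:
building a drug-signature database from treated-versus-control expression
profiles, deriving disease signatures by differential-expression
filtering, scoring, tertile classification, ROC/AUC validation against a
prescribed-drug gold standard, and multi-omics candidate selection.

## The score

Every drug condition (compound CID, cell line, dose, time) and every
disease contrast is reduced to a log2 fold-change signature
F = log2(E_perturbed / E_reference). A gene *k* shared by a drug signature
and a disease signature is *inverse* when the two fold changes have
strictly opposite signs; each inverse gene contributes a perturbation
score

    PS_k = |F_k_disease| − |F_k_drug|

(positive when a mild drug shift opposes a strong disease shift). With *n*
the size of the shared gene set and *m* the size of its pharmacogene
subset (non-inverse genes contribute 0), the drug's score is

    DRPS = max over conditions of  [ (1/n) Σ PS_gene ] × [ (1/m) Σ PS_pharmacogene ]

Ranked drugs are cut into three classes of near-equal size — high,
intermediate, low (the DRPC) — and validated per class by the
Mann–Whitney AUC of prescribed versus non-prescribed drugs. Multi-omics
candidates are drugs classed high against at least one transcriptomic and
one proteomic disease signature and never classed low.

Since external perturbation archives cannot ship with a package, `drpsc`
includes a first-class synthetic-study generator that plants reversing
compounds in a noisy drug database; every claim the package makes about
itself is verified on that generator (see the methods vignette,
`vignettes/drpsc-methods.Rmd`).

## Worked example

Simulate a complete multi-omics study — 1,000 genes, 100 planted disease
genes, 50 drugs of which 10 truly reverse the disease signature — then
score, classify, validate and select candidates:

```r
library(drpsc)
study <- simulate_study(sim_config(seed = 1))
head(study$scores_rna, 5)
#>    cid     drps gene_mean  pg_mean   n  m cell_line dose time drpc
#> 1 1007 2.114059  1.464369 1.443666 103 30       cl1 10um   6h high
#> 2 1004 2.079438  1.446491 1.437574 103 30       cl1 10um   6h high
#> 3 1006 1.986511  1.379739 1.439774 103 30       cl1 10um   6h high
#> 4 1009 1.971192  1.370468 1.438335 103 30       cl1 10um   6h high
#> 5 1010 1.961140  1.367011 1.434619 103 30       cl1 10um   6h high
```

Each row is one drug: `drps` is its score, achieved at the condition
(`cell_line`, `dose`, `time`) shown, with `gene_mean` and `pg_mean` the two
component means over `n` shared genes and `m` shared pharmacogenes, and
`drpc` the tertile class. The planted reversers are CIDs 1001–1010; all
ten top the table. Validation against the gold standard (the reversers):

```r
study$auc
#>          class n_pos n_neg auc
#> 1         high    10     7   1
#> 2 intermediate     0    17  NA
#> 3          low     0    16  NA
#> 4       global    10    40   1
```

All positives land in the high class and separate perfectly from the
high-class negatives (AUC 1); classes without positives have no defined
AUC. The multi-omics candidate rule (high in the transcriptomic *and* the
proteomic table, never low) recovers every reverser plus a few
noise drugs that happened to rank high in both layers:

```r
study$candidates
#>  [1] 1001 1002 1003 1004 1005 1006 1007 1008 1009 1010 1020 1026 1028 1031 1035
#> [16] 1043 1048
```

The micro-scale arithmetic is easy to check by hand: a drug with
F = (−1, +1) on two genes against a disease with F = (+3, +2) inverts only
gene 1 (PS = 3 − 1 = 2), so the gene mean is 2/2 = 1; if gene 1 is the
only shared pharmacogene the pharmacogene mean is 2/1 = 2:

```r
condition_score(
  perturbation_signature(c(g1 = -1, g2 = 1), "DGPS",
                         key = condition_key(1, "cl", "d", "t")),
  perturbation_signature(c(g1 = 3, g2 = 2), "CGPS", disease = "x"),
  pharmacogene_list("g1"))
#> <condition_score 1|cl|d|t> product 2 (gene_mean 1 over n=2, pg_mean 2 over m=1)
```

File-based workflows (TSV/GCT matrices, signature-database directories,
score tables) go through `run_pipeline()` or the command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "drpsc.R", package = "drpsc"))')" \
  pipeline --out demo_run --seed 1
```

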