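# crocr — risk prediction on common *and* rare variants with collapsing ROC models

`crocr` builds genetic risk prediction models from case-control genotype
data that mixes common variants with rare ones (MAF < 0.01). It is aimed at
statistical geneticists working with candidate-gene or exome panels where a
large fraction of the variants are too rare for ordinary locus selection to
use, yet collectively carry real signal.

## The method

Individuals are scored by the **likelihood ratio** of their multilocus
genotype. For a model on loci $L = (l_1,\dots,l_K)$, each observed genotype
tuple $G_m$ is a risk group scored by

$$LR(G_m) = \frac{P(G_m \mid \text{case})}{P(G_m \mid \text{control})},$$

estimated from group counts with Haldane smoothing. Ranking subjects by LR
yields the optimal ROC curve over those groups, summarized by the
Mann–Whitney AUC (ties count ½).

* **FROC** (`fit_froc()`): greedy forward selection — each step adds the
  locus that most increases the training AUC — with the model size chosen by
  stratified k-fold cross-validation.
* **CROC** (`fit_croc()`): before selection, a multistage collapsing
  procedure greedily grows groups of rare variants into **pseudo-common
  carrier indicators** (1 if the subject carries a minor allele at any
  variant in the group), raising their effective frequency so selection can
  use them; forward selection then runs over common + pseudo-common
  variants. With no rare variants present, CROC reduces exactly to FROC.

A transparent simulator (`sim_config()` / `simulate_dataset()` /
`run_depletion_sweep()`) generates Hardy–Weinberg genotypes with a logistic
disease liability and known causal truth, for calibration and method
comparison. See `vignettes/croc-methods.Rmd` for the full model description
and design choices.

## Worked example

Simulate a candidate-gene style dataset (120 cases / 280 controls, 50 common
variants of which 10 causal, 400 rare variants of which 100 weakly causal)
and fit a CROC model:

```r
library(crocr)

cfg <- sim_config(n_cases = 120, n_controls = 280, n_common = 50, n_rare = 400,
                  causal_common = 10, causal_rare = 100,
                  effect_common = log(2.2), effect_rare = log(4),
                  baseline_prevalence = 0.3, seed = 2026)
train <- simulate_dataset(cfg)

fit <- fit_croc(train, folds = 10, seed = 42)
fit
#> <CROC model> 4 selected loci (path length 9)
#>   loci: PCV1, PCV2, cv30, cv38
#>   training AUC 0.9603 | mean CV AUC 0.9394 (10-fold)
#>   collapsing plan: 153 pseudo-common variants from 347 rare variants

head(tidy(fit), 4)
#>    step locus train_auc cv_auc selected
#> 1     1 PCV1      0.864  0.864 TRUE
#> 2     2 PCV2      0.925  0.924 TRUE
#> 3     3 cv30      0.942  0.928 TRUE
#> 4     4 cv38      0.960  0.939 TRUE
```

The first two predictors are pseudo-common variants (`PCV1`, `PCV2`) — rare
variant groups the collapsing stage assembled — followed by two common loci.
`train_auc` is the in-sample AUC after each addition; `cv_auc` is the
cross-validated estimate that chose the final size. `predict(fit, newdata)`
returns per-sample LR scores; `autoplot(fit)` draws the selection trace and
`write_model(fit, "model.json")` serializes the model (byte-reproducibly)
for reuse.

The characteristic comparison — drop the common variants, keep the rares,
and measure held-out AUC on an independent replicate of the same truth:

```r
sweep <- run_depletion_sweep(cfg, common_counts = c(0, 50), repeats = 5, seed = 7)
sweep[, c("common_count", "method", "mean_auc", "ci_lo", "ci_hi")]
#>   common_count method mean_auc ci_lo ci_hi
#> 1            0   croc    0.604 0.554 0.642
#> 2            0   froc    0.521 0.479 0.576
#> 3           50   croc    0.632 0.612 0.666
#> 4           50   froc    0.602 0.549 0.645
```

With only rare variants in the data (`common_count = 0`), forward selection
alone is barely better than chance (AUC ≈ 0.52) while the collapsing
approach stays predictive (≈ 0.60); with the informative commons restored
the two converge. `plot_sweep(sweep)` draws this with confidence ribbons.

## Command line

A thin wrapper over the same functions supports shell pipelines:

```sh
crocr=$(Rscript -e 'cat(system.file("exec", "crocr", package = "crocr"))')
Rscript $crocr simulate --seed 11 --out-genotypes g.tsv --out-phenotype p.tsv
Rscript $crocr fit --genotypes g.tsv --phenotype p.tsv --seed 3 --out model.json
Rscript $crocr predict --model model.json --genotypes g.tsv --phenotype p.tsv
```

`fit` accepts `--no-collapse` (pure FROC), `--maf-threshold`, `--folds`,
`--pseudocount`, `--collapse-coding {indicator,burden}` and
`--cv-mode {fixed-path,nested}`; genotypes come from a TSV (samples × 
variants, minor-allele counts) or a biallelic VCF (`--format vcf`).

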