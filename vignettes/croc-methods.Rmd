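---
title: "Collapsing ROC models for risk prediction on common and rare variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsing ROC models for risk prediction on common and rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocr)
```

## The problem

Genetic risk prediction asks how well an individual's disease status can be
anticipated from their genotypes. Predictors built on common susceptibility
loci alone have shown modest accuracy, and sequencing studies add a large
number of rare variants (minor allele frequency, MAF, below 1%) that standard
selection algorithms essentially cannot use: a variant carried by two or
three people in a sample of a few hundred contributes almost nothing to any
single-locus measure of discrimination, however real its effect.

`crocr` implements two related approaches for case-control samples typed at
a mixture of common and rare biallelic variants:

* **FROC** (forward ROC): greedy forward selection of predictor loci that
  maximizes the area under the likelihood-ratio-ordered ROC curve, with the
  model size chosen by stratified cross-validation.
* **CROC** (collapsing ROC): a multistage collapsing step first aggregates
  rare variants into *pseudo-common* carrier indicators, then runs the same
  forward selection over common plus pseudo-common variants.

## Likelihood-ratio scoring and the optimal ROC curve

For a model using loci $L = (l_1, \dots, l_K)$, each individual carries a
*multilocus genotype*: the tuple of minor-allele counts at those loci. Each
distinct tuple observed in the training data is a risk group $G_m$,
$m = 1, \dots, M$. The group's score is its likelihood ratio

$$LR(G_m) = \frac{P(G_m \mid \text{case})}{P(G_m \mid \text{control})},$$

estimated from the group's case and control counts. Ranking individuals by
$LR$ is optimal in the Neyman–Pearson sense: among all orderings of the risk
groups, the LR ordering attains the highest ROC curve at every operating
point, and therefore the highest AUC. The test suite verifies this directly
by exhaustively permuting group orderings on small instances.

The AUC itself is computed as the Mann–Whitney two-sample statistic

$$\widehat{AUC} = \frac{1}{N_D N_{\bar D}}
  \sum_{i \in \text{cases}} \sum_{j \in \text{controls}} \psi(s_i, s_j),
  \qquad
  \psi(a, b) = \begin{cases} 1 & a > b \\ 1/2 & a = b \\ 0 & a < b, \end{cases}$$

which equals the trapezoidal area under the empirical ROC curve with tied
scores handled by diagonal segments. Ties are exact here, not a
floating-point accident: individuals in the same risk group receive the same
LR value computed from the same rational expression.

### Zero-frequency protection

A genotype group observed only in cases would have an infinite raw LR. By
default the estimate adds a Haldane-style pseudocount of $c = 0.5$ per group
and class:

$$\widehat{LR}(G_m) =
  \frac{(a_m + c)/(N_D + cM)}{(b_m + c)/(N_{\bar D} + cM)},$$

where $a_m, b_m$ are the group's case and control counts. This keeps every
LR finite and strictly positive. One subtlety is worth stating: the
*unsmoothed* frequency-ratio ordering is exactly the AUC-optimal ordering of
the observed groups (the test suite verifies this by exhaustive
permutation), while the smoothed ordering can swap very sparse groups — a
group seen in one case and no controls drops below a group seen in ten
cases and two controls. That costs a sliver of training AUC on sparse
tables and in exchange gives finite, stable prediction scores; rank order
is unaffected wherever both groups have non-trivial counts. Setting `pseudocount = 0` switches
to raw frequency ratios clamped into $[10^{-6}, 10^{6}]$ (`lr_cap`).

At prediction time a genotype tuple never seen in training has no estimated
LR; it receives `unseen_lr = 1`, i.e. neutral evidence. Missing genotype
calls are imputed to the major-allele homozygote by default
(`missing = "impute0"`); a `"category"` mode instead treats missingness as
its own genotype level.

## Forward selection and model-size choice

Selection starts from the null model (AUC 0.5). At each step every remaining
candidate is evaluated by the training AUC of the LR table over the current
loci plus that candidate; the best candidate joins the model, with ties
broken toward the lowest variant index so fits are reproducible. The path
stops when the best improvement is no larger than `epsilon` (default 0 —
"stops when the AUC no longer increases"), when `max_model_size` (default
20) is reached, or when candidates run out. The size cap bounds the
combinatorial growth of genotype groups; a warning is emitted once the
cross-tabulation exceeds 4096 observed groups, at which point LR estimates
are inevitably sparse.

Because the training AUC is non-decreasing by construction, it cannot choose
the model size; more groups always fit the training data better and overfit
more. The size is chosen by stratified $k$-fold cross-validation
(default `folds = 10`; cases and controls are shuffled separately with the
run seed and dealt round-robin, so every fold's case:control ratio is within
one individual of the sample's). Two protocols are available:

* `cv_mode = "fixed-path"` (default): the forward path is built once on the
  full data; each fold re-estimates the LR tables at the path's prefixes on
  its training rows and scores its held-out rows. The size with the best
  mean held-out AUC wins, ties going to the smaller model.
* `cv_mode = "nested"`: each fold re-runs forward selection from scratch on
  its training rows.

The fixed-path protocol is cheap and keeps the reported path well defined,
but its held-out estimates for sizes beyond the first are mildly
*optimistic*: the loci occupying those path positions were chosen using all
rows, including each fold's held-out rows. In simulations with a single
strong causal locus this shows up as the cross-validated choice often
keeping one or two incidental loci alongside the causal one (which is
essentially always found at step one). The nested protocol removes that
leak at $k$ times the cost; its fold-held-out AUC is an honest estimate, and
under the null it is centred at 0.5 (this is asserted in the test suite).
Neither protocol biases evaluation on genuinely independent data, which is
how all method comparisons in this package are scored.

## The multistage collapsing procedure

Rare variants are defined by pooled-sample MAF strictly below
`maf_threshold` (default 0.01). A group $S$ of rare variants is collapsed
into a pseudo-common variant by the carrier-union (CAST-style) indicator

$$X_S(i) = \mathbf{1}\{\exists\, l \in S : g_{il} \ge 1\},$$

i.e. 1 for individuals carrying at least one minor allele anywhere in the
group. A summed minor-allele count ("burden") coding is available behind
`coding = "burden"` but is not the default.

One pseudo-common variant is grown greedily: the seed is the available rare
variant whose single-variant indicator has the highest AUC (ties to the
lowest index); each subsequent step absorbs the rare variant that most
increases the AUC of the updated union, stopping when no addition improves
it. The within-group AUC sequence is therefore strictly increasing after the
seed. The procedure then repeats on the remaining rares until none are left,
so the finished *collapsing plan* is a disjoint, exhaustive partition of the
rare set. Uninformative singleton groups are still emitted — exhausting the
rare set is part of the contract — and it is the downstream forward
selection that discards useless pseudo-variants.

Because growth is AUC-guided, a control-enriched (protective) rare variant
is never absorbed into a case-enriched (risk) group: the union would lower
the AUC. Risk and protective variants therefore segregate into different
groups, which is how this multistage form of collapsing accommodates
bidirectional effects that a single all-rares burden variable would cancel
out. Protective groups tend to stay small, since growing a below-0.5-AUC
indicator "upward" is rarely possible; they remain available to the forward
selection, whose LR tables handle either direction of association.

Inside cross-validation the collapsing plan is, by default, the one built on
the full training data (`collapse_cv = "fixed"`), mirroring the fixed-path
selection protocol; `collapse_cv = "per-fold"` rebuilds the plan inside each
fold and implies nested selection. On data with no rare variants the
collapsing stage is empty and CROC reduces *exactly* to FROC: the same seed
produces a byte-identical serialized model, which the test suite asserts.

## The synthetic data generator

The benchmark whose shape this package emulates (a mini-exome
candidate-gene panel: 697 individuals of whom 209 are cases, 533 SNPs of
which 400 are rare, MAFs from 0.0007 to 0.45) is access-restricted, so
`sim_config()` / `simulate_dataset()` provide a transparent generative
substitute whose ground truth is known and parameterizable:

* per-variant MAFs drawn uniformly from configurable ranges
  (defaults $[0.05, 0.45]$ for common, $[0.0007, 0.01]$ for rare variants);
* genotypes under Hardy–Weinberg equilibrium,
  $g \sim \text{Binomial}(2, \text{MAF})$, with no linkage disequilibrium;
* disease status from a logistic liability
  $\text{logit}\, P(\text{case}) = \beta_0 + \sum_j \beta_j g_j$ over the
  causal variants, where $\beta_0$ is the logit of `baseline_prevalence`
  (the disease probability of an individual with no causal minor alleles);
* rejection sampling of individuals until the requested case and control
  counts are reached.

Defaults mirror the benchmark's shape: 209 cases, 488 controls, 133 common
and 400 rare variants, baseline prevalence 0.3 (the benchmark's case
fraction). Default effect sizes, used when causal counts are requested
without explicit effects, are odds ratios of 1.5 per allele for common and
10 per allele for rare causal variants — values typical of the effect-size
asymmetry assumed in rare-variant association work.

Two closed forms guide calibration and are re-derived independently in the
test suite: the population AUC of a carrier indicator with case/control
carrier probabilities $p_D, p_{\bar D}$ is
$0.5 + (p_D - p_{\bar D})/2$, and the population AUC of a single biallelic
locus follows from enumerating its three genotype groups under the logistic
model. Two consequences are worth noting. First, a rare-variant union with
population carrier frequency $q$ cannot exceed an AUC of
$0.5 + q/(2 \cdot \text{prevalence})$, so recovery experiments that need a
union AUC near 0.65 use a baseline prevalence of 0.10; at prevalence 0.3 the
target is unreachable for any effect size. Second, when cases are
oversampled relative to the prevalence (e.g. a balanced design at prevalence
0.1), strongly causal rare variants have enrichment-inflated sample MAFs
that can cross the 0.01 threshold and leak into the common set; study
designs in this package therefore match the case fraction to the baseline
prevalence when the rare/common boundary itself matters.

### What the generator does and does not emulate

It reproduces the *shape* that makes the method comparison meaningful — a
noise-dominated mixture of common variants and very rare variants, binary
phenotype, known causal subsets with configurable direction and strength —
and its two-replicate evaluation (train on one replicate, test on an
independent replicate of the same generative truth) keeps rare variants
present in both datasets, the problem that motivated the original
two-replicate design, while avoiding the train/test correlation that design
suffers. It does not emulate linkage disequilibrium, population structure,
genotyping error, or gene–environment effects. Passing tests therefore
demonstrate correctness and calibration of the algorithms under the stated
generative model, not performance on real sequence data.

### Study conditions used by the comparison experiments

The depletion sweep (`run_depletion_sweep()`) drops a random subset of the
common variants while keeping all rares, fits CROC and FROC on a training
replicate with a shared per-repeat seed (so comparisons are paired), and
scores both on an independent replicate. The packaged study conditions are
120 cases / 280 controls (case fraction equal to the prevalence of 0.3, for
the MAF-boundary reason above); 50 common variants of which 10 are causal at
OR 2.2; and 400 rare variants of which 100 are causal at OR 4. At those
effect sizes a causal rare variant has two to four carriers in the sample
and a single-variant AUC near 0.505 — individually indistinguishable from
noise, which is precisely the regime in which forward selection cannot use
rare variants and collapsing can. At the zero-common endpoint CROC reaches a
held-out AUC near 0.59 against FROC's 0.53, and the gap closes as
informative commons return; null calibration uses the same sample shape with
all effects zero (200 replicates in the acceptance tests, at which scale the
Monte-Carlo standard error of the mean AUC is about 0.002). These problem
sizes were chosen once, from the closed forms above, as the smallest designs
in which the phenomena of interest are clearly resolved.

## Numerical and degenerate-input choices

* AUC computations aggregate individuals by distinct score value and use
  exact tie handling; the implementation is checked against a literal
  pairwise double loop for exact equality.
* All greedy ties (forward selection, collapsing seed and growth) break
  toward the lowest variant index; fits with the same data, configuration
  and seed are bit-reproducible, and the model JSON writer emits
  shortest-round-trip number literals so a written model reloads to
  bit-identical predictions.
* `folds` must not exceed the smaller class count; data with a single
  phenotype class is rejected by every estimation routine.
* An empty rare set yields an empty collapsing plan (CROC = FROC); an empty
  forward path (no candidate improves on AUC 0.5) yields a null model that
  scores every individual at the neutral LR of 1.
* In VCF input the minor allele is re-derived from the pooled sample, not
  trusted from REF/ALT; sites where ALT is the major allele are flipped with
  a warning, and multiallelic records are rejected with their coordinates.

## Known limitations

* The LR table is a full cross-tabulation: beyond roughly a dozen loci the
  groups become sparse and prediction leans increasingly on the unseen-tuple
  fallback. The size cap and cross-validation mitigate but do not remove
  this.
* Fixed-path cross-validation is optimistic for model sizes beyond the
  first (see above); use nested mode when the CV curve itself is the
  estimand.
* Collapsing uses a hard MAF threshold; variants near the boundary can move
  between the common and rare sets across replicates of the same truth.
* The greedy group growth has no look-ahead: a pair of rares that is only
  jointly informative will not be collapsed together unless one of them
  improves the AUC on its own.
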