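---
title: "Methods: multimodal G x E x M yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal G x E x M yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maizeGxEM)
```

## The problem

Maize grain yield in multi-environment trials is shaped jointly by genotype
(G), environment (E), and management (M). The Genomes to Fields (G2F) style
of release ships six tables — trial records keyed by environment
(`location_year`) and hybrid, per-environment metadata (treatment, planting
date, issue comments), daily weather (16 features), soil profiles (23
features), crop-simulator outputs over soil depths and phenological stages,
and genotype call strings per hybrid and locus. `maizeGxEM` implements the
full path from these tables to a field-level yield prediction: joins,
imputation, feature engineering, a multimodal convolutional network
ensembled with gradient boosting, baselines, metrics, and a rule-based
hybrid-classification tool.

## Preprocessing

**Imputation hierarchy.** Treatment labels are imputed with the column mode
(lexicographic tie-break for determinism). Soil and simulated environmental
features use a two-pass hierarchy: first the mean of the same feature at the
same location over other years, then the state mean; anything still missing
is flagged rather than silently filled. Non-missing cells are never touched
— a property the test suite asserts on random tables.

**Weather.** Daily series are aggregated to 48 weeks, week $w$ covering
days $7(w-1)+1 \dots 7w$; days 337 onward are dropped so every environment
yields an exact $48 \times 16$ grid. The aggregator defaults to the mean for
all 16 features, with a per-feature override (e.g. weekly sums for
precipitation) because sums and means differ only by the constant factor 7
within complete weeks; the mean is the safer default when a week is used as
a level, not a total. Inputs shorter than 336 days are an error, and
already-weekly data is rejected rather than re-aggregated.

**Genotype encoding and locus selection.** Diploid call strings map to
dosages: `0/0` to 0, `0/1`/`1/0` to 0.5, `1/1` to 1, and every rarer
multi-allelic call to a single sentinel 0.15. Loci with any missing call are
dropped by default (a fractional threshold policy is available). The
informative-locus rule keeps a locus when, over $H$ hybrids, its count of
zeros is strictly below $(4000/4928)\,H$, its count of heterozygous 0.5
calls is at least $(1000/4928)\,H$, and no 0.15 code appears. The two
fractions re-express absolute counts from a 4,928-hybrid cohort so the rule
scales to any cohort size; the strict/non-strict inequalities follow the
rule's wording exactly. From the surviving loci a uniform random subset
(default 300) feeds the models; a regression test checks that model quality
is insensitive to which subset is drawn.

## Engineered yield features

For each state-hybrid combination observed in training years, the mean,
maximum, and minimum yields are features. Unseen combinations in the test
year are imputed as the average of the state-level mean and state-level mode
of each statistic column; the mode of a continuous column is defined on a
0.1 Mg/ha grid (most frequent value, smallest on ties) since a continuous
mode is otherwise ill-defined. Hybrid-level mean/max/min plus the mean
yields of the two parents (split from the `Parent1/Parent2` cross name,
each parent pooling every cross it appears in, with no reciprocal-cross
normalization) cover hybrids seen only rarely. Finally, a per-state yield
trend is fitted by ordinary least squares of yield on calendar year at row
level (every trial is one point, matching the idea of regressing each
state's yield values rather than yearly means):

$$\widehat{\text{yield}}_{s,n} = a_{s0} + a_{s1}\, n$$

Calendar year is used for $n$ directly (the `year_origin` argument switches
to an index from the first training year; both parameterizations give
identical predictions). Single-year states get slope 0 and the state mean as
intercept, flagged as degenerate. All features are computed strictly from
rows at or before the training cutoff; a leakage audit asserts that
corrupting every test-year yield changes no feature value.

## Models

**Baselines.** LASSO (glmnet, fixed L1 penalty 0.05), random forest (ranger:
400 trees, depth 15, $\sqrt{p}$ candidate features, node size 15 — the
closest available control to a minimum-split size of 15), and XGBoost
(depth 5, eta 0.05, subsample 0.75, 4,000 trees, exact method, single
thread for reproducibility) all consume the flat concatenation of every
block.

**The network engine.** No deep-learning framework is attached; the package
carries its own small, fully-tested engine: valid (unpadded) 1-D and 2-D
convolutions via im2col and one BLAS multiply, average pooling, embeddings,
dense layers, ELU activations, minibatch Adam on a mean-squared-error loss,
and optional L1 penalties on dense weights. Backpropagated gradients are
verified against central finite differences for every layer type in the
test suite.

**ELU.** $g(x) = x$ for $x > 0$ and $\alpha(e^x - 1)$ otherwise, with
$\alpha = 1$ by default; it is continuous at 0 and monotone for every
$\alpha > 0$, and is used on every layer except the linear outputs.

**Single-modal CNN-DNN.** All inputs flattened to one vector per row, then:
two 1-D convolutions (32 and 16 filters, kernel 5), average pooling (size
2), two further 1-D convolutions, a flatten, and three dense layers ending
in the scalar yield.

**Multimodal CNN-DNN.** Six branches: weather as a $48 \times 16$ grid
through two 2-D convolutions, pooling, flatten, dense; soil and genotype
through 1-D convolution blocks (these features have no meaningful order, so
kernels act as learned local feature mixers); metadata through one embedding
per categorical (dimension $\min(8, \lceil \text{cardinality}/2 \rceil)$,
plus a shared slot for unseen test levels) concatenated with the numeric
columns and two 1-D convolutions; the environmental-soil block as 7
parallel 2-D sub-blocks (six $10 \times 9$ depth-by-stage grids and the
$9 \times 9$ Flow grid) whose outputs are concatenated; and the phenology
features through a 1-D block. All branch outputs concatenate into two
L1-regularized dense layers (coefficient $10^{-4}$) and a linear output.
Exact filter counts and kernels are configuration, defaulting to the
32-then-16, kernel-5 pattern where the spatial extent allows it and kernel
3 on the small environmental grids (a $10\times9$ grid cannot survive two
kernel-5 convolutions plus pooling).

**Training choices.** Inputs are standardized per block (per column for the
metadata numerics) and the response is centered and scaled by training
statistics. Loss is MSE; the optimizer is Adam at learning rate 0.01, batch
size 32. Epoch counts are configuration; the defaults (60) suit the
synthetic cohort sizes below. Training is bit-reproducible for a fixed seed.

**Oversampling.** Before the yield-feature model is fitted, every observed
treatment except the standard and late-planting labels is oversampled:
4,000 resamples with replacement per eligible treatment, plus 1,000
resamples per eligible treatment relabeled as late planting (training data
contains no genuine late-planting rows in the emulated scenario). With five
eligible treatments this appends exactly 25,000 rows; originals are never
modified. The relabel pass spans the same eligible set as the 4,000 pass —
that is the only reading consistent with the 25,000 total.

**Ensemble.** The yield-feature XGBoost (metadata plus hybrid-level and
state-hybrid-level features only — no weather, soil, genotype, or simulated
environment columns) and the multimodal network are combined as
$w_{x}\,\hat y_{x} + w_{c}\,\hat y_{c}$ with $w_x + w_c = 1$. Weights are
chosen by scanning $w_x \in \{0, 0.1, \dots, 1\}$ for minimum RMSE on a
validation split; ties resolve toward the network. The validation split is
the last training year held out: both component models are refitted without
it for the weight search, then refitted on the full training window with
the chosen weights. The scan provably equals an exhaustive 11-point search
(oracle test).

## Evaluation

RMSE, its ratio to the observed mean (RRMSE), mean absolute error over the
observed mean (MAPE), and Pearson correlation, overall and per treatment.
The MAPE definition divides the *mean* absolute error by the observed mean:
a literal sum-form without the $1/n$ would grow with sample size and could
not sit on the reported 19–25% scale; the sum-form remains available via
`mape(..., literal = TRUE)`. Per-treatment squared errors conserve the
overall squared error under $n$-weighting, which the suite checks.

## Hybrid classification

Each hybrid-by-treatment yield distribution is summarized by its maximum,
minimum, median, and mean, then mapped to one of six classes by the first
matching branch: max at or below `t_low` is *extremely low*; min at or
above `t_high` is *extremely high*; a distribution straddling both
thresholds with span above `wide_span` is *wide range*; then the median
decides *high* / *low* / *moderate*. Defaults `t_low = 6`, `t_high = 10`,
`wide_span = 8` Mg/ha are an explicit reconstruction: they are chosen so a
drought distribution with modes near 6 and 12 Mg/ha lands in *wide range*
and typical standard-treatment distributions (mean near 10) in *high*. The
mean is carried and can replace the median via `use_mean`. All three
thresholds are arguments and CLI flags. The rule is total and, excluding
*wide range*, monotone under uniform yield shifts (property-tested).

## The synthetic generator

`generate_dataset()` emits the six tables at configurable scale with a
known ground-truth record. Yield is built additively: baseline 9.44 Mg/ha
(a typical multi-environment training mean; the matching spread arises from
state effects of sd 1.5 Mg/ha plus noise sd 1.0), ten causal loci at
±0.3 Mg/ha per dosage unit, treatment offsets (e.g. −2.5 for drought), a
late-planting penalty of 0.05 Mg/ha per day beyond day 140, Gaussian noise,
and clipping at zero. Missingness is injected per table (5% treatment/soil/
environment cells, 1% genotype calls — at desk scale the any-missing drop
policy removes roughly half the loci, leaving the informative-locus filter
a realistic population to select from). Weather is a seasonal sinusoid plus
environment-specific levels; the environmental tables are smooth random
depth-by-stage fields whose first group tracks the state effect so the
block carries real signal. The generator emulates shapes, keys,
missingness, and additive G x E x M structure; it does **not** emulate
weather dynamics, crop physiology, spatial correlation between neighboring
states, or heteroscedastic yield noise — so passing tests demonstrate that
the machinery recovers known structure, not that the models reach any
particular accuracy on real G2F data.

## Problem sizes and numerical choices

The shipped tests run on a 5-state, 2-locations-per-state, 2014–2021 cohort
of 60 hybrids and 500 loci (~2,900 trial rows), with the network fits on a
300-row training subsample against the full held-out 2021 split, filter
counts 8/4, and 25 epochs — sizes chosen so the whole suite exercises every
stage in minutes on one core. Model-quality comparisons (multimodal versus
single-modal, and versus the constant-mean predictor) are made at those
sizes across three seeds. Degenerate inputs are handled explicitly: empty
eligible-treatment sets warn and append nothing; single-year states get
flagged zero-slope trends; unseen categorical levels share one embedding
slot; all-missing columns and all-removed loci raise actionable errors.

## Known limitations

The engine is plain R: adequate at these scales but not for the full G2F
release (hundreds of thousands of plots), where a GPU framework would
replace it behind the same interfaces. The classification thresholds are a
documented reconstruction, not recovered constants. Headline accuracies
from the full public release are not reproducible at desk scale and are
deliberately not asserted anywhere in the suite.
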