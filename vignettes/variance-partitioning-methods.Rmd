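---
title: "Distance-based variance partitioning for longitudinal infant microbiota cohorts: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance partitioning methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Infant gut microbiota composition in a birth cohort varies with perinatal
exposures (birth mode, intrapartum antibiotic prophylaxis, parity),
gastrointestinal function (defecation frequency, stool consistency), diet,
and — often dominantly — with technical processing variables such as the DNA
extraction batch and the sequencing depth. This package quantifies each
covariate's share of community-level variation: the coefficient of
determination $R^2$ of a distance-based permutational multivariate analysis
of variance (PERMANOVA), computed per sampling age, adjusted for technical
confounders, screened across a covariate panel with false-discovery control,
and combined into cumulative models by small-sample AIC backward selection.
Because a real cohort of this kind cannot ship with an R package, every stage
is exercised against a Dirichlet-multinomial cohort simulator that plants
covariate effects of known magnitude, so recovery, calibration and power are
measurable rather than assumed.

## The distance model

For samples $i,j$ with genus-level relative abundances $p_{ti}$, quantitative
Bray–Curtis dissimilarity is

$$d_{ij} \;=\; 1 - \frac{2\sum_t \min(p_{ti},p_{tj})}
{\sum_t p_{ti} + \sum_t p_{tj}},$$

which on proportions reduces to $1-\sum_t \min(p_{ti},p_{tj})$. A count-space
variant (same formula on raw counts) is available behind
`bray_curtis(space = "count")`; the two differ whenever read depths differ.
We default to proportions because the modelled quantity is the composition.
Pearson ($1-r$ across taxa) and Aitchison (Euclidean on centred log-ratios,
pseudocount 1) distances are provided for sensitivity analyses, as is
family-level aggregation.

Gower centring turns squared dissimilarities into an inner-product matrix
$G = (I-\tfrac{1}{n}\mathbf{1}\mathbf{1}^\top)(-\tfrac12 d^2)(I-\tfrac{1}{n}\mathbf{1}\mathbf{1}^\top)$
whose trace is the total sum of squares. For an ordered term list with
cumulative hat projectors $H_k$, the $k$-th term's sequential (Type I) sum of
squares is $\operatorname{tr}(H_k G H_k)-\operatorname{tr}(H_{k-1}GH_{k-1})$,
its $R^2$ the ratio to $\operatorname{tr}(G)$, and its pseudo-$F$ the usual
mean-square ratio against the residual. Sequential decomposition is the point:
technical confounders (extraction batch as a categorical factor, processed
reads as a continuous covariate) occupy the leading positions, so every
candidate is measured on what remains after the confounders took their share.

Inference is by unrestricted permutation of sample identities — joint
row/column permutation of $G$ — recomputing every term's $F$ per permutation,
with $p=(1+\#\{F^*\ge F\})/(1+B)$ and $B=999$ by default. The
repeated-measures non-exchangeability of the pooled all-timepoint model is a
known limitation inherited from the unrestricted scheme; we keep it because
the per-age models (the primary analyses) have one sample per subject, and
document rather than fix the pooled case (restricted permutation blocks are
out of scope). For $n\le 7$ an explicit permutation matrix can be supplied,
making the test exact; the test suite verifies exact-enumeration equivalence
and, on Euclidean distances, equality of single-factor $R^2$ with classical
per-coordinate ANOVA $\eta^2$ at $10^{-8}$.

Aliased terms (for example a candidate identical to a confounder, or a factor
with one observed level inside a stratum) keep their position with zero
degrees of freedom and an `aliased` flag rather than failing the fit.

## Beta-dispersion

A significant PERMANOVA term can reflect unequal within-group spread rather
than a location shift. The dispersion check embeds the distance matrix by
principal coordinates keeping *all* axes; squared distance to the group
centroid is the sum over positive-eigenvalue axes minus the sum over
negative-eigenvalue axes (floored at zero before the square root), the
standard correction for semi-metric dissimilarities like Bray–Curtis. A
one-way $F$ on these distances is tested by permuting group labels and
recomputing centroids. Screens flag `uneven_dispersion` at $p<0.05$ next to
each variable so location claims can be read with the appropriate caution.
Against `vegan::betadisper` (used strictly as a cross-check), centroid
distances agree to $10^{-8}$.

## Screening, FDR and redundancy diagnostics

`screen_all()` runs the confounder-adjusted engine per timepoint and
variable, applies Benjamini–Hochberg adjustment *within the timepoint's
variable family*, and calls a variable significant under the dual rule
$p<0.05$ **and** $q<0.1$. The FDR family is configurable because the natural
family (per figure panel, per age, global) is a judgement call; per
timepoint-and-sample-type is the default and is logged. Interactions
(`var1:var2`) are screened sequentially after both mains and admitted as
cumulative-model candidates only at $p<0.05$; stratified screens (for
example parity within the three delivery classes) report raw per-stratum
p-values and skip strata smaller than the design size plus five.

Covariate redundancy is measured two ways: Spearman correlations (flagging
$|\rho|>0.3$, strictly) and symmetric uncertainty
$SU = 2\,\mathrm{MI}(X,Y)/(H(X)+H(Y))$ with plug-in entropies in nats and
equal-frequency discretisation of numeric variables into
$\lceil n^{1/3}\rceil$ bins. $SU(X,X)=1$; $SU=0$ exactly when the empirical
mutual information vanishes; constant variables yield a missing value rather
than a division by zero.

## Cumulative models under small-sample AIC

The selection criterion is
$$\mathrm{AICc} = 2k + n\ln(\mathrm{RSS}/n) + \frac{2k(k+1)}{n-k-1},$$
with $\mathrm{RSS}$ the residual SS of the distance model and $k$ the number
of design-matrix columns including the intercept (aliased columns excluded —
"number of parameters" is otherwise ambiguous for multi-level factors). A
variant replacing $n\ln(\mathrm{RSS}/n)$ by $n+\ln(\mathrm{RSS}/n)$ is
selectable via `form = "literal"`; it makes the criterion nearly insensitive
to fit quality, which contradicts the purpose of a selection criterion, so
the standard least-squares form is the default and both are recorded in the
trace.

Backward elimination starts from the full model (confounders never
droppable), evaluates every droppable term per step — interactions before
their mains; a main becomes droppable only when no retained interaction
references it — and accepts the single removal with the lowest AICc only if
it improves the criterion by **at least two units**. Ties break toward the
larger-df removal, then lexicographically, for determinism. Permutation
p-values are computed for the initial and final models only; intermediate
steps need only RSS.

The two-unit rule has a structural consequence worth stating: removing a
one-df term can improve AICc by at most $2$ (when RSS is unchanged), minus
the correction-term change, so single-df null covariates are essentially
never droppable at moderate $n$. This is a property of the criterion, not a
defect of the search. Cohort covariates in this setting are predominantly
multi-level (three delivery classes, three defecation classes, multi-level
stool and survey scales, many-level extraction plates), and the selection
benchmarks therefore plant multi-level (six-level) null candidates; with
those, 100 replicates at 300 subjects retain all three true medium-tier
terms in $\ge 95\%$ of replicates with a median of zero null survivors.

The pooled all-timepoint model orders terms (reads, subject identity,
sampling age, remaining variables). Any covariate constant within subject is
absorbed by the subject factor and reported as aliased with zero df — the
pooled model measures individual identity and age; time-varying covariates
(GI function, diet) are the meaningful remaining terms.

## Alpha diversity

After a single rarefaction draw to the smallest retained depth (seed
recorded; averaging over draws is not attempted), the panel reports Shannon
diversity in nats, observed richness, bias-corrected Chao1
$S_{obs}+F_1(F_1-1)/(2(F_2+1))$ (well-defined when doubletons are absent),
Pielou evenness $H/\ln S_{obs}$ (missing below two observed taxa), and a
rarity index defined as the sample skewness (third standardised moment,
unbiased-variance denominator) of $\ln(1+x)$ over all taxa including zeros.
The rarity definition is stated rather than inherited: upstream
implementations trim by quantile classes in ways their documentation does
not pin down, so a clean, reproducible definition is preferred and labelled.

## Differential abundance

Per-taxon tests run only on genera present in strictly more than 10% of
samples. The mean structure is `count ~ covariate (+ adjustment)` with
$\log(\text{reads})$ offset; the fitting cascade is negative binomial first,
Poisson when NB fails (non-convergence or a dispersion estimate at the
boundary, $\theta\notin(10^{-3},10^{5})$), quasi-Poisson when the Poisson
Pearson $\chi^2/\mathrm{df}$ exceeds 1.5, and generalised least squares on
$\ln(\text{relative abundance} + \tfrac12\min_{>0})$ as the last resort. The
thresholds are declared package defaults (the upstream wrapper this mirrors
does not publish its exact triggers); every row records the family used and
the diagnostics that chose it, making the cascade a pure function of the
data. Wald p-values are BH-adjusted across taxa within one
covariate-by-timepoint analysis; the dual rule applies. Reference levels
follow the "more standard" convention (vaginal delivery without antibiotics,
multiparous, lowest defecation class), configurable per variable.

## The cohort simulator

`simulate_cohort()` draws, per retained subject-visit, a composition from a
log-linear model: a fixed genus panel (twenty named genera with realistic
early/late log-abundance trajectories — bifidobacteria dominant early,
Bacteroides and butyrate producers rising toward two years — plus a
rank-abundance tail), a per-subject random intercept (SD 0.8 by default), an
optional family-shared intercept for transmission analyses, planted
covariate log-fold-changes, and a multiplicative batch effect on a random
20% taxon subset per extraction batch. The linear predictor is softmaxed,
Dirichlet-perturbed (concentration 50), and sampled multinomially at a
log-normal depth (median 16.8k reads). Covariates carry the cohort's
dependence structure: every C-section has intrapartum antibiotics by
construction, parity and the older-siblings indicator disagree with
probability 0.02, breastfeeding prevalence falls from 96% to 20% over two
years, defecation frequency and stool consistency drift with age, and
extraction batches of 80 fill chronologically across two sequencing
platforms. One global seed feeds named substreams (covariates, visits,
composition, depths, ...), so any component can be regenerated alone and a
fixed seed reproduces counts bit-identically.

What the generator does **not** emulate: phylogenetic correlation between
taxa, zero-inflation beyond the Dirichlet-multinomial, seasonal or
questionnaire measurement error, informative missingness of visits, and
realistic within-subject autocorrelation beyond a constant random intercept
(no quantitative field target exists for it, so the intercept scale is an
exposed parameter). Passing tests therefore demonstrate that the *methods*
recover *planted* structure under a plausible generative model — not that
any particular real-cohort estimate is correct.

### Effect tiers and their calibration

Planted effects are declared in variance-fraction tiers. Because Bray–Curtis
PERMANOVA $R^2$ has no closed form under Dirichlet-multinomial sampling,
tiers are calibrated by simulation (`expected_r2()`: deep-depth cohorts,
engine re-run per timepoint and variable). The calibrated log-fold-change
magnitudes are 0.35 (small), 0.6 (medium) and 0.9 (large) on the affected
taxon subset, inducing roughly 1%, 2% and 6% of Bray–Curtis variance at 300
families. Two desk-scale choices deserve a note. First, the small tier
targets ~1% rather than ~0.5%: with ~225 samples per timepoint the null
expectation of a one-df term's $R^2$ is $1/(n-1)\approx0.45\%$, so a 0.5%
tier would sit inside the null floor; 1% is the smallest tier the study size
can order reliably. Second, the tier-calibration truth places the small tier
on the balanced parity indicator — a covariate with a 96/4 split (early
breastfeeding) dilutes any planted tier below that floor, which is itself an
instructive property of variance partitioning in homogeneous cohorts. The
calibration run (seed recorded) is frozen in
`inst/extdata/expected_r2_tiers.tsv` and recovery is always compared against
that frozen expectation within three combined Monte-Carlo SDs.

## Problem sizes used by the packaged benchmarks

The benchmark functions (`bench_*`) fix their own scales: 50 random
instances for the classical-oracle equivalence plus exhaustive enumeration
at $n=6,7$; 1000 null communities ($n=40$, $B=199$) for type-I error; three
replicate 300-family cohorts for tier recovery; 100 replicates (300
subjects, 3 true + 7 null candidates) for selection; 20 replicates at 200
subjects for the DA cascade; 25 replicates at 100 families per arm for dyads;
100 null and 40 alternative replicates at 100 samples per group for
dispersion. These sizes were chosen as the smallest at which the binomial
Monte-Carlo error of each rate is well inside the acceptance band it is
compared against.

## Degenerate inputs and numerical choices

Distances are validated (symmetry to $10^{-12}$, zero diagonal,
non-negativity, unit bound for Bray–Curtis) and written at 12 decimal
digits, making file round-trips exact at that precision. Zero-depth samples
are errors for relative abundance; samples below their age-specific depth
cutoff (3000 reads through three months, 5000 after — strictly below) are
removed before analysis; samples with strictly more than 20%
unknown-annotated reads are excluded before the unknown taxa themselves are
dropped; depth filtering runs before the unknown-fraction exclusion by
default (order configurable — the operative wording does not fix it).
Variable screening marks, never deletes: categorical variables where all but
one level have fewer than ten samples in a scope, and variables with more
than 75% missingness in a scope, are flagged per scope with reasons.
Boundary conventions are uniformly strict inequalities. Missing covariate
values are `NA`, never zero, and samples with missing design values are
dropped per fit with a logged count. Permutation p-values use the $+1/+1$
convention and can never be exactly zero.

## Known limitations

* The pooled model's permutation p-values ignore repeated measures (see
  above); treat them as descriptive.
* Between-subject covariates are aliased in the pooled model by design.
* GLS fallback treats log-transformed proportions as homoscedastic within
  the mean structure; it is a last resort and labelled per row.
* The simulator's batch effect is multiplicative and taxon-sparse; batch
  effects that act through taxon *detection* (dropout) are not modelled.
* Marginal (Type III) sums of squares, restricted permutations, UniFrac
  distances and zero-inflated or mixed-effects DA models are out of scope.
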