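---
title: "Methods and design of stresscycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of stresscycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresscycle)
```

This vignette documents the statistical models implemented in
`stresscycle`, the choices made where several defensible options existed,
and what the synthetic-data calibration does and does not establish about
real data.

## 1. Directional fold-change classification

A transcriptome comparison enters the pipeline as per-gene ratios of
stress to non-stress expression (`fold_change_table`). How those ratios
were produced — normalization, replicate handling, platform — is upstream
of this package; the classifier only assumes they are positive and
comparable across the comparisons being contrasted. Working on plain
fold-changes with a hard cutoff is deliberately platform-agnostic: it is
the common currency into which both RNA-seq and legacy microarray data can
be converted, at the price of ignoring per-gene variance (see
*Limitations*).

Classification uses **strict** inequalities: up-regulated means FC > 2,
down-regulated means FC < 0.5, and a gene sitting exactly at a cutoff
belongs to neither set. Up, down and the remainder therefore partition the
measured universe. Both cutoffs are arguments (`up_cutoff`, `down_cutoff`,
constrained to `up > 1 > down > 0`); 2 and 0.5 are the field's
conventional two-fold thresholds and the package defaults. Genes with
missing or non-positive values are excluded before classification and the
exclusion is counted on the object rather than silently dropped.

## 2. The intersection z-score

Given directional sets from two comparisons, similarity is measured on
the intersection of the **up** sets and, separately, of the **down** sets.
Because the expected overlap grows with the set sizes, the raw count is
standardized against a random-overlap null:

* draw a uniform random subset of size $n_1$ and an independent uniform
  random subset of size $n_2$ from the universe of $N$ measured genes;
* record the intersection size; repeat `n_mc` times (default 10,000);
* report $z = (k_{obs} - \bar k_{null}) / s_{null}$, with $s_{null}$ the
  sample standard deviation (denominator $n_{mc}-1$).

The z is signed: positive for enrichment, negative for depletion.

**Universe.** The null universe defaults to the genes measured in *both*
comparisons. When contrasting datasets from different platforms the
intersection universe is the only fair choice — a gene that one platform
cannot report can never contribute to the observed overlap, and leaving it
in the universe would inflate z. A `universe = "union"` mode exists for
same-platform comparisons.

**Both sets are redrawn** every iteration. Conditioning on one set fixed
and randomizing the other yields the identical hypergeometric null, so
this choice is auditable rather than consequential:

$$k \sim \mathrm{Hypergeom},\quad
E[k] = \frac{n_1 n_2}{N},\quad
\mathrm{Var}[k] = \frac{n_1 n_2 (N-n_1)(N-n_2)}{N^2 (N-1)}.$$

`analytic_overlap_z()` implements this closed form (in double precision —
the variance numerator overflows integer arithmetic at genome scale) and
serves as the independent oracle for the Monte-Carlo route. The test suite
checks the closed form against exhaustive enumeration of the
hypergeometric pmf at $N = 20$ (agreement to $10^{-10}$), checks the
Monte-Carlo z against the analytic z to within 0.15 at
$N = 1000, n_1 = n_2 = 100$, `n_mc` = 50,000, and verifies that the full
simulate → classify → score pipeline under a null with no planted overlap
yields z with mean ≈ 0 and sd ≈ 1 over 500 seeds.

**Degenerate nulls** (an empty set, a set equal to the whole universe)
have zero spread; z is then reported as `NA` with an explicit
`degenerate` flag rather than as an arbitrary number.

**Reproducibility.** Every stochastic entry point takes a mandatory
integer `seed`, restores the caller's RNG state on exit, and is
bit-reproducible for a fixed seed.

```{r}
analytic_overlap_z(5, 8, 20, 4)
```

## 3. Protein half-life estimation

Translation shut-off assays block protein synthesis at $t = 0$
(chloramphenicol) and follow the remaining protein by quantified
immunoblot band intensities. The model is single-exponential decay,

$$I(t) = I_0\, e^{-kt}, \qquad t_{1/2} = \ln 2 / k,$$

fitted as ordinary least squares of $\log I$ on $t$:

* each replicate is first divided by its own time-0 intensity, making
  curves unit-free and replicate scale irrelevant (a replicate rescaled by
  any $c > 0$ gives the identical estimate);
* replicates are averaged pointwise (mean ± sample sd, the quantities one
  plots);
* the fit is on the averaged curve, with a **free intercept**: loading or
  quantification error in the $t=0$ band then perturbs the intercept, not
  the slope. `per_replicate = TRUE` additionally fits each replicate and
  reports the spread of the per-replicate half-lives, since with few
  replicates either convention is defensible.

A non-negative fitted slope is truncated to $k = 0$ and flagged
`stable` ($t_{1/2} = \infty$) — the regime of proteins whose turnover
shuts down, e.g. under starvation — rather than reporting a negative decay
rate. No plateau term is fitted: a two-parameter model is all that
replicate-averaged blot data can support.

**Detection floor.** Normalized intensities at or below $10^{-6}$ of the
time-0 signal (including exact zeros, which densitometry does produce) are
floored to $10^{-6}$ and counted; the log would otherwise be undefined. A
fit in which more than 30% of points were floored is flagged
`low_confidence`. This is why fast decays need a dense early schedule: a
2-minute half-life sampled every 10 minutes spends most of the time course
below the floor, and the package flags exactly that. Sampling grids are
arbitrary (no interpolation); times are minutes since shut-off, and any
stress pre-incubation is carried as metadata only.

```{r}
fit <- fit_half_life(simulate_decay(t_half = 26, noise_cv = 0.1, seed = 1))
fit
coef(fit)
```

## 4. qPCR quantification

All formulas work in base-2 cycle space with amplification efficiency
fixed at 2 per cycle; no standard-curve efficiency correction is applied.
Technical replicates (typically triplicates) are aggregated by the
arithmetic mean of Ct before any formula; their spread is propagated, under
the perfect-efficiency assumption, to a multiplicative uncertainty factor
$2^{SE(\Delta\Delta Ct)}$ in the table-level wrapper.

* **Relative expression**: $2^{-\Delta\Delta Ct}$ with
  $\Delta Ct = Ct_{target} - Ct_{reference}$ per condition and the
  reference an endogenous control (e.g. 16S rRNA).
* **Percent of input** (ChIP-qPCR): the input aliquot is only a fraction
  $f$ of the IP material (default $f = 0.05$, a 5% input), so the input Ct
  is first adjusted to represent 100% by subtracting $\log_2(1/f)$ cycles
  — the unique base-2-consistent reading of "adjusting the input to 100%"
  — and the recovery is $100 \cdot 2^{(Ct_{input}^{adj} - Ct_{IP})}$.
* **Relative occupancy**: one percent-of-input value expressed as a
  percentage of a baseline condition's value.

```{r}
relative_expression_ddct(25, 10, 22, 10)
percent_input(20, 22, input_fraction = 0.05)
relative_occupancy(0.225, 1.25)
```

## 5. What the synthetic generators emulate

`simulate_regulon_pair()` draws a genome of `n_genes` (default 4000, the
scale of a small bacterial genome) in which a **shared** regulon
(defaults: 400 up, 280 down — a few hundred genes, ~10% of the genome up
and ~7% down, the magnitude seen in strong stress responses) responds in
both comparisons, condition-specific genes (default 70 per direction)
respond in one, and all other genes fluctuate around 1. Effects are
log-normal: responding genes get $2^x$ with
$x \sim N(\pm 2, 0.3)$ log2 units (a four-fold typical effect, safely
past the two-fold cutoff), background genes $x \sim N(0, 0.3)$.
Log-normality is the natural choice for a ratio-valued quantity.
Critically, the shared block is one random draw while each condition's
specific genes are drawn *independently* from the remainder: with zero
shared genes the two regulons are genuinely independent, which is what
makes the generator usable as a null calibration of the whole pipeline.

`simulate_decay()` produces $e^{-\ln 2\, t / t_{1/2}}$ with independent
multiplicative log-normal noise of mean 1 and CV `noise_cv` (default 0.1,
a realistic densitometry error) per point and replicate.
`simulate_ct_table()` maps known template ratios to Ct values
($Ct = base - \log_2(\text{ratio}) + N(0, \sigma)$ per technical
replicate) for a treated and a control sample plus a ratio-1 reference.

What passing the calibration tests **does** show: the statistics are
implemented correctly (oracle agreement), the null is honest (z ~ N(0,1)
when nothing is shared), and the estimators recover known truth at
realistic noise (median half-life within 10% for true values 2–26 min;
ddCt geometric-mean recovery within the noise-propagation band). What it
does **not** show: robustness to features real data have and the
generators lack — correlated genes within operons, platform-specific
mean-variance structure, deviations from single-exponential decay
(delayed protease engagement, biphasic pools), primer efficiencies below
2, or pipetting error correlated across a triplicate.

## 6. Problem sizes and runtime choices

The shipped test-suite sizes — `n_mc` = 50,000 with 20 seeds for the
oracle-agreement check, 500 regulon pairs at $N = 4000$ for null
calibration (scored analytically; the Monte-Carlo route is separately
validated against the analytic one), 200 simulations per half-life truth —
were chosen as the smallest designs whose Monte-Carlo error is an order of
magnitude below the tolerance being asserted, so the suite runs in about a
minute while remaining statistically meaningful.

## 7. Known limitations

* Hard fold-change cutoffs ignore expression level and variance; a gene at
  FC 1.99 and one at 2.01 are treated as categorically different. The
  z-score inherits this: it measures overlap of thresholded sets, not
  correlation of effect sizes.
* The hypergeometric null assumes exchangeable genes; co-regulated operons
  violate independence and make |z| generous. Comparisons between z-scores
  are therefore more meaningful than their absolute calibration on real
  genomes.
* The half-life fit weights all (log) time points equally; late points
  with low signal-to-noise carry as much weight as early ones. The
  `low_confidence` flag marks the worst cases but is not a variance model.
* qPCR uncertainty propagation assumes perfect efficiency and independent
  technical replicates.
* Gene identifiers are opaque case-sensitive strings; joining datasets
  that mix locus tags and gene names is the user's responsibility.
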