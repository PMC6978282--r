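---
title: "Phylogenetic hierarchical models for factorial biomass experiments"
author: "phylofactorial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic hierarchical models for factorial biomass experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofactorial)
```

## The problem

Seedlings of many species are grown in a 2 x 2 factorial design — two pot
shapes (a regular tapered pot and a flat rhizobox of equal volume) crossed
with two nutrient levels (water only vs. fertilized) — and harvested for root
and shoot dry mass. Two responses summarise each plant: total biomass (root +
shoot) and the root:shoot ratio, a measure of biomass allocation. Because the
species share evolutionary history, their average sizes and their responses
to the treatments cannot be treated as independent draws: related species
tend to respond similarly. This package fits the corresponding Bayesian
phylogenetic hierarchical model and ships a synthetic-data generator with the
exact generative structure the model assumes, so the whole pipeline can be
validated by parameter recovery without any external data.

## The model

For plant $i$ of species $s$, with pot indicator $P$ (1 = flat) and nutrient
indicator $N$ (1 = fertilized), each response (the natural log of total
biomass in grams, or the natural log of the root:shoot ratio) is modelled as

$$y_i \sim \mathrm{Normal}(\alpha_s + \beta_{1,s} P_i + \beta_{2,s} N_i +
\beta_{3,s} P_i N_i,\ \sigma).$$

The two responses are fit as two separate, fully parameterised models.
Species-specific parameters are tied together through the phylogeny: for each
family $par \in \{\alpha, \beta_1, \beta_2, \beta_3\}$,

$$par \sim \mathrm{MVN}\!\left(\mu_{par} \mathbf{1},\;
\gamma_{par}\, C_{\lambda_{par}}\right),$$

where $C$ is the species correlation matrix implied by the tree,
$C_\lambda$ multiplies its off-diagonal entries by Pagel's
$\lambda \in [0,1]$ (0 = no phylogenetic signal, 1 = Brownian expectation),
and $\gamma > 0$ scales the whole matrix (the species-level variance of the
family). Hyperpriors: $\mu_\alpha$ uniform on the reals, each $\lambda$
uniform on $[0,1]$, $\mu_{\beta_{1..3}}$ Cauchy(0, 5), and $\sigma$ and each
$\gamma$ half-Cauchy(0, 5). The "Cauchy with a sign constraint" reading as a
positive-truncated half-Cauchy is the only one consistent with the
constraints $\gamma, \sigma > 0$; a Cauchy location is colloquially called a
"mean" although the Cauchy has none.

### The phylogenetic correlation matrix

`shared_path_vcv()` builds the Brownian variance–covariance matrix (entry
$(i,j)$ = branch length shared from the root to the MRCA of tips $i$ and
$j$). Trees are required to be ultrametric (relative diagonal spread below
`1e-6`; non-ultrametric trees are rejected rather than silently extended),
and the matrix is normalised by the common root-to-tip depth into a
correlation matrix. The normalisation is deliberate: it decouples the tree's
time units from the model, so $\gamma$ alone carries the variance scale and
$\lambda$ keeps its standard interpretation. $C_\lambda = \lambda C +
(1-\lambda) I$ is a convex blend of a positive-definite matrix with the
identity and is therefore positive definite for all $\lambda \in [0,1]$;
`assert_positive_definite()` adds at most a `1e-8` diagonal jitter to absorb
floating-point loss near $\lambda = 1$ on deep trees.

### Detection-limit censoring

The balance resolves 0.1 mg. Root masses below that limit are replaced by
half the limit (0.05 mg) before the root:shoot ratio is formed; "below" is
strict, so a recorded 0.1 mg passes unchanged. By default the substituted
value also enters total biomass, so each plant carries one coherent mass pair
— the difference is at most 0.05 mg against a shoot mass three to four orders
larger, but `substitute_in_total = FALSE` switches to the raw root mass if
wanted. `exclude_below_detection = TRUE` instead drops the flagged plants
entirely (the sensitivity re-analysis); no other imputation or outlier
handling is done.

## Inference

The posterior is sampled by a collapsed blocked Gibbs sampler
(`fit_phlm()`): for each effect family the population mean $\mu_{par}$ is
updated from its conditional with the species effects integrated out (a
Woodbury identity in species space makes this an $S \times S$ computation),
the $S$ species effects are then drawn exactly from their multivariate-normal
conditional, and $\lambda$, $\gamma$ and $\sigma$ are updated by univariate
slice sampling (Neal 2003) — on $[0,1]$ for $\lambda$ and on the log scale
with a Jacobian correction for $\gamma$ and $\sigma$. Slice sampling is
rejection-free and tuning-free, and the collapsed mean update avoids the
classic centered-hierarchy pathology in which $\mu$ and its effects
random-walk against each other (which would otherwise be fatal under the
heavy-tailed Cauchy hyperprior when a family is weakly informed). The
correctness of the whole scheme is checked three ways in the test suite: the
joint density against a brute-force oracle, a conjugate sub-case against its
closed-form posterior, and a dual-route comparison against an independent
coordinate-slice sampler (`run_mcmc()`) run on `log_posterior()` directly.

Chains are initialised at the response mean with small jitter (mid-support
values for $\lambda$, $\gamma$, $\sigma$), retried up to 10 times if the
posterior is non-finite. Default run configuration is 4 chains of 4,000
iterations with 2,000 warmup; all randomness derives from one integer seed
and identical configuration reproduces draws bitwise. Convergence is gated on
the split-chain $\widehat{R}$ (each chain halved before the between/within
variance ratio), with the pass interval $[0.99, 1.01]$; constant draws define
$\widehat{R} = 1$. One caveat the package documents rather than hides: a
parameter whose posterior is an untruncated Cauchy (a $\mu_\beta$ family with
no data at all) has no finite variance, so a variance-based $\widehat{R}$ is
meaningless for it; the degenerate validation designs therefore gate on the
data-informed parameters.

## Reporting

`effect_report()` reduces the three population effects to the standard
table: posterior mean and equal-tailed 95% credible interval on the log
scale, and the same three numbers exponentiated to the multiplicative
(ratio) scale. Equal-tailed quantile intervals (2.5%/97.5%) are used rather
than HPD because quantiles commute exactly with monotone maps, which is what
makes the paired log/ratio presentation self-consistent; the reported ratio
mean is the exponential of the log-scale posterior mean (the paired-table
convention), not the mean of exponentiated draws. Display rounding is 4
decimals; machine outputs keep full precision.

## The synthetic-data generator

`simulate_tree()` draws a pure-birth tree and rescales its depth to 1;
`simulate_species_effects()` runs the multivariate-normal prior generatively;
`simulate_experiment()` draws replicate counts uniformly from the design
ranges (5–6 per species x nutrient cell in regular pots, 5–13 in flat pots,
15 species by default), then draws both log responses from their Normal
models and couples them into one mass pair per plant via the bijection
root = total * r/(1+r), shoot = total/(1+r). This coupling preserves both
marginal models exactly while producing valid raw records. Masses are
rounded to the 0.1 mg balance resolution; roots below the detection limit
are stored as 0 with a flag (the balance cannot read them), and shoots are
floored at the smallest recordable reading.

Default ground truths for the population effects are realistic log-scale
effect sizes for a seedling pot experiment — a strong positive nutrient
effect on biomass (about 2.8-fold) and a strong negative one on the
root:shoot ratio (about 0.46-fold), with weak pot and interaction effects.
The quantities a real study rarely reports were fixed once as package
defaults: $\lambda = 0.5$ for every family (intermediate phylogenetic
signal), $\gamma_\alpha = 1$ (species intercepts spanning roughly an order
of magnitude), $\gamma_\beta = 0.25$ for the treatment families (chosen so
that posterior interval widths at $S = 15$ match those typical of published
experiments of this size, log-scale CI half-widths around 0.25–0.7),
$\sigma = 0.7$ (biomass) and 0.5 (ratio) residual SD on the log scale, and
grand intercepts of $-4.6$ (log grams, i.e. ~10 mg reference-cell plants)
and $-0.7$ (log ratio ~0.5).

What the generator does *not* emulate: germination timing, mortality or
transplant failure (beyond the replicate-count ranges), measurement error
other than 0.1 mg rounding and censoring, any dependence between the two
responses beyond the mass-pair coupling, and real phylogenies' non-Yule
branch-length structure (a real tree can be dropped in as Newick). Passing
recovery tests therefore demonstrates correctness of the inference under the
model's own assumptions — not robustness to model misspecification in field
data.

## Validation by parameter recovery

`recovery_experiment()` closes the loop: simulate tree, effects and
experiment at known truth, fit both responses, and record per-hyperparameter
posterior means, 95% credible intervals, interval coverage of the truth and
the convergence gate, excluding non-converged fits from the aggregates. The
shipped test suite runs 5 replicate simulations at the default design with 2
chains of 1,500 iterations (750 warmup) per fit — sizes chosen so the whole
suite stays interactive while leaving the binomial tolerance on 95% coverage
at 5 replicates meaningful (coverage must land in [0.75, 1] and absolute
mean bias below 0.3); larger recovery runs (e.g. 20 simulations) are a
one-line change to the same function. A companion qualitative check fits
data generated at the default truths and verifies the published sign
pattern: the nutrient effect credibly positive for biomass and credibly
negative for the ratio in at least 4 of 5 seeded runs, with pot and
interaction effects mostly straddling the null.

## Numerical notes and limitations

* All covariance work runs through one symmetric eigendecomposition of $C$
  per fit; $C_\lambda$'s eigenvalues are $\lambda d_i + 1 - \lambda$, so
  every $\lambda$/$\gamma$ density evaluation is $O(S)$ after an $O(S^2)$
  projection.
* Ties at the detection limit are resolved by the strict inequality; masses
  exactly at 0.1 mg are never substituted.
* `lambda` is one parameter per effect family, matching the per-family
  subscripts of the prior; a single shared `lambda` is the natural
  alternative reading and is not implemented.
* The sampler is not gradient-based; for much larger species counts
  (hundreds) the $S \times S$ solves and the one-coordinate-at-a-time
  hyperparameter updates would become the bottleneck.
* Credible-interval coverage statements are calibrated under the generator's
  assumptions; censoring is handled by substitution (as in the analysis
  model), not by a latent-variable censored likelihood, so heavy censoring
  (tiny plants) biases the smallest ratios upward by construction.
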