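---
title: "Methods: summary-statistics fine-mapping, colocalization, TWAS, MR and gene tiering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics fine-mapping, colocalization, TWAS, MR and gene tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetier)
```

`genetier` integrates GWAS and molecular-QTL summary statistics into tiered
gene-prioritization tables. This vignette is the package's account of the
statistical machinery: the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## The summary-statistics model

Everything downstream of harmonization consumes only a z-score vector and
the local LD (correlation) matrix `R` for each region. The working
likelihood is the standard RSS model: under a sparse vector of true
standardized effects `λ`,

$$ z \sim \mathcal{N}(R\lambda,\; R). $$

Betas and standard errors travel through the tables for schema fidelity
(`se = 1/\sqrt{n}`, `beta = z \cdot se`), but no stage uses them except the
MR ratio, which works on the standardized exposure scale precisely so that
only `z` and `R` matter. Assumptions inherited from this model: in-sample
LD matches the reference panel, effects are sparse within a region, and
regions are independent.

## Harmonization

Allele alignment matches each variant's (ref, alt) pair to the LD panel:
direct match, swap (negating `z`), strand flip, or flip-plus-swap; flips
are attempted only for unambiguous pairs, since complementing A/T or C/G
is degenerate. Unreconcilable or missing alleles drop the variant.
Strand-ambiguous variants, MAF < 0.0025 (strict), missingness > 1%, and
duplicate ids are then filtered.

The z/LD consistency check computes, per variant, the leave-one-out
conditional moments of `z_i` under `z ~ N(0, R)` and flags
`|z_i - E[z_i|z_{-i}]| / \sqrt{v_i} > t_{max}`. The threshold `t_max = 4`
is configurable; the model names no cutoff, and 4 SD is conservative
relative to common sumstats-diagnostic practice. Numerically the check is
one inversion of `R + \varepsilon I` (ridge `\varepsilon = 10^{-6}`), whose
leave-one-out conditioning blocks equal the ridge-regularized blocks
exactly; the conditional variance is floored at `10^{-4}`.

Removed or missing z-scores are imputed from LD:
`\hat z_m = R_{m,o} R_{o,o}^{+} z_o` with quality
`q_m = R_{m,o} R_{o,o}^{+} R_{o,m}`, the pseudoinverse truncating singular
values below `rcond = 0.01` of the largest. An imputation is kept only when
`q > 0.6` and the variant has at least 5 observed neighbors with
`|r| \ge 0.2`. The "minimum LD" requirement is genuinely ambiguous (a
neighbor count, an `|r|` bound, or a window); we read it as "at least 5
informative neighbors" and expose both the count and the `|r|` floor as
configuration, so either reading is reachable. The chain runs once, in
order — filters, outlier removal, imputation — with no fixed-point
iteration.

## Fine-mapping

The engine is an iterative Bayesian sum-of-single-effects model on
`(z, R)`. For effect `l`, the residual z-score is
`\tilde z = z - R \sum_{l' \ne l} \alpha_{l'} \mu_{l'}`; with a
`N(0, V)` prior and unit residual variance the per-variant log Bayes
factor is

$$ \mathrm{lbf}_j = \tfrac12\log\frac{1}{1+V}
   + \tfrac12 \tilde z_j^2 \frac{V}{1+V}, $$

`\alpha` is the softmax of `lbf` over a uniform prior, and the posterior
mean is `\mu_j = \tilde z_j V/(1+V)`.

Numerical and design choices:

- **Prior-variance grid** `{0, 0.01, 0.04, 0.16, 0.64, 2.56}` on the
  z-score scale, refit per effect per iteration by grid maximization of the
  single-effect marginal likelihood. Including 0 lets an unsupported effect
  switch off (flat `\alpha`, excluded from PIPs and credible sets); a
  nonzero `V` must beat `V = 0` by 0.1 log-likelihood units, the usual
  null-preference guard on the z scale. Grid ties prefer the smaller `V`.
  The grid ceiling understates very large effects, which flattens `\alpha`
  slightly and therefore errs toward larger (more conservative) credible
  sets, not smaller ones.
- **Convergence**: maximum absolute PIP change `< 10^{-4}` or 100
  iterations; non-convergence warns but returns results.
- **L schedule**: start at 5, escalate by 5 to at most 10 whenever a
  highest-coverage credible set is attributed to the last available effect
  (the natural "all effects used" trigger, since no explicit criterion is
  given for the iterative optimization of L).
- **Skip rule**: regions with max PIP `< 0.025` are marked skipped and
  yield no credible sets.
- **Credible sets**: per effect and coverage (95/70/50%), the minimal
  prefix of variants by descending `\alpha` (ties broken by ascending
  position, for reproducibility) reaching the coverage; purity is the
  minimum pairwise `|r|`, with sets larger than 20 members thinned by a
  deterministic index stride so at most ~200 pairs are evaluated. Sets
  with purity `< 0.5` are discarded — the common fine-mapping default.
  `PIP_j = 1 - \prod_l (1 - \alpha_{lj})` over active effects.
- **Diagnostics**: regions without a credible set emit the top-PIP variant
  as a fallback record; between-set absolute correlations above 0.8 are
  flagged; regions are classified single-/multi-set; unusually large sets
  (> 50 members by default) are flagged potentially unstable. The
  diagnostic classification is emitted only — the sum-of-single-effects
  engine is always the inference engine.

## Colocalization

External colocalization tables (region, CoS id, trait set, variant, VCP)
are first-class inputs and flow through prioritization unchanged. Because
the boosting-based multi-trait colocalizer that produces such tables is a
separate tool, the package ships a clearly labelled reference
approximation: `clpp_v = \prod_t \mathrm{PIP}_t(v)`, candidates restricted
to variants in a credible set of every trait with `clpp \ge 0.01`, and a
95% confidence set taken as the minimal prefix of candidates by descending
CLPP mass (normalized). Every output records its source (`external` or
`clpp`), so evidence provenance survives into the tier tables. CLPP is
conservative by construction (`clpp_v \le \min_t \mathrm{PIP}_t(v)`) and
cannot represent allelic-heterogeneity sharing the way a joint model can.

## TWAS

The burden statistic for a weight vector `w` (a gene's predicted molecular
level) is `z_{TWAS} = w^\top z / \sqrt{w^\top R w}`, exactly standard
weight-based TWAS from summary statistics. Weight variants missing from
the harmonized summary statistics are dropped rather than re-imputed —
imputation already happened upstream, and silently repeating it would blur
the stage boundary. `w^\top R w < 10^{-8}` marks the test unstable.
Models are retained when cross-validation `R^2 > 0.01` and `P_{cv} < 0.05`
(both strict), the best model per gene×context being the highest `R^2`.
Significance uses the fixed threshold `2.5 \times 10^{-6}` and/or
Bonferroni at 0.05 over the retained tests; the Bonferroni family defaults
to the current run's per-trait retained set and accepts a user-supplied
family size, since the intended family (per trait, per context, or global)
is not pinned down.

## Mendelian randomization

Instruments are highest-coverage credible sets with cPIP > 0.5. "Exposure
effects scaled by their standard errors" is read as standardizing the
exposure to its z-score — the only reading that makes the Wald ratio
well-defined from summary statistics alone — so
`\theta_v = \beta_{out,v} / z_{exp,v}` is the outcome effect per SD of the
genetically predicted exposure. The per-variant standard error is the
first-order delta approximation `se_{out,v}/|z_{exp,v}|` (no
exposure-uncertainty term), with a weak-instrument guard excluding
`|z_{exp}| < 2`. Within a set, ratios are combined with normalized PIP
weights; the default set-level standard error
`\sqrt{\sum a_v^2 se_v^2}` treats within-set ratios as independent given
the set, with the conservative alternative `\sum a_v se_v` selectable.
Across sets, fixed-effect IVW pooling gives `\theta_{meta}`, `se_{meta}`,
Cochran's `Q` and `I^2 = \max(0, (Q - (k-1))/Q)`; the significance gate is
≥ 1 set, cPIP > 0.9, `p < 0.05`, `I^2 < 0.5`. MR output is screening
evidence for tiering, not causal proof.

## Tiering and enrichment

Tier 1 requires TWAS and colocalization support in both the imaging-trait
(DNE) category and the endpoint categories; Tier 2 relaxes endpoints to
TWAS-only; Tier 3 relaxes the DNE requirement to TWAS *or* colocalization.
Each gene gets the best tier it satisfies, which makes the assignment
monotone: adding evidence can only improve it. The endpoint requirement is
genuinely ambiguous between "all endpoint categories" and "any endpoint
category" — the definition reads as "all", while tier tables citing single
endpoints imply "any". Both are first-class (`endpoint_mode`), defaulting
to `"any"`; significant MR may substitute for endpoint TWAS via
`mr_as_endpoint_evidence` (default off). PD-labelled traits are accepted
but excluded from tier rules by default.

Enrichment is upper-tail hypergeometric over-representation per gene set,
BH-adjusted within a collection, significant at FDR < 0.1. The background
defaults to all genes in the annotation/collection union; only
over-representation is tested.

## The synthetic-data generator

The generator defines the study conditions, not a tuning surface. It
emulates: multivariate-normal z-scores exactly consistent with a chosen LD
structure (AR(1), block, or identity) and planted causal non-centralities;
shared causal variants across traits and contexts (the same index per
region, by construction); TWAS weights equal to planted molecular effect
vectors plus `N(0, sd^2)` noise restricted to each gene's cis window;
planted strand-ambiguous and low-MAF variants to exercise QC (always away
from causal variants); gene annotations with one causal-variant gene and
decoys per region; and a gene-set collection with one planted enriched
set. One RNG stream per (region, trait) is derived from the master seed by
stable string hashing, so adding a trait never perturbs existing traits.

Defaults: 100 variants per region, AR(1) `\rho = 0.9` (strong local LD,
the hard case for fine-mapping), non-centrality 6 for planted effects
(a genome-wide-significant but not overwhelming signal), MAF uniform on
(0.01, 0.5), weight noise SD 0.05, cross-validation `R^2` 0.15 for
causal-variant genes and 0.005 (below retention) for decoys. The
effect-size distribution of real imaging-trait loci is unknown; these are
calibration choices, not estimates.

What it does **not** emulate: realistic human LD maps or imputation
panels, individual-level genotypes, allele-frequency/effect-size coupling,
sample overlap between traits, polygenic background, or winner's-curse
selection of regions. Passing calibration on this generator therefore
shows the machinery is correct and calibrated under its own assumptions —
not that real-data operating characteristics will match.

## Calibration experiments and problem sizes

The acceptance suite, all single-CPU, uses these study conditions:

- **Credible-set coverage**: 500 regions, `p = 200`, AR(1) `\rho = 0.9`,
  one causal variant at non-centrality 5; coverage is the fraction of
  emitted 95% (resp. 70%) sets containing the planted variant.
- **MR calibration**: exposure regions of `p = 50`, AR(1) `\rho = 0.5`,
  one instrument with `|z| \approx 8`; 2,000 null replicates for the
  rejection rate, 500 replicates at `\gamma = 0.5` for bias and CI
  coverage. Moderate LD was chosen so the credible set concentrates on
  the true instrument, isolating the calibration of the ratio/IVW
  statistics from fine-mapping resolution.
- **Colocalization discrimination**: 200 shared-causal and 200
  disjoint-causal replicates at `p = 200`, `\rho = 0.9`, non-centrality 6.
- **Tier recovery**: 100 end-to-end single-region pipeline replicates.

## Known limitations

- The CLPP approximation is a stand-in with documented provenance, not a
  joint colocalization model; external tables are preferred when
  available.
- Under strong LD a small fraction of pure-noise regions (about 1% at
  `p = 200`, `\rho = 0.9`) yields a spurious credible set from a
  correlated noise cluster; the skip rule and purity filter catch the
  rest.
- MR assumes valid instruments within credible sets; no pleiotropy-robust
  estimators (Egger, weighted median) are provided.
- The prior-variance grid tops out at 2.56 on the z² scale; very strong
  signals get wider, conservative credible sets rather than tighter ones.
- Multi-ancestry harmonization, functional priors, and genome-build
  conversion are out of scope.
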