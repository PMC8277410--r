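---
title: "Methods: composite hospital scoring with principal components and entropy weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite hospital scoring with principal components and entropy weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdi)
```

## The problem

Public hospitals in China are increasingly compared through composite
rankings, but the performance information that is actually public is
limited: bibliometric output, markers of academic standing, and a thin set
of quality-and-safety proxies such as malpractice litigation ratios. `chdi`
implements a scoring chain for exactly this situation: a hospitals ×
indicators table whose columns are grouped into three domains —
*research and development*, *academic reputation*, and
*quality and safety* — is reduced domain by domain to a small number of
latent components, those components are combined into domain scores, and
the domain scores are aggregated into a single ranked development index.

The chain, stage by stage:

1. **Validation and direction adjustment.** Cost-direction indicators
   (larger is worse, e.g. the ratio of compensated malpractice cases) are
   negated so that "larger is better" holds for every column. Negation
   rather than reciprocals preserves the linear correlation structure the
   component models rely on.
2. **Suitability diagnostics.** For all-numeric domains the
   Kaiser–Meyer–Olkin statistic compares squared correlations with squared
   anti-image partial correlations; a domain passes when KMO strictly
   exceeds 0.7. Domains containing ordinal or nominal indicators are
   checked with Cronbach's alpha against the same threshold, because they
   are scored with the categorical model, whose diagnostic convention this
   is. Bartlett's sphericity test is deliberately not included.
3. **Indicator-subset search.** All $2^p - 1$ nonempty subsets of a
   domain's indicators (bounded at $p \le 16$) are evaluated; a subset is
   *acceptable* when its diagnostic passes and the two retained components
   reach the cumulative-variance floor. Among acceptable subsets the
   largest wins — more indicators give more informative component scores —
   with ties broken by higher cumulative variance, then lexicographic
   order. If nothing is acceptable the full set is returned, flagged.
4. **Component models.** All-numeric domains get correlation-matrix PCA.
   Domains with categorical indicators get CATPCA: optimal scaling by
   alternating least squares, where category quantifications and the PCA
   solution are updated in turn. Two components are retained by default.
5. **Logit transformation.** Retained component scores $F_{hi}$ are mapped
   to $(0,1)$ by $S_{hi} = 1/(1 + e^{-(C_i/G(m)) F_{hi}})$, where $C_i$ is
   the component's variance share and $G(m)$ the cumulative variance of the
   retained set.
6. **Entropy weighting.** Within a domain, components are combined with
   weights proportional to their diversification degree
   $d_i = 1 - e_i$, where $e_i$ is the normalized Shannon entropy of the
   column of transformed scores.
7. **Aggregation and ranking.** Domain scores are combined with
   configurable domain weights (equal by default), min–max rescaled so the
   top hospital attains the output scale (1 or 100) and the bottom 0, and
   ranked with average ranks on ties. Pearson correlations among the domain
   scores and the raw total are attached as a construct-validity report.

## Reconstructed formulas

Two parts of the chain are **reconstructions**, and the package documents
them as such rather than as settled convention:

* **The logit transformation.** The transformation is specified here by
  its ingredients — a final score per component built from the component
  score $F_i$, its variance $C_i$ and the accumulated variance $G(m)$ —
  and the `scaled_logistic` default is the simplest strictly increasing
  map onto $(0,1)$ using exactly those ingredients. It weights a
  component's score by its relative importance $C_i/G(m)$ before the
  logistic squash, so earlier components spread further from 0.5. A
  `plain_logistic` variant (no scaling) is kept as a configuration option;
  the two coincide whenever a single component is retained, which the test
  suite checks as an algebraic identity.
* **Entropy weights.** The standard entropy-weight formulas are used:
  column shares $p_{hi} = x_{hi}/\sum_h x_{hi}$, entropy
  $e_i = -\tfrac{1}{\ln n}\sum_h p_{hi}\ln p_{hi}$, diversification
  $d_i = 1-e_i$, weights $w_i = d_i/\sum d_i$. The logit stage guarantees
  the strictly positive input this requires. A column with no variation
  carries zero weight; if every column is constant the combiner falls back
  to equal weights with a warning rather than dividing by zero.

A related open point is whether entropy weights should be computed on raw
or transformed component scores. The package computes them on the
transformed scores: raw component scores are centered at zero, where the
share/entropy machinery is undefined, so the transformation is what makes
the entropy method well-posed at all.

## CATPCA: numerical choices

The alternating least-squares loop minimizes the loss
$\lVert Z - XA^\top \rVert^2$ over component scores $X$, loadings $A$, and
column quantifications $Z$ constrained to mean 0 and variance 1:

* **Quantification update.** Given $X$ and $A$, the least-squares target
  for column $j$ is $XA_j$. Nominal columns take unrestricted category
  centroids; ordinal columns project the centroids onto the monotone cone
  with a weighted pool-adjacent-violators step (weights = category
  counts), preserving the declared category order. The result is
  restandardized; because the feasible set contains the previous iterate,
  the variance accounted for (VAF) by the retained components never
  decreases, which the tests assert on every iteration trace.
* **Initialization.** Ordinal columns start from their standardized
  category-index coding — so the initial solution equals plain PCA on the
  integer coding, and the final VAF can only improve on it (a tested
  invariant). Nominal columns start from seeded random quantifications;
  the seed is recorded in the fitted model.
* **Convergence.** Iteration stops when the VAF changes by less than
  `tol` (default `1e-6`) or at `max_iter` (default 200); non-convergence
  returns the best iterate with a warning and a flag. Inside the subset
  search, candidate models are screened at a coarser tolerance
  (`1e-5`, 100 iterations) since acceptability only needs VAF to about
  three decimals; the chosen subset is refitted at full tolerance.
* **Degeneracies.** A quantification update that collapses a column to a
  constant keeps the previous iterate for that column. Categorical columns
  must have at least two observed levels.
* **Sign convention.** Each retained component is reflected so its
  largest-magnitude loading is positive, making loading reports and
  serialized models deterministic.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `retention_rule` / `k` | `fixed_k`, 2 | retain exactly two components per domain; a `cumulative_variance` rule is available because retention is motivated by variance explained |
| `min_cumulative_variance` | 0.85 | floor used by the cumulative-variance rule and by subset acceptability (fraction of total variance) |
| `kmo_threshold` | 0.7 | strict lower bound for KMO / alpha |
| `domain_weights` | 1/3 each | cross-domain aggregation weights; a stakeholder panel would normally set these, so equal weights are an explicit neutral default, not a recommendation |
| `logit_variant` | `scaled_logistic` | see above |
| `output_scale` | 1 | 1 or 100; the top hospital attains exactly this value |
| `seed` | 1 | controls nominal initialization and is recorded in models and manifests |

The subset-search floor of 0.85 deserves a note: 0.80 is the usual
rule-of-thumb for "components explain enough". We set the default slightly
higher because the floor doubles as the *acceptability* criterion of the
subset search, where it has to separate coherent indicator sets from sets
padded with an uninformative column; with two retained components, adding
one pure-noise indicator to an 11-indicator set whose components capture
~0.90 of variance drags the cumulative share to ~0.82, which a 0.80 floor
would wrongly accept. Both the floor and the threshold are ordinary
configuration fields.

## What the synthetic generator emulates — and what it does not

The scoring chain was designed for a cohort of about 310 tertiary
hospitals whose indicator table is not public. The generator therefore
reproduces the *structure* such data are assumed to have, so that every
stage is testable:

* 310 units by default; three **correlated latent strength factors** (one
  per domain, pairwise correlations 0.78 / 0.62 / 0.60 — all positive,
  quality weakest) plus an independent secondary factor per domain;
* per-domain indicator menus of 13 (research), 9 (reputation) and 3
  (quality) candidates, with 2, 3 and 0 pure-noise columns respectively,
  so the subset search has a designed recovery target of 11, 6 and 3;
* **value families** matched to the indicator types: publication and
  citation counts are lognormal-then-rounded (heavy right tails across
  hospitals — a modelling choice, not an empirical claim), malpractice
  ratios are logistic-squashed proportions generated with reversed
  polarity, and reputation indicators are small-integer ordinals obtained
  by quantile-cutting the latent score (which guarantees every declared
  level is observed and monotonicity in the factor).

Communalities are deliberately high (roughly 0.85–0.9 after the family
transforms), so that two components per domain capture well over 81% of
the variance and the diagnostics clear their thresholds with margin at
$n = 310$. Passing tests on this fixture therefore show that the chain
*recovers designed structure under realistic marginals and sample size* —
they do not show anything about the marginal distributions, measurement
error, or source-overlap quirks of real hospital data, whose joint
distribution is unknowable from public information. Real indicator menus
also overlap heavily (papers "by authors" vs "by first author"); the data
model stores such columns independently and makes no attempt to
deduplicate them.

## Problem sizes used in the test suite

Unit tests run on 20–300 units with 2–6 indicators; end-to-end checks run
the full 310-unit, 25-indicator fixture, including the exhaustive
$2^{13}$-subset research-domain search and its independent oracle. These
sizes keep the complete suite within a couple of minutes while exercising
every code path at the cohort scale the chain was designed for.

## Known limitations

* The cross-domain weights of the original expert panel are unknown; equal
  weights are a neutral default and any substantive use should set its
  own.
* Min–max rescaling pins the top hospital at the scale maximum by
  construction; published index values whose top entry is below the
  maximum cannot be reproduced by this formula and no attempt is made to
  reverse-engineer them.
* No factor rotation is offered (components are used unrotated), no
  missing-data EM inside CATPCA (incomplete hospitals are rejected or
  dropped explicitly), and no rank uncertainty intervals are reported.
* The subset search is exhaustive and intentionally refuses more than 16
  indicators per domain.
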