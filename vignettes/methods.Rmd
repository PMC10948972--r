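---
title: "Methods: two-step SDMs for land-use change scenarios"
author: "landshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step SDMs for land-use change scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `landshift`, the
parameters that matter, the design choices that were genuinely open, and the
limits of what the synthetic validation can show.

## Why two steps

Presence-only biological records carry two confounded signals: whether the
climate admits a species at all, and whether the local land cover supports
it. The package separates them. A climatic envelope, fitted over the whole
study extent, decides *where the species could be*; a land-use model, fitted
only against climatically suitable background, decides *how likely it is to
be there given the cover composition*. Predictions multiply the two: the
land-use probability is set to exactly zero outside the envelope. Climate
change enters solely by swapping the envelope mask — the land-use
coefficients are never refitted — so climate and land-use effects stay
cleanly attributable.

## The climatic envelope ensemble

Three learners with deliberately different reliance on absence data are
fitted to four bioclim predictors (mean annual temperature BIO1,
isothermality BIO3, annual precipitation BIO12, wettest-month precipitation
BIO13):

* a **rectilinear envelope** using only presences: the score of a point is
  the minimum over variables of the percentile tail depth
  $2\min(F(v), 1-F(v))$, where $F$ is the presence-sample empirical CDF with
  the midpoint convention $F(v) = (\#\{z<v\} + \tfrac12\#\{z=v\})/n$. The
  midpoint convention is what makes the envelope's centre score 1 and makes
  a variable that is constant across presences behave sensibly (score 1 at
  its value, 0 elsewhere). Points outside the presence min–max score 0.
* a **logistic GLM** with linear terms and an intercept (the no-intercept
  rule belongs to the land-use model only, where it is forced by the
  compositional covariates);
* a **random forest** with 500 trees, default feature subsampling and a
  seed derived from the run seed — the determinism tests require fixed
  hyperparameters.

Each learner's 5-fold cross-validated mean AUC (Mann–Whitney form, ties
counted ½; folds stratified by class, seeded) must reach 0.6, and a species
is kept only if at least two learners pass. Thresholds maximise
sensitivity + specificity over midpoints between adjacent distinct scores;
the objective is computed as the integer $TP\cdot n_{neg} + TN\cdot n_{pos}$
so ties are exact and break deterministically toward the smallest cutoff.
Presence is voted at score ≥ threshold (closed bound), and a cell enters the
consensus mask when at least $\lceil \tfrac23 m \rceil$ of the $m$ passing
learners vote for it — with two passing learners this demands both votes,
the faithful reading of "two-thirds" as a proportion (a simple-majority rule
is available by configuration).

## The land-use response

Within the envelope, occurrence is a logistic function of the 24 cover
percentages with no constant term — the composition sums to 100, so an
intercept would be aliased. Covariates are expressed in percentage points
(0–100) because the prior was elicited on that scale: independent zero-mean
normals on each coefficient with sd 1, meaning a 68% prior chance that one
percentage point of a class shifts the log-odds by less than 1. An
alternative sd of 1/6 is available; the two bracket the elicitation and the
default is the weaker sd = 1.

Inference is MAP plus Laplace: a damped Newton iteration on the penalised
log-likelihood (the prior guarantees a finite optimum even under complete
separation), with the posterior covariance taken as the inverse negative
Hessian at the MAP. The Gaussian summary is not a convenience choice — the
downstream area-uncertainty calculation linearises through it, and the
draw-based gain/loss probabilities sample from it. A random-walk Metropolis
sampler in the test suite checks that the Laplace standard deviations track
a sampling-based posterior within 20% at realistic problem sizes.

A pooled binomial mixed-effects model on the first 7 principal components of
the cover composition (global fixed effects; per-species random intercept
and slopes with diagonal covariance, simplified to a random intercept when
the fit fails) provides the per-species evaluation AUC used to screen
species, mirroring the envelope screen's 0.6 floor. It is a screening and
thresholding device only; headline probabilities always come from the
per-species Bayesian models, and thresholds are carried as metadata but
never applied to expected-area sums.

## Scenarios and allocation

National production changes convert to land areas with
round-half-away-from-zero cell counts; the post-increase horticulture
*total* is debited from the redistributable grazing cells and the natural
remainder is obtained by subtraction of the rounded totals, not by
independent rounding. (A corollary, verified in the tests: a "no production
change" input with a non-zero current horticulture stock is infeasible under
this arithmetic, because the existing stock would still be debited.)

Three allocation strategies move the converted area:

* **Local** — every modifiable cell exchanges the same proportions of its
  own grazing (removal proportional to the three grazing classes' shares;
  natural gains split equally among the three natural covers).
* **Best / Worst** — modifiable cells are ranked by the expected improvement
  in average species occurrence per unit area exchanged from grazing to
  horticulture, estimated by a finite-difference probe: one percentage point
  of cell area (capped at the cell's grazing content) is moved into
  horticulture and the masked probability change at posterior-mean
  coefficients, averaged over species, is divided by the area moved. An
  analytic form $\sum_s p_s(1-p_s)(\beta_{hort} - \bar\beta_{graz})$ would
  differ only at second order; the finite difference was chosen because it
  remains exact for large probes and zero-grazing edge cases. The walk
  converts each cell's entire grazing until the national target is met, with
  one fractional boundary cell; horticulture and natural conversions walk
  the same ordering from opposite ends, and "worst" reverses both.

The national targets are fractions of the grazing stock in *modifiable*
cells. This keeps the three strategies exchanging identical national
amounts (local allocation can only touch modifiable cells), which is what
makes their outcomes comparable.

## Impact statistics

For species $s$, habitable area is $A_s = \sum_{c \in \text{modifiable}}
p_s(c)$, reported as a fraction of modifiable cells and averaged over
species. Its posterior sd uses the delta method with gradient
$g = \sum_c p(1-p)\,x_c$; posterior draws (default 10,000, seeded per
species) give the probability of a ≥10% gain or loss relative to the
no-change comparator under the climate pairing declared per scenario
(future-climate scenarios compare against the current-climate no-change
baseline by default). Draws are aligned within species and independent
across species — the models are fitted separately, and the count of species
gaining/losing per draw therefore follows a Poisson-binomial-type
distribution whose central 95% interval is reported via inverse-CDF
quantiles (appropriate for an integer-valued quantity). A draw with zero
baseline area counts as a gain iff its scenario area is positive and never
as a loss — 10% of zero is degenerate and the convention is logged.

## The synthetic study system

`synthetic_config()` defaults define the study conditions used throughout
the tests and the acceptance script, chosen once as a plausible
temperate-maritime system:

| parameter | default | why |
|---|---|---|
| grid | 50 × 50 cells of 2×2 km | large enough for 500-cell pseudoabsence pools, small enough for minutes-scale runs |
| cover | Dirichlet(1) over 24 classes, 1 smoothing pass | flat concentration gives identifying cover contrast; one 4-neighbour averaging pass adds the spatial clustering the Best/Worst strategies need |
| modifiable fraction | 0.42 | share of cells open to change |
| climate | BIO1 8→12 °C across rows (noise sd 0.3), BIO12 600→1000 mm (sd 25), BIO13 = 0.25·BIO12 | gradients wide enough that envelopes bind |
| future | +2 °C, ×1.1 precipitation | mid-range mid-century change |
| species | 30; envelope half-widths 20–40% of the observed BIO1/BIO12 range; coefficients N(0, 0.2²) per percentage point | envelopes that shrink visibly under +2 °C; coefficient spread strong enough that habitat association, not noise, drives occurrence |
| detection | 0.5 per occupied cell; dates uniform 1970–2020; 1-km sub-cell uniform | opportunistic recording without modelling recorder behaviour |

What the generator does *not* emulate: recorder spatial bias, taxonomic
drift, coastline geometry, spatially autocorrelated climate noise, dispersal
or species interactions. Passing recovery tests therefore show the
estimators are correct under the stated generating process, not that real
records are this well behaved.

One point deserves emphasis. On a 2,500-cell grid, common virtual species
occupy so much of their envelope that the buffered pseudoabsence rule
(exclude presences and their 8 neighbours) exhausts the eligible pool —
tens of pseudoabsences against hundreds of presences — which degrades
coefficient estimates for exactly those species. That is a small-grid
artefact of the background-sampling rule, not of the Bayesian fit, so the
coefficient-recovery checks fit the model on the full record-vs-no-record
contrast over each species' *true* envelope (the same design as the
single-species recovery example), while the pipeline itself keeps the
buffered sampling that real presence-only data require. Envelope-mask
recovery is measured separately against ground truth.

## Numerical choices and degenerate inputs

* Newton iteration: damped by objective-based step halving; convergence at
  step ∞-norm < 1e-10 or gradient ∞-norm ≤ 1e-6; zero observations return
  the prior exactly.
* Posterior draws use an eigendecomposition square root, so rank-deficient
  and exactly-zero covariances sample without jitter.
* AUC requires both classes and errors otherwise; a CV fold with a
  single-class split is skipped with a warning, and leave-one-out (k = n)
  therefore fails loudly rather than returning a meaningless mean.
* Cell indexing is 0-based row/col with half-open 2-km cells (a 1-km point
  belongs to cell ⌊coord/2⌋, lower-left origin); "within one cell" is queen
  (8-neighbour) adjacency, configurable to rook.
* Pseudoabsence pool exhaustion caps the sample with a warning; an empty
  pool is a per-species stage error.
* The scaling-factor downscaler is additive for temperature variables and
  multiplicative for precipitation, with a zero-precipitation baseline ratio
  defined as 1 and BIO13 clipped back into [BIO12/12, BIO12].
* The decadal ensemble operator takes any model count (means over years
  within model, then over models).

## Problem sizes

The test suite runs in about a minute on one core: unit fixtures are tens to
hundreds of cells, the Metropolis oracle uses 800 observations × 25,000
kept iterations, and the recovery checks use the default 2,500-cell,
30-species system. The acceptance script repeats the recovery checks and a
full pipeline run (six scenarios × 10,000 draws per species) in a few
minutes.

## Known limitations

* The Gaussian posterior summary can misstate tail probabilities when the
  MAP sits in a strongly curved region (near-separable species); the
  MCMC cross-check bounds this at test scale but real data can be worse.
* Expected-area point estimates evaluate probabilities at the posterior
  mean; the draw-mean differs by a Jensen gap that is negligible at the
  tested covariance scales but grows with posterior width.
* The evaluation mixed model uses nAGQ = 0 (penalised quasi-likelihood
  integration) for speed; it is a screen, not an inferential endpoint.
* Allocation strategies treat cells as independent; no contiguity or
  landscape-connectivity constraint is imposed on where conversion lands.
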