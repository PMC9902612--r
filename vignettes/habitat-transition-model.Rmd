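---
title: "Modeling habitat transitions from joint GPS and accelerometer data"
author: "habitrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling habitat transitions from joint GPS and accelerometer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitrans)
```

## The problem

Tracking devices on wintering geese record a GPS position every 30 minutes
and a 3-second tri-axial accelerometer (ACC) burst every 6 minutes (10 Hz,
30 samples per axis). Each GPS fix carries a landcover (habitat) label, a
wintering-region label and the device temperature. ACC bursts, once
classified into behaviors (forage, walk, stationary, flight), describe what
the bird was doing between fixes. The scientific question is how the
probability of *transitioning* between landcover types depends on behavior,
temperature, time of day and wintering region — habitat *use* dynamics,
which require no availability assumptions, as opposed to habitat selection.

`habitrans` implements the full analysis pipeline: ACC burst utilities and
a behavior-classifier harness, GPS/ACC fusion and covariate construction, a
Bayesian discrete-time Markov transition model fit by Pólya-Gamma Gibbs
sampling, posterior summaries and diagnostics, and a synthetic-data
generator with known ground truth so that every stage can be validated by
parameter recovery.

## The transition model

Let habitat at fix $t$ of individual $n$ be a label among $H$ categories,
and let $J$ denote the baseline habitat (open water/unconsolidated shore by
default — used for roosting and loafing, with frequent transitions to every
other type). The probability of moving from habitat $i$ at time $t$ to
habitat $j$ at $t+1$ follows a multinomial logistic model:

$$
\log\frac{p_{nijt}}{p_{niJt}} = \sum_{r \in \mathcal{R}_j}\beta_{0jr}
I(\mathrm{Region}_{nt} = r) + \beta_{1j}\cos(\mathrm{Diel}_{nt}) +
\beta_{2j}\sin(\mathrm{Time}_{nt}) + \beta_{3ij}\mathrm{Forage}_{nt} +
\beta_{4ij}\mathrm{Walk}_{nt} + \beta_{5ij}\mathrm{Stationary}_{nt} +
\beta_{6ij}\mathrm{Temp}_{nt},
$$

with all coefficients into $J$ fixed at 0. Region intercepts and the two
harmonic time-of-day slopes are *habitat-specific* (they depend only on the
destination $j$), while behavior and temperature slopes are
*transition-specific* (they depend on origin and destination). The region
intercepts are hierarchical, $\beta_{0jr} \sim N(\beta_{0j}, 100)$ with
$\beta_{0j} \sim N(0, 100)$; every other coefficient gets an independent
vague $N(0, 100)$ prior. The priors on slopes are a design choice of this
package (symmetry with the intercept prior); only the intercept priors are
pinned down by the study design the package follows.

Structural zeros: a (region, origin, destination) cell can be excluded —
its probability is then exactly 0 and its records contribute nothing — when
the destination does not occur in the region, or when the transition is
never observed (per region by default; globally behind the
`scope = "global"` flag of `structuralMask()`, since either reading of the
exclusion rule is defensible). The baseline destination is always allowed
wherever it is available, which keeps every record's denominator positive.

## Sampling

The sampler (`gibbsFit()`) uses the conditional binary reduction of the
multinomial logit: for destination $j$, conditional on the other
destinations' linear predictors, each eligible record is a Bernoulli
observation with success log-odds $\eta_j - c$, where
$c = \log\sum_{k \ne j,\ \text{allowed}} e^{\eta_k}$ is an offset. A latent
Pólya-Gamma $\omega \sim \mathrm{PG}(1, \eta_j - c)$ per record makes the
likelihood conditionally Gaussian, so all coefficients feeding destination
$j$ — its region intercepts, time slopes and per-origin behavior and
temperature slopes — are drawn *jointly* from one conjugate Gaussian full
conditional, followed by the conjugate Normal update of the intercept
hyper-mean. Destinations are visited in fixed habitat order, which makes
runs reproducible under a seed. The alternative stick-breaking scheme
would also work; the block scheme was chosen because its conditional
likelihood is exact and the per-destination joint update mixes well.

The PG(1, z) variates come from the exact alternating-series rejection
sampler implemented in compiled code (`src/pg_gibbs.cpp`); it is valid for
all real z (the inverse-Gaussian branch handles large |z|, with the
mixture weights computed in log space), and all randomness flows through
R's RNG so `set.seed()` governs an entire fit. Softmax and offset
computations use max-subtracted log-sum-exp throughout. The conditional
precision always includes the prior precision, so the joint update is well
defined unless the design produces non-finite values; a Cholesky failure
is reported with the offending destination block named.

Default chain settings are 50,000 iterations with 10,000 burn-in and one
chain, matching the study configuration; tests and the acceptance script
run reduced chains (2,000 iterations, 500 burn-in; the sampler validation
runs use 4,000–6,000), which chain-length settings are configuration, not
behavior. Convergence is assessed with trace plots, autocorrelation
(`acfValues()`) and Geweke z-scores (`gewekeDiag()`, default 0.1/0.5
segment fractions, autoregressive spectral standard errors as in coda).

## Preprocessing rules

* **Backward burst assignment** (`assignBursts()`): bursts in
  $[\mathrm{fix}_k, \mathrm{fix}_{k+1})$ attach to $\mathrm{fix}_k$; a
  burst exactly at a fix timestamp belongs to that fix (closed-left
  convention, so no burst is counted twice). When the next fix is missing,
  bursts more than 60 minutes after the previous fix are dropped.
* **Sequence segmentation** (`segmentSequences()`): a gap strictly greater
  than 120 minutes starts a new sequence; 120 minutes exactly does not.
* **Transitions** (`buildTransitionRecords()`): only consecutive fixes
  exactly one fix period (30 min) apart within a sequence form a record.
  A single interior missing fix (a 60-min gap, below the 120-min split)
  therefore yields *no* record rather than a longer-step transition: a
  bridged step would change the Markov step length and mix two covariate
  windows. Self-transitions are ordinary records.
* **Behavior proportions** (`behaviorProportions()`): label counts over
  assigned bursts divided by burst count — each 3-s burst is treated as an
  equal sample of time. Forage, walk and stationary enter the design;
  flight is excluded (proportions sum to one, so including all four would
  be collinear). Fixes with no assigned bursts drop out.
* **Covariates** (`timeCovariates()`, `standardizeRecords()`): harmonic
  clock covariates $\cos(2\pi h/24)$ (positive at night, negative midday)
  and $\sin(2\pi h/24)$ (positive midnight–noon); behavior proportions and
  temperature are centered and scaled by dataset-wide sample moments
  ($n-1$ denominator), pooled over individuals to match the single model
  fit. Timestamps are assumed already in local time.

## The synthetic-data generator

`simConfig()` + `simulateTracks()` + `simulateBursts()` emulate the study
design: 8 landcover categories, 7 wintering regions with region-specific
habitat availability (by default corn is absent from the Chenier Plain and
rice from the Rolling/High Plains, so structural zeros are exercised), 30-min
fixes with i.i.d. missingness (default 5%, a typical solar-tag fix-failure
rate), 6-min bursts, habitat-conditioned Dirichlet behavior mixes (crops
forage-heavy; open water and woody wetlands stationary-heavy, mimicking
roosting; flight rare), and a diel AR(1) temperature process (winter Gulf
coast defaults: mean 10 °C, 4 °C diel amplitude, AR coefficient 0.7,
innovation sd 1.5 °C). Default track dimensions are 20 individuals ×
1,500 steps — the scale used for the package's parameter-recovery
validation. Each individual keeps one region for the whole track: the
region-intercept structure is preserved while the design matrix stays
simple (real geese move between regions; region switching could be added
behind a config flag without changing the model).

Two generator choices matter for interpretation:

* **Transitions are driven by burst-count proportions.** At each fix a
  Dirichlet behavior mix is drawn, the interval's five burst labels are
  drawn i.i.d. from it, and the *empirical fifths* (standardized) drive
  the next transition. Covariates rebuilt downstream from burst labels are
  then exactly the generating covariates, so end-to-end recovery is free
  of covariate measurement error by construction. Had the latent Dirichlet
  vector been used instead, burst-derived covariates would be noisy
  versions of the generating ones and every slope would be attenuated.
* **Standardization moments.** The generator standardizes with closed-form
  moments (uniform-habitat-mix Dirichlet burst-count moments; the AR(1) +
  cosine stationary moments) and stores them in the returned `SimTruth`.
  Because behavior mixes are habitat-conditioned, realized sample moments
  depend on realized habitat occupancy and can only agree with any
  pre-computable moments up to sampling error. Recovery runs therefore
  standardize with the stored generating moments
  (`standardizeRecords(spec = ...)`), which puts fitted and generating
  coefficients on identical scales; `recoveryReport()` also rescales slope
  truths by the sd ratio when the scales differ.

What passing recovery tests show — and what they do not: the generator
matches the model's own data-generating process (by design), so recovery
validates the sampler, the preprocessing contracts and the structural-zero
bookkeeping. It does not validate the model against real geese: real data
have region switching, state-dependent missingness, misclassified
behaviors, habitat-labeling error and non-Markov dependence, none of which
the generator emulates.

## The ACC behavior harness

Burst utilities follow the device contracts: per-axis affine calibration to
g; 10-s bursts subsampled to the 3-s scheme by keeping the *first* 30
samples (the deterministic, order-preserving choice; the study protocol
does not specify the segment); flight labeled where device speed exceeds
4.63 km/h (strict inequality); training sets capped at 150 bursts per
behavior by seeded subsampling. Burst summary features are a fixed,
documented 19-vector (per-axis mean, sd, min, max, range, mean absolute
dynamic component, and their ODBA-style sum); the original analysis defers
its feature list to external references, so this harness fixes its own for
reproducibility. `trainAndPredict()` wraps off-the-shelf learners (random
forest by default, SVM, LDA, kNN) over a seeded stratified 80/20 split, and
`evaluateClassifier()` reports overall accuracy, per-class precision and
per-class recall. On the generator's template bursts the harness reaches
held-out accuracy above 0.95 — a property of the synthetic templates that
mirrors, but cannot reproduce, accuracies reported from video-annotated
field data.

## A small worked example

```{r example, eval = FALSE}
habs <- defaultHabitats()
regs <- defaultRegions()[1:2]
rh <- list("MAV" = habs, "Chenier Plain" = setdiff(habs, "corn"))
truthCo <- randomCoefficients(habs, defaultBaseline(), regs, rh,
                              maxAbs = 1, seed = 101)
cfg <- simConfig(habitats = habs, regions = regs, regionHabitats = rh,
                 trueCoefficients = truthCo, nIndividuals = 20L,
                 nSteps = 1500L, seed = 102L)
sim <- simulateTracks(cfg)
bursts <- simulateBursts(sim$grid, cfg)
pp <- preprocessTracks(sim$fixes, bursts, regionHabitats = rh,
                       habitats = habs, regions = regs,
                       standardization = covariateMoments(sim$truth))
spec <- transitionModelSpec(habitats = habs, regions = regs,
                            regionHabitats = rh, mask = pp$mask,
                            nIter = 2000L, burnIn = 500L, seed = 103L)
post <- gibbsFit(pp$records, spec)
rec <- recoveryReport(post, sim$truth, standardization = pp$standardization)
attr(rec, "coverage")      # 95% CrI coverage over well-identified coefficients
attr(rec, "correlation")   # truth vs posterior-mean correlation
plotEffects(summarizeDraws(post), families = "intercept")
```

## Numerical choices and limitations

* Equal-tailed credible intervals (2.5%–97.5% quantiles), not HPD.
* Geweke segment fractions default to 0.1/0.5, the conventional defaults
  of the diagnostic; spectral standard errors use an AIC-selected AR fit.
* `recoveryReport()` marks coefficients with fewer than 30 eligible
  records, and the prior-identified intercept hyper-means, as not well
  identified; aggregate coverage and correlation are computed over the
  rest.
* Degenerate inputs error early: zero-variance covariates in
  standardization, unlabeled bursts, unsorted tables, records landing on
  masked cells, chains too short or constant in the diagnostics.
* Problem sizes in the test-suite and acceptance runs: the sampler oracle
  uses ~500 records with a 481×481 quadrature grid; the closed-form check
  5,000 records; the recovery study 20 × 1,500 steps (≈27,000 records)
  with a 2,000-iteration chain — sizes at which each check is decisive for
  its question while the whole suite stays convenient to run.
* Hidden-state models, continuous-time formulations, individual or spatial
  random effects, and model selection across effect structures are out of
  scope; the habitat state is observed and the step length is fixed.
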