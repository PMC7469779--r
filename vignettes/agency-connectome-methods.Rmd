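---
title: "Methods: agency psychophysics and connectome regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agency psychophysics and connectome regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agencynet)
```

## The problem

The sense of agency — the feeling that one's own action caused an event —
degrades as the delay between an action and its sensory effect grows.
`agencynet` implements a complete analysis chain for studies that
quantify this attenuation with an adaptive attribution task and then ask
which features of resting-state brain network topology predict it across
subjects. The chain has four stages: (1) an interleaved weighted up-down
staircase presenting action–effect delays and collecting self/computer
attributions; (2) Gaussian fitting of the per-delay normalized
self-attribution counts, yielding three behavioural indices; (3)
construction of a weighted similarity graph from ROI time series, with
percolation thresholding and node centrality metrics; and (4) a screened
forward stepwise regression of node metrics on behaviour. A synthetic
cohort generator with planted ground truth makes all four stages testable
without access to human data.

## The staircase and its equilibrium

The task presents an action–effect delay between 90 and 1,620 ms and asks
for a forced-choice attribution ("I triggered the effect" vs "the computer
did"). Two weighted up-down tracks run concurrently — one descending from
1,620 ms, one ascending from 90 ms, 70 trials each — with their 140 trial
slots interleaved by a seeded uniform shuffle so participants cannot track
either staircase. Each self response increases that track's delay by
90 ms; each computer response decreases it by 180 ms; delays saturate at
the range ends (the simplest rule consistent with a fixed 90–1,620 ms
range, since no reflection behaviour is defined there).

A weighted up-down procedure has zero expected drift where
$p \cdot S_{up} = (1 - p) \cdot S_{down}$, i.e. at
$p^* = S_{down} / (S_{up} + S_{down})$. For the 90/180 ms steps used here
this is $p^* = 2/3$: the track hovers around the delay at which the
subject still claims agency two times in three. `equilibrium_probability()`
exposes this formula for any step pair. (A commonly quoted convergence
level of 80.3% for up/down step ratios of this family does not follow
from the zero-drift equation for these steps; the package computes the
level rather than assuming one.)

A single track's last-20-trial mean sits slightly below the equilibrium
delay (the stationary distribution is left-skewed because the down-step
is twice the up-step) and fluctuates with an SD of roughly half a
down-step. The package's convergence summary therefore averages the
ascending and descending tracks' last-20 means — the standard
psychophysics practice of combining complementary staircases, which
cancels their opposite approach biases. With a logistic observer
(PSE 600 ms, slope 80 ms) this estimate lands within ±90 ms (one up-step)
of the true equilibrium delay in ≥95% of sessions.

## The observer model

Simulated subjects respond via a decreasing logistic psychometric
function with lapse rate $\lambda$:
$$P(\text{self} \mid d) = (1-\lambda)\frac{1}{1 + e^{(d -
\text{pse})/\beta}} + \lambda/2.$$
A monotone attenuation curve is the standard generative assumption for
attribution behaviour; the Gaussian shape that the analysis stage fits
describes the *adaptively sampled histogram* (the staircase revisits
delays near the uncertainty region, producing a hump), not the observer
itself. Defaults for synthetic cohorts — PSE ~ N(600, 150²) ms clamped
to the task range, slope ~ N(100, 20²) ms floored at 40 ms, lapse
0.02 — put simulated index distributions in the range typical of healthy
adults on this task (group mean peak delay near 600 ms, peak values
around 0.2).

## Behavioural indices

For each subject the number of self responses at each sampled delay is
divided by the total session trial count (140), and the resulting curve
is fitted by unweighted least squares to a three-parameter Gaussian
$y(d) = a\,e^{-(d-\mu)^2/(2\sigma^2)}$ (no baseline offset: the indices
of interest are the peak, its location and the width). The indices are:

* **t_PSE** (`mu`, ms) — the delay of the curve peak, read as the point
  of subjective equality;
* **peak value** (`a`) — consistency of self-attribution at that delay;
* **curve SD** (`sigma`, ms) — the width of the time window over which
  a partial sense of agency persists.

Fitting uses Levenberg–Marquardt (`minpack.lm`) with a bounded
quasi-Newton fallback, initialised at the raw maximum (amplitude), its
delay (mean) and the y-weighted delay SD (sigma), with bounds
$a \in [0,1]$, $\mu \in [0, 2000]$ ms, $\sigma \in [30, 2000]$ ms.
Non-convergence is flagged, not thrown. $R^2 = 1 - SS_{res}/SS_{tot}$ is
computed over the sampled delays only; delays never visited by the
staircase are not zero-filled, since the adaptive procedure defines the
sampling support. Subjects with $R^2$ below `r2_min` (default 0.30; the
exclusion precedent in this literature is a subject rejected at
$R^2 = .23$, with no cutoff printed, so the threshold is configurable)
are flagged invalid and excluded downstream. Whether the "peak value"
of such curves should be the fitted amplitude or the raw maximum is not
settled usage; the fitted amplitude is used, and both are reported.

```{r}
obs <- make_observer(625, 100, 0.02)
trials <- run_session(obs, seed = 42)
fit <- fit_agency_curve(aggregate_curve(trials))
fit
derive_indices(fit)
```

Note that the fitted t_PSE sits below the observer's generative PSE: the
sampling hump concentrates near the staircase equilibrium delay
($P(\text{self}) = 2/3$, which lies below the 50% point) and is further
shaped by the asymmetric step rule. Across observers the two are
strongly monotonically related (r > 0.9 in the test suite), which is
what the cross-subject correlation and regression stages rely on.

## Correlations with covariates

Pearson correlations between indices and covariates (trait scores, task
accuracies) are tested with the Fisher variance-stabilizing transform,
$z = \operatorname{atanh}(r)\sqrt{n-3}$, two-tailed against the standard
normal. All pairs submitted in one call form a single
Benjamini–Hochberg family at q = 0.05; the family scope is left to the
caller because no universal convention exists for how many indices and
covariate batteries belong together. Missing data are handled
pairwise-complete. The Fisher approximation is mildly anti-conservative
at n near 37 (empirical size ≈ 0.053 at nominal 0.05); the package's FDR
calibration checks therefore exercise the step-up procedure on exact
uniform null p-values, which is the property BH itself guarantees.

## Connectome construction

ROI time series (one column per region; the intended use is a 100-region
parcellation grouped in seven networks, 240 volumes at TR = 3 s) are
demeaned, linearly detrended, despiked by robust winsorization (clipped
at median ± 4 MAD — "despiking" names an intent, not an algorithm, so
the simplest robust rule is used), and band-pass filtered. The filter
zeroes discrete Fourier bins outside the band, which is zero-phase by
construction and has an exact passband verifiable on the spectrum. The
nominal band is 0.01–0.25 Hz, but at TR = 3 s the Nyquist frequency is
≈0.167 Hz, so the upper edge is capped there and the filter acts as a
0.01 Hz high-pass.

Edges are weighted by the **squared** Pearson correlation between ROI
time courses, so strongly anticorrelated regions count as similar —
appropriate because the sign of hemodynamic coupling is not
interpretable as dissimilarity. The complete weighted graph is then
thresholded at the **percolation threshold**: the largest cutoff τ at
which the graph remains a single connected component. τ equals the
bottleneck (minimum) edge weight of the maximum spanning tree, computed
via igraph; edges with weight exactly τ are retained (dropping the tie
class would disconnect the graph). The test suite verifies the MST
bottleneck against an independent descending-threshold search on random
matrices.

Three node metrics are computed on the retained graph:

* **degree strength** — sum of retained edge weights (binary degree by
  flag);
* **clustering coefficient** — the Onnela geometric-mean weighted
  generalization
  $\hat c_i = \frac{2}{k_i(k_i-1)}\sum_{j<h}
  (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$, with weights normalized by
  the graph maximum. The classical binary coefficient is available by
  flag, but the retained graph is weighted and discarding weights would
  waste exactly the information the similarity construction carries;
* **betweenness centrality** — shortest-path betweenness with edge
  length $1/w$ (the standard mapping for similarity weights;
  $1 - w$ available), fractional counting of tied shortest paths,
  normalized by $(n-1)(n-2)/2$.

## Brain–behavior regression

For one behavioural index and one metric type at a time (metric types
are never pooled into one candidate set):

1. **Screen**: each node's metric is regressed on the index in a simple
   linear regression; only nodes with p < .05 survive. With z-scored
   variables the reported statistics satisfy $\beta^2 = R^2$,
   $\text{adj}R^2 = 1-(1-R^2)\frac{n-1}{n-2}$ and
   $F = \frac{R^2}{1-R^2}(n-2)$ on (1, n−2) df.
2. **Tolerance filter**: each surviving candidate's tolerance
   (1 − R² of regressing it on the other candidates) must be ≥ 0.30.
   Tolerance is computed among the screened candidates (screening
   defines the candidate set; computing it among all 100 nodes would let
   excluded nodes veto included ones), and every member of an exactly
   collinear (zero-tolerance) set is dropped rather than keeping one
   arbitrarily.
3. **Forward stepwise**: starting from the empty model, the candidate
   with the largest partial F enters while that F exceeds 4; ties break
   by label order. An empty final model is a valid outcome. Final model
   statistics use $\text{adj}R^2 = 1-(1-R^2)\frac{n-1}{n-k-1}$ and
   F on (k, n−k−1) df.

With ~20 null candidates and F-to-enter 4 (≈ p < .053 at df (1, 35)), a
first entry occurs in roughly two-thirds of null replicates — an
expected property of stepwise selection, which is why the preliminary
screen and the tolerance rule exist; the suite asserts this calibration
at its analytic value.

## The synthetic cohort and what it does (not) emulate

`cohort_spec()` fixes the simulated study design: 37 subjects, 100 ROIs
in 7 equal contiguous communities, 240 timepoints at TR = 3 s. Traits
are coupled to the observers' true PSE through a Gaussian copula (exact
target correlations in expectation; an infeasible target matrix is
repaired by eigenvalue clipping at a positive floor and rescaling to
unit diagonal). Trait scales are arbitrary standardized variables, since
real trait inventories have idiosyncratic scales that do not affect
correlation-based analyses. Connectomes follow a block correlation
model, r_within = 0.30 inside communities and r_between = 0.05 across —
values in the range typical of parcel-averaged resting-state
correlations. The planted effect shifts one node's within-community
correlation level by `planted_amplitude` (default 0.25) times
$u_j = \rho z_j + \sqrt{1-\rho^2}e_j$, mixing the subject's standardized
behavioural index with noise so the across-subject coupling–behaviour
correlation targets ρ; matrices are clipped and PSD-repaired. One master
seed drives everything; per-subject streams use fixed offsets, so
cohorts are bit-reproducible while subjects remain independent.

The generator emulates the statistical structure the pipeline consumes:
staircase response streams, trait–index correlations, community-blocked
covariance and a node–behaviour association. It does **not** emulate
hemodynamic response shapes, scanner noise spectra, motion or
physiological artifacts, spatial autocorrelation between neighbouring
parcels, or heavy-tailed trait distributions. Passing tests therefore
demonstrate that the estimators and the selection machinery are correct
and calibrated on data satisfying their assumptions — not that those
assumptions hold in any given fMRI dataset.

## Numerical choices and problem sizes

The test suite and the acceptance script keep simulations at sizes that
make their Monte-Carlo error small relative to the asserted tolerances
while staying quick: 100 seeded sessions for staircase convergence, 100
random graphs of 4–12 nodes against brute-force oracles, 50 planted
replicates at the full 37 × 100 design for recovery, 25 null replicates
for screen calibration and 1,000 replicates (m = 14) for FDR
calibration. Thresholds asserted against stochastic quantities carry
explicit Monte-Carlo slack (three standard errors) rather than point
equality.

Degenerate inputs are handled deterministically: constant time-series
columns are an error in similarity construction (a zero-variance region
is a data defect, not a zero correlation); constant metric columns are
dropped from the screen with a warning; |r| = 1 correlations are
reported with infinite z and excluded from the FDR family; an empty
stepwise model predicts the behavioural mean.

## Known limitations

* The pipeline starts from ROI-level time series; no imaging formats or
  spatial preprocessing are handled.
* The Gaussian index model has no baseline term, so observers with a
  high lapse floor are poorly fitted by design — such subjects are
  exactly the ones the R² exclusion rule is meant to remove.
* Stepwise selection with an F-to-enter rule does not control selection
  inference; reported p-values of the final model are conditional on
  selection, as in the original procedure this package mirrors.
* The percolation threshold is unique only up to ties in the bottleneck
  weight; with continuous similarity values ties have measure zero, but
  duplicated columns can create them, and the retained-tie rule decides
  those cases.
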