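---
title: "Decoding brain-state dynamics from network fMRI time series"
author: "brainStateDyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding brain-state dynamics from network fMRI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainStateDyn)
```

## The model

`brainStateDyn` treats network-averaged BOLD time series as the output of a
hidden Markov model with Gaussian emissions. At every repetition time (TR)
the brain occupies one of K discrete states; state k is a whole-brain
configuration described by a mean activation pattern over the D canonical
brain networks together with a full D x D covariance. The state sequence
evolves with a time-invariant K x K transition matrix. Runs from all
subjects, sessions and conditions are temporally concatenated and fitted
jointly, so one set of states is shared by the whole cohort and dynamics
can be compared across conditions; during inference no probability flows
across run boundaries, and all runs share a single initial-state
distribution.

Everything downstream operates on point decodings of this model: the
Viterbi state path and the forward-backward posteriors per run. From the
paths the package derives fractional occupancy (FO; the fraction of TRs in
each state), dwell times (mean duration of uninterrupted visits),
empirical transition matrices, sliding-window inter-subject consistency,
cross-session Jaccard overlap, Szymkiewicz-Simpson coupling of states to
annotated stimulus features, state-conditioned physiological deviations,
and inter-subject representational similarity (IS-RSA) between brain
dynamics and questionnaire ratings.

### Maximum-likelihood EM rather than variational Bayes

The reference workflow for this family of analyses uses variational-Bayes
inversion. This package deliberately fits by maximum-likelihood EM
(Baum-Welch): every quantity consumed downstream (state means, Viterbi
paths, FO, transition probabilities) is defined on point estimates, which
EM provides deterministically for a given seed, and the likelihood it
reports is exact, which lets the test suite verify the recursions against
brute-force path enumeration to 1e-10. The trade-off is the absence of
posterior uncertainty on the parameters and of a free-energy criterion;
the number of states is chosen by AIC instead (below).

Numerical choices:

* **Scaling.** The forward-backward and Viterbi recursions subtract the
  per-timepoint maximum log emission density and renormalise each step;
  the log-likelihood is recovered exactly from the scaling constants. A
  timepoint whose emission density underflows in every state raises an
  error suggesting stronger regularisation rather than returning garbage.
* **Covariance ridge.** Every M-step adds `1e-6 * trace(S)/D` to the
  covariance diagonal. With D = 14 networks and runs of a few hundred
  volumes, unregularised estimates can become numerically singular when a
  state's occupancy dips.
* **Initialisation.** Each restart seeds k-means on a subsample of rows;
  cluster centres initialise the means and the pooled *within-cluster*
  covariance initialises every state. The within-cluster (not global)
  covariance matters: with well-separated states the global covariance is
  dominated by between-state spread and is nearly singular along it, the
  initial emission model barely discriminates, and EM can collapse into a
  single effective state. Transitions start at 0.9 self-probability with a
  uniform off-diagonal; the initial distribution starts uniform.
* **Convergence.** Relative log-likelihood change below `tol` (default
  1e-6) or `maxIter` (default 500, mirroring common practice). The
  reported log-likelihood is re-evaluated at the returned parameters, so
  it equals an independent forward pass exactly.
* **Ties.** Viterbi ties break toward the lowest state index, applied
  identically in the forward maximisation and backtracking, so decodings
  are deterministic.
* **State alignment.** Restarted or refitted models label states
  arbitrarily; `alignStates()` matches states by maximising total Pearson
  correlation between state-mean vectors via an exact assignment solver
  (Jonker-Volgenant), and `applyStatePermutation()` applies the
  relabelling consistently to parameters, paths and posteriors.

### Choosing the number of states

`selectStates()` fits each candidate K and tabulates
`AIC = 2k - 2 lnL` with
`k = K D + K D(D+1)/2 + K(K-1) + (K-1)`, recommending the AIC minimiser
among models whose every state keeps fractional occupancy above a floor
(default 0.5%); models carrying effectively unoccupied states are treated
as past the useful resolution of the data. Users should know that AIC is
an intrinsically marginal criterion for this model family: the
maximum-likelihood gain of one spurious Gaussian state (obtained by
splitting a true state along a sampled noise direction) empirically tracks
a large fraction of the AIC penalty across a wide range of problem sizes.
The penalty grows quadratically with D while the noise of the comparison
grows much more slowly, so selection is sharp when the emission dimension
is generous relative to K and unreliable when states live in few
dimensions. The packaged selection study therefore validates recovery at
D = 18 networks (6 segments x 150 TRs, 3 generating states), where the
recommendation is correct in 95-100% of replicates; at D = 5-14 the same
study hovers at 55-80% and should not be read as a defect of the
implementation but as a property of AIC on this family.

## The synthetic cohort generator

`generateCohort()` emulates the study design the analysis targets: 14
subjects, two sessions three months apart, each session one eyes-closed
rest run (220 volumes) and one movie run (535 volumes) at TR 2.2 s, with
the first five volumes of every run discarded during preparation (giving
the 20,860 x 14 concatenated matrix for the default cohort). The
generator's regimes encode the two phenomena the statistics are meant to
detect:

* **Rest is bistable and idiosyncratic.** Each subject-session rest run is
  an independent Markov chain concentrated on a small set of dominant
  states (defaults: states 5 and 9, self-probability 0.9, with most of the
  leak flowing between the dominant states). Rest paths therefore agree
  poorly across subjects and sessions.
* **Movie viewing is stimulus-locked.** One master state sequence, drawn
  from a movie-regime transition matrix (self-probability 0.8, a favoured
  cyclic successor at 0.1, uniform remainder), is shared by all subjects
  and both sessions. Each subject-session copy is circularly shifted by at
  most `jitterTr` TRs (misalignment of transition timing) and corrupted by
  per-TR flips toward the dominant rest states — attention lapses that
  re-engage the intrinsic regime.
* **Engagement couples behaviour to dynamics.** Each subject has a latent
  engagement score in \[0,1\]. The effective flip probability is
  `flipProb + 0.4 * engagementCoupling * (1 - engagement)`: disengaged
  subjects drift toward rest-like occupancy during the movie. The same
  score drives `attachQuestionnaire()` (boredom inversely, enjoyment /
  emotion / audio quality directly, mixed with uniform noise weighted
  `1 - coupling`). Flips must target a *non-uniform* state profile for
  this coupling to be detectable by IS-RSA: a uniform flip target shifts
  every FO vector affinely toward the uniform distribution, and Pearson
  correlation distance is invariant to affine shifts, so the engagement
  signal would cancel identically. Directing lapses at the intrinsic rest
  states is both the phenomenon being emulated and the mathematically
  non-degenerate choice.

State means are Walsh-type +/- sign patterns (rows 2..K+1 of the Walsh
system, which are balanced and never constant) with entry amplitude
`meanSeparation * sqrt(covScale)`; two states differing in h pattern
entries sit `2 * meanSeparation * sqrt(h)` pooled SDs apart. Emission
covariance is `covScale * I`. These defaults make states clearly
separable, which is what recovery tests require; real BOLD states overlap
far more, carry correlated noise, haemodynamic smoothing and
scanner drift, none of which the generator emulates — passing recovery
tests here demonstrates correctness of the machinery, not expected
performance on real data.

Physiology (`attachPhysio()`): heart rate = 70 bpm + per-state offset +
AR(1) noise; pupil diameter = 3.0 a.u. + per-state offset − `lumCoupling`
x mean-centred luminance + AR(1) noise; luminance is an independent
smooth AR(1) trace. The negative pupil-luminance coupling reproduces the
sign of the association seen in naturalistic viewing. Default offsets
(−3 bpm on state 3; +0.3 a.u. pupil on states 1-2, −0.4 on state 4)
mirror the direction of reported state-physiology couplings without
copying any numeric claims. `attachAnnotations()` converts master-path
epochs of chosen state sets into half-open `[onset, offset)` second
intervals, the same dialect `binarizeAnnotations()` consumes (TR t is
marked if `[t*TR, (t+1)*TR)` intersects any interval).

## Preprocessing

`prepareRun()` applies, in fixed order: drop the first `dropN = 5`
volumes; zero-phase (forward-backward) 4th-order Butterworth band-pass
between 0.01 and 0.15 Hz; ordinary-least-squares confound regression with
an intercept; per-network z-scoring. The order is recorded in each run's
provenance. Whether z-scoring precedes or follows filtering is not
dictated by the underlying workflow description; this package fixes
drop -> filter -> regress -> z-score and documents it rather than
guessing. Band edges must lie strictly inside (0, Nyquist); at TR 2.2 s
the Nyquist frequency is ~0.227 Hz, so a 0.15 Hz upper edge is close to
the transition band and the filter's effect on near-edge components is
gradual, as for any 4th-order Butterworth. The synthetic pipeline defaults
to `band = NULL` because simulated emissions contain no drift or aliased
physiological noise for the filter to remove.

## Statistics: conventions and decisions

* **Dwell time** is the mean duration of uninterrupted visits (not the
  total time in state, which is FO x run length); both readings appear in
  descriptions of such analyses, and the visit-duration reading is used
  consistently here.
* **Transitions** are counted within runs only; concatenation boundaries
  contribute no pairs. Group contrasts exclude the diagonal.
* **The 20% transition threshold** keeps off-diagonal edges at or above
  the weight rank `ceiling(0.2 * K(K-1))`, retaining all boundary ties.
* **The transition-graph permutation statistic** forms, per directed edge,
  a paired t statistic between conditions, keeps edges above a
  user-supplied primary threshold (the cluster-forming height has no
  canonical value and is deliberately a required argument), scores weakly
  connected components by edge count, and compares them against the
  maximum component size under within-subject condition flips. When
  `2^n <= nPerm` all sign patterns are enumerated and the p-value is
  exact.
* **Sliding-window consistency** uses a centred window (default 9 volumes
  = 19.8 s at TR 2.2) truncated at run edges; for each state it counts
  subjects expressing the state at least once in the window; the
  consistency percentage is the maximum count over states, with modal-state
  ties resolved toward the lowest index.
* **Path dissimilarity** between two subjects is 1 minus the mean
  per-state Jaccard index over states expressed by at least one of the
  two; the same per-state-then-average reduction is used for
  cross-session consistency, keeping the two analyses commensurable.
* **Szymkiewicz-Simpson coupling** compares each subject's state
  expression vector with a binarized annotation track;
  `|a AND b| / min(|a|, |b|)`, undefined (reported missing, never zero)
  when either vector is empty. The null shuffles the annotation vector
  uniformly — one shared shuffle per iteration across subjects, matching
  a subject-averaged statistic — and an autocorrelation-preserving
  circular-shift mode is available but off by default. The z score
  against the permutation null is reported alongside the permutation
  p-value `(1 + #{null >= obs}) / (nPerm + 1)`; one-sided, since the
  question is enrichment. Family-wise control is Bonferroni over K states
  x categories (0.05/60 = 8.3e-4 for 10 states and 6 categories).
* **Physiological deviations** are mean trace value during a state minus
  the run mean, so the occupancy-weighted deviations sum to zero exactly
  per subject — a useful invariant the tests assert. Note this means a
  planted additive offset on state k is recovered as `delta_k / (1 - FO_k)`,
  not as `delta_k` itself.
* **IS-RSA** uses Euclidean distance for questionnaires, `1 - Pearson r`
  (not `1 - |r|`) for FO profiles and off-diagonal-flattened transition
  matrices, and Jaccard path dissimilarity for paths. The Mantel statistic
  correlates strictly-lower triangles; the null jointly permutes rows and
  columns of the second matrix; `n! <= nPerm` triggers exact enumeration.
  One-sided (positive association), matching the directional hypothesis
  that similar dynamics accompany similar ratings.
* **Classical MDS** is the double-centred Gram eigendecomposition with a
  deterministic sign convention (largest-magnitude coordinate positive per
  axis) so embeddings reproduce across runs.

## Problem sizes used by the packaged studies

The test suite and the acceptance script validate the machinery at sizes
a laptop handles in minutes, chosen as the smallest studies that make the
tested properties decisive: parameter recovery at K = 4, D = 6, 14
segments x 750 TRs (transition error < 0.05, state-mean correlation >
0.99, Viterbi accuracy > 95%); model selection at K_true = 3, D = 18, 6 x
150 (see above); regime contrasts and engagement coupling on 14-subject
default cohorts over 20 and 100 replicates; permutation calibration with
1000 null datasets at 500 permutations each. The permutation defaults in
the analysis functions themselves remain 5000.

## Known limitations

* No haemodynamic convolution, voxel-level simulation, motion or
  physiological-noise artefacts in the generator; recovery results bound
  correctness, not field performance.
* Maximum-likelihood point estimation: no parameter uncertainty, no
  free-energy model comparison.
* AIC state-count selection is marginal in low emission dimensions (see
  above).
* The `18 x 17` distance-matrix bookkeeping sometimes described for
  IS-RSA is interpreted as standard symmetric n x n matrices with the
  strictly-lower triangle vectorised.
* Annotation binarization marks a TR on any overlap with an interval;
  sub-TR interval structure is not represented.
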