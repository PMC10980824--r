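---
title: "Multiscale resting-state envelope dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale resting-state envelope dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mserd)
```

## What the package models

Resting-state electrophysiological recordings show structure at two distinct
timescales. At the sub-second scale, source-space power envelopes switch
between a small repertoire of recurring spatial patterns — transient network
states with lifetimes on the order of 100–200 ms. At the supra-second scale,
the slow co-fluctuation of amplitude envelopes between regions defines a
functional connectome. `mserd` implements both analyses on a common envelope
representation, links them through *state networks*, and relates both to
behavioural indices from a sequential finger-tapping task. Because real
recordings of this kind are rarely shareable, the package ships a generator
that produces every input with known ground truth, so each stage is testable
end to end.

## Fast dynamics: the envelope HMM

The central model is a K-state hidden Markov model with Gaussian emissions,
fitted on the standardized, concatenated, PCA-reduced envelope matrix
(`env_hmm()`). The generative assumption is that at each 25-ms step one of K
states is active, states follow a first-order Markov chain
(`pi`, transition matrix `A`), and the observed component vector is drawn
from a state-specific full-covariance Gaussian. The defaults mirror the
canonical envelope-HMM setup: `K = 8` states, 10 EM restarts with the
best-scoring fit retained, 40 principal components, envelopes at 40 Hz.

Design choices that were genuinely open:

* **Inference.** Parameters are estimated by maximum-likelihood EM
  (Baum–Welch) and restarts are ranked by negative log-likelihood (lower is
  better). Variational-Bayes envelope-HMM implementations rank restarts by a
  free-energy functional instead; we use the likelihood because it admits
  exact oracles (additivity over independent segments, label invariance,
  dominance of the generating model), while the decoding interface is
  identical. The selection criterion sits behind `model_score()` and is
  deliberately pluggable.
* **Initialisation.** Each restart draws K distinct observations as random
  centers, refines them with a few seeded Lloyd (k-means) iterations on a
  subsample — the cheap standard guard against merged-state local optima —
  uses the global covariance for every state, and starts from a sticky
  transition matrix (self-transition 0.9). Randomness across restarts comes
  only from the seeded draws, which keeps fits bit-reproducible given
  `(seed, n_restarts)`.
* **Convergence.** Relative log-likelihood change below `1e-6` or 500
  iterations. Degenerate covariances are repaired by diagonal loading with a
  warning.
* **Ties.** Viterbi decoding breaks exact ties toward the lower state
  index, so decoded paths are deterministic.
* **Segments.** Recordings are concatenated subject-major, session-minor;
  the chain restarts at the initial distribution at every recording onset,
  and all per-recording statistics are computed after de-concatenation.

State labels are arbitrary. Any cross-run comparison must first align
states; `match_states()` provides exact assignment (enumeration, K ≤ 9) under
either absolute-cosine similarity (scale- and sign-blind; appropriate for
power maps) or Euclidean distance (appropriate for signed state means).

### Temporal parameters

For each state, subject and session, `temporal_params()` computes by
run-length encoding: fractional occupancy FO, number of occurrences NO, mean
lifetime MLT (seconds), and mean interval length MIL (seconds). Two
conventions needed fixing: MIL counts only inactive gaps lying strictly
between two visits (leading/trailing inactivity is excluded), and unvisited
states get `NO = 0`, `FO = 0` and missing MLT/MIL, with missingness
propagated into group statistics rather than imputed. The identities
`sum(FO) = 1` and `MLT * NO = FO * T` (for `NO > 0`) are enforced by tests.

### State power maps and state networks

`state_power_maps()` computes, per state and node, the partial correlation
between the state's activation indicator and the node envelope, controlling
for the other states' indicators. Because the K indicators sum to one, one
state is dropped from the control set as a reference (the last state, or
`K - 1` when mapping the last state itself); this removes the exact
collinearity without changing the interpretation. Maps are computed against
the standardized node envelopes (pre-PCA), not the component scores. A
state's network is the node subset where `|map|` reaches 60% of its maximum
absolute value (`extract_state_network()`, scale-invariant by construction).

## Slow dynamics: envelope connectomes

`envelope_correlation()` computes the Pearson correlation between node
envelopes after moving-average smoothing. The smoothing window is the one
free timescale parameter: the literature's "slow" envelope correlation is
citation-defined rather than printed, so the default is 1.0 s and the value
is configurable. `node_power()` supplies the per-node variance vector used
to control for power-induced connectivity effects.

Source leakage correction in sensor-space pipelines requires the inverse
operator, which is out of scope here; the package instead offers generic
pairwise regression orthogonalization (`orthogonalize()`, and
`leakage_correction = "pairwise"` in `envelope_correlation()`), defaulting to
off for synthetic data, which has no leakage unless a mixing matrix is
requested from the generator.

The node registry is data, not code: a TSV with id, name, MNI coordinates
and source. The bundled file carries the 116 standard AAL region labels plus
10 synthetic motor-literature placeholder nodes (126 in total) with missing
coordinates; users with real data supply their own registry. Coordinates are
metadata only — nothing geometric is computed from them.

## Network-based statistics

`nbs_fwer()` implements permutation FWER control over connected components
of suprathreshold edges. Edge statistics are paired t values (condition
contrasts) or Pearson correlations with a covariate, thresholded at
`t > 3.5`; correlations are passed through `t = r * sqrt((n-2)/(1-r^2))` so
one cutoff serves both designs. Component size is the edge count. The null
distribution of the maximum component size is built from 5000 permutations
by default — sign flips of within-subject difference matrices for the paired
design (exact exchangeability under the paired null), covariate reshuffling
for the correlation design — and p-values use the `+1` Monte-Carlo
correction, so they are never zero. Positive and negative tails are analysed
separately. The permutation loop exploits the fact that per-edge sums of
squares are sign-flip invariant, reducing each permutation to one matrix
product, with the component scan in compiled code.

## Behavioural indices

A block of the tapping task is 30 s of cyclic reproduction of the 5-element
sequence 4-1-3-2-4. Per-press correctness is decided against the cyclic
expectation with a one-press-lookahead realignment: a mismatch is scored as
a substitution (the expectation advances by one) unless treating it as a
skip to the key's next occurrence in the cycle makes the following press
match. The block score is `GPI = (correct presses per second) x (correct /
total presses)` — the exact published combination of speed and accuracy is
in supplementary material we do not have, so the package uses this monotone
combination and keeps it behind a single replaceable function (`gpi()`).

Derived indices: BMP is the mean of the two best learning-block GPIs; the
learning index is the percent change from baseline to BMP, with baseline the
mean of learning blocks 2–3 (block 1 is excluded as task discovery); offline
changes are best-test-GPI minus BMP per testing window. Z-normalisation is
within-subject over the learning blocks — the normalisation population was
an open choice; within-subject is the only variant that removes both
additive and multiplicative group offsets exactly, which is the stated
purpose of normalising.

## Scalar statistics

`rm_anova()` wraps a type-III multivariate linear model with a
within-subject design (session x induction, group between), applying the
Greenhouse–Geisser correction to an effect's df and p when its Mauchly test
gives p < 0.05. Subjects with incomplete cells are excluded cell-wise and
the analysed n is reported; the missing-data policy for unvisited HMM states
is cell-wise exclusion with per-test n. `spearman_ci()` uses average ranks,
an asymptotic two-sided p, and a Fisher-z interval with SE `1/sqrt(n-3)` —
the interval construction was unstated upstream, and Fisher-z is the common
software default. The Bonferroni family for state temporal parameters counts
independent quantities: `(K - 1)` states (one is determined by the others)
times `(n_params - 1)` parameters, i.e. 21 for 8 states and 4 parameters.
`wilcoxon_signed_rank()` reports the negative-rank statistic with exact p up
to n = 25 (no ties) and a continuity-corrected normal approximation beyond.

## The synthetic generator and what it does (not) emulate

`sim_config()` fixes the study conditions: 30 subjects, 7 sessions, 126
nodes, 8 states, 40 Hz, 5-minute sessions, a sticky chain whose expected
dwell (6 samples = 150 ms) sits in the transient-state range, uniform
initial probabilities, and one mean-power offset pattern per state with
additive Gaussian node noise. The additive-Gaussian observation model was
chosen to match the HMM's emission assumption, making parameter-recovery
tests well-posed; leakage is emulated, when requested, by a fixed linear
mixing matrix, because leakage is instantaneous and linear in theory.
Inter-node amplitude coupling enters through a noise covariance. All
randomness derives from one master seed through a deterministic counter
scheme (`stream_seed()`), so any single recording can be regenerated in
isolation.

What passing tests therefore show: the estimation machinery recovers the
parameters of data that satisfy its assumptions, the permutation procedures
attain their nominal error rates under exchangeable nulls, and the index
arithmetic is correct. What they do not show: robustness to non-Gaussian
envelope marginals, 1/f spectra, volume-conduction structure beyond linear
mixing, state-duration distributions that are not geometric, or behavioural
error processes beyond independent substitutions.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations are sized for a single CPU:
parameter recovery uses 10 subjects x 20000 samples x 16 nodes x 8 states at
pattern SNR 3 (10 seeds in the suite, 5 in the script); FWER calibration
uses 20 subjects, the 126-node registry scale, 1000 permutations per
replicate (500 replicates in the suite, 300 in the script); type-I
calibrations use 200–1000 replicates. These sizes give binomial standard
errors around one percentage point on calibration rates.

## Known limitations

* The likelihood-based restart selection is not the variational free energy
  of Bayesian envelope-HMM implementations; no equivalence is claimed.
* The exact published speed–accuracy formula behind the block score is
  unavailable; scores are flagged as computed under the package's formula.
* The geometric leakage-correction scheme is not implemented (it needs the
  source-reconstruction operator); pairwise orthogonalization stands in its
  pipeline position.
* MIL/MLT are undefined for unvisited states and propagate as missing;
  group statistics must use cell-wise exclusion (the default here) or model
  missingness explicitly.

## A small worked run

```{r, eval = FALSE}
cfg <- run_config(
  sim = sim_config(n_subjects = 10, n_sessions = 7, n_nodes = 20,
                   n_states = 8, samples_per_session = 4000,
                   pattern_scale = 3, seed = 1),
  n_components = 20, n_restarts = 10, nbs_n_perm = 1000)
res <- run_pipeline(cfg, out_dir = "run1", verbose = TRUE)
summary(res$model)
head(res$temporal)
res$nbs
```
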