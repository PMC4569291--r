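---
title: "Prospective planning on reward lattices: models, design decisions, and what the synthetic cohorts show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospective planning on reward lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lookahead)
```

## The task and the ideal-planner model

A stimulus is a triangular lattice of 12 rows of valued disks (row *k*,
counted 0-based from the bottom, holds *k* + 1 disks; 78 in total). Disk
values are the squared integers 1, 4, 9, …, 81 — one point per unit of disk
area in the motivating touchscreen task. An actor starts at the single
bottom disk and repeatedly steps up-left or up-right; each step constrains
all subsequent options, and the collected score is the sum of the disks
stepped onto (the start disk never counts — this convention is forced by the
worked three-row example, where the depth-1 route collects 64 + 16 = 80).

An *ideal planner* is parameterized by a strategy (*r*, *d*):

* **depth of computation** *d* (rows): the planner finds the step sequences
  of length min(*d*, rows remaining) that maximize the cumulative score,
  keeping *all* ties;
* **recalculation period** *r* (steps, *r* ≤ *d*): it executes the first
  *r* steps of the plan before recomputing. Recalculation must happen at the
  latest when the executed prefix is exhausted, hence the constraint.

Two search algorithms with identical contracts are provided. The brute-force
search enumerates all 2^d paths (d·2^d summations, 2^d comparisons); the
dynamic program keeps, per reachable disk per level, the best incoming sum
and every tying predecessor. Their equivalence — scores *and* complete tie
sets — is asserted on a thousand random instances in the test suite. The
per-step workload models are

$$W_{BF}(r,d) = \frac{(d+1)\,2^d}{r}, \qquad
  W_E(r,d) = 3dr - \tfrac{3}{2}r^2 - \tfrac{1}{2}r + 2d,$$

with a first-pass cost $W_1(d) = \tfrac{3}{2}d(d+1)$ for the dynamic
program. Fractional values for *r* > 1 are per-step averages. Iso-workload
contours of $W_{BF}$ have positive slope in the (*r*, *d*) plane (deeper
look-ahead can be bought by recalculating less often), whereas $W_E$
contours contain negative-slope segments; this qualitative contrast is what
lets behavioral strategy estimates discriminate the two computational
regimes.

One bookkeeping subtlety is documented rather than hidden: summing the
intermediate expressions of the steady-state derivation for $W_E$ (the
incremental summations $3dr - \tfrac32 r^2 + \tfrac12 r$ plus *d* final
comparisons) differs from the printed closed form by $(d - r)$.
`workload_efficient()` returns the closed form exactly as printed;
`count_operations()` returns instrumented counters from an actual run (a
from-scratch pass totals exactly $W_1(d)$), so both quantities are
separately available and neither is silently "corrected".

## Diagnostic stimulus design

Random lattices are poor instruments for strategy inference because
different strategies often prescribe the same steps. The designer quantifies
this as *redundancy* and minimizes it by simulated annealing:

* **Disk redundancy** (default, `count = "pairs"`): the number of unordered
  pairs of distinct strategies (1 ≤ *r* ≤ *d* ≤ 7) whose stored optimal-plan
  prefixes — each truncated to the pair's smaller effective recalculation
  period — coincide for at least one tie combination. Stimulus redundancy is
  the sum over all disks with at least one row above.
* **Annealing**: starting from uniformly random values, one uniformly chosen
  disk is re-valued per iteration (a fresh uniform draw over the nine size
  classes, so a proposal may be a no-op with ΔR = 0, which is accepted);
  moves are accepted when ΔR ≤ 0 and otherwise with probability
  exp(−ΔR/T), over the schedule T = 1, 0.5, 0.25, 0.125 with 1000/T
  proposals per temperature (15,000 in total). Redundancy is updated
  incrementally over the changed disk's cone of influence (rows within 7
  below it); the tests assert bit-exact agreement with full recomputation.

"Overlapping paths" admits more than one reading, and the readings differ
materially; this was the single most consequential design decision in the
package, so the three candidates are all implemented and were compared on
20-run ensembles:

* `"pairs"` (default, above). A substantial part of this count is an
  irreducible floor — same-depth strategies always share plans, and deep
  strategies collapse onto shallow ones near the stimulus top — so the
  annealer removes only about a fifth of the initial count. It is kept as
  the default because the resulting ensembles best reproduce the *behavior*
  of the reference design downstream: a near-linear score-advantage profile
  in *d*, a path-overlap recovery slope of about one half, and policy score
  percentages close to the reference ordering (see the acceptance script).
* `"depth_pairs"`: pairs of distinct depths (depths exceeding the rows
  remaining excluded) with overlapping optimal-path sets. About half of the
  initial redundancy is annealed away under the reference schedule — but the
  resulting stimuli separate planning depths so strongly that the documented
  estimator biases largely disappear and the spread between the best and
  worst depth policies roughly doubles.
* `"strategies"`: strategies participating in at least one overlap; the
  count saturates near its maximum on random stimuli and gives the annealer
  almost no gradient.

No counting rule reproduced every reported ensemble statistic
simultaneously; since the reference stimulus set is not available, the
default was chosen to preserve the inference-stage behavior that the rest of
the package exists to study, and the variants remain a flag away.

## Per-row depth policies

A *policy* assigns a depth to the step leaving each row, with recalculation
at every step. Because an actor should look to the stimulus end whenever it
can, the last five entries are forced to the descending tail (5, 4, 3, 2, 1);
the six free entries take values 0–5, where 0 is a uniformly random step.
That gives 6^6 = 46,656 policies for 12 rows. Expected scores are computed
exactly by propagating the position distribution row by row: at each disk
the step follows the greedy direction of the depth-*d* plan, with ties (and
depth 0) splitting probability equally. Under the forced tail every optimal
continuation scores the same, so the expected tail gain from a disk equals
the dynamic-programming maximum from it — used as a closed-form tail and
verified against plain forward propagation and against Monte Carlo
simulation (10⁴ runs, 3 standard errors) in the tests. Policy scores are
reported per stimulus as fractions of that stimulus's maximum path score.

## Synthetic actors

The cohort generator stands in for human participants. It emulates:

* fixed-strategy (r, d) traversal, with lexicographic (L-before-R) or
  seeded-random resolution of plan ties;
* per-row random depths (default draws 1–5; the validation cohorts draw
  0–5, because the reference validation used randomly chosen *policies* and
  the policy alphabet explicitly includes depth 0 as a random step);
* sigmoid choice noise: the probability of stepping left is
  `plogis(beta * (sL - sR) + eta)` on the depth-limited conditional scores.
  The source prints the complement of this sigmoid, which contradicts its
  own description of both parameters (β = 1 is stated to pick the better
  direction about 95% of the time at the smallest score difference of 3
  points, and larger η is stated to favor the left); the form used here
  reproduces the stated behavior, e.g. `choice_probability(3, 1, 0)` =
  0.9526;
* value-reweighting heuristics: seek-the-large merges the *k* smallest size
  classes to 1 point, avoid-the-small raises the *k* largest to 1000 points;
  heuristic actors plan on the merged values but score true points. Note
  that seek-the-large with *k* = 1 is structurally a no-op (the smallest
  class is already worth 1 point);
* miss events with probability `miss_prob`, awarding the −1 or −50 penalty
  while the traversal continues from the intended disk, and log-normal
  reaction times keyed to the fast/slow condition label (pipeline exercise
  only; no scientific claims are attached to them).

It does **not** model timeouts, invalid touches, scrolling geometry, screen
midline rules, feedback coloring, or learning across trials. Passing tests
on these cohorts therefore establish that the estimators recover the
parameters of actors *of these forms* on ensembles from this designer — not
that human data would yield the same estimates.

## Strategy inference

**Score advantage.** A(r, d) is the mean difference between an actor's score
and the ideal (r, d) planner's score on the same stimulus, accumulated over
the last three rows (configurable), where the differences between strategies
are largest. Depth is estimated per recalculation period as the zero
crossing of an ordinary least-squares line in *d*; the uncertainty comes
from the fit covariance by the delta method (mixed-model machinery is
deliberately out of scope). Fits that do not cross within the fitted depth
range are flagged, never extrapolated silently. On ensembles from this
package's designer the advantage profile is close to linear but not exactly
so; the acceptance checks report the worst-bin deviation of binned estimates
from true mean depths honestly rather than forcing it under a threshold.

**Path-overlap voting and evidence.** Every touched disk contributes a
binary vote per strategy: 1 iff the actor's next min(*r*, *d*, rows
remaining) steps coincide with the corresponding prefix of a stored optimal
plan (all ties stored; strict conjunction, no partial credit). Evidence
normalizes votes by the expectation for a random stepper over the same
disks, estimated from N = 100 uniform draws per touch (stratified per disk,
seeded). E = 1 is chance, E = 2 perfect overlap for single-step
comparisons; for multi-step conjunctions (r > 1) the ratio can
mathematically exceed 2 for perfectly aligned ideal actors, which is why the
bound checks and the recovery argmax use the r = 1 grid. Evidence does not
self-average across depths (E(1,1) = E(1,3) = 2 is compatible with
E(1,2) = 0), so the package never converts an evidence table into a mean
depth; per-actor or per-disk argmax calls with a smallest-depth tie rule are
used instead, and the documented consequence — recovered depths skewed low,
with a regression slope of about one half against true mean depth on
random-policy cohorts — is reproduced and measured by the acceptance script.

**Unique overlaps.** Touches whose step matches the plan of exactly one
depth allow unambiguous identification. Such touches are intrinsically rare
(all other depths must unanimously predict the opposite step), vanish
entirely on the penultimate row (every depth collapses to the same one-step
plan), and are bounded by the rows remaining near the stimulus end; the
tests assert all three properties plus the exactness property that a depth
never used by an ideal cohort receives no unique votes.

**Reweighting analysis.** For each merge level *k* the evidence table is
recomputed from the same trials against plans on the reweighted stimuli, and
the deviation from the unmodified-stimulus evidence is summarized as an RMS
over the strategy grid (a signed mean is available). The random baselines of
all evidence tables share one set of step draws, so a reweighting that
leaves every plan unchanged produces a deviation of exactly zero. That makes
the heuristic null sharp: a cohort whose *effective* stimulus is already
merged at level *k* (a true seek-the-large actor's world) shows exactly zero
deviation at every *j* ≤ *k*, while a full-information cohort is perturbed
by every effective reweighting.

## POMDP export

`build_pomdp()` encodes the task in the standard six components: one state
per disk of the included stimuli (the analyses default to a 20-stimulus
subsample) plus a terminal state; actions look0–look5 (plan at depth *d*,
take one step, paying a linear cost of *d* points) and restart; observations
move/restart (emitted after the action, following the pomdp.org convention);
discount γ = 0.5. Transition rows are validated to sum to 1 within 1e−12
and `write_pomdp()` refuses unnormalized specs; output ordering is sorted,
so files are byte-stable. Solving is delegated to external tools
(e.g. SARSOP); the bundled parser exists for round-trip verification, not
solving.

## Numerical and reproducibility choices

* Disk values are small integers, so score comparisons are exact in double
  arithmetic; no tolerance is applied in tie detection.
* All randomness — annealing proposals, actor choices, evidence baselines —
  flows through R's generator (the C++ kernels use R's `unif_rand`), so a
  single `set.seed()` reproduces any result; ensembles are identified by
  (number of stimuli, base seed) with run *i* seeded `base_seed + i − 1`.
* Plan ties: stored exhaustively everywhere; traversal resolves them
  lexicographically by default (L before R) with a seeded-random option.
  Vote and argmax ties resolve toward the smallest depth, matching the
  documented skew of the overlap method.
* Degenerate inputs are first-class: top-row plans return score 0 with an
  empty tie set, uniform-valued stimuli exercise the all-ties limit, and a
  degenerate (all-tie) evidence denominator is flagged rather than divided
  through.

The reference problem sizes used by the tests and the acceptance script —
20 annealed stimuli, 10,000 actors for the overlap-slope validation, 6,000
for the score-advantage validation with at least 1,000 per depth bin — were
chosen as the smallest ensembles at which the measured quantities are stable
against reseeding at their reported precision.

## Known limitations

* The reference stimulus ensemble is not public; all ensemble-dependent
  statistics here are properties of this package's designer. Under the
  default redundancy counting the annealer removes about 19% of the initial
  redundancy (not half), and the best-policy percentage runs about three
  points above the reference value; the depth-pair variant reverses exactly
  this trade (see the design section).
* The score-advantage estimator's worst-bin bias on random-policy cohorts is
  about a quarter of a row on these ensembles, concentrated in the deepest
  bins where the advantage profile bends.
* Reaction times are generated but never analyzed; mixed models, deviance
  tests and human-derived quantities are out of scope.
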