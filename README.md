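# lookahead

Bounded-depth planning and strategy inference on branching reward lattices.

## The problem

In many natural tasks an agent makes a rapid sequence of binary choices in
which every step constrains the options available later: the number of
prospective futures grows as 2^d with the planning horizon d. `lookahead`
implements an analysis framework for such tasks built around a triangular
lattice of valued disks (1–81 points, the squared integers). An actor starts
at the bottom disk and steps upward, left or right, collecting the value of
every disk it lands on; the total reward depends on how far ahead the actor
evaluates cumulative scores before committing to a step.

An ideal planner is described by two parameters:

* **depth of computation** *d* — how many forthcoming rows it sums over
  before choosing, and
* **recalculation period** *r* — how many steps of the computed plan it
  executes before planning again (*r* ≤ *d*).

Exhaustively summing all paths to depth *d* every *r* steps costs

> W_BF(r, d) = (d + 1) 2^d / r

elementary operations per step, while the row-by-row dynamic program costs
only W_E(r, d) = 3dr − (3/2)r² − (1/2)r + 2d (first pass
W₁(d) = (3/2)d(d + 1)). Iso-workload contours of the two algorithms slope in
opposite directions in the (r, d) plane, which is what makes the pair (r, d)
inferable from behavior under resource limits.

The package provides, end to end:

* tie-preserving optimal path search (brute force and dynamic programming,
  instrumented with operation counters);
* a Metropolis annealer that designs **diagnostic stimuli** by minimizing
  *redundancy* — the number of strategy pairs predicting overlapping paths —
  over a temperature schedule 1, 0.5, 0.25, 0.125 with 1000/T proposals each;
* exhaustive enumeration and exact expected-score evaluation of all
  6^6 = 46,656 per-row depth **policies** (free depths 0–5, forced descending
  tail 5, 4, 3, 2, 1);
* **synthetic actor cohorts**: fixed-strategy, per-row random depth, sigmoid
  choice noise (P_L = plogis(β(s_L − s_R) + η)), value-reweighting heuristics
  (seek-the-large, avoid-the-small), miss events with −1/−50 penalties;
* **strategy inference** from trial logs: score advantage
  A(r, d) = S_actor − S_ideal(r, d) over the last three rows with
  zero-crossing depth estimation, path-overlap voting with normalized
  evidence E(r, d) = V_s/⟨V_R⟩ ∈ [0, 2], unique-overlap depth maps, and the
  reweighting (heuristic) analysis;
* export of the task as a POMDP in the pomdp.org file format for external
  solvers such as SARSOP.

## Worked example

The three-row introductory lattice (16 and 64 points on the second row; 81
and 16 on the reachable corners of the third):

```r
library(lookahead)
f <- fig1_stimulus()
print(f)
#> Stimulus 'fig1': 3 rows, 6 disks
#>   row  2: 81  9 16
#>   row  1: 16 64
#>   row  0: 1

simulate_actor(f, strategy(1, 1))   # greedy, one row at a time
#> depth-1 actor: R R -> 80 points
simulate_actor(f, strategy(1, 2))   # sees the 81 two rows up
#> depth-2 actor: L L -> 97 points
```

The short-sighted actor grabs the 64 and is then locked out of the 81,
finishing with 80 points; the two-row planner sacrifices 48 points on its
first step and finishes with 97. Designing a full-size diagnostic stimulus
and scoring the fixed maximum-look-ahead policy on it:

```r
design <- anneal_stimulus(seed = 1)           # 12 rows, 15,000 proposals
#> redundancy 23633 -> 19087 (19% lower), max score 442
policy_expected_fraction(design$stimulus, max_lookahead_policy())
#> Policy score: mean fraction 0.9548 over 1 stimuli (variance 0)
```

Always looking five rows ahead recovers only ~95% of this stimulus's maximum
score: the stimuli are designed so that no fixed habit is optimal everywhere.

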