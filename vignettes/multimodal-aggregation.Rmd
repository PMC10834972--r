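---
title: "Multimodal crowd-estimate aggregation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal crowd-estimate aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A crowd of participants is asked to order small subsets of a 30-image
universe by the number of dots each image contains, and to guess the count
in each image. Each participant `ℓ` thus supplies an ordinal ballot
`a^ℓ` (competition-style rank positions over their subset, position 1 =
fewest dots) and a numerical ballot `b^ℓ` (positive counts over the same
subset). The analysis goal is a collective strict ranking of all 30 images,
evaluated against a known ground truth. This vignette documents the models
implemented by `crowdrank`, the synthetic crowd the package generates to
exercise them, and every numerical or design choice that was genuinely open.

# Data model and conventions

* Rankings are named integer vectors in the **competition convention**:
  each position equals one plus the number of items ranked strictly ahead,
  so ties look like `(1, 1, 3)`. All the distances below depend only on the
  sign structure `sign(a_i - a_j)`, so any tie-preserving labeling is
  equivalent; one convention is fixed for reproducible serialization.
* Image identifiers are opaque strings; where a deterministic tie-break is
  needed (score ties, enumeration order) it is lexicographic in the id.
* `rank_of()` converts numerical values to this convention
  (`rank(x, ties.method = "min")`); `project_ranking()` restricts a ranking
  to a subset and re-compacts positions, preserving order and ties.

# Distance functions

For complete inputs over the same support:

* Kemeny–Snell: `d_KS = ½ Σ_i Σ_j |sign(a¹_i−a¹_j) − sign(a²_i−a²_j)|`.
  A strictly reversed pair contributes 2, a tie-versus-strict pair 1.
* Cook–Kress: `d_CK = ½ Σ_i Σ_j |(b¹_i−b¹_j) − (b²_i−b²_j)|`, invariant
  under adding a constant to either vector.

Incomplete inputs are projected onto the common support `c` and normalized:
`d_NPKS = d_KS / (c(c−1)/2)` and `d_NPCK = d_CK / (4R⌈c/2⌉⌊c/2⌋)`, both
defined as 0 when `c < 2`. The range `R = U − L` is computed **once per
aggregation instance** over all numerical inputs involved, not per ballot
pair ("the inputs" of an aggregation are instance-level).

Two deliberate asymmetries deserve note:

* **Evaluation metric vs. objective.** The collective-accuracy metric
  `d* = ground_truth_accuracy()` is defined as the *discordant-pair count*
  over `m(m−1)/2`, so its range is exactly `[0, 1]` (0 = sign-identical,
  1 = full reversal) and tie-versus-strict pairs are not penalized. The COA
  objective instead uses `d_NPKS`/`d_NPCK` exactly as written above — under
  which a full reversal of a strict ranking scores 2, since `d_KS` counts
  each discordant pair twice. Each convention is used where it is
  authoritative; conflating them would either break the `[0, 1]` claim for
  `d*` or change the optimization model.
* **Tie handling.** A tie-versus-strict pair counts 1 toward `d_KS` but 0
  toward the discordant-pair count; each follows its own definition.

The printed normalizers are kept as stated even though they are not tight
everywhere (`d_NPKS` can reach 2; for the extremal two-block construction
`d_NPCK` stays below ½). Rather than second-guess the intended scaling, the
COA model exposes `term_weights = (w_ord, w_card)` (both default 1) so the
relative weight of the two terms can be adjusted explicitly.

# Voting rules and their multimodal extension

`plurality_scores()`, `borda_scores()` and `copeland_scores()` accept
incomplete, tied ballots over a universe:

* plurality: one point per ballot to every alternative in position 1
  (co-first ties each score);
* Borda: a ballot of support size `m` gives `m − a_i` points to each ranked
  alternative. `m` is each ballot's **own** support size: within one
  aggregation instance all ballots share the task size, but heterogeneous
  profiles remain well defined and the per-ballot maximum stays `m − 1`;
* Copeland: pairwise wins minus defeats, ties and uncovered pairs 0.

Alternatives absent from a ballot receive nothing from it; the balanced
allocation design (below) keeps this fair. `scores_to_ranking()` orders by
non-increasing score with either `keep_ties` or deterministic lexicographic
`by_id` tie-breaking. `by_id` is the default for reproducible consensus
outputs; the evaluation sweeps use `keep_ties` because `d*` treats
tie-versus-strict pairs as non-discordant — breaking score ties arbitrarily
would add pure tie-break noise to the measured distance.

Numerical ballots are converted with `rank_of(b^ℓ)` and pooled with the
ordinal ballots: a coupled-estimate group of `g` participants yields `2g`
ballots; `aggregate_mixed_groups()` instead mixes the ordinal ballots of one
group with the converted numerical ballots of a disjoint group.

# The COA model

COA finds the numerical consensus `r` over the universe `V` minimizing
`Σ_ℓ d_NPCK(b^ℓ, r) + Σ_ℓ d_NPKS(a^ℓ, rank(r))`.

**Strictness.** The consensus ranking is restricted to strict orderings via
an epsilon-separation constant (`epsilon = 1` by default — the dot-count
granularity). Nothing in the model definition produces consensus ties
naturally ("rank(r) is induced by ordering the numerical values in r"), and
strictness keeps `d*` well defined.

**Mixed-integer formulation** (`solve_coa()`): binary `x_ij` per unordered
pair (`x_ij = 1` ⇔ `r_i < r_j`), transitivity
`0 ≤ x_ij + x_jk − x_ik ≤ 1` on ordered triples; continuous
`r_i ∈ [L, U]` (the instance input range) linked by
`r_j − r_i ≥ ε − M(1 − x_ij)` and `r_i − r_j ≥ ε − M·x_ij` with
`M = (U − L) + ε`, the tightest valid constant given the bounds. The
cardinal term is linearized with auxiliaries
`z ≥ ±((b_i − b_j) − (r_i − r_j))` weighted `1/(4R⌈m⁄2⌉⌊m⁄2⌋)` per ballot
pair; the ordinal term is linear in `x` with weight `2/(m(m−1)/2)` per
disagreeing strict pair and a constant `1/(m(m−1)/2)` for each ballot-tied
pair (a strict consensus always disagrees with a tie by exactly 1). These
weights are exactly those induced by the printed distance definitions.

**Backend.** The environment provides no R MIP solver, so the model is
handed to HiGHS through `scipy.optimize` (`milp`/`linprog`) in a `python`
subprocess with JSON round-tripping — a thin, swappable interface; any
branch-and-bound solver with incumbent/bound reporting qualifies. The
default per-instance time limit is 600 s; at the limit the incumbent is
returned with its optimality gap `(incumbent − bound)/incumbent`. The
relative MIP gap tolerance is `1e-9` so that "optimal" solves agree with
the exhaustive oracle to well below the `1e-6` acceptance tolerance.

**Exhaustive oracle** (`brute_force_coa()`, universes of ≤ 7 images):
enumerates all strict orderings lexicographically; the ordinal term is a
constant per ordering and the cardinal term is an inner LP over values
monotone along the ordering (ε-separated, bounded in `[L, U]`). Ties
between orderings are resolved to the first optimum in enumeration order.
The test suite also checks this oracle against a third, independent check:
with integer estimates, integer bounds and `ε = 1`, the inner LP's
constraint matrix is a network (difference) matrix, so an integer-valued
optimal consensus exists and exhaustive search over distinct-integer grids
is exact.

# The synthetic crowd

The generator reproduces the study design that the analyses assume:

* **Universe**: 30 images with distinct integer counts, by default exactly
  the integers 50..79 assigned to images at random; one universe per task
  size.
* **Allocation** (`allocate_tasks()`): the permutation-partition scheme —
  permute 1..30, cut into consecutive subsets of the task size
  (2/3/5/6 all divide 30), repeat with fresh permutations as needed. With
  `g` participants each image is viewed `g·m/30` times whenever that is
  integral; a partial final block leaves view counts within 1.
* **Perception noise**: numerosity perception is approximately
  scale-invariant, so noise is multiplicative log-normal (Weber-like):
  ordering follows latent percepts `c_i · exp(σ_ord ε_i)` and guesses are
  `round(c_i · exp(σ_num ε'_i))` clipped to ≥ 1. Defaults
  `σ_ord = 0.10, σ_num = 0.15`: with counts 50–79 adjacent images differ by
  ~1.5 %, so these values produce the qualitative regime of the human data
  — individuals mostly correct on easy pairs, frequently wrong on adjacent
  ones, and median self-consistency well below 1. No quantitative human
  noise level is stated anywhere, so these are calibrated to qualitative
  directions only and are not revisited per experiment.
* **Elicitation conditions**: under `independent`, `ε'` is independent of
  `ε`. Under `joint`, with probability `consistency_lambda = 0.8` the
  numerical values are re-sorted to match the submitted ordering (value
  multiset preserved). This models anchoring on one's own visible ordering:
  it raises ordinal/numerical self-consistency without changing the
  marginal numerical error, which is exactly the observed signature of
  joint elicitation (less self-contradiction, worse collective accuracy,
  because the second modality no longer provides an independent error
  draw).

**What a green test does and does not establish.** The simulator reproduces
the *directions* of the empirical findings — higher self-consistency under
joint elicitation, lower collective `d*` under independent elicitation,
`d*` shrinking with group size — not the study's printed medians, which
depend on unknowable human noise parameters. One empirical direction is
*not* reproduced, deliberately: the finding that a coupled-estimate group
beats separate-estimate groups of the same total ballot count. Under the
independent-error model a coupled group (its 2g ballots concentrated on g
subsets) has, if anything, slightly *less* diverse pairwise coverage than
two separate groups (2g distinct subsets), and simulation confirms coupled
≈ separate with a small deficit. The study attributes its coupled advantage
to within-person ("inner crowd") effects; the obvious way to add
within-person structure — a shared latent percept for both modalities —
would make the two ballots redundant and coupled strictly worse, so no such
mechanism is invented. The corresponding acceptance check is left failing
with this analysis rather than met by construction.

Also not modeled: completion times (the interquartile-range outlier filter
is provided as a stand-alone utility for optional timing columns),
participant demographics, and dot-image rendering.

# Evaluation pipelines

* `self_consistency()`: Kendall, Spearman and Pearson between `a^ℓ` and
  `rank_of(b^ℓ)`. The Kendall variant is tau-b (tie-adjusted), since
  converted numerical ballots tie frequently; Pearson is computed on the
  rank vectors (that is what is being compared). Zero-variance vectors give
  `NA`, excluded from medians — relevant for 2-image tasks, where the
  coefficient is only ever ±1 or undefined.
* `individual_error_distribution()`: per-participant discordant pairs
  against the truth projected to their subset, binned `0..m(m−1)/2`;
  percentages sum to 100 per task size.
* `group_size_sweep()`: the subsetting scheme behind group-size curves is
  not stated in the source analyses, so it is randomized with replicates
  (default 20) and median/min/max are reported. Subsets are drawn as whole
  allocation blocks first (preserving balanced coverage) plus a random
  remainder. COA participates with its 600 s default limit; test-suite
  sweeps keep universes ≤ 7 images so the exact path is used — full
  30-image COA sweeps are supported but can take the documented 10 minutes
  per instance.
* `coupled_vs_separate()`: fresh simulated pool per replicate; multimodal
  Borda for both designs (the computationally easy rule with the best
  sweep performance).
* `iqr_outlier_filter()`: fences at `Q1 − 1.5·IQR`, `Q3 + 1.5·IQR` with
  linear-interpolation quartiles (R's default `type = 7`); flags are
  affine-invariant.
* `run_pipeline()` chains simulate/load → validate → consistency → error
  histograms → sweep (→ coupled-vs-separate) and writes CSVs plus a JSON
  summary; outputs are byte-identical for identical seeds.

# Degenerate inputs and numerical choices

* Ballots of support 1 are legal; both normalized distances return 0 for
  them, and they contribute nothing to COA.
* `npck` with zero range and a nonzero distance errors (undefined
  normalization) rather than returning an arbitrary value.
* A universe of `n` images requires `(n−1)·ε ≤ U − L` for a feasible strict
  consensus; with the default universe (range 29, ε = 1) this is exactly
  tight, pinning consensus values to unit spacing.
* Oracle/MIP agreement tolerance is `1e-6`; solver determinism is down to
  HiGHS, which is deterministic for a fixed problem, so equal seeds give
  equal pipelines end to end.
* All randomness flows through explicit seeds (`withr::with_seed`), leaving
  the caller's RNG state untouched.

# Known limitations

* The MIP path requires an external `python`/`scipy` at run time; without
  it every voting-rule analysis still works, and `brute_force_coa` errors
  only when it needs the LP backend (instances with cardinal ballots).
* The simulator's noise parameters are a stated world, not a fit; matching
  the study's printed medians would require the deposited human data.
* No alternative distances (footrule, Cayley), no further voting rules
  (STV, Schulze), no heuristic COA solvers, and no polyhedral analysis of
  the formulation.
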