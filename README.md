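# crowdrank

Aggregation of multimodal crowd estimates on ordering tasks.

Crowdsourced ordering studies ask many participants to rank a small subset
of alternatives — here, images ranked by how many dots they contain — and,
optionally, to also guess the underlying quantity for each alternative.
Every participant therefore contributes two logically related estimates over
their subset: an **ordinal** ballot `a` (a ranking, position 1 = fewest
dots) and a **numerical** ballot `b` (a dot-count guess per image).
`crowdrank` is for researchers studying wisdom-of-crowds effects on such
tasks: it implements the distance functions, voting rules and the
cardinal-and-ordinal aggregation (COA) optimization model needed to turn
hundreds of partial, noisy, mutually contradictory ballots into one
collective ranking of the full image universe, plus a synthetic crowd
generator and evaluation pipelines so every stage can be exercised without
any human dataset.

## The models

**Distances.** For complete tied rankings the Kemeny–Snell distance is the
halved sign double sum
`d_KS(a¹, a²) = ½ Σᵢ Σⱼ |sign(a¹ᵢ − a¹ⱼ) − sign(a²ᵢ − a²ⱼ)|`,
and for complete numerical vectors the Cook–Kress distance is
`d_CK(b¹, b²) = ½ Σᵢ Σⱼ |(b¹ᵢ − b¹ⱼ) − (b²ᵢ − b²ⱼ)|`.
Incomplete inputs are first projected onto their common support `c` of
alternatives and normalized: `d_NPKS = d_KS / (c(c−1)/2)` and
`d_NPCK = d_CK / (4R⌈c/2⌉⌊c/2⌋)`, where `R = U − L` is the range of the
numerical inputs; both are 0 when fewer than two alternatives are shared.

**COA.** The consensus is the numerical vector `r` over the universe `V`
(with induced strict ranking `rank(r)`) minimizing

```
min_r  Σ_ℓ d_NPCK(b^ℓ, r) + Σ_ℓ d_NPKS(a^ℓ, rank(r))
```

an NP-hard problem solved here both exactly (exhaustive ordering enumeration
with an inner linear program, `brute_force_coa()`) and as an anytime
mixed-integer program with binary precedence variables, transitivity
constraints, big-M linking and optimality-gap reporting (`solve_coa()`,
default 10-minute time limit).

**Voting.** Plurality, Borda and Copeland scores on (incomplete, tied)
ballots; numerical ballots enter by conversion to `rank(b)`, so a coupled
group of `g` participants contributes `2g` ballots
(`aggregate_multimodal()`), and separate groups can mix one modality each
(`aggregate_mixed_groups()`).

Collective accuracy is `d* ∈ [0, 1]`: discordant pairs against the true
ordering divided by the maximum `m(m−1)/2`.

## Worked example

```r
library(crowdrank)

cfg <- simulation_config(n_participants = 150, task_size = 5, seed = 42,
                         noise = noise_profile("independent"))
ds <- simulate_crowd(cfg)
#> <crowd_dataset> 150 participants, task size 5, 30 images

round(consistency_medians(self_consistency(ds)), 3)
#>  kendall spearman  pearson
#>    0.487    0.608    0.600

est <- aggregate_multimodal(ds$records, universe = ds$universe$alternatives,
                            rule = "borda", tie_break = "keep_ties")
ground_truth_accuracy(est, truth_ranking(ds$universe))
#> [1] 0.03678161

group_size_sweep(ds, c("borda", "copeland"), c(30, 75, 150),
                 replicates = 10, seed = 7)
#>     method group_size     median        min        max
#> 1    borda         30 0.10344828 0.07126437 0.13103448
#> 2 copeland         30 0.10919540 0.07586207 0.14482759
#> 3    borda         75 0.07356322 0.04137931 0.10804598
#> 4 copeland         75 0.07586207 0.05517241 0.08965517
#> 5    borda        150 0.03678161 0.03678161 0.03678161
#> 6 copeland        150 0.03678161 0.03678161 0.03678161
```

The median Kendall tau of ~0.49 says individual participants contradict
their own numerical guesses noticeably; the sweep shows the
wisdom-of-crowds effect — the collective ranking's normalized distance to
the truth (`d*`) falls from ~0.10 at 30 participants to ~0.037 when all 150
are aggregated (0 would be a perfect ordering of all 30 images).

A tiny COA consensus (exact path):

```r
r1 <- participant_record("p1", "independent", 3,
        ordinal_ballot("p1", c(A = 1L, B = 2L, C = 3L)),
        numerical_ballot("p1", c(A = 52, B = 61, C = 70)))
r2 <- participant_record("p2", "independent", 3,
        ordinal_ballot("p2", c(A = 2L, B = 1L, C = 3L)),
        numerical_ballot("p2", c(A = 58, B = 55, C = 72)))
coa_consensus(list(r1, r2), exact = TRUE)
#> <coa_solution> status = optimal objective = 0.816667 gap = 0
#>   consensus: A < B < C
```

## Command line

```sh
inst/cli/crowdrank simulate --participants 300 --task-size 5 \
    --condition independent --seed 7 --out data/
inst/cli/crowdrank aggregate --rule borda --in data/ --out consensus.csv
inst/cli/crowdrank run --participants 300 --task-size 5 --seed 7 --out out/
```

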