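# Independent score oracle: literal per-ballot formulas, no shared code
# with the implementation.
oracle_scores <- function(ballots, universe, rule) {
  s <- stats::setNames(numeric(length(universe)), universe)
  for (b in ballots) {
    if (rule == "plurality") {
      for (i in names(b)) if (b[[i]] == 1L) s[i] <- s[i] + 1
    } else if (rule == "borda") {
      for (i in names(b)) s[i] <- s[i] + (length(b) - b[[i]])
    } else {
      for (i in names(b)) for (j in names(b)) {
        if (i != j) {
          if (b[[i]] < b[[j]]) s[i] <- s[i] + 1
          if (b[[i]] > b[[j]]) s[i] <- s[i] - 1
        }
      }
    }
  }
  s
}

test_that("plurality counts (possibly tied) first places", {
  uni <- c("A", "B", "C")
  ballots <- list(c(A = 1L, B = 2L, C = 3L),
                  c(A = 1L, C = 2L, B = 3L),
                  c(B = 1L, A = 2L, C = 3L))
  expect_equal(plurality_scores(ballots, uni)$scores,
               c(A = 2, B = 1, C = 0))
  expect_equal(plurality_scores(list(c(A = 1L, B = 1L, C = 3L)), uni)$scores,
               c(A = 1, B = 1, C = 0))
  expect_error(plurality_scores(list(), uni), "empty")
})

test_that("borda uses each ballot's own support size", {
  uni <- c("A", "B", "C")
  expect_equal(borda_scores(list(c(A = 1L, B = 2L, C = 3L)), uni)$scores,
               c(A = 2, B = 1, C = 0))
  b <- list(c(A = 1L, B = 2L, C = 3L), c(A = 1L, B = 2L, C = 3L))
  expect_equal(borda_scores(b, uni)$scores, c(A = 4, B = 2, C = 0))
  # heterogeneous sizes: m = 3 ballot and m = 2 ballot
  h <- list(c(A = 1L, B = 2L, C = 3L), c(C = 1L, A = 2L))
  expect_equal(borda_scores(h, uni)$scores,
               c(A = 2 + 0, B = 1, C = 0 + 1))
})

test_that("copeland scores pairwise wins minus defeats", {
  uni <- c("A", "B", "C")
  expect_equal(copeland_scores(list(c(A = 1L, B = 2L, C = 3L)), uni)$scores,
               c(A = 2, B = 0, C = -2))
  opposed <- list(c(A = 1L, B = 2L, C = 3L), c(A = 3L, B = 2L, C = 1L))
  expect_equal(copeland_scores(opposed, uni)$scores, c(A = 0, B = 0, C = 0))
  # ties contribute 0
  expect_equal(copeland_scores(list(c(A = 1L, B = 1L, C = 3L)), uni)$scores,
               c(A = 1, B = 1, C = -2))
})

test_that("all three rules match the literal score oracle on random profiles", {
  set.seed(51)
  uni <- paste0("i", 1:6)
  for (k in 1:15) {
    ballots <- lapply(1:5, function(p) {
      sub <- sort(sample(uni, sample(2:6, 1)))
      rank_of(stats::setNames(sample.int(4, length(sub), replace = TRUE), sub))
    })
    for (rule in c("plurality", "borda", "copeland")) {
      fn <- switch(rule, plurality = plurality_scores,
                   borda = borda_scores, copeland = copeland_scores)
      expect_equal(fn(ballots, uni)$scores,
                   oracle_scores(ballots, uni, rule))
    }
  }
})

test_that("voting rules are neutral, additive and unanimous", {
  set.seed(52)
  uni <- paste0("i", 1:5)
  ballots <- lapply(1:6, function(p) random_strict_ranking(5, uni))
  relabel <- stats::setNames(paste0("j", 5:1), uni)
  for (fn in list(plurality_scores, borda_scores, copeland_scores)) {
    base <- fn(ballots, uni)$scores
    # neutrality: relabeling ids permutes scores
    perm_ballots <- lapply(ballots, function(b)
      stats::setNames(b, relabel[names(b)]))
    permuted <- fn(perm_ballots, unname(relabel[uni]))$scores
    expect_equal(unname(permuted[relabel[uni]]), unname(base))
    # additivity over concatenated profiles
    expect_equal(fn(c(ballots, ballots), uni)$scores, 2 * base)
  }
  # unanimity: identical strict ballots are returned as the consensus by
  # Borda and Copeland; plurality only scores first places, so unanimity
  # holds at the winner level
  one <- random_strict_ranking(5, uni)
  for (fn in list(borda_scores, copeland_scores)) {
    expect_equal(scores_to_ranking(fn(rep(list(one), 4), uni), "by_id"),
                 one[uni])
  }
  plu <- scores_to_ranking(plurality_scores(rep(list(one), 4), uni), "by_id")
  expect_equal(names(plu)[plu == 1L], names(one)[one == 1L])
})

test_that("borda ranking equals the mean-rank ranking on complete strict profiles", {
  set.seed(53)
  uni <- paste0("i", 1:6)
  for (k in 1:10) {
    ballots <- lapply(1:7, function(p) random_strict_ranking(6, uni))
    borda <- scores_to_ranking(borda_scores(ballots, uni), "keep_ties")
    mean_rank <- rank_of(colMeans(do.call(rbind,
                                          lapply(ballots, function(b) b[uni]))))
    expect_equal(borda, mean_rank)
  }
})

test_that("scores_to_ranking orders by non-increasing score with both tie modes", {
  s <- c(A = 2, B = 1, C = 0)
  expect_equal(scores_to_ranking(s, "by_id"), c(A = 1L, B = 2L, C = 3L))
  eq <- c(B = 1, A = 1, C = 1)
  expect_equal(scores_to_ranking(eq, "keep_ties"),
               c(B = 1L, A = 1L, C = 1L))
  expect_equal(sort(names(sort(scores_to_ranking(eq, "by_id")))),
               c("A", "B", "C"))
  expect_equal(scores_to_ranking(eq, "by_id")[["A"]], 1L)
})

test_that("aggregate_multimodal pools a and rank(b) per participant", {
  est <- c(A = 50, B = 60, C = 70)
  recs <- lapply(1:3, function(k) consistent_record(paste0("p", k), est))
  # fully consistent records: result equals the shared ordering, scores doubled
  agg <- aggregate_multimodal(recs, rule = "borda")
  expect_equal(agg, c(A = 1L, B = 2L, C = 3L))
  ballots <- c(lapply(recs, function(r) r$ordinal$positions),
               lapply(recs, function(r) rank_of(r$numerical$estimates)))
  expect_equal(borda_scores(ballots, c("A", "B", "C"))$scores,
               2 * borda_scores(lapply(recs, function(r) r$ordinal$positions),
                                c("A", "B", "C"))$scores)

  # mixed fixture vs exhaustive oracle over the 2|records| ballots
  set.seed(54)
  uni <- paste0("i", 1:4)
  recs2 <- lapply(1:3, function(k) {
    sub <- sort(sample(uni, 3))
    make_record(paste0("q", k),
                random_strict_ranking(3, sub),
                stats::setNames(sample(50:79, 3), sub))
  })
  ball2 <- c(lapply(recs2, function(r) r$ordinal$positions),
             lapply(recs2, function(r) rank_of(r$numerical$estimates)))
  for (rule in c("plurality", "borda", "copeland")) {
    expect_equal(aggregate_multimodal(recs2, universe = uni, rule = rule),
                 scores_to_ranking(oracle_scores(ball2, uni, rule), "by_id"))
  }
  expect_error(aggregate_multimodal(list()), "empty")
})

test_that("aggregate_mixed_groups needs disjoint groups and matches the oracle", {
  est <- c(A = 50, B = 60, C = 70)
  g1 <- list(consistent_record("p1", est))
  g2 <- list(consistent_record("p2", est))
  expect_equal(aggregate_mixed_groups(g1, g2, rule = "borda"),
               c(A = 1L, B = 2L, C = 3L))
  expect_error(aggregate_mixed_groups(g1, g1), "overlap")

  # identical ballot multiset as coupled aggregation when the groups clone
  # each other's estimates
  set.seed(55)
  uni <- paste0("i", 1:4)
  recsA <- lapply(1:3, function(k) {
    sub <- sort(sample(uni, 3))
    make_record(paste0("a", k), random_strict_ranking(3, sub),
                stats::setNames(sample(50:79, 3), sub))
  })
  recsB <- lapply(recsA, function(r)
    make_record(paste0("b_", r$participant_id), r$ordinal$positions,
                r$numerical$estimates))
  coupled <- aggregate_multimodal(recsA, universe = uni, rule = "borda")
  separate <- aggregate_mixed_groups(recsA, recsB, universe = uni,
                                     rule = "borda")
  expect_equal(separate, coupled)
})
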