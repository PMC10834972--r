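# Shared fixtures and independent oracles used across test files.

# random strict ranking over m named items
random_strict_ranking <- function(m, ids = paste0("i", seq_len(m))) {
  stats::setNames(sample.int(m), ids)
}

# random tied ranking: draw values with repeats, competition-rank them
random_tied_ranking <- function(m, ids = paste0("i", seq_len(m))) {
  rank_of(stats::setNames(sample.int(max(2L, m - 1L), m, replace = TRUE), ids))
}

# independent discordance oracle: count unordered strictly-reversed pairs
# by explicit double loop (no sign-matrix tricks)
oracle_discordant <- function(a1, a2) {
  a2 <- a2[names(a1)]
  ids <- names(a1)
  cnt <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      d1 <- a1[[i]] - a1[[j]]; d2 <- a2[[i]] - a2[[j]]
      if ((d1 < 0 && d2 > 0) || (d1 > 0 && d2 < 0)) cnt <- cnt + 1L
    }
  }
  cnt
}

# halved sign double-sum evaluated literally
oracle_kemeny <- function(a1, a2) {
  a2 <- a2[names(a1)]
  tot <- 0
  for (i in seq_along(a1)) for (j in seq_along(a1))
    tot <- tot + abs(sign(a1[[i]] - a1[[j]]) - sign(a2[[i]] - a2[[j]]))
  tot / 2
}

# literal Cook-Kress double sum
oracle_cook_kress <- function(b1, b2) {
  b2 <- b2[names(b1)]
  tot <- 0
  for (i in seq_along(b1)) for (j in seq_along(b1))
    tot <- tot + abs((b1[[i]] - b1[[j]]) - (b2[[i]] - b2[[j]]))
  tot / 2
}

# fully consistent participant: ordinal ballot agrees with numerical ballot
consistent_record <- function(id, estimates, condition = "independent") {
  numerical <- numerical_ballot(id, estimates)
  participant_record(id, condition, length(estimates),
                     ordinal_ballot(id, rank_of(estimates)),
                     numerical)
}

# record with explicit positions and estimates
make_record <- function(id, positions, estimates,
                        condition = "independent") {
  participant_record(id, condition, length(positions),
                     ordinal_ballot(id, positions),
                     numerical_ballot(id, estimates))
}

# small random COA instance over n_img images with wide-range estimates
random_coa_instance <- function(n_img, n_participants, epsilon = 1) {
  ids <- paste0("i", seq_len(n_img))
  ords <- list(); nums <- list()
  for (p in seq_len(n_participants)) {
    m <- sample(2:n_img, 1L)
    sub <- sort(sample(ids, m))
    est <- stats::setNames(sample(40:90, m), sub)
    # ordinal ballot noisy and occasionally tied
    latent <- est * exp(0.2 * stats::rnorm(m))
    pos <- if (stats::runif(1) < 0.2)
      rank_of(stats::setNames(round(latent / 10), sub))
    else rank_of(stats::setNames(latent, sub))
    ords[[p]] <- ordinal_ballot(paste0("p", p), pos)
    nums[[p]] <- numerical_ballot(paste0("p", p), est)
  }
  # make sure the estimate range can hold n_img separated values
  nums[[1]]$estimates[1] <- 40
  nums[[length(nums)]]$estimates[
    length(nums[[length(nums)]]$estimates)] <- 90
  coa_instance(ids, ords, nums, epsilon = epsilon)
}

# zero-noise simulation config for deterministic datasets
perfect_config <- function(n = 30L, task_size = 5L, seed = 1L,
                           condition = "independent") {
  simulation_config(
    n_participants = n, task_size = task_size, seed = seed,
    noise = noise_profile(condition, sigma_ordinal = 0,
                          sigma_numerical = 0))
}
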