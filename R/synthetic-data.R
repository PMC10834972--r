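# Synthetic crowd generator.  Emulates the dot-ordering study design: a
# 30-image universe with distinct integer dot counts in [50, 79],
# permutation-partition task allocation (subsets of size 2/3/5/6 that tile
# the universe block by block), and participants whose percepts carry
# multiplicative log-normal (Weber-like) noise.  Two elicitation conditions
# are emulated: "independent" draws the ordinal and numerical errors
# independently, while "joint" re-sorts the numerical draws to match the
# submitted ordering with probability consistency_lambda, which raises
# ordinal/numerical self-consistency without changing the marginal numerical
# error.

#' Noise profile of a simulated participant population
#'
#' @param condition `"joint"` or `"independent"` elicitation interface.
#' @param sigma_ordinal log-scale standard deviation of the perception noise
#'   driving the ordering task (default 0.10).
#' @param sigma_numerical log-scale standard deviation of the numerical
#'   guesses (default 0.15).
#' @param consistency_lambda probability, under the joint interface, that a
#'   participant's numerical values are re-sorted to match their submitted
#'   ordering (default 0.8; ignored under `"independent"`).
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(condition = c("independent", "joint"),
                          sigma_ordinal = 0.10, sigma_numerical = 0.15,
                          consistency_lambda = 0.8) {
  condition <- match.arg(condition)
  stopifnot(sigma_ordinal >= 0, sigma_numerical >= 0,
            consistency_lambda >= 0, consistency_lambda <= 1)
  structure(list(condition = condition,
                 sigma_ordinal = sigma_ordinal,
                 sigma_numerical = sigma_numerical,
                 consistency_lambda = consistency_lambda),
            class = "noise_profile")
}

#' Simulation configuration
#'
#' @param n_participants number of simulated participants (default 300, the
#'   per-condition group size of the study design).
#' @param task_size images per participant subset; one of 2, 3, 5, 6.
#' @param n_images universe size (default 30).
#' @param count_min,count_max inclusive dot-count range (defaults 50 and 79;
#'   with the default universe size every integer in the range is used).
#' @param noise a [noise_profile()].
#' @param seed integer seed driving the whole dataset.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 300L, task_size = 5L,
                              n_images = 30L, count_min = 50L,
                              count_max = 79L,
                              noise = noise_profile("independent"),
                              seed = 1L) {
  stopifnot(inherits(noise, "noise_profile"))
  if (count_max - count_min + 1L < n_images)
    stop("simulation_config: count range cannot hold ", n_images,
         " distinct integers")
  if (n_images %% task_size != 0L)
    stop("simulation_config: task_size must divide n_images")
  structure(list(n_participants = as.integer(n_participants),
                 task_size = as.integer(task_size),
                 n_images = as.integer(n_images),
                 count_min = as.integer(count_min),
                 count_max = as.integer(count_max),
                 noise = noise, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate an image universe
#'
#' Draws `n_images` distinct integer dot counts from
#' `[count_min, count_max]` and assigns them to opaque image identifiers.
#' With the defaults the counts are exactly the integers 50..79 in a random
#' assignment to images.
#'
#' @param n_images,count_min,count_max see [simulation_config()].
#' @param seed optional integer; when given, the draw is deterministic and
#'   leaves the global RNG untouched.
#' @return A [universe()].
#' @export
make_universe <- function(n_images = 30L, count_min = 50L, count_max = 79L,
                          seed = NULL) {
  if (count_max - count_min + 1L < n_images)
    stop("make_universe: count range cannot hold ", n_images,
         " distinct integers")
  draw <- function() {
    counts <- sample(seq.int(count_min, count_max), n_images)
    universe(sprintf("img%02d", seq_len(n_images)), as.integer(counts))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Permutation-partition task allocation
#'
#' Image subsets are generated block by block: the integers `1..n_images`
#' are randomly permuted and the first `task_size` of them assigned to the
#' first participant of the block, the next `task_size` to the second, and
#' so on until the permutation is exhausted; a fresh permutation starts the
#' next block.  Whenever `n_participants * task_size` is divisible by
#' `n_images`, every image is therefore viewed exactly
#' `n_participants * task_size / n_images` times; a partial final block
#' leaves view counts differing by at most one.
#'
#' @param n_participants number of subsets to allocate.
#' @param task_size images per subset; must divide `n_images`.
#' @param n_images universe size.
#' @param seed optional integer for a deterministic draw.
#' @return An object of class `allocation_plan` with `assignments` (list of
#'   integer index vectors into the universe), `task_size`, `n_images`,
#'   `seed`.
#' @export
allocate_tasks <- function(n_participants, task_size, n_images = 30L,
                           seed = NULL) {
  if (n_images %% task_size != 0L)
    stop("allocate_tasks: task_size must divide n_images")
  draw <- function() {
    per_block <- n_images %/% task_size
    n_blocks <- ceiling(n_participants / per_block)
    assignments <- vector("list", n_participants)
    p <- 0L
    for (blk in seq_len(n_blocks)) {
      perm <- sample.int(n_images)
      for (s in seq_len(per_block)) {
        p <- p + 1L
        if (p > n_participants) break
        assignments[[p]] <- perm[((s - 1L) * task_size + 1L):(s * task_size)]
      }
    }
    assignments
  }
  assignments <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(assignments = assignments,
                 task_size = as.integer(task_size),
                 n_images = as.integer(n_images), seed = seed),
            class = "allocation_plan")
}

#' Per-image view counts of an allocation plan
#'
#' @param plan an [allocate_tasks()] result.
#' @return Integer vector of length `n_images`: how many subsets contain
#'   each image.
#' @export
view_counts <- function(plan) {
  stopifnot(inherits(plan, "allocation_plan"))
  tabulate(unlist(plan$assignments), nbins = plan$n_images)
}

#' Simulate one participant
#'
#' The ordering is the ranking of latent percepts
#' `q_i = c_i * exp(sigma_ordinal * e_i)` with `e_i` iid standard normal
#' (ties, possible only at `sigma_ordinal = 0` on distinct counts, are
#' broken as by infinitesimal jitter, so the submitted ordering is strict).
#' The numerical guesses are `round(c_i * exp(sigma_numerical * e'_i))`
#' clipped to at least 1, with `e'` independent of `e`.  Under the joint
#' condition, with probability `consistency_lambda` the guessed values are
#' re-sorted so their order matches the submitted ordering (the value
#' multiset is preserved).
#'
#' Uses the current global RNG stream; seed at the crowd level.
#'
#' @param universe a [universe()].
#' @param subset character vector of image ids in the universe.
#' @param profile a [noise_profile()].
#' @param participant_id identifier for the resulting record.
#' @return A [participant_record()].
#' @export
simulate_participant <- function(universe, subset, profile,
                                 participant_id = "p1") {
  stopifnot(inherits(universe, "universe"), inherits(profile, "noise_profile"))
  subset <- as.character(subset)
  if (!all(subset %in% universe$alternatives))
    stop("simulate_participant: subset outside the universe")
  counts <- universe$true_counts[subset]
  m <- length(subset)

  q <- counts * exp(profile$sigma_ordinal * stats::rnorm(m))
  positions <- stats::setNames(as.integer(rank(q, ties.method = "first")),
                               subset)

  b <- pmax(1, round(counts * exp(profile$sigma_numerical * stats::rnorm(m))))
  if (profile$condition == "joint" &&
      stats::runif(1) < profile$consistency_lambda) {
    b <- stats::setNames(sort(as.numeric(b))[positions], subset)
  }
  participant_record(participant_id, profile$condition, m,
                     ordinal_ballot(participant_id, positions),
                     numerical_ballot(participant_id,
                                      stats::setNames(as.numeric(b), subset)))
}

#' Simulate a full crowd dataset
#'
#' Draws the universe, the allocation plan and every participant from a
#' single seeded RNG stream, so the whole dataset is reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A [crowd_dataset()] that passes [validate_dataset()].
#' @export
simulate_crowd <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    uni <- make_universe(config$n_images, config$count_min, config$count_max)
    plan <- allocate_tasks(config$n_participants, config$task_size,
                           config$n_images)
    records <- lapply(seq_len(config$n_participants), function(p) {
      subset <- uni$alternatives[plan$assignments[[p]]]
      simulate_participant(uni, subset, config$noise,
                           participant_id = sprintf("p%04d", p))
    })
    crowd_dataset(uni, records, config$task_size)
  })
}
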