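# Evaluation pipelines: per-participant self-consistency between the two
# estimate modalities, individual error distributions against the ground
# truth, group-size accuracy sweeps across aggregation methods, and the
# coupled- versus separate-estimate-group comparison.  The collective
# accuracy metric throughout is d* = ground_truth_accuracy: the normalized
# discordant-pair distance (in [0,1]) between a collective ranking and the
# true ordering of the universe.

#' Per-participant self-consistency of the two estimate modalities
#'
#' For every record, computes the Kendall (tau-b), Spearman and Pearson
#' correlation coefficients between the ordinal ballot `a` and the converted
#' numerical ballot `rank_of(b)` on the participant's support.  Coefficients
#' are undefined (NA) when either vector has zero variance, e.g. an all-tied
#' converted ballot; NA values are excluded from the medians.
#'
#' @param dataset a [crowd_dataset()].
#' @return A data.frame of class `consistency_table` with one row per
#'   participant (`participant_id`, `task_size`, `condition`, `kendall`,
#'   `spearman`, `pearson`).  Medians per coefficient are available through
#'   [consistency_medians()].
#' @export
self_consistency <- function(dataset) {
  stopifnot(inherits(dataset, "crowd_dataset"))
  if (length(dataset$records) == 0L) stop("self_consistency: empty dataset")
  rows <- lapply(dataset$records, function(r) {
    a <- as.numeric(r$ordinal$positions)
    b <- as.numeric(rank_of(r$numerical$estimates)[names(r$ordinal$positions)])
    safe_cor <- function(method) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      suppressWarnings(stats::cor(a, b, method = method))
    }
    data.frame(participant_id = r$participant_id,
               task_size = r$task_size,
               condition = r$interface_condition,
               kendall = safe_cor("kendall"),
               spearman = safe_cor("spearman"),
               pearson = safe_cor("pearson"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("consistency_table", class(out))
  out
}

#' Median self-consistency per coefficient
#'
#' @param table a [self_consistency()] result.
#' @return Named numeric vector of NA-excluded medians (kendall, spearman,
#'   pearson).
#' @export
consistency_medians <- function(table) {
  vapply(c("kendall", "spearman", "pearson"),
         function(cc) stats::median(table[[cc]], na.rm = TRUE), numeric(1))
}

#' Distribution of individual ordinal estimation errors
#'
#' For each participant, counts the discordant pairs between the chosen
#' ballot (the ordinal ballot, or the ranking converted from the numerical
#' ballot) and the ground truth projected onto the participant's subset,
#' then tabulates the percentage of participants attaining each possible
#' error count `0..m(m-1)/2`.
#'
#' @param dataset a [crowd_dataset()].
#' @param source `"ordinal"` or `"converted_numerical"`.
#' @return Data.frame with columns `task_size`, `discordant`, `count`,
#'   `pct`; percentages sum to 100 within each task size.
#' @export
individual_error_distribution <- function(dataset,
                                          source = c("ordinal",
                                                     "converted_numerical")) {
  source <- match.arg(source)
  stopifnot(inherits(dataset, "crowd_dataset"))
  truth <- dataset$universe$true_counts
  errs <- vapply(dataset$records, function(r) {
    est <- if (source == "ordinal") r$ordinal$positions
           else rank_of(r$numerical$estimates)
    discordant_pairs(est, rank_of(truth[names(est)]))
  }, integer(1))
  sizes <- vapply(dataset$records, function(r) r$task_size, integer(1))
  out <- do.call(rbind, lapply(sort(unique(sizes)), function(m) {
    bins <- 0:(m * (m - 1) / 2)
    cnt <- vapply(bins, function(k) sum(errs[sizes == m] == k), integer(1))
    data.frame(task_size = m, discordant = bins, count = cnt,
               pct = 100 * cnt / sum(cnt))
  }))
  rownames(out) <- NULL
  out
}

# Draw a participant subset of the requested size: whole permutation blocks
# first (preserving balanced image coverage), then a random remainder.
draw_group <- function(dataset, size, pool = seq_along(dataset$records)) {
  if (size > length(pool)) stop("draw_group: group size exceeds records")
  block <- length(dataset$universe$alternatives) %/% dataset$task_size
  n_blocks_pool <- length(pool) %/% block
  whole <- size %/% block
  picked <- integer(0)
  if (whole > 0 && n_blocks_pool > 0) {
    # pool is assumed to be in allocation order; take whole aligned blocks
    blocks <- split(pool[seq_len(n_blocks_pool * block)],
                    rep(seq_len(n_blocks_pool), each = block))
    take <- sample.int(length(blocks), min(whole, length(blocks)))
    picked <- unlist(blocks[take], use.names = FALSE)
  }
  rest <- setdiff(pool, picked)
  need <- size - length(picked)
  if (need > 0) picked <- c(picked, sample(rest, need))
  sort(picked)
}

aggregate_by_method <- function(records, universe, method,
                                coa_time_limit = 600) {
  if (method == "coa") {
    sol <- coa_consensus(records, universe = universe,
                         exact = length(universe) <= 7,
                         time_limit_seconds = coa_time_limit)
    sol$consensus_ranking
  } else {
    aggregate_multimodal(records, universe = universe, rule = method,
                         tie_break = "keep_ties")
  }
}

#' Group-size accuracy sweep
#'
#' For every method and group size, draws `replicates` random participant
#' subsets (whole allocation blocks first, then a random remainder),
#' aggregates both estimate modalities from each subset and measures
#' `d* = ground_truth_accuracy` against the true ordering of the universe.
#'
#' @param dataset a [crowd_dataset()].
#' @param methods subset of `c("plurality", "borda", "copeland", "coa")`.
#' @param group_sizes integer vector of group sizes (each at most the number
#'   of records).
#' @param replicates random subsets per cell (default 20).
#' @param seed integer seed for the subset draws.
#' @param coa_time_limit seconds per COA solve (default 600).
#' @return An object of class `sweep_result`: list with `rows` (method,
#'   group_size, replicate, d_star) and `summary` (median/min/max per cell).
#' @export
group_size_sweep <- function(dataset, methods = c("borda", "copeland"),
                             group_sizes, replicates = 20L, seed = 1L,
                             coa_time_limit = 600) {
  stopifnot(inherits(dataset, "crowd_dataset"))
  methods <- match.arg(methods,
                       c("plurality", "borda", "copeland", "coa"),
                       several.ok = TRUE)
  if (any(group_sizes > length(dataset$records)))
    stop("group_size_sweep: group size exceeds number of records")
  uni <- dataset$universe$alternatives
  truth <- truth_ranking(dataset$universe)
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(group_sizes, function(g) {
      do.call(rbind, lapply(seq_len(replicates), function(rep) {
        idx <- draw_group(dataset, g)
        recs <- dataset$records[idx]
        do.call(rbind, lapply(methods, function(me) {
          est <- aggregate_by_method(recs, uni, me, coa_time_limit)
          data.frame(method = me, group_size = g, replicate = rep,
                     d_star = ground_truth_accuracy(est, truth))
        }))
      }))
    }))
  })
  summary <- stats::aggregate(d_star ~ method + group_size, rows,
                              function(v) c(median = stats::median(v),
                                            min = min(v), max = max(v)))
  summary <- cbind(summary[c("method", "group_size")],
                   as.data.frame(summary$d_star))
  structure(list(rows = rows, summary = summary), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$summary)
  invisible(x)
}

#' Coupled- versus separate-estimate groups
#'
#' Per replicate, a fresh crowd is simulated from `config`; a
#' coupled-estimate group of size `g` contributes both modalities (2g
#' ballots, multimodal Borda), while a separate-estimate pair `(g1, g2)`
#' mixes the ordinal ballots of `g1` participants with the converted
#' numerical ballots of `g2` *other* participants (Borda on g1+g2 ballots).
#'
#' @param config a [simulation_config()]; its `n_participants` must cover
#'   `max(coupled_sizes)` and `max(rowSums of separate pairs)`.
#' @param coupled_sizes integer vector of coupled group sizes.
#' @param separate_size_pairs list of integer pairs `c(g_ordinal,
#'   g_numerical)`.
#' @param replicates number of fresh simulated crowds (default 20).
#' @param seed integer; replicate r uses dataset seed `seed + r`.
#' @return Data.frame with one row per (setting, replicate): columns
#'   `setting`, `n_participants_used`, `replicate`, `d_star`.
#' @export
coupled_vs_separate <- function(config, coupled_sizes = 100L,
                                separate_size_pairs = list(c(100L, 100L)),
                                replicates = 20L, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  need <- max(c(coupled_sizes,
                vapply(separate_size_pairs, sum, numeric(1))))
  if (need > config$n_participants)
    stop("coupled_vs_separate: config pool smaller than the largest setting")
  rows <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
    cfg <- config
    cfg$seed <- as.integer(seed + rep)
    ds <- simulate_crowd(cfg)
    uni <- ds$universe$alternatives
    truth <- truth_ranking(ds$universe)
    withr::with_seed(cfg$seed + 1000000L, {
      out <- lapply(coupled_sizes, function(g) {
        idx <- draw_group(ds, g)
        est <- aggregate_multimodal(ds$records[idx], universe = uni,
                                    rule = "borda", tie_break = "keep_ties")
        data.frame(setting = sprintf("coupled_%d", g),
                   n_participants_used = g, replicate = rep,
                   d_star = ground_truth_accuracy(est, truth))
      })
      out2 <- lapply(separate_size_pairs, function(gg) {
        idx <- draw_group(ds, gg[1] + gg[2])
        a_idx <- idx[seq_len(gg[1])]
        b_idx <- idx[gg[1] + seq_len(gg[2])]
        est <- aggregate_mixed_groups(ds$records[a_idx], ds$records[b_idx],
                                      universe = uni, rule = "borda",
                                      tie_break = "keep_ties")
        data.frame(setting = sprintf("separate_%d_%d", gg[1], gg[2]),
                   n_participants_used = gg[1] + gg[2], replicate = rep,
                   d_star = ground_truth_accuracy(est, truth))
      })
      do.call(rbind, c(out, out2))
    })
  }))
  rownames(rows) <- NULL
  rows
}

#' Interquartile-range outlier filter
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with quartiles
#' computed by the linear-interpolation convention
#' (`stats::quantile(type = 7)`, the R default).
#'
#' @param values numeric vector with at least 4 values.
#' @return List with `kept` (values inside the fences) and `outlier`
#'   (logical flags, one per input value).
#' @export
iqr_outlier_filter <- function(values) {
  if (length(values) < 4L)
    stop("iqr_outlier_filter: at least 4 values are required")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  outlier <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  list(kept = values[!outlier], outlier = outlier)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a crowd dataset, validates it, and writes the
#' self-consistency table, the individual error histograms (for both ballot
#' sources), the group-size sweep and an optional coupled-versus-separate
#' comparison, plus a JSON summary.  Outputs are byte-identical across runs
#' with the same configuration and seed.
#'
#' @param config a [simulation_config()] (ignored when `input_dir` is given).
#' @param output_dir directory for the result files.
#' @param input_dir optional directory with an existing CSV dataset; when
#'   given, simulation is skipped.
#' @param methods,group_sizes,replicates passed to [group_size_sweep()];
#'   `group_sizes` defaults to c(n/4, n/2, n) for n records.
#' @param run_coupled logical; also run [coupled_vs_separate()] (only
#'   meaningful with a simulation config).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = simulation_config(), output_dir,
                         input_dir = NULL,
                         methods = c("borda", "copeland"),
                         group_sizes = NULL, replicates = 20L,
                         run_coupled = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message("crowdrank: ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- if (is.null(input_dir)) {
    say("simulating crowd (seed ", config$seed, ")")
    stage("simulate", simulate_crowd(config))
  } else {
    say("loading dataset from ", input_dir)
    stage("load", read_crowd_dataset(input_dir))
  }
  stage("validate", {
    v <- validate_dataset(ds)
    if (nrow(v) > 0) stop(nrow(v), " invariant violations")
  })

  say("self-consistency")
  cons <- stage("self_consistency", self_consistency(ds))
  utils::write.csv(cons, file.path(output_dir, "consistency.csv"),
                   row.names = FALSE)

  say("individual error distributions")
  hist <- stage("error_distribution", rbind(
    cbind(source = "ordinal",
          individual_error_distribution(ds, "ordinal")),
    cbind(source = "converted_numerical",
          individual_error_distribution(ds, "converted_numerical"))))
  utils::write.csv(hist, file.path(output_dir, "error_hist.csv"),
                   row.names = FALSE)

  if (is.null(group_sizes)) {
    n <- length(ds$records)
    group_sizes <- unique(pmax(1L, c(n %/% 4L, n %/% 2L, n)))
  }
  say("group-size sweep (", paste(methods, collapse = ", "), ")")
  sweep <- stage("sweep",
                 group_size_sweep(ds, methods, group_sizes, replicates,
                                  seed = if (is.null(input_dir))
                                    config$seed else 1L))
  utils::write.csv(sweep$rows, file.path(output_dir, "sweep.csv"),
                   row.names = FALSE)

  cvs <- NULL
  if (run_coupled && is.null(input_dir)) {
    say("coupled vs separate comparison")
    g <- min(100L, length(ds$records) %/% 2L)
    cvs <- stage("coupled_vs_separate",
                 coupled_vs_separate(config, coupled_sizes = g,
                                     separate_size_pairs = list(c(g, g)),
                                     replicates = replicates,
                                     seed = config$seed))
    utils::write.csv(cvs, file.path(output_dir, "coupled_vs_separate.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    n_records = length(ds$records),
    task_size = ds$task_size,
    consistency_medians = as.list(consistency_medians(cons)),
    sweep = sweep$summary)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; outputs in ", output_dir)
  invisible(list(dataset = ds, consistency = cons, error_hist = hist,
                 sweep = sweep, coupled_vs_separate = cvs))
}
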