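test_that("self_consistency computes tau-b, rho and Pearson per record", {
  est <- c(A = 50, B = 60, C = 70)
  ds <- crowd_dataset(universe(c("A", "B", "C"), c(50L, 60L, 70L)),
                      list(consistent_record("p1", est)), 3L)
  tab <- self_consistency(ds)
  expect_equal(unname(unlist(tab[1, c("kendall", "spearman", "pearson")])),
               c(1, 1, 1))

  # exact reversal
  rev_rec <- make_record("p2", c(A = 3L, B = 2L, C = 1L), est)
  ds2 <- crowd_dataset(ds$universe, list(rev_rec), 3L)
  expect_equal(unname(unlist(self_consistency(ds2)[1, 4:6])), c(-1, -1, -1))

  # tie in the converted ballot: tau-b against the hand concordance formula
  rec <- make_record("p3", c(A = 1L, B = 2L, C = 3L, D = 4L),
                     c(A = 50, B = 55, C = 55, D = 60))
  ds3 <- crowd_dataset(universe(c("A", "B", "C", "D"),
                                c(50L, 55L, 60L, 65L)), list(rec), 4L)
  got <- self_consistency(ds3)$kendall[1]
  # pairs: C = 5 concordant, D = 0, one tie in rank(b); n0 = 6, tie block of 2
  expect_equal(got, (5 - 0) / sqrt((6 - 0) * (6 - 1)))

  # zero-variance converted ballot yields NA, excluded from medians
  flat <- make_record("p4", c(A = 1L, B = 2L), c(A = 55, B = 55))
  ds4 <- crowd_dataset(universe(c("A", "B"), c(50L, 60L)),
                       list(flat, consistent_record("p5", c(A = 50, B = 60))),
                       2L)
  tab4 <- self_consistency(ds4)
  expect_true(is.na(tab4$kendall[1]))
  expect_equal(consistency_medians(tab4)[["kendall"]], 1)
})

test_that("individual_error_distribution bins discordant pairs per task size", {
  dsq <- simulate_crowd(perfect_config(n = 12L, task_size = 6L))
  h <- individual_error_distribution(dsq, "ordinal")
  expect_equal(h$discordant, 0:15)   # bins span 0..m(m-1)/2
  expect_equal(h$pct[h$discordant == 0], 100)
  expect_equal(sum(h$pct), 100, tolerance = 1e-9)

  # hand-built fixture: errors 0, 1 and 3 among three records
  uni <- universe(c("A", "B", "C"), c(50L, 60L, 70L))
  recs <- list(
    make_record("p1", c(A = 1L, B = 2L, C = 3L), c(A = 50, B = 60, C = 70)),
    make_record("p2", c(A = 2L, B = 1L, C = 3L), c(A = 50, B = 60, C = 70)),
    make_record("p3", c(A = 3L, B = 2L, C = 1L), c(A = 50, B = 60, C = 70)))
  h2 <- individual_error_distribution(crowd_dataset(uni, recs, 3L), "ordinal")
  expect_equal(h2$count, c(1L, 1L, 0L, 1L))
  expect_equal(h2$pct, c(1, 1, 0, 1) / 3 * 100)
  h3 <- individual_error_distribution(crowd_dataset(uni, recs, 3L),
                                      "converted_numerical")
  expect_equal(h3$count, c(3L, 0L, 0L, 0L))
})

test_that("group_size_sweep draws balanced subsets and summarizes d*", {
  # zero noise with full-universe ballots: every method recovers the truth
  # (with subset ballots voting scores are subset-composition dependent, so
  # d* > 0 can occur even without noise)
  full_cfg <- simulation_config(n_participants = 8L, task_size = 6L,
                                n_images = 6L, seed = 2L,
                                noise = noise_profile("independent", 0, 0))
  full <- group_size_sweep(simulate_crowd(full_cfg),
                           c("borda", "copeland", "coa"), c(4L, 8L),
                           replicates = 2L, seed = 9L)
  expect_true(all(full$rows$d_star == 0))

  dsq <- simulate_crowd(perfect_config(n = 24L, task_size = 5L))
  sw <- group_size_sweep(dsq, c("borda", "copeland"), c(6L, 24L),
                         replicates = 3L, seed = 5L)
  expect_true(all(sw$rows$d_star >= 0 & sw$rows$d_star <= 1))
  expect_equal(nrow(sw$rows), 2 * 2 * 3)
  # full-size group: single deterministic subset, replicates identical
  full <- sw$rows[sw$rows$group_size == 24L & sw$rows$method == "borda", ]
  expect_equal(length(unique(full$d_star)), 1L)
  # summaries are order statistics of the rows
  cell <- sw$rows[sw$rows$group_size == 6L & sw$rows$method == "borda",
                  "d_star"]
  srow <- sw$summary[sw$summary$group_size == 6L &
                       sw$summary$method == "borda", ]
  expect_equal(srow$median, median(cell))
  expect_equal(srow$min, min(cell))
  expect_equal(srow$max, max(cell))
  expect_error(group_size_sweep(dsq, "borda", 100L), "exceeds")
})

test_that("group_size_sweep supports the exact COA path on small universes", {
  cfg <- simulation_config(n_participants = 8L, task_size = 2L,
                           n_images = 4L, count_min = 50L, count_max = 79L,
                           seed = 13L)
  ds <- simulate_crowd(cfg)
  sw <- group_size_sweep(ds, c("borda", "coa"), c(4L, 8L), replicates = 2L,
                         seed = 3L)
  expect_true(all(is.finite(sw$rows$d_star)))
  expect_true(all(sw$rows$d_star >= 0 & sw$rows$d_star <= 1))
})

test_that("iqr_outlier_filter uses linear-interpolation quartiles and 1.5 IQR fences", {
  r <- iqr_outlier_filter(c(1:10, 1000))
  # Q1 = 3.5, Q3 = 8.5, IQR = 5 -> fences [-4, 16]
  expect_equal(which(r$outlier), 11L)
  expect_equal(r$kept, 1:10)

  tight <- iqr_outlier_filter(c(10, 11, 12, 13, 14))
  expect_false(any(tight$outlier))

  # IQR 0: any deviant value is flagged
  flat <- iqr_outlier_filter(c(5, 5, 5, 5, 7))
  expect_equal(which(flat$outlier), 5L)
  expect_error(iqr_outlier_filter(c(1, 2, 3)), "4 values")

  # affine invariance of the flags
  set.seed(71)
  for (k in 1:10) {
    v <- rnorm(20)
    expect_equal(iqr_outlier_filter(3.2 * v - 7)$outlier,
                 iqr_outlier_filter(v)$outlier)
  }
})

test_that("coupled_vs_separate bookkeeping and zero-noise behavior", {
  cfg <- simulation_config(n_participants = 24L, task_size = 6L,
                           n_images = 6L, seed = 1L,
                           noise = noise_profile("independent", 0, 0))
  out <- coupled_vs_separate(cfg, coupled_sizes = 6L,
                             separate_size_pairs = list(c(6L, 6L)),
                             replicates = 2L, seed = 4L)
  expect_true(all(out$d_star == 0))
  expect_equal(sort(unique(out$setting)), c("coupled_6", "separate_6_6"))
  # separate groups use g1 + g2 distinct participants
  expect_equal(unique(out$n_participants_used[out$setting == "separate_6_6"]),
               12L)
  expect_error(coupled_vs_separate(cfg, coupled_sizes = 30L), "pool")
})

test_that("run_pipeline writes all artifacts and is byte-identical per seed", {
  cfg <- simulation_config(n_participants = 24L, task_size = 5L, seed = 3L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, d1, replicates = 2L, quiet = TRUE)
  run_pipeline(cfg, d2, replicates = 2L, quiet = TRUE)
  files <- c("consistency.csv", "error_hist.csv", "sweep.csv", "summary.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # loading an external dataset skips simulation
  ddir <- withr::local_tempdir()
  write_crowd_dataset(simulate_crowd(cfg), ddir)
  d3 <- withr::local_tempdir()
  res <- run_pipeline(output_dir = d3, input_dir = ddir, replicates = 2L,
                      quiet = TRUE)
  expect_equal(length(res$dataset$records), 24L)
  expect_true(file.exists(file.path(d3, "sweep.csv")))
})

test_that("the CLI simulates and aggregates end to end", {
  dir <- withr::local_tempdir()
  crowdrank_cli(c("simulate", "--participants", "12", "--task-size", "3",
                  "--seed", "5", "--out", dir))
  expect_true(file.exists(file.path(dir, "ordinal.csv")))
  out <- file.path(dir, "consensus.csv")
  crowdrank_cli(c("aggregate", "--rule", "borda", "--in", dir,
                  "--out", out))
  cons <- utils::read.csv(out)
  expect_equal(nrow(cons), 30L)
  expect_setequal(cons$position, 1:30)
})
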