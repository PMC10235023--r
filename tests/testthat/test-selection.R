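# A mid-size multi-cohort study with one strong planted protein, reused
# across the selection tests.
selection_study <- function(seed = 1, planted_or = 2.0, n_proteins = 60,
                            sets_per_cohort = 60) {
  ids <- sprintf("P%04d", seq_len(n_proteins))
  tr <- truth_table(ids)
  if (!is.na(planted_or)) tr <- plant_effect(tr, ids[1], beta0 = log(planted_or))
  cfg <- sim_config(
    cohorts = data.frame(name = c("EPIC", "HUNT", "CPS"),
                         n_sets = rep(sets_per_cohort, 3),
                         full_library = TRUE),
    n_proteins = n_proteins, n_shared = n_proteins, n_panels = 2,
    n_shared_panels = 2, n_duplicates = 0, truth = tr, lod_quantile = 0,
    seed = seed)
  st <- generate_study(cfg)
  list(study = st, matrix = preprocess_study(st)$matrix)
}

test_that("identical seeds reproduce the selection result exactly", {
  s <- selection_study(seed = 5)
  cfg <- resampling_config(n_iter = 20, forced_discovery_cohorts = "EPIC",
                           seed = 7)
  a <- resample_select(s$matrix, s$study$subjects, cfg)
  b <- resample_select(s$matrix, s$study$subjects, cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$iteration_log, b$iteration_log)
})

test_that("a strongly planted protein is selected and frequencies are coherent", {
  s <- selection_study(seed = 3)
  sel <- resample_select(s$matrix, s$study$subjects,
                         resampling_config(n_iter = 50,
                                           forced_discovery_cohorts = "EPIC",
                                           seed = 9))
  tab <- sel$table
  expect_true(tab$selected[tab$protein == "P0001"])
  expect_true(all(tab$joint_pass_freq <=
                    pmin(tab$discovery_pass_freq, tab$replication_pass_freq) + 1e-12))
  expect_true(all(sel$iteration_log$forced_in_discovery))
  # sets stay intact: discovery+replication set counts always total all sets
  expect_true(all(sel$iteration_log$n_discovery_sets +
                    sel$iteration_log$n_replication_sets == 180))
  # forced cohort is in discovery every iteration
  expect_true(all(grepl("EPIC", sel$iteration_log$discovery_cohorts)))
})

test_that("raising the selection frequency never grows the selected set", {
  s <- selection_study(seed = 11, planted_or = 1.6)
  subj <- s$study$subjects
  base <- resample_select(s$matrix, subj,
                          resampling_config(n_iter = 40,
                                            forced_discovery_cohorts = "EPIC",
                                            selection_frequency = 0.2, seed = 2))
  freqs <- base$table$joint_pass_freq
  prev <- NULL
  for (sf in c(0.2, 0.5, 0.8, 1.0)) {
    cur <- base$table$protein[freqs >= sf]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # and a re-run with a higher threshold gives exactly the thresholded set
  hi <- resample_select(s$matrix, subj,
                        resampling_config(n_iter = 40,
                                          forced_discovery_cohorts = "EPIC",
                                          selection_frequency = 0.8, seed = 2))
  expect_identical(hi$table$protein[hi$table$selected],
                   base$table$protein[freqs >= 0.8])
})

test_that("selection_frequency zero with one iteration reduces to the pass set", {
  s <- selection_study(seed = 13)
  sel <- resample_select(s$matrix, s$study$subjects,
                         resampling_config(n_iter = 1,
                                           forced_discovery_cohorts = "EPIC",
                                           selection_frequency = 0, seed = 4))
  expect_identical(sel$table$selected, sel$table$joint_pass_freq > 0)
})

test_that("forcing every cohort into discovery is a configuration error", {
  s <- selection_study(seed = 15, n_proteins = 10, sets_per_cohort = 30)
  expect_error(resample_select(s$matrix, s$study$subjects,
                               resampling_config(
                                 n_iter = 2,
                                 forced_discovery_cohorts = c("EPIC", "HUNT",
                                                              "CPS"))),
               "replication side would be empty")
  expect_error(resample_select(s$matrix, s$study$subjects,
                               resampling_config(
                                 n_iter = 2,
                                 forced_discovery_cohorts = "NSHDS")),
               "absent from the study")
})

test_that("proteins missing in some cohorts are fit only where measured", {
  ids <- sprintf("P%04d", 1:20)
  tr <- plant_effect(truth_table(ids), "P0011", beta0 = log(2.2))
  cfg <- sim_config(
    cohorts = data.frame(name = c("EPIC", "NSHDS", "HUNT"),
                         n_sets = c(60, 40, 60),
                         full_library = c(TRUE, TRUE, FALSE)),
    n_proteins = 20, n_shared = 10, n_panels = 2, n_shared_panels = 1,
    n_duplicates = 0, truth = tr, lod_quantile = 0, seed = 17)
  st <- generate_study(cfg)
  m <- preprocess_study(st)$matrix
  a <- associate_all(m, st$subjects)
  # extra-panel proteins (P0011..) have sets only from the full-library cohorts
  expect_true(all(a$n_sets[11:20] == 100))
  expect_true(all(a$n_sets[1:10] == 160))
  expect_lt(a$p[a$protein == "P0011"], 1e-4)
})

test_that("single split selection needs a discovery pass", {
  ids <- sprintf("P%04d", 1:30)
  # effect confined to the replication cohorts: planted protein must fail
  cfg <- sim_config(
    cohorts = data.frame(name = c("EPIC", "NSHDS", "HUNT", "CPS"),
                         n_sets = c(60, 40, 80, 80), full_library = TRUE),
    n_proteins = 30, n_shared = 30, n_panels = 2, n_shared_panels = 2,
    n_duplicates = 0, truth = truth_table(ids), lod_quantile = 0, seed = 19)
  st <- generate_study(cfg)
  m <- preprocess_study(st)$matrix
  # inject an effect only in the replication cohorts, after generation
  rep_rows <- st$subjects$cohort %in% c("HUNT", "CPS") & st$subjects$case == 1
  m2 <- m
  m2[rep_rows, "P0001"] <- m2[rep_rows, "P0001"] + 1.2
  r <- single_split_select(m2, st$subjects, c("EPIC", "NSHDS"),
                           min_sets_per_side = 20)
  expect_false(r$table$selected[r$table$protein == "P0001"])
  expect_lt(r$table$p_replication[1], 0.05)

  # a strong everywhere-measured effect is found by both methods
  tr <- plant_effect(truth_table(ids), "P0002", beta0 = log(2.4))
  cfg2 <- sim_config(
    cohorts = cfg$cohorts, n_proteins = 30, n_shared = 30, n_panels = 2,
    n_shared_panels = 2, n_duplicates = 0, truth = tr, lod_quantile = 0,
    seed = 21)
  st2 <- generate_study(cfg2)
  m3 <- preprocess_study(st2)$matrix
  both1 <- single_split_select(m3, st2$subjects, c("EPIC", "NSHDS"),
                               min_sets_per_side = 20)
  both2 <- resample_select(m3, st2$subjects,
                           resampling_config(n_iter = 30,
                                             forced_discovery_cohorts =
                                               c("EPIC", "NSHDS"),
                                             min_sets_per_side = 20, seed = 1))
  expect_true(both1$table$selected[both1$table$protein == "P0002"])
  expect_true(both2$table$selected[both2$table$protein == "P0002"])

  expect_error(single_split_select(m3, st2$subjects,
                                   c("EPIC", "NSHDS", "HUNT", "CPS")),
               "replication side is empty")
})

test_that("selection overlap summaries count correctly", {
  mk <- function(sel) structure(list(table = data.frame(
    protein = sprintf("P%02d", 1:10), selected = sel)), class = "selection_result")
  a <- mk(c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(compare_selections(a, a)[c("both", "only_a", "only_b")],
               list(both = 2L, only_a = 0L, only_b = 0L))
  b <- mk(c(FALSE, FALSE, TRUE, TRUE, TRUE, rep(FALSE, 5)))
  cmp <- compare_selections(a, b)
  expect_equal(cmp$both, 0L); expect_equal(cmp$only_a, 2L)
  expect_equal(cmp$only_b, 3L)
  c_other <- mk(rep(FALSE, 10)); c_other$table$protein[1] <- "X"
  expect_error(compare_selections(a, c_other), "different protein sets")
})
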