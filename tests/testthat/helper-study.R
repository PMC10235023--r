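# Small study builders shared across tests.

one_cohort <- function(n_sets, name = "A", full = TRUE) {
  data.frame(name = name, n_sets = n_sets, full_library = full,
             stringsAsFactors = FALSE)
}

# A compact study: one cohort, few proteins, optional planted log OR on the
# first protein, no LOD censoring unless asked.
quick_study <- function(n_sets = 200, n_proteins = 4, beta0 = 0,
                        beta_lead = 0, gamma_surv = 0, gamma_lead = 0,
                        smoking_assoc = 0, lod_quantile = 0, seed = 1,
                        cohorts = one_cohort(n_sets), within_pair_corr = 0.2) {
  ids <- sprintf("P%04d", seq_len(n_proteins))
  tr <- truth_table(ids)
  tr <- plant_effect(tr, ids[1], beta0 = beta0, beta_lead = beta_lead,
                     gamma_surv = gamma_surv, gamma_lead = gamma_lead,
                     smoking_assoc = smoking_assoc)
  cfg <- sim_config(cohorts = cohorts, n_proteins = n_proteins,
                    n_shared = n_proteins, n_panels = 1, n_shared_panels = 1,
                    n_duplicates = 0, truth = tr,
                    within_pair_corr = within_pair_corr,
                    lod_quantile = lod_quantile, seed = seed)
  generate_study(cfg)
}

# Synthetic 1:1 subjects frame for hand-built difference fixtures: the case
# member carries the difference value, the control zero.
subjects_for_diffs <- function(n_sets) {
  data.frame(sample_id = paste0(rep(sprintf("s%03d", seq_len(n_sets)), each = 2),
                                c("_case", "_ctrl")),
             set_id = rep(sprintf("s%03d", seq_len(n_sets)), each = 2),
             case = rep(c(1L, 0L), n_sets),
             stringsAsFactors = FALSE)
}

values_for_diffs <- function(diffs) {
  v <- numeric(2 * length(diffs))
  v[seq(1, length(v), 2)] <- diffs
  v
}

# Brute-force grid maximizer of the written 1:1 conditional likelihood.
grid_clogit <- function(diffs, grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, function(b) sum(stats::plogis(b * diffs, log.p = TRUE)),
               numeric(1))
  grid[which.max(ll)]
}
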