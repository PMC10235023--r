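#' Configuration for the resampling discovery-replication algorithm
#'
#' @param n_iter number of resampling iterations (500 in the original design).
#' @param discovery_fraction fraction of matched sets assigned to discovery
#'   within each non-forced cohort.
#' @param forced_discovery_cohorts cohorts placed wholly in discovery in
#'   every iteration (the cohorts whose data chose the assay panels).
#' @param selection_frequency minimum fraction of iterations a protein must
#'   pass jointly to be selected.
#' @param require_sign_concordance require the discovery and replication log
#'   odds ratios to share a sign for an iteration to count as a pass.
#' @param min_sets_per_side minimum complete matched sets a protein needs on
#'   each side to enter an iteration.
#' @param seed integer seed; the whole run is a pure function of it.
#' @return A `resampling_config` list.
#' @export
resampling_config <- function(n_iter = 500L, discovery_fraction = 0.7,
                              forced_discovery_cohorts = c("EPIC", "NSHDS"),
                              selection_frequency = 0.5,
                              require_sign_concordance = TRUE,
                              min_sets_per_side = 25L, seed = 1L) {
  stopifnot(n_iter >= 1, discovery_fraction > 0, discovery_fraction < 1,
            selection_frequency >= 0, selection_frequency <= 1)
  structure(list(n_iter = as.integer(n_iter),
                 discovery_fraction = discovery_fraction,
                 forced_discovery_cohorts = forced_discovery_cohorts,
                 selection_frequency = selection_frequency,
                 require_sign_concordance = require_sign_concordance,
                 min_sets_per_side = as.integer(min_sets_per_side),
                 seed = as.integer(seed)),
            class = "resampling_config")
}

#' Resampling discovery-replication selection of risk proteins
#'
#' In each iteration the matched sets (never individuals) are split into a
#' discovery (70%) and replication (30%) side, balanced within cohort;
#' forced cohorts go wholly to discovery. Each protein is fit by conditional
#' logistic regression on both sides; an iteration counts as a pass when the
#' discovery p-value is below `0.05 / ENT` and the replication p-value below
#' 0.05 (and, by default, the two estimates share a sign). Proteins passing
#' in at least `selection_frequency` of iterations are selected. The ENT is
#' computed once on the full standardized matrix of the protein set in play.
#'
#' @param matrix standardized samples x proteins matrix (the protein-set
#'   track: pass only columns measured in the cohorts being analysed).
#' @param subjects metadata with `set_id`, `case`, `cohort`.
#' @param config a [resampling_config()].
#' @return A `selection_result` list: `table` (per-protein pass frequencies
#'   and selected flag), `ent`, `config`, `iteration_log` (per-iteration
#'   discovery cohort composition and set counts).
#' @export
resample_select <- function(matrix, subjects, config = resampling_config()) {
  stopifnot(inherits(config, "resampling_config"))
  forced <- config$forced_discovery_cohorts
  cohorts <- unique(subjects$cohort)
  missing_forced <- setdiff(forced, cohorts)
  if (length(missing_forced))
    stop("forced discovery cohort(s) absent from the study: ",
         paste(missing_forced, collapse = ", "))
  if (length(setdiff(cohorts, forced)) == 0)
    stop("replication side would be empty: every cohort is forced into ",
         "discovery")

  ent <- effective_number_of_tests(matrix)
  p_disc_thr <- ent$threshold

  D <- set_differences(matrix, subjects)
  # cohort of each matched set (shared by construction)
  cs <- subjects[subjects$case == 1L, ]
  set_cohort <- cs$cohort[match(rownames(D), cs$set_id)]

  P <- ncol(D)
  pass <- matrix(FALSE, P, config$n_iter,
                 dimnames = list(colnames(D), NULL))
  pass_d <- pass; pass_r <- pass
  eligible <- matrix(FALSE, P, config$n_iter)
  log_rows <- vector("list", config$n_iter)

  set.seed(config$seed)
  for (it in seq_len(config$n_iter)) {
    disc <- set_cohort %in% forced
    for (co in setdiff(cohorts, forced)) {
      idx <- which(set_cohort == co)
      n_disc <- round(length(idx) * config$discovery_fraction)
      disc[sample(idx, n_disc)] <- TRUE
    }
    fd <- clogit_uni_many(D[disc, , drop = FALSE],
                          min_sets = config$min_sets_per_side)
    fr <- clogit_uni_many(D[!disc, , drop = FALSE],
                          min_sets = config$min_sets_per_side)
    ok <- !is.na(fd$p) & !is.na(fr$p)
    hit_d <- ok & fd$p < p_disc_thr
    hit_r <- ok & fr$p < 0.05
    hit <- hit_d & hit_r
    if (config$require_sign_concordance)
      hit <- hit & sign(fd$beta) == sign(fr$beta)
    pass_d[, it] <- hit_d
    pass_r[, it] <- hit_r
    pass[, it] <- hit
    eligible[, it] <- ok
    log_rows[[it]] <- data.frame(
      iteration = it, n_discovery_sets = sum(disc),
      n_replication_sets = sum(!disc),
      forced_in_discovery = all(set_cohort[!disc] %in% setdiff(cohorts, forced)),
      discovery_cohorts = paste(sort(unique(set_cohort[disc])), collapse = ";"))
  }
  freq <- rowMeans(pass)
  sel <- if (config$selection_frequency > 0)
    freq >= config$selection_frequency
  else freq > 0  # boundary: selected = passed at least one iteration
  tab <- data.frame(protein = colnames(D),
                    discovery_pass_freq = rowMeans(pass_d),
                    replication_pass_freq = rowMeans(pass_r),
                    joint_pass_freq = freq,
                    n_eligible_iter = rowSums(eligible),
                    selected = sel,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, ent = ent, config = config,
                 iteration_log = do.call(rbind, log_rows)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Resampling selection: %d protein(s) selected of %d (ENT = %d)\n",
              sum(x$table$selected), nrow(x$table), x$ent$ent))
  invisible(x)
}

#' Single split-sample discovery-replication selection
#'
#' Sensitivity-analysis variant: one fixed split in which the named cohorts
#' form the discovery set and all others the replication set. A protein is
#' selected if its BH-FDR adjusted p-value is below 0.05 in discovery and its
#' raw p-value below 0.05 in replication (sign concordance required).
#'
#' @inheritParams resample_select
#' @param discovery_cohorts cohorts forming the discovery side.
#' @param min_sets_per_side minimum complete sets per side per protein.
#' @return A `selection_result` with a one-iteration table (`p_discovery`,
#'   `fdr_discovery`, `p_replication`, `selected`).
#' @export
single_split_select <- function(matrix, subjects,
                                discovery_cohorts = c("EPIC", "NSHDS"),
                                min_sets_per_side = 25L) {
  cohorts <- unique(subjects$cohort)
  if (!all(discovery_cohorts %in% cohorts))
    stop("discovery cohort(s) absent from the study: ",
         paste(setdiff(discovery_cohorts, cohorts), collapse = ", "))
  if (length(setdiff(cohorts, discovery_cohorts)) == 0)
    stop("replication side is empty")
  D <- set_differences(matrix, subjects)
  cs <- subjects[subjects$case == 1L, ]
  set_cohort <- cs$cohort[match(rownames(D), cs$set_id)]
  disc <- set_cohort %in% discovery_cohorts
  fd <- clogit_uni_many(D[disc, , drop = FALSE], min_sets = min_sets_per_side)
  fr <- clogit_uni_many(D[!disc, , drop = FALSE], min_sets = min_sets_per_side)
  fdr <- bh_fdr(fd$p)
  sel <- !is.na(fdr) & !is.na(fr$p) & fdr < 0.05 & fr$p < 0.05 &
    sign(fd$beta) == sign(fr$beta)
  tab <- data.frame(protein = colnames(D), p_discovery = fd$p,
                    fdr_discovery = fdr, p_replication = fr$p,
                    beta_discovery = fd$beta, beta_replication = fr$beta,
                    selected = sel, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, discovery_cohorts = discovery_cohorts),
            class = "selection_result")
}

#' Compare two selection results
#'
#' @param a,b `selection_result` objects over the same protein universe.
#' @return List: `both`, `only_a`, `only_b` (counts), and `table` with
#'   per-protein selection flags under each method.
#' @export
compare_selections <- function(a, b) {
  pa <- a$table$protein; pb <- b$table$protein
  if (!setequal(pa, pb)) stop("selection results cover different protein sets")
  tab <- data.frame(protein = pa,
                    selected_a = a$table$selected,
                    selected_b = b$table$selected[match(pa, pb)],
                    stringsAsFactors = FALSE)
  list(both = sum(tab$selected_a & tab$selected_b),
       only_a = sum(tab$selected_a & !tab$selected_b),
       only_b = sum(!tab$selected_a & tab$selected_b),
       table = tab)
}
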