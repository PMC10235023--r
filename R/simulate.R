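#' Default cohort layout for a simulated multi-cohort study
#'
#' Six prospective cohorts with 1:1 matched case-control sets. Two cohorts
#' (EPIC, NSHDS) measure the full protein library; the remaining four measure
#' only the shared panels. Set counts follow the published study design.
#'
#' @return A data.frame with columns `name`, `n_sets`, `full_library`.
#' @export
default_cohorts <- function() {
  data.frame(
    name = c("EPIC", "NSHDS", "HUNT", "CPS", "MCCS", "SCHS"),
    n_sets = c(188L, 64L, 164L, 115L, 108L, 92L),
    full_library = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Table of planted per-protein effects
#'
#' Holds the ground truth a simulated study is generated from. All effects
#' default to zero (a fully null study); use [plant_effect()] to set them.
#'
#' @param protein_ids character vector of protein identifiers.
#' @return A data.frame with one row per protein and columns:
#'   \describe{
#'     \item{beta0}{log odds ratio per SD of protein at diagnosis (lead time 0)}
#'     \item{beta_lead}{linear change in the log OR per year of lead time}
#'     \item{gamma_surv}{log hazard ratio per SD for post-diagnosis mortality,
#'       at diagnosis}
#'     \item{gamma_lead}{protein-by-lead-time log-HR interaction per year}
#'     \item{smoking_assoc}{linear coefficient of the protein on standardized
#'       smoking intensity (cross-sectional)}
#'   }
#' @export
truth_table <- function(protein_ids) {
  data.frame(
    protein = as.character(protein_ids),
    beta0 = 0, beta_lead = 0,
    gamma_surv = 0, gamma_lead = 0,
    smoking_assoc = 0,
    stringsAsFactors = FALSE
  )
}

#' Plant an effect for one protein in a truth table
#'
#' @param truth a truth table from [truth_table()].
#' @param protein protein id to modify.
#' @param beta0,beta_lead,gamma_surv,gamma_lead,smoking_assoc effect values;
#'   omitted ones are left unchanged.
#' @return The modified truth table.
#' @export
plant_effect <- function(truth, protein, beta0 = NULL, beta_lead = NULL,
                         gamma_surv = NULL, gamma_lead = NULL,
                         smoking_assoc = NULL) {
  i <- match(protein, truth$protein)
  if (is.na(i)) stop("unknown protein in truth table: ", protein)
  for (f in c("beta0", "beta_lead", "gamma_surv", "gamma_lead",
              "smoking_assoc")) {
    v <- get(f)
    if (!is.null(v)) truth[[f]][i] <- v
  }
  truth
}

#' Configuration for a simulated matched case-control proteomics study
#'
#' Defaults emulate the design of a six-cohort nested case-control study of
#' imminent lung cancer: 731 matched 1:1 sets, 1162 proteins on 14 assay
#' panels of which 484 proteins (6 panels) are measured in every cohort and
#' the rest only in the two full-library cohorts, 112 proteins duplicated on
#' a second panel, blood drawn up to 3 years before diagnosis.
#'
#' @param cohorts data.frame of cohort specs (see [default_cohorts()]).
#' @param n_proteins total number of distinct proteins.
#' @param n_shared number of proteins on panels measured in every cohort.
#' @param n_panels total number of assay panels.
#' @param n_shared_panels number of panels measured in every cohort.
#' @param n_duplicates number of proteins also assayed on a second panel.
#' @param truth truth table; defaults to all-null.
#' @param within_pair_corr correlation of protein values within a matched
#'   pair, induced by matching; in `[0, 1)`.
#' @param lod_quantile pooled quantile at which each protein's limit of
#'   detection sits; in `[0, 0.5]`. Zero disables below-LOD censoring.
#' @param lead_time_max_years maximum lead time between draw and diagnosis.
#' @param survival_params list with `scale` (baseline mean survival, years)
#'   and `censor_rate` (independent exponential censoring rate per year).
#' @param duplicate_noise_sd measurement noise added to the duplicate assay.
#' @param seed integer RNG seed; generation is a pure function of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cohorts = default_cohorts(),
                       n_proteins = 1162L, n_shared = 484L,
                       n_panels = 14L, n_shared_panels = 6L,
                       n_duplicates = 112L,
                       truth = NULL,
                       within_pair_corr = 0.2,
                       lod_quantile = 0.05,
                       lead_time_max_years = 3,
                       survival_params = list(scale = 2, censor_rate = 0.1),
                       duplicate_noise_sd = 0.3,
                       seed = 1L) {
  stopifnot(is.data.frame(cohorts),
            all(c("name", "n_sets", "full_library") %in% names(cohorts)),
            all(cohorts$n_sets >= 1L),
            n_shared <= n_proteins,
            n_shared_panels <= n_panels,
            n_duplicates <= n_proteins,
            within_pair_corr >= 0, within_pair_corr < 1,
            lead_time_max_years > 0)
  if (lod_quantile < 0 || lod_quantile > 0.5)
    stop("lod_quantile must lie in [0, 0.5]")
  ids <- sprintf("P%04d", seq_len(n_proteins))
  if (is.null(truth)) truth <- truth_table(ids)
  if (!all(truth$protein %in% ids))
    stop("truth table names proteins absent from the panel map")
  shared_panels <- sprintf("panel_%02d", seq_len(n_shared_panels))
  extra_panels <- sprintf("panel_%02d",
                          seq(n_shared_panels + 1L, length.out = n_panels - n_shared_panels))
  panel <- character(n_proteins)
  panel[seq_len(n_shared)] <-
    rep_len(shared_panels, n_shared)
  if (n_shared < n_proteins)
    panel[seq(n_shared + 1L, n_proteins)] <-
      rep_len(extra_panels, n_proteins - n_shared)
  structure(list(
    cohorts = cohorts, n_proteins = as.integer(n_proteins),
    protein_ids = ids, panel_map = panel,
    shared_panels = shared_panels, extra_panels = extra_panels,
    n_duplicates = as.integer(n_duplicates),
    truth = truth, within_pair_corr = within_pair_corr,
    lod_quantile = lod_quantile,
    lead_time_max_years = lead_time_max_years,
    survival_params = survival_params,
    duplicate_noise_sd = duplicate_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Marginal distributions used for case attributes, loosely matching the
# demographic structure of a smoking-history cohort consortium.
.histology_levels <- c("adenocarcinoma", "squamous", "large_cell",
                       "small_cell", "other")
.histology_probs <- c(0.34, 0.20, 0.04, 0.16, 0.26)
.stage_probs <- c(0.12, 0.11, 0.38, 0.39)  # TNM I..IV
.smoking_levels <- c("former_ge10", "former_lt10", "current_lt15",
                     "current_ge15")
.smoking_probs <- c(0.30, 0.16, 0.19, 0.35)

#' Generate a simulated matched case-control proteomics study
#'
#' For each matched pair, the two members' protein vectors are drawn from a
#' correlated multivariate normal (correlation `within_pair_corr` within the
#' pair, proteins independent given planted structure), and the case label is
#' assigned within the pair with probability
#' `exp(eta_1) / (exp(eta_1) + exp(eta_2))` where
#' `eta_i = sum_j beta_j(L) x_ij` and `beta_j(L) = beta0_j + beta_lead_j * L`.
#' The 1:1 conditional-logistic model therefore holds exactly with the
#' planted coefficients. Duplicated proteins appear as a noisy second assay
#' on another panel; values below each protein's LOD (a pooled quantile) are
#' masked; cohorts carry `NA` for panels they do not measure.
#'
#' @param config a [sim_config()] object.
#' @return A `sim_study` list with elements `subjects` (per-sample metadata),
#'   `matrix` (samples x assays, log2-scale, below-LOD values masked `NA`
#'   with the mask in `below_lod`), `below_lod` (logical mask, same shape),
#'   `annotations` (assay, protein, panel, lod, shared flag), and `truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ch <- config$cohorts
  n_sets <- sum(ch$n_sets)
  P <- config$n_proteins
  ids <- config$protein_ids
  rho <- config$within_pair_corr

  set_id <- sprintf("S%04d", seq_len(n_sets))
  cohort <- rep(ch$name, ch$n_sets)
  sex <- ifelse(stats::runif(n_sets) < 0.33, "female", "male")
  smoking_status <- sample(.smoking_levels, n_sets, TRUE, .smoking_probs)
  age_case <- round(stats::rnorm(n_sets, 65, 9), 1)
  age_ctrl <- round(age_case + stats::runif(n_sets, -1, 1), 1)
  lead_time <- stats::runif(n_sets, 0, config$lead_time_max_years)

  # member-level continuous smoking metrics, consistent with the shared
  # 4-category status (2 members per set)
  smoke_metrics <- function(status) {
    n <- length(status)
    cig <- numeric(n); yrs <- pmax(stats::rnorm(n, 38, 11), 5)
    cess <- numeric(n)
    cur_lt <- status == "current_lt15"; cur_ge <- status == "current_ge15"
    f_lt <- status == "former_lt10";   f_ge <- status == "former_ge10"
    cig[cur_lt] <- stats::runif(sum(cur_lt), 3, 14.5)
    cig[cur_ge] <- 15 + stats::rgamma(sum(cur_ge), 2, 0.25)
    cig[f_lt | f_ge] <- 5 + stats::rgamma(sum(f_lt | f_ge), 2, 0.15)
    cess[f_lt] <- stats::runif(sum(f_lt), 0.5, 9.5)
    cess[f_ge] <- 10 + stats::rexp(sum(f_ge), 1 / 8)
    data.frame(cigs_per_day = round(cig, 1), years_smoked = round(yrs, 1),
               years_since_cessation = round(cess, 1))
  }
  sm1 <- smoke_metrics(smoking_status)
  sm2 <- smoke_metrics(smoking_status)

  # latent standard-normal protein values for the two members of each pair:
  # x = sqrt(rho) * z_pair + sqrt(1 - rho) * z_member (marginal SD 1)
  zp <- matrix(stats::rnorm(n_sets * P), n_sets, P)
  x1 <- sqrt(rho) * zp + sqrt(1 - rho) * matrix(stats::rnorm(n_sets * P), n_sets, P)
  x2 <- sqrt(rho) * zp + sqrt(1 - rho) * matrix(stats::rnorm(n_sets * P), n_sets, P)

  # cross-sectional smoking association: shift by planted coefficient times
  # standardized intensity
  sa <- config$truth$smoking_assoc
  if (any(sa != 0)) {
    zint1 <- (sm1$cigs_per_day - 15) / 10
    zint2 <- (sm2$cigs_per_day - 15) / 10
    x1 <- x1 + outer(zint1, sa)
    x2 <- x2 + outer(zint2, sa)
  }

  # retrospective case assignment: P(member 1 is the case) = softmax of the
  # planted linear predictors, so the conditional likelihood is exact
  bl <- sweep(outer(lead_time, config$truth$beta_lead), 2,
              config$truth$beta0, "+")
  eta1 <- rowSums(bl * x1)
  eta2 <- rowSums(bl * x2)
  case_is_1 <- stats::runif(n_sets) < stats::plogis(eta1 - eta2)

  xcase <- ifelse(matrix(case_is_1, n_sets, P), x1, x2)
  xctrl <- ifelse(matrix(case_is_1, n_sets, P), x2, x1)

  histology <- sample(.histology_levels, n_sets, TRUE, .histology_probs)
  stage <- sample(1:4, n_sets, TRUE, .stage_probs)

  # post-diagnosis survival for cases: exponential with planted log-HR
  sp <- config$survival_params
  gl <- sweep(outer(lead_time, config$truth$gamma_lead), 2,
              config$truth$gamma_surv, "+")
  loghr <- rowSums(gl * xcase)
  t_death <- stats::rexp(n_sets, rate = exp(loghr) / sp$scale)
  t_cens <- if (sp$censor_rate > 0) stats::rexp(n_sets, sp$censor_rate) else Inf
  surv_time <- pmin(t_death, t_cens)
  death <- as.integer(t_death <= t_cens)

  risk_score <- function(sm) {
    0.03 * sm$cigs_per_day + 0.02 * sm$years_smoked -
      0.015 * sm$years_since_cessation + stats::rnorm(nrow(sm), 0, 0.7)
  }
  rs1 <- risk_score(sm1); rs2 <- risk_score(sm2)

  # member 1/2 smoking metrics and risk scores reassigned to case/control roles
  pick <- function(a, b) ifelse(case_is_1, a, b)
  sm_case <- data.frame(cigs_per_day = pick(sm1$cigs_per_day, sm2$cigs_per_day),
                        years_smoked = pick(sm1$years_smoked, sm2$years_smoked),
                        years_since_cessation = pick(sm1$years_since_cessation,
                                                     sm2$years_since_cessation))
  sm_ctrl <- data.frame(cigs_per_day = pick(sm2$cigs_per_day, sm1$cigs_per_day),
                        years_smoked = pick(sm2$years_smoked, sm1$years_smoked),
                        years_since_cessation = pick(sm2$years_since_cessation,
                                                     sm1$years_since_cessation))
  subjects <- rbind(
    cbind(data.frame(sample_id = paste0(set_id, "_case"), set_id = set_id,
                     cohort = cohort, case = 1L, sex = sex, age = age_case,
                     smoking_status = smoking_status,
                     stringsAsFactors = FALSE),
          sm_case,
          data.frame(lead_time = lead_time, histology = histology,
                     stage = stage, survival_time = surv_time, death = death,
                     risk_score = pick(rs1, rs2))),
    cbind(data.frame(sample_id = paste0(set_id, "_ctrl"), set_id = set_id,
                     cohort = cohort, case = 0L, sex = sex, age = age_ctrl,
                     smoking_status = smoking_status,
                     stringsAsFactors = FALSE),
          sm_ctrl,
          data.frame(lead_time = NA_real_, histology = NA_character_,
                     stage = NA_integer_, survival_time = NA_real_,
                     death = NA_integer_, risk_score = pick(rs2, rs1)))
  )
  subjects <- subjects[order(subjects$set_id, -subjects$case), ]
  rownames(subjects) <- NULL

  # assemble the assay matrix on an NPX-like log2 scale: protein baseline
  # means ~ N(3, 1), unit SD around them
  mu <- stats::rnorm(P, 3, 1)
  vals <- rbind(xcase, xctrl)  # first all cases (set order), then controls
  ord <- order(rep(set_id, 2), -rep(1:0, each = n_sets))
  vals <- vals[ord, , drop = FALSE]
  mat <- sweep(vals, 2, mu, "+")
  colnames(mat) <- ids
  rownames(mat) <- subjects$sample_id

  # duplicated assays: a noisy re-measurement on a different panel within the
  # same availability group, with a little extra missingness
  ndup <- config$n_duplicates
  annotations <- data.frame(assay = ids, protein = ids,
                            panel = config$panel_map,
                            shared = config$panel_map %in% config$shared_panels,
                            stringsAsFactors = FALSE)
  if (ndup > 0) {
    dup_idx <- seq_len(ndup)  # deterministic: first ndup proteins
    dmat <- mat[, dup_idx, drop = FALSE] +
      matrix(stats::rnorm(nrow(mat) * ndup, 0, config$duplicate_noise_sd),
             nrow(mat), ndup)
    extra_na <- matrix(stats::runif(length(dmat)) < 0.02, nrow(dmat))
    dmat[extra_na] <- NA
    colnames(dmat) <- paste0(ids[dup_idx], "_d")
    # place the duplicate on another panel of the same availability group
    dpanel <- vapply(dup_idx, function(i) {
      grp <- if (annotations$shared[i]) config$shared_panels else config$extra_panels
      grp <- setdiff(grp, annotations$panel[i])
      if (length(grp) == 0) annotations$panel[i] else grp[1 + (i %% length(grp))]
    }, character(1))
    annotations <- rbind(annotations,
                         data.frame(assay = colnames(dmat),
                                    protein = ids[dup_idx], panel = dpanel,
                                    shared = annotations$shared[dup_idx],
                                    stringsAsFactors = FALSE))
    mat <- cbind(mat, dmat)
  }

  # cohort panel availability: non-full-library cohorts miss the extra panels
  shared_assay <- annotations$shared[match(colnames(mat), annotations$assay)]
  full_lib <- ch$full_library[match(subjects$cohort, ch$name)]
  if (any(!shared_assay)) {
    mat[!full_lib, !shared_assay] <- NA
  }

  # below-LOD censoring at a pooled quantile of the measured values
  below <- matrix(FALSE, nrow(mat), ncol(mat),
                  dimnames = dimnames(mat))
  lod <- rep(-Inf, ncol(mat))
  if (config$lod_quantile > 0) {
    lod <- apply(mat, 2, stats::quantile, probs = config$lod_quantile,
                 na.rm = TRUE, names = FALSE)
    below <- sweep(mat, 2, lod, "<")
    below[is.na(below)] <- FALSE
    mat[below] <- NA
  }
  annotations$lod <- lod[match(annotations$assay, colnames(mat))]

  structure(list(subjects = subjects, matrix = mat, below_lod = below,
                 annotations = annotations, truth = config$truth,
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated matched case-control proteomics study\n")
  cat(sprintf("  %d matched sets (%d samples), %d cohorts\n",
              nrow(x$subjects) / 2, nrow(x$subjects),
              length(unique(x$subjects$cohort))))
  cat(sprintf("  %d assays for %d proteins; %.1f%% values below LOD\n",
              ncol(x$matrix), length(unique(x$annotations$protein)),
              100 * mean(x$below_lod)))
  invisible(x)
}

#' Write the study tables as delimited text
#'
#' Writes `matrix.tsv` (sample_id + one column per assay), `subjects.tsv`,
#' `annotations.tsv` and `truth.tsv` into `dir`. Missing values are written
#' as `NA`.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "subjects.tsv", "annotations.tsv",
                            "truth.tsv"))
  m <- data.frame(sample_id = rownames(study$matrix), study$matrix,
                  check.names = FALSE)
  utils::write.table(m, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$subjects, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$annotations, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read study tables written by [write_study()]
#'
#' @param dir directory containing `matrix.tsv`, `subjects.tsv`,
#'   `annotations.tsv` and (optionally) `truth.tsv`.
#' @return A `sim_study`-shaped list (the below-LOD mask is reconstructed
#'   from the annotations' LOD where values are missing).
#' @export
read_study <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE)
  m <- rd("matrix.tsv")
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$sample_id
  truth <- if (file.exists(file.path(dir, "truth.tsv"))) rd("truth.tsv") else NULL
  below <- is.na(mat)
  structure(list(subjects = rd("subjects.tsv"), matrix = mat,
                 below_lod = below, annotations = rd("annotations.tsv"),
                 truth = truth),
            class = "sim_study")
}
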