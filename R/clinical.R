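#' A synthetic mean-sojourn-time table
#'
#' Mean preclinical sojourn time (years) per TNM stage, sex, and histology.
#' These values are a SYNTHETIC stand-in with the qualitative structure of
#' published natural-history estimates (shorter dwell times at higher stage
#' and for small-cell tumors); they are not the published estimates, which
#' are supplied by the user as a delimited table when available.
#'
#' @return data.frame: stage (1-4), sex, histology, sojourn_years.
#' @export
synthetic_sojourn_table <- function() {
  grid <- expand.grid(stage = 1:4,
                      sex = c("female", "male"),
                      histology = c("adenocarcinoma", "squamous",
                                    "large_cell", "small_cell", "other"),
                      stringsAsFactors = FALSE)
  base <- c(`1` = 2.0, `2` = 1.2, `3` = 0.9, `4` = 0.6)
  hist_mult <- c(adenocarcinoma = 1.3, squamous = 1.0, large_cell = 0.9,
                 small_cell = 0.5, other = 1.0)
  sex_mult <- c(female = 1.1, male = 1.0)
  grid$sojourn_years <- round(base[as.character(grid$stage)] *
                                hist_mult[grid$histology] *
                                sex_mult[grid$sex], 3)
  grid
}

sojourn_lookup <- function(sojourn_table, stage, sex, histology) {
  i <- which(sojourn_table$stage == stage & sojourn_table$sex == sex &
               sojourn_table$histology == histology)
  if (length(i) != 1)
    stop("sojourn table has no unique entry for stage ", stage, ", ", sex,
         ", ", histology)
  sojourn_table$sojourn_years[i]
}

#' Back-calculate the stage at blood draw for one case
#'
#' Deterministic backward walk through mean preclinical sojourn times:
#' starting at the diagnosed stage, subtract that stage's mean sojourn time
#' from the lead time; while the remainder is positive, step to the
#' next-lower stage and subtract its sojourn time. The stage in which the
#' remainder becomes non-positive is the estimated stage at draw; a lead
#' time exceeding the total preclinical window returns the lowest modelled
#' stage.
#'
#' @param stage diagnosed TNM stage (integer, lowest modelled stage is 1).
#' @param sex,histology case attributes indexing the sojourn table.
#' @param lead_time years between blood draw and diagnosis (>= 0).
#' @param sojourn_table data.frame as [synthetic_sojourn_table()].
#' @return Integer estimated stage at blood draw.
#' @export
stage_at_blood_draw <- function(stage, sex, histology, lead_time,
                                sojourn_table = synthetic_sojourn_table()) {
  if (is.na(stage) || is.na(histology)) stop("missing stage or histology")
  if (lead_time < 0) stop("negative lead time")
  s <- as.integer(stage)
  remainder <- lead_time - sojourn_lookup(sojourn_table, s, sex, histology)
  while (remainder > 0 && s > 1) {
    s <- s - 1L
    remainder <- remainder - sojourn_lookup(sojourn_table, s, sex, histology)
  }
  s
}

#' Distribution of estimated stage at blood draw across cases
#'
#' Applies [stage_at_blood_draw()] to every case with complete stage and
#' histology information and tabulates the estimated stage-at-draw
#' proportions, including the cumulative proportion at stage 2 or earlier.
#'
#' @param subjects study metadata (cases identified by `case == 1`).
#' @param sojourn_table sojourn-time table.
#' @return List: `table` (stage, n, proportion), `prop_stage_le2`,
#'   `prop_stage_le1`, `n_cases_used`, `n_excluded`.
#' @export
summarize_stage_shift <- function(subjects,
                                  sojourn_table = synthetic_sojourn_table()) {
  cases <- subjects[subjects$case == 1L, ]
  ok <- !is.na(cases$stage) & !is.na(cases$histology) &
    !is.na(cases$lead_time)
  used <- cases[ok, ]
  if (nrow(used) == 0) stop("no case has complete stage/histology/lead time")
  est <- mapply(stage_at_blood_draw, used$stage, used$sex, used$histology,
                used$lead_time, MoreArgs = list(sojourn_table = sojourn_table))
  tab <- as.data.frame(table(stage = factor(est, levels = 1:4)),
                       stringsAsFactors = FALSE)
  names(tab) <- c("stage", "n")
  tab$proportion <- tab$n / nrow(used)
  list(table = tab,
       prop_stage_le2 = mean(est <= 2),
       prop_stage_le1 = mean(est <= 1),
       estimated_stage = est,
       n_cases_used = nrow(used), n_excluded = sum(!ok))
}

#' Post-diagnosis survival model with lead-time interaction
#'
#' Cox proportional hazards regression among cases, from diagnosis to death
#' from any cause, with the baseline hazard stratified by cohort and sex,
#' adjustment for age, and a protein-by-lead-time interaction so that the
#' protein main effect is its log hazard ratio at the time of diagnosis
#' (lead time 0). Efron handling of ties.
#'
#' @param values protein values aligned to `subjects` rows.
#' @param subjects study metadata; cases need `survival_time`, `death`,
#'   `lead_time`, `age`, `cohort`, `sex`.
#' @param protein label.
#' @return One-row data.frame: protein, log_hr_at_dx, hr, ci_low, ci_high,
#'   p, interaction (per year), se_interaction, p_interaction, n_events.
#' @export
fit_cox <- function(values, subjects, protein = "protein") {
  cases <- subjects$case == 1L
  df <- data.frame(time = subjects$survival_time[cases],
                   death = subjects$death[cases],
                   age = subjects$age[cases],
                   x = as.numeric(values)[cases],
                   lead = subjects$lead_time[cases],
                   cohort = subjects$cohort[cases],
                   sex = subjects$sex[cases])
  df <- df[stats::complete.cases(df), ]
  if (sum(df$death) == 0) stop("no events in any stratum")
  fit <- survival::coxph(
    survival::Surv(time, death) ~ age + x + x:lead +
      survival::strata(cohort, sex),
    data = df, ties = "efron")
  cf <- summary(fit)$coefficients
  b <- cf["x", "coef"]; se <- cf["x", "se(coef)"]
  if (!is.finite(b) || abs(b) > 15)
    stop("non-convergence: monotone partial likelihood for the protein term")
  data.frame(protein = protein, log_hr_at_dx = b, hr = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             se = se, p = cf["x", "Pr(>|z|)"],
             interaction = cf["x:lead", "coef"],
             se_interaction = cf["x:lead", "se(coef)"],
             p_interaction = cf["x:lead", "Pr(>|z|)"],
             n_events = sum(df$death), n = nrow(df),
             stringsAsFactors = FALSE)
}
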