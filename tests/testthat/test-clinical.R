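# independent brute-force oracle for the backward stage walk
oracle_stage <- function(stage, sex, histology, lead, tab) {
  s <- stage
  rem <- lead
  repeat {
    rem <- rem - tab$sojourn_years[tab$stage == s & tab$sex == sex &
                                     tab$histology == histology]
    if (rem <= 0 || s == 1) return(s)
    s <- s - 1
  }
}

test_that("stage at draw follows the backward sojourn walk", {
  tab <- data.frame(stage = rep(1:3, 2), sex = rep(c("male", "female"), each = 3),
                    histology = "squamous",
                    sojourn_years = rep(c(2, 1.5, 1), 2))
  # zero lead time: diagnosed stage
  expect_equal(stage_at_blood_draw(3, "male", "squamous", 0, tab), 3L)
  # the forced example: 2.0 - 1.0 = 1.0 < 1.5 -> stage II
  expect_equal(stage_at_blood_draw(3, "male", "squamous", 2.0, tab), 2L)
  # lead exceeding the whole window: lowest modelled stage
  expect_equal(stage_at_blood_draw(3, "male", "squamous", 50, tab), 1L)
  # monotone in lead time
  stages <- vapply(seq(0, 6, 0.25), function(L)
    stage_at_blood_draw(3, "male", "squamous", L, tab), integer(1))
  expect_true(all(diff(stages) <= 0))
  expect_error(stage_at_blood_draw(3, "male", "squamous", -1, tab),
               "negative lead time")
  expect_error(stage_at_blood_draw(NA, "male", "squamous", 1, tab),
               "missing stage")
})

test_that("stage-shift summary matches the per-case oracle on 1000 cases", {
  st <- quick_study(n_sets = 1000, n_proteins = 2, seed = 91)
  # short sojourn times so lead times actually shift stages
  tab <- synthetic_sojourn_table()
  tab$sojourn_years <- tab$sojourn_years / 2
  shift <- summarize_stage_shift(st$subjects, tab)
  cases <- st$subjects[st$subjects$case == 1L, ]
  oracle <- mapply(oracle_stage, cases$stage, cases$sex, cases$histology,
                   cases$lead_time, MoreArgs = list(tab = tab))
  expect_identical(shift$estimated_stage, as.integer(oracle))
  expect_equal(shift$prop_stage_le2, mean(oracle <= 2), tolerance = 1e-12)
  expect_equal(sum(shift$table$n), 1000)

  # all lead times zero: distribution equals the diagnosed-stage distribution
  st0 <- st; st0$subjects$lead_time[st0$subjects$case == 1L] <- 0
  s0 <- summarize_stage_shift(st0$subjects, tab)
  expect_equal(s0$table$n,
               as.vector(table(factor(cases$stage, levels = 1:4))))

  # sojourn times all longer than the maximum lead: no stage changes
  tab_long <- synthetic_sojourn_table(); tab_long$sojourn_years <- 10
  s_long <- summarize_stage_shift(st$subjects, tab_long)
  expect_identical(s_long$estimated_stage, as.integer(cases$stage))
})

test_that("the stratified Cox model recovers planted survival effects", {
  st <- quick_study(n_sets = 2000, n_proteins = 2, gamma_surv = 0.3,
                    gamma_lead = -0.1, seed = 93,
                    cohorts = data.frame(name = c("A", "B"),
                                         n_sets = c(1000, 1000),
                                         full_library = TRUE))
  x <- st$matrix[, 1] - mean(st$matrix[, 1])
  fit <- fit_cox(x, st$subjects, "P0001")
  expect_lt(abs(fit$log_hr_at_dx - 0.3), 1.96 * fit$se * 1.5)
  expect_lt(abs(fit$interaction - (-0.1)), 1.96 * fit$se_interaction * 1.5)
  expect_gt(fit$ci_high, fit$hr); expect_lt(fit$ci_low, fit$hr)

  # invariance to a positive rescaling of survival time
  st2 <- st; st2$subjects$survival_time <- st2$subjects$survival_time * 3.7
  fit2 <- fit_cox(x, st2$subjects, "P0001")
  expect_equal(fit2$log_hr_at_dx, fit$log_hr_at_dx, tolerance = 1e-8)

  # a null protein's CI covers HR = 1
  fit_null <- fit_cox(st$matrix[, 2], st$subjects, "P0002")
  expect_true(fit_null$ci_low < 1 && fit_null$ci_high > 1)
})

test_that("stratification absorbs cohort-specific baseline hazards", {
  # cohort B has a 6x baseline hazard; stratified fit stays unbiased while
  # an unstratified fit of the same data is pulled away from the truth
  set.seed(95)
  n <- 3000
  cohort <- rep(c("A", "B"), each = n / 2)
  x <- stats::rnorm(n)
  # protein higher in the high-hazard cohort: confounding by cohort
  x[cohort == "B"] <- x[cohort == "B"] + 1.5
  base <- ifelse(cohort == "A", 0.2, 1.2)
  time <- stats::rexp(n, base * exp(0.3 * x))
  subj <- data.frame(case = 1L, survival_time = time, death = 1L,
                     age = stats::rnorm(n, 65, 5), lead_time = 0,
                     cohort = cohort, sex = "male", x = x)
  strat <- fit_cox(x, subj)
  unstrat <- survival::coxph(survival::Surv(time, rep(1, n)) ~ x)
  expect_lt(abs(strat$log_hr_at_dx - 0.3), 3 * strat$se)
  expect_gt(abs(unname(coef(unstrat)) - 0.3), abs(strat$log_hr_at_dx - 0.3))

  # stratified partial likelihood = sum of per-stratum partial likelihoods
  fullfit <- survival::coxph(survival::Surv(survival_time, death) ~ x +
                               survival::strata(cohort), data = subj)
  fa <- survival::coxph(survival::Surv(survival_time, death) ~ x,
                        data = subj[subj$cohort == "A", ],
                        init = coef(fullfit),
                        control = survival::coxph.control(iter.max = 0))
  fb <- survival::coxph(survival::Surv(survival_time, death) ~ x,
                        data = subj[subj$cohort == "B", ],
                        init = coef(fullfit),
                        control = survival::coxph.control(iter.max = 0))
  expect_equal(fullfit$loglik[2], fa$loglik[2] + fb$loglik[2],
               tolerance = 1e-6)
})

test_that("survival modelling errors are informative", {
  st <- quick_study(n_sets = 50, n_proteins = 2, seed = 97)
  st$subjects$death[st$subjects$case == 1L] <- 0L
  expect_error(fit_cox(st$matrix[, 1], st$subjects), "no events")
})
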