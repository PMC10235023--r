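test_that("symmetric differences give an exactly null estimate", {
  subj <- subjects_for_diffs(4)
  fit <- fit_clogit(values_for_diffs(c(1, 1, -1, -1)), subj)
  expect_equal(fit$beta, 0, tolerance = 1e-10)
  expect_equal(fit$or_sd, 1, tolerance = 1e-10)
})

test_that("Newton estimate matches brute-force grid maximization", {
  diffs_sets <- list(
    c(1, 1, 1, 1, 1, 1, -1, -1, -1, 1),
    c(0.5, -1.2, 2, 0.3, -0.4, 1.1, -2.2, 0.8),
    rnorm_fixed <- {set.seed(17); stats::rnorm(12)}
  )
  for (d in diffs_sets) {
    subj <- subjects_for_diffs(length(d))
    fit <- fit_clogit(values_for_diffs(d), subj)
    expect_lt(abs(fit$beta - grid_clogit(d)), 1e-3)
    # the CI is exactly exp(beta +/- 1.96 se)
    expect_equal(fit$ci_low, exp(fit$beta - 1.96 * fit$se), tolerance = 1e-12)
    expect_equal(fit$ci_high, exp(fit$beta + 1.96 * fit$se), tolerance = 1e-12)
  }
})

test_that("monotone likelihood raises a non-convergence error", {
  subj <- subjects_for_diffs(5)
  expect_error(fit_clogit(values_for_diffs(rep(1, 5)), subj),
               "monotone likelihood")
  expect_error(fit_clogit(values_for_diffs(c(-1, -2, -0.5, -1, -3)), subj),
               "monotone likelihood")
})

test_that("fewer than two usable sets is an error", {
  subj <- subjects_for_diffs(2)
  v <- values_for_diffs(c(1, NA))
  v[4] <- NA  # kill the second set entirely
  expect_error(fit_clogit(v, subj), "insufficient data")
})

test_that("estimates agree with the survival package on a simulated study", {
  st <- quick_study(n_sets = 300, n_proteins = 2, beta0 = log(1.8), seed = 41)
  mine <- fit_clogit(st$matrix[, 1], st$subjects, protein = "P0001")
  df <- data.frame(y = st$subjects$case, x = st$matrix[, 1],
                   set = st$subjects$set_id)
  # survival's conditional logistic fit (exact partial likelihood)
  ref <- survival::coxph(survival::Surv(rep(1, nrow(df)), y) ~ x +
                           survival::strata(set),
                         data = df, ties = "exact")
  expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
})

test_that("set-level constants in covariates leave the fit unchanged", {
  st <- quick_study(n_sets = 150, n_proteins = 2, beta0 = log(1.5), seed = 43)
  x <- st$matrix[, 1]
  z <- stats::rnorm(nrow(st$subjects))
  base <- fit_clogit(x, st$subjects, covariates = cbind(z = z))
  # add a set-specific constant to the covariate: differences are unchanged
  shift <- stats::rnorm(length(unique(st$subjects$set_id)))
  z2 <- z + shift[match(st$subjects$set_id, unique(st$subjects$set_id))]
  shifted <- fit_clogit(x, st$subjects, covariates = cbind(z = z2))
  expect_equal(base$beta, shifted$beta, tolerance = 1e-10)
  expect_equal(base$se, shifted$se, tolerance = 1e-10)
  expect_equal(base$p, shifted$p, tolerance = 1e-10)
})

test_that("rescaling the protein rescales beta and preserves the Wald test", {
  st <- quick_study(n_sets = 200, n_proteins = 2, beta0 = log(1.6), seed = 44)
  f1 <- fit_clogit(st$matrix[, 1], st$subjects)
  f2 <- fit_clogit(3 * st$matrix[, 1], st$subjects)
  expect_equal(f2$beta, f1$beta / 3, tolerance = 1e-8)
  expect_equal(f2$p, f1$p, tolerance = 1e-8)
})

test_that("smoking adjustment: within-set constants cancel; confounding attenuates", {
  st <- quick_study(n_sets = 200, n_proteins = 2, beta0 = log(1.7), seed = 45)
  x <- st$matrix[, 1]
  crude <- fit_clogit(x, st$subjects)
  # covariates identical within every set cancel in the conditional
  # likelihood: adjusted estimate equals the crude one exactly
  setnum <- as.numeric(factor(st$subjects$set_id))
  adj0 <- fit_clogit(x, st$subjects,
                     covariates = cbind(a = setnum, b = setnum^2))
  expect_equal(adj0$beta, crude$beta, tolerance = 1e-12)
  expect_equal(adj0$se, crude$se, tolerance = 1e-12)

  # hand-built confounded design: case status driven only by a smoking-like
  # covariate correlated with the protein
  set.seed(46)
  n <- 800
  s_case <- stats::rnorm(n, 0.8); s_ctrl <- stats::rnorm(n, 0)
  x_case <- s_case + stats::rnorm(n, 0, 0.6)
  x_ctrl <- s_ctrl + stats::rnorm(n, 0, 0.6)
  subj <- subjects_for_diffs(n)
  v <- numeric(2 * n); v[seq(1, 2 * n, 2)] <- x_case; v[seq(2, 2 * n, 2)] <- x_ctrl
  sv <- numeric(2 * n); sv[seq(1, 2 * n, 2)] <- s_case; sv[seq(2, 2 * n, 2)] <- s_ctrl
  crude2 <- fit_clogit(v, subj)
  adj2 <- fit_clogit(v, subj, covariates = cbind(smoke = sv))
  expect_gt(crude2$beta, 0)
  expect_lt(abs(adj2$beta), abs(crude2$beta))  # attenuated toward the null
})

test_that("adjustment changes little when the protein effect is smoking-free", {
  st <- quick_study(n_sets = 600, n_proteins = 2, beta0 = log(1.8),
                    smoking_assoc = 0, seed = 47)
  crude <- fit_clogit(st$matrix[, 1], st$subjects, protein = "P0001")
  adj <- fit_adjusted_clogit(st$matrix[, 1], st$subjects, protein = "P0001")
  expect_lt(abs(adj$beta - crude$beta), 2 * crude$se)
  expect_true(adj$adjusted)
})

test_that("smoking linear models recover planted coefficients in controls", {
  hits <- 0L; nrep <- 30L
  for (s in seq_len(nrep)) {
    st <- quick_study(n_sets = 500, n_proteins = 2, smoking_assoc = 0.3,
                      seed = 100 + s)
    # planted slope is on standardized intensity (cigs - 15)/10
    z <- (st$subjects$cigs_per_day - 15) / 10
    r <- fit_smoking_linear(st$matrix[, 1], st$subjects, "intensity",
                            "controls")
    est10 <- r$coefficient * 10  # per standardized-intensity unit
    hits <- hits + (abs(est10 - 0.3) < 1.96 * r$se * 10)
  }
  expect_gte(hits, 0.9 * nrep - 2)
})

test_that("smoking linear p-values are uniform under the null", {
  ps <- vapply(seq_len(120), function(s) {
    st <- quick_study(n_sets = 120, n_proteins = 2, seed = 300 + s)
    fit_smoking_linear(st$matrix[, 2], st$subjects, "intensity",
                       "combined")$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a constant smoking metric raises a rank-deficiency error", {
  st <- quick_study(n_sets = 60, n_proteins = 2, seed = 50)
  st$subjects$cigs_per_day <- 10
  expect_error(fit_smoking_linear(st$matrix[, 1], st$subjects, "intensity",
                                  "controls"),
               "rank-deficient")
})
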