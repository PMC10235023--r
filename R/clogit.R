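#' @useDynLib protomark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Within-set case-minus-control differences for a 1:1 matched study.
# Returns a sets x variables matrix; rows are matched sets.
set_differences <- function(values, subjects) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(subjects))
  cs <- subjects$case == 1L
  ord_case <- order(subjects$set_id[cs])
  ord_ctrl <- order(subjects$set_id[!cs])
  ids_case <- subjects$set_id[cs][ord_case]
  ids_ctrl <- subjects$set_id[!cs][ord_ctrl]
  common <- intersect(ids_case, ids_ctrl)
  d <- values[cs, , drop = FALSE][ord_case, , drop = FALSE][match(common, ids_case), , drop = FALSE] -
       values[!cs, , drop = FALSE][ord_ctrl, , drop = FALSE][match(common, ids_ctrl), , drop = FALSE]
  rownames(d) <- common
  d
}

# Newton-Raphson maximization of the 1:1 conditional likelihood
#   prod_s exp(b'x_case_s) / (exp(b'x_case_s) + exp(b'x_ctrl_s))
# on the within-set difference matrix D (complete rows only).
# |score|_inf < tol or 50 iterations; step-halving on likelihood decrease.
clogit_newton <- function(D, tol = 1e-8, maxit = 50L) {
  D <- D[stats::complete.cases(D), , drop = FALSE]
  k <- ncol(D); n <- nrow(D)
  if (n < 2) stop("insufficient data: fewer than 2 usable matched sets")
  for (j in seq_len(k)) {
    nz <- D[D[, j] != 0, j]
    if (length(nz) > 0 && (all(nz > 0) || all(nz < 0)))
      stop("monotone likelihood: no finite estimate for covariate '",
           colnames(D)[j] %||% paste0("x", j),
           "' (all within-set differences share one sign)")
  }
  b <- rep(0, k)
  loglik <- function(b) sum(stats::plogis(drop(D %*% b), log.p = TRUE))
  ll <- loglik(b)
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(D %*% b))
    score <- drop(crossprod(D, 1 - p))
    info <- crossprod(D * sqrt(p * (1 - p)))
    step <- solve(info, score)
    # step-halving if the likelihood would decrease
    lam <- 1
    repeat {
      b_new <- b + lam * step
      ll_new <- loglik(b_new)
      if (ll_new >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    b <- b_new; ll <- ll_new
    if (max(abs(score)) < tol) break
  }
  p <- stats::plogis(drop(D %*% b))
  info <- crossprod(D * sqrt(p * (1 - p)))
  se <- sqrt(diag(solve(info)))
  list(beta = b, se = se, loglik = ll, n_sets = n,
       converged = max(abs(drop(crossprod(D, 1 - p)))) < 1e-6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assoc_row <- function(protein, fit, adjusted) {
  b <- fit$beta[1]; se <- fit$se[1]
  data.frame(protein = protein, beta = b, se = se,
             or_sd = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(b / se)),
             n_sets = fit$n_sets, adjusted = adjusted,
             stringsAsFactors = FALSE)
}

#' Conditional logistic regression for one protein on 1:1 matched sets
#'
#' Fits the matched-pair conditional likelihood by Newton iterations on the
#' within-set case-minus-control contrasts, giving the log odds ratio per
#' unit (per SD for a standardized protein), Wald standard error from the
#' observed information, the 95% CI `exp(beta +/- 1.96 se)`, and a two-sided
#' Wald p-value. Sets with a missing protein value in either member are
#' dropped.
#'
#' @param values numeric vector of protein values aligned to `subjects` rows,
#'   or a samples x variables matrix whose first column is the protein.
#' @param subjects metadata with `sample_id`, `set_id`, `case`.
#' @param covariates optional matrix/data.frame of additional covariates
#'   (same row alignment) entered alongside the protein.
#' @param protein label for the output row.
#' @return One-row data.frame (an association result): protein, beta, se,
#'   or_sd, ci_low, ci_high, p, n_sets, adjusted.
#' @examples
#' cfg <- sim_config(cohorts = data.frame(name = "A", n_sets = 80,
#'                                        full_library = TRUE),
#'                   n_proteins = 5, n_shared = 5, n_panels = 2,
#'                   n_shared_panels = 2, n_duplicates = 0,
#'                   lod_quantile = 0, seed = 7)
#' st <- generate_study(cfg)
#' fit_clogit(st$matrix[, "P0001"], st$subjects, protein = "P0001")
#' @export
fit_clogit <- function(values, subjects, covariates = NULL,
                       protein = "protein") {
  v <- cbind(as.matrix(values)[, 1, drop = FALSE])
  colnames(v) <- protein
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    v <- cbind(v, cv)
  }
  D <- set_differences(v, subjects)
  if (ncol(D) > 1) {
    # covariates constant within every set difference out of the likelihood
    zero <- apply(D[, -1, drop = FALSE], 2,
                  function(cc) all(cc[!is.na(cc)] == 0))
    D <- D[, c(TRUE, !zero), drop = FALSE]
  }
  fit <- clogit_newton(D)
  assoc_row(protein, fit, adjusted = !is.null(covariates))
}

#' Smoking-adjusted conditional logistic regression
#'
#' As [fit_clogit()], with cigarettes per day, years smoked, and years since
#' cessation entered as continuous covariates (each standardized over the
#' study before differencing).
#'
#' @inheritParams fit_clogit
#' @export
fit_adjusted_clogit <- function(values, subjects, protein = "protein") {
  sm <- as.matrix(subjects[, c("cigs_per_day", "years_smoked",
                               "years_since_cessation")])
  sm <- scale(sm)
  fit_clogit(values, subjects, covariates = sm, protein = protein)
}

#' Crude (and optionally adjusted) associations for every protein
#'
#' Runs [fit_clogit()] per column of the standardized matrix. The crude path
#' uses a fast vectorized univariate Newton solve shared with the resampling
#' selection algorithm.
#'
#' @param matrix standardized samples x proteins matrix.
#' @param subjects metadata with `set_id` and `case`.
#' @param adjusted if `TRUE`, adjust for smoking intensity, duration, and
#'   years since cessation.
#' @param min_sets minimum complete sets required per protein.
#' @return data.frame of association results, one row per protein.
#' @export
associate_all <- function(matrix, subjects, adjusted = FALSE, min_sets = 2L) {
  if (!adjusted) {
    D <- set_differences(matrix, subjects)
    f <- clogit_uni_many(D, min_sets = min_sets)
    out <- data.frame(protein = colnames(matrix), beta = f$beta, se = f$se,
                      or_sd = exp(f$beta),
                      ci_low = exp(f$beta - 1.96 * f$se),
                      ci_high = exp(f$beta + 1.96 * f$se),
                      p = f$p, n_sets = f$n_sets, adjusted = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  res <- lapply(colnames(matrix), function(pid) {
    tryCatch(fit_adjusted_clogit(matrix[, pid], subjects, protein = pid),
             error = function(e) {
               data.frame(protein = pid, beta = NA_real_, se = NA_real_,
                          or_sd = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          n_sets = NA_integer_, adjusted = TRUE,
                          stringsAsFactors = FALSE)
             })
  })
  do.call(rbind, res)
}

# Vectorized univariate conditional-logistic fits, one per column of the
# difference matrix D (NA-tolerant). Columns with fewer than min_sets
# complete sets, a separating sign pattern, or a diverging estimate get NA.
clogit_uni_many <- function(D, min_sets = 2L, maxit = 40L, tol = 1e-10) {
  D0 <- D
  D0[is.na(D0)] <- 0
  ok <- !is.na(D)
  n_sets <- colSums(ok)
  npos <- colSums(D > 0, na.rm = TRUE)
  nneg <- colSums(D < 0, na.rm = TRUE)
  usable <- n_sets >= min_sets & npos > 0 & nneg > 0
  beta <- rep(NA_real_, ncol(D))
  if (!any(usable)) {
    return(list(beta = beta, se = beta, p = beta, n_sets = n_sets))
  }
  beta[usable] <- 0
  for (it in seq_len(maxit)) {
    B <- matrix(beta, nrow(D), ncol(D), byrow = TRUE)
    eta <- D0 * B
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    score <- colSums(D0 * (1 - p) * ok)
    info <- colSums(D0 * D0 * w * ok)
    step <- ifelse(info > 0, score / info, 0)
    step <- pmax(pmin(step, 2), -2)  # damp huge first steps
    beta <- beta + step
    if (max(abs(step), na.rm = TRUE) < tol) break
  }
  diverged <- !is.na(beta) & abs(beta) > 12
  beta[diverged] <- NA
  B <- matrix(beta, nrow(D), ncol(D), byrow = TRUE)
  p <- stats::plogis(D0 * B)
  info <- colSums(D0 * D0 * p * (1 - p) * ok)
  se <- ifelse(info > 0, sqrt(1 / info), NA_real_)
  se[is.na(beta)] <- NA
  pv <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, se = se, p = pv, n_sets = n_sets)
}

#' Cross-sectional linear model of a protein on a smoking metric
#'
#' Ordinary least squares of the standardized protein on one smoking metric
#' (intensity, duration, or years since cessation), adjusted for cohort
#' (indicator contrasts), age, sex, and 4-category smoking status; the
#' combined population additionally adjusts for case status.
#'
#' @param values protein values aligned to `subjects` rows.
#' @param subjects metadata (needs cohort, age, sex, smoking_status, case and
#'   the metric columns).
#' @param metric one of `"intensity"`, `"duration"`, `"cessation"`.
#' @param population `"controls"` or `"combined"`.
#' @param protein label for the output row.
#' @return One-row data.frame: protein, metric, coefficient, se, p, population.
#' @export
fit_smoking_linear <- function(values, subjects,
                               metric = c("intensity", "duration", "cessation"),
                               population = c("controls", "combined"),
                               protein = "protein") {
  metric <- match.arg(metric)
  population <- match.arg(population)
  mcol <- switch(metric, intensity = "cigs_per_day",
                 duration = "years_smoked",
                 cessation = "years_since_cessation")
  df <- data.frame(y = as.numeric(values), m = subjects[[mcol]],
                   age = subjects$age, sex = subjects$sex,
                   cohort = subjects$cohort,
                   smoking_status = subjects$smoking_status,
                   case = subjects$case)
  if (population == "controls") df <- df[df$case == 0L, ]
  if (metric == "cessation") {
    df <- df[grepl("^former", df$smoking_status), ]
  }
  df <- df[stats::complete.cases(df), ]
  # adjustment terms with no variation in the analysis subset drop out
  terms <- c("m", "age")
  for (v in c("sex", "cohort", "smoking_status"))
    if (length(unique(df[[v]])) >= 2) terms <- c(terms, sprintf("factor(%s)", v))
  if (population == "combined" && length(unique(df$case)) >= 2)
    terms <- c(terms, "case")
  form <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(form, data = df)
  cf <- summary(fit)$coefficients
  if (is.na(stats::coef(fit)["m"]) || !"m" %in% rownames(cf))
    stop("rank-deficient design: smoking metric is collinear with the ",
         "adjustment set")
  data.frame(protein = protein, metric = metric,
             coefficient = cf["m", 1], se = cf["m", 2], p = cf["m", 4],
             population = population, n = nrow(df),
             stringsAsFactors = FALSE)
}
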