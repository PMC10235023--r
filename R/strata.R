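#' Lead-time category of each matched set
#'
#' Categories `<1`, `1-2`, `2-3` years between blood draw and diagnosis.
#' @keywords internal
lead_time_category <- function(lead_time) {
  cut(lead_time, breaks = c(0, 1, 2, 3), labels = c("<1y", "1-2y", "2-3y"),
      include.lowest = TRUE, right = FALSE)
}

#' Stratified odds ratios with heterogeneity and trend tests
#'
#' Fits the matched conditional-logistic model separately within strata of a
#' set-level variable. Case attributes (histology, stage, lead time) define
#' the stratum of a whole set; cohort and smoking status are shared within a
#' set by matching. Heterogeneity across strata is tested by Cochran's Q on
#' the stratum log ORs with inverse-variance weights (chi-squared, k-1 df).
#' For ordinal strata (stage, lead time) a trend is tested by
#' inverse-variance-weighted linear regression of the log OR on the category
#' score.
#'
#' @param values standardized protein values aligned to `subjects` rows.
#' @param subjects study metadata.
#' @param stratum_var one of `"histology"`, `"stage"`, `"smoking_status"`,
#'   `"cohort"`, `"lead_time"`.
#' @param min_sets strata with fewer complete sets are omitted and flagged.
#' @param protein label for the output.
#' @return List of class `stratified_result`: `strata` (per-stratum
#'   association rows), `q_stat`, `p_het`, `trend_slope`, `p_trend` (ordinal
#'   only), `omitted` (underpowered strata).
#' @export
stratified_or <- function(values, subjects,
                          stratum_var = c("histology", "stage",
                                          "smoking_status", "cohort",
                                          "lead_time"),
                          min_sets = 10L, protein = "protein") {
  stratum_var <- match.arg(stratum_var)
  cases <- subjects[subjects$case == 1L, ]
  stratum_of_set <- switch(stratum_var,
    histology = cases$histology,
    stage = ifelse(cases$stage <= 2, "early (1-2)", "late (3-4)"),
    smoking_status = ifelse(grepl("^current", cases$smoking_status),
                            "current", "former"),
    cohort = cases$cohort,
    lead_time = as.character(lead_time_category(cases$lead_time)))
  names(stratum_of_set) <- cases$set_id
  ordinal <- stratum_var %in% c("stage", "lead_time")

  D <- set_differences(as.matrix(values), subjects)
  strat <- stratum_of_set[rownames(D)]
  lev <- if (stratum_var == "lead_time") c("<1y", "1-2y", "2-3y")
         else sort(unique(stats::na.omit(strat)))
  rows <- list(); omitted <- character(0)
  for (s in lev) {
    d <- D[!is.na(strat) & strat == s, , drop = FALSE]
    d <- d[!is.na(d[, 1]), , drop = FALSE]
    if (nrow(d) < min_sets) { omitted <- c(omitted, s); next }
    fit <- tryCatch(clogit_newton(d), error = function(e) NULL)
    if (is.null(fit)) { omitted <- c(omitted, s); next }
    r <- assoc_row(protein, fit, adjusted = FALSE)
    r$stratum <- s
    rows[[s]] <- r
  }
  strata <- if (length(rows)) do.call(rbind, rows) else NULL
  q_stat <- p_het <- trend_slope <- p_trend <- NA_real_
  if (!is.null(strata) && nrow(strata) >= 2) {
    b <- strata$beta; w <- 1 / strata$se^2
    cq <- cochran_q(b, strata$se)
    q_stat <- cq$q
    p_het <- cq$p
    if (ordinal) {
      score <- match(strata$stratum, lev)
      xw <- sum(w * score) / sum(w)
      sxx <- sum(w * (score - xw)^2)
      if (sxx > 0) {
        trend_slope <- sum(w * (score - xw) * b) / sxx
        se_slope <- sqrt(1 / sxx)
        p_trend <- 2 * stats::pnorm(-abs(trend_slope / se_slope))
      }
    }
  }
  structure(list(protein = protein, stratum_var = stratum_var,
                 strata = strata, q_stat = q_stat, p_het = p_het,
                 trend_slope = trend_slope, p_trend = p_trend,
                 omitted = omitted),
            class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("Stratified ORs for %s by %s\n", x$protein, x$stratum_var))
  if (!is.null(x$strata))
    print(x$strata[, c("stratum", "or_sd", "ci_low", "ci_high", "p", "n_sets")],
          row.names = FALSE)
  cat(sprintf("  Q = %.3f, p_het = %.3g", x$q_stat, x$p_het))
  if (!is.na(x$p_trend)) cat(sprintf(", p_trend = %.3g", x$p_trend))
  cat("\n")
  invisible(x)
}

#' Cochran's Q test for heterogeneity of stratum estimates
#'
#' Inverse-variance weighted heterogeneity statistic
#' `Q = sum w_i (b_i - b_bar_w)^2` with `w_i = 1/se_i^2`, referred to a
#' chi-squared distribution on `k - 1` degrees of freedom.
#'
#' @param beta stratum log odds ratios.
#' @param se their standard errors.
#' @return List with `q` and `p`.
#' @examples
#' cochran_q(c(0.1, 0.5), c(0.1, 0.1))  # Q = 8, p ~ 0.0047
#' @export
cochran_q <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 2, all(se > 0))
  w <- 1 / se^2
  bw <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bw)^2)
  list(q = q, p = stats::pchisq(q, df = length(beta) - 1, lower.tail = FALSE))
}

#' Rank-concordance AUC (Mann-Whitney, ties count one half)
#'
#' @param score numeric risk score.
#' @param label 0/1 case status.
#' @return The AUC.
#' @export
auc_mw <- function(score, label) {
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("need both cases and controls to compute AUC")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental discrimination of a protein over a baseline risk score
#'
#' Computes the concordance AUC of the baseline risk score for case status,
#' and the AUC of the linear predictor from an unconditional logistic model
#' of case status on baseline score plus protein; reports both and their
#' difference.
#'
#' @param values protein values aligned to `subjects` rows.
#' @param subjects metadata with `case` and the baseline score column.
#' @param baseline_col name of the baseline risk score column.
#' @param protein label.
#' @return One-row data.frame: protein, auc_baseline, auc_with_protein,
#'   delta_auc, n.
#' @export
delta_auc <- function(values, subjects, baseline_col = "risk_score",
                      protein = "protein") {
  df <- data.frame(y = subjects$case, base = subjects[[baseline_col]],
                   x = as.numeric(values))
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$y)) < 2)
    stop("need both cases and controls to compute AUC")
  a0 <- auc_mw(df$base, df$y)
  fit <- suppressWarnings(stats::glm(y ~ base + x, family = stats::binomial(),
                                     data = df))
  lp <- drop(stats::model.matrix(fit) %*% stats::coef(fit))
  a1 <- auc_mw(lp, df$y)
  data.frame(protein = protein, auc_baseline = a0, auc_with_protein = a1,
             delta_auc = a1 - a0, n = nrow(df), stringsAsFactors = FALSE)
}
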