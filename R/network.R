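#' Residualize proteins against nuisance covariates
#'
#' Per protein, ordinary least squares residuals against the covariate
#' design (default: age, sex, cohort, smoking status). With no covariates the
#' matrix is only centered. Missing protein values stay missing.
#'
#' @param matrix samples x proteins matrix.
#' @param subjects metadata aligned to rows.
#' @param covariates character vector of metadata columns to remove.
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(matrix, subjects,
                        covariates = c("age", "sex", "cohort",
                                       "smoking_status")) {
  if (length(covariates) == 0)
    return(scale(matrix, center = TRUE, scale = FALSE))
  df <- subjects[, covariates, drop = FALSE]
  for (v in covariates)
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  # single-level factors carry no variance to remove
  keep <- vapply(df, function(cc) is.numeric(cc) ||
                   length(levels(cc)) >= 2, logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0) return(scale(matrix, center = TRUE, scale = FALSE))
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  out <- matrix
  out[] <- NA
  cc_x <- stats::complete.cases(df)
  for (j in seq_len(ncol(matrix))) {
    ok <- cc_x & !is.na(matrix[, j])
    if (sum(ok) <= ncol(X)) next
    fit <- stats::lm.fit(X[ok, , drop = FALSE], matrix[ok, j])
    out[ok, j] <- fit$residuals
  }
  out
}

#' Pairwise Pearson correlations of residualized proteins, by group
#'
#' @param residual_matrix residual matrix from [residualize()].
#' @param subjects metadata with `case`.
#' @param group `"cases"` or `"controls"`.
#' @param min_pairs pairs with fewer complete observations are set `NA`.
#' @return Symmetric correlation matrix (pairwise-complete observations).
#' @export
pairwise_correlations <- function(residual_matrix, subjects,
                                  group = c("cases", "controls"),
                                  min_pairs = 3L) {
  group <- match.arg(group)
  rows <- if (group == "cases") subjects$case == 1L else subjects$case == 0L
  m <- residual_matrix[rows, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(m))
  cc[obs < min_pairs] <- NA
  diag(cc) <- 1
  cc
}

# one graphical-lasso fit on a covariance/correlation matrix
glasso_adjacency <- function(S, rho) {
  fit <- glasso_cpp(S, rho)
  d <- diag(fit$theta)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("graphical lasso produced a non-positive-definite precision ",
         "estimate; increase the penalty")
  fit$adj
}

#' Stability-selected sparse partial-correlation network
#'
#' Estimates a sparse conditional-dependence (partial correlation) network
#' among residualized proteins in one group (cases or controls) by graphical
#' lasso with stability selection: the penalty is chosen on a grid by a
#' StARS-style instability criterion over random 50% subsamples, and an edge
#' is called stable when its precision entry is nonzero in at least
#' `stability_threshold` of the subsamples at the chosen penalty.
#'
#' @param residual_matrix residual matrix from [residualize()].
#' @param subjects metadata with `case`.
#' @param group `"cases"` or `"controls"`.
#' @param penalty_grid decreasing vector of L1 penalties; default a
#'   log-spaced grid from the largest absolute off-diagonal correlation down
#'   to a tenth of it.
#' @param n_resamples number of subsamples (without replacement).
#' @param subsample_fraction fraction of samples per subsample.
#' @param stability_threshold minimum selection frequency for a stable edge.
#' @param instability_target StARS instability bound used to pick the
#'   penalty.
#' @param seed RNG seed; the result is a pure function of data, config, seed.
#' @return A `network_result`: `edges` (protein_a, protein_b, frequency,
#'   stable), `degrees` (stable-edge degree per protein), `penalty` chosen,
#'   `penalty_grid`, `instability`, `group`, `n_resamples`.
#' @export
stable_network <- function(residual_matrix, subjects,
                           group = c("cases", "controls"),
                           penalty_grid = NULL, n_resamples = 100L,
                           subsample_fraction = 0.5,
                           stability_threshold = 0.9,
                           instability_target = 0.05, seed = 1L) {
  group <- match.arg(group)
  stopifnot(n_resamples >= 2, ncol(residual_matrix) >= 2)
  rows <- if (group == "cases") subjects$case == 1L else subjects$case == 0L
  m <- residual_matrix[rows, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  if (nrow(m) < 10) stop("too few complete samples for network estimation")
  S_full <- stats::cor(m)
  if (is.null(penalty_grid)) {
    rmax <- max(abs(S_full[upper.tri(S_full)]))
    penalty_grid <- exp(seq(log(rmax), log(rmax / 10), length.out = 8))
  }
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)

  nsub <- max(2L, floor(nrow(m) * subsample_fraction))
  up <- upper.tri(S_full)
  freq <- matrix(0, sum(up), length(penalty_grid))
  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    idx <- sample(nrow(m), nsub)
    S <- stats::cor(m[idx, , drop = FALSE])
    for (g in seq_along(penalty_grid)) {
      adj <- glasso_adjacency(S, penalty_grid[g])
      freq[, g] <- freq[, g] + adj[up]
    }
  }
  freq <- freq / n_resamples
  # StARS: instability per penalty, monotonized from the sparsest end
  instab <- colMeans(2 * freq * (1 - freq))
  instab_mono <- cummax(instab)
  ok <- which(instab_mono <= instability_target)
  chosen <- if (length(ok)) max(ok) else 1L
  rho <- penalty_grid[chosen]
  f <- freq[, chosen]
  pairs <- which(up, arr.ind = TRUE)
  ids <- colnames(residual_matrix)
  edges <- data.frame(protein_a = ids[pairs[, 1]],
                      protein_b = ids[pairs[, 2]],
                      frequency = f, stable = f >= stability_threshold,
                      stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(p), ids)
  if (any(edges$stable)) {
    t1 <- table(factor(edges$protein_a[edges$stable], levels = ids))
    t2 <- table(factor(edges$protein_b[edges$stable], levels = ids))
    deg <- as.integer(t1 + t2)
    names(deg) <- ids
  }
  structure(list(edges = edges, degrees = deg, penalty = rho,
                 penalty_grid = penalty_grid, instability = instab,
                 group = group, n_resamples = n_resamples,
                 stability_threshold = stability_threshold),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("Stability network (%s): %d stable edge(s) of %d pairs, penalty %.3f\n",
              x$group, sum(x$edges$stable), nrow(x$edges), x$penalty))
  invisible(x)
}
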