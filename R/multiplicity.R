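#' Effective number of tests from principal components
#'
#' The effective number of tests (ENT) is the number of principal components
#' of the protein correlation matrix needed to explain 95% of the variance in
#' protein abundance. Used as the Bonferroni denominator in the
#' discovery-replication criterion (`0.05 / ENT`). Missing entries are
#' mean-imputed (zero on a standardized matrix) solely for the
#' eigendecomposition; all-constant proteins are excluded with a warning.
#'
#' @param matrix samples x proteins matrix (typically cohort-standardized).
#' @param explained target cumulative explained-variance fraction.
#' @return List of class `ent_result`: `ent`, `threshold` (= 0.05/ent),
#'   `explained_curve` (cumulative fractions), `n_proteins`, `n_samples`.
#' @examples
#' m <- matrix(rnorm(200), 20, 10)
#' effective_number_of_tests(m)$ent
#' @export
effective_number_of_tests <- function(matrix, explained = 0.95) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stop("need at least 2 samples")
  sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    warning(sum(const), " all-constant protein(s) excluded from the ",
            "eigendecomposition")
    matrix <- matrix[, !const, drop = FALSE]
  }
  z <- scale(matrix)
  z[is.na(z)] <- 0
  cc <- stats::cor(z)
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  curve <- cumsum(ev) / sum(ev)
  ent <- which(curve >= explained)[1]
  structure(list(ent = as.integer(ent), threshold = 0.05 / ent,
                 explained_curve = curve,
                 n_proteins = ncol(matrix), n_samples = nrow(matrix)),
            class = "ent_result")
}

#' @export
print.ent_result <- function(x, ...) {
  cat(sprintf("Effective number of tests: %d of %d proteins (n = %d)\n",
              x$ent, x$n_proteins, x$n_samples))
  cat(sprintf("  Bonferroni threshold 0.05/ENT = %.3g\n", x$threshold))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, `min over j >= i of p_(j) * m / j`, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed and preserved).
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
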