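#' Substitute below-LOD values by LOD/sqrt(2)
#'
#' Replaces every masked (below limit-of-detection) entry of the assay matrix
#' by that assay's LOD divided by sqrt(2), the manufacturer-recommended
#' substitution for left-censored relative-abundance values. Unmasked entries
#' are returned unchanged and the mask itself is kept for QC.
#'
#' @param matrix samples x assays numeric matrix (masked entries may be `NA`).
#' @param below_lod logical mask of the same shape marking below-LOD entries.
#' @param annotations data.frame with columns `assay` and `lod`.
#' @return The matrix with masked entries substituted.
#' @export
substitute_lod <- function(matrix, below_lod, annotations) {
  stopifnot(identical(dim(matrix), dim(below_lod)))
  lod <- annotations$lod[match(colnames(matrix), annotations$assay)]
  need <- colSums(below_lod) > 0
  if (any(need & (is.na(lod) | !is.finite(lod))))
    stop("missing or non-finite LOD for assays with below-LOD values: ",
         paste(colnames(matrix)[need & (is.na(lod) | !is.finite(lod))],
               collapse = ", "))
  if (any(need & lod == 0))
    warning("assay with LOD = 0 has below-LOD values; substituting 0")
  sub <- matrix(rep(lod / sqrt(2), each = nrow(matrix)), nrow(matrix))
  matrix[below_lod] <- sub[below_lod]
  matrix
}

#' Resolve duplicated protein assays
#'
#' Some proteins are measured on more than one assay panel. For each such
#' protein one assay is retained: the one with the lowest missingness, with
#' the highest variance (computed on the samples where all duplicates of the
#' protein were measured) as tie-break. Retained columns are renamed to the
#' protein id.
#'
#' @param matrix samples x assays matrix after LOD substitution.
#' @param annotations data.frame with columns `assay` and `protein`.
#' @return List with `matrix` (one column per protein) and `decisions`
#'   (data.frame: protein, chosen assay, dropped assays).
#' @export
resolve_duplicates <- function(matrix, annotations) {
  ann <- annotations[match(colnames(matrix), annotations$assay), ]
  groups <- split(seq_len(ncol(matrix)), ann$protein)
  keep <- integer(0)
  dec <- list()
  for (pid in names(groups)) {
    idx <- groups[[pid]]
    if (length(idx) == 1L) {
      keep <- c(keep, idx)
      next
    }
    miss <- colMeans(is.na(matrix[, idx, drop = FALSE]))
    cand <- idx[miss == min(miss)]
    if (length(cand) > 1L) {
      both <- rowSums(is.na(matrix[, idx, drop = FALSE])) == 0
      v <- apply(matrix[both, cand, drop = FALSE], 2, stats::var)
      cand <- cand[which.max(v)]
    } else cand <- cand[1]
    keep <- c(keep, cand)
    dec[[pid]] <- data.frame(protein = pid, chosen = colnames(matrix)[cand],
                             dropped = paste(colnames(matrix)[setdiff(idx, cand)],
                                             collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  keep <- sort(keep)
  out <- matrix[, keep, drop = FALSE]
  colnames(out) <- ann$protein[keep]
  list(matrix = out,
       decisions = if (length(dec)) do.call(rbind, dec)
                   else data.frame(protein = character(), chosen = character(),
                                   dropped = character()))
}

#' Standardize each protein within cohort
#'
#' Centers and scales each protein to mean 0 and SD 1 within every cohort,
#' over non-missing entries; missing entries stay missing. Proteins with zero
#' within-cohort variance are set to `NA` in that cohort and flagged.
#'
#' @param matrix samples x proteins matrix.
#' @param subjects metadata with `sample_id` and `cohort`, aligned to rows.
#' @return List with `matrix` and `flagged` (data.frame protein/cohort pairs
#'   excluded for zero variance or too few values).
#' @export
standardize_within_cohort <- function(matrix, subjects) {
  stopifnot(nrow(matrix) == nrow(subjects))
  flagged <- list()
  for (co in unique(subjects$cohort)) {
    r <- subjects$cohort == co
    sub <- matrix[r, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    sd <- apply(sub, 2, stats::sd, na.rm = TRUE)
    n_ok <- colSums(!is.na(sub))
    bad <- which(!is.na(sd) & (sd == 0 | n_ok < 2))
    std <- sweep(sweep(sub, 2, mu, "-"), 2, sd, "/")
    if (length(bad)) {
      std[, bad] <- NA
      flagged[[co]] <- data.frame(protein = colnames(matrix)[bad], cohort = co,
                                  reason = ifelse(sd[bad] == 0, "zero variance",
                                                  "fewer than 2 values"),
                                  stringsAsFactors = FALSE)
    }
    matrix[r, ] <- std
  }
  list(matrix = matrix,
       flagged = if (length(flagged)) do.call(rbind, c(flagged, make.row.names = FALSE))
                 else data.frame(protein = character(), cohort = character(),
                                 reason = character()))
}

#' Per-protein below-LOD QC report
#'
#' Computes, per assay, the percentage of values below LOD per cohort and
#' pooled, and flags assays with pooled below-LOD percentage under 20% as
#' passing QC.
#'
#' @param below_lod logical mask, samples x assays.
#' @param subjects metadata aligned to rows (needs `cohort`).
#' @param measured optional logical matrix marking entries actually measured
#'   (panels available); defaults to all `TRUE`.
#' @return data.frame: assay, per-cohort percentages, pooled percentage,
#'   `passes_lod_qc`.
#' @export
protein_qc <- function(below_lod, subjects, measured = NULL) {
  if (is.null(measured)) measured <- matrix(TRUE, nrow(below_lod), ncol(below_lod))
  pooled <- 100 * colSums(below_lod & measured) / pmax(colSums(measured), 1)
  out <- data.frame(assay = colnames(below_lod),
                    pct_below_lod = pooled,
                    passes_lod_qc = pooled < 20,
                    stringsAsFactors = FALSE)
  for (co in unique(subjects$cohort)) {
    r <- subjects$cohort == co
    m <- measured[r, , drop = FALSE]
    out[[paste0("pct_below_lod_", co)]] <-
      100 * colSums(below_lod[r, , drop = FALSE] & m) / pmax(colSums(m), 1)
  }
  rownames(out) <- NULL
  out
}

#' Run the full measurement-level preprocessing
#'
#' LOD substitution, duplicate resolution, then within-cohort
#' standardization, in that order, with a QC report.
#'
#' @param study a `sim_study` (or list with `matrix`, `below_lod`,
#'   `annotations`, `subjects`).
#' @return List: `matrix` (standardized, one column per protein), `qc`
#'   (below-LOD report), `duplicate_decisions`, `flagged` (zero-variance
#'   exclusions).
#' @export
preprocess_study <- function(study) {
  measured <- !is.na(study$matrix) | study$below_lod
  m <- substitute_lod(study$matrix, study$below_lod, study$annotations)
  qc <- protein_qc(study$below_lod, study$subjects, measured)
  dup <- resolve_duplicates(m, study$annotations)
  std <- standardize_within_cohort(dup$matrix, study$subjects)
  list(matrix = std$matrix, qc = qc, duplicate_decisions = dup$decisions,
       flagged = std$flagged)
}
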