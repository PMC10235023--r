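#' Validate study input tables
#'
#' Checks matched-set completeness (exactly one case and one control per
#' set, same cohort, sex and smoking category, ages within one year), LOD
#' availability for assays with masked values, and panel consistency between
#' the matrix and the annotations. Violations are reported, not raised.
#'
#' @param study a `sim_study`-shaped list (`subjects`, `matrix`,
#'   `below_lod`, `annotations`).
#' @param age_tolerance maximum within-set age difference in years.
#' @return data.frame of violations (`kind`, `where`, `detail`); zero rows
#'   when the study is valid.
#' @export
validate_inputs <- function(study, age_tolerance = 1) {
  v <- list()
  add <- function(kind, where, detail)
    v[[length(v) + 1]] <<- data.frame(kind = kind, where = where,
                                      detail = detail,
                                      stringsAsFactors = FALSE)
  s <- study$subjects
  for (sid in unique(s$set_id)) {
    m <- s[s$set_id == sid, ]
    if (sum(m$case == 1L) != 1L || sum(m$case == 0L) != 1L) {
      add("set_composition", sid,
          sprintf("%d case(s), %d control(s)", sum(m$case == 1L),
                  sum(m$case == 0L)))
      next
    }
    if (length(unique(m$cohort)) != 1L)
      add("matching", sid, "case and control from different cohorts")
    if (length(unique(m$sex)) != 1L)
      add("matching", sid, "sex differs within set")
    if (length(unique(m$smoking_status)) != 1L)
      add("matching", sid, "smoking category differs within set")
    if (abs(diff(m$age)) > age_tolerance + 1e-9)
      add("matching", sid, sprintf("age difference %.2f years", abs(diff(m$age))))
  }
  if (!is.null(study$matrix)) {
    if (!identical(rownames(study$matrix), s$sample_id))
      add("alignment", "matrix", "matrix rows do not match subjects")
    ann <- study$annotations
    unknown <- setdiff(colnames(study$matrix), ann$assay)
    for (a in unknown) add("annotation", a, "assay missing from annotations")
    if (!is.null(study$below_lod)) {
      lod <- ann$lod[match(colnames(study$matrix), ann$assay)]
      need <- colSums(study$below_lod) > 0
      bad <- which(need & (is.na(lod) | !is.finite(lod)))
      for (a in colnames(study$matrix)[bad])
        add("lod", a, "below-LOD values but no finite LOD")
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(kind = character(), where = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

# per-stage seeds derived from the global seed by a stable hash of the stage
# name, so toggling one stage cannot shift another stage's randomness
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' Run the full discovery pipeline
#'
#' Executes the stages simulate (or load) -> preprocess -> associate ->
#' select -> stratify/discriminate -> network -> clinical course, writing
#' each stage's table as tab-separated text into `out_dir` together with a
#' JSON run manifest (seed, config hash, stage timings, exclusion counts).
#' Disabled stages are skipped.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `seed`; either `simulate` (arguments to [sim_config()]) or `input_dir`
#'   (tables written by [write_study()]); optional `stages` (character
#'   vector of stages to run); `selection` (arguments to
#'   [resampling_config()]); `network` (arguments to [stable_network()]);
#'   `sojourn_table` (path to a delimited table, defaults to the packaged
#'   synthetic one); `baseline_score` (metadata column name);
#'   `top_proteins` (how many selected/top proteins to carry into the
#'   downstream stages).
#' @param out_dir output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "preprocess", "associate", "select",
                  "stratify", "network", "course")
  stages <- config$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config_hash = config_hash(config),
                   stages = stages, timings = list(), exclusions = list())
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- load or simulate -----------------------------------------------------
  if (!is.null(config$input_dir)) {
    study <- read_study(config$input_dir)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- stage_seed(seed, "simulate")
    # YAML configs carry cohorts / planted effects as lists of records
    if (!is.null(sim_args$cohorts) && !is.data.frame(sim_args$cohorts))
      sim_args$cohorts <- do.call(rbind, lapply(sim_args$cohorts, as.data.frame))
    planted <- sim_args$planted
    sim_args$planted <- NULL
    cfg0 <- do.call(sim_config, sim_args)
    if (!is.null(planted)) {
      for (pe in planted) cfg0$truth <- do.call(plant_effect,
                                                c(list(cfg0$truth), pe))
    }
    study <- generate_study(cfg0)
    if ("simulate" %in% stages) write_study(study, out_dir)
  }
  viol <- validate_inputs(study)
  if (nrow(viol) > 0) {
    wt(viol, "violations")
    stop("input validation failed (", nrow(viol), " violation(s)); see ",
         file.path(out_dir, "violations.tsv"))
  }
  manifest$timings$simulate <- tic() - t0

  # --- preprocess -----------------------------------------------------------
  t0 <- tic()
  pp <- preprocess_study(study)
  mat <- pp$matrix
  if ("preprocess" %in% stages) {
    wt(pp$qc, "qc_report")
    wt(pp$duplicate_decisions, "duplicate_decisions")
  }
  manifest$exclusions$zero_variance <- nrow(pp$flagged)
  manifest$timings$preprocess <- tic() - t0

  # --- associate ------------------------------------------------------------
  assoc <- NULL
  if (any(c("associate", "select", "stratify", "network", "course") %in% stages)) {
    t0 <- tic()
    assoc <- associate_all(mat, study$subjects)
    if ("associate" %in% stages) wt(assoc, "associations")
    manifest$timings$associate <- tic() - t0
  }

  # --- select ---------------------------------------------------------------
  selected <- character(0)
  if ("select" %in% stages) {
    t0 <- tic()
    sel_args <- config$selection %||% list()
    sel_args$seed <- stage_seed(seed, "select")
    have <- unique(study$subjects$cohort)
    if (is.null(sel_args$forced_discovery_cohorts))
      sel_args$forced_discovery_cohorts <-
        intersect(c("EPIC", "NSHDS"), have)
    sel <- resample_select(mat, study$subjects,
                           do.call(resampling_config, sel_args))
    wt(sel$table, "selection")
    wt(sel$iteration_log, "selection_iterations")
    manifest$ent <- sel$ent$ent
    selected <- sel$table$protein[sel$table$selected]
    manifest$timings$select <- tic() - t0
  }
  # downstream stages run on the selected proteins, topped up with the
  # strongest remaining associations to top_proteins
  top_n <- config$top_proteins %||% 10L
  focus <- utils::head(union(selected, assoc$protein[order(assoc$p)]),
                       max(top_n, length(selected)))

  # --- stratify + discrimination --------------------------------------------
  if ("stratify" %in% stages) {
    t0 <- tic()
    strat_rows <- list(); disc_rows <- list()
    score_col <- config$baseline_score %||% "risk_score"
    for (pid in focus) {
      for (sv in c("histology", "stage", "smoking_status", "cohort",
                   "lead_time")) {
        sr <- stratified_or(mat[, pid], study$subjects, sv, protein = pid)
        if (!is.null(sr$strata)) {
          r <- sr$strata
          r$stratum_var <- sv; r$q_stat <- sr$q_stat; r$p_het <- sr$p_het
          r$p_trend <- sr$p_trend
          strat_rows[[paste(pid, sv)]] <- r
        }
      }
      disc_rows[[pid]] <- delta_auc(mat[, pid], study$subjects,
                                    baseline_col = score_col, protein = pid)
    }
    if (length(strat_rows)) wt(do.call(rbind, strat_rows), "stratified")
    if (length(disc_rows)) wt(do.call(rbind, disc_rows), "discrimination")
    manifest$timings$stratify <- tic() - t0
  }

  # --- network --------------------------------------------------------------
  if ("network" %in% stages && length(focus) >= 2) {
    t0 <- tic()
    net_args <- config$network %||% list()
    resid <- residualize(mat[, focus, drop = FALSE], study$subjects)
    edges <- list()
    for (grp in c("cases", "controls")) {
      args <- c(list(residual_matrix = resid, subjects = study$subjects,
                     group = grp, seed = stage_seed(seed, paste0("network_", grp))),
                net_args)
      nr <- do.call(stable_network, args)
      e <- nr$edges; e$group <- grp
      edges[[grp]] <- e
    }
    wt(do.call(rbind, edges), "network_edges")
    manifest$timings$network <- tic() - t0
  }

  # --- clinical course ------------------------------------------------------
  if ("course" %in% stages) {
    t0 <- tic()
    st <- if (!is.null(config$sojourn_table))
      utils::read.table(config$sojourn_table, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    else synthetic_sojourn_table()
    shift <- summarize_stage_shift(study$subjects, st)
    wt(shift$table, "stage_at_draw")
    surv_rows <- lapply(focus, function(pid)
      tryCatch(fit_cox(mat[, pid], study$subjects, protein = pid),
               error = function(e) NULL))
    surv_rows <- surv_rows[!vapply(surv_rows, is.null, logical(1))]
    if (length(surv_rows)) wt(do.call(rbind, surv_rows), "survival")
    manifest$stage_le2_at_draw <- shift$prop_stage_le2
    manifest$timings$course <- tic() - t0
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
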