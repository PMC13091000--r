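## End-to-end orchestration: simulate -> tensors -> ALPS -> QC -> models.

#' Read and validate a run configuration
#'
#' YAML with optional blocks `phantom`, `cohort` (argument overrides for
#' [phantomSpec()] / [cohortSpec()]), `placement` (overrides for
#' [autoPlacementParams()]), `qc` (group_var, k), `models` (outcomes to
#' fit), plus top-level `seed` and `output_dir`.  The returned list is
#' fully populated so a run is reproducible from its config alone.
#'
#' @param path YAML file path; alternatively a list already in memory.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 42L)
  cfg$output_dir <- cfg$output_dir %||% "dtialps-run"
  cfg$phantom <- cfg$phantom %||% list()
  cfg$cohort <- cfg$cohort %||% list()
  cfg$placement <- cfg$placement %||% list()
  cfg$qc <- utils::modifyList(list(group_var = "group", k = 1.5),
                              cfg$qc %||% list())
  cfg$models <- cfg$models %||%
    list(outcomes = c("alps_bilateral", "alps_left", "alps_right"),
         ei = TRUE)
  for (blk in c("phantom", "cohort", "placement"))
    if (!is.list(cfg[[blk]]))
      stop("config validation: block '", blk, "' must be a mapping")
  bad <- setdiff(names(cfg$phantom), names(formals(phantomSpec)))
  if (length(bad)) stop("config validation: unknown phantom fields: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$cohort), names(formals(cohortSpec)))
  if (length(bad)) stop("config validation: unknown cohort fields: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$placement), names(formals(autoPlacementParams)))
  if (length(bad)) stop("config validation: unknown placement fields: ",
                        paste(bad, collapse = ", "))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Two strands, both seeded from the config: (1) imaging — build the tensor
#' phantom, simulate a diffusion-weighted series, fit tensors, place the
#' ROIs automatically and compute the ALPS index plus the CC Dxx control;
#' (2) cohort — simulate the longitudinal table and MRS subset, apply the
#' IQR/bilateral QC rules, fit the trajectory mixed models per outcome with
#' BH-FDR over the hemisphere family, and fit the E/I regression.  Writes
#' CSV/JSON outputs and a provenance record to `output_dir`.
#'
#' @param config path to a YAML config or a list (see [readRunConfig()]).
#' @param seed overrides the config seed.
#' @return (invisibly) list with `alps`, `cc_control`, `cohort`, `qc`,
#'   `lmm` (per outcome), `fdr`, `ei`, and `provenance`.
#' @export
runPipeline <- function(config, seed = NULL) {
  cfg <- readRunConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  ## -- imaging strand ------------------------------------------------------
  pspec <- do.call(phantomSpec, c(cfg$phantom,
                                  if (!"seed" %in% names(cfg$phantom))
                                    list(seed = cfg$seed)))
  ph <- buildTensorPhantom(pspec)
  dwi <- phantomToDwi(ph$tensor, s0 = 1, noise_sd = pspec@noise_sd,
                      seed = pspec@seed)
  tv <- reorientToCanonical(fitTensorLogLinear(dwi))
  pl <- do.call(autoPlacementParams,
                c(list(slab_z = pspec@slab_z), cfg$placement))
  fa <- faMap(tv)
  slab <- array(FALSE, dim(fa@data))
  slab[, , pl@slab_z[1]:pl@slab_z[2]] <- TRUE
  e1 <- principalDirection(tv, mask = slab)
  rois <- placeRoisAuto(fa, e1, pl, include_cc = TRUE)
  comp <- tensorComponents(tv)
  alps <- computeAlps(comp$Dxx, comp$Dyy, comp$Dzz, rois)
  cc <- computeCcControl(comp$Dxx, rois)

  ## -- cohort strand -------------------------------------------------------
  cspec <- do.call(cohortSpec, c(cfg$cohort,
                                 if (!"seed" %in% names(cfg$cohort))
                                   list(seed = cfg$seed)))
  cohort <- simulateCohort(cspec)
  qc <- filterAlpsTable(cohort, group_var = cfg$qc$group_var, k = cfg$qc$k)
  fits <- list()
  for (oc in cfg$models$outcomes) {
    mask <- switch(oc, alps_left = "keep_left", alps_right = "keep_right",
                   "keep_bilateral")
    fits[[oc]] <- fitTrajectoryLmm(qc$table, outcome = oc,
                                   keep_mask = mask)
  }
  grp_term <- grep("^group", fits[[1]]@coefficients$term, value = TRUE)[1]
  pv <- vapply(fits, function(f)
    f@coefficients$p[f@coefficients$term == grp_term], numeric(1))
  fdr <- bhFdr(pv, labels = names(fits))
  mrs <- simulateMrs(cohort, cspec)
  ei <- if (isTRUE(cfg$models$ei)) fitEiOls(mrs) else NULL

  ## -- outputs -------------------------------------------------------------
  out <- cfg$output_dir
  writeCohortTable(qc$table, file.path(out, "cohort_alps.csv"))
  writeCohortTable(mrs, file.path(out, "mrs.csv"))
  writeFilterReport(qc$report_left, file.path(out, "filter_left.json"))
  writeFilterReport(qc$report_right, file.path(out, "filter_right.json"))
  writeRoiSet(rois, file.path(out, "rois.json"))
  lmm_json <- lapply(fits, function(f)
    list(model_used = f@model_used, converged = f@converged,
         n_obs = f@n_obs, n_participants = f@n_participants,
         coefficients = f@coefficients))
  jsonlite::write_json(
    list(alps = list(left = alps@alps_left, right = alps@alps_right,
                     bilateral = alps@alps_bilateral,
                     qc_flags = alps@qc_flags),
         cc_control = cc, lmm = lmm_json, fdr = fdr,
         ei = if (!is.null(ei))
           list(r_squared = ei@r_squared, n = ei@n,
                coefficients = ei@coefficients)),
    file.path(out, "models.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  prov <- list(package_version = as.character(utils::packageVersion("dtialps")),
               seed = cfg$seed,
               config_hash = sum(utils::head(
                 utf8ToInt(paste(deparse(cfg), collapse = "")), 1e5)),
               n_scans = nrow(cohort),
               n_scans_kept_bilateral = sum(qc$table$keep_bilateral),
               n_mrs = nrow(mrs),
               outputs = c("cohort_alps.csv", "mrs.csv", "filter_left.json",
                           "filter_right.json", "rois.json", "models.json"))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(alps = alps, cc_control = cc, cohort = cohort, qc = qc,
                 lmm = fits, fdr = fdr, ei = ei, provenance = prov))
}

#' Batch contingency tests from a counts table
#'
#' Reads a CSV with columns label, a, b, c, d (2x2 cells row-wise:
#' a b / c d) and runs [contingencyTest()] on each row — the workflow used
#' for demographic-table group comparisons.
#'
#' @param counts_path CSV path, or a data.frame.
#' @return data.frame with label, test_used, statistic, p.
#' @export
cmdTable1 <- function(counts_path) {
  tab <- if (is.data.frame(counts_path)) counts_path else
    utils::read.csv(counts_path, stringsAsFactors = FALSE)
  need <- c("label", "a", "b", "c", "d")
  if (!all(need %in% names(tab)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- contingencyTest(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
    data.frame(label = tab$label[i], test_used = r@test_used,
               statistic = r@statistic, p = r@p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
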