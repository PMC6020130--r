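#' Run the full connectome analysis pipeline
#'
#' End-to-end orchestration over a synthetic cohort: simulation of
#' per-subject connectivity matrices and motion traces, head-motion
#' quality control (excluded subjects are dropped from every
#' downstream table), metric computation across the proportional
#' threshold grid with null-normalized small-worldness,
#' permutation-based group comparison, clinical-association scans for
#' both clinical scores, and hub detection from group-mean nodal
#' metrics averaged across the threshold grid. All result tables plus
#' a reproducibility manifest (configuration values, derived stage
#' seeds, package version and a configuration hash) are written to
#' \code{config$outputDir}. Identical configuration and master seed
#' reproduce byte-identical outputs.
#'
#' @param config configuration list from [loadConfig()] /
#'   [defaultRunConfig()].
#' @return invisibly, a list with the in-memory results: cohort, qc,
#'   metrics, groupResults, associations, hubs, paths.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  outFile <- function(name) file.path(config$outputDir, name)
  seeds <- list(
    simulate = deriveStageSeed(config$seed, "simulate"),
    motion = deriveStageSeed(config$seed, "motion"),
    nulls = deriveStageSeed(config$seed, "nulls"),
    permutation = deriveStageSeed(config$seed, "permutation"),
    scan = deriveStageSeed(config$seed, "scan")
  )

  # -- simulate ------------------------------------------------------
  sim <- tryCatch(
    makeCohort(cohortSpec(nPatients = config$nPatients,
                          nControls = config$nControls,
                          seed = seeds$simulate)),
    error = function(e) stop("[simulate] ", conditionMessage(e))
  )
  cohort <- sim$cohort

  # -- motion QC -----------------------------------------------------
  qc <- tryCatch({
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      trace <- makeMotionTrace(config$nVolumes, config$motionAmplitude,
                               seed = seeds$motion + i)
      res <- motionQC(trace, limit = config$motionLimitMm,
                      radius = config$rotationRadiusMm)
      data.frame(subject = cohort$subject[i],
                 max_trans_mm = res$maxTransMm,
                 max_rot_mm = res$maxRotMm,
                 decision = res$decision,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }, error = function(e) stop("[qc] ", conditionMessage(e)))
  retained <- qc$subject[qc$decision == "retain"]
  cohort <- cohort[cohort$subject %in% retained, ]
  connectomes <- sim$connectomes[retained]
  if (length(unique(cohort$group)) < 2L) {
    stop("[qc] quality control removed an entire group")
  }

  # -- graph metrics -------------------------------------------------
  grid <- thresholdGrid(config$thresholdMin, config$thresholdMax,
                        config$thresholdStep)
  metrics <- tryCatch(
    computeMetrics(connectomes, thresholds = grid, nNull = config$nNull,
                   seed = seeds$nulls),
    error = function(e) stop("[metrics] ", conditionMessage(e))
  )

  # -- group comparison ----------------------------------------------
  groupResults <- tryCatch(
    groupComparison(metrics, cohort, nPerm = config$nPerm,
                    seed = seeds$permutation, q = config$fdrQ),
    error = function(e) stop("[group-test] ", conditionMessage(e))
  )

  # -- clinical associations (patients only) -------------------------
  associations <- tryCatch({
    out <- list()
    for (sc in c("puts", "ygtss")) {
      out[[sc]] <- clinicalAssociationScan(
        metrics, cohort, score = sc, q = config$fdrQ,
        nPerm = config$nPerm, seed = seeds$scan
      )
    }
    out
  }, error = function(e) stop("[association] ", conditionMessage(e)))

  # -- hubs: group-mean nodal metrics averaged over the grid ---------
  hubs <- tryCatch({
    nod <- metrics$nodal
    rows <- lapply(unique(cohort$group), function(g) {
      subj <- cohort$subject[cohort$group == g]
      sub <- nod[nod$subject %in% subj, ]
      mDeg <- tapply(sub$value[sub$metric == "degree"],
                     sub$node[sub$metric == "degree"], mean)
      mBtw <- tapply(sub$value[sub$metric == "betweenness"],
                     sub$node[sub$metric == "betweenness"], mean)
      hubIdx <- suppressWarnings(detectHubs(mDeg, mBtw, zCut = config$hubZ))
      if (!length(hubIdx)) return(NULL)
      data.frame(group = g, node = as.integer(names(mDeg))[hubIdx],
                 name = roiLabelTable()$name[as.integer(names(mDeg))[hubIdx]],
                 mean_degree = unname(mDeg[hubIdx]),
                 mean_betweenness = unname(mBtw[hubIdx]),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(), node = integer(), name = character(),
                 mean_degree = numeric(), mean_betweenness = numeric())
  }, error = function(e) stop("[hubs] ", conditionMessage(e)))

  # -- write everything ----------------------------------------------
  writeCohortTable(sim$cohort, outFile("cohort.tsv"))
  .writeTSV(qc, outFile("qc.tsv"))
  .writeTSV(metrics$nodal, outFile("metrics_nodal.tsv"))
  .writeTSV(metrics$global, outFile("metrics_global.tsv"))
  .writeTSV(groupResults, outFile("group_results.tsv"))
  .writeTSV(associations$puts, outFile("association_puts.tsv"))
  .writeTSV(associations$ygtss, outFile("association_ygtss.tsv"))
  .writeTSV(hubs, outFile("hubs.tsv"))

  cfgPath <- outFile("config.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("dtiConnectome"))),
    paste0("config_md5: ", unname(tools::md5sum(cfgPath))),
    paste0("master_seed: ", config$seed),
    vapply(names(seeds), function(s) {
      paste0("seed_", s, ": ", seeds[[s]])
    }, character(1)),
    paste0("subjects_retained: ", nrow(cohort)),
    paste0("threshold_levels: ", length(grid))
  )
  writeLines(manifest, outFile("manifest.txt"))

  invisible(list(cohort = cohort, qc = qc, metrics = metrics,
                 groupResults = groupResults, associations = associations,
                 hubs = hubs, seeds = seeds,
                 outputDir = config$outputDir))
}
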