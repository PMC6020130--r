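#' Default run configuration
#'
#' Every numeric default equals the study's stated analysis value:
#' threshold grid 0.15-0.40 in steps of 0.01 (26 levels), 500 null
#' networks, 1000 permutations, hub z-cut 2.0, FA floor 0.2, 0.5 mm
#' tracking step, 60 degree curvature limit, 1.5 mm motion limit with
#' rotations converted at a 50 mm radius, FDR at 0.05.
#'
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    outputDir = "connectome-run",
    nPatients = 28L,
    nControls = 30L,
    nVolumes = 33L,
    motionAmplitude = 0.3,
    thresholdMin = 0.15,
    thresholdMax = 0.40,
    thresholdStep = 0.01,
    nNull = 500L,
    nPerm = 1000L,
    hubZ = 2.0,
    faFloor = 0.2,
    stepMm = 0.5,
    maxAngleDeg = 60,
    jitterKappa = 0,
    samplesPerSeed = 1L,
    motionLimitMm = 1.5,
    rotationRadiusMm = 50,
    fdrQ = 0.05,
    fdrMethod = "BH",
    seed = 1L
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML key-value file, rejects unknown keys by name, and
#' fills missing keys with the defaults of [defaultRunConfig()]. An
#' empty or absent file yields the full default configuration.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) {
      template <- cfg[[k]]
      value <- user[[k]]
      cfg[[k]] <- if (is.integer(template)) as.integer(value)
        else if (is.numeric(template)) as.numeric(value)
        else value
    }
  }
  grid <- thresholdGrid(cfg$thresholdMin, cfg$thresholdMax,
                        cfg$thresholdStep)
  cfg$nThresholdLevels <- length(grid)
  cfg
}

#' Derive a stage-specific RNG seed from the master seed
#'
#' Fixed per-stage offsets let each pipeline stage be rerun in
#' isolation while staying reproducible from a single master seed.
#' Results stay below 2^31 - 1.
#'
#' @param masterSeed integer master seed.
#' @param stage one of "simulate", "motion", "nulls", "permutation",
#'   "scan".
#' @return integer seed.
#' @export
deriveStageSeed <- function(masterSeed,
                            stage = c("simulate", "motion", "nulls",
                                      "permutation", "scan")) {
  stage <- match.arg(stage)
  offset <- c(simulate = 1, motion = 2, nulls = 3, permutation = 4,
              scan = 5)[stage]
  as.integer((as.numeric(masterSeed) * 48271 + offset * 1000003) %%
               2147483647)
}

#' Validate pipeline inputs
#'
#' Checks the contracts the analysis depends on: the atlas carries
#' exactly 24 region labels, gradient directions are unit vectors for
#' weighted volumes with exactly one b = 0 volume, and the cohort
#' table is complete (no missing covariates; clinical scores present
#' for patients).
#'
#' @param atlas optional [ROIAtlas-class].
#' @param volume optional [DiffusionVolume-class].
#' @param cohort optional cohort data.frame.
#' @return list with \code{valid} (logical) and \code{messages}
#'   (character vector of failures, empty when valid).
#' @export
validateInputs <- function(atlas = NULL, volume = NULL, cohort = NULL) {
  msgs <- character()
  if (!is.null(atlas)) {
    nl <- nRegions(atlas)
    if (nl != 24L) {
      msgs <- c(msgs, sprintf("atlas has %d region labels; expected 24", nl))
    }
  }
  if (!is.null(volume)) {
    v <- tryCatch(validObject(volume), error = function(e) conditionMessage(e))
    if (is.character(v)) msgs <- c(msgs, v)
  }
  if (!is.null(cohort)) {
    need <- c("subject", "group", "age", "iq", "tiv")
    miss <- setdiff(need, names(cohort))
    if (length(miss)) {
      msgs <- c(msgs, paste("cohort table missing columns:",
                            paste(miss, collapse = ", ")))
    } else {
      if (any(!is.finite(as.matrix(cohort[, c("age", "iq", "tiv")])))) {
        msgs <- c(msgs, "cohort covariates contain missing values")
      }
      pat <- cohort$group == "TS"
      for (sc in intersect(c("ygtss", "puts"), names(cohort))) {
        if (any(!is.finite(cohort[[sc]][pat]))) {
          msgs <- c(msgs, sprintf("clinical score %s missing for patients", sc))
        }
      }
    }
  }
  list(valid = length(msgs) == 0L, messages = msgs)
}
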