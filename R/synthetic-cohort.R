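#' The 24-region atlas label table
#'
#' The study's 12 bilateral regions of interest: five sensorimotor
#' areas (M1, S1, SMA, pre-SMA, dorsal premotor cortex), five
#' basal-ganglia structures (caudate, putamen, globus pallidus,
#' thalamus, nucleus accumbens) and the anterior and posterior insula,
#' each in both hemispheres. Labels run 1..24 with left before right.
#'
#' @return data.frame with columns label, name, hemisphere, system.
#' @export
roiLabelTable <- function() {
  base <- c("M1", "S1", "SMA", "preSMA", "PMd",
            "caudate", "putamen", "pallidum", "thalamus", "accumbens",
            "ant_insula", "post_insula")
  system <- rep(c("sensorimotor", "basal-ganglia", "insula"),
                times = c(5, 5, 2))
  data.frame(
    label = 1:24,
    name = paste(rep(base, each = 2), c("L", "R"), sep = "_"),
    hemisphere = rep(c("left", "right"), 12),
    system = rep(system, each = 2),
    stringsAsFactors = FALSE
  )
}

# node index by region name, e.g. .roiIndex("putamen_L")
.roiIndex <- function(name) {
  lt <- roiLabelTable()
  i <- match(name, lt$name)
  if (is.na(i)) stop("unknown ROI name: ", name)
  lt$label[i]
}

#' Construct a cohort specification
#'
#' Defaults reproduce the statistical structure of the study sample:
#' 28 patients and 30 controls on 24 nodes, hub-like strength at the
#' left SMA and right putamen in both groups, a group elevation of
#' betweenness centrality at the left putamen in patients
#' (standardized effect d = 1.2), and positive associations between
#' the premonitory-urge score (PUTS) and local efficiency at two
#' insula nodes. Pass \code{groupEffect = list()} and
#' \code{clinicalEffects = list()} for a null cohort.
#'
#' @param nPatients,nControls group sizes.
#' @param weightDistribution list(meanlog, sdlog) for the baseline
#'   log-normal streamline-count law.
#' @param edgeNoiseSd between-subject log-normal edge noise SD.
#' @param hubNodes node indices with elevated strength in both groups.
#' @param hubGain strength multiplier at hub nodes.
#' @param groupEffect list(node, metric, d); node may be an index or
#'   an ROI name from [roiLabelTable()].
#' @param clinicalEffects list of list(node, metric, score, effect).
#' @param covariateRanges list(age = c(min, max), iq = c(mean, sd),
#'   tiv = c(mean, sd)).
#' @param seed RNG seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 28L, nControls = 30L,
                       weightDistribution = list(meanlog = log(30),
                                                 sdlog = 0.7),
                       edgeNoiseSd = 0.35,
                       hubNodes = c("SMA_L", "putamen_R"),
                       hubGain = 2.5,
                       groupEffect = list(node = "putamen_L",
                                          metric = "betweenness",
                                          d = 1.2),
                       clinicalEffects = list(
                         list(node = "ant_insula_L",
                              metric = "local_efficiency",
                              score = "puts", effect = 0.6),
                         list(node = "post_insula_R",
                              metric = "local_efficiency",
                              score = "puts", effect = 0.6)
                       ),
                       covariateRanges = list(age = c(8.6, 21.8),
                                              iq = c(115, 13),
                                              tiv = c(1.4e6, 1.2e5)),
                       seed = 1L) {
  toIdx <- function(x) {
    if (is.character(x)) .roiIndex(x) else as.integer(x)
  }
  hubNodes <- vapply(hubNodes, toIdx, integer(1))
  if (length(groupEffect)) groupEffect$node <- toIdx(groupEffect$node)
  clinicalEffects <- lapply(clinicalEffects, function(ce) {
    ce$node <- toIdx(ce$node)
    ce
  })
  new("CohortSpec",
    nPatients = as.integer(nPatients), nControls = as.integer(nControls),
    nNodes = 24L, weightDistribution = weightDistribution,
    edgeNoiseSd = edgeNoiseSd, hubNodes = as.integer(hubNodes),
    hubGain = hubGain, groupEffect = groupEffect,
    clinicalEffects = clinicalEffects, covariateRanges = covariateRanges,
    seed = as.integer(seed)
  )
}

# nodal metric of a weight matrix after proportional thresholding
.nodalMetric <- function(w, node, metric, level) {
  adj <- proportionalThreshold(w, level)
  switch(metric,
    degree = nodeDegree(adj)[node],
    betweenness = betweennessCentrality(adj)[node],
    clustering = clusteringCoefficient(adj)[node],
    local_efficiency = localEfficiency(adj)[node],
    path_length = as.numeric(nodalPathLength(adj))[node],
    stop("unsupported planting metric: ", metric)
  )
}

# multiply a node's incident edge weights by alpha
.scaleNode <- function(w, node, alpha) {
  w[node, ] <- w[node, ] * alpha
  w[, node] <- w[, node] * alpha
  diag(w) <- 0
  w
}

# calibrate the incident-edge scale factor producing a target mean
# shift of the nodal metric across the supplied matrices
.calibrateAlpha <- function(mats, node, metric, level, targetShift) {
  grid <- c(0.4, 0.55, 0.7, 0.85, 1, 1.2, 1.45, 1.75, 2.1, 2.6, 3.2)
  resp <- vapply(grid, function(a) {
    mean(vapply(mats, function(w) {
      .nodalMetric(.scaleNode(w, node, a), node, metric, level)
    }, numeric(1)))
  }, numeric(1))
  base <- resp[grid == 1]
  g <- resp - base
  dev <- g - targetShift
  best <- which.min(abs(dev))
  # refine by linear interpolation across the nearest sign change
  cross <- which(dev[-length(dev)] * dev[-1] <= 0)
  if (length(cross)) {
    i <- cross[which.min(abs(grid[cross] - grid[best]))]
    if (dev[i + 1] != dev[i]) {
      return(grid[i] + (grid[i + 1] - grid[i]) *
               (0 - dev[i]) / (dev[i + 1] - dev[i]))
    }
  }
  grid[best]
}

#' Generate a synthetic two-group connectome cohort
#'
#' Simulates per-subject 24 x 24 streamline-count matrices (symmetric,
#' zero diagonal, nonnegative integers) with parallel mean-AD edge
#' weights, plus the cohort covariate table. The generative model is a
#' shared log-normal baseline matrix with hub-node strength gain,
#' subject-level multiplicative log-normal edge noise, and planted
#' effects applied by scaling the target node's incident edges:
#'
#' \itemize{
#'   \item the group effect scales patient matrices by a factor
#'     calibrated (against the cohort's own between-subject metric
#'     spread, at the 0.25 threshold) to shift the nodal metric by
#'     \code{d} standard deviations;
#'   \item each clinical effect drives a per-patient latent that both
#'     scales the node's incident edges (one metric SD per latent
#'     unit) and loads on the named clinical score, producing a
#'     covariate-adjusted metric-score association of the requested
#'     sign.
#' }
#'
#' Clinical scores (YGTSS 0-100, PUTS 9-36) are generated for patients
#' only; controls carry NA, matching how these instruments are
#' administered.
#'
#' @param spec a [CohortSpec-class].
#' @param calibrationThreshold proportional threshold at which planted
#'   effects are calibrated.
#' @return list with \code{connectomes} (named list of
#'   [ConnectivityMatrix-class]), \code{cohort} (data.frame with
#'   columns subject, group, age, iq, tiv, ygtss, puts) and
#'   \code{calibration} (the fitted scale factors).
#' @export
makeCohort <- function(spec, calibrationThreshold = 0.25) {
  validObject(spec)
  set.seed(spec@seed)
  nP <- spec@nPatients
  nC <- spec@nControls
  n <- nP + nC
  nn <- spec@nNodes
  m <- nn * (nn - 1) / 2
  ut <- upper.tri(matrix(0, nn, nn))

  # shared baseline with hub gain
  B <- matrix(0, nn, nn)
  B[ut] <- stats::rlnorm(m, spec@weightDistribution$meanlog,
                         spec@weightDistribution$sdlog)
  B <- B + t(B)
  if (length(spec@hubNodes)) {
    gain <- rep(1, nn)
    gain[spec@hubNodes] <- spec@hubGain
    B <- B * outer(gain, gain, pmax)
    diag(B) <- 0
  }

  # covariates
  cr <- spec@covariateRanges
  age <- stats::runif(n, cr$age[1], cr$age[2])
  iq <- stats::rnorm(n, cr$iq[1], cr$iq[2])
  tiv <- stats::rnorm(n, cr$tiv[1], cr$tiv[2])

  # subject-level edge noise
  mats <- vector("list", n)
  for (s in seq_len(n)) {
    Z <- matrix(0, nn, nn)
    Z[ut] <- stats::rnorm(m, 0, spec@edgeNoiseSd)
    Z <- Z + t(Z)
    mats[[s]] <- B * exp(Z)
  }
  patIdx <- seq_len(nP)

  calibration <- list()

  # group effect: uniform incident-edge scaling of patient matrices
  if (length(spec@groupEffect) && spec@groupEffect$d != 0) {
    ge <- spec@groupEffect
    v0 <- vapply(mats, .nodalMetric, numeric(1),
                 node = ge$node, metric = ge$metric,
                 level = calibrationThreshold)
    sigmaM <- stats::sd(v0)
    if (sigmaM == 0) {
      warning("metric has zero spread; group effect not planted")
    } else {
      # first pass targets a mean shift of d baseline SDs; one
      # refinement pass corrects for the variance the scaling itself
      # adds, so the realized pooled-SD effect size lands near d
      target <- ge$d * sigmaM
      ctl <- v0[-patIdx]
      alpha <- 1
      for (iter in 1:4) {
        alpha <- .calibrateAlpha(mats[patIdx], ge$node, ge$metric,
                                 calibrationThreshold, target)
        v1 <- vapply(patIdx, function(s) {
          .nodalMetric(.scaleNode(mats[[s]], ge$node, alpha), ge$node,
                       ge$metric, calibrationThreshold)
        }, numeric(1))
        pooled <- sqrt((stats::var(v1) * (nP - 1) +
                          stats::var(ctl) * (nC - 1)) / (nP + nC - 2))
        realized <- (mean(v1) - mean(ctl)) / pooled
        if (!is.finite(realized) || realized == 0 ||
            abs(realized - ge$d) < 0.08 * abs(ge$d)) break
        target <- target * ge$d / realized
      }
      for (s in patIdx) mats[[s]] <- .scaleNode(mats[[s]], ge$node, alpha)
      calibration$groupAlpha <- alpha
    }
  }

  # clinical effects: latent-driven incident-edge scaling in patients;
  # the score later loads on the realized (post-surgery) standardized
  # metric so the planted association strength is attained exactly
  latents <- NULL
  realizedZ <- NULL
  if (length(spec@clinicalEffects)) {
    nE <- length(spec@clinicalEffects)
    latents <- matrix(stats::rnorm(nP * nE), nP, nE)
    realizedZ <- latents
    alphaU <- numeric(nE)
    for (k in seq_len(nE)) {
      ce <- spec@clinicalEffects[[k]]
      v0 <- vapply(mats[patIdx], .nodalMetric, numeric(1),
                   node = ce$node, metric = ce$metric,
                   level = calibrationThreshold)
      sigmaM <- stats::sd(v0)
      if (sigmaM == 0) {
        warning("metric has zero spread; clinical effect ", k,
                " not planted")
        next
      }
      alphaU[k] <- .calibrateAlpha(mats[patIdx], ce$node, ce$metric,
                                   calibrationThreshold, sigmaM)
      for (s in patIdx) {
        mats[[s]] <- .scaleNode(mats[[s]], ce$node,
                                alphaU[k]^latents[s, k])
      }
      v1 <- vapply(mats[patIdx], .nodalMetric, numeric(1),
                   node = ce$node, metric = ce$metric,
                   level = calibrationThreshold)
      if (stats::sd(v1) > 0) realizedZ[, k] <- as.numeric(scale(v1))
    }
    calibration$clinicalAlpha <- alphaU
  }

  # clinical scores: latent loadings plus independent noise, patients only
  scoreParams <- list(
    ygtss = c(mean = 33, sd = 15.3, min = 0, max = 100),
    puts = c(mean = 20.4, sd = 5.8, min = 9, max = 36)
  )
  scores <- list(ygtss = rep(NA_real_, n), puts = rep(NA_real_, n))
  for (nm in names(scoreParams)) {
    p <- scoreParams[[nm]]
    eps <- stats::rnorm(nP)
    z <- eps
    if (!is.null(latents)) {
      kIdx <- which(vapply(spec@clinicalEffects,
                           function(ce) ce$score == nm, logical(1)))
      if (length(kIdx)) {
        r <- vapply(spec@clinicalEffects[kIdx], function(ce) {
          es <- ce$effect
          sign(es) * abs(es) / sqrt(1 + es^2)
        }, numeric(1))
        tot <- sum(r^2)
        if (tot > 0.95) r <- r * sqrt(0.95 / tot)
        z <- realizedZ[, kIdx, drop = FALSE] %*% r +
          sqrt(1 - sum(r^2)) * eps
      }
    }
    val <- round(p["mean"] + p["sd"] * as.numeric(z))
    scores[[nm]][patIdx] <- pmin(pmax(val, p["min"]), p["max"])
  }

  # integer streamline counts and parallel mean-AD weights
  subjects <- c(sprintf("TS%02d", seq_len(nP)),
                sprintf("CS%02d", seq_len(nC)))
  connectomes <- vector("list", n)
  for (s in seq_len(n)) {
    cm <- round(mats[[s]])
    cm[cm < 0] <- 0
    diag(cm) <- 0
    adW <- matrix(0, nn, nn)
    adW[ut] <- pmax(stats::rnorm(m, 1.2e-3, 1e-4), 1e-4)
    adW <- adW + t(adW)
    adW[cm == 0] <- 0
    connectomes[[s]] <- new("ConnectivityMatrix", counts = cm,
                            meanAD = adW, subject = subjects[s])
  }
  names(connectomes) <- subjects

  cohort <- data.frame(
    subject = subjects,
    group = rep(c("TS", "CS"), c(nP, nC)),
    age = age, iq = iq, tiv = tiv,
    ygtss = scores$ygtss, puts = scores$puts,
    stringsAsFactors = FALSE
  )
  list(connectomes = connectomes, cohort = cohort,
       calibration = calibration)
}
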