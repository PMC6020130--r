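# Permutation-based group inference with nuisance covariates and the
# clinical-association regression scan.

# ordinary least squares t statistic for one term; errors on singular
# designs
.olsT <- function(y, X, termIdx) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  XtXinv <- chol2inv(qr.R(qrX))
  b <- qr.coef(qrX, y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  list(beta = b[termIdx], t = b[termIdx] / sqrt(s2 * XtXinv[termIdx, termIdx]),
       df = df)
}

# Freedman-Lane permutation distribution of the t statistic for column
# termIdx of Xfull, permuting residuals of the reduced (covariate-only)
# design Zred; vectorized over permutations
.flPermT <- function(y, Xfull, termIdx, Zred, nPerm) {
  n <- length(y)
  p <- ncol(Xfull)
  XtXinv <- chol2inv(chol(crossprod(Xfull)))
  A <- XtXinv %*% t(Xfull)
  qrZ <- qr(Zred)
  fitRed <- qr.fitted(qrZ, y)
  eRed <- y - fitRed
  perms <- matrix(0L, n, nPerm)
  for (j in seq_len(nPerm)) perms[, j] <- sample.int(n)
  Ystar <- fitRed + matrix(eRed[perms], n, nPerm)
  B <- A %*% Ystar
  RSS <- colSums((Ystar - Xfull %*% B)^2)
  s2 <- RSS / (n - p)
  B[termIdx, ] / sqrt(s2 * XtXinv[termIdx, termIdx])
}

#' Permutation test of a group difference with nuisance covariates
#'
#' Fits the linear model metric ~ group + age + IQ + TIV, takes the
#' group-term t statistic as the observed statistic, and builds its
#' null distribution by Freedman-Lane residual permutation: residuals
#' of the reduced (covariate-only) model are permuted, added back to
#' the reduced fit, and the full model refit. The two-sided p-value
#' uses the add-one estimator p = (1 + #(|t*| >= |t|)) / (1 + nPerm)
#' and so never returns zero.
#'
#' Subjects are processed in sorted-identifier order internally, so
#' the p-value does not depend on row order, and the t statistic is
#' invariant to affine rescaling of covariates.
#'
#' @param values numeric metric values, one per cohort row.
#' @param cohort data.frame with columns subject, group, age, iq, tiv.
#' @param nPerm number of permutations.
#' @param seed RNG seed; NULL leaves the RNG stream untouched (for
#'   batch callers that seed once).
#' @return list with \code{statistic} (group t), \code{p}, \code{df}
#'   and \code{nPerm}.
#' @export
permutationGroupTest <- function(values, cohort, nPerm = 1000L,
                                 seed = 1L) {
  stopifnot(length(values) == nrow(cohort))
  groups <- unique(cohort$group)
  if (length(groups) != 2L) stop("need exactly two nonempty groups")
  covars <- cohort[, c("age", "iq", "tiv")]
  if (any(!is.finite(as.matrix(covars)))) {
    stop("covariates must be complete for all included subjects")
  }
  ord <- order(cohort$subject)
  values <- values[ord]
  cohort <- cohort[ord, ]
  if (any(!is.finite(values))) stop("metric values must be finite")
  if (stats::sd(values) == 0) {
    warning("metric is constant across subjects; p = 1")
    return(list(statistic = 0, p = 1, df = NA_integer_, nPerm = nPerm))
  }
  g01 <- as.numeric(cohort$group == sort(groups)[2])
  Xf <- cbind(1, g01, scale(cohort$age), scale(cohort$iq),
              scale(cohort$tiv))
  Z <- Xf[, -2, drop = FALSE]
  obs <- .olsT(values, Xf, 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tstar <- .flPermT(values, Xf, 2L, Z, nPerm)
  p <- (1 + sum(abs(tstar) >= abs(obs$t) - 1e-12)) / (1 + nPerm)
  list(statistic = unname(obs$t), p = p, df = obs$df, nPerm = nPerm)
}

#' Group comparison across the full metric table
#'
#' Runs [permutationGroupTest()] for every (metric, node, threshold)
#' cell of a nodal metric table and every (metric, threshold) cell of
#' a global table, correcting p-values per metric (across its nodes
#' and thresholds) by FDR.
#'
#' @param metrics list with data.frames \code{nodal} and \code{global}
#'   from [computeMetrics()].
#' @param cohort cohort covariate table.
#' @param nPerm permutations per test.
#' @param seed master seed for the permutation stream.
#' @param q FDR level.
#' @return data.frame with columns metric, node (NA for global
#'   metrics), threshold, t, p, p_fdr.
#' @export
groupComparison <- function(metrics, cohort, nPerm = 1000L, seed = 1L,
                            q = 0.05) {
  set.seed(as.integer(seed))
  rows <- list()
  runCell <- function(df, metricName, node, thr) {
    vals <- df$value[match(cohort$subject, df$subject)]
    if (any(!is.finite(vals))) {
      # undefined cells (e.g. path length of an isolated node,
      # assortativity of a regular network) carry NA statistics
      return(data.frame(metric = metricName, node = node, threshold = thr,
                        t = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    res <- suppressWarnings(
      permutationGroupTest(vals, cohort, nPerm = nPerm, seed = NULL)
    )
    data.frame(metric = metricName, node = node, threshold = thr,
               t = res$statistic, p = res$p, stringsAsFactors = FALSE)
  }
  nod <- metrics$nodal
  for (mn in unique(nod$metric)) {
    sub <- nod[nod$metric == mn, ]
    for (thr in unique(sub$threshold)) {
      s2 <- sub[sub$threshold == thr, ]
      for (nd in unique(s2$node)) {
        rows[[length(rows) + 1L]] <-
          runCell(s2[s2$node == nd, ], mn, nd, thr)
      }
    }
  }
  glo <- metrics$global
  for (mn in setdiff(unique(glo$metric), c("gamma", "lambda"))) {
    sub <- glo[glo$metric == mn, ]
    for (thr in unique(sub$threshold)) {
      rows[[length(rows) + 1L]] <-
        runCell(sub[sub$threshold == thr, ], mn, NA_integer_, thr)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (mn in unique(out$metric)) {
    sel <- out$metric == mn
    out$p_fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out
}

#' Clinical-association regression scan
#'
#' For one clinical score, fits score ~ metric + age + IQ + TIV at
#' every (threshold, node, metric) cell over the patients, recording
#' the metric-term slope, t statistic, parametric p (and optionally a
#' Freedman-Lane permutation p), with Benjamini-Hochberg FDR over the
#' whole scan family. Nodal metrics contribute one cell per node;
#' global metrics enter replicated across nodes, so a full grid holds
#' 26 x 24 x 9 = 5,616 cells. Cells whose metric is constant across
#' patients (e.g. density, which proportional thresholding fixes by
#' design) carry NA statistics.
#'
#' @param metrics list with \code{nodal} and \code{global} tables from
#'   [computeMetrics()] (patients and controls may both be present;
#'   only patients are used).
#' @param cohort cohort table; rows with group "TS" and a non-missing
#'   score are included.
#' @param score clinical score column name ("puts" or "ygtss").
#' @param q FDR level.
#' @param nPerm permutations for the permutation p (0 = parametric
#'   only).
#' @param seed RNG seed for the permutation stream.
#' @return data.frame with columns threshold, node, metric, beta, t,
#'   p, p_perm, p_fdr, significant.
#' @export
clinicalAssociationScan <- function(metrics, cohort, score = "puts",
                                    q = 0.05, nPerm = 0L, seed = 1L) {
  stopifnot(score %in% names(cohort))
  pat <- cohort[cohort$group == "TS" & is.finite(cohort[[score]]), ]
  pat <- pat[order(pat$subject), ]
  nPat <- nrow(pat)
  if (nPat < 6L) stop("fewer patients than regression parameters")
  y <- pat[[score]]
  Z <- cbind(1, scale(pat$age), scale(pat$iq), scale(pat$tiv))

  nod <- metrics$nodal
  glo <- metrics$global
  nod <- nod[nod$subject %in% pat$subject, ]
  glo <- glo[glo$subject %in% pat$subject, ]
  thresholds <- sort(unique(c(nod$threshold, glo$threshold)))
  nodes <- sort(unique(nod$node))
  nodalMetrics <- unique(nod$metric)
  globalMetrics <- setdiff(unique(glo$metric), c("gamma", "lambda"))

  if (nPerm > 0) set.seed(as.integer(seed))
  rows <- list()
  fitCell <- function(x, thr, nd, mn) {
    beta <- tval <- pval <- pperm <- NA_real_
    if (all(is.finite(x)) && stats::sd(x) > 0) {
      X <- cbind(Z[, 1], x, Z[, -1])
      fit <- .olsT(y, X, 2L)
      beta <- unname(fit$beta)
      tval <- unname(fit$t)
      pval <- 2 * stats::pt(-abs(tval), fit$df)
      if (nPerm > 0) {
        tstar <- .flPermT(y, X, 2L, Z, nPerm)
        pperm <- (1 + sum(abs(tstar) >= abs(tval) - 1e-12)) / (1 + nPerm)
      }
    }
    data.frame(threshold = thr, node = nd, metric = mn, beta = beta,
               t = tval, p = pval, p_perm = pperm,
               stringsAsFactors = FALSE)
  }
  for (thr in thresholds) {
    nthr <- nod[nod$threshold == thr, ]
    gthr <- glo[glo$threshold == thr, ]
    for (mn in nodalMetrics) {
      nm <- nthr[nthr$metric == mn, ]
      for (nd in nodes) {
        cell <- nm[nm$node == nd, ]
        x <- cell$value[match(pat$subject, cell$subject)]
        rows[[length(rows) + 1L]] <- fitCell(x, thr, nd, mn)
      }
    }
    for (mn in globalMetrics) {
      cell <- gthr[gthr$metric == mn, ]
      x <- cell$value[match(pat$subject, cell$subject)]
      for (nd in nodes) {
        rows[[length(rows) + 1L]] <- fitCell(x, thr, nd, mn)
      }
    }
  }
  out <- do.call(rbind, rows)
  fdr <- fdrCorrect(out$p, q = q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$reject
  out
}

#' False discovery rate correction
#'
#' Step-up FDR adjustment over one family of p-values:
#' Benjamini-Hochberg by default, Benjamini-Yekutieli on request.
#' Rejections at level q are exactly the hypotheses with adjusted
#' p <= q; adjusted values are monotone in the raw p-value ranks.
#'
#' @param p numeric p-values (NA allowed, propagated).
#' @param q FDR level.
#' @param method "BH" or "BY".
#' @return list with \code{adjusted} p-values and logical
#'   \code{reject} mask.
#' @export
fdrCorrect <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(list(adjusted = numeric(), reject = logical()))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  adj <- stats::p.adjust(p, method = method)
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}
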