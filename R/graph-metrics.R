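# Binarized graph metrics over proportionally thresholded networks.
# Path-based quantities are delegated to igraph; the thresholding rule,
# efficiency conventions and null normalization are defined here.

.asGraph <- function(net) {
  igraph::graph_from_adjacency_matrix(
    (as.matrix(net) > 0) * 1L, mode = "undirected", diag = FALSE
  )
}

# all-pairs geodesic distances of a small dense binary network by
# breadth-first layer expansion (Inf where unreachable)
.binDist <- function(net) {
  A <- (as.matrix(net) > 0) * 1
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reached <- diag(n) > 0
  frontier <- reached
  k <- 0L
  while (any(frontier) && k < n) {
    k <- k + 1L
    nxt <- (frontier %*% A) > 0
    new <- nxt & !reached
    if (!any(new)) break
    D[new] <- k
    reached <- reached | new
    frontier <- new
  }
  D
}

#' Proportional threshold grid
#'
#' The analysis grid of network densities: 0.15 to 0.40 in steps of
#' 0.01, i.e. 26 levels.
#'
#' @param min,max,step grid bounds and spacing (proportions).
#' @return numeric vector of levels.
#' @export
thresholdGrid <- function(min = 0.15, max = 0.40, step = 0.01) {
  round(seq(min, max, by = step), 10)
}

#' Proportional thresholding and binarization
#'
#' Retains exactly \code{k = round(level * N(N-1)/2)} strongest
#' off-diagonal weights (round-half-even; ties broken by lexicographic
#' edge order for reproducibility) and binarizes, so every subject's
#' network has the same density at a given level. If fewer than k
#' weights are nonzero, all nonzero weights are kept with a warning.
#'
#' @param weights symmetric nonnegative matrix with zero diagonal.
#' @param level proportion of edges to keep, in (0, 1].
#' @return binary (0/1) symmetric matrix with attribute \code{level}.
#' @examples
#' w <- matrix(0, 4, 4)
#' w[upper.tri(w)] <- 1:6
#' w <- w + t(w)
#' proportionalThreshold(w, 0.5)  # keeps the 3 strongest edges
#' @export
proportionalThreshold <- function(weights, level) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(n == ncol(weights), level > 0, level <= 1)
  if (any(abs(weights - t(weights)) > 1e-9)) {
    stop("weight matrix must be symmetric")
  }
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[upper.tri(weights)]
  m <- length(w)
  k <- round(level * m)
  nnz <- sum(w > 0)
  if (nnz < k) {
    warning(sprintf(
      "only %d nonzero weights available for target edge count %d; keeping all",
      nnz, k
    ))
    k <- nnz
  }
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  adj <- matrix(0, n, n)
  adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(weights)
  attr(adj, "level") <- level
  adj
}

#' @rdname graphMetrics
#' @export
nodeDegree <- function(net) {
  rowSums(as.matrix(net) > 0)
}

#' @rdname graphMetrics
#' @export
networkDensity <- function(net) {
  net <- as.matrix(net)
  n <- nrow(net)
  sum(net[upper.tri(net)] > 0) / (n * (n - 1) / 2)
}

#' Binary graph metrics
#'
#' The nodal and global metrics computed on each binarized network:
#' degree; betweenness centrality (unnormalized shortest-path counts,
#' each unordered pair counted once); nodal characteristic path length
#' (mean geodesic distance to reachable nodes, with the reachable
#' fraction attached as an attribute); clustering coefficient
#' (triangle fraction, zero for degree < 2); local efficiency (global
#' efficiency of the subgraph induced by a node's neighbours, zero
#' below two neighbours); density; global efficiency (mean inverse
#' geodesic distance over ordered pairs, 1/Inf = 0); and degree
#' assortativity (NaN with a warning when the degree variance over
#' edges is zero).
#'
#' @param net binary adjacency matrix (any nonzero entry is an edge).
#' @return numeric vector (nodal metrics) or scalar (global metrics).
#' @name graphMetrics
NULL

#' @rdname graphMetrics
#' @export
betweennessCentrality <- function(net) {
  as.numeric(igraph::betweenness(.asGraph(net), directed = FALSE,
                                 normalized = FALSE))
}

#' @rdname graphMetrics
#' @export
nodalPathLength <- function(net) {
  D <- .binDist(net)
  diag(D) <- Inf
  out <- apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NaN
  })
  attr(out, "reachableFraction") <-
    apply(D, 1, function(r) mean(is.finite(r)))
  out
}

#' @rdname graphMetrics
#' @export
characteristicPathLength <- function(net) {
  D <- .binDist(net)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NaN)
  mean(d)
}

#' @rdname graphMetrics
#' @export
globalEfficiency <- function(net) {
  D <- .binDist(net)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(D)
  sum(inv) / (n * (n - 1))
}

#' @rdname graphMetrics
#' @export
localEfficiency <- function(net) {
  net <- (as.matrix(net) > 0) * 1
  n <- nrow(net)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(net[v, ] > 0)
    if (length(nb) < 2L) next
    out[v] <- globalEfficiency(net[nb, nb, drop = FALSE])
  }
  out
}

#' @rdname graphMetrics
#' @export
clusteringCoefficient <- function(net) {
  as.numeric(igraph::transitivity(.asGraph(net), type = "local",
                                  isolates = "zero"))
}

#' @rdname graphMetrics
#' @export
assortativityCoefficient <- function(net) {
  r <- suppressWarnings(igraph::assortativity_degree(.asGraph(net)))
  if (is.na(r)) {
    warning("assortativity undefined: zero degree variance over edges")
    return(NaN)
  }
  r
}

# edge list (k x 2, 1-based) of a binary adjacency matrix
.edgeList <- function(net) {
  e <- which(upper.tri(net) & net > 0, arr.ind = TRUE)
  storage.mode(e) <- "integer"
  e
}

#' Degree-preserving null networks
#'
#' Generates an ensemble of randomized networks with exactly the node
#' count, edge count and degree sequence of the source network, by
#' attempted double-edge swaps (\code{swapsPerEdge * E} attempts per
#' null; proposals creating self-loops or duplicate edges are
#' rejected). If the network admits no valid swap (fewer than two
#' edges without a shared endpoint), unrewired copies are returned
#' with a warning.
#'
#' @param net binary adjacency matrix.
#' @param n ensemble size.
#' @param swapsPerEdge attempted swaps per edge per null.
#' @param seed RNG seed.
#' @return list of binary adjacency matrices.
#' @export
generateNulls <- function(net, n = 500L, swapsPerEdge = 10L, seed = 1L) {
  net <- (as.matrix(net) > 0) * 1
  nv <- nrow(net)
  e <- .edgeList(net)
  swappable <- FALSE
  if (nrow(e) >= 2L) {
    for (a in seq_len(nrow(e) - 1L)) {
      rest <- e[-seq_len(a), , drop = FALSE]
      disjoint <- rest[, 1] != e[a, 1] & rest[, 1] != e[a, 2] &
        rest[, 2] != e[a, 1] & rest[, 2] != e[a, 2]
      if (any(disjoint)) {
        swappable <- TRUE
        break
      }
    }
  }
  if (!swappable) {
    warning("no valid degree-preserving swap exists; returning copies")
    return(replicate(n, net, simplify = FALSE))
  }
  set.seed(as.integer(seed))
  ens <- .cpp_null_ensemble(e, nv, as.integer(n), as.integer(swapsPerEdge))
  lapply(ens, function(ee) {
    a <- matrix(0, nv, nv)
    a[ee] <- 1
    a[ee[, c(2, 1), drop = FALSE]] <- 1
    a
  })
}

# fast path used by computeMetrics: null-ensemble mean clustering and
# characteristic path length without materializing the networks
.nullStats <- function(net, n, swapsPerEdge) {
  e <- .edgeList((as.matrix(net) > 0) * 1)
  .cpp_null_stats(e, nrow(net), as.integer(n), as.integer(swapsPerEdge))
}

#' Small-worldness against a null ensemble
#'
#' gamma is the network's mean nodal clustering normalized by the null
#' ensemble mean; lambda the characteristic path length normalized the
#' same way; the small-world coefficient is sigma = gamma / lambda.
#' sigma > 1 indicates small-world organization. A network normalized
#' against copies of itself gives gamma = lambda = sigma = 1 exactly.
#'
#' @param net binary adjacency matrix.
#' @param nulls a list of null adjacency matrices (from
#'   [generateNulls()]) or a two-column matrix of per-null mean
#'   clustering and characteristic path length.
#' @return named numeric vector (gamma, lambda, sigma).
#' @export
smallWorldness <- function(net, nulls) {
  if (is.list(nulls)) {
    stats <- t(vapply(
      nulls,
      function(x) c(mean(clusteringCoefficient(x)),
                    characteristicPathLength(x)),
      numeric(2)
    ))
  } else {
    stats <- as.matrix(nulls)
  }
  nullC <- mean(stats[, 1])
  nullL <- mean(stats[, 2])
  if (!is.finite(nullC) || nullC == 0 || !is.finite(nullL) || nullL == 0) {
    warning("null ensemble mean is zero or undefined; sigma undefined")
    return(c(gamma = NaN, lambda = NaN, sigma = NaN))
  }
  g <- mean(clusteringCoefficient(net)) / nullC
  l <- characteristicPathLength(net) / nullL
  c(gamma = g, lambda = l, sigma = g / l)
}

#' Hub detection from group-mean nodal metrics
#'
#' z-scores each metric across nodes and flags nodes reaching
#' \code{z >= zCut} on both degree and betweenness centrality.
#'
#' @param meanDegree,meanBetweenness group-mean nodal values.
#' @param zCut z-score threshold.
#' @return integer vector of hub node indices (possibly empty).
#' @export
detectHubs <- function(meanDegree, meanBetweenness, zCut = 2) {
  stopifnot(length(meanDegree) == length(meanBetweenness))
  if (stats::sd(meanDegree) == 0 || stats::sd(meanBetweenness) == 0) {
    warning("zero variance across nodes; no hubs detectable")
    return(integer())
  }
  zd <- as.numeric(scale(meanDegree))
  zb <- as.numeric(scale(meanBetweenness))
  which(zd >= zCut & zb >= zCut)
}

#' Ring lattice with random shortcuts
#'
#' Builds a circulant ring lattice (each node joined to its \code{nei}
#' nearest neighbours on either side) and rewires a fraction of edges
#' to uniformly chosen shortcuts, keeping the graph simple and the
#' edge count fixed. The classic construction whose clustering stays
#' lattice-like while path lengths drop: a small-world benchmark
#' network.
#'
#' @param nNodes number of nodes.
#' @param nei lattice neighbourhood radius (degree = 2 * nei).
#' @param pRewire fraction of edges rewired to shortcuts.
#' @param seed RNG seed.
#' @return binary adjacency matrix.
#' @export
smallWorldNetwork <- function(nNodes = 24L, nei = 3L, pRewire = 0.1,
                              seed = 1L) {
  adj <- matrix(0, nNodes, nNodes)
  for (s in seq_len(nei)) {
    i <- seq_len(nNodes)
    j <- ((i - 1 + s) %% nNodes) + 1
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  set.seed(as.integer(seed))
  e <- .edgeList(adj)
  nRew <- ceiling(pRewire * nrow(e))
  pick <- sample(nrow(e), nRew)
  for (idx in pick) {
    # replace this edge with a uniformly chosen absent edge
    absent <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    if (!nrow(absent)) break
    newE <- absent[sample(nrow(absent), 1), ]
    old <- e[idx, ]
    adj[old[1], old[2]] <- adj[old[2], old[1]] <- 0
    adj[newE[1], newE[2]] <- adj[newE[2], newE[1]] <- 1
  }
  adj
}

#' Metric table over subjects and thresholds
#'
#' Thresholds every subject's streamline-count matrix across the full
#' grid, computes the five nodal metrics (degree, betweenness, path
#' length, clustering, local efficiency) and four global metrics
#' (density, global efficiency, assortativity, small-worldness, the
#' latter normalized against \code{nNull} degree-preserving nulls and
#' reported with its gamma and lambda components), and returns long
#'-format tables.
#'
#' @param connectomes list of [ConnectivityMatrix-class] objects (or
#'   plain weight matrices), named by subject.
#' @param thresholds proportional threshold levels.
#' @param nNull null-ensemble size per (subject, threshold); 0 skips
#'   small-worldness.
#' @param swapsPerEdge swap attempts per edge per null.
#' @param seed RNG seed for the null ensembles.
#' @return list of data.frames: \code{nodal} with columns subject,
#'   threshold, node, metric, value; \code{global} with subject,
#'   threshold, metric, value.
#' @export
computeMetrics <- function(connectomes, thresholds = thresholdGrid(),
                           nNull = 500L, swapsPerEdge = 10L, seed = 1L) {
  subjects <- names(connectomes)
  if (is.null(subjects)) {
    subjects <- vapply(seq_along(connectomes), function(i) {
      x <- connectomes[[i]]
      if (is(x, "ConnectivityMatrix")) subjectID(x) else paste0("S", i)
    }, character(1))
  }
  set.seed(as.integer(seed))
  nodalList <- list()
  globalList <- list()
  nodalMetrics <- c("degree", "betweenness", "path_length",
                    "clustering", "local_efficiency")
  for (si in seq_along(connectomes)) {
    x <- connectomes[[si]]
    w <- if (is(x, "ConnectivityMatrix")) counts(x) else as.matrix(x)
    for (lev in thresholds) {
      adj <- proportionalThreshold(w, lev)
      n <- nrow(adj)
      vals <- cbind(
        degree = nodeDegree(adj),
        betweenness = betweennessCentrality(adj),
        path_length = as.numeric(nodalPathLength(adj)),
        clustering = clusteringCoefficient(adj),
        local_efficiency = localEfficiency(adj)
      )
      nodalList[[length(nodalList) + 1L]] <- data.frame(
        subject = subjects[si], threshold = lev,
        node = rep(seq_len(n), times = length(nodalMetrics)),
        metric = rep(nodalMetrics, each = n),
        value = as.vector(vals),
        stringsAsFactors = FALSE
      )
      gm <- c(
        density = networkDensity(adj),
        global_efficiency = globalEfficiency(adj),
        assortativity = suppressWarnings(
          tryCatch(assortativityCoefficient(adj), error = function(e) NaN)
        )
      )
      if (nNull > 0) {
        sw <- smallWorldness(adj, .nullStats(adj, nNull, swapsPerEdge))
        gm <- c(gm, small_worldness = unname(sw["sigma"]),
                gamma = unname(sw["gamma"]), lambda = unname(sw["lambda"]))
      }
      globalList[[length(globalList) + 1L]] <- data.frame(
        subject = subjects[si], threshold = lev,
        metric = names(gm), value = unname(gm),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    nodal = do.call(rbind, nodalList),
    global = do.call(rbind, globalList)
  )
}
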