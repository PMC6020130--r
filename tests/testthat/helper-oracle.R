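# Brute-force graph-metric oracle by exhaustive simple-path
# enumeration. Deliberately independent of the package's metric code
# (and of igraph): distances and shortest-path counts come from
# enumerating every simple path between every pair of nodes. Only
# usable for small graphs (<= 8 nodes).

# all simple paths from s to t as a list of node vectors
oracleSimplePaths <- function(adj, s, t) {
  n <- nrow(adj)
  out <- new.env()
  out$paths <- vector("list", 64)
  out$k <- 0L
  visited <- rep(FALSE, n)
  rec <- function(v, path) {
    if (v == t) {
      out$k <- out$k + 1L
      if (out$k > length(out$paths)) {
        out$paths <- c(out$paths, vector("list", length(out$paths)))
      }
      out$paths[[out$k]] <- path
      return(invisible())
    }
    for (u in which(adj[v, ] > 0)) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        rec(u, c(path, u))
        visited[u] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  rec(s, s)
  out$paths[seq_len(out$k)]
}

# per-pair geodesic distance and number of shortest paths, plus the
# count of shortest paths crossing each interior node
oraclePairData <- function(adj, s, t) {
  paths <- oracleSimplePaths(adj, s, t)
  if (!length(paths)) {
    return(list(dist = Inf, nShortest = 0,
                through = rep(0, nrow(adj))))
  }
  lens <- vapply(paths, length, integer(1)) - 1L
  d <- min(lens)
  sp <- paths[lens == d]
  through <- rep(0, nrow(adj))
  for (p in sp) {
    inner <- setdiff(p, c(s, t))
    through[inner] <- through[inner] + 1
  }
  list(dist = d, nShortest = length(sp), through = through)
}

oracleDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      D[s, t] <- D[t, s] <- oraclePairData(adj, s, t)$dist
    }
  }
  D
}

oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      pd <- oraclePairData(adj, s, t)
      if (pd$nShortest > 0) bc <- bc + pd$through / pd$nShortest
    }
  }
  bc
}

oracleGlobalEfficiency <- function(adj) {
  D <- oracleDistances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

oracleLocalEfficiency <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) >= 2) {
      out[v] <- oracleGlobalEfficiency(adj[nb, nb, drop = FALSE])
    }
  }
  out
}

oracleNodalPathLength <- function(adj) {
  D <- oracleDistances(adj)
  diag(D) <- Inf
  apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NaN
  })
}

oracleCharPathLength <- function(adj) {
  D <- oracleDistances(adj)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NaN)
  mean(d)
}

oracleClustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (adj[nb[i], nb[j]] > 0) tri <- tri + 1
      }
    }
    out[v] <- 2 * tri / (k * (k - 1))
  }
  out
}

oracleAssortativity <- function(adj) {
  deg <- rowSums(adj > 0)
  e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  suppressWarnings(stats::cor(x, y))
}

# random simple undirected graph; moderate densities keep exhaustive
# enumeration tractable
randomGraph <- function(n, p) {
  adj <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  adj[upper.tri(adj)] <- as.numeric(stats::runif(m) < p)
  adj + t(adj)
}
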