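# Independent brute-force implementations used as oracles. These share
# no code with the package: distances come from Floyd-Warshall, path
# counts from per-source BFS layering, and every metric is computed by
# naive counting loops.

mkNet <- function(m, nonnative = character(), id = "orc") {
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                        paste0("a", seq_len(ncol(m))))
  labs <- c(rownames(m), colnames(m))
  org <- stats::setNames(ifelse(labs %in% nonnative, "nonnative", "native"),
                         labs)
  interactionNetwork(m, org, id)
}

oracleNetworkMetrics <- function(m, weighting = "simple") {
  I <- nrow(m); J <- ncol(m)
  L <- 0
  for (i in seq_len(I)) for (j in seq_len(J)) L <- L + (m[i, j] != 0)
  kA <- vapply(seq_len(J), function(j) sum(m[, j] != 0), numeric(1))
  kP <- vapply(seq_len(I), function(i) sum(m[i, ] != 0), numeric(1))
  if (weighting == "simple") {
    gen <- sum(kA) / J; vul <- sum(kP) / I
  } else {
    gen <- sum(kA^2) / sum(kA); vul <- sum(kP^2) / sum(kP)
  }
  list(connectance = L / (I * J), mean_links = L / (I + J),
       generality = gen, vulnerability = vul)
}

oraclePSI <- function(m, beta = 1) {
  dP <- rowSums(m != 0); dA <- colSums(m != 0)
  vapply(seq_len(ncol(m)), function(j) {
    terms <- numeric()
    for (i in seq_len(nrow(m)))
      if (m[i, j] != 0) terms <- c(terms, 1 / dP[i])
    sum(terms) * (1 / dA[j])^beta
  }, numeric(1))
}

# one-mode projection adjacency for the given level
oracleProjection <- function(m, level) {
  x <- if (level == "plant") m else t(m)
  n <- nrow(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && any(x[i, ] != 0 & x[j, ] != 0)) adj[i, j] <- TRUE
  adj
}

oracleFloydWarshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# shortest-path counts from each source by BFS layering
oraclePathCounts <- function(adj, dist) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    finite <- order(dist[s, ])
    for (t in finite) {
      if (t == s || !is.finite(dist[s, t])) next
      preds <- which(adj[, t] & dist[s, ] == dist[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracleCentrality <- function(m, level) {
  adj <- oracleProjection(m, level)
  n <- nrow(adj)
  if (n == 1L) return(list(betweenness = 0, closeness = 1))
  d <- oracleFloydWarshall(adj)
  sigma <- oraclePathCounts(adj, d)
  btw <- numeric(n)
  if (n >= 3L) {
    for (v in seq_len(n)) {
      tot <- 0
      for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
      btw[v] <- tot / ((n - 1) * (n - 2) / 2)
    }
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    dv <- d[v, -v]
    r <- sum(is.finite(dv))
    clo[v] <- if (r == 0) 0 else (r / (n - 1)) * (r / sum(dv[is.finite(dv)]))
  }
  list(betweenness = btw, closeness = clo)
}

# all binary matrices of the given shape with no empty row or column
enumerateMatrices <- function(I, J) {
  out <- list()
  for (code in 0:(2^(I * J) - 1)) {
    m <- matrix(as.integer(intToBits(code)[seq_len(I * J)]), I, J)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0))
      out[[length(out) + 1L]] <- m
  }
  out
}

# exact expected one-step secondary extinctions after removing
# nP plants and nA animals, by enumerating all removal sets
oracleExpectedSecondary <- function(net, nP, nA) {
  plants <- plantLabels(net); animals <- animalLabels(net)
  setsP <- if (nP == 0) list(character()) else
    apply(utils::combn(plants, nP), 2, identity, simplify = FALSE)
  setsA <- if (nA == 0) list(character()) else
    apply(utils::combn(animals, nA), 2, identity, simplify = FALSE)
  vals <- unlist(lapply(setsP, function(sp)
    vapply(setsA, function(sa)
      secondaryExtinctions(net, c(sp, sa)), numeric(1))))
  list(mean = mean(vals), values = vals)
}

# closed-form paired t oracle
oraclePairedT <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# small random valid network for property tests
randomNet <- function(I, J, p = 0.4, nonnativeFrac = 0, seed = NULL,
                      id = "rand") {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(I * J, 1, p), I, J)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("p", seq_len(I)), paste0("a", seq_len(J)))
  labs <- c(rownames(m), colnames(m))
  nn <- labs[stats::runif(length(labs)) < nonnativeFrac]
  mkNet(m, nonnative = nn, id = id)
}
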