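## Species- and network-level structural metrics for binary bipartite
## networks. All metrics operate on presence/absence links only.

#' Network-level metrics: connectance, mean links, generality, vulnerability
#'
#' For a network with I plants, J animals and L links:
#' connectance = L / (I * J), the realized proportion of all possible
#' plant--animal links; mean links = L / (I + J), the average number of
#' links per species. Generality is the mean number of plant partners
#' per animal and vulnerability the mean number of animal partners per
#' plant; with `weighting = "simple"` these are plain degree means,
#' with `"degree_weighted"` each species is weighted by its own degree
#' (sum(k^2)/sum(k), the marginal-weighted form computed by standard
#' network software), which emphasises generalists.
#'
#' @param net an [InteractionNetwork-class].
#' @param weighting `"simple"` (default) or `"degree_weighted"`.
#' @return one-row `data.frame` with columns `network_id`, `study_id`,
#'   `n_plants`, `n_animals`, `n_links`, `connectance`, `mean_links`,
#'   `generality`, `vulnerability`, `weighting`.
#' @examples
#' networkMetrics(toyNetwork())                    # generality 2
#' networkMetrics(toyNetwork(), "degree_weighted") # generality 7/3
#' @export
networkMetrics <- function(net, weighting = c("simple", "degree_weighted")) {
  stopifnot(is(net, "InteractionNetwork"))
  weighting <- match.arg(weighting)
  inc <- incidence(net)
  I <- nrow(inc); J <- ncol(inc); L <- sum(inc)
  kA <- colSums(inc)   # animal degrees
  kP <- rowSums(inc)   # plant degrees
  if (weighting == "simple") {
    gen <- mean(kA); vul <- mean(kP)
  } else {
    gen <- sum(kA^2) / sum(kA); vul <- sum(kP^2) / sum(kP)
  }
  data.frame(network_id = networkId(net), study_id = studyId(net),
             n_plants = I, n_animals = J, n_links = L,
             connectance = L / (I * J), mean_links = L / (I + J),
             generality = gen, vulnerability = vul,
             weighting = weighting, stringsAsFactors = FALSE)
}

#' One-mode projection centrality (betweenness and closeness)
#'
#' Projects the bipartite network onto one trophic level (two same-level
#' species adjacent iff they share at least one partner) and computes,
#' on the unweighted projection: shortest-path betweenness normalized by
#' (n-1)(n-2)/2 for n >= 3 (0 otherwise), and component-scaled closeness
#' of node v, (r_v/(n-1)) * (r_v / sum of d(v, u) over reachable u),
#' which equals (n-1)/sum(d) on a connected graph, is 0 for an isolated
#' node, and 1 for a single-node projection.
#'
#' @param net an [InteractionNetwork-class].
#' @param level `"plant"` or `"animal"`.
#' @return `data.frame` with columns `species`, `betweenness`,
#'   `closeness`, one row per species of the level, in level order.
#' @export
projectionCentrality <- function(net, level = c("plant", "animal")) {
  stopifnot(is(net, "InteractionNetwork"))
  level <- match.arg(level)
  inc <- incidence(net)
  m <- if (level == "plant") inc else t(inc)
  adj <- (m %*% t(m)) > 0
  diag(adj) <- FALSE
  n <- nrow(adj)
  labs <- rownames(m)
  if (n == 1L)
    return(data.frame(species = labs, betweenness = 0, closeness = 1,
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_adjacency_matrix(adj + 0, mode = "undirected")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  btw <- if (n >= 3L) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  D <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    fin <- is.finite(d)
    r <- sum(fin)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(d[fin]))
  }, numeric(1))
  data.frame(species = labs, betweenness = unname(btw),
             closeness = clo, stringsAsFactors = FALSE)
}

#' Pollination Service Index for animals
#'
#' Importance of each animal as a partner for the plants of the network.
#' For binary data, PSI of animal j with plant-partner set P(j) is
#' sum over i in P(j) of (1/d_i) * (1/d_j)^beta, where d_i is the
#' plant's degree and d_j the animal's degree. With `beta = 1` values
#' lie in (0, 1]; PSI = 1 indicates an animal on which each of its
#' plants depends exclusively (the 1 x 1 mutual-dependence case).
#'
#' @param net an [InteractionNetwork-class].
#' @param beta nonnegative exponent on the animal's own dependence
#'   share; default 1.
#' @return named numeric vector over animal labels.
#' @examples
#' psiIndex(toyNetwork())["A1"]   # 11/18
#' @export
psiIndex <- function(net, beta = 1) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("beta must be a single nonnegative number")
  inc <- incidence(net)
  dP <- rowSums(inc)
  dA <- colSums(inc)
  psi <- vapply(seq_len(ncol(inc)), function(j) {
    part <- inc[, j] == 1L
    sum(1 / dP[part]) * (1 / dA[j])^beta
  }, numeric(1))
  stats::setNames(psi, colnames(inc))
}

#' Species-level metric table
#'
#' One row per species of the network: partner count (degree),
#' normalized degree (degree divided by the opposite-level size),
#' projection betweenness and closeness from [projectionCentrality()],
#' and, for animals, the Pollination Service Index from [psiIndex()]
#' (`NA` for plants).
#'
#' @param net an [InteractionNetwork-class].
#' @param beta PSI exponent, passed to [psiIndex()].
#' @return `data.frame` with columns `network_id`, `study_id`,
#'   `species`, `level`, `origin`, `degree`, `normalized_degree`,
#'   `betweenness`, `closeness`, `psi`.
#' @export
speciesMetrics <- function(net, beta = 1) {
  stopifnot(is(net, "InteractionNetwork"))
  inc <- incidence(net)
  orig <- origin(net)
  cenP <- projectionCentrality(net, "plant")
  cenA <- projectionCentrality(net, "animal")
  psi <- psiIndex(net, beta = beta)
  plants <- data.frame(
    species = rownames(inc), level = "plant",
    degree = unname(rowSums(inc)),
    normalized_degree = unname(rowSums(inc)) / ncol(inc),
    betweenness = cenP$betweenness, closeness = cenP$closeness,
    psi = NA_real_, stringsAsFactors = FALSE)
  animals <- data.frame(
    species = colnames(inc), level = "animal",
    degree = unname(colSums(inc)),
    normalized_degree = unname(colSums(inc)) / nrow(inc),
    betweenness = cenA$betweenness, closeness = cenA$closeness,
    psi = unname(psi), stringsAsFactors = FALSE)
  out <- rbind(plants, animals)
  out$origin <- unname(orig[out$species])
  cbind(data.frame(network_id = networkId(net), study_id = studyId(net),
                   stringsAsFactors = FALSE),
        out[, c("species", "level", "origin", "degree",
                "normalized_degree", "betweenness", "closeness", "psi")])
}
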