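## Reduced and control network families: targeted removal of named
## species (e.g. all non-natives), matched random removal of natives,
## and size-preserving null models.

.DEGENERATE_MIN <- 2L  # fewer than 2 species at either level => excluded

#' Remove named species from a network
#'
#' Deletes the rows/columns of the named species. Remaining species left
#' with zero partners are recorded as `orphaned` (they are the one-step
#' secondary extinctions) and dropped from the reduced incidence, so the
#' reduced network is itself valid. When fewer than 2 species remain at
#' either level the result is flagged `excluded` (degenerate: too small
#' for null-model and paired comparisons) and carries no reduced network.
#'
#' @param net an [InteractionNetwork-class].
#' @param names character vector of species labels to remove (may be
#'   empty, giving an identity result).
#' @return a [RemovalResult-class].
#' @examples
#' res <- removeSpecies(toyNetwork(), "A1")
#' orphanedSpecies(res)   # "P2"
#' @export
removeSpecies <- function(net, names = character()) {
  stopifnot(is(net, "InteractionNetwork"))
  names <- as.character(names)
  unknown <- setdiff(names, c(plantLabels(net), animalLabels(net)))
  if (length(unknown))
    stop(sprintf("species not in network: %s", paste(unknown, collapse = ", ")))
  inc <- incidence(net)
  rmP <- intersect(names, rownames(inc))
  rmA <- intersect(names, colnames(inc))
  keepP <- setdiff(rownames(inc), rmP)
  keepA <- setdiff(colnames(inc), rmA)
  red <- inc[keepP, keepA, drop = FALSE]
  ## orphans hold no surviving links, so dropping them cannot orphan others
  orphP <- rownames(red)[rowSums(red) == 0]
  orphA <- colnames(red)[colSums(red) == 0]
  red <- red[setdiff(rownames(red), orphP),
             setdiff(colnames(red), orphA), drop = FALSE]
  excluded <- nrow(red) < .DEGENERATE_MIN || ncol(red) < .DEGENERATE_MIN
  reduced <- NULL
  if (!excluded)
    reduced <- interactionNetwork(red, origin(net)[c(rownames(red), colnames(red))],
                                  networkId(net), studyId(net), networkType(net))
  new("RemovalResult", reduced = reduced,
      removedPlants = rmP, removedAnimals = rmA,
      orphaned = c(orphP, orphA), excluded = excluded)
}

#' Remove all non-native species (natives-only network)
#'
#' @param net an [InteractionNetwork-class].
#' @return a [RemovalResult-class]; the identity result (with a warning)
#'   when the network contains no non-native species.
#' @export
removeNonnatives <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  nn <- names(which(isNonnative(net)))
  if (!length(nn))
    warning(sprintf("network '%s' contains no non-native species; identity removal",
                    networkId(net)))
  removeSpecies(net, nn)
}

#' Matched random removal of native species
#'
#' The size-matched control for [removeNonnatives()]: removes, uniformly
#' at random without replacement among native species, exactly as many
#' plants as there are non-native plants and as many animals as there
#' are non-native animals. Deterministic given `rngSeed`.
#'
#' @param net an [InteractionNetwork-class].
#' @param rngSeed integer seed; `NULL` uses the current RNG state.
#' @return a [RemovalResult-class].
#' @export
matchedRandomRemoval <- function(net, rngSeed = NULL) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!is.null(rngSeed)) set.seed(rngSeed)
  nn <- isNonnative(net)
  lv <- speciesLevel(net)
  for (level in c("plant", "animal")) {
    nNat <- sum(!nn & lv == level)
    nNon <- sum(nn & lv == level)
    if (nNat < nNon)
      stop(sprintf("fewer native than non-native species at the %s level", level))
  }
  natP <- names(which(!nn & lv == "plant"))
  natA <- names(which(!nn & lv == "animal"))
  pick <- c(.sampleExact(natP, sum(nn & lv == "plant")),
            .sampleExact(natA, sum(nn & lv == "animal")))
  removeSpecies(net, pick)
}

## sample() treats a length-1 x as 1:x; avoid that trap
.sampleExact <- function(x, size) {
  if (size == 0L) return(character())
  x[sample.int(length(x), size)]
}

#' Size- and fill-conserving null models after random extinctions
#'
#' For each replicate: (i) draw `nRemovePlants` plants and
#' `nRemoveAnimals` animals uniformly at random from ALL species
#' (regardless of origin) and delete them; (ii) redistribute the
#' surviving links as a uniform random binary matrix on the reduced
#' dimensions, conditioned on the replicate's surviving link total, with
#' draws containing an empty row or column rejected (capped at 10,000
#' attempts per replicate). Every replicate therefore conserves the
#' reduced dimensions exactly and its own post-removal link total
#' exactly, so connectance comparisons isolate rewiring rather than
#' fill. A degree-sequence-preserving alternative (`method = "swap"`,
#' curveball trades on the post-removal matrix with orphans dropped) is
#' available but is not the default.
#'
#' @param net an [InteractionNetwork-class].
#' @param nRemovePlants,nRemoveAnimals integers; reduced dimensions must
#'   be at least 2 x 2.
#' @param reps number of replicates (default 1000).
#' @param rngSeed integer seed; `NULL` uses the current RNG state.
#' @param method `"fill"` (default, uniform fixed-fill) or `"swap"`.
#' @param maxRedraws for sparse networks a particular extinction draw
#'   can leave a link total that is practically impossible to
#'   redistribute without empty margins; with `maxRedraws > 0` such a
#'   replicate redraws its extinction set (up to the given number of
#'   times) instead of aborting, conditioning the null on
#'   redistributable draws. Default 0: the replicate errors.
#' @return list of `reps` [InteractionNetwork-class] objects.
#' @export
nullModel <- function(net, nRemovePlants, nRemoveAnimals, reps = 1000,
                      rngSeed = NULL, method = c("fill", "swap"),
                      maxRedraws = 0L) {
  stopifnot(is(net, "InteractionNetwork"))
  method <- match.arg(method)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  inc <- incidence(net)
  Ip <- nrow(inc) - nRemovePlants
  Jp <- ncol(inc) - nRemoveAnimals
  if (Ip < 2L || Jp < 2L)
    stop("reduced dimensions must be at least 2 x 2")
  lapply(seq_len(reps), function(k) {
    filled <- NULL
    for (draw in seq_len(maxRedraws + 1L)) {
      rmP <- .sampleExact(rownames(inc), nRemovePlants)
      rmA <- .sampleExact(colnames(inc), nRemoveAnimals)
      red <- inc[setdiff(rownames(inc), rmP),
                 setdiff(colnames(inc), rmA), drop = FALSE]
      filled <- if (method == "fill") {
        tryCatch(.uniformFill(nrow(red), ncol(red), sum(red),
                              rownames(red), colnames(red)),
                 error = function(e)
                   if (draw <= maxRedraws) NULL else stop(e))
      } else {
        .curveball(red[rowSums(red) > 0, colSums(red) > 0, drop = FALSE])
      }
      if (!is.null(filled)) break
    }
    interactionNetwork(filled,
                       origin(net)[c(rownames(filled), colnames(filled))],
                       sprintf("%s_null%04d", networkId(net), k),
                       studyId(net), networkType(net))
  })
}

## uniform binary matrix with exactly L ones and no empty row/column,
## by rejection from the unconditioned uniform fixed-fill distribution
.uniformFill <- function(I, J, L, rlab, clab, maxAttempts = 10000L) {
  if (L < max(I, J) || L > I * J)
    stop(sprintf(
      "fill of %d links on a %d x %d matrix with no empty row/column is infeasible",
      L, I, J))
  for (att in seq_len(maxAttempts)) {
    idx <- sample.int(I * J, L)
    ri <- (idx - 1L) %% I + 1L
    ci <- (idx - 1L) %/% I + 1L
    if (all(tabulate(ri, I) > 0L) && all(tabulate(ci, J) > 0L)) {
      m <- matrix(0L, I, J, dimnames = list(rlab, clab))
      m[idx] <- 1L
      return(m)
    }
  }
  stop(sprintf(
    "no valid fill found in %d attempts; a %d-link fill on %d x %d is practically infeasible",
    maxAttempts, L, I, J))
}

## curveball trades: degree-preserving randomization of a binary matrix
.curveball <- function(m, nTrades = 5L * nrow(m)) {
  I <- nrow(m)
  if (I < 2L) return(m)
  rows <- apply(m, 1L, function(r) which(r == 1L), simplify = FALSE)
  for (t in seq_len(nTrades)) {
    ab <- sample.int(I, 2L)
    a <- rows[[ab[1]]]; b <- rows[[ab[2]]]
    shared <- intersect(a, b)
    onlyA <- setdiff(a, shared); onlyB <- setdiff(b, shared)
    pool <- c(onlyA, onlyB)
    if (length(pool) < 2L || !length(onlyA) || !length(onlyB)) next
    newA <- .sampleExact(pool, length(onlyA))
    rows[[ab[1]]] <- c(shared, newA)
    rows[[ab[2]]] <- c(shared, setdiff(pool, newA))
  }
  out <- matrix(0L, I, ncol(m), dimnames = dimnames(m))
  for (i in seq_len(I)) out[i, rows[[i]]] <- 1L
  out
}
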