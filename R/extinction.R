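## Secondary-extinction accounting. A secondary extinction is a species
## left with zero interaction partners after other species are removed
## (one-step operational definition; no rewiring).

#' One-step secondary extinctions after a targeted removal
#'
#' Deletes the named species and counts the remaining species that now
#' lack any partner. No iterative cascade is applied (and none is
#' possible for a single simultaneous removal: a partnerless survivor
#' holds no surviving links, so its loss orphans nobody else).
#'
#' @param net an [InteractionNetwork-class].
#' @param names species labels to remove.
#' @return integer count of secondary extinctions.
#' @examples
#' secondaryExtinctions(toyNetwork(), "A1")  # 1: P2 loses its sole partner
#' @export
secondaryExtinctions <- function(net, names = character()) {
  stopifnot(is(net, "InteractionNetwork"))
  names <- as.character(names)
  unknown <- setdiff(names, c(plantLabels(net), animalLabels(net)))
  if (length(unknown))
    stop(sprintf("species not in network: %s", paste(unknown, collapse = ", ")))
  if (!length(names)) return(0L)
  inc <- incidence(net)
  keepP <- setdiff(rownames(inc), names)
  keepA <- setdiff(colnames(inc), names)
  red <- inc[keepP, keepA, drop = FALSE]
  sum(rowSums(red) == 0L) + sum(colSums(red) == 0L)
}

#' Random-loss secondary-extinction curves
#'
#' Monte-Carlo simulation of random species losses: each replicate draws
#' `nRemovePlants` plants and `nRemoveAnimals` animals uniformly at
#' random, permutes the combined set into a removal order (levels
#' interleaved uniformly), and records the cumulative number of
#' secondary extinctions after each primary removal. A secondary
#' extinction at step m is a species outside the replicate's primary
#' removal set whose partners are all among the first m removals;
#' primary removals are never double-counted as secondary. With
#' `cascade = TRUE` orphaned species are additionally treated as gone
#' when assessing later orphans (iterated to a fixed point per step);
#' for one-shot bipartite removals this coincides with the one-step
#' count, since a partnerless species holds no surviving links.
#'
#' @param net an [InteractionNetwork-class].
#' @param nRemovePlants,nRemoveAnimals number of primary removals per
#'   level; must not exceed the level sizes.
#' @param reps number of replicates (default 1000).
#' @param rngSeed integer seed; `NULL` uses the current RNG state.
#' @param cascade logical, default `FALSE`.
#' @return long-format `data.frame` with columns `replicate`, `step`,
#'   `species_removed`, `cumulative_secondary` (step m row holds the
#'   count after the first m removals; the implicit step-0 count is 0).
#' @seealso [expectedSecondaryAt()]
#' @export
randomLossCurves <- function(net, nRemovePlants, nRemoveAnimals,
                             reps = 1000, rngSeed = NULL, cascade = FALSE) {
  stopifnot(is(net, "InteractionNetwork"))
  inc <- incidence(net)
  if (nRemovePlants < 0 || nRemovePlants > nrow(inc) ||
      nRemoveAnimals < 0 || nRemoveAnimals > ncol(inc))
    stop("infeasible per-level removal counts")
  M <- nRemovePlants + nRemoveAnimals
  if (!is.null(rngSeed)) set.seed(rngSeed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    rmP <- .sampleExact(rownames(inc), nRemovePlants)
    rmA <- .sampleExact(colnames(inc), nRemoveAnimals)
    ord <- .sampleExact(c(rmP, rmA), M)
    cum <- .curveOneReplicate(inc, ord, cascade)
    out[[r]] <- data.frame(replicate = r,
                           step = seq_len(M),
                           species_removed = ord,
                           cumulative_secondary = cum,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## cumulative one-step secondary extinctions along one removal order
.curveOneReplicate <- function(inc, ord, cascade) {
  if (!length(ord)) return(integer())
  plants <- rownames(inc); animals <- colnames(inc)
  inRemoval <- c(plants, animals) %in% ord
  names(inRemoval) <- c(plants, animals)
  survA <- rowSums(inc)   # surviving animal partners per plant
  survP <- colSums(inc)   # surviving plant partners per animal
  gone <- character()     # removed or (cascade) orphaned
  orphans <- character()
  cum <- integer(length(ord))
  dropOne <- function(sp) {
    if (sp %in% plants) {
      js <- animals[inc[sp, ] == 1L]
      survP[js] <<- survP[js] - 1L
    } else {
      is <- plants[inc[, sp] == 1L]
      survA[is] <<- survA[is] - 1L
    }
  }
  for (m in seq_along(ord)) {
    dropOne(ord[m])
    gone <- c(gone, ord[m])
    repeat {
      cand <- c(plants[survA[plants] == 0L], animals[survP[animals] == 0L])
      cand <- setdiff(cand[!inRemoval[cand]], orphans)
      if (!length(cand)) break
      orphans <- c(orphans, cand)
      if (!cascade) break
      for (sp in cand) dropOne(sp)
    }
    cum[m] <- length(orphans)
  }
  cum
}

#' Expected secondary extinctions after m random losses
#'
#' Mean and standard error, over the replicates of a
#' [randomLossCurves()] simulation, of the cumulative secondary
#' extinctions after the first `m` primary removals.
#'
#' @param curves the `data.frame` returned by [randomLossCurves()].
#' @param m number of primary removals; 0 returns 0 +/- 0.
#' @return named list with `mean`, `se`, `n_replicates`, `m`.
#' @export
expectedSecondaryAt <- function(curves, m) {
  if (m == 0)
    return(list(mean = 0, se = 0,
                n_replicates = length(unique(curves$replicate)), m = 0))
  if (!m %in% curves$step)
    stop(sprintf("m = %d is outside the simulated removal range", m))
  x <- curves$cumulative_secondary[curves$step == m]
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
       n_replicates = length(x), m = m)
}
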