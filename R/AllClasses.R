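#' @import methods
NULL

.NETWORK_TYPES <- c("pollination", "seed_dispersal", "other")
.ORIGINS <- c("native", "nonnative")

#' InteractionNetwork: an annotated binary bipartite network
#'
#' The central data object of the package: a labeled binary incidence
#' matrix for a plant--animal mutualistic network (rows = plants, the
#' lower trophic level; columns = animals, the higher trophic level),
#' together with a per-species origin annotation (native vs non-native)
#' and study metadata used as a blocking factor in cross-network
#' statistics.
#'
#' @slot networkId single string identifying the network.
#' @slot studyId single string identifying the source study; networks
#'   from the same study share a `studyId` and are blocked together in
#'   mixed-effects comparisons.
#' @slot networkType one of `"pollination"`, `"seed_dispersal"`, `"other"`.
#' @slot incidence integer 0/1 matrix with unique rownames (plant labels)
#'   and colnames (animal labels); entry `[i, j] == 1` iff plant i and
#'   animal j interact. Every row and column has at least one 1: an
#'   observed network contains no partnerless species.
#' @slot origin named character vector mapping every species label to
#'   `"native"` or `"nonnative"`.
#'
#' @seealso [interactionNetwork()] for the user-facing constructor,
#'   [readIncidenceCSV()], [generateNetwork()].
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(
    networkId   = "character",
    studyId     = "character",
    networkType = "character",
    incidence   = "matrix",
    origin      = "character"
  )
)

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  inc <- object@incidence
  if (length(object@networkId) != 1L || is.na(object@networkId) ||
      !nzchar(object@networkId))
    msg <- c(msg, "networkId must be a single non-empty string")
  if (length(object@studyId) != 1L || is.na(object@studyId))
    msg <- c(msg, "studyId must be a single string")
  if (length(object@networkType) != 1L ||
      !object@networkType %in% .NETWORK_TYPES)
    msg <- c(msg, sprintf("networkType must be one of %s",
                          paste(.NETWORK_TYPES, collapse = ", ")))
  if (!is.numeric(inc))
    return(c(msg, "incidence must be a numeric matrix"))
  if (nrow(inc) < 1L || ncol(inc) < 1L)
    msg <- c(msg, "incidence must have at least one row and one column")
  if (!all(inc %in% c(0, 1)))
    msg <- c(msg, "incidence entries must all be 0 or 1")
  pl <- rownames(inc); al <- colnames(inc)
  if (is.null(pl) || is.null(al))
    return(c(msg, "incidence must carry row and column species labels"))
  labs <- c(pl, al)
  if (anyDuplicated(labs))
    msg <- c(msg, sprintf("duplicate species labels: %s",
                          paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  zr <- pl[rowSums(inc) == 0]
  if (length(zr))
    msg <- c(msg, sprintf("plant(s) without any partner: %s",
                          paste(zr, collapse = ", ")))
  zc <- al[colSums(inc) == 0]
  if (length(zc))
    msg <- c(msg, sprintf("animal(s) without any partner: %s",
                          paste(zc, collapse = ", ")))
  miss <- setdiff(labs, names(object@origin))
  if (length(miss))
    msg <- c(msg, sprintf("species missing an origin annotation: %s",
                          paste(miss, collapse = ", ")))
  bad <- setdiff(unique(object@origin), .ORIGINS)
  if (length(bad))
    msg <- c(msg, sprintf("invalid origin value(s): %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' NetworkCollection: an ordered set of networks
#'
#' A container for a set of [InteractionNetwork-class] objects (one
#' empirical or synthetic network each) with unique network ids, the unit
#' on which cross-network statistics operate.
#'
#' @slot networks list of `InteractionNetwork` objects.
#' @exportClass NetworkCollection
setClass("NetworkCollection", slots = c(networks = "list"))

setValidity("NetworkCollection", function(object) {
  ok <- vapply(object@networks, is, logical(1), class2 = "InteractionNetwork")
  if (!all(ok))
    return("all elements must be InteractionNetwork objects")
  ids <- vapply(object@networks, function(n) n@networkId, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicate network ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' RemovalResult: outcome of a species-removal experiment
#'
#' Records the reduced network after deleting a set of species, the
#' species that were left partnerless by the deletion (the one-step
#' secondary extinctions, dropped from the reduced incidence but always
#' reported), and whether the reduced network is too degenerate to
#' analyse (fewer than 2 species remaining at either level).
#'
#' @slot reduced the reduced [InteractionNetwork-class], or `NULL` when
#'   `excluded` is `TRUE`.
#' @slot removedPlants,removedAnimals character vectors of deleted labels.
#' @slot orphaned character vector of species left with zero partners.
#' @slot excluded logical flag; `TRUE` when the reduction is degenerate.
#' @exportClass RemovalResult
setClass("RemovalResult",
  slots = c(
    reduced        = "ANY",
    removedPlants  = "character",
    removedAnimals = "character",
    orphaned       = "character",
    excluded       = "logical"
  )
)

setValidity("RemovalResult", function(object) {
  if (length(object@excluded) != 1L || is.na(object@excluded))
    return("excluded must be TRUE or FALSE")
  if (!object@excluded && !is(object@reduced, "InteractionNetwork"))
    return("reduced must be an InteractionNetwork when excluded is FALSE")
  TRUE
})

#' Construct an InteractionNetwork
#'
#' @param incidence numeric matrix with plant rownames and animal
#'   colnames; nonzero entries are binarized (with a warning if any
#'   entry exceeds 1, since interaction strengths are discarded).
#' @param origin named character vector over all species labels with
#'   values `"native"`, `"nonnative"` or `"unknown"`; `"unknown"` is
#'   conservatively coerced to `"native"` with a warning, so that only
#'   species positively known to be introduced count as non-native.
#' @param networkId,studyId identifier strings.
#' @param networkType `"pollination"` (default), `"seed_dispersal"` or
#'   `"other"`.
#' @return a validated [InteractionNetwork-class] object.
#' @examples
#' m <- matrix(c(1, 1, 1, 1, 0, 1, 0, 0, 1), 3, 3,
#'             dimnames = list(c("P1", "P2", "P3"), c("A1", "A2", "A3")))
#' org <- c(P1 = "native", P2 = "native", P3 = "native",
#'          A1 = "nonnative", A2 = "native", A3 = "native")
#' net <- interactionNetwork(m, org, "toy3")
#' nLinks(net)
#' @export
interactionNetwork <- function(incidence, origin, networkId,
                               studyId = networkId,
                               networkType = "pollination") {
  if (!is.matrix(incidence) || !is.numeric(incidence))
    stop("incidence must be a numeric matrix")
  if (anyNA(incidence))
    stop("incidence contains missing values")
  if (any(incidence > 1)) {
    warning("quantitative interaction values found; binarizing to presence/absence")
  }
  inc <- (incidence != 0) + 0L
  storage.mode(inc) <- "integer"
  origin <- .coerceOrigin(origin)
  new("InteractionNetwork",
      networkId = as.character(networkId),
      studyId = as.character(studyId),
      networkType = match.arg(networkType, .NETWORK_TYPES),
      incidence = inc, origin = origin)
}

## "unknown" counts as native: misclassifying toward native only widens the
## native group's spread and so inflates Type II, never Type I, error.
.coerceOrigin <- function(origin) {
  if (is.null(names(origin)) || anyNA(names(origin)))
    stop("origin must be a named character vector")
  origin <- vapply(origin, as.character, character(1))
  unk <- origin == "unknown"
  if (any(unk)) {
    warning(sprintf("origin 'unknown' coerced to 'native' for: %s",
                    paste(names(origin)[unk], collapse = ", ")))
    origin[unk] <- "native"
  }
  bad <- setdiff(unique(origin), .ORIGINS)
  if (length(bad))
    stop(sprintf("invalid origin value(s): %s", paste(bad, collapse = ", ")))
  origin
}

#' Construct a NetworkCollection
#'
#' @param networks a list of [InteractionNetwork-class] objects (or
#'   several networks passed as `...`).
#' @param ... individual networks, if `networks` is missing.
#' @return a [NetworkCollection-class].
#' @export
networkCollection <- function(networks = list(), ...) {
  extra <- list(...)
  if (is(networks, "InteractionNetwork")) networks <- list(networks)
  new("NetworkCollection", networks = c(networks, extra))
}

setMethod("show", "InteractionNetwork", function(object) {
  nn <- sum(object@origin[c(rownames(object@incidence),
                            colnames(object@incidence))] == "nonnative")
  cat(sprintf(
    "InteractionNetwork '%s' (%s, study '%s')\n  %d plants x %d animals, %d links (connectance %.3f), %d non-native\n",
    object@networkId, object@networkType, object@studyId,
    nrow(object@incidence), ncol(object@incidence), sum(object@incidence),
    mean(object@incidence), nn))
})

setMethod("show", "NetworkCollection", function(object) {
  cat(sprintf("NetworkCollection of %d network(s)\n", length(object@networks)))
  if (length(object@networks)) {
    ids <- vapply(object@networks, function(n) n@networkId, character(1))
    cat("  ids:", paste(utils::head(ids, 8), collapse = ", "),
        if (length(ids) > 8) "..." else "", "\n")
  }
})

setMethod("show", "RemovalResult", function(object) {
  cat(sprintf(
    "RemovalResult: removed %d plant(s), %d animal(s); %d orphaned; excluded = %s\n",
    length(object@removedPlants), length(object@removedAnimals),
    length(object@orphaned), object@excluded))
})

#' @describeIn InteractionNetwork number of networks in a collection
#' @param x a `NetworkCollection`.
#' @export
setMethod("length", "NetworkCollection", function(x) length(x@networks))

#' @rdname networkCollection
#' @param x a `NetworkCollection`.
#' @param i index or network id.
#' @export
setMethod("[[", "NetworkCollection", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@networks, function(n) n@networkId, character(1))
    i <- match(i, ids)
    if (is.na(i)) stop("no network with that id")
  }
  x@networks[[i]]
})
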