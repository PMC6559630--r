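#' Accessors for InteractionNetwork and RemovalResult objects
#'
#' Slot access goes through these accessors, never through `@`.
#' `plantLabels`/`animalLabels` return the ordered species names of each
#' level; `nPlants`, `nAnimals` and `nLinks` return the dimensions I and
#' J and the link total L; `origin` returns the named nativity vector
#' and `isNonnative` a named logical over all species; `speciesLevel`
#' returns `"plant"`/`"animal"` per species.
#'
#' @param x an [InteractionNetwork-class] (or [RemovalResult-class] for
#'   the removal accessors).
#' @return see the individual descriptions.
#' @name network-accessors
#' @aliases incidence networkId studyId networkType plantLabels
#'   animalLabels nPlants nAnimals nLinks origin isNonnative speciesLevel
#' @examples
#' net <- toyNetwork()
#' plantLabels(net)
#' nLinks(net)
NULL

#' @rdname network-accessors
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))
#' @rdname network-accessors
#' @export
setMethod("incidence", "InteractionNetwork", function(x) x@incidence)

#' @rdname network-accessors
#' @export
setGeneric("networkId", function(x) standardGeneric("networkId"))
#' @rdname network-accessors
#' @export
setMethod("networkId", "InteractionNetwork", function(x) x@networkId)

#' @rdname network-accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))
#' @rdname network-accessors
#' @export
setMethod("studyId", "InteractionNetwork", function(x) x@studyId)

#' @rdname network-accessors
#' @export
setGeneric("networkType", function(x) standardGeneric("networkType"))
#' @rdname network-accessors
#' @export
setMethod("networkType", "InteractionNetwork", function(x) x@networkType)

#' @rdname network-accessors
#' @export
setGeneric("plantLabels", function(x) standardGeneric("plantLabels"))
#' @rdname network-accessors
#' @export
setMethod("plantLabels", "InteractionNetwork",
          function(x) rownames(x@incidence))

#' @rdname network-accessors
#' @export
setGeneric("animalLabels", function(x) standardGeneric("animalLabels"))
#' @rdname network-accessors
#' @export
setMethod("animalLabels", "InteractionNetwork",
          function(x) colnames(x@incidence))

#' @rdname network-accessors
#' @export
setGeneric("nPlants", function(x) standardGeneric("nPlants"))
#' @rdname network-accessors
#' @export
setMethod("nPlants", "InteractionNetwork", function(x) nrow(x@incidence))

#' @rdname network-accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname network-accessors
#' @export
setMethod("nAnimals", "InteractionNetwork", function(x) ncol(x@incidence))

#' @rdname network-accessors
#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))
#' @rdname network-accessors
#' @export
setMethod("nLinks", "InteractionNetwork", function(x) sum(x@incidence))

#' @rdname network-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname network-accessors
#' @export
setMethod("origin", "InteractionNetwork", function(x)
  x@origin[c(rownames(x@incidence), colnames(x@incidence))])

#' @rdname network-accessors
#' @export
setGeneric("isNonnative", function(x) standardGeneric("isNonnative"))
#' @rdname network-accessors
#' @export
setMethod("isNonnative", "InteractionNetwork", function(x)
  origin(x) == "nonnative")

#' @rdname network-accessors
#' @export
setGeneric("speciesLevel", function(x) standardGeneric("speciesLevel"))
#' @rdname network-accessors
#' @export
setMethod("speciesLevel", "InteractionNetwork", function(x) {
  lv <- c(rep("plant", nrow(x@incidence)), rep("animal", ncol(x@incidence)))
  names(lv) <- c(rownames(x@incidence), colnames(x@incidence))
  lv
})

#' @rdname network-accessors
#' @export
setGeneric("reducedNetwork", function(x) standardGeneric("reducedNetwork"))
#' @rdname network-accessors
#' @export
setMethod("reducedNetwork", "RemovalResult", function(x) x@reduced)

#' @rdname network-accessors
#' @export
setGeneric("orphanedSpecies", function(x) standardGeneric("orphanedSpecies"))
#' @rdname network-accessors
#' @export
setMethod("orphanedSpecies", "RemovalResult", function(x) x@orphaned)

#' @rdname network-accessors
#' @export
setGeneric("removedSpecies", function(x) standardGeneric("removedSpecies"))
#' @rdname network-accessors
#' @export
setMethod("removedSpecies", "RemovalResult", function(x)
  c(x@removedPlants, x@removedAnimals))

#' @rdname network-accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))
#' @rdname network-accessors
#' @export
setMethod("isExcluded", "RemovalResult", function(x) x@excluded)

#' A 3 x 3 worked example network
#'
#' The small plant--animal network used throughout the documentation and
#' tests: plants P1--P3, animals A1--A3, six links, with the
#' supergeneralist animal A1 annotated non-native. Its metric values are
#' all checkable by hand (connectance 6/9, simple generality 2, PSI of
#' A1 = 11/18, one secondary extinction when A1 is removed).
#'
#' @return an [InteractionNetwork-class].
#' @export
toyNetwork <- function() {
  m <- matrix(c(1L, 1L, 0L,
                1L, 0L, 0L,
                1L, 1L, 1L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("A1", "A2", "A3")))
  interactionNetwork(m,
    c(P1 = "native", P2 = "native", P3 = "native",
      A1 = "nonnative", A2 = "native", A3 = "native"),
    networkId = "TOY3", studyId = "toy-study")
}
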