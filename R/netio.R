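## Readers and writers for annotated bipartite networks.
##
## File conventions (all plain text):
##   incidence CSV : first cell blank or "species"; header row = animal
##                   labels; each data row = plant label + 0/1 cells
##                   (nonzero counts are binarized on read).
##   edge list TSV : header plant<TAB>animal[<TAB>weight]; duplicate
##                   edges collapse to one link; label order is
##                   first-appearance order.
##   nativity CSV  : header species,level,origin with level in
##                   {plant, animal} and origin in
##                   {native, nonnative, unknown}.

.readNativity <- function(path) {
  nat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "level", "origin")
  if (!all(need %in% names(nat)))
    stop("nativity table must have columns species, level, origin")
  if (anyDuplicated(nat$species))
    stop(sprintf("duplicate species in nativity table: %s",
                 paste(unique(nat$species[duplicated(nat$species)]),
                       collapse = ", ")))
  bad <- setdiff(unique(nat$level), c("plant", "animal"))
  if (length(bad))
    stop(sprintf("invalid level value(s) in nativity table: %s",
                 paste(bad, collapse = ", ")))
  nat
}

.checkNativityCovers <- function(nat, plants, animals) {
  missP <- setdiff(plants, nat$species[nat$level == "plant"])
  missA <- setdiff(animals, nat$species[nat$level == "animal"])
  if (length(missP) || length(missA))
    stop(sprintf("species missing from nativity table: %s",
                 paste(c(missP, missA), collapse = ", ")))
  stats::setNames(nat$origin, nat$species)[c(plants, animals)]
}

#' Read a network from an incidence-matrix CSV plus a nativity table
#'
#' Reads a binary (or count, binarized with a warning) plant x animal
#' incidence matrix and joins the per-species nativity annotations.
#' Species annotated `"unknown"` are conservatively stored as native.
#'
#' @param path incidence CSV (see file conventions in the package
#'   vignette): header of animal labels, first column of plant labels.
#' @param nativityPath CSV with columns `species,level,origin`.
#' @param networkId,studyId identifier strings.
#' @param networkType `"pollination"`, `"seed_dispersal"` or `"other"`.
#' @return a validated [InteractionNetwork-class].
#' @examples
#' d <- tempfile(); n <- tempfile()
#' writeNetwork(toyNetwork(), d, n)
#' net <- readIncidenceCSV(d, n, networkId = "TOY3")
#' @export
readIncidenceCSV <- function(path, nativityPath, networkId,
                             studyId = networkId,
                             networkType = "pollination") {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = NULL,
                         stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("incidence CSV must have a label column and at least one animal column")
  plants <- as.character(raw[[1]])
  animals <- colnames(raw)[-1]
  if (anyDuplicated(plants))
    stop(sprintf("duplicate plant labels: %s",
                 paste(unique(plants[duplicated(plants)]), collapse = ", ")))
  if (anyDuplicated(animals))
    stop(sprintf("duplicate animal labels: %s",
                 paste(unique(animals[duplicated(animals)]), collapse = ", ")))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at plant '%s', animal '%s'",
                 plants[bad[1]], animals[bad[2]]))
  }
  dimnames(num) <- list(plants, animals)
  orig <- .checkNativityCovers(.readNativity(nativityPath), plants, animals)
  interactionNetwork(num, orig, networkId, studyId, networkType)
}

#' Read a network from a plant/animal edge list TSV
#'
#' Produces a network equivalent to the incidence reader: duplicate
#' edges collapse to a single link; row/column order is the order of
#' first appearance in the file.
#'
#' @inheritParams readIncidenceCSV
#' @param path TSV with header `plant`, `animal` and optionally `weight`
#'   (weights are ignored beyond presence).
#' @return a validated [InteractionNetwork-class].
#' @export
readEdgeListTSV <- function(path, nativityPath, networkId,
                            studyId = networkId,
                            networkType = "pollination") {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("plant", "animal") %in% names(ed)))
    stop("edge list must have columns plant and animal")
  if (nrow(ed) == 0L)
    stop("no interactions in edge list")
  plants <- unique(ed$plant)
  animals <- unique(ed$animal)
  inc <- matrix(0L, length(plants), length(animals),
                dimnames = list(plants, animals))
  inc[cbind(match(ed$plant, plants), match(ed$animal, animals))] <- 1L
  orig <- .checkNativityCovers(.readNativity(nativityPath), plants, animals)
  interactionNetwork(inc, orig, networkId, studyId, networkType)
}

#' Write a network to an incidence CSV and nativity CSV
#'
#' Round-trip property: reading the written pair back with
#' [readIncidenceCSV()] reproduces incidence, labels and origin exactly.
#'
#' @param net an [InteractionNetwork-class].
#' @param path destination incidence CSV.
#' @param nativityPath destination nativity CSV; defaults to
#'   `<path>.nativity.csv`.
#' @return invisibly, the two paths written.
#' @export
writeNetwork <- function(net, path,
                         nativityPath = paste0(path, ".nativity.csv")) {
  stopifnot(is(net, "InteractionNetwork"))
  inc <- incidence(net)
  df <- data.frame(species = rownames(inc), inc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  nat <- data.frame(species = c(plantLabels(net), animalLabels(net)),
                    level = unname(speciesLevel(net)),
                    origin = unname(origin(net)),
                    stringsAsFactors = FALSE)
  utils::write.csv(nat, nativityPath, row.names = FALSE, quote = TRUE)
  invisible(c(incidence = path, nativity = nativityPath))
}
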