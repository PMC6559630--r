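# Readers, writers and validation of annotated bipartite networks.

writeToyFiles <- function(dir = tempfile()) {
  dir.create(dir)
  inc <- file.path(dir, "toy.csv")
  nat <- file.path(dir, "toy_nativity.csv")
  writeLines(c("species,A1,A2,A3",
               "P1,1,1,0",
               "P2,1,0,0",
               "P3,1,1,1"), inc)
  writeLines(c("species,level,origin",
               "P1,plant,native", "P2,plant,native", "P3,plant,native",
               "A1,animal,nonnative", "A2,animal,native",
               "A3,animal,native"), nat)
  list(inc = inc, nat = nat, dir = dir)
}

test_that("incidence CSV reader reproduces the worked 3x3 network", {
  f <- writeToyFiles()
  net <- readIncidenceCSV(f$inc, f$nat, networkId = "TOY3",
                          studyId = "toy-study")
  expect_s4_class(net, "InteractionNetwork")
  expect_equal(nPlants(net), 3L)
  expect_equal(nAnimals(net), 3L)
  expect_equal(nLinks(net), 6L)
  expect_identical(incidence(net), incidence(toyNetwork()))
  expect_identical(origin(net), origin(toyNetwork()))
})

test_that("minimal 1x1 network is valid and counts one link", {
  d <- tempfile(); dir.create(d)
  writeLines(c("species,A1", "P1,1"), file.path(d, "m.csv"))
  writeLines(c("species,level,origin", "P1,plant,native",
               "A1,animal,native"), file.path(d, "n.csv"))
  net <- readIncidenceCSV(file.path(d, "m.csv"), file.path(d, "n.csv"), "mini")
  expect_equal(nLinks(net), 1L)
})

test_that("counts are binarized with a warning and unknown origin coerces to native", {
  f <- writeToyFiles()
  writeLines(c("species,A1,A2", "P1,3,0", "P2,1,2"), f$inc)
  writeLines(c("species,level,origin", "P1,plant,native",
               "P2,plant,unknown", "A1,animal,native",
               "A2,animal,unknown"), f$nat)
  expect_warning(expect_warning(
    net <<- readIncidenceCSV(f$inc, f$nat, "w"),
    "binarizing"), "unknown")
  expect_equal(nLinks(net), 3L)
  expect_true(all(origin(net) == "native"))
})

test_that("reader errors name the offending species or cell", {
  f <- writeToyFiles()
  # all-zero row names the plant
  writeLines(c("species,A1,A2", "P1,1,1", "P2,0,0"), f$inc)
  writeLines(c("species,level,origin", "P1,plant,native",
               "P2,plant,native", "A1,animal,native",
               "A2,animal,native"), f$nat)
  expect_error(readIncidenceCSV(f$inc, f$nat, "z"), "P2")
  # non-numeric cell reports coordinates
  writeLines(c("species,A1,A2", "P1,1,x", "P2,1,1"), f$inc)
  expect_error(readIncidenceCSV(f$inc, f$nat, "z"), "P1.*A2")
  # duplicate labels
  writeLines(c("species,A1,A2", "P1,1,1", "P1,1,1"), f$inc)
  expect_error(readIncidenceCSV(f$inc, f$nat, "z"), "duplicate")
  # missing nativity entry
  writeLines(c("species,A1,A2", "P1,1,1", "P2,1,1"), f$inc)
  writeLines(c("species,level,origin", "P1,plant,native",
               "A1,animal,native", "A2,animal,native"), f$nat)
  expect_error(readIncidenceCSV(f$inc, f$nat, "z"), "P2")
})

test_that("edge list reader is equivalent to the incidence reader", {
  f <- writeToyFiles()
  el <- file.path(f$dir, "toy.tsv")
  writeLines(c("plant\tanimal",
               "P1\tA1", "P1\tA2", "P2\tA1",
               "P3\tA1", "P3\tA2", "P3\tA3",
               "P1\tA1"), el)  # duplicated edge collapses
  net <- readEdgeListTSV(el, f$nat, networkId = "TOY3",
                         studyId = "toy-study")
  expect_identical(incidence(net), incidence(toyNetwork()))
  expect_equal(nLinks(net), 6L)
  writeLines("plant\tanimal", el)
  expect_error(readEdgeListTSV(el, f$nat, "e"), "no interactions")
})

test_that("write/read round-trip is exact for toy and synthetic networks", {
  for (net in list(toyNetwork(),
                   mkNet(matrix(1, 1, 1)),
                   generateNetwork(synthConfig(nPlants = 50, nAnimals = 80,
                                               rngSeed = 11)))) {
    p <- tempfile()
    writeNetwork(net, p)
    back <- readIncidenceCSV(p, paste0(p, ".nativity.csv"),
                             networkId(net), studyId(net), networkType(net))
    expect_identical(incidence(back), incidence(net))
    expect_identical(origin(back), origin(net))
  }
})

test_that("validity rejects malformed incidence structures", {
  m <- matrix(c(1, 2), 1, 2, dimnames = list("p", c("a", "b")))
  org <- c(p = "native", a = "native", b = "native")
  expect_warning(interactionNetwork(m, org, "x"), "binarizing")
  expect_error(interactionNetwork(matrix(1, 1, 1), c(x = "native"), "x"),
               "labels")
  expect_error(
    mkNet(matrix(c(1, 1, 0, 0), 2, 2,
                 dimnames = list(c("p1", "p2"), c("a1", "a2")))),
    "a2")
})
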