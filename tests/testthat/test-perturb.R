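# Targeted removals, matched random controls and null models.

test_that("removeSpecies deletes species, records orphans, flags degeneracy", {
  net <- toyNetwork()
  res <- removeSpecies(net, "A1")
  expect_identical(orphanedSpecies(res), "P2")
  red <- reducedNetwork(res)
  expect_equal(nPlants(red), 2L)
  expect_equal(nAnimals(red), 2L)
  expect_equal(nLinks(red), 3L)
  expect_false(isExcluded(res))
  # identity removal
  idres <- removeSpecies(net, character())
  expect_identical(incidence(reducedNetwork(idres)), incidence(net))
  expect_length(orphanedSpecies(idres), 0)
  # removing every animal is degenerate
  expect_true(isExcluded(removeSpecies(net, c("A1", "A2", "A3"))))
  expect_error(removeSpecies(net, "nope"), "not in network")
})

test_that("removeNonnatives strips exactly the non-native species", {
  res <- removeNonnatives(toyNetwork())
  expect_identical(removedSpecies(res), "A1")
  expect_identical(orphanedSpecies(res), "P2")
  allnat <- mkNet(incidence(toyNetwork()))
  expect_warning(res2 <- removeNonnatives(allnat), "no non-native")
  expect_identical(incidence(reducedNetwork(res2)), incidence(allnat))
  # non-natives sole partners of every plant -> degenerate
  m <- matrix(1, 2, 1, dimnames = list(c("p1", "p2"), "a1"))
  expect_true(isExcluded(removeNonnatives(mkNet(m, nonnative = "a1"))))
})

test_that("sequential disjoint removals match removal of the union", {
  set.seed(31)
  for (k in 1:5) {
    net <- randomNet(6, 6, p = 0.45, seed = 400 + k)
    pick <- sample(c(plantLabels(net), animalLabels(net)), 4)
    oneShot <- removeSpecies(net, pick)
    first <- removeSpecies(net, pick[1:2])
    if (isExcluded(first) || isExcluded(oneShot)) next
    second <- try(removeSpecies(reducedNetwork(first),
                                intersect(pick[3:4],
                                          c(plantLabels(reducedNetwork(first)),
                                            animalLabels(reducedNetwork(first))))),
                  silent = TRUE)
    if (inherits(second, "try-error") || isExcluded(second)) next
    expect_identical(incidence(reducedNetwork(second)),
                     incidence(reducedNetwork(oneShot)))
  }
})

test_that("matched random removal matches non-native counts and is uniform", {
  net <- toyNetwork()   # one non-native animal, no non-native plants
  picks <- vapply(1:4000, function(s) {
    res <- matchedRandomRemoval(net, rngSeed = s)
    expect_length(removedSpecies(res), 1L)
    removedSpecies(res)
  }, character(1))
  expect_true(all(picks %in% c("A2", "A3")))  # only natives eligible
  expect_equal(mean(picks == "A2"), 0.5, tolerance = 0.05)
  # determinism
  r1 <- matchedRandomRemoval(net, rngSeed = 99)
  r2 <- matchedRandomRemoval(net, rngSeed = 99)
  expect_identical(removedSpecies(r1), removedSpecies(r2))
  # precondition: fewer natives than non-natives at a level
  m <- matrix(1, 2, 2, dimnames = list(c("p1", "p2"), c("a1", "a2")))
  expect_error(matchedRandomRemoval(mkNet(m, nonnative = c("a1", "a2")), 1),
               "animal")
})

test_that("null models conserve dimensions and per-replicate link totals", {
  net <- toyNetwork()
  reps <- nullModel(net, 0, 1, reps = 200, rngSeed = 5)
  expect_length(reps, 200)
  for (x in reps) {
    expect_equal(nPlants(x), 3L)
    expect_equal(nAnimals(x), 2L)
    inc <- incidence(x)
    expect_true(all(rowSums(inc) > 0) && all(colSums(inc) > 0))
  }
  # with no removals the fill equals the original link count exactly
  net10 <- randomNet(10, 10, seed = 77)
  reps0 <- nullModel(net10, 0, 0, reps = 100, rngSeed = 6)
  expect_true(all(vapply(reps0, nLinks, numeric(1)) == nLinks(net10)))
  expect_true(all(vapply(reps0, function(x)
    networkMetrics(x)$connectance, numeric(1)) ==
      nLinks(net10) / 100))
  # degenerate request
  expect_error(nullModel(net, 2, 0, reps = 2, rngSeed = 1), "at least 2 x 2")
  # determinism
  a <- nullModel(net, 0, 1, reps = 5, rngSeed = 8)
  b <- nullModel(net, 0, 1, reps = 5, rngSeed = 8)
  expect_identical(lapply(a, incidence), lapply(b, incidence))
})

test_that("swap null models preserve both degree sequences", {
  net <- randomNet(8, 9, p = 0.4, seed = 55)
  reps <- nullModel(net, 0, 0, reps = 30, rngSeed = 3, method = "swap")
  inc <- incidence(net)
  for (x in reps) {
    m <- incidence(x)[rownames(inc), colnames(inc)]
    expect_identical(rowSums(m), rowSums(inc))
    expect_identical(colSums(m), colSums(inc))
  }
})

test_that("infeasible fills are reported", {
  # removing an off-diagonal plant/animal pair from the 3x3 identity
  # leaves a single link on a 2x2 matrix: no valid fill exists, and
  # across 50 replicates such a pair is drawn essentially surely
  m <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("a", 1:3)))
  expect_error(nullModel(mkNet(m), 1, 1, reps = 50, rngSeed = 2),
               "infeasible")
})
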