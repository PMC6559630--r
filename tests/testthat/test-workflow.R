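# End-to-end orchestration: variant assembly, exclusions, determinism,
# focal-species removal.

smallCollection <- function(seed = 10, n = 8)
  generateCollection(synthConfig(nPlants = 20, nAnimals = 20,
                                 fracNonnativePlants = 0.1,
                                 fracNonnativeAnimals = 0.1,
                                 rngSeed = seed), nNetworks = n)

test_that("variantMetrics produces all four variants per usable network", {
  coll <- smallCollection()
  v <- variantMetrics(coll, nullReps = 40, rngSeed = 3)
  usable <- unique(v$network_id[!v$excluded])
  for (id in usable)
    expect_setequal(v$variant[v$network_id == id],
                    c("full", "natives_only", "random_control", "null_mean"))
  expect_true(all(c("connectance", "mean_links", "generality",
                    "vulnerability") %in% names(v)))
  # full-variant rows agree with direct networkMetrics calls
  for (i in seq_len(length(coll))) {
    nm <- networkMetrics(coll[[i]])
    row <- v[v$network_id == networkId(coll[[i]]) & v$variant == "full", ]
    expect_equal(row$connectance, nm$connectance)
    expect_equal(row$mean_links, nm$mean_links)
  }
})

test_that("excluded networks are dropped from every paired contrast", {
  coll <- smallCollection()
  # a 2x2 network whose only animal partners are non-native: degenerate
  m <- matrix(1, 3, 2, dimnames = list(paste0("xp", 1:3),
                                       paste0("xa", 1:2)))
  dg <- mkNet(m, nonnative = c("xa1", "xa2"), id = "degenerate")
  coll2 <- networkCollection(c(coll@networks, list(dg)))
  v <- variantMetrics(coll2, nullReps = 30, rngSeed = 4)
  expect_true(any(v$excluded))
  expect_true("degenerate" %in% v$network_id[v$excluded])
  tab <- networkComparisonTable(v)
  nUsable <- length(unique(v$network_id[!v$excluded]))
  expect_true(all(tab$n_pairs == nUsable))
  expect_true(all(tab$df == nUsable - 1))
})

test_that("runStudy is deterministic and its report is self-consistent", {
  coll <- smallCollection(seed = 77, n = 6)
  r1 <- runStudy(coll, nullReps = 25, extinctionReps = 25, rngSeed = 5)
  r2 <- runStudy(coll, nullReps = 25, extinctionReps = 25, rngSeed = 5)
  expect_identical(r1$variants, r2$variants)
  expect_identical(r1$comparisons, r2$comparisons)
  expect_identical(r1$secondary, r2$secondary)
  expect_equal(nrow(r1$comparisons), 16)  # 4 metrics x 4 contrasts
  expect_error(runStudy(networkCollection(list(coll[[1]]))), "at least 2")
  # output files written when requested
  out <- tempfile()
  runStudy(coll, nullReps = 10, extinctionReps = 10, rngSeed = 5,
           outDir = out)
  expect_true(all(file.exists(file.path(out,
    c("variant_metrics.tsv", "paired_comparisons.tsv",
      "secondary_extinctions.tsv", "species_metrics.tsv",
      "run_log.txt")))))
})

test_that("focal supergeneralist removal lowers mean links in every host network", {
  cfg <- synthConfig(rngSeed = 31)
  coll <- generateCollection(cfg, nNetworks = 20, focalSpecies = "HB",
                             focalNetworks = 14)
  has <- vapply(coll@networks, function(n) "HB" %in% animalLabels(n),
                logical(1))
  expect_equal(sum(has), 14)
  res <- removeFocalSpecies(coll, "HB")
  per <- res$per_network
  for (id in unique(per$network_id)) {
    f <- per$mean_links[per$network_id == id & per$variant == "full"]
    r <- per$mean_links[per$network_id == id & per$variant == "reduced"]
    expect_gt(f, r)
  }
  expect_equal(res$comparisons$n_pairs[1], 14)
  expect_error(removeFocalSpecies(coll, "A01x"), "fewer than 2")
})

test_that("degree-1 focal species removal changes exactly one link and column", {
  # append a degree-1 non-native animal to two copies of the toy network
  addLeaf <- function(id) {
    inc <- incidence(toyNetwork())
    inc2 <- cbind(inc, leaf = c(0L, 0L, 1L))
    interactionNetwork(inc2, c(origin(toyNetwork()),
                               leaf = "nonnative"), id, "toy-study")
  }
  coll <- networkCollection(list(addLeaf("t1"), addLeaf("t2")))
  res <- removeFocalSpecies(coll, "leaf")
  per <- res$per_network
  f <- per[per$variant == "full", ]; r <- per[per$variant == "reduced", ]
  # closed form: (L-1)/(I*(J-1)) vs L/(I*J) with I=3, J=4, L=7
  expect_equal(unique(f$connectance), 7 / 12)
  expect_equal(unique(r$connectance), 6 / 9)
  expect_equal(unique(f$mean_links), 7 / 7)
  expect_equal(unique(r$mean_links), 6 / 6)
  # identical networks give constant nonzero differences: no variance,
  # so the comparison rows carry the means but NA test statistics
  expect_true(all(is.na(res$comparisons$t)))
  expect_equal(res$comparisons$mean_diff[res$comparisons$metric ==
                                           "connectance"], 7 / 12 - 6 / 9)
})
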