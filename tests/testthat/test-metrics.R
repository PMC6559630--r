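# Species- and network-level metrics against hand derivations and the
# brute-force oracle.

test_that("toy network metrics match hand-derived values", {
  net <- toyNetwork()
  nm <- networkMetrics(net)
  expect_equal(nm$connectance, 6 / 9)
  expect_equal(nm$mean_links, 1)
  expect_equal(nm$generality, 2)
  expect_equal(nm$vulnerability, 2)
  nw <- networkMetrics(net, "degree_weighted")
  expect_equal(nw$generality, 14 / 6)
  expect_equal(nw$vulnerability, 14 / 6)
  full <- mkNet(matrix(1, 4, 5))
  expect_equal(networkMetrics(full)$connectance, 1)
})

test_that("species metrics report degrees, normalized degrees and PSI", {
  sm <- speciesMetrics(toyNetwork())
  g <- function(sp, col) sm[[col]][sm$species == sp]
  expect_equal(g("A1", "degree"), 3)
  expect_equal(g("A1", "normalized_degree"), 1)
  expect_equal(g("P2", "normalized_degree"), 1 / 3)
  expect_equal(g("A1", "psi"), 11 / 18)
  expect_equal(g("A3", "psi"), 1 / 3)
  expect_true(all(is.na(sm$psi[sm$level == "plant"])))
  expect_false(anyNA(sm$psi[sm$level == "animal"]))
  one <- speciesMetrics(mkNet(matrix(1, 1, 1)))
  expect_equal(one$normalized_degree, c(1, 1))
  expect_equal(one$psi[one$level == "animal"], 1)
})

test_that("projection centrality handles complete, path and disconnected cases", {
  # plant projection of the toy network is K3: no betweenness, closeness 1
  cen <- projectionCentrality(toyNetwork(), "plant")
  expect_equal(cen$betweenness, rep(0, 3))
  expect_equal(cen$closeness, rep(1, 3))
  # plants u-v-w form a path through v (u,v share a; v,w share b)
  path <- mkNet(matrix(c(1, 1, 0,
                         0, 1, 1), nrow = 3,
                       dimnames = list(c("u", "v", "w"), c("a", "b"))))
  cen <- projectionCentrality(path, "plant")
  expect_equal(cen$betweenness[cen$species == "v"], 1)
  expect_equal(cen$closeness[cen$species == "v"], 1)
  expect_equal(cen$closeness[cen$species == "u"], 2 / 3)
  # animal a2 shares no plant with a1: isolated node has closeness 0
  disc <- mkNet(matrix(c(1, 1, 0,
                         0, 0, 1), nrow = 3,
                       dimnames = list(c("p1", "p2", "p3"), c("a1", "a2"))))
  cen <- projectionCentrality(disc, "animal")
  expect_equal(cen$closeness[cen$species == "a2"], 0)
})

test_that("psi rejects negative beta and responds to beta", {
  net <- toyNetwork()
  expect_error(psiIndex(net, beta = -1), "nonnegative")
  expect_equal(unname(psiIndex(net, beta = 0)["A1"]), 11 / 6)
})

test_that("metrics are invariant to row/column permutation", {
  set.seed(42)
  for (k in 1:5) {
    net <- randomNet(5, 6, seed = 100 + k)
    inc <- incidence(net)
    perm <- inc[sample(nrow(inc)), sample(ncol(inc))]
    pnet <- mkNet(perm)
    expect_equal(networkMetrics(net)[-(1:2)], networkMetrics(pnet)[-(1:2)])
    a <- speciesMetrics(net); b <- speciesMetrics(pnet)
    b <- b[match(a$species, b$species), ]
    for (col in c("degree", "normalized_degree", "betweenness",
                  "closeness", "psi"))
      expect_equal(a[[col]], b[[col]])
  }
})

test_that("adding a link never decreases connectance, mean links or degrees", {
  set.seed(7)
  for (k in 1:5) {
    net <- randomNet(5, 5, p = 0.35, seed = 200 + k)
    inc <- incidence(net)
    zero <- which(inc == 0, arr.ind = TRUE)
    if (!nrow(zero)) next
    cell <- zero[sample(nrow(zero), 1), ]
    inc2 <- inc; inc2[cell[1], cell[2]] <- 1L
    net2 <- mkNet(inc2)
    expect_gt(networkMetrics(net2)$connectance, networkMetrics(net)$connectance)
    expect_gt(networkMetrics(net2)$mean_links, networkMetrics(net)$mean_links)
    expect_true(all(speciesMetrics(net2)$degree >= speciesMetrics(net)$degree))
  }
})

test_that("metric bounds hold on random networks", {
  set.seed(9)
  for (k in 1:8) {
    net <- randomNet(sample(2:7, 1), sample(2:7, 1), seed = 300 + k)
    sm <- speciesMetrics(net)
    nm <- networkMetrics(net)
    expect_true(nm$connectance > 0 && nm$connectance <= 1)
    expect_true(all(sm$normalized_degree > 0 & sm$normalized_degree <= 1))
    expect_true(all(sm$closeness >= 0 & sm$closeness <= 1))
    psi <- sm$psi[sm$level == "animal"]
    expect_true(all(psi > 0 & psi <= 1))
    kA <- sm$degree[sm$level == "animal"]
    kP <- sm$degree[sm$level == "plant"]
    expect_true(nm$generality >= min(kA) && nm$generality <= max(kA))
    expect_true(nm$vulnerability >= min(kP) && nm$vulnerability <= max(kP))
  }
})

test_that("simple and degree-weighted generality agree iff animal degrees are equal", {
  even <- mkNet(matrix(1, 3, 4))
  expect_equal(networkMetrics(even)$generality,
               networkMetrics(even, "degree_weighted")$generality)
  uneven <- toyNetwork()
  expect_false(isTRUE(all.equal(
    networkMetrics(uneven)$generality,
    networkMetrics(uneven, "degree_weighted")$generality)))
})
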