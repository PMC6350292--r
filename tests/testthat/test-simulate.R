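test_that("Yule trees are rooted, ultrametric and seed-reproducible", {
  tr <- simulateTree(3, 1, 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.ultrametric(simulateTree(25, 2, 5)))
  expect_identical(ape::write.tree(simulateTree(12, 1, 9)),
                   ape::write.tree(simulateTree(12, 1, 9)))
  expect_false(identical(ape::write.tree(simulateTree(12, 1, 9)),
                         ape::write.tree(simulateTree(12, 1, 10))))
  expect_error(simulateTree(2, 1, 1), "nTips")
  # Newick round-trip preserves topology and branch lengths
  big <- simulateTree(40, 1, 33)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(big, path)
  back <- ape::read.tree(path)
  expect_equal(ape::cophenetic.phylo(back)[big$tip.label, big$tip.label],
               ape::cophenetic.phylo(big), tolerance = 1e-9)
})

test_that("expected tree age matches the Yule closed form", {
  b <- 1.5; n <- 10; nRep <- 1000
  ages <- vapply(seq_len(nRep), function(i) {
    tr <- simulateTree(n, b, 10000 + i)
    tr$root.edge + max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- sum(1 / (b * seq_len(n)))
  se <- sd(ages) / sqrt(nRep)
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("oxygen-state histories have controlled transitions", {
  tr <- simulateTree(20, 1, 3)
  expect_true(all(simulateOxygenStates(tr, 0, 3) == "anaerobic"))
  st <- simulateOxygenStates(tr, 4, 3)
  expect_identical(st, simulateOxygenStates(tr, 4, 3))
  expect_error(simulateOxygenStates(tr, 1000, 3), "nTransitions")
  # tip states equal flip parity along the root-to-tip path (ape oracle)
  flips <- attr(st, "flipped_edges")
  root <- length(tr$tip.label) + 1L
  for (tip in seq_along(tr$tip.label)) {
    nodes <- ape::nodepath(tr, root, tip)
    edges <- vapply(seq_len(length(nodes) - 1L), function(k)
      which(tr$edge[, 1] == nodes[k] & tr$edge[, 2] == nodes[k + 1]),
      integer(1))
    parity <- sum(edges %in% flips) %% 2L
    expect_equal(unname(st[tr$tip.label[tip]]),
                 if (parity == 1L) "aerobic" else "anaerobic")
  }
  # a single flip makes exactly one clade aerobic
  st1 <- simulateOxygenStates(tr, 1, 8)
  aero <- names(st1)[st1 == "aerobic"]
  expect_gt(length(aero), 0L)
  if (length(aero) > 1L) {
    mrca <- ape::getMRCA(tr, aero)
    expect_setequal(ape::extract.clade(tr, mrca)$tip.label, aero)
  }
  # recovered event count never exceeds the number of flips
  for (i in 1:10) {
    stN <- simulateOxygenStates(tr, 5, 100 + i)
    expect_lte(length(findStateChangeEvents(tr, stN)), 5L)
  }
})

test_that("simulated traits follow the state-shifted Brownian model", {
  tr <- simulateTree(15, 1, 21)
  st <- simulateOxygenStates(tr, 3, 21)
  noiseFree <- simulateGCTrait(tr, st, intercept = 1, slope = 2, sigma2 = 0,
                               lambda = 1, seed = 21)
  x <- attr(noiseFree, "ground_truth")$x
  expect_equal(as.numeric(noiseFree), unname(1 + 2 * x))
  y1 <- simulateGCTrait(tr, st, 0, 0, 1, 1, seed = 4)
  expect_identical(y1, simulateGCTrait(tr, st, 0, 0, 1, 1, seed = 4))
  expect_false(identical(unname(y1),
                         unname(simulateGCTrait(tr, st, 0, 0, 1, 1, seed = 5))))
})

test_that("generated CDSs hit their site-class GC targets", {
  cds <- generateCDS(1000, 0.5, 0.5, seed = 6)
  expect_lt(abs(gcAt4FDS(cds)$gc - 0.5), 0.001 + 1e-12)
  expect_identical(as.character(generateCDS(50, 0.3, 0.7, seed = 2)),
                   as.character(generateCDS(50, 0.3, 0.7, seed = 2)))
  full <- generateCDS(100, 1, 0.4, seed = 3)
  expect_equal(gcAt4FDS(full)$gc, 1)
  # measured composition equals the generator's own bookkeeping exactly
  set.seed(51)
  for (i in 1:10) {
    t4 <- runif(1); tz <- runif(1); n <- sample(10:200, 1)
    g <- generateCDS(n, t4, tz, seed = i)
    expect_equal(gcAt4FDS(g)$gc, attr(g, "gc4_realised"))
    expect_equal(gcAtZRS(g)$gc, attr(g, "gczrs_realised"))
    expect_lte(abs(gcAt4FDS(g)$gc - t4), 1 / n)
    expect_lte(abs(gcAtZRS(g)$gc - tz), 1 / n)
    # in-frame, stop-free by construction
    expect_equal(gcAt4FDS(g)$n_sites, n)
    expect_equal(gcAtZRS(g)$n_sites, n)
  }
})

test_that("16S pairs realise their identity target, gaps excluded", {
  pair <- generate16SPair(1000, 90, seed = 7)
  expect_equal(identityPercent(pair[1], pair[2]), 90)
  expect_identical(generate16SPair(100, 95, seed = 8),
                   generate16SPair(100, 95, seed = 8))
  ident <- generate16SPair(200, 100, seed = 9)
  expect_identical(ident[["a"]], ident[["b"]])
  gapped <- generate16SPair(1000, 90, seed = 7, gapColumns = 50)
  expect_equal(identityPercent(gapped[1], gapped[2]), 90)
  expect_equal(nchar(gapped[["a"]]), 1050L)
})
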