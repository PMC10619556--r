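# Modified cosine, constrained network construction, component reporting,
# and parent-subnetwork annotation.

test_that("cosine is 1 for identical spectra and 0 for disjoint ones", {
  set.seed(21)
  sp <- randomSpectrum("A", nPeaks = 8)
  self <- modifiedCosine(sp, sp)
  expect_equal(self$cosine, 1, tolerance = 1e-12)
  expect_equal(self$matched_ions, 8L)

  a <- Ms2Spectrum("A", 500, c(100, 200, 300), c(1, 1, 1))
  b <- Ms2Spectrum("B", 500, c(150, 250, 350), c(1, 1, 1))
  none <- modifiedCosine(a, b)
  expect_equal(none$cosine, 0)
  expect_equal(none$matched_ions, 0L)
})

test_that("cosine is symmetric and invariant to intensity scaling", {
  set.seed(22)
  for (i in 1:10) {
    a <- randomSpectrum("A", sample(3:8, 1))
    b <- randomSpectrum("B", sample(3:8, 1))
    ab <- modifiedCosine(a, b)
    ba <- modifiedCosine(b, a)
    expect_equal(ab$cosine, ba$cosine, tolerance = 1e-12)
    expect_equal(ab$matched_ions, ba$matched_ions)
    a2 <- Ms2Spectrum("A", precursorMz(a), peaks(a)[, 1], peaks(a)[, 2] * 555)
    expect_equal(modifiedCosine(a2, b)$cosine, ab$cosine, tolerance = 1e-12)
  }
})

test_that("greedy matching agrees with the exhaustive matching oracle", {
  set.seed(23)
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # narrow m/z range makes eligible-pair conflicts common
    a <- randomSpectrum("A", n1, mzRange = c(100, 140))
    b <- randomSpectrum("B", n2, mzRange = c(100, 140))
    got <- modifiedCosine(a, b, fragTol = 0.5)
    want <- bruteForceCosine(a, b, fragTol = 0.5)
    expect_equal(got$cosine, want$cosine, tolerance = 1e-9)
  }
})

test_that("identical spectra form a triangle in one component", {
  mk <- function(id) Ms2Spectrum(id, 500, seq(100, 400, length.out = 8),
                                 c(5, 3, 8, 2, 9, 4, 7, 6) * 1e3)
  net <- buildNetwork(list(mk("a"), mk("b"), mk("c")))
  expect_equal(nrow(networkEdges(net)), 3)
  expect_equal(length(unique(componentMembership(net))), 1)
})

test_that("precursor shifts beyond the maximum are not connected", {
  frag <- seq(100, 400, length.out = 8)
  ints <- rep(1e4, 8)
  a <- Ms2Spectrum("a", 450, frag, ints)
  b <- Ms2Spectrum("b", 1050, frag, ints)  # shift 600 > 500
  net <- buildNetwork(list(a, b))
  expect_equal(nrow(networkEdges(net)), 0)
  expect_equal(length(unique(componentMembership(net))), 2)
  netWide <- buildNetwork(list(a, b), maxShift = 700)
  expect_equal(nrow(networkEdges(netWide)), 1)
})

test_that("a hub with 12 strong neighbors keeps at most 10 under top-K", {
  frag <- seq(100, 400, length.out = 10)
  ints <- c(9, 5, 7, 3, 8, 2, 6, 4, 10, 1) * 1e3
  center <- Ms2Spectrum("center", 500, frag, ints)
  # neighbors share the center fragments with slightly degraded intensities
  # and distinct precursors; pairwise neighbor cosines also exist, but the
  # center's degree must be capped at 10
  nbrs <- lapply(1:12, function(k) {
    Ms2Spectrum(paste0("n", sprintf("%02d", k)), 500 + k,
                frag, ints * (1 + 0.03 * k))
  })
  net <- buildNetwork(c(list(center), nbrs), topK = 10)
  deg <- table(c(networkEdges(net)$node_a, networkEdges(net)$node_b))
  expect_true(all(deg <= 10))
  expect_equal(unname(deg["center"]), 10)
})

test_that("surviving edges always satisfy every constraint", {
  set.seed(25)
  for (rep in 1:5) {
    n <- 12
    base <- sort(runif(10, 100, 420))
    sps <- lapply(seq_len(n), function(k) {
      keep <- runif(10) < 0.8
      if (sum(keep) < 2) keep[1:2] <- TRUE
      Ms2Spectrum(paste0("s", k), runif(1, 430, 1100),
                  base[keep] + rnorm(sum(keep), 0, 0.01),
                  rlnorm(sum(keep), log(1e4), 0.6))
    })
    net <- buildNetwork(sps)
    e <- networkEdges(net)
    if (nrow(e) > 0) {
      expect_true(all(e$cosine > 0.5))
      expect_true(all(e$matched_ions >= 6))
      expect_true(all(abs(e$precursor_shift) <= 500))
    }
    deg <- table(c(e$node_a, e$node_b))
    expect_true(all(deg <= 10))
  }
})

test_that("component summary reports sizes, annotation counts and headline flag", {
  empty <- new("MolecularNetwork",
               nodes = data.frame(feature_id = character(0),
                                  precursor_mz = numeric(0)),
               edges = data.frame(node_a = character(0), node_b = character(0),
                                  cosine = numeric(0), matched_ions = integer(0),
                                  precursor_shift = numeric(0)),
               membership = setNames(integer(0), character(0)), params = list())
  expect_equal(nrow(componentSummary(empty)), 0)

  ids <- c(paste0("a", 1:12), paste0("b", 1:3))
  nodes <- data.frame(feature_id = ids, precursor_mz = seq_along(ids) + 100,
                      annotated = c(rep(TRUE, 4), rep(FALSE, 11)),
                      log2fc = rep(2, 15))
  memb <- setNames(c(rep(1L, 12), rep(2L, 3)), ids)
  net <- new("MolecularNetwork", nodes = nodes,
             edges = data.frame(node_a = character(0), node_b = character(0),
                                cosine = numeric(0), matched_ions = integer(0),
                                precursor_shift = numeric(0)),
             membership = memb, params = list())
  cs <- componentSummary(net, minSize = 10)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$n_nodes, c(12, 3))
  expect_equal(cs$n_annotated[1], 4)
  expect_identical(cs$headline, c(TRUE, FALSE))
  expect_equal(sum(cs$headline), 1)
})

test_that("the parent subnetwork is annotated against predictions", {
  set.seed(26)
  sim <- simulateExperiment(simConfig(seed = 26, maxTotal = 2, nDecoys = 10))
  pred <- enumerateBiotransformants("C15 H12 I3 N O4",
                                    maxTotal = 2, maxPhase2 = 1,
                                    includeParent = TRUE)
  net <- buildNetwork(sim$spectra)
  sub <- annotateSubnetwork(net, "PARENT", pred, polarity = "pos")
  expect_identical(sub$status[1], "parent")
  expect_equal(sub$delta_mz[1], 0)
  gluc <- sim$truth$planted[sim$truth$planted$path == "Glucuronide Conjugation", ]
  row <- sub[sub$feature_id == gluc$feature_id, ]
  expect_identical(row$status, "annotated")
  expect_identical(row$path, "Glucuronide Conjugation")
  expect_error(annotateSubnetwork(net, "NOPE", pred), "not in the network")
})

test_that("an unpredicted shifted spectrum becomes a candidate-novel node", {
  frag <- seq(100, 400, length.out = 10)
  ints <- rep(1e4, 10)
  parent <- Ms2Spectrum("PARENT", 500, frag, ints)
  odd <- Ms2Spectrum("ODD", 500 + 123.4567, frag + 123.4567, ints)
  pred <- data.frame(formula = "F", mass = 600, mzPos = 601.007,
                     mzNeg = 598.993, nSteps = 1L, nPhase2 = 0L, path = "P")
  net <- buildNetwork(list(parent, odd))
  sub <- annotateSubnetwork(net, "PARENT", pred, polarity = "pos")
  row <- sub[sub$feature_id == "ODD", ]
  expect_identical(row$status, "candidate-novel")
  expect_equal(row$delta_mz, 123.4567, tolerance = 1e-6)
})

test_that("networks export to GraphML and TSV", {
  frag <- seq(100, 400, length.out = 8)
  sps <- lapply(c("a", "b"), function(id) Ms2Spectrum(id, 500, frag, frag))
  net <- buildNetwork(sps)
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  writeNetwork(net, gml, "graphml",
               nodeData = data.frame(feature_id = c("a", "b"), log2fc = c(1, 2)))
  writeNetwork(net, tsv, "tsv")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_true("log2fc" %in% igraph::vertex_attr_names(g))
  e <- read.delim(tsv)
  expect_equal(nrow(e), 1)
  expect_true(all(c("cosine", "matched_ions") %in% colnames(e)))
})
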