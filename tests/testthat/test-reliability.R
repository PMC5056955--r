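test_that("Fisher transform is exact, invertible and clamps at unity", {
  expect_equal(as.numeric(fisherZ(0)), 0)
  expect_equal(as.numeric(fisherZ(0.5)), 0.549306144334055,
               tolerance = 1e-12)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZInv(as.numeric(fisherZ(grid))), grid,
               tolerance = 1e-12)
  z1 <- fisherZ(1)
  expect_true(attr(z1, "clamped"))
  expect_true(is.finite(z1))
  expect_error(fisherZ(1.2), "not a correlation")
})

test_that("group means use Fisher-Z averaging only for correlation metrics", {
  m1 <- cmFrom(rep(0.2, 3), 3, metric = "aec")
  m2 <- cmFrom(rep(0.6, 3), 3, metric = "aec")
  gm <- groupMean(studyNetworks(list(m1, m2)))
  want <- tanh((atanh(0.2) + atanh(0.6)) / 2)
  expect_equal(values(gm)[1, 2], want, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(want, 0.4)))  # differs from plain mean

  p1 <- cmFrom(rep(0.2, 3), 3, metric = "pli")
  p2 <- cmFrom(rep(0.6, 3), 3, metric = "pli")
  gp <- groupMean(studyNetworks(list(p1, p2)))
  expect_equal(values(gp)[1, 2], 0.4, tolerance = 1e-12)

  # identical matrices average to themselves
  gi <- groupMean(studyNetworks(list(m1, m1)))
  expect_equal(values(gi), values(m1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("split-half consistency is 1 (clamped) for identical sessions", {
  edges <- runif(10)
  nets <- studyFromEdges(rep(list(edges), 12),
                         rep(sprintf("s%d", 1:4), each = 3),
                         rep(c("r1", "r2", "r3"), 4), n = 5)
  sh <- splitHalfConsistency(nets, nPartitions = 20, seed = 1)
  expect_equal(sh$rho, rep(1, 20))
  expect_true(all(attr(sh$z, "clamped")))
  expect_error(splitHalfConsistency(
    studyFromEdges(rep(list(edges), 3), c("s1", "s2", "s3"),
                   c("r1", "r1", "r1"), n = 5)), "4 subjects")
})

test_that("split-half distribution is centred for independent sessions", {
  set.seed(2)
  nEdge <- choose(20, 2)  # 190 edges: null SD of rho is ~1/sqrt(188)
  nets <- studyFromEdges(replicate(30, rnorm(nEdge), simplify = FALSE),
                         rep(sprintf("s%02d", 1:10), each = 3),
                         rep(c("r1", "r2", "r3"), 10), n = 20)
  sh <- splitHalfConsistency(nets, nPartitions = 100, seed = 3)
  # partitions reuse the same sessions, so the median behaves like a
  # single null draw: bound it at ~3 null SDs
  expect_lt(abs(median(sh$rho)), 3 / sqrt(nEdge - 2))
})

test_that("split-half detects a shared network over noise", {
  set.seed(3)
  truth <- runif(45)
  nets <- studyFromEdges(
    replicate(24, truth + rnorm(45, 0, 0.3), simplify = FALSE),
    rep(sprintf("s%02d", 1:8), each = 3),
    rep(c("r1", "r2", "r3"), 8), n = 10)
  sh <- splitHalfConsistency(nets, nPartitions = 100, seed = 4)
  # null: same layout, no shared structure
  nullNets <- studyFromEdges(replicate(24, rnorm(45), simplify = FALSE),
                             rep(sprintf("s%02d", 1:8), each = 3),
                             rep(c("r1", "r2", "r3"), 8), n = 10)
  shNull <- splitHalfConsistency(nullNets, nPartitions = 100, seed = 4)
  expect_gt(median(sh$rho), quantile(shNull$rho, 0.99))
})

test_that("within-subject pairs follow the session-pair bookkeeping", {
  set.seed(4)
  edges <- replicate(183, rnorm(45), simplify = FALSE)
  nets <- studyFromEdges(edges, rep(sprintf("s%02d", 1:61), each = 3),
                         rep(c("r1", "r2", "r3"), 61), n = 10)
  ws <- withinSubjectConsistency(nets)
  expect_equal(nrow(ws), 183L)  # 61 subjects x 3 unordered pairs
  # duplicated sessions correlate perfectly
  dup <- studyFromEdges(rep(list(edges[[1]]), 2), c("s1", "s1"),
                        c("r1", "r2"), n = 10)
  expect_equal(withinSubjectConsistency(dup)$rho, 1)
  # single-session subject is skipped with a warning
  mix <- studyFromEdges(edges[1:3], c("s1", "s1", "s2"),
                        c("r1", "r2", "r1"), n = 10)
  expect_warning(wmix <- withinSubjectConsistency(mix), "single session")
  expect_equal(nrow(wmix), 1L)
})

test_that("between-subject consistency spans cross-subject pairs only", {
  edges <- replicate(6, rnorm(45), simplify = FALSE)
  nets <- studyFromEdges(edges, rep(c("s1", "s2", "s3"), each = 2),
                         rep(c("r1", "r2"), 3), n = 10)
  bs <- betweenSubjectConsistency(nets)
  expect_length(bs, 12L)  # 15 session pairs minus 3 within-subject
  # identical matrices across subjects give all 1
  same <- studyFromEdges(rep(list(edges[[1]]), 4),
                         c("s1", "s1", "s2", "s2"),
                         c("r1", "r2", "r1", "r2"), n = 10)
  expect_equal(as.numeric(betweenSubjectConsistency(same)), rep(1, 4))
  # subject-mean scheme reduces to one value per subject pair
  bsm <- betweenSubjectConsistency(nets, scheme = "subject_mean")
  expect_length(bsm, 3L)
})

test_that("between-subject consistency falls as subject variability grows", {
  set.seed(5)
  truth <- runif(45)
  medians <- vapply(c(0.1, 0.4, 1.2), function(sdv) {
    subjEdges <- lapply(1:8, function(s) truth + rnorm(45, 0, sdv))
    edges <- unlist(lapply(subjEdges, function(e)
      replicate(2, e + rnorm(45, 0, 0.05), simplify = FALSE)),
      recursive = FALSE)
    nets <- studyFromEdges(edges, rep(sprintf("s%d", 1:8), each = 2),
                           rep(c("r1", "r2"), 8), n = 10)
    median(betweenSubjectConsistency(nets))
  }, numeric(1))
  expect_true(all(diff(medians) < 0))
})

test_that("edge contributions decompose the Pearson correlation exactly", {
  set.seed(6)
  for (k in 1:5) {
    x <- rnorm(40); y <- rnorm(40)
    sh <- edgeContributions(x, y)
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    expect_equal(attr(sh, "rho"), oraclePearson(x, y), tolerance = 1e-12)
    expect_equal(attr(sh, "rho"), cor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(20)
  shx <- edgeContributions(x, x)
  expect_equal(as.numeric(shx), (x - mean(x))^2 / sum((x - mean(x))^2),
               tolerance = 1e-12)
  expect_error(edgeContributions(rep(1, 5), rnorm(5)), "constant")
})

test_that("edge vectorisation respects directedness", {
  M <- matrix(1:16, 4)
  expect_length(vectoriseEdges(M, directed = FALSE), 6L)
  expect_length(vectoriseEdges(M, directed = TRUE), 12L)
})
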