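makeChain <- function(strength = 0.7) {
  makeGroundTruthModel(groundTruthSpec(
    c("A", "B"), data.frame(from = "A", to = "B"),
    edgeStrength = strength))
}

test_that("transition counting matches the slice-pair structure", {
  m <- makeChain()
  struct <- modelStructure(m)
  s <- sampleTimeSeries(m, "control", "cyt_protein", T = 14, seed = 2)
  cnt <- collectTransitions(list(s), struct)
  # one series of 14 points: 13 transitions per node
  expect_equal(cnt@nTransitions, 13L)
  expect_equal(sum(cnt@nodeCounts$B$counts), 13)
  expect_equal(sum(cnt@nodeCounts$A$counts), 13)
  # initial-slice counts: one observation
  expect_equal(sum(cnt@initialCounts$A$counts), 1)

  # length-1 series: zero transitions
  s1 <- trinarySeries(matrix(0L, 2, 1, dimnames = list(c("A", "B"), NULL)),
                      "cyt_protein", "control")
  expect_equal(collectTransitions(list(s1), struct)@nTransitions, 0L)

  # two identical series double every count
  cnt2 <- collectTransitions(list(s, s), struct)
  expect_equal(cnt2@nodeCounts$B$counts, 2L * cnt@nodeCounts$B$counts)

  # counts are invariant to series ordering
  sA <- sampleTimeSeries(m, "EGF", "cyt_protein", T = 8, seed = 5)
  sB <- sampleTimeSeries(m, "SHH", "nuc_protein", T = 8, seed = 6)
  cAB <- collectTransitions(list(sA, sB), struct)
  cBA <- collectTransitions(list(sB, sA), struct)
  expect_equal(cAB@nodeCounts, cBA@nodeCounts)

  # out-of-range states are a data error
  bad <- matrix(2L, 2, 3, dimnames = list(c("A", "B"), NULL))
  expect_error(
    collectTransitions(list(trinarySeries(bad, "cyt_protein", "control")),
                       struct))
})

test_that("parameter smoothing follows the pseudo-count formula", {
  smooth <- function(counts, pseudo = 1) (counts + pseudo) /
    sum(counts + pseudo)
  m <- makeChain()
  struct <- modelStructure(m)
  cnt <- collectTransitions(
    list(sampleTimeSeries(m, "control", "cyt_protein", T = 5, seed = 3)),
    struct)
  # hand-set counts to the worked cases
  cnt@nodeCounts$B$counts[1, ] <- c(0L, 0L, 0L)
  cnt@nodeCounts$B$counts[2, ] <- c(5L, 2L, 1L)
  fit <- learnParameters(cnt, struct)
  expect_equal(unname(transitionCPTs(fit)$B$prob[1, ]), rep(1 / 3, 3))
  expect_equal(unname(transitionCPTs(fit)$B$prob[2, ]),
               c(6 / 11, 3 / 11, 2 / 11))
  expect_equal(unname(transitionCPTs(fit)$B$prob[2, ]),
               smooth(c(5, 2, 1)))
  # consistency limit
  cnt@nodeCounts$B$counts[3, ] <- c(1000000L, 0L, 0L)
  fit2 <- learnParameters(cnt, struct)
  expect_gt(transitionCPTs(fit2)$B$prob[3, 1], 0.999997)
  # all entries strictly positive, rows sum to one
  expect_true(all(transitionCPTs(fit2)$B$prob > 0))
  expect_equal(unname(rowSums(transitionCPTs(fit2)$B$prob)), rep(1, 3))
  expect_error(learnParameters(cnt, struct, pseudo = 0))
})

test_that("joint log probability matches closed forms", {
  u <- uniformModel(c("A", "B"))
  s <- sampleTimeSeries(u, "control", "cyt_protein", T = 14, seed = 1)
  # uniform edgeless model: closed form (1/3)^(n (T)) over all slices
  expect_equal(jointLogProb(u, s), log((1 / 3)^(2 * 14)))
  expect_lte(jointLogProb(u, s), 0)

  # deterministic transitions contribute zero log-probability
  sp <- groundTruthSpec(c("A", "B"),
                        data.frame(from = c("A", "A"), to = c("A", "B")),
                        edgeStrength = 1)
  d <- makeGroundTruthModel(sp)
  st <- matrix(1L, 2, 6, dimnames = list(c("A", "B"), NULL))
  st["B", 1] <- 0L
  ser <- trinarySeries(st, "cyt_protein", "control")
  expect_equal(jointLogProb(d, ser), log(1 / 3) + log(1 / 3))

  # unobserved entries are rejected
  st[1, 2] <- NA
  expect_error(jointLogProb(u, trinarySeries(st, "cyt_protein", "control")),
               "unobserved")
})

test_that("the joint distribution is normalised (enumeration oracle)", {
  # random-parameter 2-node model via smoothing of random counts
  m0 <- makeChain(0.6)
  struct <- modelStructure(m0)
  set.seed(42)
  cnt <- collectTransitions(
    forwardSampleSet(m0, list(list(condition = "control",
                                   context = "cyt_protein")),
                     T = 30, seed = 13),
    struct)
  m <- learnParameters(cnt, struct)
  grid <- expand.grid(rep(list(c(-1L, 0L, 1L)), 4L))
  total <- sum(apply(grid, 1, function(g) {
    st <- matrix(as.integer(g), nrow = 2,
                 dimnames = list(c("A", "B"), NULL))
    exp(jointLogProb(m, trinarySeries(st, "cyt_protein", "control")))
  }))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("parameters are recovered from sampled transitions", {
  m <- makeChain(0.7)
  struct <- modelStructure(m)
  # ~3e4 transitions: about 1e4 per parent state of B
  sets <- forwardSampleSet(
    m, rep(list(list(condition = "control", context = "cyt_protein")), 60),
    T = 501, seed = 77)
  fit <- learnParameters(collectTransitions(sets, struct), struct)
  tv <- max(abs(transitionCPTs(fit)$B$prob - transitionCPTs(m)$B$prob))
  expect_lt(tv, 0.02)
})

test_that("model JSON and series TSV round-trip through disk", {
  m <- plantedStudyModel(0.9)
  ser <- simulateStudySeries(m, T = 5, seed = 31)
  fit <- fitDBN(ser[1:9], scoreConfig(maxParents = 2),
                priorKnowledge("strong"))
  fj <- tempfile(fileext = ".json")
  writeModelJSON(fit, fj)
  back <- readModelJSON(fj)
  expect_equal(parentSets(back), parentSets(fit))
  expect_equal(transitionCPTs(back), transitionCPTs(fit))
  expect_equal(initialCPTs(back), initialCPTs(fit))

  ft <- tempfile(fileext = ".tsv")
  writeTrinarySeriesSet(ser, ft, header = "# test artifact")
  back2 <- readTrinarySeriesSet(ft)
  expect_equal(length(back2), length(ser))
  for (i in seq_along(ser)) {
    expect_identical(stateMatrix(back2[[i]]), stateMatrix(ser[[i]]))
    expect_identical(seriesCondition(back2[[i]]), seriesCondition(ser[[i]]))
    expect_identical(stimAssignment(back2[[i]]), stimAssignment(ser[[i]]))
  }
})
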