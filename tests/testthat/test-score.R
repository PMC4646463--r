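test_that("plug-in mutual information behaves on canonical tables", {
  # product-form counts: independent margins
  expect_lt(mutualInformation(outer(c(2, 4, 6), c(3, 3, 6))), 1e-12)
  # perfect binary copy: ln 2
  expect_equal(mutualInformation(matrix(c(4, 0, 0, 4), 2)), log(2))
  # information bound: MI <= min(H(rows), H(cols))
  set.seed(10)
  ent <- function(n) { p <- n[n > 0] / sum(n); -sum(p * log(p)) }
  for (i in 1:50) {
    tab <- matrix(rpois(9, 3), 3)
    if (sum(tab) == 0) next
    expect_lte(mutualInformation(tab),
               min(ent(rowSums(tab)), ent(colSums(tab))) + 1e-12)
  }
  expect_error(mutualInformation(matrix(0, 2, 2)), "empty")
})

copySeries <- function() {
  # B(t) copies A(t-1); A takes values -1 (x4) and +1 (x4) over 8 transitions
  A <- c(-1L, -1L, -1L, -1L, 1L, 1L, 1L, 1L, 1L)
  B <- c(0L, A[-9])
  trinarySeries(rbind(A = A, B = B), "cyt_protein", "control")
}

test_that("MIT family score reproduces the worked copy-parent example", {
  ser <- list(copySeries())
  sc <- mitFamilyScore("B", "A", ser)
  # 2*8*ln2 - chi-square 0.90 quantile at (3-1)(3-1) = 4 d.f.
  expect_equal(sc, 2 * 8 * log(2) - qchisq(0.90, 4), tolerance = 1e-12)
  expect_equal(sc, 3.3110, tolerance = 1e-3)
  # empty parent set scores zero by definition
  expect_identical(mitFamilyScore("B", character(0), ser), 0)
  # parent cap is enforced
  expect_error(mitFamilyScore("B", c("A", "B"), ser,
                              scoreConfig(maxParents = 1)), "maxParents")
})

test_that("constant child yields pure negative penalty", {
  st <- rbind(A = sample(c(-1L, 0L, 1L), 20, replace = TRUE),
              B = rep(1L, 20))
  ser <- list(trinarySeries(st, "cyt_protein", "control"))
  sc <- mitFamilyScore("B", "A", ser)
  expect_equal(sc, -qchisq(0.9, 4))
  expect_lt(sc, 0)
})

test_that("penalty weakens as the type-I rate rises", {
  ser <- list(copySeries())
  alphas <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  scores <- vapply(alphas, function(a)
    mitFamilyScore("B", "A", ser, scoreConfig(alpha = a)), numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("optimal parent search equals brute-force enumeration", {
  cfg <- scoreConfig(alpha = 0.1, maxParents = 3)
  for (seed in 1:60) {
    nN <- sample(3:5, 1)
    ser <- randomSeriesSet(nN, nSeries = sample(1:3, 1),
                           T = sample(4:15, 1), seed = 1000 + seed)
    sp <- slicePairs(ser)
    nodes <- rownames(stateMatrix(ser[[1]]))
    child <- nodes[1]
    cand <- nodes
    got <- optimalParents(child, cand, ser, cfg, priorKnowledge("none"))
    want <- naiveBestParents(sp$cur[, child], sp$prev, cand, 0.1, 3)
    expect_identical(got, want)
  }
  expect_identical(optimalParents("A", character(0), randomSeriesSet(2, 1, 5, 1)),
                   character(0))
})

test_that("a dominant copy edge is selected against noise candidates", {
  sp <- groundTruthSpec(c("A", "B", "C", "D"),
                        data.frame(from = "A", to = "B"), edgeStrength = 1)
  m <- makeGroundTruthModel(sp)
  ser <- forwardSampleSet(m, rep(list(list(condition = "control",
                                           context = "cyt_protein")), 10),
                          T = 15, seed = 3)
  got <- optimalParents("B", c("A", "C", "D"), ser,
                        scoreConfig(selfLoops = FALSE))
  expect_identical(got, "A")
})

test_that("weak mode with factor 1 equals no-prior mode exactly", {
  ser <- randomSeriesSet(4, 2, 10, seed = 5)
  lit <- data.frame(from = c("A", "B"), to = c("B", "C"))
  cfg <- scoreConfig()
  for (child in c("B", "C")) {
    a <- optimalParents(child, LETTERS[1:4], ser, cfg,
                        priorKnowledge("weak", lit, weakFactor = 1))
    b <- optimalParents(child, LETTERS[1:4], ser, cfg,
                        priorKnowledge("none", lit))
    expect_identical(a, b)
  }
})

test_that("weak mode relaxes the penalty only for literature edges", {
  ser <- list(copySeries())
  lit <- data.frame(from = "A", to = "B")
  sNone <- mitFamilyScore("B", "A", ser, scoreConfig(),
                          priorKnowledge("none", lit))
  sWeak <- mitFamilyScore("B", "A", ser, scoreConfig(),
                          priorKnowledge("weak", lit, weakFactor = 2))
  expect_equal(sWeak - sNone, qchisq(0.9, 4) - qchisq(0.8, 4))
})

test_that("structure learning is decomposable and respects strong mode", {
  m <- plantedStudyModel(0.9)
  ser <- simulateStudySeries(m, T = 14, seed = 17, includeControls = FALSE)
  cfg <- scoreConfig()
  lit <- defaultLiteratureEdges()

  strong <- learnStructure(ser, cfg, priorKnowledge("strong", lit))
  el <- edgeList(strong)
  litKeys <- paste(lit$from, lit$to)
  ok <- paste(el$from, el$to) %in% litKeys | el$from == el$to
  expect_true(all(ok))

  # strong mode with an empty literature set: only fixed wiring remains
  empty <- learnStructure(ser, scoreConfig(selfLoops = FALSE),
                          priorKnowledge("strong",
                                         data.frame(from = character(0),
                                                    to = character(0))))
  expect_equal(nrow(edgeList(empty)), 0)

  # per-node optima assemble into the structure (decomposability)
  none <- learnStructure(ser, scoreConfig(maxParents = 2),
                         priorKnowledge("none"))
  for (nm in sample(molecules(none), 4)) {
    cand <- union(molecules(none), nm)
    expect_identical(
      parentSets(none)[[nm]],
      optimalParents(nm, cand, ser, scoreConfig(maxParents = 2),
                     priorKnowledge("none")))
  }
})

test_that("planted edges are recovered from study-shaped data", {
  m <- plantedStudyModel(0.9)
  planted <- plantedStudyEdges()
  hits <- 0; total <- 0
  for (seed in 1:5) {
    ser <- simulateStudySeries(m, T = 14, seed = 400 + seed,
                               includeControls = FALSE)
    st <- learnStructure(ser, scoreConfig(), priorKnowledge("strong"))
    el <- paste(edgeList(st)$from, edgeList(st)$to)
    hits <- hits + sum(paste(planted$from, planted$to) %in% el)
    total <- total + nrow(planted)
  }
  expect_gt(hits / total, 0.8)
})
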