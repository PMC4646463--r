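# Construct a minimal long-format table directly (bypassing the generator)
# so the statistical behaviour is pinned by construction.
flatTable <- function(nMol = 4, nCond = 3, nTime = 5, nBio = 3, nTech = 2,
                      sd = 0.3, seed = 1, means = NULL) {
  set.seed(seed)
  mols <- sprintf("M%02d", seq_len(nMol))
  conds <- c("control", c("EGF", "SHH", "EGF+SHH")[seq_len(nCond - 1)])
  g <- expand.grid(tech_rep = seq_len(nTech), bio_rep = seq_len(nBio),
                   time = seq_len(nTime), condition = conds,
                   molecule = mols, stringsAsFactors = FALSE)
  if (is.null(means)) means <- setNames(rep(8, nMol), mols)
  g$value <- rnorm(nrow(g), means[g$molecule],
                   if (length(sd) == 1) sd else sd[g$molecule])
  data.frame(molecule = g$molecule, antibody = paste0(g$molecule, "_ab1"),
             context = "cyt_protein", condition = g$condition,
             time = g$time, bio_rep = g$bio_rep, tech_rep = g$tech_rep,
             value = g$value, detection_p = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("technical-replicate correlation is recovered", {
  # exactly duplicated technical replicates: correlation ~ 1
  tab <- flatTable(nMol = 2, seed = 2)
  tab$value[tab$tech_rep == 2] <- tab$value[tab$tech_rep == 1]
  r <- suppressWarnings(estimateTechCorrelation(tab))
  expect_true(all(r >= 0.99))

  # independent replicates: correlation near zero
  z <- matrix(0L, nrow = 40, ncol = 14,
              dimnames = list(sprintf("M%02d", 1:40), NULL))
  ser <- list(trinarySeries(z, "cyt_protein", "EGF"),
              trinarySeries(z, "cyt_protein", "control"))
  tab0 <- emulateExpression(ser, noiseModel(techRho = 0, trendSlope = 0),
                            seed = 4)
  r0 <- estimateTechCorrelation(tab0)
  expect_true(all(abs(r0) < 0.15))        # per-molecule Monte-Carlo spread
  expect_gte(mean(r0), -0.05)             # pooled estimate near zero
  expect_lte(mean(r0), 0.05)

  # generated rho = 0.8 is recovered within [0.75, 0.85]
  tab8 <- emulateExpression(ser, noiseModel(techRho = 0.8, trendSlope = 0),
                            seed = 5)
  r8 <- estimateTechCorrelation(tab8)
  expect_gte(mean(r8), 0.75)
  expect_lte(mean(r8), 0.85)

  # single technical replicate: zero with a warning (one per molecule)
  tab1 <- flatTable(nTech = 1)
  w <- capture_warnings(r1 <- estimateTechCorrelation(tab1))
  expect_true(length(w) > 0 && all(grepl("single technical", w)))
  expect_true(all(r1 == 0))
})

test_that("precision weights track the mean-variance trend", {
  # homoscedastic data: weights constant within +/- 10%
  tab <- flatTable(nMol = 150, nTime = 6, seed = 6)
  w <- precisionWeights(tab)
  expect_true(all(w > 0))
  expect_lt(max(w) / min(w), 1.21)  # max/median and median/min within 10%

  # constructed two-regime variance: low-mean weights about half
  nMol <- 40
  mols <- sprintf("M%02d", seq_len(nMol))
  means <- setNames(rep(c(5, 10), each = nMol / 2), mols)
  sds <- setNames(rep(c(sqrt(2) * 0.3, 0.3), each = nMol / 2), mols)
  tab2 <- flatTable(nMol = nMol, nTime = 6, seed = 7, sd = sds,
                    means = means)
  w2 <- precisionWeights(tab2)
  ratio <- median(w2[tab2$molecule %in% mols[1:(nMol / 2)]]) /
    median(w2[tab2$molecule %in% mols[(nMol / 2 + 1):nMol]])
  expect_gte(ratio, 0.4)
  expect_lte(ratio, 0.6)

  # too few groups: constant fallback with warning
  small <- flatTable(nMol = 2, nCond = 2, nTime = 2)
  expect_warning(ws <- precisionWeights(small), "constant")
  expect_true(all(ws == 1))
})

test_that("copied control groups give zero log-fold-change and call 0", {
  tab <- flatTable(nMol = 3, nTime = 5, seed = 8)
  # make every stimulated observation an exact copy of its control
  ctrl <- tab[tab$condition == "control", ]
  for (cond in setdiff(unique(tab$condition), "control")) {
    idx <- tab$condition == cond
    key <- paste(tab$molecule[idx], tab$time[idx], tab$bio_rep[idx],
                 tab$tech_rep[idx])
    ckey <- paste(ctrl$molecule, ctrl$time, ctrl$bio_rep, ctrl$tech_rep)
    tab$value[idx] <- ctrl$value[match(key, ckey)]
  }
  calls <- suppressWarnings(fitDifferentialCalls(tab))
  expect_true(all(abs(calls$log_fc) < 1e-10))
  expect_true(all(calls$call == 0))
  expect_true(all(calls$fdr >= calls$p_value))
})

test_that("strong shifts are called with the correct sign", {
  tab <- flatTable(nMol = 3, nTime = 5, seed = 9, sd = 0.2)
  # M01 up in EGF at all times, M02 down in SHH
  up <- tab$molecule == "M01" & tab$condition == "EGF"
  dn <- tab$molecule == "M02" & tab$condition == "SHH"
  tab$value[up] <- tab$value[up] + 2    # 10 sigma
  tab$value[dn] <- tab$value[dn] - 2
  calls <- suppressWarnings(fitDifferentialCalls(tab))
  expect_true(all(calls$call[calls$molecule == "M01" &
                               calls$condition == "EGF"] == 1))
  expect_true(all(calls$call[calls$molecule == "M02" &
                               calls$condition == "SHH"] == -1))
  expect_true(all(calls$call[calls$molecule == "M03"] == 0))

  # location invariance: a global additive shift changes nothing
  tab2 <- tab; tab2$value <- tab2$value + 5
  calls2 <- suppressWarnings(fitDifferentialCalls(tab2))
  expect_equal(calls$call, calls2$call)
  expect_equal(calls$log_fc, calls2$log_fc, tolerance = 1e-4)

  # FDR monotonicity: a stricter threshold never creates a new nonzero call
  strict <- ifelse(calls$fdr < 0.01, sign(calls$log_fc), 0)
  expect_true(all(strict == 0 | strict == calls$call))
})

test_that("antibody summarization takes the sign of the mean", {
  df <- data.frame(molecule = rep("EGFR", 3), context = "cyt_protein",
                   condition = "EGF", time = 1, call = c(1L, 1L, 0L))
  expect_equal(summarizeAntibodies(df)$call, 1L)
  df$call <- c(1L, -1L, 0L)
  expect_equal(summarizeAntibodies(df)$call, 0L)
  df2 <- df[1, ]; df2$call <- -1L
  expect_equal(summarizeAntibodies(df2)$call, -1L)
})

test_that("series assembly produces the study layout with stim wiring", {
  sm <- expand.grid(molecule = c("A", "B"), time = 1:4,
                    context = c("cyt_protein", "nuc_protein"),
                    condition = c("EGF", "SHH", "EGF+SHH"),
                    stringsAsFactors = FALSE)
  smT <- expand.grid(molecule = c("A", "B"), time = 1:4,
                     context = "transcript",
                     condition = c("EGF", "GLI", "EGF+GLI"),
                     stringsAsFactors = FALSE)
  sm <- rbind(sm, smT)
  sm$call <- 0L
  ser <- assembleSeries(sm)
  expect_length(ser, 9)
  expect_true(all(vapply(ser, nTimePoints, integer(1)) == 4))
  gli <- Filter(function(s) seriesCondition(s) == "GLI", ser)[[1]]
  expect_equal(stimAssignment(gli),
               c(EGF_stim = 0L, SHH_stim = 0L, GLI_stim = 1L))
  both <- Filter(function(s) seriesCondition(s) == "EGF+SHH", ser)[[1]]
  expect_equal(stimAssignment(both),
               c(EGF_stim = 1L, SHH_stim = 1L, GLI_stim = 0L))

  # single condition/context input gives a single series
  one <- assembleSeries(sm[sm$context == "cyt_protein" &
                             sm$condition == "EGF", ])
  expect_length(one, 1)

  # a missing time point is reported
  expect_error(assembleSeries(sm[-1, ]), "missing")
})

test_that("discretization recovers planted states end to end", {
  m <- makeGroundTruthModel(groundTruthSpec(zeroBias = 0.7))
  ser <- simulateStudySeries(m, T = 14, seed = 41)
  recov <- function(effect) {
    tab <- emulateExpression(ser, noiseModel(effectSize = effect),
                             seed = 42, nBackgroundProbes = 87)
    res <- suppressWarnings(
      discretizeExpression(tab, molecules = molecules(m)))
    mean(mapply(function(s) {
      tr <- Filter(function(z)
        seriesContext(z) == seriesContext(s) &&
        seriesCondition(z) == seriesCondition(s), ser[1:9])[[1]]
      mean(stateMatrix(s)[molecules(m), ] == stateMatrix(tr))
    }, res$series))
  }
  accStrong <- recov(6 * 0.25)   # effect = 6 sigma0
  accWeak <- recov(2 * 0.25)
  expect_gte(accStrong, 0.95)
  # accuracy grows with effect size
  expect_gt(accStrong, accWeak)
})
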