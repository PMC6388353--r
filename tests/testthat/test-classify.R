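test_that("training matrices respect the 3:1 ratio, shapes and determinism", {
  cfg <- fixConfig()
  prof <- fixProfiles()
  pos <- sampleFamily(prof$IGHV, 30L, tier = 0L, seed = 77L)
  mats <- suppressWarnings(buildTrainingMatrices(
    c(pos, sampleFamily(prof$TRBV, 9L, tier = 0L, seed = 78L)),
    c(rep("IGHV", 30L), rep("TRBV", 9L)), cfg))
  expect_setequal(names(mats), c("IGHV", "TRBV"))
  expect_length(mats$IGHV, 7L)            # depth 2: 1 + 2 + 4 nodes
  for (nm in names(mats$IGHV)) {
    m <- mats$IGHV[[nm]]
    expect_identical(nrow(m$x), 40L)      # 30 signal + ceiling(30/3)
    expect_identical(as.vector(table(m$y)[c("signal", "background")]),
                     c(30L, 10L))
  }
  ## odd count rounds the background up
  expect_identical(as.vector(table(mats$TRBV[["0.0"]]$y)["background"]), 3L)

  ## same config, same matrices
  mats2 <- suppressWarnings(buildTrainingMatrices(
    c(pos, sampleFamily(prof$TRBV, 9L, tier = 0L, seed = 78L)),
    c(rep("IGHV", 30L), rep("TRBV", 9L)), cfg))
  expect_identical(mats, mats2)

  ## depth 0 collapses to a single matrix per locus
  cfg0 <- vexConfig(depth = 0L, seed = 11L)
  expect_length(
    suppressWarnings(buildTrainingMatrices(pos, rep("IGHV", 30L), cfg0))$IGHV,
    1L)

  ## loci without positives are skipped with a warning
  expect_warning(buildTrainingMatrices(pos, rep("IGHV", 30L), cfg), "skipped")
})

test_that("trained ensembles recognize their own positives and reject shuffles", {
  models <- fixModels()
  tr <- fixTraining()
  prof <- assignLoci(predictProfiles(tr$aa, models), fixConfig())
  probs <- nodeProbs(prof)
  expect_true(all(probs >= 0 & probs <= 1))
  ## combined is the arithmetic node mean
  nodes <- prof@nodes
  expect_equal(combinedProbs(prof)[, "IGHV"],
               rowMeans(probs[, paste0("IGHV|", nodes)]), tolerance = 1e-12)
  ## root-node self probability for the true locus
  rootSelf <- probs[cbind(seq_along(tr$aa),
                          match(paste0(tr$locus, "|0.0"), colnames(probs)))]
  expect_gte(mean(rootSelf > 0.5), 0.95)
  ## locus assignment accuracy on the training set itself
  expect_gte(mean(assignedLocus(prof) == tr$locus), 0.95)

  ## residue-shuffled probes: signal probability < 0.5 for every locus
  set.seed(55)
  sh <- vapply(tr$aa[seq(1L, length(tr$aa), by = 6L)], function(a) {
    paste(sample(strsplit(a, "")[[1L]]), collapse = "")
  }, character(1))
  shp <- predictProfiles(sh, models)
  below <- apply(combinedProbs(shp), 1L, max) < 0.5
  expect_gte(mean(below), 0.90)
})

test_that("model sets serialize and reload with identical predictions", {
  models <- fixModels()
  probe <- randomAA(5L, len = 96L)
  p1 <- predictProfiles(probe, models)
  path <- withr::local_tempfile(fileext = ".rds")
  saveLocusModels(models, path)
  p2 <- predictProfiles(probe, readLocusModels(path))
  expect_identical(nodeProbs(p1), nodeProbs(p2))
  expect_error(
    suppressWarnings(readLocusModels(withr::local_tempfile(fileext = ".rds"))))
})

test_that("prediction is deterministic and guards feature compatibility", {
  models <- fixModels()
  probe <- randomAA(3L, len = 100L)
  expect_identical(nodeProbs(predictProfiles(probe, models)),
                   nodeProbs(predictProfiles(probe, models)))
  ## too short for the decomposition depth
  expect_error(predictProfiles("ACD", models), "too short")
})

test_that("adjacent-level consistency criterion compares parents to children", {
  base <- matrix(0.9, 1L, 7L,
                 dimnames = list(NULL, paste0("IGHV|", c("0.0", "1.0", "1.1",
                                                         "2.0", "2.1", "2.2", "2.3"))))
  ## children within eps of every parent
  ps <- makeProfileSet(base)
  expect_true(consistencyOk(ps, "IGHV", eps = 0.17))

  ## one child deviates by 0.30 from its parent
  bad <- base; bad[, "IGHV|1.1"] <- 0.60
  expect_false(consistencyOk(makeProfileSet(bad), "IGHV", eps = 0.17))
  ## a 0.10 gap passes at eps = 0.17
  mild <- base; mild[, "IGHV|1.1"] <- 0.80; mild[, "IGHV|2.2"] <- 0.80
  mild[, "IGHV|2.3"] <- 0.80
  expect_true(consistencyOk(makeProfileSet(mild), "IGHV", eps = 0.17))
  ## vacuous bound
  expect_true(consistencyOk(makeProfileSet(bad), "IGHV", eps = 1.0))
})

test_that("terminal criterion checks the outermost deepest nodes", {
  base <- matrix(0.9, 1L, 7L,
                 dimnames = list(NULL, paste0("TRBV|", c("0.0", "1.0", "1.1",
                                                         "2.0", "2.1", "2.2", "2.3"))))
  base[, "TRBV|2.0"] <- 0.8; base[, "TRBV|2.3"] <- 0.75
  expect_true(terminalOk(makeProfileSet(base), "TRBV", tau = 0.7))
  base[, "TRBV|2.3"] <- 0.65
  expect_false(terminalOk(makeProfileSet(base), "TRBV", tau = 0.7))
  expect_true(terminalOk(makeProfileSet(base), "TRBV", tau = 0))
})

test_that("multiresolution score is zero at perfect agreement and matches hand computation", {
  flat <- matrix(0.8, 1L, 7L,
                 dimnames = list(NULL, paste0("IGKV|", c("0.0", "1.0", "1.1",
                                                         "2.0", "2.1", "2.2", "2.3"))))
  expect_equal(mrConsistencyScore(makeProfileSet(flat), "IGKV", sigma = 0.05), 0)

  ## depth-1 hand case: p00 = 0.9, children 0.9 and 0.4, sigma = 0.1
  d1 <- matrix(c(0.9, 0.9, 0.4), 1L, 3L,
               dimnames = list(NULL, paste0("IGKV|", c("0.0", "1.0", "1.1"))))
  ps1 <- makeProfileSet(d1, depth = 1L)
  want <- (2 / 3) * (0 + (1 - exp(0.25 / 0.1)))
  expect_equal(mrConsistencyScore(ps1, "IGKV", sigma = 0.1), want,
               tolerance = 1e-12)

  ## monotone: larger deviations only lower the score
  devs <- seq(0, 0.5, by = 0.05)
  scores <- vapply(devs, function(d) {
    m <- flat; m[, "IGKV|2.2"] <- 0.8 - d
    mrConsistencyScore(makeProfileSet(m), "IGKV", sigma = 0.05)
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_true(all(scores[-1L] < 0))

  expect_error(mrConsistencyScore(makeProfileSet(flat), "IGKV", sigma = 0),
               "sigma")

  ## negated-exponent variant stays non-negative and bounded by N - 1
  alt <- mrConsistencyScore(ps1, "IGKV", sigma = 0.1, sign = "negative")
  expect_gte(alt, 0)
  expect_lte(alt, 2)
})

test_that("locus assignment takes the arg-max, applies thresholds and flags ties", {
  cols <- as.vector(t(outer(lociLabels(), c("0.0", "1.0", "1.1", "2.0", "2.1", "2.2", "2.3"),
                            function(k, n) paste0(k, "|", n))))
  m <- matrix(0.2, 3L, length(cols), dimnames = list(NULL, cols))
  m[1L, grep("^TRBV", cols)] <- 0.92          # clear accept
  m[2L, grep("^IGLV", cols)] <- 0.55          # below pMin
  m[3L, grep("^IGHV", cols)] <- 0.85          # exact tie IGHV/TRGV
  m[3L, grep("^TRGV", cols)] <- 0.85
  ps <- assignLoci(makeProfileSet(m), fixConfig())
  expect_identical(assignedLocus(ps)[1L], "TRBV")
  expect_true(accepted(ps)[1L])
  expect_false(accepted(ps)[2L])
  ## tie resolves to the fixed locus order and is flagged
  expect_identical(assignedLocus(ps)[3L], "IGHV")
  expect_true(ps@ambiguous[3L])
  expect_false(ps@ambiguous[1L])
})
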