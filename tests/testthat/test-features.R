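test_that("multiresolution decomposition splits, reconstructs and validates", {
  m <- mrDecompose("ABCDEFGH", 2L)
  expect_identical(mrNode(m, 1L, 0L), "ABCD")
  expect_identical(mrNode(m, 1L, 1L), "EFGH")
  expect_identical(unname(unlist(mrNodes(m)[4:7])), c("AB", "CD", "EF", "GH"))

  ## odd lengths: left child longer
  m5 <- mrDecompose("ABCDE", 1L)
  expect_identical(mrNode(m5, 1L, 0L), "ABC")
  expect_identical(mrNode(m5, 1L, 1L), "DE")

  ## depth 0 is the identity
  expect_identical(mrNodes(mrDecompose("XYZ", 0L)), list("0.0" = "XYZ"))

  ## too short for the depth
  expect_error(mrDecompose("AB", 2L), "too short")

  ## every level concatenates back to the input (random cases)
  set.seed(3)
  for (aa in randomAA(5L, len = sample(8:40, 1L))) {
    mm <- mrDecompose(aa, 3L)
    for (i in 0:3) {
      lvl <- paste0(unlist(mrNodes(mm)[paste0(i, ".", 0:(2^i - 1L))]), collapse = "")
      expect_identical(lvl, aa)
    }
  }
})

test_that("internal node-subsequence shortcut agrees with the full decomposition", {
  set.seed(9)
  for (aa in randomAA(6L, len = sample(16:50, 1L))) {
    m <- mrDecompose(aa, 3L)
    for (nm in names(mrNodes(m))) {
      expect_identical(VExonMiner:::.nodeSubseq(aa, nm), mrNodes(m)[[nm]])
    }
  }
})

test_that("AA-pair transform has 440 entries with the documented layout", {
  v <- aaPairTransform("AA")
  expect_length(v, 440L)
  expect_identical(unname(v["A"]), 2L)
  expect_identical(unname(v["AA"]), 1L)
  expect_identical(sum(v == 0L), 438L)

  v2 <- aaPairTransform("ACD")
  expect_identical(unname(v2[c("A", "C", "D", "AC", "CD")]), rep(1L, 5L))
  expect_identical(sum(v2), 5L)

  expect_error(aaPairTransform("ACB"), "non-standard")
})

test_that("AA-pair histogram conserves residue and pair counts", {
  set.seed(21)
  for (aa in randomAA(200L, len = sample(5:120, 1L))) {
    v <- aaPairTransform(aa)
    expect_identical(sum(v[1:20]), nchar(aa))
    expect_identical(sum(v[21:440]), nchar(aa) - 1L)
  }
})

test_that("shuffling preserves composition but generally not the pair block", {
  set.seed(33)
  changed <- 0L
  for (i in 1:20) {
    aa <- randomAA(1L, len = 80L)
    sh <- paste(sample(strsplit(aa, "")[[1L]]), collapse = "")
    v1 <- aaPairTransform(aa); v2 <- aaPairTransform(sh)
    expect_identical(v1[1:20], v2[1:20])
    if (!identical(v1[21:440], v2[21:440])) changed <- changed + 1L
  }
  expect_gte(changed, 19L)
})

test_that("the property table holds 500 standardized AAindex scales", {
  tb <- defaultPropertyTable()
  expect_identical(dim(tb$values), c(20L, 500L))
  expect_length(tb$accessions, 500L)
  expect_false(is.unsorted(tb$accessions))
  expect_true(all(abs(colMeans(tb$values)) < 1e-12))
  expect_true(all(abs(apply(tb$values, 2L, stats::sd) - 1) < 1e-12))
  expect_false(anyNA(tb$values))
  ## deterministic selection
  expect_identical(tb$accessions, defaultPropertyTable()$accessions)
})

test_that("PDT vanishes on repeats and matches direct arithmetic", {
  expect_identical(unname(pdtTransform("AAAAA")), rep(0, 500L))
  expect_identical(unname(pdtTransform("AAAAA", lam = 3L)), rep(0, 500L))
  ## period-2 repeat at lag 2: every residue equals its lag-2 neighbour
  expect_identical(unname(pdtTransform("ACACAC", lam = 2L)), rep(0, 500L))

  expect_error(pdtTransform("ACD", lam = 3L), "smaller than sequence length")

  ## two hand-made standardized properties as an arithmetic oracle for "ACDE"
  p1 <- c(A = 1, C = 2, D = 3, E = 4)
  p2 <- c(A = 2, C = 0, D = 2, E = 0)
  vals <- cbind(prop1 = rep(0, 20), prop2 = rep(0, 20))
  rownames(vals) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  ## standardization must cover all 20 residues; put the other 16 at distinct values
  full1 <- c(p1, stats::setNames(seq(5, 20), rownames(vals)[5:20]))
  full2 <- c(p2, stats::setNames(rep(c(1, 3), 8), rownames(vals)[5:20]))
  vals[, "prop1"] <- (full1 - mean(full1)) / stats::sd(full1)
  vals[, "prop2"] <- (full2 - mean(full2)) / stats::sd(full2)
  tb <- list(values = vals, accessions = c("prop1", "prop2"))
  got <- pdtTransform("ACDE", lam = 1L, table = tb)
  ## oracle: mean squared successive difference per property, then unit norm
  raw <- vapply(1:2, function(j) {
    pv <- vals[c("A", "C", "D", "E"), j]
    mean((pv[1:3] - pv[2:4])^2)
  }, numeric(1))
  want <- raw / sqrt(sum(raw^2))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("per-level hybrid featurization has the right arity and is deterministic", {
  aa <- randomAA(1L, len = 60L)
  m <- mrDecompose(aa, 2L)
  lm <- list("0" = list(kind = "pdt", lam = 3L),
             "1" = list(kind = "pdt", lam = 1L),
             "2" = list(kind = "aa_pairs"))
  fv <- hybridTransform(m, lm)
  expect_length(fv, 7L)
  expect_identical(unname(vapply(fv, length, integer(1))),
                   c(500L, 500L, 500L, 440L, 440L, 440L, 440L))

  ## uniform aa_pairs map reduces to the plain per-node transform
  lmu <- list("0" = list(kind = "aa_pairs"), "1" = list(kind = "aa_pairs"),
              "2" = list(kind = "aa_pairs"))
  fu <- hybridTransform(m, lmu)
  for (nm in names(fu)) {
    expect_identical(fu[[nm]], aaPairTransform(mrNodes(m)[[nm]]))
  }

  ## recomputation is bitwise identical
  expect_identical(fv, hybridTransform(mrDecompose(aa, 2L), lm))

  expect_error(hybridTransform(m, lmu[1:2]), "must cover levels")
})
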