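test_that("expression is mean normalized depth over the interval", {
  tr <- makeTrack(list(chr = c(rep(50, 120), 10, 20, 30, numeric(77))))
  srnas <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(11, 121, 180), c(110, 123, 200)),
    srna_id = c("a", "b", "c"))
  se <- quantifyExpression(srnas, list(s1 = tr))
  mat <- SummarizedExperiment::assay(se)
  expect_equal(unname(mat[, 1]), c(50, (10 + 20 + 30) / 3, 0))

  ## a merged interval equals the length-weighted mean of its parts
  parts <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(100, 130), c(129, 139)),
    srna_id = c("p1", "p2"))
  whole <- GenomicRanges::GRanges("chr", IRanges::IRanges(100, 139),
                                  srna_id = "w")
  mp <- SummarizedExperiment::assay(
    quantifyExpression(parts, list(s1 = tr)))
  mw <- SummarizedExperiment::assay(
    quantifyExpression(whole, list(s1 = tr)))
  expect_equal(unname(mw[1, 1]),
               unname((mp[1, 1] * 30 + mp[2, 1] * 10) / 40))
})

test_that("size factors are median-of-ratios and permutation-invariant", {
  set.seed(11)
  base <- matrix(rpois(300, 50) + 1L, 100, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  same <- cbind(a = base[, 1], b = base[, 1], c = base[, 1])
  expect_equal(unname(sizeFactorsForCounts(same)), rep(1, 3))

  doubled <- base
  doubled[, 2] <- base[, 2] * 2L
  sf <- sizeFactorsForCounts(doubled)
  ratio <- sf[["b"]] / exp(mean(log(sf[c("a", "c")])))
  sfOrig <- sizeFactorsForCounts(base)
  ratioOrig <- sfOrig[["b"]] / exp(mean(log(sfOrig[c("a", "c")])))
  expect_equal(ratio, 2 * ratioOrig, tolerance = 1e-12)

  perm <- sample(nrow(base))
  expect_equal(sizeFactorsForCounts(base[perm, ]),
               sizeFactorsForCounts(base))

  zeros <- base; zeros[, 1] <- 0L
  expect_error(sizeFactorsForCounts(zeros), "positive")
})

test_that("size factors agree with the established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  cts <- matrix(rnbinom(600, mu = 80, size = 5), 100, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  cts[cts == 0] <- 1L
  expect_equal(unname(sizeFactorsForCounts(cts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cts)),
               tolerance = 1e-8)
})

test_that("NB exact test honors its degenerate and symmetry contracts", {
  same <- c(10L, 12L, 11L)
  r <- nbExactTest(same, same, dispersion = 0.1)
  expect_equal(r$fold_change, 1)
  expect_equal(r$p, 1)

  z <- nbExactTest(c(0L, 0L, 0L), c(0L, 0L, 0L), dispersion = 0.1)
  expect_equal(z$p, 1)
  expect_equal(z$fold_change, 1)

  a <- c(10L, 15L, 12L); b <- c(40L, 35L, 50L)
  ab <- nbExactTest(a, b, dispersion = 0.05)
  ba <- nbExactTest(b, a, dispersion = 0.05)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_gt(ab$fold_change, 1)
  expect_lte(ab$p, 1)
  expect_gt(ab$p, 0)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(bhAdjust(p), bhOracle(p))
    expect_true(all(bhAdjust(p) >= p))
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the DE filter applies both thresholds strictly", {
  res <- data.frame(fold_change = c(1.5, 2.0, 2.0, 0.5, 1.2),
                    p_adj = c(0.01, 0.049, 0.05, 0.01, 0.001))
  got <- deFilter(res)
  expect_identical(got$significant, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(got$direction, c("none", "up", "up", "down", "none"))
})

test_that("condition-level DE separates induced, repressed and
          constitutive sRNAs", {
  des <- studyDesign()
  eff <- matrix(1, 30, 6, dimnames = list(NULL, levels(des$condition)))
  eff[1:5, "salt"] <- 6      # induced under salt
  eff[6:10, "salt"] <- 1 / 6 # repressed under salt
  cts <- simulateCounts(30, des, effects = eff, baseMean = 150,
                        dispersion = 0.05, seed = 21)
  de <- runDe(cts, des, conditions = "salt")
  expect_equal(nrow(de), 30L)
  expect_true(all(de$significant[1:10]))
  expect_identical(de$direction[1:5], rep("up", 5))
  expect_identical(de$direction[6:10], rep("down", 5))
  expect_lt(sum(de$significant[11:30]), 3)

  ## label swap inverts fold changes and preserves p values
  swapped <- des
  swapped$condition <- factor(
    ifelse(swapped$condition == "control", "salt",
           ifelse(swapped$condition == "salt", "control",
                  as.character(swapped$condition))),
    levels = levels(des$condition))
  de2 <- runDe(cts, swapped, conditions = "salt",
               dispersion = 0.05)
  de1 <- runDe(cts, des, conditions = "salt", dispersion = 0.05)
  expect_equal(de2$fold_change, 1 / de1$fold_change, tolerance = 1e-9)
  expect_equal(de2$p, de1$p, tolerance = 1e-9)
})

test_that("correspondence analysis reproduces its chi-square identity", {
  ## independence-model table: zero inertia
  indep <- outer(c(2, 3, 5), c(1, 4, 2, 3))
  ca0 <- correspondenceAnalysis(indep)
  expect_lt(ca0$total_inertia, 1e-12)

  ## 2x2: total inertia = chi-square / grand total
  x <- matrix(c(12, 5, 9, 21), 2)
  ca <- correspondenceAnalysis(x)
  chi <- suppressWarnings(stats::chisq.test(x, correct = FALSE))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(x), tolerance = 1e-12)

  ## row permutation permutes coordinates, preserves inertia
  set.seed(31)
  m <- matrix(rpois(60, 30) + 1, 6, 10,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:10)))
  ca1 <- correspondenceAnalysis(m)
  perm <- sample(6)
  ca2 <- correspondenceAnalysis(m[perm, ])
  expect_equal(ca2$inertia, ca1$inertia, tolerance = 1e-10)
  expect_equal(abs(ca2$row_coords), abs(ca1$row_coords[perm, ]),
               tolerance = 1e-8)

  zr <- m; zr[2, ] <- 0
  expect_error(correspondenceAnalysis(zr), "r2")
})

test_that("CA coordinates match an independent SVD and the established
          implementation", {
  set.seed(32)
  m <- matrix(rpois(100, 40) + 1, 10, 10,
              dimnames = list(paste0("r", 1:10), paste0("c", 1:10)))
  ca <- correspondenceAnalysis(m, nDim = 4)
  oracle <- caOracle(m)
  expect_equal(abs(unname(ca$row_coords)), abs(oracle$row[, 1:4]),
               tolerance = 1e-8)
  expect_equal(abs(unname(ca$col_coords)), abs(oracle$col[, 1:4]),
               tolerance = 1e-8)
  expect_equal(ca$inertia, oracle$inertia[1:4], tolerance = 1e-10)

  skip_if_not_installed("MASS")
  mc <- MASS::corresp(m, nf = 2)
  princ <- mc$rscore %*% diag(mc$cor[1:2])
  expect_equal(abs(unname(ca$row_coords[, 1:2])), abs(unname(princ)),
               tolerance = 1e-6)
})

test_that("a condition-specific sRNA ordinates next to its condition's
          samples", {
  study <- demoStudy()
  f <- plantedFeatures(study)
  mat <- S4Vectors::mcols(f)$depth[!f$is_decoy, ]
  rownames(mat) <- f$feature_id[!f$is_decoy]
  ca <- correspondenceAnalysis(mat)
  for (saltOnly in f$feature_id[f$trend_group == "induced:salt"]) {
    cosSim <- apply(ca$col_coords, 1, function(v) {
      u <- ca$row_coords[saltOnly, ]
      sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    })
    isSalt <- grepl("^salt_", names(cosSim))
    expect_true(isSalt[which.max(cosSim)])
    expect_gt(mean(cosSim[isSalt]), mean(cosSim[!isSalt]) + 0.3)
  }
})
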