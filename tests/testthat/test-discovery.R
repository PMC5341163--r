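test_that("threshold segmentation emits maximal runs above 50x", {
  d <- numeric(500)
  d[101:160] <- 60
  seg <- segmentHighExpression(makeTrack(list(chr = d)), 50)
  expect_equal(start(seg), 101L)
  expect_equal(end(seg), 160L)

  ## short runs are still emitted here (length filtering is downstream)
  d2 <- numeric(500); d2[101:140] <- 60
  seg2 <- segmentHighExpression(makeTrack(list(chr = d2)), 50)
  expect_equal(width(seg2), 40L)

  ## depth exactly at the threshold does not qualify (strict >)
  d3 <- rep(50, 500)
  expect_length(segmentHighExpression(makeTrack(list(chr = d3)), 50), 0L)
})

test_that("low-expression rescue applies the flank-ratio rule", {
  mk <- function(inside, left, right) {
    makeTrack(list(chr = c(rep(left, 50), rep(inside, 60),
                           rep(right, 50))))
  }
  ref <- GenomicRanges::GRanges("chr", IRanges::IRanges(51, 110))
  expect_length(rescueLowExpression(mk(20, 2, 2), ref, ratio = 2), 1L)
  expect_length(rescueLowExpression(mk(20, 15, 2), ref, ratio = 2), 0L)
  expect_length(rescueLowExpression(mk(0, 0, 0), ref, ratio = 2), 0L)
})

test_that("cross-sample support counts samples by Jaccard overlap", {
  hit <- GenomicRanges::GRanges("chr", IRanges::IRanges(1001, 1100))
  miss <- GenomicRanges::GRanges()
  perSample <- c(rep(list(hit), 3), rep(list(miss), 15))
  names(perSample) <- sprintf("s%02d", 1:18)
  got <- retainBySupport(perSample, minSupport = 3)
  expect_length(got, 1L)
  expect_equal(got$support, 3L)
  expect_equal(start(got), 1001L)

  got2 <- retainBySupport(perSample[c(1:2, 4:18)], minSupport = 3)
  expect_length(got2, 0L)

  all18 <- rep(list(hit), 18)
  names(all18) <- sprintf("s%02d", 1:18)
  expect_equal(retainBySupport(all18, minSupport = 3)$support, 18L)

  ## a sliver overlap (Jaccard < 0.5) does not count as observation
  sliver <- GenomicRanges::GRanges("chr", IRanges::IRanges(1091, 1190))
  mix <- c(rep(list(hit), 2), list(sliver), rep(list(miss), 15))
  names(mix) <- sprintf("s%02d", 1:18)
  expect_length(retainBySupport(mix, minSupport = 3), 0L)
})

test_that("adjacent candidates merge only with a small gap and a shared
          trend", {
  cand <- GenomicRanges::GRanges("chr",
                                 IRanges::IRanges(c(100, 181),
                                                  c(150, 260)),
                                 support = c(5L, 4L))
  up <- c(1, 2, 3, 4)
  m <- mergeAdjacent(cand, rbind(up, 2 * up), mergeGap = 50)
  expect_length(m$candidates, 1L)
  expect_equal(c(start(m$candidates), end(m$candidates)), c(100L, 260L))
  ## merged expression is the length-weighted mean of the parts
  w <- c(51, 80)
  expect_equal(m$expression[1, ],
               (up * w[1] + 2 * up * w[2]) / sum(w))

  ## gap of 60 stays apart
  far <- GenomicRanges::GRanges("chr",
                                IRanges::IRanges(c(100, 211),
                                                 c(150, 260)),
                                support = c(5L, 4L))
  expect_length(mergeAdjacent(far, rbind(up, 2 * up), 50)$candidates, 2L)

  ## anticorrelated profiles stay apart
  expect_length(mergeAdjacent(cand, rbind(up, rev(up)), 50)$candidates,
                2L)
})

test_that("boundary refinement finds the maximum coverage drop", {
  d <- numeric(400); d[100:200] <- 100
  tr <- makeTrack(list(chr = d))
  cand <- GenomicRanges::GRanges("chr", IRanges::IRanges(105, 195),
                                 support = 3L)
  r <- refineBoundaries(cand, tr, window = 20)
  expect_equal(c(start(r), end(r)), c(100L, 200L))

  ## perfectly rectangular signal with matching candidate: unchanged
  exact <- GenomicRanges::GRanges("chr", IRanges::IRanges(100, 200),
                                  support = 3L)
  r2 <- refineBoundaries(exact, tr, window = 20)
  expect_equal(c(start(r2), end(r2)), c(100L, 200L))

  ## flat plateau (no drop anywhere): tie rule keeps the boundary
  flat <- makeTrack(list(chr = rep(80, 400)))
  r3 <- refineBoundaries(cand, flat, window = 20)
  expect_equal(c(start(r3), end(r3)), c(105L, 195L))
})

test_that("location classification follows the asRNA > UTR > ncRNA
          precedence", {
  ann <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1000, 5000), c(2000, 6000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"),
    feature_class = "CDS")
  cand <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1200, 900, 3000, 6040),
                            c(1300, 980, 3100, 6120)))
  got <- classifyByLocation(cand, ann)
  ## wholly inside gA -> asRNA; 20-100 nt upstream of gA (+) -> UTR;
  ## far from both -> ncRNA; upstream window of gB (-) is [6001, 6100]
  expect_equal(got$category, c("asRNA", "UTR", "ncRNA", "UTR"))
  expect_equal(got$assoc_gene, c("gA", "gA", NA, "gB"))

  ## interval >= 101 nt from every gene is intergenic
  nc <- GenomicRanges::GRanges("chr", IRanges::IRanges(2101, 2200))
  expect_equal(classifyByLocation(nc, ann)$category, "ncRNA")
})

test_that("repeat flagging needs a long, high-identity second site", {
  set.seed(55)
  g <- makeGenome(c(chr = 20000L), gc = 0.5, seed = 56)
  gs <- as.character(g[[1]])
  dup <- substr(gs, 1001, 1080)
  substr(gs, 5001, 5080) <- dup
  mut <- strsplit(dup, "")[[1]]
  idx <- sample(80, 24)  # 70% identity copy
  mut[idx] <- vapply(mut[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  substr(gs, 9001, 9080) <- paste(mut, collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chr = gs))
  cand <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1001, 15001, 9001),
                            c(1080, 15080, 9080)))
  got <- flagRepeats(cand, g2)
  expect_identical(got$repeat_flag, c(TRUE, FALSE, FALSE))

  ## a reverse-complement second site is also a repeat
  gs2 <- as.character(g[[1]])
  substr(gs2, 5001, 5080) <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dup)))
  g3 <- Biostrings::DNAStringSet(c(chr = gs2))
  got2 <- flagRepeats(GenomicRanges::GRanges(
    "chr", IRanges::IRanges(1001, 1080)), g3)
  expect_true(got2$repeat_flag)
})

test_that("external annotation labels honor the E-value cutoff", {
  cand <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 100),
                                 srna_id = "nc1")
  tabs <- list(nr = data.frame(srna_id = "nc1", label = "hypothetical",
                               evalue = 1e-12))
  got <- ingestExternalAnnotations(cand, tabs)
  expect_equal(got$nr_label, "hypothetical")

  tabs$nr$evalue <- 1e-8
  got2 <- ingestExternalAnnotations(cand, tabs)
  expect_true(is.na(got2$nr_label))

  expect_identical(
    S4Vectors::mcols(ingestExternalAnnotations(cand, list())),
    S4Vectors::mcols(cand))

  expect_warning(
    ingestExternalAnnotations(cand, list(
      orf = data.frame(srna_id = "bogus", label = "orf1"))),
    "unknown")
  expect_error(
    ingestExternalAnnotations(cand, list(nr = data.frame(x = 1))),
    "malformed")
})

test_that("called sRNAs satisfy the length, support and partition
          invariants", {
  srnas <- demoSrnas()
  expect_true(all(width(srnas) >= 50))
  expect_true(all(srnas$support >= 3))
  expect_true(all(srnas$category %in% c("ncRNA", "asRNA", "UTR")))
  expect_false(anyDuplicated(srnas$srna_id) > 0)

  ## classification is order-independent
  perm <- sample(seq_along(srnas))
  re <- classifyByLocation(srnas[perm], studyAnnotation(demoStudy()))
  expect_identical(re$category, srnas$category[perm])
})

test_that("a vacuous support threshold yields an empty, well-formed
          call set", {
  tracks <- demoTracks()[1:4]
  got <- callSrnas(tracks, studyAnnotation(demoStudy()),
                   params = detectionParams(minSupport = 19L))
  expect_length(got, 0L)
  expect_true(all(c("srna_id", "category", "support") %in%
                    colnames(S4Vectors::mcols(got))))
})
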