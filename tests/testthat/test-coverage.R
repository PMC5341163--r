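## Fixed tiny genome shared by the mapping tests.
localGenome <- function(seed = 101, len = 20000L) {
  makeGenome(c(chr = len), gc = 0.5, seed = seed)
}

readAt <- function(genome, start, len = 100L, rep = 1L) {
  as.character(Biostrings::subseq(genome[[rep]], start,
                                  start + len - 1L))
}

asReads <- function(seqs, quals = NULL) {
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n) strrep("I", n),
                    character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
}

test_that("exact reads map in place and corrupted ends are trimmed", {
  g <- localGenome()
  clean <- readAt(g, 1001)
  res <- mapReadsIterative(asReads(c(r1 = clean)), g)
  expect_equal(res$mapped$start, 1001L)
  expect_equal(res$mapped$trims_applied, 0L)
  expect_equal(res$mapped$length, 100L)

  ## one corrupted low-quality 3' base: mapped after exactly 1 trim
  corrupt <- clean
  substr(corrupt, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                       substr(clean, 100, 100))[1]
  q <- paste0(strrep("I", 99), "#")
  res2 <- mapReadsIterative(asReads(c(r1 = corrupt), q), g)
  expect_equal(res2$mapped$start, 1001L)
  expect_equal(res2$mapped$trims_applied, 1L)
  expect_equal(res2$mapped$length, 99L)

  ## low-quality 5' base: the lower-quality end is the one trimmed
  corrupt5 <- clean
  substr(corrupt5, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                    substr(clean, 1, 1))[1]
  q5 <- paste0("#", strrep("I", 99))
  res3 <- mapReadsIterative(asReads(c(r1 = corrupt5), q5), g)
  expect_equal(res3$mapped$start, 1002L)
  expect_equal(res3$mapped$length, 99L)

  ## a 52-nt read needing 3 trims falls below 50 and is dropped
  seg <- readAt(g, 5001, 52L)
  bad <- seg
  for (k in 50:52)
    substr(bad, k, k) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seg, k, k))[1]
  qbad <- paste0(strrep("I", 49), "###")
  res4 <- mapReadsIterative(asReads(c(r1 = bad), qbad), g)
  expect_equal(nrow(res4$mapped), 0L)
  expect_equal(res4$summary$dropped, 1L)

  expect_error(mapReadsIterative(asReads("ACGT"),
                                 Biostrings::DNAStringSet()),
               "empty genome")
})

test_that("mapper agrees with a naive full-scan oracle on clean reads", {
  g <- localGenome(seed = 102)
  set.seed(7)
  starts <- sample.int(19900, 150)
  seqs <- vapply(starts, function(s) readAt(g, s), character(1))
  flip <- seq_along(seqs) %% 2 == 0
  seqs[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[flip])))
  reads <- asReads(stats::setNames(seqs, sprintf("r%03d",
                                                 seq_along(seqs))))
  res <- mapReadsIterative(reads, g)
  got <- res$mapped
  got$read <- match(got$read_id, names(reads))
  got <- got[order(got$read, got$start), c("read", "replicon", "start")]
  oracle <- naiveMapOracle(Biostrings::DNAStringSet(seqs), g)
  oracle <- oracle[order(oracle$read, oracle$start), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)))
  expect_true(all(res$mapped$trims_applied == 0L))
})

test_that("multi-mapping reads are placed at every matching locus", {
  g <- localGenome(seed = 103)
  gs <- as.character(g[[1]])
  substr(gs, 9001, 9100) <- substr(gs, 2001, 2100)
  g2 <- Biostrings::DNAStringSet(c(chr = gs))
  res <- mapReadsIterative(asReads(c(r1 = substr(gs, 2001, 2100))), g2)
  expect_equal(sort(res$mapped$start), c(2001L, 9001L))
  expect_equal(res$summary$multi_mapped, 1L)
})

test_that("coverage counts read spans and conserves bases", {
  g <- localGenome()
  one <- data.frame(read_id = "r1", replicon = "chr", start = 1L,
                    length = 100L, trims_applied = 0L)
  tr <- computeCoverage(one, g)
  expect_equal(as.numeric(trackDepth(tr)$chr[1:100]), rep(1, 100))
  expect_equal(sum(as.numeric(trackDepth(tr)$chr)), 100)

  two <- rbind(one, data.frame(read_id = "r2", replicon = "chr",
                               start = 51L, length = 100L,
                               trims_applied = 0L))
  tr2 <- computeCoverage(two, g)
  expect_equal(as.numeric(trackDepth(tr2)$chr[51:100]), rep(2, 50))
  expect_equal(sum(as.numeric(trackDepth(tr2)$chr)), 200)

  bad <- data.frame(read_id = "r", replicon = "chr", start = 19950L,
                    length = 100L, trims_applied = 0L)
  expect_error(computeCoverage(bad, g), "bounds")
})

test_that("coverage conservation holds on simulated samples", {
  study <- demoStudy()
  mp <- demoMapped()[["control_24h"]]
  tr <- computeCoverage(mp$mapped, studyGenome(study), "control_24h")
  expect_equal(sum(vapply(trackDepth(tr), function(d)
    sum(as.numeric(d)), numeric(1))),
    sum(mp$mapped$length))
})

test_that("structural-RNA masking excludes rRNA/tRNA from totals", {
  g <- localGenome()
  ann <- GenomicRanges::GRanges("chr",
                                IRanges::IRanges(c(501, 2001),
                                                 c(580, 3200)),
                                gene_id = c("trna1", "rrna1"),
                                feature_class = c("tRNA", "rRNA"))
  inTrna <- data.frame(read_id = "r1", replicon = "chr", start = 510L,
                       length = 60L, trims_applied = 0L)
  tr <- maskStructuralRna(computeCoverage(inTrna, g), ann)
  expect_equal(maskedTotal(tr), 0)

  ## no structural annotation: masking is the identity for totals
  cds <- ann; cds$feature_class <- "CDS"
  tr2 <- maskStructuralRna(computeCoverage(inTrna, g), cds)
  expect_equal(maskedTotal(tr2), 60)

  ## conservation: masked total = raw total - coverage inside masks
  mixed <- rbind(inTrna,
                 data.frame(read_id = "r2", replicon = "chr",
                            start = 10001L, length = 100L,
                            trims_applied = 0L))
  tr3 <- maskStructuralRna(computeCoverage(mixed, g), ann)
  expect_equal(maskedTotal(tr3), 160 - 60)
})

test_that("normalization hits the target exactly and is idempotent", {
  g <- localGenome()
  reads <- data.frame(read_id = sprintf("r%d", 1:5), replicon = "chr",
                      start = c(1L, 101L, 201L, 301L, 401L),
                      length = 100L, trims_applied = 0L)
  tr <- computeCoverage(reads, g)  # total 500
  norm <- normalizeToTotal(tr, 1000)
  expect_equal(scaleFactor(norm), 2)
  expect_true(isNormalized(norm))
  expect_equal(maskedTotal(norm), 1000)

  ## renormalizing is the identity
  norm2 <- normalizeToTotal(norm, 1000)
  expect_equal(scaleFactor(norm2), 1)
  expect_identical(as.numeric(trackDepth(norm2)$chr),
                   as.numeric(trackDepth(norm)$chr))

  ## a track whose total already equals the target is unchanged
  same <- normalizeToTotal(tr, 500)
  expect_equal(scaleFactor(same), 1)

  empty <- computeCoverage(reads[0, ], g)
  expect_error(normalizeToTotal(empty, 1000), "no usable coverage")
})

test_that("BedGraph round-trips a coverage track", {
  g <- localGenome()
  reads <- data.frame(read_id = sprintf("r%d", 1:3), replicon = "chr",
                      start = c(101L, 151L, 5001L), length = 100L,
                      trims_applied = 0L)
  tr <- computeCoverage(reads, g)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeBedGraph(tr, f)
  tr2 <- readBedGraph(f, c(chr = 20000L), sampleId = "s")
  expect_equal(as.numeric(trackDepth(tr2)$chr),
               as.numeric(trackDepth(tr)$chr))
})
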