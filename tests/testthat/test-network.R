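test_that("target filtering enforces rank and free-energy cutoffs", {
  preds <- data.frame(srna_id = "nc1",
                      gene_id = sprintf("g%03d", 1:150),
                      free_energy = rep(-15, 150),
                      rank = 1:150)
  kept <- filterTargets(preds)
  expect_equal(nrow(kept), 100L)
  expect_true(all(kept$rank <= 100))

  preds$free_energy[10] <- -9.5
  kept2 <- filterTargets(preds)
  expect_false("g010" %in% kept2$gene_id)
  ## exactly at the cutoff is kept (<= -10)
  preds$free_energy[11] <- -10
  expect_true("g011" %in% filterTargets(preds)$gene_id)

  expect_equal(nrow(filterTargets(preds[0, ])), 0L)
  expect_error(filterTargets(rbind(preds, preds[1, ])), "duplicate")
})

test_that("the correlation filter applies strict cutoffs and the
          Fisher z p value", {
  n <- 18
  set.seed(41)
  x <- rnorm(n)
  zx <- as.numeric(scale(x))
  ortho <- function() {
    v <- rnorm(n); as.numeric(scale(residuals(lm(v ~ zx))))
  }
  mkProfile <- function(r) r * zx + sqrt(1 - r^2) * ortho()
  samples <- sprintf("s%02d", 1:n)
  srnaExpr <- matrix(x, 1, n, dimnames = list("nc1", samples))
  tx <- rbind(g1 = mkProfile(0.4),    # |r| = 0.4 exactly: dropped
              g2 = 3 * x + 2,         # r = 1: kept, positive
              g3 = mkProfile(-0.9),   # kept, negative
              g4 = ortho(),           # r = 0: dropped
              g5 = rep(1, n))         # constant: dropped with warning
  colnames(tx) <- samples
  preds <- data.frame(srna_id = "nc1", gene_id = rownames(tx),
                      free_energy = -15, rank = 1:5)
  expect_warning(got <- correlationFilter(preds, srnaExpr, tx),
                 "constant")
  expect_setequal(got$gene_id, c("g2", "g3"))
  expect_identical(got$sign[got$gene_id == "g2"], "positive")
  expect_identical(got$sign[got$gene_id == "g3"], "negative")

  ## r = 0.9 on 4 samples: Fisher z gives p = 0.141 > 0.05, dropped
  s4 <- sprintf("t%d", 1:4)
  e4 <- matrix(c(1, 2, 3, 4), 1, dimnames = list("nc1", s4))
  zx4 <- as.numeric(scale(1:4))
  w0 <- as.numeric(scale(residuals(lm(c(1, -1, -1, 1) ~ zx4))))
  y <- 0.9 * zx4 + sqrt(1 - 0.81) * w0
  t4 <- matrix(y, 1, dimnames = list("gX", s4))
  expect_equal(cor(e4[1, ], y), 0.9, tolerance = 1e-12)
  p4 <- data.frame(srna_id = "nc1", gene_id = "gX", free_energy = -15,
                   rank = 1L)
  got4 <- correlationFilter(p4, e4, t4)
  expect_equal(nrow(got4), 0L)
  pExpected <- 2 * pnorm(-abs(atanh(0.9)) * sqrt(4 - 3))
  expect_gt(pExpected, 0.05)

  expect_error(correlationFilter(p4, e4[, 1:3, drop = FALSE],
                                 t4[, 1:3, drop = FALSE]),
               "shared samples")
})

test_that("hypergeometric P matches exhaustive enumeration on the full
          N <= 30 grid", {
  expect_equal(hypergeomP(20, 5, 5, 0), 1)
  expect_equal(hypergeomP(20, 5, 20, 5), 1)
  expect_equal(hypergeomP(20, 5, 5, 3), hyperOracle(20, 5, 5, 3),
               tolerance = 1e-12)

  maxDev <- 0
  for (N in c(1:10, 15, 20, 25, 30)) {
    for (M in 0:N) {
      for (n in 0:N) {
        for (m in 0:min(n, M)) {
          dev <- abs(hypergeomP(N, M, n, m) - hyperOracle(N, M, n, m))
          maxDev <- max(maxDev, dev)
        }
      }
    }
  }
  expect_lt(maxDev, 1e-12)

  ## P is nonincreasing in m at fixed (N, M, n)
  p <- hypergeomP(30, 10, 12, 0:10)
  expect_true(all(diff(p) <= 1e-15))

  expect_error(hypergeomP(10, 12, 5, 2), "M <= N")
  expect_error(hypergeomP(10, 5, 5, 6), "min")
})

test_that("pathway enrichment uses the annotated universe and the
          two-gene rule", {
  map <- data.frame(gene_id = sprintf("g%03d", 1:40),
                    pathway_id = rep(c("pwA", "pwB", "pwC", "pwD"),
                                     each = 10))
  ## 5 targets, 4 in pwA: strongly enriched
  got <- enrichPathways(c(sprintf("g%03d", 1:4), "g015"), map)
  expect_equal(got$pathway_id, "pwA")
  expect_equal(got[, c("N", "M", "n", "m")],
               data.frame(N = 40L, M = 10L, n = 5L, m = 4L),
               ignore_attr = TRUE)
  expect_equal(got$P, hyperOracle(40, 10, 5, 4), tolerance = 1e-12)

  ## a single-gene overlap is never reported, however small its P
  one <- enrichPathways("g001", map)
  expect_equal(nrow(one), 0L)

  ## unannotated targets reduce n but never m
  withExtra <- enrichPathways(c(sprintf("g%03d", 1:4), "g015",
                                "unannotated1", "unannotated2"), map)
  expect_equal(withExtra$n, 5L)
  expect_equal(withExtra$m, 4L)

  expect_error(enrichPathways("g001", map[0, ]), "universe")
})

test_that("planted enrichment is recovered and the filters block
          decoy routes", {
  nt <- simulateNetworkTruth(
    sprintf("nc%d", 1:6),
    enrichedPairs = data.frame(srna = c("nc1", "nc2"),
                               pathway = c("pw01", "pw07")),
    seed = 51)
  filt <- filterTargets(nt$predictions)
  expect_true(all(filt$free_energy <= -10))
  cors <- correlationFilter(filt, nt$srnaExpr, nt$transcriptome)
  net <- assembleNetwork(cors, nt$pathwayMap)
  e <- enrichmentTable(net)
  expect_true(any(e$srna_id == "nc1" & e$pathway_id == "pw01"))
  expect_true(any(e$srna_id == "nc2" & e$pathway_id == "pw07"))
  expect_true(all(e$m >= 2))

  ## an energy decoy aimed at the enriched pathway cannot contribute:
  ## plant two extra in-pathway predictions with dG > -10 and rank > 100
  unused <- setdiff(sprintf("g%04d", 1:240),
                    nt$predictions$gene_id[nt$predictions$srna_id ==
                                             "nc1"])[1:2]
  extra <- data.frame(srna_id = "nc1",
                      gene_id = unused,
                      free_energy = c(-9.5, -30),
                      rank = c(21L, 150L),
                      prediction_p = 0.01, target_strand = "+")
  preds2 <- rbind(nt$predictions, extra)
  filt2 <- filterTargets(preds2)
  expect_false(any(filt2$gene_id %in% extra$gene_id &
                     filt2$srna_id == "nc1"))
})

test_that("network assembly is bipartite with backed edges and
          deterministic ordering", {
  cors <- data.frame(
    srna_id = rep(c("nc1", "nc2", "nc3"), each = 2),
    gene_id = c("g1", "g2", "g1", "g2", "g1", "g2"),
    r = 0.9, p = 1e-6, sign = "positive")
  map <- data.frame(gene_id = c("g1", "g2", paste0("x", 1:20)),
                    pathway_id = c("pwA", "pwA", rep("pwB", 20)))
  net <- assembleNetwork(cors, map)
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g), nrow(enrichmentTable(net)))
  deg <- igraph::degree(g)
  expect_equal(unname(deg[igraph::V(g)$name == "pwA"]), 3)
  expect_true(igraph::is_bipartite(igraph::set_vertex_attr(
    g, "type", value = igraph::V(g)$type == "pathway")))
})

test_that("GraphML and SIF exports round-trip through the package
          reader", {
  cors <- data.frame(srna_id = rep("nc1", 3),
                     gene_id = c("g1", "g2", "g3"),
                     r = c(0.8, -0.7, 0.9), p = 1e-5,
                     sign = c("positive", "negative", "positive"))
  map <- data.frame(gene_id = c("g1", "g2", "g3", paste0("x", 1:30)),
                    pathway_id = c("pwA", "pwA", "pwA",
                                   rep("pwB", 30)))
  net <- assembleNetwork(cors, map)
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(net, gml, sif)
  back <- readNetworkGraphml(gml)
  g1 <- networkGraph(net); g2 <- networkGraph(back)
  expect_setequal(igraph::V(g2)$name, igraph::V(g1)$name)
  expect_identical(igraph::ecount(g2), igraph::ecount(g1))
  e1 <- enrichmentTable(net); e2 <- enrichmentTable(back)
  o1 <- order(e1$srna_id, e1$pathway_id)
  o2 <- order(e2$srna_id, e2$pathway_id)
  expect_equal(e2[o2, c("srna_id", "pathway_id", "m", "P", "sign")],
               e1[o1, c("srna_id", "pathway_id", "m", "P", "sign")],
               ignore_attr = TRUE)
  expect_equal(length(readLines(sif)), igraph::ecount(g1))

  ## empty network: valid, readable files
  empty <- assembleNetwork(cors[0, ], map)
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  sif0 <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(empty, gml0, sif0)
  back0 <- readNetworkGraphml(gml0)
  expect_equal(igraph::vcount(networkGraph(back0)), 0L)
  expect_length(readLines(sif0), 0L)
})
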