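## sRNA regulatory network: target-prediction filtering, expression
## correlation filter, hypergeometric pathway enrichment and bipartite
## graph assembly / export.

#' Filter ingested target predictions
#'
#' Retains, per sRNA, predictions with rank <= `maxRank` and
#' hybridization free energy <= `energyCutoff` (kcal/mol; more negative
#' is more favorable). Duplicate (sRNA, gene) rows are an error.
#'
#' @param predictions data.frame with columns `srna_id`, `gene_id`,
#'   `free_energy`, `rank` (ranks unique per sRNA).
#' @param maxRank Keep the top `maxRank` predictions per sRNA.
#' @param energyCutoff Free-energy cutoff (kcal/mol).
#' @return The filtered data.frame.
#' @export
filterTargets <- function(predictions, maxRank = 100L,
                          energyCutoff = -10) {
  need <- c("srna_id", "gene_id", "free_energy", "rank")
  assertThat(all(need %in% colnames(predictions)),
             "predictions need columns %s", paste(need, collapse = ", "))
  key <- paste(predictions$srna_id, predictions$gene_id)
  assertThat(!anyDuplicated(key), "duplicate (sRNA, gene) prediction rows")
  byS <- split(predictions$rank, predictions$srna_id)
  assertThat(!any(vapply(byS, anyDuplicated, integer(1)) > 0),
             "ranks must be unique per sRNA")
  predictions[predictions$rank <= maxRank &
                predictions$free_energy <= energyCutoff, , drop = FALSE]
}

#' Pearson correlation filter on paired expression profiles
#'
#' For each surviving prediction, computes the Pearson correlation of
#' the sRNA's expression profile with the target gene's transcriptome
#' profile over their shared samples, with a two-sided p value from the
#' Fisher z transform (z = atanh(r), se = 1/sqrt(n - 3)). Records with
#' |r| strictly above `rCut` and p strictly below `alpha` are kept;
#' both signs are retained since sRNA regulation can be activating as
#' well as repressive. Predictions whose sRNA or gene profile is
#' constant (correlation undefined) or absent are dropped with a
#' warning.
#'
#' @param predictions Filtered predictions ([filterTargets()]).
#' @param srnaExpr Matrix sRNA x sample.
#' @param transcriptome Matrix gene x sample.
#' @param rCut Correlation magnitude cutoff (strict).
#' @param alpha P-value cutoff (strict).
#' @return data.frame srna_id, gene_id, r, p, sign.
#' @export
correlationFilter <- function(predictions, srnaExpr, transcriptome,
                              rCut = 0.4, alpha = 0.05) {
  shared <- intersect(colnames(srnaExpr), colnames(transcriptome))
  assertThat(length(shared) >= 4L,
             "need at least 4 shared samples (have %d)", length(shared))
  n <- length(shared)
  recs <- vector("list", nrow(predictions))
  nBad <- 0L
  for (i in seq_len(nrow(predictions))) {
    sid <- predictions$srna_id[i]; gid <- predictions$gene_id[i]
    if (!(sid %in% rownames(srnaExpr)) ||
        !(gid %in% rownames(transcriptome))) { nBad <- nBad + 1L; next }
    x <- srnaExpr[sid, shared]; y <- transcriptome[gid, shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { nBad <- nBad + 1L; next }
    r <- stats::cor(x, y)
    z <- atanh(max(-1 + 1e-15, min(1 - 1e-15, r)))
    p <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
    recs[[i]] <- data.frame(srna_id = sid, gene_id = gid, r = r, p = p,
                            sign = if (r > 0) "positive" else "negative")
  }
  if (nBad > 0L)
    warning(nBad, " prediction(s) dropped: missing or constant profile")
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(srna_id = character(), gene_id = character(),
               r = numeric(), p = numeric(), sign = character())
  out[abs(out$r) > rCut & out$p < alpha, , drop = FALSE]
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n): the probability
#' of drawing at least m pathway members among n draws without
#' replacement from a universe of N genes of which M are in the pathway.
#' Computed on the log scale (vectorized over `m`).
#'
#' @param N Universe size (genes with pathway annotation).
#' @param M Pathway size within the universe.
#' @param n Number of draws (annotated targets of the sRNA).
#' @param m Observed overlap.
#' @return Probability in [0, 1].
#' @export
hypergeomP <- function(N, M, n, m) {
  assertThat(all(M >= 0 & M <= N) && all(n >= 0 & n <= N),
             "require 0 <= M <= N and 0 <= n <= N")
  assertThat(all(m >= 0 & m <= pmin(n, M)),
             "require 0 <= m <= min(n, M)")
  ifelse(m == 0, 1,
         stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE))
}

#' Hypergeometric pathway enrichment for one sRNA's targets
#'
#' The universe N is the set of genes carrying any pathway annotation;
#' n counts the sRNA's surviving targets inside that universe
#' (unannotated targets reduce neither M nor m, only fall out of n).
#' For each pathway, M and the overlap m are computed and P from
#' [hypergeomP()]; pathways with at least `minGenes` target genes and
#' P < `alpha` are reported (set `reportAll = TRUE` to keep every
#' pathway with m >= 1 for inspection).
#'
#' @param targets Character vector of target gene ids (one sRNA).
#' @param pathwayMap data.frame gene_id, pathway_id.
#' @param minGenes Minimum overlap m (default 2).
#' @param alpha P cutoff (strict).
#' @param reportAll Disable the m/P reporting filter.
#' @return data.frame pathway_id, N, M, n, m, P.
#' @export
enrichPathways <- function(targets, pathwayMap, minGenes = 2L,
                           alpha = 0.05, reportAll = FALSE) {
  assertThat(nrow(pathwayMap) > 0L, "empty pathway universe")
  universe <- unique(pathwayMap$gene_id)
  N <- length(universe)
  tIn <- unique(intersect(targets, universe))
  n <- length(tIn)
  pws <- unique(pathwayMap$pathway_id)
  M <- vapply(pws, function(pw)
    length(unique(pathwayMap$gene_id[pathwayMap$pathway_id == pw])),
    integer(1))
  m <- vapply(pws, function(pw)
    length(intersect(tIn, pathwayMap$gene_id[pathwayMap$pathway_id == pw])),
    integer(1))
  P <- hypergeomP(N, M, n, m)
  df <- data.frame(pathway_id = pws, N = N, M = M, n = n, m = m, P = P,
                   row.names = NULL)
  if (reportAll) df[df$m >= 1L, , drop = FALSE]
  else df[df$m >= minGenes & df$P < alpha, , drop = FALSE]
}

#' Assemble the bipartite sRNA-pathway regulatory network
#'
#' Runs [enrichPathways()] per sRNA on correlation-passing targets and
#' assembles one bipartite graph: sRNA and pathway nodes, one edge per
#' significantly enriched (sRNA, pathway) pair carrying P, the overlap
#' m, and the dominant correlation sign among the supporting targets.
#' Node ordering is deterministic (sorted ids).
#'
#' @param correlations data.frame from [correlationFilter()].
#' @param pathwayMap data.frame gene_id, pathway_id.
#' @param minGenes,alpha Enrichment thresholds.
#' @return A [RegulatoryNetwork-class].
#' @export
assembleNetwork <- function(correlations, pathwayMap, minGenes = 2L,
                            alpha = 0.05) {
  edges <- list()
  for (sid in sort(unique(correlations$srna_id))) {
    sub <- correlations[correlations$srna_id == sid, , drop = FALSE]
    enr <- enrichPathways(sub$gene_id, pathwayMap, minGenes, alpha)
    if (nrow(enr) == 0L) next
    for (k in seq_len(nrow(enr))) {
      pw <- enr$pathway_id[k]
      supp <- sub[sub$gene_id %in%
                    pathwayMap$gene_id[pathwayMap$pathway_id == pw], ]
      domSign <- if (sum(supp$sign == "positive") >=
                     sum(supp$sign == "negative")) "positive" else
                       "negative"
      edges[[length(edges) + 1L]] <- data.frame(
        srna_id = sid, pathway_id = pw, N = enr$N[k], M = enr$M[k],
        n = enr$n[k], m = enr$m[k], P = enr$P[k], sign = domSign)
    }
  }
  enrichment <- if (length(edges)) do.call(rbind, edges) else
    data.frame(srna_id = character(), pathway_id = character(),
               N = integer(), M = integer(), n = integer(),
               m = integer(), P = numeric(), sign = character())
  sNodes <- sort(unique(enrichment$srna_id))
  pNodes <- sort(unique(enrichment$pathway_id))
  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(sNodes) + length(pNodes) > 0) {
    g <- igraph::add_vertices(g, length(sNodes) + length(pNodes),
                              name = c(sNodes, pNodes),
                              type = c(rep("sRNA", length(sNodes)),
                                       rep("pathway", length(pNodes))))
    if (nrow(enrichment) > 0) {
      ep <- rbind(match(enrichment$srna_id, c(sNodes, pNodes)),
                  match(enrichment$pathway_id, c(sNodes, pNodes)))
      g <- igraph::add_edges(g, as.vector(ep),
                             P = enrichment$P, m = enrichment$m,
                             sign = enrichment$sign)
    }
  } else {
    ## empty graph still needs the attribute schema for round-trips
    g <- igraph::set_vertex_attr(g, "name", value = character())
    g <- igraph::set_vertex_attr(g, "type", value = character())
  }
  new("RegulatoryNetwork", graph = g, enrichment = enrichment)
}

#' Export / import a regulatory network
#'
#' Writes GraphML (all vertex/edge attributes preserved) and optionally
#' SIF (topology only, one `srna interacts pathway` line per edge).
#' `readNetworkGraphml()` restores a [RegulatoryNetwork-class] whose
#' graph round-trips losslessly.
#'
#' @param network A [RegulatoryNetwork-class].
#' @param graphmlPath GraphML output path.
#' @param sifPath Optional SIF output path.
#' @return Invisibly the GraphML path.
#' @export
exportNetwork <- function(network, graphmlPath, sifPath = NULL) {
  igraph::write_graph(network@graph, graphmlPath, format = "graphml")
  if (!is.null(sifPath)) {
    e <- network@enrichment
    lines <- if (nrow(e)) sprintf("%s\tinteracts\t%s", e$srna_id,
                                  e$pathway_id) else character()
    writeLines(lines, sifPath)
  }
  invisible(graphmlPath)
}

#' @rdname exportNetwork
#' @param path GraphML path written by [exportNetwork()].
#' @export
readNetworkGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  enrichment <- if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    vt <- igraph::V(g)$type
    names(vt) <- igraph::V(g)$name
    flip <- vt[el[, 1]] == "pathway"
    data.frame(srna_id = ifelse(flip, el[, 2], el[, 1]),
               pathway_id = ifelse(flip, el[, 1], el[, 2]),
               N = NA_integer_, M = NA_integer_, n = NA_integer_,
               m = igraph::E(g)$m, P = igraph::E(g)$P,
               sign = igraph::E(g)$sign)
  } else data.frame(srna_id = character(), pathway_id = character(),
                    N = integer(), M = integer(), n = integer(),
                    m = integer(), P = numeric(), sign = character())
  new("RegulatoryNetwork", graph = g, enrichment = enrichment)
}
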