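## Multi-tier sRNA calling from normalized coverage: threshold
## segmentation, reference-guided rescue of low-expression candidates,
## cross-sample support, merging, boundary refinement, location-based
## classification and repeat-region flagging.

#' Default detection parameters
#'
#' The calling thresholds: 50x normalized depth, 50 bp minimum length,
#' detection in at least 3 of the 18 samples, a 50 bp merge gap, UTR
#' windows of 100 nt upstream / 50 nt downstream, and a 50 bp rescue
#' flank with a 2-fold inside/flank depth ratio.
#'
#' @param ... Overrides of individual parameters.
#' @return Named list of parameters.
#' @export
detectionParams <- function(...) {
  p <- list(depthThreshold = 50, minLength = 50L, minSupport = 3L,
            mergeGap = 50L, utrUpstream = 100L, utrDownstream = 50L,
            rescueFlank = 50L, rescueRatio = 2, jaccard = 0.5,
            refineWindow = 20L, trendRule = "pearson",
            repeatIdentity = 0.8, repeatMinLen = 50L, repeatK = 20L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  assertThat(length(unknown) == 0L, "unknown detection parameter(s): %s",
             paste(unknown, collapse = ", "))
  p <- utils::modifyList(p, over)
  assertThat(all(vapply(p[c("depthThreshold", "minLength", "minSupport",
                            "mergeGap", "utrUpstream", "utrDownstream",
                            "rescueFlank", "rescueRatio")],
                        function(v) is.numeric(v) && v > 0, logical(1))),
             "detection parameters must be positive")
  p
}

#' Segment high-expression regions of a coverage track
#'
#' Emits the maximal runs of consecutive positions whose normalized depth
#' strictly exceeds the threshold. Runs shorter than the minimum sRNA
#' length are *not* discarded here; that happens at the final filtering
#' step of [callSrnas()] so that short fragments can still contribute to
#' merging.
#'
#' @param track A normalized [CoverageTrack-class].
#' @param threshold Depth threshold (default 50x).
#' @return GRanges of raw candidate intervals.
#' @export
segmentHighExpression <- function(track, threshold = 50) {
  out <- list()
  for (rep in names(track@depth)) {
    v <- slice(track@depth[[rep]], lower = threshold,
               includeLower = FALSE)
    ir <- methods::as(v, "IRanges")
    if (length(ir))
      out[[length(out) + 1L]] <- GRanges(
        factor(rep(rep, length(ir)), levels = names(track@depth)), ir)
  }
  if (length(out) == 0L) return(GRanges())
  do.call(c, out)
}

#' Rescue low-expression candidates at reference loci
#'
#' Low-transcribed sRNAs that never cross the depth threshold are
#' recovered at previously reported loci: a reference interval is
#' retained iff its mean inside depth is positive and at least
#' `ratio`-fold above the mean depth of *each* flanking window.
#'
#' @param track A normalized [CoverageTrack-class].
#' @param references GRanges of reference sRNA loci.
#' @param flank Flank width (bp).
#' @param ratio Required inside/flank mean-depth ratio.
#' @return The retained subset of `references`.
#' @export
rescueLowExpression <- function(track, references, flank = 50L,
                                ratio = 2) {
  if (length(references) == 0L) return(references)
  keep <- logical(length(references))
  for (i in seq_along(references)) {
    rep <- as.character(seqnames(references)[i])
    assertThat(rep %in% names(track@depth),
               "reference on unknown replicon '%s'", rep)
    d <- track@depth[[rep]]
    s <- start(references)[i]; e <- end(references)[i]
    assertThat(s >= 1L && e <= length(d),
               "reference interval outside replicon bounds")
    inside <- mean(as.numeric(d[s:e]))
    lf <- if (s > 1L) mean(as.numeric(d[max(1L, s - flank):(s - 1L)])) else 0
    rf <- if (e < length(d))
      mean(as.numeric(d[(e + 1L):min(length(d), e + flank)])) else 0
    keep[i] <- inside > 0 && inside >= ratio * lf && inside >= ratio * rf
  }
  references[keep]
}

## Jaccard overlap of two integer intervals on the same replicon.
intervalJaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / union
}

#' Cluster per-sample detections and retain cross-sample-supported
#' candidates
#'
#' Pools detections from all samples, clusters them by overlap, forms a
#' consensus interval per cluster as the position-wise median of member
#' starts and ends, and counts a sample as "observing" the cluster when
#' one of its detections has Jaccard overlap >= `jaccard` with the
#' consensus. Clusters observed in at least `minSupport` samples survive.
#'
#' @param perSample Named list of GRanges, one element per sample.
#' @param minSupport Minimum number of supporting samples.
#' @param jaccard Jaccard threshold defining "observed in" a sample.
#' @return GRanges of consensus candidates with a `support` column.
#' @export
retainBySupport <- function(perSample, minSupport = 3L, jaccard = 0.5) {
  assertThat(length(perSample) >= 1L, "at least one sample required")
  if (is.null(names(perSample)))
    names(perSample) <- sprintf("sample%02d", seq_along(perSample))
  nonEmpty <- perSample[vapply(perSample, length, integer(1)) > 0L]
  if (length(nonEmpty) == 0L)
    return(GRanges(support = integer()))
  pool <- do.call(c, lapply(names(nonEmpty), function(s) {
    gr <- nonEmpty[[s]]
    mcols(gr) <- DataFrame(sample = rep(s, length(gr)))
    gr
  }))
  clusters <- reduce(pool, ignore.strand = TRUE)
  hits <- findOverlaps(pool, clusters, ignore.strand = TRUE)
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    mem <- pool[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == ci]]
    cs <- as.integer(round(stats::median(start(mem))))
    ce <- as.integer(round(stats::median(end(mem))))
    obs <- vapply(split(mem, mem$sample), function(m) {
      any(vapply(seq_along(m), function(k)
        intervalJaccard(start(m)[k], end(m)[k], cs, ce) >= jaccard,
        logical(1)))
    }, logical(1))
    support <- sum(obs)
    if (support >= minSupport)
      out[[ci]] <- GRanges(seqnames(clusters)[ci], IRanges(cs, ce),
                           support = support)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(GRanges(support = integer()))
  sort(do.call(c, out), ignore.strand = TRUE)
}

## Shared-trend check used by mergeAdjacent.
sameTrend <- function(x, y, rule = c("pearson", "sign")) {
  rule <- match.arg(rule)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(FALSE)
  if (rule == "pearson") {
    r <- suppressWarnings(stats::cor(x, y))
    !is.na(r) && r > 0
  } else {
    mean(sign(x - mean(x)) == sign(y - mean(y))) > 0.5
  }
}

#' Merge adjacent candidates with a shared expression trend
#'
#' Two candidates on the same replicon separated by a gap shorter than
#' `mergeGap` whose per-sample expression vectors share a trend
#' (positive Pearson correlation by default, or majority sign
#' concordance) are replaced by their union; the rule is applied
#' iteratively to a fixpoint. The merged candidate's expression is the
#' length-weighted mean of its parts and its support the maximum of
#' theirs.
#'
#' @param candidates GRanges with a `support` column, sorted.
#' @param expression Numeric matrix, one row per candidate, columns =
#'   samples (per-sample mean depth).
#' @param mergeGap Maximum gap (bp, exclusive) allowing a merge.
#' @param trendRule `"pearson"` or `"sign"`.
#' @return List with merged `candidates` (GRanges) and `expression`
#'   (matrix, rows matching).
#' @export
mergeAdjacent <- function(candidates, expression, mergeGap = 50L,
                          trendRule = "pearson") {
  if (length(candidates) <= 1L)
    return(list(candidates = candidates, expression = expression))
  ord <- order(as.character(seqnames(candidates)), start(candidates))
  candidates <- candidates[ord]
  expression <- expression[ord, , drop = FALSE]
  repeat {
    mergedAny <- FALSE
    i <- 1L
    while (i < length(candidates)) {
      sameRep <- as.character(seqnames(candidates)[i]) ==
        as.character(seqnames(candidates)[i + 1L])
      gap <- start(candidates)[i + 1L] - end(candidates)[i] - 1L
      if (sameRep && gap < mergeGap && gap >= 0L &&
          sameTrend(expression[i, ], expression[i + 1L, ], trendRule)) {
        w1 <- width(candidates)[i]; w2 <- width(candidates)[i + 1L]
        newGr <- GRanges(seqnames(candidates)[i],
                         IRanges(start(candidates)[i],
                                 end(candidates)[i + 1L]),
                         support = max(candidates$support[i],
                                       candidates$support[i + 1L]))
        newExpr <- (expression[i, ] * w1 + expression[i + 1L, ] * w2) /
          (w1 + w2)
        keep <- setdiff(seq_along(candidates), c(i, i + 1L))
        candidates <- c(candidates[keep], newGr)
        expression <- rbind(expression[keep, , drop = FALSE], newExpr)
        ord <- order(as.character(seqnames(candidates)),
                     start(candidates))
        candidates <- candidates[ord]
        expression <- expression[ord, , drop = FALSE]
        mergedAny <- TRUE
      } else i <- i + 1L
    }
    if (!mergedAny) break
  }
  rownames(expression) <- NULL
  list(candidates = candidates, expression = expression)
}

#' Refine candidate boundaries to the point of maximum coverage decline
#'
#' Each boundary moves, within a +/- `window` nt search range, to the
#' position of the maximum single-step depth change: for the 3' side the
#' largest drop depth[i] - depth[i+1], mirrored for the 5' side. Ties
#' are broken toward the unrefined boundary (then toward the smaller
#' coordinate), so a flat plateau leaves boundaries unchanged.
#'
#' @param candidates GRanges.
#' @param track A [CoverageTrack-class] (typically the across-sample
#'   mean of normalized tracks).
#' @param window Search half-width in nt.
#' @return GRanges with adjusted starts/ends (metadata preserved).
#' @export
refineBoundaries <- function(candidates, track, window = 20L) {
  if (length(candidates) == 0L) return(candidates)
  newStart <- start(candidates)
  newEnd <- end(candidates)
  for (i in seq_along(candidates)) {
    rep <- as.character(seqnames(candidates)[i])
    d <- track@depth[[rep]]
    n <- length(d)
    s <- start(candidates)[i]; e <- end(candidates)[i]
    ## 5' boundary: maximize rise depth[p] - depth[p-1]
    lo <- max(2L, s - window); hi <- min(n, s + window)
    if (lo <= hi) {
      seg <- as.numeric(d[(lo - 1L):hi])
      rise <- diff(seg)  # rise[k] corresponds to position lo + k - 1
      pos <- lo + seq_along(rise) - 1L
      best <- pos[order(-rise, abs(pos - s), pos)][1L]
      if (rise[match(best, pos)] > 0) newStart[i] <- best
    }
    ## 3' boundary: maximize drop depth[p] - depth[p+1]
    lo <- max(1L, e - window); hi <- min(n - 1L, e + window)
    if (lo <= hi) {
      seg <- as.numeric(d[lo:(hi + 1L)])
      drop <- -diff(seg)  # drop[k] at position lo + k - 1
      pos <- lo + seq_along(drop) - 1L
      best <- pos[order(-drop, abs(pos - e), pos)][1L]
      if (drop[match(best, pos)] > 0) newEnd[i] <- best
    }
    if (newStart[i] > newEnd[i]) {  # degenerate refinement: keep original
      newStart[i] <- s; newEnd[i] <- e
    }
  }
  out <- GRanges(seqnames(candidates), IRanges(newStart, newEnd))
  mcols(out) <- mcols(candidates)
  out
}

#' Classify candidates by genomic location
#'
#' Category precedence: a candidate overlapping any gene body is an
#' asRNA (the library being unstranded, "antisense" means gene-body
#' overlap on either strand); otherwise overlap with a gene's
#' 100-nt-upstream or 50-nt-downstream window (strand-aware placement)
#' makes it a UTR candidate; everything else is an intergenic ncRNA.
#' Ties among genes are broken by largest overlap.
#'
#' @param candidates GRanges.
#' @param annotation Annotation GRanges (`gene_id`, `feature_class`).
#' @param utrUpstream,utrDownstream UTR window widths (nt).
#' @return `candidates` with added columns `category` and
#'   `assoc_gene` (the gene defining the category, NA for ncRNA).
#' @export
classifyByLocation <- function(candidates, annotation,
                               utrUpstream = 100L, utrDownstream = 50L) {
  if (length(candidates) == 0L) {
    mcols(candidates)$category <- character()
    mcols(candidates)$assoc_gene <- character()
    return(candidates)
  }
  windows <- utrWindows(annotation, utrUpstream, utrDownstream)
  category <- rep("ncRNA", length(candidates))
  assoc <- rep(NA_character_, length(candidates))
  bodyHits <- findOverlaps(candidates, annotation, ignore.strand = TRUE)
  winHits <- findOverlaps(candidates, windows, ignore.strand = TRUE)
  pickLargest <- function(i, hits, subject) {
    js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    ov <- width(pintersect(rep(candidates[i], length(js)), subject[js],
                           ignore.strand = TRUE))
    js[order(-ov, js)][1L]
  }
  for (i in seq_along(candidates)) {
    if (i %in% S4Vectors::queryHits(bodyHits)) {
      j <- pickLargest(i, bodyHits, annotation)
      category[i] <- "asRNA"
      assoc[i] <- annotation$gene_id[j]
    } else if (i %in% S4Vectors::queryHits(winHits)) {
      j <- pickLargest(i, winHits, windows)
      category[i] <- "UTR"
      assoc[i] <- windows$gene_id[j]
    }
  }
  mcols(candidates)$category <- category
  mcols(candidates)$assoc_gene <- assoc
  candidates
}

## Ungapped seed extension: compare two aligned character vectors
## starting from a perfect seed [seedLo, seedHi] (indices into the
## vectors), extending while the running score (+1 match, -2 mismatch)
## stays within xdrop of its maximum. Returns c(length, identity).
extendSeed <- function(a, b, seedLo, seedHi, xdrop = 6) {
  stopifnot(length(a) == length(b))
  extend <- function(idx) {
    score <- 0; best <- 0; bestK <- 0L; k <- 0L
    for (p in idx) {
      k <- k + 1L
      score <- score + if (a[p] == b[p]) 1 else -2
      if (score > best) { best <- score; bestK <- k }
      if (best - score > xdrop) break
    }
    bestK
  }
  nR <- if (seedHi < length(a)) extend((seedHi + 1L):length(a)) else 0L
  nL <- if (seedLo > 1L) extend((seedLo - 1L):1L) else 0L
  lo <- seedLo - nL; hi <- seedHi + nR
  len <- hi - lo + 1L
  c(length = len, identity = mean(a[lo:hi] == b[lo:hi]))
}

#' Flag candidates lying in repeat regions
#'
#' A candidate is flagged when its sequence has a second site elsewhere
#' in the genome (either strand) aligning over more than `minLen` bp at
#' more than `minIdentity` identity. Second sites are found by exact
#' k-mer seeding (k = 20) followed by ungapped X-drop extension, the
#' desk-scale analogue of a BLAST-style repeat screen.
#'
#' @param candidates GRanges.
#' @param genome A [Biostrings::DNAStringSet].
#' @param minIdentity Identity threshold (fraction, exclusive).
#' @param minLen Alignment length threshold (bp, exclusive).
#' @param k Seed length.
#' @return `candidates` with a logical `repeat_flag` column.
#' @export
flagRepeats <- function(candidates, genome, minIdentity = 0.8,
                        minLen = 50L, k = 20L) {
  flags <- logical(length(candidates))
  genomeChars <- lapply(seq_along(genome), function(i)
    strsplit(as.character(genome[[i]]), "")[[1]])
  names(genomeChars) <- names(genome)
  for (ci in seq_along(candidates)) {
    rep0 <- as.character(seqnames(candidates)[ci])
    s0 <- start(candidates)[ci]; e0 <- end(candidates)[ci]
    L <- e0 - s0 + 1L
    if (L < k) next
    candSeq <- subseq(genome[[rep0]], s0, e0)
    for (orient in c("fwd", "rev")) {
      qseq <- if (orient == "fwd") candSeq else
        reverseComplement(candSeq)
      qchars <- strsplit(as.character(qseq), "")[[1]]
      offs <- unique(c(seq(1L, L - k + 1L, by = max(1L, k %/% 2L)),
                       L - k + 1L))
      kmers <- DNAStringSet(vapply(offs, function(o)
        as.character(subseq(qseq, o, o + k - 1L)), character(1)))
      pd <- PDict(kmers)
      for (rep in names(genome)) {
        m <- matchPDict(pd, genome[[rep]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0L) next
        seedIdx <- rep.int(seq_along(nh), nh)
        seedStart <- unlist(IRanges::start(m), use.names = FALSE)
        seen <- integer()
        for (h in seq_along(seedIdx)) {
          o <- offs[seedIdx[h]]
          aStart <- seedStart[h] - (o - 1L)  # implied alignment start
          ## skip the candidate's own locus (fwd orientation, overlap)
          if (orient == "fwd" && rep == rep0 &&
              aStart < e0 && (aStart + L - 1L) > s0) next
          if (aStart %in% seen) next
          seen <- c(seen, aStart)
          gLo <- max(1L, aStart)
          gHi <- min(length(genomeChars[[rep]]), aStart + L - 1L)
          qLo <- gLo - aStart + 1L
          qHi <- gHi - aStart + 1L
          aChars <- qchars[qLo:qHi]
          bChars <- genomeChars[[rep]][gLo:gHi]
          seedLo <- o - qLo + 1L
          res <- extendSeed(aChars, bChars, max(1L, seedLo),
                            min(length(aChars), seedLo + k - 1L))
          if (res["length"] > minLen && res["identity"] > minIdentity) {
            flags[ci] <- TRUE
            break
          }
        }
        if (flags[ci]) break
      }
      if (flags[ci]) break
    }
  }
  mcols(candidates)$repeat_flag <- flags
  candidates
}

#' Attach externally computed annotation labels to called sRNAs
#'
#' Ingests tabular outputs of external annotation tools (protein-database
#' hits, non-coding RNA family assignments, ORF, ribosome-binding-site
#' and terminator predictions) keyed by sRNA id. Database hits with
#' E-value >= 1e-10 are ignored; rows naming unknown sRNAs warn and are
#' skipped; tables lacking the required columns are an error.
#'
#' @param candidates GRanges with an `srna_id` column.
#' @param tables Named list with any of `nr`, `rfam` (columns srna_id,
#'   label, evalue), `orf`, `rbs`, `terminator` (columns srna_id, label).
#' @param evalueCutoff E-value cutoff for database hits.
#' @return `candidates` with one character column per supplied table
#'   (NA where no label).
#' @export
ingestExternalAnnotations <- function(candidates, tables = list(),
                                      evalueCutoff = 1e-10) {
  known <- c("nr", "rfam", "orf", "rbs", "terminator")
  unknown <- setdiff(names(tables), known)
  assertThat(length(unknown) == 0L, "unknown annotation table(s): %s",
             paste(unknown, collapse = ", "))
  ids <- mcols(candidates)$srna_id
  assertThat(!is.null(ids), "candidates must carry an 'srna_id' column")
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    need <- if (nm %in% c("nr", "rfam")) c("srna_id", "label", "evalue")
      else c("srna_id", "label")
    assertThat(is.data.frame(tab) && all(need %in% colnames(tab)),
               "malformed '%s' table: need columns %s", nm,
               paste(need, collapse = ", "))
    if (nm %in% c("nr", "rfam"))
      tab <- tab[tab$evalue < evalueCutoff, , drop = FALSE]
    bad <- !(tab$srna_id %in% ids)
    if (any(bad)) {
      warning("skipping ", sum(bad), " '", nm,
              "' row(s) with unknown sRNA id")
      tab <- tab[!bad, , drop = FALSE]
    }
    lab <- vapply(ids, function(id) {
      v <- tab$label[tab$srna_id == id]
      if (length(v)) paste(v, collapse = ",") else NA_character_
    }, character(1))
    mcols(candidates)[[paste0(nm, "_label")]] <- unname(lab)
  }
  candidates
}

## Across-sample mean of a list of tracks (element-wise on depths).
meanTrack <- function(tracks) {
  reps <- names(tracks[[1]]@depth)
  depth <- lapply(reps, function(rep) {
    acc <- tracks[[1]]@depth[[rep]]
    if (length(tracks) > 1L)
      for (t in tracks[-1]) acc <- acc + t@depth[[rep]]
    acc / length(tracks)
  })
  names(depth) <- reps
  CoverageTrack(depth = methods::as(depth, "RleList"),
                sampleId = "mean", normalized = TRUE)
}

## Mean depth of each range on one track (vectorized via Views).
rangeMeans <- function(track, gr) {
  out <- numeric(length(gr))
  for (rep in unique(as.character(seqnames(gr)))) {
    sel <- as.character(seqnames(gr)) == rep
    v <- Views(track@depth[[rep]], start = start(gr)[sel],
               end = end(gr)[sel])
    out[sel] <- IRanges::viewMeans(v)
  }
  out
}

#' Call sRNAs across a set of normalized coverage tracks
#'
#' The full multi-tier caller: per-sample threshold segmentation (plus
#' optional reference-guided rescue), cross-sample support clustering,
#' trend-aware merging of adjacent candidates, boundary refinement on
#' the across-sample mean track, minimum-length filtering,
#' location-based classification, id assignment (nc/as/U prefix by
#' category, serial by position) and repeat flagging.
#'
#' @param tracks Named list of normalized [CoverageTrack-class] objects
#'   (names = sample ids).
#' @param annotation Annotation GRanges.
#' @param genome Genome [Biostrings::DNAStringSet] (for repeat flagging;
#'   `NULL` skips the repeat screen).
#' @param params Parameters from [detectionParams()].
#' @param references Optional GRanges of previously reported loci for
#'   the low-expression rescue tier.
#' @return GRanges of called sRNAs with columns `srna_id`, `category`,
#'   `assoc_gene`, `support`, `repeat_flag`.
#' @export
callSrnas <- function(tracks, annotation, genome = NULL,
                      params = detectionParams(), references = NULL) {
  assertThat(length(tracks) >= 1L, "at least one track required")
  perSample <- lapply(tracks, function(tr) {
    seg <- segmentHighExpression(tr, params$depthThreshold)
    if (!is.null(references) && length(references)) {
      resc <- rescueLowExpression(tr, references, params$rescueFlank,
                                  params$rescueRatio)
      mcols(resc) <- NULL
      seg <- reduce(c(seg, resc), ignore.strand = TRUE)
    }
    seg
  })
  cand <- retainBySupport(perSample, params$minSupport, params$jaccard)
  if (length(cand) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(srna_id = character(), category = character(),
                            assoc_gene = character(), support = integer(),
                            repeat_flag = logical())
    return(out)
  }
  expr <- vapply(tracks, function(tr) rangeMeans(tr, cand),
                 numeric(length(cand)))
  expr <- matrix(expr, nrow = length(cand),
                 dimnames = list(NULL, names(tracks)))
  m <- mergeAdjacent(cand, expr, params$mergeGap, params$trendRule)
  avg <- meanTrack(tracks)
  refined <- refineBoundaries(m$candidates, avg, params$refineWindow)
  keep <- width(refined) >= params$minLength &
    refined$support >= params$minSupport
  refined <- refined[keep]
  refined <- classifyByLocation(refined, annotation,
                                params$utrUpstream, params$utrDownstream)
  ## category-prefixed serial ids in genomic order
  prefix <- c(ncRNA = "nc", asRNA = "as", UTR = "U")[refined$category]
  serial <- stats::ave(seq_along(refined), refined$category,
                       FUN = seq_along)
  mcols(refined)$srna_id <- paste0(prefix, serial)
  if (!is.null(genome))
    refined <- flagRepeats(refined, genome, params$repeatIdentity,
                           params$repeatMinLen, params$repeatK)
  else mcols(refined)$repeat_flag <- NA
  mcols(refined) <- mcols(refined)[, c("srna_id", "category",
                                       "assoc_gene", "support",
                                       "repeat_flag")]
  refined
}

#' Export called sRNAs as GFF3 and a summary table
#'
#' The GFF3 uses types `ncRNA`, `antisense_RNA` and `UTR` with support
#' and repeat-flag attributes. The table mirrors a catalogue layout:
#' id, location, length, category, support, repeat flag, associated and
#' flanking genes with distances.
#'
#' @param srnas GRanges from [callSrnas()].
#' @param annotation Annotation GRanges (for flanking genes).
#' @param gffPath,tsvPath Output paths (NULL to skip either).
#' @return Invisibly, the summary data.frame.
#' @export
exportSrnas <- function(srnas, annotation, gffPath = NULL,
                        tsvPath = NULL) {
  typeMap <- c(ncRNA = "ncRNA", asRNA = "antisense_RNA", UTR = "UTR")
  left <- GenomicRanges::follow(srnas, annotation, ignore.strand = TRUE)
  right <- GenomicRanges::precede(srnas, annotation, ignore.strand = TRUE)
  df <- data.frame(
    srna_id = srnas$srna_id,
    replicon = as.character(seqnames(srnas)),
    start = start(srnas), end = end(srnas), length = width(srnas),
    category = srnas$category, support = srnas$support,
    repeat_flag = srnas$repeat_flag,
    assoc_gene = srnas$assoc_gene,
    left_gene = ifelse(is.na(left), NA, annotation$gene_id[left]),
    left_dist = ifelse(is.na(left), NA,
                       start(srnas) - end(annotation)[left] - 1L),
    right_gene = ifelse(is.na(right), NA, annotation$gene_id[right]),
    right_dist = ifelse(is.na(right), NA,
                        start(annotation)[right] - end(srnas) - 1L))
  if (!is.null(gffPath)) {
    gr <- srnas
    mcols(gr) <- DataFrame(source = "sRNAseeker",
                           type = typeMap[srnas$category],
                           ID = srnas$srna_id,
                           support = srnas$support,
                           repeat_flag = srnas$repeat_flag)
    rtracklayer::export(gr, gffPath, format = "gff3")
  }
  if (!is.null(tsvPath))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(df)
}
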