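## Synthetic study generator.
##
## Emulates a multi-replicon cyanobacterial genome with annotated
## CDS/rRNA/tRNA records, planted intergenic (ncRNA), antisense (asRNA)
## and UTR-associated sRNAs whose expression depends on the growth
## condition, unstranded short-read data with low-quality terminal
## bases, negative-binomial count fixtures, and target-prediction /
## pathway-map / paired-transcriptome tables with known enrichment truth.

STUDY_CONDITIONS <- c("control", "ethanol", "butanol", "hexane",
                      "salt", "Nstarve")
STUDY_TIMEPOINTS <- c(24L, 48L, 72L)

#' The 18-sample study design
#'
#' Six growth conditions (control plus five stress treatments) sampled at
#' three time points (24, 48 and 72 h), one library each.
#'
#' @return data.frame with columns `sample_id`, `condition`, `timepoint`.
#' @export
studyDesign <- function() {
  d <- expand.grid(timepoint = STUDY_TIMEPOINTS,
                   condition = STUDY_CONDITIONS,
                   stringsAsFactors = FALSE)[, 2:1]
  d$condition <- factor(d$condition, levels = STUDY_CONDITIONS)
  d$sample_id <- sprintf("%s_%dh", d$condition, d$timepoint)
  d[, c("sample_id", "condition", "timepoint")]
}

#' Generate a random multi-replicon genome
#'
#' Draws i.i.d. nucleotides at a specified GC content for each requested
#' replicon. Deterministic given the seed.
#'
#' @param sizes Named integer vector of replicon lengths in bp (>= 1000).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet], one element per replicon.
#' @examples
#' g <- makeGenome(c(chr = 2000), gc = 0.5, seed = 1)
#' @export
makeGenome <- function(sizes = c(chromosome = 100000L, plasmid = 10000L),
                       gc = 0.475, seed = 1L) {
  assertThat(all(sizes >= 1000), "replicon sizes must be >= 1000 bp")
  assertThat(gc > 0 && gc < 1, "GC content must lie strictly in (0, 1)")
  if (is.null(names(sizes)))
    names(sizes) <- paste0("replicon", seq_along(sizes))
  assertThat(!anyDuplicated(names(sizes)), "replicon names must be unique")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(seed, {
    seqs <- vapply(sizes, function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    DNAStringSet(seqs)
  })
}

#' Generate a gene annotation for a synthetic genome
#'
#' Places non-overlapping CDS genes, rRNA operons and tRNA genes along
#' the replicons with intergenic gaps wide enough to leave room for
#' planted intergenic sRNAs. Strands are random; coordinates are 1-based
#' inclusive.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param nGenes Number of CDS genes across all replicons.
#' @param nRrna Number of rRNA operons (placed on the largest replicon).
#' @param nTrna Number of tRNA genes.
#' @param geneLength Length range for CDS genes (bp).
#' @param gapRange Range of intergenic gaps (bp).
#' @param seed Integer seed.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `feature_class` in `{CDS, rRNA, tRNA}`.
#' @export
makeAnnotation <- function(genome, nGenes = 60L, nRrna = 2L, nTrna = 5L,
                           geneLength = c(600L, 1400L),
                           gapRange = c(250L, 600L), seed = 1L) {
  lens <- repliconLengths(genome)
  withSeed(seed, {
    ## apportion CDS genes to replicons by length; structural RNAs go on
    ## the largest replicon as in a typical bacterial chromosome
    share <- stats::setNames(pmax(1L, round(nGenes * lens / sum(lens))),
                             names(lens))
    share[which.max(lens)] <- share[which.max(lens)] + (nGenes - sum(share))
    recs <- list()
    serial <- 0L
    for (rep in names(lens)) {
      pool <- data.frame(
        class = c(rep("CDS", share[[rep]]),
                  if (rep == names(which.max(lens)))
                    c(rep("rRNA", nRrna), rep("tRNA", nTrna))))
      pool$len <- ifelse(pool$class == "CDS",
                         round(stats::runif(nrow(pool), geneLength[1],
                                            geneLength[2])),
                         ifelse(pool$class == "rRNA", 1200L, 80L))
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      pos <- 1L
      for (i in seq_len(nrow(pool))) {
        gap <- round(stats::runif(1, gapRange[1], gapRange[2]))
        start <- pos + gap
        end <- start + pool$len[i] - 1L
        if (end > lens[[rep]] - gapRange[1])
          stop("replicon '", rep, "' too small for requested annotation",
               call. = FALSE)
        serial <- serial + 1L
        recs[[length(recs) + 1L]] <- data.frame(
          replicon = rep, start = start, end = end,
          strand = sample(c("+", "-"), 1L),
          gene_id = sprintf("gene%04d", serial),
          feature_class = pool$class[i])
        pos <- end + 1L
      }
    }
    df <- do.call(rbind, recs)
    gr <- GRanges(df$replicon, IRanges(df$start, df$end), strand = df$strand,
                  gene_id = df$gene_id, feature_class = df$feature_class,
                  seqlengths = lens)
    sort(gr, ignore.strand = TRUE)
  })
}

## Windows in which a UTR-category sRNA may fall: 100 nt upstream and
## 50 nt downstream of each gene, strand-aware, clipped to the replicon.
utrWindows <- function(annotation, upstream = 100L, downstream = 50L) {
  ann <- annotation
  plus <- as.character(strand(ann)) != "-"
  upStart <- ifelse(plus, start(ann) - upstream, end(ann) + 1L)
  upEnd <- ifelse(plus, start(ann) - 1L, end(ann) + upstream)
  dnStart <- ifelse(plus, end(ann) + 1L, start(ann) - downstream)
  dnEnd <- ifelse(plus, end(ann) + downstream, start(ann) - 1L)
  w <- GRanges(rep(seqnames(ann), 2L),
               IRanges(pmax(1L, c(upStart, dnStart)),
                       pmax(1L, c(upEnd, dnEnd))),
               gene_id = rep(ann$gene_id, 2L),
               side = rep(c("upstream", "downstream"), each = length(ann)),
               seqlengths = GenomeInfoDb::seqlengths(ann))
  GenomicRanges::trim(w)
}

#' Plant ground-truth sRNA features into a synthetic genome
#'
#' Places intergenic (ncRNA), antisense (asRNA) and UTR-associated sRNA
#' features plus sub-threshold decoys, assigns each a condition-dependent
#' per-sample expression depth, and guarantees that every feature's
#' category is re-derivable from its coordinates: ncRNAs keep >= 101 nt
#' clearance from every gene boundary, UTR features lie inside the
#' 100-nt-upstream window of a gene without touching the gene body, and
#' asRNAs lie wholly inside a gene body.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation Annotation [GenomicRanges::GRanges] from
#'   [makeAnnotation()].
#' @param plan List with counts `nNc`, `nAs`, `nUtr`, `nDecoy`, length
#'   range `lengthRange` (bp), expressed depth range `onDepth`, silent
#'   depth range `offDepth` and flat `decoyDepth` (all on the normalized
#'   coverage scale), and minimum feature separation `minSeparation`.
#' @param samples Sample design data.frame (defaults to [studyDesign()]).
#' @param seed Integer seed.
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id`,
#'   `true_category`, `is_decoy`, `trend_group` (the condition the
#'   feature responds to) and a `depth` matrix column (features x
#'   samples intended mean depth).
#' @export
plantFeatures <- function(genome, annotation,
                          plan = list(), samples = studyDesign(),
                          seed = 1L) {
  defaults <- list(nNc = 20L, nAs = 12L, nUtr = 8L, nDecoy = 5L,
                   lengthRange = c(60L, 100L), onDepth = c(100, 300),
                   offDepth = c(2, 8), decoyDepth = 20,
                   minSeparation = 200L, geneClearance = 101L)
  plan <- utils::modifyList(defaults, plan)
  lens <- repliconLengths(genome)
  ann <- annotation
  nTotal <- plan$nNc + plan$nAs + plan$nUtr + plan$nDecoy

  withSeed(seed, {
    placed <- GRanges(seqlengths = lens)
    recs <- list()

    expand <- function(gr, by) {
      GenomicRanges::trim(suppressWarnings(GenomicRanges::resize(
        gr, width = width(gr) + 2L * by, fix = "center")))
    }
    clearOfGenes <- expand(ann, plan$geneClearance)
    okPlacement <- function(gr, forbidden) {
      length(findOverlaps(gr, forbidden)) == 0L &&
        length(findOverlaps(gr, expand(placed, plan$minSeparation))) == 0L
    }
    placeIntergenic <- function(L) {
      for (try in seq_len(500L)) {
        rep <- sample(names(lens), 1L, prob = lens)
        if (lens[[rep]] < L + 2L) next
        s <- sample.int(lens[[rep]] - L + 1L, 1L)
        gr <- GRanges(rep, IRanges(s, s + L - 1L), seqlengths = lens)
        if (okPlacement(gr, clearOfGenes)) return(gr)
      }
      stop("genome too crowded to place requested intergenic features",
           call. = FALSE)
    }

    ## intergenic ncRNAs and decoys
    for (i in seq_len(plan$nNc + plan$nDecoy)) {
      L <- round(stats::runif(1, plan$lengthRange[1], plan$lengthRange[2]))
      gr <- placeIntergenic(L)
      placed <- c(placed, gr)
      recs[[length(recs) + 1L]] <- list(gr = gr, category = "ncRNA",
                                        decoy = i > plan$nNc)
    }

    ## UTR features: inside the upstream window, 3 nt clear of the gene
    cds <- ann[ann$feature_class == "CDS"]
    usedGenes <- character()
    for (i in seq_len(plan$nUtr)) {
      done <- FALSE
      for (try in seq_len(500L)) {
        g <- cds[sample.int(length(cds), 1L)]
        if (g$gene_id %in% usedGenes) next
        L <- round(stats::runif(1, plan$lengthRange[1],
                                min(plan$lengthRange[2], 95L)))
        if (as.character(strand(g)) != "-") {
          e <- start(g) - 3L
          s <- e - L + 1L
          if (s < start(g) - 100L || s < 1L) next
        } else {
          s <- end(g) + 3L
          e <- s + L - 1L
          if (e > end(g) + 100L || e > lens[[as.character(seqnames(g))]])
            next
        }
        gr <- GRanges(seqnames(g), IRanges(s, e), seqlengths = lens)
        ## must not touch any gene body, and keep clear of other features
        if (length(findOverlaps(gr, ann)) > 0L) next
        if (!okPlacement(gr, GRanges())) next
        placed <- c(placed, gr)
        usedGenes <- c(usedGenes, g$gene_id)
        recs[[length(recs) + 1L]] <- list(gr = gr, category = "UTR",
                                          decoy = FALSE)
        done <- TRUE
        break
      }
      if (!done)
        stop("genome too crowded to place requested UTR features",
             call. = FALSE)
    }

    ## antisense features: wholly inside a CDS body with margin 15 nt
    for (i in seq_len(plan$nAs)) {
      done <- FALSE
      for (try in seq_len(500L)) {
        g <- cds[sample.int(length(cds), 1L)]
        if (g$gene_id %in% usedGenes) next
        L <- round(stats::runif(1, plan$lengthRange[1], plan$lengthRange[2]))
        if (width(g) < L + 30L) next
        s <- start(g) + 15L +
          sample.int(width(g) - L - 30L + 1L, 1L) - 1L
        gr <- GRanges(seqnames(g), IRanges(s, s + L - 1L), seqlengths = lens)
        if (!okPlacement(gr, GRanges())) next
        placed <- c(placed, gr)
        usedGenes <- c(usedGenes, g$gene_id)
        recs[[length(recs) + 1L]] <- list(gr = gr, category = "asRNA",
                                          decoy = FALSE)
        done <- TRUE
        break
      }
      if (!done)
        stop("genome too crowded to place requested antisense features",
             call. = FALSE)
    }

    feats <- do.call(c, lapply(recs, `[[`, "gr"))
    category <- vapply(recs, `[[`, character(1), "category")
    decoy <- vapply(recs, `[[`, logical(1), "decoy")

    ## condition-dependent depth profiles. Real features cycle through
    ## three response types, mirroring the composition of a stress
    ## study in which most sRNAs are not responsive to any one
    ## treatment: constitutive (expressed in all samples),
    ## stress-induced (expressed only under one condition) and
    ## stress-repressed (expressed everywhere except one condition).
    ## Decoys sit flat at sub-threshold depth.
    nS <- nrow(samples)
    depth <- matrix(0, nrow = length(feats), ncol = nS,
                    dimnames = list(NULL, samples$sample_id))
    trend <- character(length(feats))
    stressConds <- setdiff(STUDY_CONDITIONS, "control")
    tpMod <- c(`24` = 0.85, `48` = 1, `72` = 1.15)
    nReal <- 0L
    for (i in seq_along(feats)) {
      if (decoy[i]) {
        trend[i] <- "decoy"
        depth[i, ] <- plan$decoyDepth
        next
      }
      nReal <- nReal + 1L
      rtype <- c("constitutive", "induced", "repressed")[
        (nReal - 1L) %% 3L + 1L]
      cond <- stressConds[((nReal - 1L) %/% 3L) %%
                            length(stressConds) + 1L]
      trend[i] <- if (rtype == "constitutive") "constitutive" else
        paste(rtype, cond, sep = ":")
      base <- stats::runif(1, plan$onDepth[1], plan$onDepth[2])
      for (s in seq_len(nS)) {
        on <- switch(rtype,
                     constitutive = TRUE,
                     induced = samples$condition[s] == cond,
                     repressed = samples$condition[s] != cond)
        depth[i, s] <- if (on)
          base * tpMod[[as.character(samples$timepoint[s])]]
        else stats::runif(1, plan$offDepth[1], plan$offDepth[2])
      }
    }

    ord <- order(as.character(seqnames(feats)), start(feats))
    feats <- feats[ord]
    md <- DataFrame(
      feature_id = sprintf("planted%03d", seq_along(feats)),
      true_category = category[ord],
      is_decoy = decoy[ord],
      trend_group = trend[ord])
    md$depth <- depth[ord, , drop = FALSE]
    mcols(feats) <- md
    feats
  })
}

#' Simulate unstranded short reads for one sample
#'
#' Generates reads as transcript fragments: a planted sRNA shorter than
#' the read length yields reads spanning (almost) the whole transcript
#' with small Poisson end-raggedness, emulating size-selected sRNA
#' libraries; longer features and background transcription yield fixed
#' length reads at uniform positions. Background has three components:
#' uniform noise across the genome, mRNA-degradation coverage over CDS
#' bodies, and deep structural-RNA coverage over rRNA/tRNA genes (later
#' masked from totals). Each read is reverse-complemented with
#' probability 1/2 (unstranded library) and a configurable fraction
#' carries one corrupted terminal base at quality Q2, exercising the
#' mapper's trim-and-remap loop.
#'
#' @param study A [SyntheticStudy-class] object.
#' @param sampleId One of `studySamples(study)$sample_id`.
#' @param seed Integer seed; defaults to a per-sample seed derived from
#'   the study seed, so the 18 samples reproduce bit-identically.
#' @return A [Biostrings::QualityScaledDNAStringSet]; read names encode
#'   sample and serial number.
#' @export
simulateReads <- function(study, sampleId, seed = NULL) {
  samples <- study@samples
  assertThat(sampleId %in% samples$sample_id, "unknown sample '%s'", sampleId)
  sIdx <- match(sampleId, samples$sample_id)
  if (is.null(seed))
    seed <- deriveSeed(study@seed, paste0("reads:", sampleId))
  p <- study@params
  R <- study@readLength
  lens <- repliconLengths(study@genome)
  feats <- study@features
  depths <- if (length(feats)) mcols(feats)$depth[, sIdx] else numeric()
  lib <- samples$lib_factor[sIdx]
  ann <- study@annotation

  withSeed(seed, {
    spans <- list()  # data.frame(replicon, start, end)
    addSpans <- function(rep, s, e) {
      spans[[length(spans) + 1L]] <<- data.frame(replicon = rep,
                                                 start = s, end = e)
    }
    ## planted features: whole-transcript fragments with ragged ends
    for (i in seq_along(feats)) {
      d <- depths[i] * lib
      if (d <= 0) next
      rep <- as.character(seqnames(feats)[i])
      fs <- start(feats)[i]; fe <- end(feats)[i]
      L <- fe - fs + 1L
      if (L <= R) {
        n <- stats::rpois(1L, d)
        if (n == 0L) next
        maxJit <- max(0L, (L - 50L) %/% 2L)
        j5 <- pmin(stats::rpois(n, 0.7), maxJit)
        j3 <- pmin(stats::rpois(n, 0.7), maxJit)
        addSpans(rep, fs + j5, fe - j3)
      } else {
        n <- stats::rpois(1L, d * L / R)
        if (n == 0L) next
        s <- fs + sample.int(L - R + 1L, n, replace = TRUE) - 1L
        addSpans(rep, s, s + R - 1L)
      }
    }
    ## background transcription over annotation records
    for (i in seq_along(ann)) {
      cls <- ann$feature_class[i]
      d <- lib * if (cls == "CDS") p$mrnaBackground else p$structuralDepth
      if (d <= 0) next
      rep <- as.character(seqnames(ann)[i])
      w <- width(ann)[i]
      n <- stats::rpois(1L, d * (w + R - 1) / R)
      if (n == 0L) next
      s0 <- start(ann)[i] - R + 1L
      s <- s0 + sample.int(w + R - 1L, n, replace = TRUE) - 1L
      s <- pmin(pmax(s, 1L), lens[[rep]] - R + 1L)
      addSpans(rep, s, s + R - 1L)
    }
    ## uniform noise
    for (rep in names(lens)) {
      n <- stats::rpois(1L, lib * p$background * lens[[rep]] / R)
      if (n == 0L) next
      s <- sample.int(lens[[rep]] - R + 1L, n, replace = TRUE)
      addSpans(rep, s, s + R - 1L)
    }

    spans <- do.call(rbind, spans)
    if (is.null(spans) || nrow(spans) == 0L)
      return(QualityScaledDNAStringSet(DNAStringSet(),
                                       PhredQuality(character())))
    ## extract sequences, flip random halves to the minus strand
    seqs <- vector("list", length(lens))
    names(seqs) <- names(lens)
    ord <- order(match(spans$replicon, names(lens)), spans$start)
    spans <- spans[ord, , drop = FALSE]
    out <- DNAStringSet()
    for (rep in names(lens)) {
      sp <- spans[spans$replicon == rep, , drop = FALSE]
      if (nrow(sp) == 0L) next
      v <- Views(study@genome[[rep]], start = sp$start, end = sp$end)
      out <- c(out, as(v, "DNAStringSet"))
    }
    flip <- stats::runif(length(out)) < 0.5
    out[flip] <- reverseComplement(out[flip])
    reads <- as.character(out)

    ## corrupt one terminal base (flipped base, quality Q2) on a fraction
    quals <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    nC <- round(p$corruptFraction * length(reads))
    if (nC > 0L) {
      idx <- sample.int(length(reads), nC)
      side3 <- stats::runif(nC) < 0.5
      for (k in seq_len(nC)) {
        i <- idx[k]
        n <- nchar(reads[i])
        pos <- if (side3[k]) n else 1L
        orig <- substr(reads[i], pos, pos)
        substr(reads[i], pos, pos) <-
          sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
        substr(quals[i], pos, pos) <- "#"
      }
    }
    names(reads) <- sprintf("%s_read%06d", sampleId, seq_along(reads))
    QualityScaledDNAStringSet(DNAStringSet(reads), PhredQuality(quals))
  })
}

## Expected masked-excluded total coverage of one library at lib factor 1.
## Used as the study's per-sample normalization target so that normalized
## depths sit on the scale the planted depths were specified on.
expectedMaskedTotal <- function(genome, annotation, features, samples,
                                params, readLength) {
  R <- readLength
  lens <- repliconLengths(genome)
  featPart <- if (length(features))
    mean(colSums(mcols(features)$depth * width(features))) else 0
  cds <- annotation[annotation$feature_class == "CDS"]
  struct <- annotation[annotation$feature_class != "CDS"]
  mrnaPart <- params$mrnaBackground * sum(width(cds) + R - 1)
  spill <- params$structuralDepth * length(struct) * (R - 1)
  bgPart <- params$background * (sum(lens) - sum(width(struct)))
  featPart + mrnaPart + spill + bgPart
}

#' Build the default synthetic sRNA-seq study
#'
#' Assembles a complete in-silico study: a two-replicon genome
#' (100 kb chromosome + 10 kb plasmid by default), ~60 annotated genes
#' with two rRNA operons and five tRNAs, 40 planted sRNA features
#' (20 ncRNA, 12 asRNA, 8 UTR) expressed at 100-300x depth in their
#' trend condition over a 1x uniform background, plus 5 flat 20x decoys
#' below the 50x calling threshold. Per-sample library-size factors are
#' drawn log-normally so normalization has real work to do. The
#' normalization target is the analytically expected masked-excluded
#' total of one library, i.e. the per-study analogue of normalizing a
#' full-size experiment to a fixed total of mapped bases.
#'
#' @param plan Planting plan overrides, see [plantFeatures()].
#' @param genomeSizes Named replicon sizes (bp).
#' @param gc GC content.
#' @param nGenes CDS gene count.
#' @param readLength Read length (bp).
#' @param background Uniform noise depth (x).
#' @param mrnaBackground mRNA-degradation depth over CDS bodies (x).
#' @param structuralDepth rRNA/tRNA coverage depth (x).
#' @param corruptFraction Fraction of reads with one corrupted terminal
#'   base.
#' @param libFactorSd Log-sd of per-sample library-size factors.
#' @param seed Master seed; every per-sample stream is derived from it.
#' @return A [SyntheticStudy-class] object.
#' @export
simulateStudy <- function(plan = list(),
                          genomeSizes = c(chromosome = 100000L,
                                          plasmid = 10000L),
                          gc = 0.475, nGenes = 60L, readLength = 100L,
                          background = 1, mrnaBackground = 3,
                          structuralDepth = 30, corruptFraction = 0.1,
                          libFactorSd = 0.2, seed = 1L) {
  genome <- makeGenome(genomeSizes, gc, seed = deriveSeed(seed, "genome"))
  annotation <- makeAnnotation(genome, nGenes = nGenes,
                               seed = deriveSeed(seed, "annotation"))
  samples <- studyDesign()
  features <- plantFeatures(genome, annotation, plan, samples,
                            seed = deriveSeed(seed, "features"))
  samples$lib_factor <- withSeed(deriveSeed(seed, "libfactors"),
                                 exp(stats::rnorm(nrow(samples), 0,
                                                  libFactorSd)))
  params <- list(background = background, mrnaBackground = mrnaBackground,
                 structuralDepth = structuralDepth,
                 corruptFraction = corruptFraction)
  target <- round(expectedMaskedTotal(genome, annotation, features,
                                      samples, params, readLength))
  new("SyntheticStudy", genome = genome, annotation = annotation,
      features = features, samples = samples, targetTotal = target,
      readLength = as.integer(readLength), params = params,
      seed = as.integer(seed))
}

#' @describeIn SyntheticStudy-class Sample design table (with library
#'   factors).
#' @export
setGeneric("studySamples", function(x) standardGeneric("studySamples"))

#' @rdname SyntheticStudy-class
#' @param x A `SyntheticStudy`.
#' @export
setMethod("studySamples", "SyntheticStudy", function(x) x@samples)

#' @describeIn SyntheticStudy-class Planted ground-truth features.
#' @export
setGeneric("plantedFeatures", function(x) standardGeneric("plantedFeatures"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("plantedFeatures", "SyntheticStudy", function(x) x@features)

#' @describeIn SyntheticStudy-class Genome sequences.
#' @export
setGeneric("studyGenome", function(x) standardGeneric("studyGenome"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("studyGenome", "SyntheticStudy", function(x) x@genome)

#' @describeIn SyntheticStudy-class Gene annotation.
#' @export
setGeneric("studyAnnotation",
           function(x) standardGeneric("studyAnnotation"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("studyAnnotation", "SyntheticStudy", function(x) x@annotation)

#' Simulate a negative-binomial sRNA count matrix
#'
#' Count fixture generator for the differential-expression stage: counts
#' are negative-binomial with per-sRNA base means and per-condition fold
#' changes; dispersion 0 degenerates to Poisson. Null sRNAs (all fold
#' changes 1) share their mean across all samples.
#'
#' @param nSrnas Number of sRNAs (rows).
#' @param design Sample design data.frame (default [studyDesign()]).
#' @param effects Matrix (`nSrnas` x conditions) of fold changes, or
#'   `NULL` for an all-null matrix. Column names must be condition names.
#' @param baseMean Per-sRNA base mean vector (recycled), or `NULL` to
#'   draw log-normally around 100.
#' @param dispersion NB dispersion alpha >= 0 (variance = mu + alpha mu^2).
#' @param seed Integer seed.
#' @return Integer matrix `nSrnas` x `nrow(design)` with dimnames.
#' @export
simulateCounts <- function(nSrnas, design = studyDesign(), effects = NULL,
                           baseMean = NULL, dispersion = 0.1, seed = 1L) {
  assertThat(dispersion >= 0, "dispersion must be nonnegative")
  conds <- as.character(design$condition)
  withSeed(seed, {
    if (is.null(baseMean))
      baseMean <- stats::rlnorm(nSrnas, log(100), 0.7)
    baseMean <- rep_len(baseMean, nSrnas)
    if (is.null(effects)) {
      effects <- matrix(1, nSrnas, length(unique(conds)),
                        dimnames = list(NULL, unique(conds)))
    }
    mu <- baseMean * effects[, conds, drop = FALSE]
    counts <- if (dispersion == 0)
      stats::rpois(length(mu), mu)
    else
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    matrix(as.integer(counts), nSrnas, nrow(design),
           dimnames = list(sprintf("srna%04d", seq_len(nSrnas)),
                           design$sample_id))
  })
}

#' Simulate target predictions, a pathway map and a paired transcriptome
#' with known enrichment truth
#'
#' Builds the three inputs of the network stage so that chosen
#' (sRNA, pathway) couples are truly enriched: their true targets are
#' over-sampled from the pathway, given strongly favorable hybridization
#' energies (<= -12 kcal/mol) and transcriptome profiles correlated with
#' the sRNA (|r| ~ 0.75-0.95), while decoy predictions carry either an
#' unfavorable energy (> -10) or a profile orthogonalized against the
#' sRNA (|r| ~ 0). Under `enrichedPairs = NULL` the output is a pure
#' null: all predictions pass the energy filter but profiles are
#' independent of the sRNAs.
#'
#' @param srnaExpr Matrix sRNA x samples of sRNA expression profiles, or
#'   a character vector of sRNA ids (profiles then drawn standard
#'   normal over `nSamples` columns).
#' @param enrichedPairs data.frame with columns `srna`, `pathway` naming
#'   the truly enriched couples, or `NULL` for the null model.
#' @param nPathways,genesPerPathway Pathway map dimensions.
#' @param nUnannotated Extra genes carrying no pathway annotation.
#' @param targetsPerSrna Predictions listed per sRNA.
#' @param trueInPathway,trueOutside True-target counts for enriched
#'   sRNAs (inside the enriched pathway / elsewhere in the universe).
#' @param nSamples Shared sample count when profiles are drawn.
#' @param seed Integer seed.
#' @return List with elements `predictions` (data.frame srna_id,
#'   gene_id, free_energy, rank, prediction_p, target_strand),
#'   `pathwayMap` (data.frame gene_id, pathway_id), `transcriptome`
#'   (matrix gene x samples), `srnaExpr` (matrix), and `truth`
#'   (the enriched pairs and per-sRNA true target lists).
#' @export
simulateNetworkTruth <- function(srnaExpr, enrichedPairs = NULL,
                                 nPathways = 20L, genesPerPathway = 12L,
                                 nUnannotated = 20L, targetsPerSrna = 20L,
                                 trueInPathway = 6L, trueOutside = 2L,
                                 nSamples = 18L, seed = 1L) {
  withSeed(seed, {
    if (is.character(srnaExpr)) {
      ids <- srnaExpr
      srnaExpr <- matrix(stats::rnorm(length(ids) * nSamples),
                         nrow = length(ids),
                         dimnames = list(ids, sprintf("s%02d",
                                                      seq_len(nSamples))))
    }
    ids <- rownames(srnaExpr)
    nSamples <- ncol(srnaExpr)
    pwIds <- sprintf("pw%02d", seq_len(nPathways))
    nAnn <- nPathways * genesPerPathway
    geneIds <- sprintf("g%04d", seq_len(nAnn + nUnannotated))
    pathwayMap <- data.frame(
      gene_id = geneIds[seq_len(nAnn)],
      pathway_id = rep(pwIds, each = genesPerPathway))
    if (!is.null(enrichedPairs)) {
      assertThat(all(enrichedPairs$pathway %in% pwIds),
                 "pathway map does not cover listed pathways")
      assertThat(all(enrichedPairs$srna %in% ids),
                 "enriched pairs name unknown sRNAs")
    }

    transcriptome <- matrix(stats::rnorm(length(geneIds) * nSamples),
                            nrow = length(geneIds),
                            dimnames = list(geneIds, colnames(srnaExpr)))
    zscore <- function(v) as.numeric(scale(v))
    correlatedProfile <- function(z, rAbs, sgn) {
      noise <- zscore(stats::rnorm(length(z)))
      sgn * (rAbs * z + sqrt(1 - rAbs^2) * noise)
    }
    orthogonalProfile <- function(z) {
      v <- stats::rnorm(length(z))
      zscore(stats::residuals(stats::lm(v ~ z)))
    }

    freePool <- geneIds  # genes not yet claimed as an exclusive profile
    preds <- list()
    truthTargets <- list()
    for (sid in ids) {
      z <- zscore(srnaExpr[sid, ])
      pair <- if (!is.null(enrichedPairs))
        enrichedPairs[enrichedPairs$srna == sid, , drop = FALSE] else
          enrichedPairs
      rows <- NULL
      trueGenes <- character()
      if (!is.null(pair) && nrow(pair) > 0L) {
        for (pw in pair$pathway) {
          pool <- intersect(pathwayMap$gene_id[pathwayMap$pathway_id == pw],
                            freePool)
          assertThat(length(pool) >= trueInPathway,
                     "pathway %s exhausted; too many enriched pairs", pw)
          gIn <- sample(pool, trueInPathway)
          outPool <- setdiff(intersect(pathwayMap$gene_id, freePool),
                             pathwayMap$gene_id[pathwayMap$pathway_id == pw])
          gOut <- sample(outPool, trueOutside)
          for (g in c(gIn, gOut)) {
            sgn <- sample(c(-1, 1), 1L)
            transcriptome[g, ] <- correlatedProfile(
              z, stats::runif(1, 0.75, 0.95), sgn)
          }
          freePool <- setdiff(freePool, c(gIn, gOut))
          trueGenes <- c(trueGenes, gIn, gOut)
        }
        nDecoy <- max(0L, targetsPerSrna - length(trueGenes))
        nEDecoy <- ceiling(nDecoy / 2)
        nCDecoy <- nDecoy - nEDecoy
        cPool <- sample(intersect(freePool, pathwayMap$gene_id), nCDecoy)
        for (g in cPool) transcriptome[g, ] <- orthogonalProfile(z)
        freePool <- setdiff(freePool, cPool)
        ePool <- sample(setdiff(pathwayMap$gene_id, c(trueGenes, cPool)),
                        nEDecoy)
        gAll <- c(trueGenes, cPool, ePool)
        energy <- c(stats::runif(length(trueGenes), -25, -12),
                    stats::runif(nCDecoy, -20, -12),
                    stats::runif(nEDecoy, -9.5, -4))
      } else {
        ## null sRNA: annotated targets, favorable energies, background
        ## (independent) transcriptome profiles
        gAll <- sample(pathwayMap$gene_id, targetsPerSrna)
        energy <- stats::runif(targetsPerSrna, -20, -12)
      }
      rank <- rank(energy, ties.method = "first")
      rows <- data.frame(srna_id = sid, gene_id = gAll,
                         free_energy = energy, rank = as.integer(rank),
                         prediction_p = stats::runif(length(gAll), 0, 0.3),
                         target_strand = sample(c("+", "-"), length(gAll),
                                                replace = TRUE))
      preds[[sid]] <- rows
      truthTargets[[sid]] <- trueGenes
    }
    list(predictions = do.call(rbind, c(preds, make.row.names = FALSE)),
         pathwayMap = pathwayMap,
         transcriptome = transcriptome,
         srnaExpr = srnaExpr,
         truth = list(enrichedPairs = enrichedPairs,
                      trueTargets = truthTargets))
  })
}

#' Write a synthetic study and its ground truth to disk
#'
#' Emits the genome (FASTA), annotation (GFF3), sample design (TSV) and
#' planted-feature ground truth (TSV, with per-sample intended depths)
#' so recovery metrics can be computed without re-entering the
#' generator.
#'
#' @param study A [SyntheticStudy-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation.gff3"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  writeXStringSet(study@genome, paths["genome"])
  writeAnnotationGff(study@annotation, paths["annotation"])
  utils::write.table(study@samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f <- study@features
  gt <- data.frame(feature_id = f$feature_id,
                   replicon = as.character(seqnames(f)),
                   start = start(f), end = end(f),
                   true_category = f$true_category,
                   is_decoy = f$is_decoy,
                   trend_group = f$trend_group)
  gt <- cbind(gt, as.data.frame(mcols(f)$depth))
  utils::write.table(gt, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write / read a gene annotation as GFF3
#'
#' Thin wrappers around [rtracklayer::export()]/[rtracklayer::import()]
#' preserving the `gene_id` and `feature_class` columns (1-based
#' inclusive coordinates).
#'
#' @param annotation GRanges with `gene_id`, `feature_class`.
#' @param path File path.
#' @return `readAnnotationGff` returns the annotation GRanges.
#' @export
writeAnnotationGff <- function(annotation, path) {
  gr <- annotation
  mcols(gr) <- DataFrame(source = "sRNAseeker",
                         type = gr$feature_class,
                         phase = ifelse(gr$feature_class == "CDS", 0L,
                                        NA_integer_),
                         ID = gr$gene_id,
                         gene_id = gr$gene_id,
                         feature_class = gr$feature_class)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeAnnotationGff
#' @export
readAnnotationGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cls <- if (!is.null(gr$feature_class)) gr$feature_class else
    as.character(gr$type)
  gid <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
  mcols(gr) <- DataFrame(gene_id = gid, feature_class = cls)
  gr
}

#' Write / read FASTQ reads with qualities
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path FASTQ path (uncompressed).
#' @return `readReadsFastq` returns a `QualityScaledDNAStringSet`.
#' @export
writeReadsFastq <- function(reads, path) {
  writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  ## Biostrings attaches a metadata column while pairing sequences with
  ## qualities and warns when it drops it again; harmless here.
  suppressWarnings(
    readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
}
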