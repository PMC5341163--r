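## Read mapping by iterative trim-and-remap exact matching, per-nucleotide
## coverage, structural-RNA masking and fixed-total normalization.

## Hashed k-mer index over every replicon: all genome k-mers with their
## positions, plus an explicit position list for k-mers occurring more
## than once (repeat loci).
buildKmerIndex <- function(gstr, k) {
  kmers <- character(); reps <- character(); pos <- integer()
  for (rep in names(gstr)) {
    n <- nchar(gstr[[rep]])
    if (n < k) next
    p <- seq_len(n - k + 1L)
    kmers <- c(kmers, substring(gstr[[rep]], p, p + k - 1L))
    reps <- c(reps, rep(rep, length(p)))
    pos <- c(pos, p)
  }
  dup <- unique(kmers[duplicated(kmers)])
  dupMap <- if (length(dup))
    split(seq_along(kmers)[kmers %in% dup], kmers[kmers %in% dup])
  else list()
  list(k = k, kmers = kmers, reps = reps, pos = pos, dupMap = dupMap)
}

## Exact full-length matching of reads (possibly of mixed widths)
## against every replicon, both orientations (the library is
## unstranded): the reads' first `k` bases are located in the hashed
## genome k-mer index, then each anchor hit is verified by full-length
## string comparison. Multi-mapping reads are reported at every locus.
matchReadsExact <- function(qryFwd, qryRev, gstr, index) {
  glen <- vapply(gstr, nchar, integer(1))
  hits <- list()
  for (orient in c("fwd", "rev")) {
    q <- if (orient == "fwd") qryFwd else qryRev
    anchors <- substring(q, 1L, index$k)
    first <- match(anchors, index$kmers)
    ri <- which(!is.na(first))
    entry <- first[ri]
    ## expand anchors landing on repeated genome k-mers to all loci
    if (length(index$dupMap)) {
      isDup <- anchors[ri] %in% names(index$dupMap)
      if (any(isDup)) {
        extraRi <- integer(); extraEntry <- integer()
        for (j in which(isDup)) {
          locs <- index$dupMap[[anchors[ri[j]]]]
          extraRi <- c(extraRi, rep(ri[j], length(locs)))
          extraEntry <- c(extraEntry, locs)
        }
        keep <- !isDup
        ri <- c(ri[keep], extraRi)
        entry <- c(entry[keep], extraEntry)
      }
    }
    if (length(ri) == 0L) next
    rep <- index$reps[entry]
    s <- index$pos[entry]
    e <- s + nchar(q[ri]) - 1L
    ok <- e <= glen[rep]
    ri <- ri[ok]; rep <- rep[ok]; s <- s[ok]; e <- e[ok]
    if (length(ri) == 0L) next
    full <- logical(length(ri))
    for (rp in unique(rep)) {
      sel <- rep == rp
      full[sel] <- substring(gstr[[rp]], s[sel], e[sel]) == q[ri[sel]]
    }
    if (!any(full)) next
    hits[[length(hits) + 1L]] <- data.frame(
      idx = ri[full], replicon = rep[full], start = s[full])
  }
  if (length(hits) == 0L)
    return(data.frame(idx = integer(), replicon = character(),
                      start = integer()))
  unique(do.call(rbind, hits))
}

#' Map reads by iterative trimming of low-quality terminal bases
#'
#' Attempts an exact full-length match of every read against both strands
#' of every replicon. Reads that fail are trimmed by one base - the
#' terminal base with the lower quality score, ties going to the 3' end -
#' and retried, for up to `maxCycles` trim cycles or until the read falls
#' below `minLen`, whichever comes first. Reads that never match are
#' dropped (counted in the summary); reads matching multiple loci are
#' placed at every locus.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] with per-base
#'   Phred qualities.
#' @param genome A [Biostrings::DNAStringSet].
#' @param minLen Minimum mappable read length (bp).
#' @param maxCycles Maximum number of trim cycles.
#' @return List with `mapped` (data.frame read_id, replicon, start,
#'   length, trims_applied; one row per placement) and `summary`
#'   (data.frame reads_in, mapped, multi_mapped, trimmed, dropped,
#'   mapping_ratio).
#' @export
mapReadsIterative <- function(reads, genome, minLen = 50L, maxCycles = 50L) {
  assertThat(length(genome) > 0L && sum(Biostrings::width(genome)) > 0L,
             "empty genome")
  nIn <- length(reads)
  if (nIn == 0L)
    return(list(
      mapped = data.frame(read_id = character(), replicon = character(),
                          start = integer(), length = integer(),
                          trims_applied = integer()),
      summary = data.frame(reads_in = 0L, mapped = 0L, multi_mapped = 0L,
                           trimmed = 0L, dropped = 0L,
                           mapping_ratio = NA_real_)))
  seqs <- as(reads, "DNAStringSet")
  quals <- as.list(methods::as(quality(reads), "IntegerList"))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(nIn))
  active <- which(Biostrings::width(seqs) >= minLen)
  placements <- list()
  mappedTrims <- integer(nIn)
  everMapped <- logical(nIn)
  gstr <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(gstr) <- names(genome)
  index <- buildKmerIndex(gstr, minLen)

  for (cycle in 0:maxCycles) {
    if (length(active) == 0L) break
    if (cycle > 0L) {
      ## trim the lower-quality terminal base (ties -> 3')
      w <- Biostrings::width(seqs)[active]
      q5 <- vapply(active, function(i) quals[[i]][1L], integer(1))
      q3 <- vapply(seq_along(active), function(k)
        quals[[active[k]]][w[k]], integer(1))
      trim5 <- q5 < q3
      newStart <- ifelse(trim5, 2L, 1L)
      newEnd <- ifelse(trim5, w, w - 1L)
      seqs[active] <- subseq(seqs[active], start = newStart, end = newEnd)
      quals[active] <- mapply(function(i, s, e) quals[[i]][s:e],
                              active, newStart, newEnd, SIMPLIFY = FALSE)
      keep <- (newEnd - newStart + 1L) >= minLen
      active <- active[keep]
      if (length(active) == 0L) break
    }
    h <- matchReadsExact(as.character(seqs[active]),
                         as.character(reverseComplement(seqs[active])),
                         gstr, index)
    if (nrow(h) > 0L) {
      gi <- active[h$idx]
      placements[[length(placements) + 1L]] <- data.frame(
        read_id = ids[gi], replicon = h$replicon, start = h$start,
        length = Biostrings::width(seqs)[gi], trims_applied = cycle)
      everMapped[unique(gi)] <- TRUE
      mappedTrims[unique(gi)] <- cycle
      active <- setdiff(active, which(everMapped))
    }
  }

  mapped <- if (length(placements)) do.call(rbind, placements) else
    data.frame(read_id = character(), replicon = character(),
               start = integer(), length = integer(),
               trims_applied = integer())
  nMapped <- sum(everMapped)
  nMulti <- sum(table(mapped$read_id) > 1L)
  summary <- data.frame(
    reads_in = nIn,
    mapped = nMapped,
    multi_mapped = nMulti,
    trimmed = sum(everMapped & mappedTrims > 0L),
    dropped = nIn - nMapped,
    mapping_ratio = nMapped / nIn)
  list(mapped = mapped, summary = summary)
}

#' Per-nucleotide coverage from mapped reads
#'
#' Depth at position i is the number of mapped read placements whose span
#' covers i, strand ignored (unstranded library). The sum of all depths
#' equals the sum of placed read lengths.
#'
#' @param mapped data.frame of placements from [mapReadsIterative()].
#' @param genome A [Biostrings::DNAStringSet] (defines replicon lengths).
#' @param sampleId Sample identifier stored on the track.
#' @return A raw (unnormalized) [CoverageTrack-class].
#' @export
computeCoverage <- function(mapped, genome, sampleId = "sample") {
  lens <- repliconLengths(genome)
  if (nrow(mapped) > 0L) {
    assertThat(all(mapped$replicon %in% names(lens)),
               "placement on unknown replicon")
    ends <- mapped$start + mapped$length - 1L
    assertThat(all(mapped$start >= 1L) &&
                 all(ends <= lens[mapped$replicon]),
               "read span exceeds replicon bounds")
    gr <- GRanges(mapped$replicon, IRanges(mapped$start, ends),
                  seqlengths = lens)
    cov <- coverage(gr)
  } else {
    cov <- methods::as(lapply(lens, function(n) Rle(0L, n)), "RleList")
  }
  CoverageTrack(depth = cov[names(lens)], sampleId = sampleId)
}

#' Mask structural-RNA regions on a coverage track
#'
#' Records the rRNA/tRNA regions of the annotation on the track so that
#' coverage totals (and hence normalization) exclude them. Depth values
#' themselves are retained unmodified.
#'
#' @param track A [CoverageTrack-class].
#' @param annotation GRanges with a `feature_class` column; records with
#'   class rRNA or tRNA are masked.
#' @return The track with its mask set.
#' @export
maskStructuralRna <- function(track, annotation) {
  m <- annotation[annotation$feature_class %in% c("rRNA", "tRNA")]
  track@mask <- m
  track
}

#' Total coverage of a track outside its masked regions
#'
#' @param track A [CoverageTrack-class].
#' @return Numeric total.
#' @export
maskedTotal <- function(track) trackTotal(track, excludeMask = TRUE)

#' Normalize a sample's coverage to a fixed total of mapped bases
#'
#' Multiplies every depth (masked regions included) by
#' `targetTotal / maskedTotal`, so that the coverage total outside
#' rRNA/tRNA regions equals `targetTotal` exactly. Normalizing an
#' already-normalized track is the identity.
#'
#' @param track A [CoverageTrack-class] (mask set via
#'   [maskStructuralRna()] if structural RNA should be excluded).
#' @param targetTotal Target total mapped bases (the full-scale
#'   convention is 1e8).
#' @return The normalized track; its `scaleFactor()` records the factor.
#' @export
normalizeToTotal <- function(track, targetTotal = 1e8) {
  tot <- maskedTotal(track)
  if (tot <= 0) stop("no usable coverage", call. = FALSE)
  f <- targetTotal / tot
  track@depth <- methods::as(lapply(track@depth, function(d) d * f),
                             "RleList")
  track@normalized <- TRUE
  track@scaleFactor <- f
  methods::validObject(track)
  track
}

#' Write / read a coverage track as BedGraph
#'
#' One BedGraph file per sample holding all replicons. BedGraph uses
#' 0-based half-open intervals on disk; coordinates are converted so
#' in-memory tracks are 1-based inclusive.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @param repliconLengths Named lengths for reconstruction on import.
#' @param sampleId,normalized Track metadata on import.
#' @return `readBedGraph` returns a [CoverageTrack-class].
#' @export
writeBedGraph <- function(track, path) {
  gr <- methods::as(track@depth, "GRanges")
  names(mcols(gr)) <- "score"
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(path, repliconLengths, sampleId = "sample",
                         normalized = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(repliconLengths)
  GenomeInfoDb::seqlengths(gr) <- repliconLengths
  cov <- coverage(gr, weight = gr$score)
  CoverageTrack(depth = cov[names(repliconLengths)],
                sampleId = sampleId, normalized = normalized)
}
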