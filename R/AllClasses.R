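#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame Rle runValue
#' @importFrom IRanges IRanges RleList slice Views
#' @importFrom GenomicRanges GRanges seqnames start end width strand coverage
#'   findOverlaps countOverlaps reduce pintersect punion GRangesList
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   QualityScaledDNAStringSet PhredQuality quality subseq reverseComplement
#'   PDict matchPDict vcountPDict DNAString matchPattern
#'   readQualityScaledDNAStringSet writeQualityScaledXStringSet width
NULL

#' CoverageTrack: per-nucleotide read coverage for one sample
#'
#' Holds unstranded per-nucleotide coverage depth for every replicon of a
#' genome, for a single sequencing sample. Depths are stored run-length
#' encoded (one [S4Vectors::Rle] per replicon). A track is either *raw*
#' (integer read-span counts) or *normalized* (depths rescaled so that the
#' total coverage outside masked structural-RNA regions equals a fixed
#' target, making samples of different library size comparable).
#'
#' @slot depth An [IRanges::RleList], one run-length encoded depth vector
#'   per replicon; element lengths equal replicon lengths.
#' @slot sampleId Single character, the sample identifier.
#' @slot normalized Logical; `TRUE` after [normalizeToTotal()].
#' @slot mask A [GenomicRanges::GRanges] of structural-RNA (rRNA/tRNA)
#'   regions excluded from coverage totals, or empty if unmasked.
#' @slot scaleFactor Numeric; the factor applied by normalization
#'   (`NA` for raw tracks).
#'
#' @seealso [computeCoverage()], [maskStructuralRna()], [normalizeToTotal()]
#' @export
setClass("CoverageTrack",
  slots = c(
    depth = "RleList",
    sampleId = "character",
    normalized = "logical",
    mask = "GRanges",
    scaleFactor = "numeric"
  ),
  prototype = prototype(
    normalized = FALSE,
    mask = GenomicRanges::GRanges(),
    scaleFactor = NA_real_
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-NA string")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "'normalized' must be a single logical")
  if (any(vapply(object@depth, function(d) any(runValue(d) < 0), logical(1))))
    msg <- c(msg, "coverage depths must be nonnegative")
  if (!object@normalized) {
    intish <- vapply(object@depth, function(d) {
      v <- runValue(d)
      all(abs(v - round(v)) < 1e-9)
    }, logical(1))
    if (!all(intish))
      msg <- c(msg, "raw (unnormalized) tracks must hold integer depths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param depth An [IRanges::RleList] (or plain list of numeric vectors),
#'   one depth vector per replicon, named by replicon.
#' @param sampleId Sample identifier.
#' @param normalized Has the track been normalized to a fixed total?
#' @param mask GRanges of regions excluded from totals (rRNA/tRNA).
#' @param scaleFactor Normalization factor applied, if any.
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(depth, sampleId, normalized = FALSE,
                          mask = GenomicRanges::GRanges(),
                          scaleFactor = NA_real_) {
  if (!is(depth, "RleList"))
    depth <- methods::as(lapply(depth, Rle), "RleList")
  new("CoverageTrack", depth = depth, sampleId = sampleId,
      normalized = normalized, mask = mask, scaleFactor = scaleFactor)
}

#' @describeIn CoverageTrack-class Depth vectors as an RleList.
#' @param x,object A `CoverageTrack`.
#' @export
setGeneric("trackDepth", function(x) standardGeneric("trackDepth"))

#' @rdname CoverageTrack-class
#' @export
setMethod("trackDepth", "CoverageTrack", function(x) x@depth)

#' @describeIn CoverageTrack-class Sample identifier.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname CoverageTrack-class
#' @export
setMethod("sampleId", "CoverageTrack", function(x) x@sampleId)

#' @describeIn CoverageTrack-class Whether the track is normalized.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname CoverageTrack-class
#' @export
setMethod("isNormalized", "CoverageTrack", function(x) x@normalized)

#' @describeIn CoverageTrack-class Masked (rRNA/tRNA) regions.
#' @export
setGeneric("maskRanges", function(x) standardGeneric("maskRanges"))

#' @rdname CoverageTrack-class
#' @export
setMethod("maskRanges", "CoverageTrack", function(x) x@mask)

#' @describeIn CoverageTrack-class Normalization scale factor (NA if raw).
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))

#' @rdname CoverageTrack-class
#' @export
setMethod("scaleFactor", "CoverageTrack", function(x) x@scaleFactor)

setMethod("show", "CoverageTrack", function(object) {
  tot <- sum(vapply(object@depth, function(d) sum(as.numeric(d)), numeric(1)))
  cat("CoverageTrack for sample", object@sampleId, "\n")
  cat("  replicons:", paste(names(object@depth), collapse = ", "), "\n")
  cat("  normalized:", object@normalized,
      if (!is.na(object@scaleFactor))
        sprintf("(scale factor %.4g)", object@scaleFactor) else "", "\n")
  cat("  masked regions:", length(object@mask), "\n")
  cat(sprintf("  total coverage: %.4g\n", tot))
})

#' SyntheticStudy: a fully specified synthetic sRNA-seq experiment
#'
#' Container for one synthetic multi-condition sRNA sequencing study:
#' a multi-replicon genome, gene annotation, planted ground-truth sRNA
#' features with per-sample expression depths, and the sample design
#' (6 conditions x 3 time points = 18 samples by default). Reads and
#' coverage are generated lazily per sample by [simulateReads()].
#'
#' @slot genome A [Biostrings::DNAStringSet] of replicon sequences.
#' @slot annotation A [GenomicRanges::GRanges] with metadata columns
#'   `gene_id` and `feature_class` (CDS/rRNA/tRNA).
#' @slot features A [GenomicRanges::GRanges] of planted sRNA features with
#'   metadata columns `feature_id`, `true_category` (ncRNA/asRNA/UTR),
#'   `is_decoy`, `trend_group`, and a `depth` matrix column (one column
#'   per sample: intended per-sample mean depth on the normalized scale).
#' @slot samples A data.frame with columns `sample_id`, `condition`,
#'   `timepoint` describing the design.
#' @slot targetTotal Numeric; the expected masked-excluded total coverage
#'   of one library, used as the per-study normalization target.
#' @slot readLength Integer read length.
#' @slot params Named list of generator parameters (background rates,
#'   corruption fraction, ...).
#' @slot seed Integer master seed the study was built from.
#' @export
setClass("SyntheticStudy",
  slots = c(
    genome = "DNAStringSet",
    annotation = "GRanges",
    features = "GRanges",
    samples = "data.frame",
    targetTotal = "numeric",
    readLength = "integer",
    params = "list",
    seed = "integer"
  )
)

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (length(object@genome) == 0L)
    msg <- c(msg, "genome must contain at least one replicon")
  if (anyDuplicated(names(object@genome)))
    msg <- c(msg, "replicon names must be unique")
  if (nrow(object@samples) > 0L &&
      !all(c("sample_id", "condition", "timepoint") %in%
           colnames(object@samples)))
    msg <- c(msg, "samples must have sample_id, condition, timepoint")
  if (length(object@features) > 0L) {
    need <- c("feature_id", "true_category", "is_decoy", "trend_group",
              "depth")
    if (!all(need %in% colnames(mcols(object@features))))
      msg <- c(msg, paste("features must carry",
                          paste(need, collapse = ", ")))
    else if (!is.matrix(mcols(object@features)$depth) ||
             ncol(mcols(object@features)$depth) != nrow(object@samples))
      msg <- c(msg, "feature depth matrix must have one column per sample")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy (seed", object@seed, ")\n")
  cat(sprintf("  genome: %d replicon(s), %d bp total\n",
              length(object@genome),
              sum(Biostrings::width(object@genome))))
  cat(sprintf("  annotation: %d records (%s)\n", length(object@annotation),
              paste(names(table(object@annotation$feature_class)),
                    table(object@annotation$feature_class),
                    collapse = ", ", sep = ":")))
  nf <- length(object@features)
  cat(sprintf("  planted features: %d (%d decoys)\n", nf,
              if (nf) sum(object@features$is_decoy) else 0L))
  cat(sprintf("  samples: %d; normalization target: %.4g bases\n",
              nrow(object@samples), object@targetTotal))
})

#' RegulatoryNetwork: bipartite sRNA-pathway network
#'
#' The assembled sRNA regulatory network: a bipartite graph whose nodes
#' are sRNAs and metabolic pathways and whose edges are significantly
#' enriched (sRNA, pathway) associations. Each edge is backed by an
#' enrichment record carrying the hypergeometric parameters
#' (universe size N, pathway size M, target count n, overlap m) and
#' the enrichment probability P.
#'
#' @slot graph An [igraph::graph] object, bipartite, with vertex
#'   attribute `type` ("sRNA"/"pathway") and edge attributes `P`, `m`,
#'   `sign` (dominant correlation sign of supporting targets).
#' @slot enrichment data.frame of the enrichment records behind edges
#'   (columns srna_id, pathway_id, N, M, n, m, P, sign).
#' @export
setClass("RegulatoryNetwork",
  slots = c(graph = "ANY", enrichment = "data.frame")
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "'graph' must be an igraph object")
  else {
    if (igraph::vcount(object@graph) > 0 &&
        !all(igraph::V(object@graph)$type %in% c("sRNA", "pathway")))
      msg <- c(msg, "vertex types must be 'sRNA' or 'pathway'")
    if (igraph::ecount(object@graph) != nrow(object@enrichment))
      msg <- c(msg, "each edge must be backed by one enrichment record")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RegulatoryNetwork-class The underlying igraph object.
#' @param x,object A `RegulatoryNetwork`.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkGraph", "RegulatoryNetwork", function(x) x@graph)

#' @describeIn RegulatoryNetwork-class Enrichment records backing edges.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("enrichmentTable", "RegulatoryNetwork", function(x) x@enrichment)

setMethod("show", "RegulatoryNetwork", function(object) {
  g <- object@graph
  nS <- sum(igraph::V(g)$type == "sRNA")
  nP <- sum(igraph::V(g)$type == "pathway")
  cat("RegulatoryNetwork:", nS, "sRNA node(s),", nP, "pathway node(s),",
      igraph::ecount(g), "edge(s)\n")
})
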