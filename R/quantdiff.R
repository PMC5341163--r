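## Expression quantification, negative-binomial differential expression
## and correspondence analysis of the sRNA x sample matrix.

#' Quantify sRNA expression on normalized coverage
#'
#' The expression of an sRNA of length j spanning nucleotides i..i+j-1
#' is the summed normalized coverage depth over the interval divided by
#' j, i.e. its mean normalized depth.
#'
#' @param srnas GRanges of called sRNAs (with `srna_id`).
#' @param tracks Named list of normalized [CoverageTrack-class] objects.
#' @param samples Optional sample design data.frame (columns sample_id,
#'   condition, timepoint) used as column annotation.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expression` (sRNA x sample mean normalized depth), `rowRanges`
#'   the sRNAs and `colData` the design.
#' @export
quantifyExpression <- function(srnas, tracks, samples = NULL) {
  assertThat(all(width(srnas) > 0L), "zero-length interval")
  mat <- vapply(tracks, function(tr) rangeMeans(tr, srnas),
                numeric(length(srnas)))
  mat <- matrix(mat, nrow = length(srnas),
                dimnames = list(srnas$srna_id, names(tracks)))
  cd <- if (!is.null(samples)) {
    S4Vectors::DataFrame(samples[match(colnames(mat), samples$sample_id),
                                 , drop = FALSE],
                         row.names = colnames(mat))
  } else S4Vectors::DataFrame(row.names = colnames(mat))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = mat), rowRanges = srnas, colData = cd)
}

#' Count mapped reads per sRNA interval
#'
#' Raw (unnormalized) read counts: the number of read placements whose
#' span overlaps the interval, per sample. These feed the
#' differential-expression test; between-sample library size is handled
#' there by size factors.
#'
#' @param srnas GRanges of called sRNAs.
#' @param mappedList Named list of placement data.frames (one per
#'   sample, from [mapReadsIterative()]).
#' @return Integer matrix sRNA x sample.
#' @export
countReads <- function(srnas, mappedList) {
  mat <- vapply(mappedList, function(mp) {
    if (nrow(mp) == 0L) return(integer(length(srnas)))
    gr <- GRanges(mp$replicon, IRanges(mp$start,
                                       mp$start + mp$length - 1L))
    countOverlaps(srnas, gr, ignore.strand = TRUE)
  }, integer(length(srnas)))
  matrix(as.integer(mat), nrow = length(srnas),
         dimnames = list(srnas$srna_id, names(mappedList)))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median across sRNAs of
#' the ratio of each sample's count to the row geometric mean, using
#' only sRNAs with strictly positive counts in every sample.
#'
#' @param counts Nonnegative integer matrix, sRNA x sample.
#' @return Named numeric vector of size factors.
#' @export
sizeFactorsForCounts <- function(counts) {
  assertThat(ncol(counts) >= 2L, "need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  assertThat(any(pos), "no sRNA with positive counts in all samples")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - logGeo)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimate
#'
#' Per-sRNA dispersions are estimated on size-factor-normalized counts
#' by pooling within-group means and variances
#' (alpha = (variance - mean) / mean^2, floored at 0); the common
#' dispersion shared by the exact test is their across-sRNA mean, which
#' at a thousand sRNAs is a stable estimate of a shared dispersion.
#'
#' @param counts Integer matrix sRNA x sample.
#' @param groups Factor/character of group labels per column.
#' @param sizeFactors Optional size factors (computed if `NULL`).
#' @return List with `perGene` vector and `common` scalar.
#' @export
estimateDispersion <- function(counts, groups, sizeFactors = NULL) {
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsForCounts(counts)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  groups <- as.character(groups)
  perGene <- apply(norm, 1L, function(x) {
    mw <- 0; vw <- 0; dfTot <- 0
    for (g in unique(groups)) {
      xg <- x[groups == g]
      if (length(xg) < 2L) next
      mw <- mw + mean(xg) * (length(xg) - 1L)
      vw <- vw + stats::var(xg) * (length(xg) - 1L)
      dfTot <- dfTot + (length(xg) - 1L)
    }
    if (dfTot == 0) return(NA_real_)
    m <- mw / dfTot; v <- vw / dfTot
    if (m <= 0) return(NA_real_)
    max(0, (v - m) / m^2)
  })
  list(perGene = perGene, common = mean(perGene, na.rm = TRUE))
}

#' Negative-binomial exact test for one sRNA
#'
#' Two-sided conditional exact test in the style of early count-based
#' differential-expression methods: conditional on the total
#' (size-factor-normalized, rounded) count s = kA + kB, the probability
#' of every split (a, s-a) is computed under a negative-binomial model
#' with the supplied dispersion and a common mean estimated from s, and
#' the p value is the total probability of splits no more likely than
#' the observed one. The fold change is (meanB + 0.5)/(meanA + 0.5) on
#' normalized counts; both conditions all-zero gives p = 1, fold
#' change 1.
#'
#' @param countsA,countsB Nonnegative integer count vectors (the
#'   replicates of the two conditions).
#' @param dispersion NB dispersion alpha (>= 0; 0 = Poisson).
#' @param sizeFactorsA,sizeFactorsB Optional per-replicate size factors.
#' @return List with `fold_change` (B over A) and `p`.
#' @export
nbExactTest <- function(countsA, countsB, dispersion,
                        sizeFactorsA = NULL, sizeFactorsB = NULL) {
  assertThat(all(countsA >= 0) && all(countsB >= 0),
             "counts must be nonnegative")
  if (is.null(sizeFactorsA)) sizeFactorsA <- rep(1, length(countsA))
  if (is.null(sizeFactorsB)) sizeFactorsB <- rep(1, length(countsB))
  normA <- countsA / sizeFactorsA
  normB <- countsB / sizeFactorsB
  fc <- (mean(normB) + 0.5) / (mean(normA) + 0.5)
  kA <- round(sum(normA)); kB <- round(sum(normB))
  s <- kA + kB
  if (s == 0) return(list(fold_change = 1, p = 1))
  nA <- length(countsA); nB <- length(countsB)
  mu <- s / (nA + nB)  # common per-replicate mean under the null
  dens <- function(x, n) {
    if (dispersion > 0)
      stats::dnbinom(x, mu = n * mu, size = n / dispersion)
    else stats::dpois(x, n * mu)
  }
  a <- 0:s
  joint <- dens(a, nA) * dens(s - a, nB)
  tot <- sum(joint)
  obs <- joint[kA + 1L]
  p <- if (tot <= 0) 1 else sum(joint[joint <= obs * (1 + 1e-12)]) / tot
  list(fold_change = fc, p = min(1, max(p, .Machine$double.xmin)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; adjusted values are monotone
#' and capped at 1.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values.
#' @export
bhAdjust <- function(p) {
  assertThat(all(p >= 0 & p <= 1, na.rm = TRUE),
             "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter differential-expression results
#'
#' Significance requires fold change strictly above `fcThreshold` (or
#' strictly below its reciprocal) *and* adjusted p value strictly below
#' `alpha`; the direction (up/down) is recorded.
#'
#' @param results data.frame with columns `fold_change`, `p_adj`.
#' @param fcThreshold Fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `results` with added `significant` and `direction` columns.
#' @export
deFilter <- function(results, fcThreshold = 1.5, alpha = 0.05) {
  up <- results$fold_change > fcThreshold
  down <- results$fold_change < 1 / fcThreshold
  results$significant <- (up | down) & results$p_adj < alpha
  results$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  results
}

#' Differential expression between conditions
#'
#' Runs the NB exact test per sRNA for each stress condition against the
#' control, treating the three time points of a condition as replicates
#' (n = 3 vs 3); alternatively, `mode = "timepoint"` compares single
#' time points across conditions using the per-condition libraries of
#' that time point (n = 1 vs 1, exploratory). P values are BH-adjusted
#' within each comparison and filtered at fold change > 1.5 and
#' adjusted p < 0.05.
#'
#' @param counts Integer matrix sRNA x sample.
#' @param samples Design data.frame (sample_id, condition, timepoint).
#' @param reference Reference condition (default "control").
#' @param conditions Conditions to test (default: all non-reference).
#' @param mode `"condition"` (timepoints as replicates) or
#'   `"timepoint"` (restrict each comparison to one time point).
#' @param timepoints Time points used in `"timepoint"` mode.
#' @param fcThreshold,alpha Significance thresholds.
#' @param dispersion Common dispersion; `NULL` estimates it per
#'   comparison by [estimateDispersion()].
#' @return data.frame with one row per (sRNA, comparison): fold_change,
#'   p, p_adj, significant, direction.
#' @export
runDe <- function(counts, samples, reference = "control",
                  conditions = NULL, mode = c("condition", "timepoint"),
                  timepoints = NULL, fcThreshold = 1.5, alpha = 0.05,
                  dispersion = NULL) {
  mode <- match.arg(mode)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  conds <- as.character(samples$condition)
  if (is.null(conditions))
    conditions <- setdiff(unique(conds), reference)
  sf <- sizeFactorsForCounts(counts)
  out <- list()
  comparisons <- if (mode == "condition") {
    lapply(conditions, function(cd) list(
      name = cd,
      A = which(conds == reference), B = which(conds == cd)))
  } else {
    if (is.null(timepoints)) timepoints <- unique(samples$timepoint)
    unlist(lapply(conditions, function(cd) lapply(timepoints, function(tp)
      list(name = sprintf("%s_%dh", cd, tp),
           A = which(conds == reference & samples$timepoint == tp),
           B = which(conds == cd & samples$timepoint == tp)))),
      recursive = FALSE)
  }
  for (cmp in comparisons) {
    sub <- counts[, c(cmp$A, cmp$B), drop = FALSE]
    groups <- rep(c("A", "B"), c(length(cmp$A), length(cmp$B)))
    disp <- dispersion
    if (is.null(disp))
      disp <- estimateDispersion(sub, groups,
                                 sf[c(cmp$A, cmp$B)])$common
    if (!is.finite(disp)) disp <- 0
    res <- t(vapply(seq_len(nrow(counts)), function(i) {
      r <- nbExactTest(counts[i, cmp$A], counts[i, cmp$B], disp,
                       sf[cmp$A], sf[cmp$B])
      c(r$fold_change, r$p)
    }, numeric(2)))
    df <- data.frame(srna_id = rownames(counts), comparison = cmp$name,
                     fold_change = res[, 1], p = res[, 2],
                     p_adj = bhAdjust(res[, 2]))
    out[[cmp$name]] <- deFilter(df, fcThreshold, alpha)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Correspondence analysis of a nonnegative matrix
#'
#' Classical CA: the matrix is scaled to proportions, standardized
#' residuals from the independence model are formed from the row and
#' column masses, decomposed by SVD, and principal coordinates computed
#' for rows and columns. Inertia per dimension is the squared singular
#' value; total inertia equals the chi-square statistic of the table
#' divided by its grand total.
#'
#' @param mat Nonnegative matrix (e.g. sRNA x sample expression) with
#'   no all-zero row or column.
#' @param nDim Number of dimensions to return (default 2).
#' @return List of class `CaResult`: `row_coords`, `col_coords`
#'   (principal coordinates), `inertia` (per returned dimension),
#'   `total_inertia`, `explained` (fraction per dimension).
#' @export
correspondenceAnalysis <- function(mat, nDim = 2L) {
  assertThat(all(mat >= 0), "matrix entries must be nonnegative")
  assertThat(sum(mat) > 0, "grand total must be positive")
  zr <- rowSums(mat) == 0; zc <- colSums(mat) == 0
  if (any(zr)) stop("all-zero row(s): ",
                    paste(rownames(mat)[zr], collapse = ", "),
                    call. = FALSE)
  if (any(zc)) stop("all-zero column(s): ",
                    paste(colnames(mat)[zc], collapse = ", "),
                    call. = FALSE)
  P <- mat / sum(mat)
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c)) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  keep <- seq_len(min(nDim, length(sv$d)))
  rowCoords <- diag(1 / sqrt(r)) %*% sv$u %*% diag(sv$d, nrow = length(sv$d))
  colCoords <- diag(1 / sqrt(c)) %*% sv$v %*% diag(sv$d, nrow = length(sv$d))
  rowCoords <- rowCoords[, keep, drop = FALSE]
  colCoords <- colCoords[, keep, drop = FALSE]
  dimnames(rowCoords) <- list(rownames(mat), paste0("Dim", keep))
  dimnames(colCoords) <- list(colnames(mat), paste0("Dim", keep))
  total <- sum(sv$d^2)
  structure(list(row_coords = rowCoords, col_coords = colCoords,
                 inertia = sv$d[keep]^2, total_inertia = total,
                 explained = if (total > 0) sv$d[keep]^2 / total else
                   rep(0, length(keep))),
            class = "CaResult")
}

#' @export
print.CaResult <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns\n")
  cat(sprintf("  total inertia %.6g; dims explain %s\n", x$total_inertia,
              paste(sprintf("%.1f%%", 100 * x$explained),
                    collapse = ", ")))
  invisible(x)
}
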