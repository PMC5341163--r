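## End-to-end orchestration: validated config, staged execution with
## logging, deterministic seeding, machine-readable summary.

## Config schema: section -> key -> c(type, positivity). Defaults mirror
## the published thresholds: 50x depth, 50 bp, 3 samples, 100/50 nt UTR
## windows, FC 1.5, alpha 0.05, rank 100, -10 kcal/mol, |r| 0.4.
configSchema <- function() {
  list(
    seed = list(default = 1L, type = "integer"),
    outdir = list(default = "srnaseeker_run", type = "character"),
    paths = list(
      genome = list(default = NULL, type = "character"),
      annotation = list(default = NULL, type = "character"),
      reads = list(default = NULL, type = "character"),
      coverage = list(default = NULL, type = "character"),
      samples = list(default = NULL, type = "character"),
      predictions = list(default = NULL, type = "character"),
      pathway_map = list(default = NULL, type = "character"),
      transcriptome = list(default = NULL, type = "character")),
    detection = list(
      depthThreshold = list(default = 50, type = "numeric", positive = TRUE),
      minLength = list(default = 50L, type = "integer", positive = TRUE),
      minSupport = list(default = 3L, type = "integer", positive = TRUE),
      mergeGap = list(default = 50L, type = "integer", positive = TRUE),
      utrUpstream = list(default = 100L, type = "integer", positive = TRUE),
      utrDownstream = list(default = 50L, type = "integer",
                           positive = TRUE),
      rescueFlank = list(default = 50L, type = "integer", positive = TRUE),
      rescueRatio = list(default = 2, type = "numeric", positive = TRUE),
      jaccard = list(default = 0.5, type = "numeric", positive = TRUE),
      refineWindow = list(default = 20L, type = "integer",
                          positive = TRUE),
      trendRule = list(default = "pearson", type = "character")),
    normalization = list(
      targetTotal = list(default = "auto", type = "numericOrAuto")),
    de = list(
      fcThreshold = list(default = 1.5, type = "numeric", positive = TRUE),
      alpha = list(default = 0.05, type = "numeric", positive = TRUE),
      mode = list(default = "condition", type = "character"),
      reference = list(default = "control", type = "character")),
    network = list(
      maxRank = list(default = 100L, type = "integer", positive = TRUE),
      energyCutoff = list(default = -10, type = "numeric"),
      rCut = list(default = 0.4, type = "numeric", positive = TRUE),
      corAlpha = list(default = 0.05, type = "numeric", positive = TRUE),
      minGenes = list(default = 2L, type = "integer", positive = TRUE),
      enrichAlpha = list(default = 0.05, type = "numeric",
                         positive = TRUE)))
}

coerceValue <- function(value, spec, key, errors, warnings) {
  if (is.null(value)) return(list(value = NULL, errors = errors,
                                  warnings = warnings))
  if (spec$type %in% c("numeric", "integer", "numericOrAuto")) {
    if (spec$type == "numericOrAuto" && identical(value, "auto"))
      return(list(value = "auto", errors = errors, warnings = warnings))
    if (is.character(value)) {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num)) {
        errors <- c(errors, sprintf(
          "key '%s': expected a number, got \"%s\"", key, value))
        return(list(value = value, errors = errors, warnings = warnings))
      }
      warnings <- c(warnings, sprintf(
        "key '%s': coerced string \"%s\" to number", key, value))
      value <- num
    }
    if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
      errors <- c(errors, sprintf("key '%s': expected a single number",
                                  key))
      return(list(value = value, errors = errors, warnings = warnings))
    }
    if (isTRUE(spec$positive) && value <= 0)
      errors <- c(errors, sprintf("key '%s': must be positive (got %s)",
                                  key, value))
    if (spec$type == "integer") value <- as.integer(round(value))
  } else if (spec$type == "character") {
    if (!is.character(value) || length(value) != 1L)
      errors <- c(errors, sprintf("key '%s': expected a single string",
                                  key))
  }
  list(value = value, errors = errors, warnings = warnings)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or `NULL` (all defaults).
#' Unknown keys are rejected; missing keys get the published default
#' thresholds; string-typed numbers are coerced with a warning; every
#' type or sign violation is collected and reported in one error.
#'
#' @param config Path to a YAML file, a list, or `NULL`.
#' @return The normalized config (nested list) with an attribute
#'   `warnings` listing coercions.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    assertThat(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  assertThat(is.list(config), "config must be a list or YAML file")
  schema <- configSchema()
  errors <- character(); warnings <- character()
  out <- list()
  unknownTop <- setdiff(names(config), names(schema))
  if (length(unknownTop))
    errors <- c(errors, sprintf("unknown key '%s'", unknownTop))
  for (section in names(schema)) {
    spec <- schema[[section]]
    if (!is.null(spec$type)) {  # scalar top-level entry
      value <- if (section %in% names(config)) config[[section]] else
        spec$default
      res <- coerceValue(value, spec, section, errors, warnings)
      out[[section]] <- res$value
      errors <- res$errors; warnings <- res$warnings
      next
    }
    sub <- if (section %in% names(config)) config[[section]] else list()
    if (!is.list(sub)) {
      errors <- c(errors, sprintf("section '%s' must be a mapping",
                                  section))
      sub <- list()
    }
    unknown <- setdiff(names(sub), names(spec))
    if (length(unknown))
      errors <- c(errors, sprintf("unknown key '%s.%s'", section, unknown))
    secOut <- list()
    for (key in names(spec)) {
      value <- if (key %in% names(sub)) sub[[key]] else
        spec[[key]]$default
      res <- coerceValue(value, spec[[key]],
                         paste(section, key, sep = "."), errors, warnings)
      if (!is.null(res$value)) secOut[[key]] <- res$value
      errors <- res$errors; warnings <- res$warnings
    }
    out[[section]] <- secOut
  }
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  for (w in warnings) warning(w, call. = FALSE)
  attr(out, "warnings") <- warnings
  out
}

## Canonical JSON of the config (outdir excluded so runs into different
## directories hash identically) and its md5.
configHash <- function(config) {
  cfg <- config
  cfg$outdir <- NULL
  attr(cfg, "warnings") <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  unname(tools::md5sum(f))
}

#' Score called sRNAs against planted ground truth
#'
#' A planted feature counts as *recovered* when some called sRNA has
#' Jaccard overlap >= 0.5 with it and both boundaries lie within
#' `tolerance` nt of the truth. Category accuracy is evaluated on
#' recovered features; decoys are "called" if any sRNA reaches Jaccard
#' >= 0.5 with them.
#'
#' @param srnas Called sRNAs (GRanges with `category`).
#' @param features Planted features (GRanges with `true_category`,
#'   `is_decoy`).
#' @param tolerance Boundary tolerance in nt.
#' @return List: n_planted, n_recovered, recovery_rate,
#'   category_accuracy, n_decoys, decoys_called, mean_boundary_error.
#' @export
recoveryReport <- function(srnas, features, tolerance = 10L) {
  real <- features[!features$is_decoy]
  decoys <- features[features$is_decoy]
  matchOne <- function(f) {
    sameRep <- as.character(seqnames(srnas)) ==
      as.character(seqnames(f))
    if (!any(sameRep)) return(NULL)
    cand <- srnas[sameRep]
    jac <- vapply(seq_along(cand), function(k)
      intervalJaccard(start(cand)[k], end(cand)[k], start(f), end(f)),
      numeric(1))
    if (max(jac) < 0.5) return(NULL)
    cand[which.max(jac)]
  }
  recovered <- 0L; catOk <- 0L; bErr <- numeric()
  for (i in seq_along(real)) {
    hit <- matchOne(real[i])
    if (is.null(hit)) next
    dS <- abs(start(hit) - start(real)[i])
    dE <- abs(end(hit) - end(real)[i])
    bErr <- c(bErr, dS, dE)
    if (dS <= tolerance && dE <= tolerance) {
      recovered <- recovered + 1L
      if (hit$category == real$true_category[i]) catOk <- catOk + 1L
    }
  }
  decoyCalls <- sum(vapply(seq_along(decoys), function(i)
    !is.null(matchOne(decoys[i])), logical(1)))
  list(n_planted = length(real),
       n_recovered = recovered,
       recovery_rate = if (length(real)) recovered / length(real) else
         NA_real_,
       category_accuracy = if (recovered) catOk / recovered else
         NA_real_,
       n_decoys = length(decoys),
       decoys_called = decoyCalls,
       mean_boundary_error = if (length(bErr)) mean(bErr) else NA_real_)
}

#' Run the full sRNA discovery pipeline
#'
#' Executes the stages in order - read simulation or loading, iterative
#' mapping, coverage, masking, normalization, sRNA calling,
#' quantification, differential expression, correspondence analysis,
#' network construction - writing every stage's outputs plus a
#' machine-readable `summary.json` into the run directory. With no
#' input paths configured, the bundled synthetic study is generated
#' and analyzed end to end, and a recovery report against the planted
#' ground truth is included. Reruns with the same config and seed are
#' bit-identical.
#'
#' @param config Anything [validateConfig()] accepts.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config = NULL, quiet = FALSE) {
  config <- validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  logFile <- file.path(outdir, "run.log")
  if (file.exists(logFile)) unlink(logFile)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
    cat(sub("^\\[[0-9:]+\\] ", "", line), "\n", file = logFile,
        append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  manifest <- character()
  register <- function(path) manifest <<- c(manifest, path)
  seed <- config$seed
  logmsg("run starts; config hash %s; seed %d", hash, seed)
  logmsg("effective thresholds: depth>%s, length>=%s, support>=%s, FC>%s, alpha<%s",
         config$detection$depthThreshold, config$detection$minLength,
         config$detection$minSupport, config$de$fcThreshold,
         config$de$alpha)

  demo <- is.null(config$paths$genome)
  if (demo) {
    logmsg("no inputs configured: generating the synthetic demo study")
    study <- simulateStudy(seed = seed)
    genome <- study@genome
    annotation <- study@annotation
    samples <- study@samples
    inputDir <- file.path(outdir, "inputs")
    register(writeStudy(study, inputDir))
  } else {
    for (p in c("genome", "annotation")) {
      path <- config$paths[[p]]
      assertThat(!is.null(path) && file.exists(path),
                 "missing input file for '%s': %s", p,
                 if (is.null(path)) "(not configured)" else path)
    }
    genome <- readDNAStringSet(config$paths$genome)
    names(genome) <- sub(" .*", "", names(genome))
    annotation <- readAnnotationGff(config$paths$annotation)
    assertThat(!is.null(config$paths$samples) &&
                 file.exists(config$paths$samples),
               "missing input file for 'samples': %s",
               if (is.null(config$paths$samples)) "(not configured)" else
                 config$paths$samples)
    samples <- utils::read.delim(config$paths$samples)
    study <- NULL
  }
  lens <- repliconLengths(genome)

  ## --- mapping + coverage -------------------------------------------
  covDir <- file.path(outdir, "coverage")
  dir.create(covDir, showWarnings = FALSE)
  tracks <- list(); rawTracks <- list(); mappedList <- list()
  mapSummaries <- list()
  for (s in samples$sample_id) {
    if (demo) {
      reads <- simulateReads(study, s)
    } else if (!is.null(config$paths$coverage)) {
      path <- file.path(config$paths$coverage, paste0(s, ".bedgraph"))
      assertThat(file.exists(path), "missing coverage file: %s", path)
      raw <- readBedGraph(path, lens, sampleId = s)
      raw <- maskStructuralRna(raw, annotation)
      tt <- if (identical(config$normalization$targetTotal, "auto")) 1e8
        else config$normalization$targetTotal
      tracks[[s]] <- normalizeToTotal(raw, tt)
      rawTracks[[s]] <- raw
      next
    } else {
      path <- file.path(config$paths$reads, paste0(s, ".fastq"))
      assertThat(file.exists(path), "missing reads file: %s", path)
      reads <- readReadsFastq(path)
    }
    mp <- mapReadsIterative(reads, genome)
    mappedList[[s]] <- mp$mapped
    mapSummaries[[s]] <- cbind(sample_id = s, mp$summary)
    raw <- computeCoverage(mp$mapped, genome, sampleId = s)
    raw <- maskStructuralRna(raw, annotation)
    tt <- config$normalization$targetTotal
    if (identical(tt, "auto"))
      tt <- if (demo) study@targetTotal else 1e8
    norm <- normalizeToTotal(raw, tt)
    rawTracks[[s]] <- raw
    tracks[[s]] <- norm
    register(writeBedGraph(raw, file.path(covDir,
                                          paste0(s, ".raw.bedgraph"))))
    register(writeBedGraph(norm, file.path(covDir,
                                           paste0(s, ".bedgraph"))))
    logmsg("sample %s: %d/%d reads mapped (scale factor %.3f)", s,
           mp$summary$mapped, mp$summary$reads_in, norm@scaleFactor)
  }
  if (length(mapSummaries)) {
    ms <- do.call(rbind, c(mapSummaries, make.row.names = FALSE))
    path <- file.path(outdir, "mapping_summary.tsv")
    utils::write.table(ms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    register(path)
  }

  ## --- discovery ----------------------------------------------------
  det <- do.call(detectionParams, config$detection)
  srnas <- callSrnas(tracks, annotation, genome, det)
  logmsg("called %d sRNAs (%s)", length(srnas),
         paste(names(table(srnas$category)), table(srnas$category),
               sep = ":", collapse = ", "))
  gffPath <- file.path(outdir, "srnas.gff3")
  tsvPath <- file.path(outdir, "srnas.tsv")
  srnaTable <- exportSrnas(srnas, annotation, gffPath, tsvPath)
  register(gffPath); register(tsvPath)

  recovery <- NULL
  if (demo && length(srnas)) {
    recovery <- recoveryReport(srnas, study@features)
    logmsg("recovery: %d/%d planted features, %d/%d decoys called",
           recovery$n_recovered, recovery$n_planted,
           recovery$decoys_called, recovery$n_decoys)
  }

  ## --- quantification + DE + CA -------------------------------------
  summary <- list(schema_version = "1.0", config_hash = hash, seed = seed,
                  n_samples = nrow(samples))
  deCounts <- NULL; caExplained <- NULL; netSize <- NULL
  exprMat <- NULL
  if (length(srnas)) {
    se <- quantifyExpression(srnas, tracks, samples)
    exprMat <- SummarizedExperiment::assay(se, "expression")
    path <- file.path(outdir, "expression.tsv")
    utils::write.table(data.frame(srna_id = rownames(exprMat), exprMat,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    register(path)
    counts <- countReads(srnas, mappedList)
    if (length(mappedList)) {
      path <- file.path(outdir, "counts.tsv")
      utils::write.table(data.frame(srna_id = rownames(counts), counts,
                                    check.names = FALSE),
                         path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      register(path)
      de <- runDe(counts, samples, reference = config$de$reference,
                  mode = config$de$mode,
                  fcThreshold = config$de$fcThreshold,
                  alpha = config$de$alpha)
      path <- file.path(outdir, "de_results.tsv")
      utils::write.table(de, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      register(path)
      deCounts <- as.list(tapply(de$significant, de$comparison, sum))
      logmsg("differentially expressed sRNAs per comparison: %s",
             paste(names(deCounts), unlist(deCounts), sep = ":",
                   collapse = ", "))
    }
    caInput <- exprMat[rowSums(exprMat) > 0, colSums(exprMat) > 0,
                       drop = FALSE]
    if (nrow(caInput) >= 3 && ncol(caInput) >= 3) {
      ca <- correspondenceAnalysis(caInput)
      for (part in c("row", "col")) {
        coords <- ca[[paste0(part, "_coords")]]
        path <- file.path(outdir, paste0("ca_", part, "s.tsv"))
        utils::write.table(data.frame(id = rownames(coords), coords),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        register(path)
      }
      caExplained <- ca$explained
    }
  }

  ## --- network -------------------------------------------------------
  net <- NULL
  ncIds <- if (length(srnas)) srnas$srna_id[srnas$category == "ncRNA"]
    else character()
  if (demo && length(ncIds) >= 3 && !is.null(exprMat)) {
    enriched <- data.frame(srna = ncIds[1:3],
                           pathway = c("pw01", "pw02", "pw03"))
    nt <- simulateNetworkTruth(exprMat[ncIds, , drop = FALSE],
                               enrichedPairs = enriched,
                               seed = deriveSeed(seed, "network"))
    predictions <- nt$predictions
    pathwayMap <- nt$pathwayMap
    transcriptome <- nt$transcriptome
    srnaExpr <- nt$srnaExpr
    for (nm in c("predictions", "pathwayMap")) {
      path <- file.path(outdir, paste0(nm, ".tsv"))
      utils::write.table(get(nm), path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      register(path)
    }
  } else if (!demo && !is.null(config$paths$predictions)) {
    predictions <- utils::read.delim(config$paths$predictions)
    pathwayMap <- utils::read.delim(config$paths$pathway_map)
    tr <- utils::read.delim(config$paths$transcriptome, row.names = 1L)
    transcriptome <- as.matrix(tr)
    srnaExpr <- exprMat
  } else predictions <- NULL
  if (!is.null(predictions)) {
    filt <- filterTargets(predictions, config$network$maxRank,
                          config$network$energyCutoff)
    cors <- correlationFilter(filt, srnaExpr, transcriptome,
                              config$network$rCut,
                              config$network$corAlpha)
    net <- assembleNetwork(cors, pathwayMap, config$network$minGenes,
                           config$network$enrichAlpha)
    register(exportNetwork(net, file.path(outdir, "network.graphml"),
                           file.path(outdir, "network.sif")))
    path <- file.path(outdir, "enrichment.tsv")
    utils::write.table(net@enrichment, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    register(path)
    netSize <- list(n_srnas = sum(igraph::V(net@graph)$type == "sRNA"),
                    n_pathways = sum(igraph::V(net@graph)$type ==
                                       "pathway"),
                    n_edges = igraph::ecount(net@graph))
    logmsg("network: %d sRNA node(s), %d pathway node(s), %d edge(s)",
           netSize$n_srnas, netSize$n_pathways, netSize$n_edges)
  }

  ## --- summary -------------------------------------------------------
  catCounts <- if (length(srnas)) as.list(table(srnas$category)) else
    list()
  summary$srna_counts <- catCounts
  summary$n_srnas <- length(srnas)
  summary$de_significant <- deCounts
  summary$ca_explained <- caExplained
  summary$network <- netSize
  summary$recovery <- recovery
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifestDf <- data.frame(file = sub(paste0("^", outdir, "/?"), "",
                                      unlist(manifest)),
                           config_hash = hash)
  utils::write.table(manifestDf, file.path(outdir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("run complete: %s", file.path(outdir, "summary.json"))
  invisible(summary)
}
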