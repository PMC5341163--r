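## The default synthetic study, mapped and normalized once per test run
## and shared across test files (building it dominates test cost).

.demoCache <- new.env(parent = emptyenv())

demoStudy <- function() {
  if (is.null(.demoCache$study))
    .demoCache$study <- simulateStudy(seed = 1)
  .demoCache$study
}

## Mapped placements and normalized tracks for every sample.
demoMapped <- function() {
  if (is.null(.demoCache$mapped)) {
    study <- demoStudy()
    genome <- studyGenome(study)
    ann <- studyAnnotation(study)
    mapped <- list(); tracks <- list(); corrupted <- list()
    for (s in studySamples(study)$sample_id) {
      reads <- simulateReads(study, s)
      corrupted[[s]] <- grepl("#", as.character(Biostrings::quality(reads)),
                              fixed = TRUE)
      names(corrupted[[s]]) <- names(reads)
      mp <- mapReadsIterative(reads, genome)
      raw <- computeCoverage(mp$mapped, genome, sampleId = s)
      raw <- maskStructuralRna(raw, ann)
      mapped[[s]] <- mp
      tracks[[s]] <- normalizeToTotal(raw, study@targetTotal)
    }
    .demoCache$mapped <- mapped
    .demoCache$tracks <- tracks
    .demoCache$corrupted <- corrupted
  }
  .demoCache$mapped
}

demoTracks <- function() {
  demoMapped()
  .demoCache$tracks
}

demoCorrupted <- function() {
  demoMapped()
  .demoCache$corrupted
}

demoSrnas <- function() {
  if (is.null(.demoCache$srnas)) {
    study <- demoStudy()
    .demoCache$srnas <- callSrnas(demoTracks(), studyAnnotation(study),
                                  studyGenome(study))
  }
  .demoCache$srnas
}
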