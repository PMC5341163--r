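## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards. All exported stochastic
## functions route their randomness through this.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministically derive a stage-specific seed from the master seed,
## keeping the result inside the 32-bit integer range.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Replicon lengths of a DNAStringSet as a named numeric vector.
repliconLengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## Sum of an Rle restricted to / excluding a set of ranges (IRanges)
## on one replicon depth vector.
rleSum <- function(depth) sum(as.numeric(depth))

## Total coverage of a track, optionally excluding its masked regions.
trackTotal <- function(track, excludeMask = TRUE) {
  total <- sum(vapply(track@depth, rleSum, numeric(1)))
  if (!excludeMask || length(track@mask) == 0L) return(total)
  masked <- 0
  for (rep in names(track@depth)) {
    mr <- track@mask[as.character(seqnames(track@mask)) == rep]
    if (length(mr) == 0L) next
    ir <- IRanges::reduce(IRanges::ranges(mr))
    d <- track@depth[[rep]]
    ir <- IRanges::restrict(ir, start = 1L, end = length(d))
    if (length(ir))
      masked <- masked + sum(vapply(seq_along(ir), function(i)
        sum(as.numeric(d[IRanges::start(ir)[i]:IRanges::end(ir)[i]])),
        numeric(1)))
  }
  total - masked
}

## Stop unless condition, with sprintf-style message.
assertThat <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
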