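# Shared fixtures, built once per test session and memoised.

.fixtureEnv <- new.env(parent = emptyenv())

fxDefault <- function() {
  if (is.null(.fixtureEnv$fx)) {
    spec <- fixtureSpec()
    .fixtureEnv$spec <- spec
    .fixtureEnv$fx <- makeGenomeAndAnnotation(spec)
  }
  .fixtureEnv$fx
}

fxSpec <- function() { fxDefault(); .fixtureEnv$spec }

fxReads <- function() {
  if (is.null(.fixtureEnv$reads))
    .fixtureEnv$reads <- makeReads(fxDefault(), fxSpec())
  .fixtureEnv$reads
}

fxMapResult <- function() {
  if (is.null(.fixtureEnv$mapres))
    .fixtureEnv$mapres <- callJunctions(fxReads()$reads,
                                        fxDefault()$models,
                                        fxDefault()$genome, runConfig())
  .fixtureEnv$mapres
}

fxEvents <- function() {
  if (is.null(.fixtureEnv$events))
    .fixtureEnv$events <- classifyEvents(fxMapResult(), fxDefault()$models,
                                         fxDefault()$genome,
                                         organoid = integer(0), runConfig(),
                                         makeRearrangements(fxDefault()))
  .fixtureEnv$events
}

# a minimal hand-built two-gene annotation on a tiny genome, for unit tests
# that need full control over coordinates
tinyModels <- function() {
  exons <- data.frame(
    geneId = c("gX", "gX", "gX", "gY", "gY"),
    txId = c("gX.t1", "gX.t1", "gX.t1", "gY.t1", "gY.t1"),
    biotype = "protein_coding",
    contig = "ctg",
    strand = "+",
    exonRank = c(1L, 2L, 3L, 1L, 2L),
    start = c(100L, 300L, 500L, 900L, 1100L),
    end = c(200L, 400L, 620L, 1000L, 1220L),
    stringsAsFactors = FALSE)
  tx <- data.frame(
    geneId = c("gX", "gY"), txId = c("gX.t1", "gY.t1"),
    biotype = "protein_coding", contig = "ctg", strand = "+",
    cdsStart = c(130L, 930L), cdsEnd = c(590L, 1190L),
    stringsAsFactors = FALSE)
  TranscriptSet(exons, tx)
}
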