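#' Run configuration with the method's published defaults
#'
#' Central knob registry.  Every numeric default that has a published value
#' uses it: 9-bp index words, 13-bp read k-mers, the \emph{fewer than two}
#' normal-organoid reads novelty rule, the >10 bp premature-polyA distance,
#' the fusion ranking thresholds (unique reads per gene more than five,
#' coefficient of variation below 25\%, orientation inconsistency below
#' 5\%), the five-read expression threshold, the >50 bp NMD-zone rule and
#' the 40-cluster cap of the Dirichlet-process sampler.
#'
#' @param ... overrides of individual entries (must name existing entries).
#' @return named list of settings.
#' @export
runConfig <- function(...) {
  cfg <- list(
    wordSize = 9L,             # exon index word (bp)
    kmerSize = 13L,            # read shatter k-mer (bp)
    readLength = 75L,          # nominal fixture read length (bp)
    organoidMaxReads = 2L,     # reject events seen in >= 2 organoid reads
    polyAMinDistance = 10L,    # premature polyA: > 10 bp from canonical edge
    polyAMinRun = 8L,          # minimum non-templated A-run (bp)
    fusionMinUniqueReads = 5L, # rank route: more than five per gene
    fusionMaxCV = 25,          # percent
    fusionMaxInconsistency = 5,# percent
    fusionMaxMultimapFrac = 0.20,
    insertSize = 500L,         # library insert for breakpoint compatibility
    expressionMinReads = 5L,   # "expressed" = coverage >= 5
    nmdDistance = 50L,         # NMD target zone: > 50 bp upstream of last junction
    maxMismatch = 2L,          # mismatches admitted during fragment extension
    minAnchor = 13L,           # exact k-mer anchor required on each side
    relaxedWordSize = 7L,      # retry word size for unresolved fragments
    relaxedMaxMismatch = 5L,
    antisenseMinDepth = 3L,    # antisense exon plateau depth
    antisenseEdgeTol = 2L,     # edge consensus tolerance (bp)
    samplerC = 40L,            # DP cluster cap
    samplerIters = 5000L,
    samplerBurnIn = 2000L,
    samplerThin = 5L,
    proposalScale = 20         # Metropolis-Hastings beta proposal scale d
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}
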