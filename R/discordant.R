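# Discordant-pair fusion discovery.
#
# Read pairs whose two ends map to different genes are clustered per gene
# pair, scored on position dispersion, unique-fragment support and
# orientation consistency, and merged with split-read evidence into a
# high-confidence fusion list.

# map one end as a singleton: exact occurrences in the genome, both strands
.mapSingleton <- function(seq, genome) {
  hits <- list()
  p <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(p)
  for (contig in names(genome)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPattern(if (str == "+") p else rc,
                                    genome[[contig]])
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          contig = contig, start = Biostrings::start(m) - 1L,
          strand = str, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# dispersion of pair positions inside the insert-size frame anchored at the
# breakpoint-proximal cluster edge, as percent coefficient of variation
.clusterCV <- function(pos, strand, readLength, insertSize) {
  inner <- if (strand == "+") pos + readLength else pos
  rel <- if (strand == "+") inner - (max(inner) - insertSize)
         else (min(inner) + insertSize) - inner
  rel <- pmax(rel, 0)
  m <- mean(rel)
  if (m == 0) return(0)
  100 * stats::sd(rel) / m
}

#' Cluster discordant read pairs into fusion candidates
#'
#' Ends are remapped as singletons; pairs whose ends fall into two different
#' genes are grouped by gene pair, pairs with a mitochondrial end are
#' excluded, and per-candidate metrics are computed: supporting and unique
#' fragments per gene, multimapping fraction, per-gene coefficient of
#' variation of mapping positions (percent, within the insert-size frame),
#' and the fraction of pairs with an orientation inconsistent with the
#' cluster's modal one.
#'
#' @param pairs data.frame(name, seq1, seq2).
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param cfg a \code{runConfig()} list.
#' @return data.frame of fusion candidates (one row per gene pair).
#' @export
clusterDiscordantPairs <- function(pairs, models, genome,
                                   cfg = runConfig()) {
  fp <- geneFootprints(models)
  mito <- intersect(c("chrM", "MT"), names(genome))
  geneAt <- function(contig, pos) {
    g <- fp$geneId[fp$contig == contig & fp$start <= pos & pos < fp$end]
    if (length(g)) sort(g)[1] else NA_character_
  }
  rl <- cfg$readLength

  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    if (is.na(pairs$seq2[i])) next
    h1 <- .mapSingleton(pairs$seq1[i], genome)
    h2 <- .mapSingleton(pairs$seq2[i], genome)
    if (is.null(h1) || is.null(h2)) next
    if (length(mito) && (any(h1$contig %in% mito) ||
                         any(h2$contig %in% mito))) next
    multi <- nrow(h1) > 1L || nrow(h2) > 1L
    h1 <- h1[1, ]; h2 <- h2[1, ]
    g1 <- geneAt(h1$contig, h1$start)
    g2 <- geneAt(h2$contig, h2$start)
    if (is.na(g1) || is.na(g2) || g1 == g2) next
    # orient the pair so gene A is the lexicographically first gene
    if (g1 > g2) { tmp <- h1; h1 <- h2; h2 <- tmp
                   tmpg <- g1; g1 <- g2; g2 <- tmpg }
    rows[[length(rows) + 1L]] <- data.frame(
      name = pairs$name[i], geneA = g1, geneB = g2,
      posA = h1$start, strandA = h1$strand,
      posB = h2$start, strandB = h2$strand,
      multimapping = multi, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(geneA = character(0), geneB = character(0),
                      nPairs = integer(0), uniqueA = integer(0),
                      uniqueB = integer(0), cvA = numeric(0),
                      cvB = numeric(0), inconsistentPct = numeric(0),
                      multimapFrac = numeric(0), posA = numeric(0),
                      posB = numeric(0)))
  d <- do.call(rbind, rows)
  sp <- split(d, paste(d$geneA, d$geneB))
  out <- lapply(sp, function(cl) {
    orient <- paste(cl$strandA, cl$strandB)
    modal <- names(sort(table(orient), decreasing = TRUE))[1]
    cons <- cl[orient == modal, , drop = FALSE]
    data.frame(
      geneA = cl$geneA[1], geneB = cl$geneB[1], nPairs = nrow(cl),
      uniqueA = length(unique(cl$posA)), uniqueB = length(unique(cl$posB)),
      cvA = .clusterCV(cons$posA, cons$strandA[1], cfg$readLength,
                       cfg$insertSize),
      cvB = .clusterCV(cons$posB, cons$strandB[1], cfg$readLength,
                       cfg$insertSize),
      inconsistentPct = 100 * mean(orient != modal),
      multimapFrac = mean(cl$multimapping),
      posA = max(cl$posA), posB = min(cl$posB),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank a fusion candidate against the published thresholds
#'
#' "Extremely high ranking" requires more than five unique reads in each
#' gene, a coefficient of variation below 25 percent on both sides,
#' orientation inconsistency below 5 percent, and a minimal multimapping
#' fraction.
#'
#' @param cand one row of \code{clusterDiscordantPairs()} output.
#' @param cfg a \code{runConfig()} list.
#' @return list(pass, breakdown) where breakdown names each criterion.
#' @export
rankFusionCandidate <- function(cand, cfg = runConfig()) {
  breakdown <- c(
    uniqueReads = cand$uniqueA > cfg$fusionMinUniqueReads &&
                  cand$uniqueB > cfg$fusionMinUniqueReads,
    cv = cand$cvA < cfg$fusionMaxCV && cand$cvB < cfg$fusionMaxCV,
    orientation = cand$inconsistentPct < cfg$fusionMaxInconsistency,
    multimapping = cand$multimapFrac <= cfg$fusionMaxMultimapFrac)
  list(pass = all(breakdown), breakdown = breakdown)
}

#' Merge discordant-pair and split-read fusion evidence
#'
#' A candidate is high-confidence when a split-read junction links the same
#' gene pair with compatible breakpoints (pair positions 5' of the split
#' breakpoint within the library insert size), or when it passes the full
#' ranking on its own.
#'
#' @param candidates output of \code{clusterDiscordantPairs()}.
#' @param junctions classified event table (fusion categories) or the raw
#'   junction table annotated with geneL/geneR columns.
#' @param models a \code{TranscriptSet}.
#' @param cfg a \code{runConfig()} list.
#' @return candidates with \code{splitReadSupport}, \code{rankPass} and
#'   \code{highConfidence} columns.
#' @export
mergeFusionEvidence <- function(candidates, junctions, models,
                                cfg = runConfig()) {
  if (nrow(candidates) == 0) {
    candidates$splitReadSupport <- logical(0)
    candidates$rankPass <- logical(0)
    candidates$highConfidence <- logical(0)
    return(candidates)
  }
  supported <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ca <- candidates[i, ]
    for (k in seq_len(nrow(junctions))) {
      jw <- junctions[k, ]
      gpair <- sort(c(jw$geneL, jw$geneR))
      if (any(is.na(gpair))) next
      if (!identical(gpair, sort(c(ca$geneA, ca$geneB)))) next
      jA <- if (jw$geneL == ca$geneA) jw$posL else jw$posR
      jB <- if (jw$geneL == ca$geneA) jw$posR else jw$posL
      okA <- abs(ca$posA - jA) <= cfg$insertSize
      okB <- abs(ca$posB - jB) <= cfg$insertSize
      if (okA && okB) { supported[i] <- TRUE; break }
    }
  }
  rankPass <- vapply(seq_len(nrow(candidates)), function(i)
    rankFusionCandidate(candidates[i, ], cfg)$pass, logical(1))
  candidates$splitReadSupport <- supported
  candidates$rankPass <- rankPass
  candidates$highConfidence <- supported | rankPass
  candidates
}
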