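# Point-mutation expression analysis: genome vs transcriptome variant
# allele fractions, NMD-zone classification of nonsense mutations, and
# splice-position annotation.

#' Genomic and transcriptomic variant allele fractions
#'
#' VAF = alt / (ref + alt) per assay; a site is "expressed" when five or
#' more RNA-seq reads cover the base.  Zero RNA coverage leaves the
#' transcriptomic VAF undefined (NA) with expressed = FALSE; the record is
#' kept.
#' @param subs substitutions data.frame (see \code{readSubstitutions}).
#' @param cfg a \code{runConfig()} list.
#' @return the input with \code{vafGenome}, \code{vafTranscriptome},
#'   \code{vafDiff}, \code{rnaCoverage}, \code{expressed} columns.
#' @export
computeVaf <- function(subs, cfg = runConfig()) {
  stopifnot(all(subs$dnaRef >= 0), all(subs$dnaAlt >= 0),
            all(subs$rnaRef >= 0), all(subs$rnaAlt >= 0))
  dnaCov <- subs$dnaRef + subs$dnaAlt
  rnaCov <- subs$rnaRef + subs$rnaAlt
  vg <- ifelse(dnaCov > 0, subs$dnaAlt / dnaCov, NA_real_)
  vt <- ifelse(rnaCov > 0, subs$rnaAlt / rnaCov, NA_real_)
  subs$vafGenome <- vg
  subs$vafTranscriptome <- vt
  subs$vafDiff <- vt - vg
  subs$rnaCoverage <- rnaCov
  subs$expressed <- rnaCov >= cfg$expressionMinReads
  subs
}

#' NMD-zone classification of a nonsense mutation
#'
#' A premature stop is in the nonsense-mediated-decay target zone when it
#' lies more than \code{nmdDistance} bp (default 50, configurable up to the
#' mechanistic 50-55 window) upstream of the last exon-exon junction in
#' transcript coordinates; stops in the last exon (or in single-exon
#' transcripts) escape.  Transcript choice: canonical = longest CDS among
#' the gene's isoforms unless \code{txId} is given; isoforms sharing the
#' last junction agree by construction, and a differing isoform set flags
#' the call as ambiguous.
#'
#' @param sub one substitution row (needs contig, pos, consequence).
#' @param models a \code{TranscriptSet}.
#' @param txId optional transcript to use.
#' @param cfg a \code{runConfig()} list.
#' @return list(zone = "nmd_target_zone" | "nmd_escape_zone" |
#'   "not_applicable", distance, txId, ambiguous).
#' @export
classifyNmdZone <- function(sub, models, txId = NULL, cfg = runConfig()) {
  if (!identical(sub$consequence, "nonsense"))
    return(list(zone = "not_applicable", distance = NA_integer_,
                txId = NA_character_, ambiguous = FALSE))
  tt <- transcriptTable(models)
  cand <- tt[tt$contig == sub$contig, , drop = FALSE]
  inTx <- vapply(cand$txId, function(id) {
    e <- exonsOf(models, id)
    any(e$start <= sub$pos & sub$pos < e$end)
  }, logical(1))
  cand <- cand[inTx, , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(zone = "not_applicable", distance = NA_integer_,
                txId = NA_character_, ambiguous = FALSE))
  if (is.null(txId)) {
    cdsLen <- ifelse(is.na(cand$cdsStart), 0L, cand$cdsEnd - cand$cdsStart)
    txId <- cand$txId[order(-cdsLen)][1]
  }

  zoneFor <- function(id) {
    e <- exonsOf(models, id)
    if (nrow(e) < 2L) return(list(zone = "nmd_escape_zone", distance = NA))
    txPos <- .txLen5(e, if (e$strand[1] == "+") sub$pos else sub$pos + 1L)
    lastJunc <- sum(e$end[-nrow(e)] - e$start[-nrow(e)])
    dist <- lastJunc - txPos
    list(zone = if (dist > cfg$nmdDistance) "nmd_target_zone"
         else "nmd_escape_zone", distance = dist)
  }
  z <- zoneFor(txId)
  others <- setdiff(cand$txId, txId)
  amb <- any(vapply(others, function(id)
    zoneFor(id)$zone != z$zone, logical(1)))
  list(zone = z$zone, distance = z$distance, txId = txId, ambiguous = amb)
}

#' Splice-relative position of a substitution
#'
#' Intronic offsets are counted +1, +2, ... from the donor (first intronic
#' base after the exon) and -1, -2, ... back from the acceptor (last
#' intronic base before the exon); exonic positions are reported separately
#' with their distance to the nearest junction.  Ties resolve to the
#' nearest border.
#' @param sub one substitution row.
#' @param models a \code{TranscriptSet}.
#' @return list(label, intronic, distance, txId); label like "+2", "-1" or
#'   "exon".
#' @export
annotateSplicePosition <- function(sub, models) {
  tt <- transcriptTable(models)
  best <- NULL
  for (id in tt$txId[tt$contig == sub$contig]) {
    e <- exonsOf(models, id)
    e <- e[order(e$start), ]
    fpStart <- min(e$start); fpEnd <- max(e$end)
    if (sub$pos < fpStart || sub$pos >= fpEnd) next
    strand <- e$strand[1]
    inExon <- any(e$start <= sub$pos & sub$pos < e$end)
    if (inExon) {
      edges <- c(e$start, e$end)
      dist <- min(abs(sub$pos - edges), abs(sub$pos - (edges - 1L)))
      cand <- list(label = "exon", intronic = FALSE, distance = dist,
                   txId = id)
    } else {
      i <- which(utils::head(e$end, -1L) <= sub$pos &
                 sub$pos < e$start[-1L])[1]
      iStart <- e$end[i]; iEnd <- e$start[i + 1L]
      # genomic offsets from the two intron ends
      fromLeft <- sub$pos - iStart + 1L   # 1 = first intronic base (right of
      fromRight <- iEnd - sub$pos         # the left exon); 1 = last before
      if (strand == "+") {                # the right exon
        donorOff <- fromLeft; acceptorOff <- fromRight
      } else {
        donorOff <- fromRight; acceptorOff <- fromLeft
      }
      if (donorOff <= acceptorOff)
        cand <- list(label = sprintf("+%d", donorOff), intronic = TRUE,
                     distance = donorOff, txId = id)
      else
        cand <- list(label = sprintf("-%d", acceptorOff), intronic = TRUE,
                     distance = acceptorOff, txId = id)
    }
    if (is.null(best) || cand$distance < best$distance) best <- cand
  }
  if (is.null(best))
    return(list(label = NA_character_, intronic = NA, distance = NA,
                txId = NA_character_))
  best
}

#' Per-position aberrant-splice fraction table
#'
#' For each splice-relative position label, the fraction of mutations at
#' that position whose sample carries a linked abnormal splice isoform
#' (absent from the normal organoids), with an exact binomial confidence
#' interval.  The comparison baseline is intronic mutations more than
#' 100 bp from the nearest exon, labelled "deep_intron".
#'
#' @param muts data.frame with a \code{label} column (from
#'   \code{annotateSplicePosition}), \code{intronic}, \code{distance}, and
#'   a logical \code{linkedAberrantSplice} column.
#' @return data.frame(label, n, nLinked, fraction, lower, upper).
#' @export
spliceMutationAssociation <- function(muts) {
  lab <- ifelse(muts$intronic & muts$distance > 100, "deep_intron",
                muts$label)
  sp <- split(seq_len(nrow(muts)), lab)
  out <- lapply(names(sp), function(l) {
    ix <- sp[[l]]
    k <- sum(muts$linkedAberrantSplice[ix])
    n <- length(ix)
    bt <- stats::binom.test(k, n)
    data.frame(label = l, n = n, nLinked = k, fraction = k / n,
               lower = bt$conf.int[1], upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
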