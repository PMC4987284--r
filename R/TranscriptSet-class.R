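#' TranscriptSet: gene models against which "novel" is defined
#'
#' An S4 container for transcript annotation: per-exon genomic intervals in
#' the internal 0-based half-open convention, stored in transcription order
#' (5' to 3' along the transcript), plus per-transcript metadata including an
#' optional CDS span.  Everything downstream -- the split-read pre-filter,
#' the exon index, the event taxonomy, frame prediction and NMD-zone calls --
#' interrogates this object through its accessors.
#'
#' @slot exons data.frame with columns \code{geneId}, \code{txId},
#'   \code{biotype}, \code{contig}, \code{strand}, \code{exonRank} (1-based,
#'   transcription order), \code{start}, \code{end} (0-based half-open).
#' @slot transcripts data.frame with columns \code{geneId}, \code{txId},
#'   \code{biotype}, \code{contig}, \code{strand}, \code{cdsStart},
#'   \code{cdsEnd} (0-based half-open genomic span; NA when non-coding).
#' @export
setClass("TranscriptSet",
  representation(exons = "data.frame", transcripts = "data.frame"))

.validTranscriptSet <- function(object) {
  ex <- object@exons
  tx <- object@transcripts
  need <- c("geneId", "txId", "biotype", "contig", "strand",
            "exonRank", "start", "end")
  if (!all(need %in% names(ex)))
    return(paste("exons lacks columns:",
                 paste(setdiff(need, names(ex)), collapse = ", ")))
  if (any(ex$end <= ex$start))
    return("empty or inverted exon interval")
  if (!all(ex$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  ok <- c("protein_coding", "pseudogene", "processed_transcript")
  if (!all(ex$biotype %in% ok))
    return("biotype outside the supported set")
  for (id in unique(ex$txId)) {
    e <- ex[ex$txId == id, ]
    e <- e[order(e$exonRank), ]
    if (!identical(e$exonRank, seq_len(nrow(e))))
      return(paste("exonRank not 1..n for", id))
    gstart <- if (e$strand[1] == "+") e$start else rev(e$start)
    if (is.unsorted(gstart, strictly = TRUE) && nrow(e) > 1)
      return(paste("exons of", id, "not in transcription order"))
    o <- order(e$start)
    if (any(e$start[o][-1] < e$end[o][-nrow(e)]))
      return(paste("overlapping exons in", id))
    t <- tx[tx$txId == id, ]
    if (nrow(t) == 1 && !is.na(t$cdsStart)) {
      inExon <- any(t$cdsStart >= e$start & t$cdsStart < e$end)
      inExon2 <- any(t$cdsEnd > e$start & t$cdsEnd <= e$end)
      if (!inExon || !inExon2)
        return(paste("CDS of", id, "outside exon union"))
    }
  }
  TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#' @param exons,transcripts see the class slots.
#' @return a \code{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, transcripts) {
  methods::new("TranscriptSet",
               exons = as.data.frame(exons),
               transcripts = as.data.frame(transcripts))
}

#' @describeIn TranscriptSet exon table (transcription order)
#' @param x a \code{TranscriptSet}.
#' @export
exons <- function(x) x@exons

#' @describeIn TranscriptSet transcript metadata table
#' @export
transcriptTable <- function(x) x@transcripts

#' @describeIn TranscriptSet exons of one transcript, transcription order
#' @param txId transcript identifier.
#' @export
exonsOf <- function(x, txId) {
  e <- x@exons[x@exons$txId == txId, , drop = FALSE]
  if (nrow(e) == 0) stop("unknown transcript: ", txId)
  e[order(e$exonRank), , drop = FALSE]
}

setMethod("show", "TranscriptSet", function(object) {
  cat(sprintf("TranscriptSet: %d transcripts, %d genes, %d exons on %d contig(s)\n",
              nrow(object@transcripts),
              length(unique(object@transcripts$geneId)),
              nrow(object@exons),
              length(unique(object@exons$contig))))
})

#' Gene footprints
#'
#' The footprint of a gene is the strand-aware union span of its transcripts:
#' one interval per gene on its contig.
#' @param x a \code{TranscriptSet}.
#' @return data.frame(geneId, contig, strand, start, end).
#' @export
geneFootprints <- function(x) {
  ex <- x@exons
  sp <- split(ex, ex$geneId)
  out <- do.call(rbind, lapply(sp, function(e) {
    data.frame(geneId = e$geneId[1], contig = e$contig[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genes whose footprint contains a genomic position
#' @param x a \code{TranscriptSet}.
#' @param contig,pos 0-based genomic position.
#' @return character vector of gene ids (possibly length > 1 for overlapping
#'   genes, reported as ambiguous by callers).
#' @export
genesAt <- function(x, contig, pos) {
  fp <- geneFootprints(x)
  fp$geneId[fp$contig == contig & fp$start <= pos & pos < fp$end]
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented so the result reads 5' to 3'.
#' @param x a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param txId transcript id.
#' @return character DNA string.
#' @export
splicedSequence <- function(x, genome, txId) {
  e <- exonsOf(x, txId)
  parts <- vapply(seq_len(nrow(e)), function(i) {
    s <- genomeSlice(genome, e$contig[i], e$start[i], e$end[i])
    if (e$strand[i] == "-") revComp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}
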