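# Internal coordinate convention: 0-based half-open [start, end) on the
# forward genome strand.  All text formats keep their native conventions
# (GTF/VCF 1-based inclusive, BEDPE 0-based half-open); conversion happens
# only in the readers/writers.

#' Extract a genomic slice as a character string
#'
#' @param genome a named \code{DNAStringSet} (one entry per contig).
#' @param contig contig name.
#' @param start0,end0 0-based half-open interval.
#' @return character of length \code{end0 - start0}.
#' @export
genomeSlice <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome))
    stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (start0 < 0L || end0 > len || start0 > end0)
    stop(sprintf("slice [%d,%d) outside contig %s (length %d)",
                 start0, end0, contig, len))
  as.character(Biostrings::subseq(genome[[contig]], start0 + 1L, end0))
}

#' Reverse complement of a DNA string
#' @param x character DNA string.
#' @return character.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Base at a strand-aware transcript-direction offset
#'
#' For strand "+" returns the base at \code{pos} (0-based); for strand "-"
#' the complement of that base, so walking increasing transcript coordinates
#' corresponds to decreasing genomic coordinates handled by the caller.
#' @keywords internal
strandBase <- function(genome, contig, pos, strand) {
  b <- genomeSlice(genome, contig, pos, pos + 1L)
  if (strand == "-") chartr("ACGTN", "TGCAN", b) else b
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome named \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
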