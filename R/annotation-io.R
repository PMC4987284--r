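#' Read transcript annotation from GTF/GFF
#'
#' Parses exon and CDS records into a \code{TranscriptSet}.  Attribute names
#' are not assumed to be Ensembl's: \code{attrMap} maps the internal keys
#' \code{gene}, \code{transcript} and \code{biotype} onto the attribute keys
#' present in the file.  Coordinates are converted from the 1-based inclusive
#' GTF convention to the internal 0-based half-open one, and exons are sorted
#' into transcription order (reverse genomic order on the minus strand).
#'
#' @param path GTF/GFF file.
#' @param attrMap named character vector with entries \code{gene},
#'   \code{transcript}, \code{biotype}.
#' @return a \code{TranscriptSet}.
#' @export
readAnnotation <- function(path,
                           attrMap = c(gene = "gene_id",
                                       transcript = "transcript_id",
                                       biotype = "gene_biotype")) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("annotation parse error in ",
                                          path, ": ", conditionMessage(e)))
  md <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(key, default = NA_character_) {
    if (key %in% names(md)) as.character(md[[key]]) else
      rep(default, length(gr))
  }
  feat <- tolower(pick("type"))
  df <- data.frame(
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr) - 1L,   # -> 0-based half-open
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    feature = feat,
    geneId  = pick(attrMap[["gene"]]),
    txId    = pick(attrMap[["transcript"]]),
    biotype = pick(attrMap[["biotype"]], "protein_coding"),
    stringsAsFactors = FALSE)
  df$biotype[is.na(df$biotype)] <- "protein_coding"
  exdf <- df[df$feature == "exon", , drop = FALSE]
  if (nrow(exdf) == 0) stop("no exon records in ", path)
  if (any(is.na(exdf$geneId)) || any(is.na(exdf$txId)))
    stop("exon records lacking gene/transcript identifiers in ", path)

  exl <- lapply(split(exdf, exdf$txId), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    e$exonRank <- seq_len(nrow(e))
    e
  })
  ex <- do.call(rbind, exl)
  rownames(ex) <- NULL

  cdsdf <- df[df$feature == "cds", , drop = FALSE]
  txIds <- unique(ex$txId)
  tx <- do.call(rbind, lapply(txIds, function(id) {
    e <- ex[ex$txId == id, ][1, ]
    cd <- cdsdf[cdsdf$txId == id, , drop = FALSE]
    data.frame(geneId = e$geneId, txId = id, biotype = e$biotype,
               contig = e$contig, strand = e$strand,
               cdsStart = if (nrow(cd)) min(cd$start) else NA_integer_,
               cdsEnd = if (nrow(cd)) max(cd$end) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(tx) <- NULL
  TranscriptSet(ex[, c("geneId", "txId", "biotype", "contig", "strand",
                       "exonRank", "start", "end")], tx)
}

#' Write a TranscriptSet as GTF
#'
#' Emits exon records (and CDS spans when present) with gene_id,
#' transcript_id and gene_biotype attributes; coordinates go back to the
#' 1-based inclusive GTF convention.  \code{readAnnotation(writeAnnotation(x))}
#' is lossless for every field the container carries.
#' @param x a \code{TranscriptSet}.
#' @param path output file.
#' @export
writeAnnotation <- function(x, path) {
  ex <- exons(x)
  tx <- transcriptTable(x)
  att <- function(g, t, b)
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', g, t, b)
  lines <- sprintf("%s\tSomaticTx\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$contig, ex$start + 1L, ex$end, ex$strand,
                   att(ex$geneId, ex$txId, ex$biotype))
  cds <- tx[!is.na(tx$cdsStart), , drop = FALSE]
  if (nrow(cds))
    lines <- c(lines,
               sprintf("%s\tSomaticTx\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                       cds$contig, cds$cdsStart + 1L, cds$cdsEnd,
                       cds$strand, att(cds$geneId, cds$txId, cds$biotype)))
  writeLines(lines, path)
  invisible(path)
}

#' Read somatic rearrangements from BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2
#' [type].  Breakpoint positions are taken as start1/start2 (0-based); the
#' strand columns carry breakpoint orientation.
#' @param path BEDPE file.
#' @return data.frame(id, contigA, posA, orientA, contigB, posB, orientB, type).
#' @export
readBedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 10) stop("BEDPE needs >= 10 columns: ", path)
  out <- data.frame(id = as.character(d[[7]]),
                    contigA = as.character(d[[1]]), posA = as.integer(d[[2]]),
                    orientA = as.character(d[[9]]),
                    contigB = as.character(d[[4]]), posB = as.integer(d[[5]]),
                    orientB = as.character(d[[10]]),
                    type = if (ncol(d) >= 11) as.character(d[[11]])
                           else NA_character_,
                    stringsAsFactors = FALSE)
  out
}

#' Write rearrangements as BEDPE
#' @param r data.frame as returned by \code{readBedpe}.
#' @param path output file.
#' @export
writeBedpe <- function(r, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t%s\t%s\t%s",
                   r$contigA, r$posA, r$posA + 1L,
                   r$contigB, r$posB, r$posB + 1L,
                   r$id, r$orientA, r$orientB,
                   ifelse(is.na(r$type), ".", r$type))
  writeLines(lines, path)
  invisible(path)
}

#' Read somatic substitutions with DNA/RNA allele depths
#'
#' Accepts a VCF whose INFO field carries \code{DNA_AD=ref,alt;RNA_AD=ref,alt}
#' and optionally \code{CSQ=consequence}, or a TSV with columns
#' contig, pos (1-based), ref, alt, dnaRef, dnaAlt, rnaRef, rnaAlt,
#' consequence.  Positions are converted to 0-based.
#' @param path VCF (.vcf) or TSV file.
#' @return data.frame(contig, pos, ref, alt, dnaRef, dnaAlt, rnaRef, rnaAlt,
#'   consequence).
#' @export
readSubstitutions <- function(path) {
  if (grepl("\\.vcf$", path)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    grab <- function(info, key) {
      m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
             character(1))
    }
    info <- vapply(f, `[[`, character(1), 8)
    dna <- strsplit(grab(info, "DNA_AD"), ",")
    rna <- strsplit(grab(info, "RNA_AD"), ",")
    out <- data.frame(
      contig = vapply(f, `[[`, character(1), 1),
      pos = as.integer(vapply(f, `[[`, character(1), 2)) - 1L,
      ref = vapply(f, `[[`, character(1), 4),
      alt = vapply(f, `[[`, character(1), 5),
      dnaRef = as.integer(vapply(dna, `[`, character(1), 1)),
      dnaAlt = as.integer(vapply(dna, `[`, character(1), 2)),
      rnaRef = as.integer(vapply(rna, `[`, character(1), 1)),
      rnaAlt = as.integer(vapply(rna, `[`, character(1), 2)),
      consequence = grab(info, "CSQ"),
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    out$pos <- out$pos - 1L
  }
  bad <- nchar(out$ref) != 1 | nchar(out$alt) != 1 | out$ref == out$alt
  if (any(bad)) stop("non-SNV or degenerate substitution record(s)")
  out
}

#' Write substitutions as a minimal VCF
#' @param subs data.frame as from \code{readSubstitutions}.
#' @param path output file.
#' @export
writeSubstitutions <- function(subs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DNA_AD,Number=2,Type=Integer,Description=\"DNA ref,alt depths\">",
           "##INFO=<ID=RNA_AD,Number=2,Type=Integer,Description=\"RNA ref,alt depths\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDNA_AD=%d,%d;RNA_AD=%d,%d;CSQ=%s",
                  subs$contig, subs$pos + 1L, subs$ref, subs$alt,
                  subs$dnaRef, subs$dnaAlt, subs$rnaRef, subs$rnaAlt,
                  subs$consequence)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify the gene context of rearrangement breakpoints
#'
#' Each genic rearrangement receives exactly one context label; intergenic
#' events on both sides receive none (NA).  A gene footprint hit by two or
#' more rearrangements marks all of its rearrangements as
#' \code{local_complexity}.  Overlapping genes make a breakpoint ambiguous:
#' the first gene (by id) is used for labelling and the \code{ambiguous} flag
#' is set.
#'
#' @param rearr data.frame of rearrangements (see \code{readBedpe}).
#' @param models a \code{TranscriptSet}.
#' @return data.frame(id, context, geneA, geneB, ambiguous).
#' @export
classifyRearrangementContext <- function(rearr, models) {
  fp <- geneFootprints(models)
  hit <- function(contig, pos) {
    if (!contig %in% c(fp$contig, exons(models)$contig))
      stop("breakpoint on unknown contig: ", contig)
    fp[fp$contig == contig & fp$start <= pos & pos < fp$end, , drop = FALSE]
  }
  gA <- lapply(seq_len(nrow(rearr)),
               function(i) hit(rearr$contigA[i], rearr$posA[i]))
  gB <- lapply(seq_len(nrow(rearr)),
               function(i) hit(rearr$contigB[i], rearr$posB[i]))

  # count rearrangements per footprint for the local-complexity rule
  hits <- table(unlist(lapply(seq_len(nrow(rearr)), function(i)
    unique(c(gA[[i]]$geneId, gB[[i]]$geneId)))))
  complexGenes <- names(hits)[hits >= 2]

  intronOf <- function(gene, contig, pos) {
    # index of the intron containing pos in the gene's first transcript,
    # NA when pos falls in an exon
    txs <- transcriptTable(models)
    id <- txs$txId[txs$geneId == gene][1]
    e <- exonsOf(models, id)
    e <- e[order(e$start), ]
    if (any(e$start <= pos & pos < e$end)) return(NA_integer_)
    which(utils::head(e$end, -1) <= pos & pos < e$start[-1])[1]
  }

  # orientation convention: "+" = the retained segment lies at lower genomic
  # coordinates than the breakpoint, "-" = at higher coordinates.  A break
  # keeps the gene's 5' portion when retained-side and gene strand agree.
  keep5 <- function(strand, orient) {
    (strand == "+" && orient == "+") || (strand == "-" && orient == "-")
  }

  out <- lapply(seq_len(nrow(rearr)), function(i) {
    a <- gA[[i]]; b <- gB[[i]]
    amb <- nrow(a) > 1 || nrow(b) > 1
    geneA <- if (nrow(a)) sort(a$geneId)[1] else NA_character_
    geneB <- if (nrow(b)) sort(b$geneId)[1] else NA_character_
    isComplex <- (!is.na(geneA) && geneA %in% complexGenes) ||
                 (!is.na(geneB) && geneB %in% complexGenes)
    ctx <- if (is.na(geneA) && is.na(geneB)) {
      NA_character_
    } else if (isComplex) {
      "local_complexity"
    } else if (!is.na(geneA) && !is.na(geneB) && geneA == geneB) {
      iA <- intronOf(geneA, rearr$contigA[i], rearr$posA[i])
      iB <- intronOf(geneA, rearr$contigB[i], rearr$posB[i])
      if (!is.na(iA) && !is.na(iB) && iA == iB) "within_single_intron"
      else "cross_intron_same_gene"
    } else if (!is.na(geneA) && !is.na(geneB)) {
      sA <- a$strand[a$geneId == geneA][1]
      sB <- b$strand[b$geneId == geneB][1]
      k5A <- keep5(sA, rearr$orientA[i])
      k5B <- keep5(sB, rearr$orientB[i])
      if (k5A && k5B) "gene_gene_5to5"
      else if (!k5A && !k5B) "gene_gene_3to3"
      else "gene_gene_same_orientation"
    } else {
      gene <- if (!is.na(geneA)) geneA else geneB
      s <- if (!is.na(geneA)) a$strand[a$geneId == gene][1]
           else b$strand[b$geneId == gene][1]
      orient <- if (!is.na(geneA)) rearr$orientA[i] else rearr$orientB[i]
      if (keep5(s, orient)) "gene_to_intergenic_5" else "gene_to_intergenic_3"
    }
    data.frame(id = rearr$id[i], context = ctx, geneA = geneA, geneB = geneB,
               ambiguous = amb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
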