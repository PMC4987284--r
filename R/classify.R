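# Event taxonomy.
#
# Junctions from the split-read mapper are arranged into biologically
# meaningful categories: exon skips and exon reusages (same transcript,
# non-adjacent exons, 5'->3' vs 3'->5'), alternative donors/acceptors
# (edge offsets with canonical GT-AG context), premature polyadenylation
# (non-templated A runs), and fusion subclasses by gene orientation, with
# reading-frame prediction and a novelty filter against both the annotation
# and a normal-organoid junction background.

.txLen5 <- function(e, pos) {
  # transcript length 5' of a genomic boundary (e: exons in tx order)
  if (e$strand[1] == "+") sum(pmax(0L, pmin(e$end, pos) - e$start))
  else sum(pmax(0L, e$end - pmax(e$start, pos)))
}

.edgeOffset <- function(e, pos, role) {
  # signed offset of a junction edge from the nearest canonical exon edge;
  # positive = shifted into the intron (exon extension), negative = inside
  # the exon (cryptic reduction); returns (exonRank, offset)
  canon <- if (role == "donor") {
    if (e$strand[1] == "+") e$end else e$start
  } else {
    if (e$strand[1] == "+") e$start else e$end
  }
  off <- if (e$strand[1] == "+") {
    if (role == "donor") pos - canon else canon - pos
  } else {
    if (role == "donor") canon - pos else pos - canon
  }
  i <- which.min(abs(off))
  c(rank = e$exonRank[i], offset = off[i])
}

.annotatedJunction <- function(models, j) {
  # is the junction an adjacent-exon splice of some annotated transcript?
  for (id in transcriptTable(models)$txId) {
    e <- exonsOf(models, id)
    if (e$strand[1] != j$strandL || e$strand[1] != j$strandR) next
    if (e$contig[1] != j$contigL) next
    for (i in seq_len(nrow(e) - 1L)) {
      dPos <- if (e$strand[1] == "+") e$end[i] else e$start[i]
      aPos <- if (e$strand[1] == "+") e$start[i + 1L] else e$end[i + 1L]
      if (dPos == j$posL && aPos == j$posR) return(TRUE)
    }
  }
  FALSE
}

#' Junction -> organoid-background count table
#'
#' Runs the key-normalised read counts of a mapper result into the named
#' vector the novelty filter consumes (junction keys and premature-polyA
#' keys).
#' @param mapResult result of \code{callJunctions()} on normal-sample reads.
#' @return named integer vector.
#' @export
organoidBackground <- function(mapResult) {
  out <- integer(0)
  jt <- mapResult$junctions
  if (nrow(jt)) {
    keys <- vapply(seq_len(nrow(jt)), function(i)
      junctionKey(as.list(jt[i, ])), character(1))
    out <- stats::setNames(jt$nFwd + jt$nRev, keys)
  }
  pt <- mapResult$polyA
  if (nrow(pt)) {
    keys <- paste(pt$contig, pt$pos, pt$sense, "polyA", sep = ":")
    out <- c(out, stats::setNames(pt$nFwd + pt$nRev, keys))
  }
  out
}

#' Predict the reading frame of a fusion junction
#'
#' Computes the cumulative CDS length 5' of the breakpoint in the donor
#' transcript and the codon phase entering the acceptor transcript's CDS at
#' its breakpoint; the fusion is in frame when the two phases agree mod 3.
#' Breakpoints in UTR give \code{utr_involved} (flagged potentially
#' productive when the acceptor retains its own translation start);
#' non-coding partners give \code{noncoding}.
#'
#' @param models a \code{TranscriptSet}.
#' @param txA,posA donor transcript id and its junction boundary (genomic).
#' @param txB,posB acceptor transcript id and boundary.
#' @return list(frame, potentiallyProductive).
#' @export
predictFrame <- function(models, txA, posA, txB, posB) {
  tt <- transcriptTable(models)
  rows <- tt[match(c(txA, txB), tt$txId), ]
  if (any(is.na(rows$txId))) stop("unknown transcript")
  if (any(rows$biotype != "protein_coding"))
    return(list(frame = "noncoding", potentiallyProductive = FALSE))
  if (any(is.na(rows$cdsStart)))
    stop("protein_coding transcript lacks an annotated CDS")

  side <- function(tx, pos) {
    e <- exonsOf(models, tx)
    t <- tt[tt$txId == tx, ]
    len5 <- .txLen5(e, pos)
    cdsLo <- if (e$strand[1] == "+") t$cdsStart else t$cdsEnd
    cdsHi <- if (e$strand[1] == "+") t$cdsEnd else t$cdsStart
    cdsTxStart <- .txLen5(e, cdsLo)
    cdsTxEnd <- .txLen5(e, cdsHi)
    list(len5 = len5, cdsTxStart = cdsTxStart, cdsTxEnd = cdsTxEnd,
         inUtr5 = len5 <= cdsTxStart, inUtr3 = len5 >= cdsTxEnd,
         cdsLen5 = min(max(len5 - cdsTxStart, 0L), cdsTxEnd - cdsTxStart))
  }
  A <- side(txA, posA)
  B <- side(txB, posB)
  if (A$inUtr5 || A$inUtr3 || B$inUtr5 || B$inUtr3) {
    return(list(frame = "utr_involved",
                potentiallyProductive = A$inUtr5 && B$inUtr5))
  }
  list(frame = if ((A$cdsLen5 - B$cdsLen5) %% 3L == 0L) "in_frame"
       else "out_of_frame",
       potentiallyProductive = FALSE)
}

#' Classify a premature polyadenylation candidate
#'
#' A polyA event is accepted when the A run is non-templated (the genome
#' does not continue with an A run past the junction in transcript sense),
#' the junction lies inside an exon of a protein-coding gene, and it sits
#' more than \code{polyAMinDistance} bp away from the canonical 3' edge of
#' the transcript.  Accepted events are subclassified into coding-exon vs
#' UTR by the CDS span.
#'
#' @param p one row of the mapper's polyA table.
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param cfg a \code{runConfig()} list.
#' @return list(accepted, reason, gene, txId, subclass, distance).
#' @export
detectEarlyPolyA <- function(p, models, genome, cfg = runConfig()) {
  run <- cfg$polyAMinRun
  clen <- length(genome[[p$contig]])
  templated <- if (p$sense == "+") {
    p$pos + run <= clen &&
      genomeSlice(genome, p$contig, p$pos, p$pos + run) == strrep("A", run)
  } else {
    p$pos - run >= 0L &&
      genomeSlice(genome, p$contig, p$pos - run, p$pos) == strrep("T", run)
  }
  if (templated)
    return(list(accepted = FALSE, reason = "templated A-run"))

  fp <- geneFootprints(models)
  fp <- fp[fp$contig == p$contig & fp$strand == p$sense &
           fp$start <= p$pos & p$pos < fp$end, , drop = FALSE]
  if (nrow(fp) == 0)
    return(list(accepted = FALSE, reason = "no same-sense gene at junction"))
  gene <- sort(fp$geneId)[1]
  tt <- transcriptTable(models)
  txs <- tt[tt$geneId == gene, ]
  if (all(txs$biotype != "protein_coding"))
    return(list(accepted = FALSE, reason = "gene not protein_coding"))
  tx <- txs[txs$biotype == "protein_coding", ][1, ]
  e <- exonsOf(models, tx$txId)
  inExon <- any(e$start < p$pos & p$pos <= e$end)
  if (!inExon)
    return(list(accepted = FALSE, reason = "junction not exonic"))
  dist <- if (p$sense == "+") max(e$end) - p$pos else p$pos - min(e$start)
  if (dist <= cfg$polyAMinDistance)
    return(list(accepted = FALSE,
                reason = sprintf("within %d bp of canonical edge",
                                 cfg$polyAMinDistance)))
  subclass <- if (is.na(tx$cdsStart)) "utr"
  else if (p$sense == "+" && p$pos > tx$cdsEnd) "utr"
  else if (p$sense == "-" && p$pos < tx$cdsStart) "utr"
  else "coding_exon"
  list(accepted = TRUE, reason = NA_character_, gene = gene,
       txId = tx$txId, subclass = subclass, distance = dist)
}

.matchGeneToIntergenic <- function(j, geneL, models, rearr,
                                   scanWindow = 300000L) {
  # a gene-to-intergenic rearrangement explains the junction when its genic
  # breakpoint keeps the 5' portion of the donor gene and the RNA acceptor
  # lies downstream of the intergenic DNA breakpoint within scan range
  if (is.null(rearr) || is.na(geneL)) return(NULL)
  fp <- geneFootprints(models)
  inGene <- function(contig, pos, gene) {
    r <- fp[fp$geneId == gene, ]
    r$contig == contig & r$start <= pos & pos < r$end
  }
  anyGene <- function(contig, pos)
    any(fp$contig == contig & fp$start <= pos & pos < fp$end)
  strandOf <- function(gene) fp$strand[fp$geneId == gene]
  keep5 <- function(strand, orient) {
    (strand == "+" && orient == "+") || (strand == "-" && orient == "-")
  }
  for (i in seq_len(nrow(rearr))) {
    for (swap in c(FALSE, TRUE)) {
      gc <- if (swap) rearr$contigB[i] else rearr$contigA[i]
      gp <- if (swap) rearr$posB[i] else rearr$posA[i]
      go <- if (swap) rearr$orientB[i] else rearr$orientA[i]
      ic <- if (swap) rearr$contigA[i] else rearr$contigB[i]
      ip <- if (swap) rearr$posA[i] else rearr$posB[i]
      if (!inGene(gc, gp, geneL)) next
      if (anyGene(ic, ip)) next
      if (!keep5(strandOf(geneL), go)) next
      if (ic != j$contigR) next
      if (j$posR <= ip || j$posR - ip > scanWindow) next
      return(list(rearrId = rearr$id[i], breakpointIntergenic = ip,
                  breakpointGenic = gp))
    }
  }
  NULL
}

#' Classify one junction event
#'
#' Applies the novelty filter (fewer than two normal-organoid reads, no
#' annotated transcript explaining the junction) and then the decision
#' tree: same-transcript non-adjacent exons become exon skips (5'->3') or
#' exon reusages (3'->5'), each subcategorised by canonical vs cryptic
#' edges; adjacent exons with a shifted GT-AG edge become alternative
#' donors/acceptors; two genes become fusion subclasses by sense, with a
#' supplied rearrangement table routing gene-to-intergenic splices; exon
#' skips and reusages additionally require at least one forward and one
#' reverse split read.
#'
#' @param j one row of the mapper's junction table (data.frame or list).
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param organoid named count vector from \code{organoidBackground()}.
#' @param cfg a \code{runConfig()} list.
#' @param rearr optional rearrangement data.frame (see \code{readBedpe}).
#' @return one-row data.frame of the classified (or rejected) event.
#' @export
classifyJunction <- function(j, models, genome, organoid = integer(0),
                             cfg = runConfig(), rearr = NULL) {
  j <- as.list(j)
  base <- data.frame(
    contigL = j$contigL, posL = j$posL, strandL = j$strandL,
    contigR = j$contigR, posR = j$posR, strandR = j$strandR,
    nFwd = j$nFwd, nRev = j$nRev,
    category = NA_character_, accepted = FALSE, reason = NA_character_,
    geneL = NA_character_, geneR = NA_character_, txId = NA_character_,
    canonicalEdges = NA, crypticSide = NA_character_,
    exonsLost = NA_integer_, exonsReused = NA_integer_,
    frame = NA_character_, potentiallyProductive = NA,
    exonEntry = NA_integer_, novelExon = NA,
    createdIntronLength = NA_integer_, reciprocal = FALSE,
    stringsAsFactors = FALSE)
  reject <- function(reason) { base$reason <- reason; base }
  accept <- function(category, ...) {
    upd <- list(...)
    base$category <- category; base$accepted <- TRUE
    for (nm in names(upd)) base[[nm]] <- upd[[nm]]
    base
  }

  key <- junctionKey(j)
  if (key %in% names(organoid) && organoid[[key]] >= cfg$organoidMaxReads)
    return(reject("seen in normal organoids"))
  if (.annotatedJunction(models, j))
    return(reject("annotated splice junction"))

  fp <- geneFootprints(models)
  hitsL <- fp[fp$contig == j$contigL & fp$start <= j$posL &
              j$posL < fp$end, , drop = FALSE]
  hitsR <- fp[fp$contig == j$contigR & fp$start <= j$posR &
              j$posR < fp$end, , drop = FALSE]
  if (nrow(hitsL) == 0 && nrow(hitsR) == 0)
    return(reject("intergenic-both-sides"))

  tt <- transcriptTable(models)
  maxEdge <- 50L

  # same-gene path: a transcript on the junction strand covering both loci
  sameGenes <- intersect(hitsL$geneId[hitsL$strand == j$strandL],
                         hitsR$geneId[hitsR$strand == j$strandR])
  if (j$strandL == j$strandR && length(sameGenes)) {
    cands <- list()
    for (id in tt$txId[tt$geneId %in% sameGenes &
                       tt$strand == j$strandL]) {
      e <- exonsOf(models, id)
      d <- .edgeOffset(e, j$posL, "donor")
      a <- .edgeOffset(e, j$posR, "acceptor")
      if (abs(d[["offset"]]) > maxEdge || abs(a[["offset"]]) > maxEdge) next
      cands[[length(cands) + 1L]] <- list(tx = id, d = d, a = a)
    }
    if (length(cands)) {
      # annotate to the transcript that minimises exons lost
      span <- vapply(cands, function(cc)
        abs(cc$a[["rank"]] - cc$d[["rank"]]), numeric(1))
      cc <- cands[[order(span)[1]]]
      iD <- cc$d[["rank"]]; offD <- cc$d[["offset"]]
      iA <- cc$a[["rank"]]; offA <- cc$a[["offset"]]
      canonical <- offD == 0L && offA == 0L
      cryptic <- if (canonical) NA_character_
                 else if (offD != 0L) "5p" else "3p"
      gene <- tt$geneId[tt$txId == cc$tx]
      if (iA == iD + 1L) {
        if (canonical) return(reject("annotated splice junction"))
        if (!isCanonicalSplice(j))
          return(reject("alternative donor/acceptor without GT-AG"))
        return(accept(if (offD != 0L) "alt_donor" else "alt_acceptor",
                      geneL = gene, geneR = gene, txId = cc$tx,
                      canonicalEdges = FALSE, crypticSide = cryptic))
      }
      if (j$nFwd < 1L || j$nRev < 1L)
        return(reject("requires a forward and a reverse split read"))
      if (iA > iD + 1L)
        return(accept("exon_skip", geneL = gene, geneR = gene, txId = cc$tx,
                      canonicalEdges = canonical, crypticSide = cryptic,
                      exonsLost = iA - iD - 1L))
      return(accept("exon_reusage", geneL = gene, geneR = gene, txId = cc$tx,
                    canonicalEdges = canonical, crypticSide = cryptic,
                    exonsReused = iD - iA + 1L))
    }
  }

  # two-gene / intergenic path
  pickGene <- function(hits, strand) {
    if (nrow(hits) == 0) return(list(gene = NA_character_, sense = NA))
    m <- hits[hits$strand == strand, , drop = FALSE]
    if (nrow(m)) list(gene = sort(m$geneId)[1], sense = TRUE)
    else list(gene = sort(hits$geneId)[1], sense = FALSE)
  }
  gl <- pickGene(hitsL, j$strandL)
  gr <- pickGene(hitsR, j$strandR)

  g2i <- .matchGeneToIntergenic(j, gl$gene, models, rearr)
  if (!is.null(g2i) && isTRUE(gl$sense)) {
    entry <- NA_integer_; novel <- TRUE
    if (!is.na(gr$gene) && isTRUE(gr$sense)) {
      for (id in tt$txId[tt$geneId == gr$gene]) {
        e <- exonsOf(models, id)
        aPos <- if (e$strand[1] == "+") e$start else e$end
        hit <- which(aPos == j$posR)
        if (length(hit)) { entry <- e$exonRank[hit[1]]; novel <- FALSE; break }
      }
    }
    return(accept("gene_to_intergenic_fusion",
                  geneL = gl$gene, geneR = gr$gene,
                  exonEntry = entry, novelExon = novel,
                  # RNA intron spans donor -> DNA break, then the joined
                  # intergenic stretch up to the splice acceptor
                  createdIntronLength =
                    abs(g2i$breakpointGenic - j$posL) +
                    abs(j$posR - g2i$breakpointIntergenic)))
  }

  if (is.na(gl$gene) || is.na(gr$gene))
    return(reject(if (is.na(gl$gene)) "no gene at left locus"
                  else "no gene at right locus"))

  cat <- if (isTRUE(gl$sense) && isTRUE(gr$sense)) "fusion_same_orientation"
  else if (isTRUE(gl$sense) && !isTRUE(gr$sense)) "fusion_5to5_antisense"
  else "fusion_3to3"

  frame <- NA_character_; pp <- NA
  if (cat == "fusion_same_orientation") {
    txL <- tt$txId[tt$geneId == gl$gene & tt$biotype == "protein_coding"]
    txR <- tt$txId[tt$geneId == gr$gene & tt$biotype == "protein_coding"]
    if (length(txL) && length(txR)) {
      fr <- predictFrame(models, txL[1], j$posL, txR[1], j$posR)
      frame <- fr$frame; pp <- fr$potentiallyProductive
    } else frame <- "noncoding"
  }
  accept(cat, geneL = gl$gene, geneR = gr$gene, frame = frame,
         potentiallyProductive = pp)
}

#' Classify every junction and polyA candidate of a mapper run
#'
#' Driver over \code{classifyJunction()} and \code{detectEarlyPolyA()};
#' reciprocal 5'-to-5' antisense pairs (both promoters active) are flagged.
#'
#' @param mapResult result of \code{callJunctions()}.
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param organoid named count vector from \code{organoidBackground()}.
#' @param cfg a \code{runConfig()} list.
#' @param rearr optional rearrangement table.
#' @return data.frame of classified events (accepted and rejected rows).
#' @export
classifyEvents <- function(mapResult, models, genome,
                           organoid = integer(0), cfg = runConfig(),
                           rearr = NULL) {
  rows <- list()
  jt <- mapResult$junctions
  for (i in seq_len(nrow(jt)))
    rows[[length(rows) + 1L]] <-
      classifyJunction(jt[i, ], models, genome, organoid, cfg, rearr)
  pt <- mapResult$polyA
  for (i in seq_len(nrow(pt))) {
    p <- as.list(pt[i, ])
    key <- paste(p$contig, p$pos, p$sense, "polyA", sep = ":")
    if (key %in% names(organoid) &&
        organoid[[key]] >= cfg$organoidMaxReads) {
      res <- list(accepted = FALSE, reason = "seen in normal organoids")
    } else {
      res <- detectEarlyPolyA(p, models, genome, cfg)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contigL = p$contig, posL = p$pos, strandL = p$sense,
      contigR = NA_character_, posR = NA_integer_, strandR = NA_character_,
      nFwd = p$nFwd, nRev = p$nRev,
      category = if (isTRUE(res$accepted)) "early_polyA" else NA_character_,
      accepted = isTRUE(res$accepted), reason = res$reason,
      geneL = if (isTRUE(res$accepted)) res$gene else NA_character_,
      geneR = NA_character_,
      txId = if (isTRUE(res$accepted)) res$txId else NA_character_,
      canonicalEdges = NA, crypticSide = NA_character_,
      exonsLost = NA_integer_, exonsReused = NA_integer_,
      frame = NA_character_, potentiallyProductive = NA,
      exonEntry = NA_integer_,
      novelExon = NA,
      createdIntronLength = NA_integer_, reciprocal = FALSE,
      stringsAsFactors = FALSE)
    if (isTRUE(res$accepted))
      rows[[length(rows)]]$crypticSide <- res$subclass
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # reciprocal 5'-to-5' pairs
  anti <- which(out$accepted & out$category == "fusion_5to5_antisense")
  if (length(anti) > 1L) {
    for (i in anti) for (k in anti) {
      if (i != k && out$geneL[i] == out$geneR[k] &&
          out$geneR[i] == out$geneL[k])
        out$reciprocal[c(i, k)] <- TRUE
    }
  }
  out
}

#' Delimit novel antisense exons under 5'-to-5' fusion events
#'
#' Builds per-base read depth over the antisense gene footprint from the
#' contiguously mapping reads the transcriptome cannot explain, and reports
#' maximal runs of depth >= \code{antisenseMinDepth} as novel antisense
#' exons, with strand-aware GT-AG concordance flags at both edges and the
#' plateau's maximum depth as a recurrence measure.
#'
#' @param events classified event table (only fusion_5to5_antisense rows
#'   are used).
#' @param placements the \code{placements} element of \code{callJunctions()}.
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param cfg a \code{runConfig()} list.
#' @return data.frame(geneL, geneR, start, end, donorCanonical,
#'   acceptorCanonical, maxDepth); zero rows when no event has coverage.
#' @export
detectAntisenseExons <- function(events, placements, models, genome,
                                 cfg = runConfig()) {
  out <- list()
  fp <- geneFootprints(models)
  anti <- events[events$accepted &
                 events$category == "fusion_5to5_antisense", , drop = FALSE]
  for (i in seq_len(nrow(anti))) {
    ev <- anti[i, ]
    r <- fp[fp$geneId == ev$geneR, ]
    if (nrow(r) == 0) next
    width <- r$end - r$start
    depth <- integer(width)
    pl <- placements[placements$contig == r$contig &
                     placements$refStart >= r$start &
                     placements$refEnd <= r$end, , drop = FALSE]
    for (q in seq_len(nrow(pl))) {
      a <- pl$refStart[q] - r$start + 1L
      b <- pl$refEnd[q] - r$start
      depth[a:b] <- depth[a:b] + 1L
    }
    ok <- depth >= cfg$antisenseMinDepth
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    asStrand <- ev$strandR
    for (q in which(runs$values)) {
      s <- r$start + starts[q] - 1L
      e <- r$start + ends[q]
      if (asStrand == "-") {
        donorOK <- revComp(genomeSlice(genome, r$contig, s - 2L, s)) == "GT"
        accOK <- revComp(genomeSlice(genome, r$contig, e, e + 2L)) == "AG"
      } else {
        donorOK <- genomeSlice(genome, r$contig, e, e + 2L) == "GT"
        accOK <- genomeSlice(genome, r$contig, s - 2L, s) == "AG"
      }
      out[[length(out) + 1L]] <- data.frame(
        geneL = ev$geneL, geneR = ev$geneR, start = s, end = e,
        donorCanonical = donorOK, acceptorCanonical = accOK,
        maxDepth = max(depth[starts[q]:ends[q]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(geneL = character(0), geneR = character(0),
                      start = integer(0), end = integer(0),
                      donorCanonical = logical(0),
                      acceptorCanonical = logical(0),
                      maxDepth = integer(0)))
  do.call(rbind, out)
}
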