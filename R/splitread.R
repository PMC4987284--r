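# Seed-and-extend split-read mapper.
#
# Pipeline: pre-filter reads explained by the annotated transcriptome,
# shatter survivors into k-mers, exact-match the k-mers against a word index
# of all exon sequence, merge hits on common diagonals into fragments, grow
# fragments base by base into their unmapped neighbours until the breakpoint
# is resolved, and settle microhomology ambiguity with the GT-AG rule.

#' Shatter a read into k-mers
#'
#' Yields \code{floor(L / k)} k-mers of length \code{k} covering the 5'
#' portion plus, when a remainder exists, one short k-mer holding the 3' end
#' (the lowest-quality part of the read).  A 75-bp read at k = 13 gives five
#' 13-mers and one 10-mer.
#'
#' @param seq read sequence (character).
#' @param k k-mer size in bp (default 13).
#' @return data.frame(off, len) with 0-based read offsets; attribute
#'   \code{short} flags a read shorter than \code{k}.
#' @export
shatterRead <- function(seq, k = 13L) {
  L <- nchar(seq)
  if (L < k) {
    out <- data.frame(off = 0L, len = L)
    attr(out, "short") <- TRUE
    return(out)
  }
  m <- L %/% k
  off <- (seq_len(m) - 1L) * k
  len <- rep(k, m)
  r <- L - m * k
  if (r > 0L) {
    off <- c(off, L - r)
    len <- c(len, r)
  }
  out <- data.frame(off = as.integer(off), len = as.integer(len))
  attr(out, "short") <- FALSE
  out
}

#' Build the exon word index
#'
#' Hashes every \code{wordSize}-bp word of every distinct annotated exon to
#' its genomic position(s).  Exons shorter than the word size contribute no
#' words (warned once).
#'
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param wordSize word length in bp, >= 4 (default 9).
#' @return an exon index (opaque list with a lookup environment).
#' @export
buildExonIndex <- function(models, genome, wordSize = 9L) {
  stopifnot(wordSize >= 4L)
  ex <- exons(models)
  ux <- unique(ex[, c("contig", "start", "end")])
  env <- new.env(hash = TRUE, parent = emptyenv())
  nshort <- 0L
  for (i in seq_len(nrow(ux))) {
    s <- ux$start[i]; e <- ux$end[i]
    if (e - s < wordSize) { nshort <- nshort + 1L; next }
    seq <- genomeSlice(genome, ux$contig[i], s, e)
    n <- nchar(seq) - wordSize + 1L
    words <- substring(seq, 1:n, wordSize:nchar(seq))
    pos <- s + 0:(n - 1L)
    for (j in seq_len(n)) {
      w <- words[j]
      env[[w]] <- c(env[[w]], list(c(ux$contig[i], pos[j])))
    }
  }
  if (nshort > 0L)
    warning(nshort, " exon(s) shorter than the word size contribute no words")
  # dedupe positions shared by overlapping exon copies
  for (w in ls(env)) {
    m <- unique(do.call(rbind, env[[w]]))
    env[[w]] <- m
  }
  structure(list(wordSize = as.integer(wordSize), words = env),
            class = "ExonIndex")
}

#' Build a genome-wide word index
#'
#' Same structure as the exon index but over every position of every contig.
#' This is the index behind the relaxed retry of the clean step: fragments
#' that stay unmapped against annotated exon territory (for instance novel
#' antisense exons unmasked inside introns) are re-searched against the
#' whole genome with a shorter word.
#' @param genome named \code{DNAStringSet}.
#' @param wordSize word length in bp (default 7).
#' @return an exon-index-shaped object.
#' @export
buildGenomeIndex <- function(genome, wordSize = 7L) {
  stopifnot(wordSize >= 4L)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (contig in names(genome)) {
    seq <- as.character(genome[[contig]])
    n <- nchar(seq) - wordSize + 1L
    if (n < 1L) next
    words <- substring(seq, 1:n, wordSize:nchar(seq))
    for (j in seq_len(n)) {
      w <- words[j]
      env[[w]] <- c(env[[w]], list(c(contig, j - 1L)))
    }
  }
  for (w in ls(env)) env[[w]] <- unique(do.call(rbind, env[[w]]))
  structure(list(wordSize = as.integer(wordSize), words = env),
            class = "ExonIndex")
}

#' @export
print.ExonIndex <- function(x, ...) {
  cat(sprintf("ExonIndex: word size %d bp, %d distinct words\n",
              x$wordSize, length(ls(x$words))))
  invisible(x)
}

indexLookup <- function(index, word) {
  v <- index$words[[word]]
  if (is.null(v)) return(NULL)
  v
}

# exact-match k-mers of the read (both orientations) against the index;
# positions verified against the genome over the full k-mer, no mismatches
kmerScan <- function(seq, index, genome, k) {
  L <- nchar(seq)
  w <- index$wordSize
  scanOne <- function(s, strand) {
    km <- shatterRead(s, k)
    # complement the 5'-anchored grid with a 3'-anchored phase so that any
    # breakpoint leaving >= k bases on a side also leaves an intact k-mer
    # there, irrespective of its offset modulo k
    Ls <- nchar(s)
    if (Ls >= k) {
      rightOff <- Ls - k * seq_len(Ls %/% k)
      extra <- setdiff(rightOff, km$off)
      if (length(extra))
        km <- rbind(km, data.frame(off = as.integer(extra), len = k))
    }
    hits <- list()
    for (i in seq_len(nrow(km))) {
      off <- km$off[i]; len <- km$len[i]
      if (len < w) next
      kmer <- substr(s, off + 1L, off + len)
      cand <- indexLookup(index, substr(kmer, 1L, w))
      if (is.null(cand)) next
      for (j in seq_len(nrow(cand))) {
        contig <- cand[j, 1]
        p <- as.integer(cand[j, 2])
        clen <- length(genome[[contig]])
        if (p + len > clen) next
        if (genomeSlice(genome, contig, p, p + len) != kmer) next
        rs <- if (strand == "+") off else L - off - len
        hits[[length(hits) + 1L]] <- data.frame(
          readStart = rs, len = len, contig = contig, refStart = p,
          strand = strand, full = (len == k), stringsAsFactors = FALSE)
      }
    }
    hits
  }
  out <- c(scanOne(seq, "+"), scanOne(revComp(seq), "-"))
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

# merge hits sharing a diagonal into fragments
mergeHits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  diag <- ifelse(hits$strand == "+",
                 hits$refStart - hits$readStart,
                 hits$refStart + hits$len - 1L + hits$readStart)
  key <- paste(hits$contig, hits$strand, diag)
  sp <- split(hits, key)
  frags <- do.call(rbind, lapply(sp, function(h) {
    data.frame(readStart = min(h$readStart),
               readEnd = max(h$readStart + h$len),
               contig = h$contig[1],
               refStart = min(h$refStart),
               refEnd = max(h$refStart + h$len),
               strand = h$strand[1],
               nFull = sum(h$full),
               stringsAsFactors = FALSE)
  }))
  rownames(frags) <- NULL
  frags[order(frags$readStart, -frags$nFull), , drop = FALSE]
}

# genome coordinate a read position maps to under a fragment's diagonal
fragGpos <- function(frag, readPos) {
  if (frag$strand == "+") frag$refStart + (readPos - frag$readStart)
  else frag$refEnd - 1L - (readPos - frag$readStart)
}

# grow a fragment base by base into its unmapped neighbour; a mismatch is
# admitted only when preceded (in extension direction) by `perfectRun`
# matching bases, up to `maxMM` mismatches
extendFragment <- function(seq, frag, genome, direction,
                           maxMM = 2L, perfectRun = 2L) {
  L <- nchar(seq)
  clen <- length(genome[[frag$contig]])
  run <- perfectRun  # the seed itself is a perfect match
  mm <- integer(0)
  if (direction == "right") {
    i <- frag$readEnd
    while (i < L) {
      g <- fragGpos(frag, i)
      if (g < 0L || g >= clen) break
      b <- strandBase(genome, frag$contig, g, frag$strand)
      if (b == substr(seq, i + 1L, i + 1L)) {
        run <- run + 1L
      } else if (length(mm) < maxMM && run >= perfectRun) {
        mm <- c(mm, i); run <- 0L
      } else break
      i <- i + 1L
    }
    list(reach = i, mismatches = mm)
  } else {
    i <- frag$readStart - 1L
    while (i >= 0L) {
      g <- fragGpos(frag, i)
      if (g < 0L || g >= clen) break
      b <- strandBase(genome, frag$contig, g, frag$strand)
      if (b == substr(seq, i + 1L, i + 1L)) {
        run <- run + 1L
      } else if (length(mm) < maxMM && run >= perfectRun) {
        mm <- c(mm, i); run <- 0L
      } else break
      i <- i - 1L
    }
    list(reach = i + 1L, mismatches = mm)
  }
}

# --- junction representation ----------------------------------------------

flipStrand <- function(s) ifelse(s == "+", "-", "+")

junctionKey <- function(j) {
  paste(j$contigL, j$posL, j$strandL, j$contigR, j$posR, j$strandR,
        sep = ":")
}

flipJunction <- function(j) {
  list(contigL = j$contigR, posL = j$posR, strandL = flipStrand(j$strandR),
       contigR = j$contigL, posR = j$posL, strandR = flipStrand(j$strandL),
       donor = revComp(j$acceptor), acceptor = revComp(j$donor))
}

isCanonicalSplice <- function(j) j$donor == "GT" && j$acceptor == "AG"

# canonical representation: prefer GT-AG sense, then a '+' left strand,
# then the lexicographically smaller key
normalizeJunction <- function(j) {
  f <- flipJunction(j)
  pick <- if (isCanonicalSplice(j) && !isCanonicalSplice(f)) "j"
  else if (isCanonicalSplice(f) && !isCanonicalSplice(j)) "f"
  else if (j$strandL == "+" && f$strandL != "+") "j"
  else if (f$strandL == "+" && j$strandL != "+") "f"
  else if (junctionKey(j) <= junctionKey(f)) "j" else "f"
  if (pick == "j") list(junction = j, flipped = FALSE)
  else list(junction = f, flipped = TRUE)
}

# loci and splice dinucleotides of a concrete split position s
# (read coordinate at which the right side begins)
splitLoci <- function(Lf, Rf, s, genome) {
  dinuc <- function(contig, a, b, rc = FALSE) {
    clen <- length(genome[[contig]])
    if (a < 0L || b > clen) return("NN")
    d <- genomeSlice(genome, contig, a, b)
    if (rc) revComp(d) else d
  }
  if (Lf$strand == "+") {
    posL <- Lf$refStart + (s - Lf$readStart)
    donor <- dinuc(Lf$contig, posL, posL + 2L)
  } else {
    posL <- Lf$refEnd - (s - Lf$readStart)
    donor <- dinuc(Lf$contig, posL - 2L, posL, rc = TRUE)
  }
  if (Rf$strand == "+") {
    posR <- Rf$refStart + (s - Rf$readStart)
    acceptor <- dinuc(Rf$contig, posR - 2L, posR)
  } else {
    posR <- Rf$refEnd - (s - Rf$readStart)
    acceptor <- dinuc(Rf$contig, posR, posR + 2L, rc = TRUE)
  }
  list(contigL = Lf$contig, posL = posL, strandL = Lf$strand,
       contigR = Rf$contig, posR = posR, strandR = Rf$strand,
       donor = donor, acceptor = acceptor)
}

#' Settle an ambiguous breakpoint with the GT-AG rule
#'
#' Microhomology between the two sides of a breakpoint makes a range of
#' split positions equivalent; among them the one whose flanking intronic
#' dinucleotides read GT..AG (on either sense) is selected.  When no split
#' (or more than one) is canonical, the placement with the leftmost genomic
#' coordinate of the left locus is chosen deterministically.
#'
#' @param seq read sequence.
#' @param Lf,Rf left and right fragments (internal records).
#' @param sR,eL the valid split range in read coordinates.
#' @param genome named \code{DNAStringSet}.
#' @return normalized junction record plus the chosen split.
#' @keywords internal
cleanSplit <- function(seq, Lf, Rf, sR, eL, genome) {
  splits <- sR:eL
  cands <- lapply(splits, function(s) splitLoci(Lf, Rf, s, genome))
  canonical <- vapply(cands, function(j)
    (j$donor == "GT" && j$acceptor == "AG") ||
    (j$donor == "CT" && j$acceptor == "AC"), logical(1))
  use <- if (sum(canonical) >= 1L) which(canonical) else seq_along(cands)
  posL <- vapply(cands[use], function(j) j$posL, numeric(1))
  sel <- use[order(posL, splits[use])][1]
  j <- cands[[sel]]
  n <- normalizeJunction(j)
  list(junction = n$junction, flipped = n$flipped, split = splits[sel])
}

# classify a non-templated tail as a premature polyadenylation signature;
# returns NULL or a polyA record with the transcript-sense locus
polyATail <- function(seq, frag, reach, side, minRun) {
  L <- nchar(seq)
  if (side == "end") {
    tail <- substr(seq, reach + 1L, L)
    if (nchar(tail) < minRun) return(NULL)
    if (frag$strand == "+") {
      if (gsub("A", "", tail) != "") return(NULL)
      pos <- fragGpos(frag, reach - 1L) + 1L
      list(contig = frag$contig, pos = pos, sense = "+",
           tailLen = nchar(tail), orientation = "forward")
    } else {
      if (gsub("A", "", tail) != "") return(NULL)
      pos <- fragGpos(frag, reach - 1L)
      list(contig = frag$contig, pos = pos, sense = "-",
           tailLen = nchar(tail), orientation = "forward")
    }
  } else {
    head <- substr(seq, 1L, reach)
    if (nchar(head) < minRun) return(NULL)
    if (gsub("T", "", head) != "") return(NULL)
    if (frag$strand == "-") {
      # reverse-complement read of a '+'-sense transcript
      pos <- fragGpos(frag, reach) + 1L
      list(contig = frag$contig, pos = pos, sense = "+",
           tailLen = nchar(head), orientation = "reverse")
    } else {
      # reverse-complement read of a '-'-sense transcript
      pos <- fragGpos(frag, reach)
      list(contig = frag$contig, pos = pos, sense = "-",
           tailLen = nchar(head), orientation = "reverse")
    }
  }
}

#' Resolve one read against the genome
#'
#' Runs shatter / k-mer match / merge / extend / clean for a single read and
#' reports whether it maps contiguously, spans a junction, carries a
#' non-templated polyA tail, or cannot be resolved.
#'
#' @param seq read sequence.
#' @param index an \code{ExonIndex}.
#' @param genome named \code{DNAStringSet}.
#' @param cfg a \code{runConfig()} list.
#' @param relaxed logical; use the relaxed retry parameters.
#' @return list with \code{status} and status-specific fields.
#' @export
resolveRead <- function(seq, index, genome, cfg = runConfig(),
                        relaxed = FALSE) {
  L <- nchar(seq)
  k <- cfg$kmerSize  # shatter size is fixed; relaxation changes the index
                     # word and the mismatch policy, not the anchor length
  maxMM <- if (relaxed) cfg$relaxedMaxMismatch else cfg$maxMismatch
  perfectRun <- if (relaxed) 1L else 2L
  hits <- kmerScan(seq, index, genome, k)
  frags <- mergeHits(hits)
  if (is.null(frags)) return(list(status = "nohit"))

  ext <- lapply(seq_len(nrow(frags)), function(i) {
    f <- frags[i, ]
    le <- extendFragment(seq, f, genome, "left", maxMM, perfectRun)
    re <- extendFragment(seq, f, genome, "right", maxMM, perfectRun)
    list(frag = f, left = le$reach, right = re$reach,
         lmm = le$mismatches, rmm = re$mismatches,
         mm = c(le$mismatches, re$mismatches))
  })

  # contiguous full-length placement?
  for (e in ext) {
    if (e$left == 0L && e$right == L) {
      f <- e$frag
      span <- sort(c(fragGpos(f, 0L), fragGpos(f, L - 1L)))
      return(list(status = "contiguous", contig = f$contig,
                  refStart = span[1], refEnd = span[2] + 1L,
                  strand = f$strand, mismatches = e$mm))
    }
  }

  # candidate split pairs: a left fragment anchored to the read start and a
  # right fragment anchored to the read end, each holding >= 1 exact k-mer
  anchored <- function(e) e$frag$nFull >= 1L
  res <- list()
  for (a in ext) for (b in ext) {
    if (identical(a, b)) next
    if (!anchored(a) || !anchored(b)) next
    if (a$frag$readStart >= b$frag$readStart) next
    if (a$left != 0L || b$right != L) next
    eL <- a$right; sR <- b$left
    if (sR > eL) next
    sR2 <- max(sR, a$frag$readStart + 1L)
    eL2 <- min(eL, b$frag$readEnd - 1L)
    if (sR2 > eL2) next
    cl <- cleanSplit(seq, a$frag, b$frag, sR2, eL2, genome)
    cl$mismatches <- c(a$mm, b$mm)
    cl$fragments <- rbind(a$frag, b$frag)
    res[[length(res) + 1L]] <- cl
  }
  if (length(res)) {
    keys <- vapply(res, function(r) junctionKey(r$junction), character(1))
    if (length(unique(keys)) == 1L) {
      r <- res[[1]]
      return(list(status = "junction", junction = r$junction,
                  flipped = r$flipped, split = r$split,
                  mismatches = r$mismatches, fragments = r$fragments))
    }
    return(list(status = "unresolved", reason = "ambiguous placement"))
  }

  # no split pair: a mapped 5' (or 3') piece with a homopolymer tail?
  # trailing mismatches accepted during extension are rolled back first so
  # the non-templated tail is not shortened by forced mismatch consumption
  for (e in ext) {
    if (e$left == 0L && e$right < L) {
      reach <- e$right
      while ((reach - 1L) %in% e$rmm) reach <- reach - 1L
      pa <- polyATail(seq, e$frag, reach, "end", cfg$polyAMinRun)
      if (!is.null(pa)) return(c(list(status = "polyA"), pa))
    }
    if (e$right == L && e$left > 0L) {
      reach <- e$left
      while (reach %in% e$lmm) reach <- reach + 1L
      pa <- polyATail(seq, e$frag, reach, "start", cfg$polyAMinRun)
      if (!is.null(pa)) return(c(list(status = "polyA"), pa))
    }
  }
  list(status = "unresolved", reason = "no resolving placement")
}

#' Pre-filter reads explained by the annotated transcriptome
#'
#' Removes reads fully contained in an exon or split exactly across adjacent
#' exons of an annotated transcript (both cases are substrings of a spliced
#' transcript sequence, in either orientation), read pairs with an end on
#' the mitochondrial contig, and reads with two or more N bases.  The
#' filter is total: everything else is retained.
#'
#' @param pairs data.frame(name, seq1, seq2); seq2 may be NA for single-end.
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}; a contig named "chrM" or "MT" is
#'   treated as mitochondrial.
#' @return data.frame(name, seq) of retained reads, names suffixed /1, /2.
#' @export
prefilterReads <- function(pairs, models, genome) {
  txSeqs <- vapply(transcriptTable(models)$txId,
                   function(id) splicedSequence(models, genome, id),
                   character(1))
  subject <- Biostrings::DNAStringSet(c(txSeqs,
                                        vapply(txSeqs, revComp, character(1))))
  mito <- intersect(c("chrM", "MT"), names(genome))
  mitoSeq <- if (length(mito)) genome[[mito[1]]] else NULL

  inTranscriptome <- function(s) {
    p <- Biostrings::DNAString(s)
    any(Biostrings::vcountPattern(p, subject) > 0)
  }
  onMito <- function(s) {
    if (is.null(mitoSeq)) return(FALSE)
    p <- Biostrings::DNAString(s)
    Biostrings::countPattern(p, mitoSeq) > 0 ||
      Biostrings::countPattern(Biostrings::reverseComplement(p), mitoSeq) > 0
  }
  countN <- function(s) nchar(gsub("[^N]", "", s))

  keep <- list()
  for (i in seq_len(nrow(pairs))) {
    seqs <- c(pairs$seq1[i], pairs$seq2[i])
    seqs <- seqs[!is.na(seqs)]
    if (any(vapply(seqs, function(s) countN(s) < 2 && onMito(s),
                   logical(1)))) next   # pair excluded: mate on chrM
    for (j in seq_along(seqs)) {
      s <- seqs[j]
      if (countN(s) >= 2) next
      if (inTranscriptome(s)) next
      keep[[length(keep) + 1L]] <- data.frame(
        name = paste0(pairs$name[i], "/", j), seq = s,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(keep))
    return(data.frame(name = character(0), seq = character(0)))
  do.call(rbind, keep)
}

#' Discover junctions from a read set (whole-pipeline driver)
#'
#' Pre-filters, indexes, resolves every retained read and aggregates split
#' reads into junction events with read support by orientation, unique-read
#' counts, splice-motif context and the per-read unique-base average.
#' Deterministic: identical input yields identical tables.
#'
#' @param pairs data.frame(name, seq1, seq2).
#' @param models a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet}.
#' @param cfg a \code{runConfig()} list.
#' @return list with \code{junctions}, \code{polyA}, \code{placements}
#'   (contiguously mapping retained reads) and \code{unresolved} data.frames.
#' @export
callJunctions <- function(pairs, models, genome, cfg = runConfig()) {
  reads <- prefilterReads(pairs, models, genome)
  empty <- list(
    junctions = data.frame(contigL = character(0), posL = integer(0),
                           strandL = character(0), contigR = character(0),
                           posR = integer(0), strandR = character(0),
                           donor = character(0), acceptor = character(0),
                           nFwd = integer(0), nRev = integer(0),
                           nUnique = integer(0), uniqueBasesAvg = numeric(0),
                           reads = character(0)),
    polyA = data.frame(contig = character(0), pos = integer(0),
                       sense = character(0), tailLen = integer(0),
                       nFwd = integer(0), nRev = integer(0),
                       reads = character(0)),
    placements = data.frame(name = character(0), contig = character(0),
                            refStart = integer(0), refEnd = integer(0),
                            strand = character(0)),
    unresolved = data.frame(name = character(0), reason = character(0)))
  if (nrow(reads) == 0) return(empty)

  index <- buildExonIndex(models, genome, cfg$wordSize)
  relaxedIndex <- NULL

  junc <- list(); poly <- list(); plc <- list(); unres <- list()
  for (i in seq_len(nrow(reads))) {
    r <- resolveRead(reads$seq[i], index, genome, cfg)
    if (r$status %in% c("unresolved", "nohit")) {
      if (is.null(relaxedIndex))
        relaxedIndex <- buildGenomeIndex(genome, cfg$relaxedWordSize)
      r2 <- resolveRead(reads$seq[i], relaxedIndex, genome, cfg,
                        relaxed = TRUE)
      if (!r2$status %in% c("unresolved", "nohit")) r <- r2
    }
    if (r$status == "junction") {
      junc[[length(junc) + 1L]] <- c(r$junction,
        list(orientation = if (r$flipped) "reverse" else "forward",
             name = reads$name[i], seq = reads$seq[i],
             fragments = list(r$fragments)))
    } else if (r$status == "polyA") {
      poly[[length(poly) + 1L]] <- data.frame(
        contig = r$contig, pos = r$pos, sense = r$sense,
        tailLen = r$tailLen, orientation = r$orientation,
        name = reads$name[i], stringsAsFactors = FALSE)
    } else if (r$status == "contiguous") {
      plc[[length(plc) + 1L]] <- data.frame(
        name = reads$name[i], contig = r$contig, refStart = r$refStart,
        refEnd = r$refEnd, strand = r$strand, stringsAsFactors = FALSE)
    } else {
      unres[[length(unres) + 1L]] <- data.frame(
        name = reads$name[i],
        reason = if (!is.null(r$reason)) r$reason else r$status,
        stringsAsFactors = FALSE)
    }
  }

  out <- empty
  if (length(junc)) {
    keys <- vapply(junc, function(j)
      junctionKey(j[c("contigL", "posL", "strandL",
                      "contigR", "posR", "strandR")]), character(1))
    rows <- lapply(split(seq_along(junc), keys), function(ix) {
      js <- junc[ix]
      j0 <- js[[1]]
      # per-read unique-base average: read bases whose genomic footprint is
      # shared with no other supporting read of the same event
      foot <- lapply(js, function(j) {
        fr <- j$fragments[[1]]
        unlist(lapply(seq_len(nrow(fr)), function(q)
          paste(fr$contig[q], fr$refStart[q]:(fr$refEnd[q] - 1L))))
      })
      tab <- table(unlist(lapply(foot, unique)))
      uba <- mean(vapply(foot, function(f)
        sum(tab[unique(f)] == 1L), numeric(1)))
      data.frame(contigL = j0$contigL, posL = j0$posL, strandL = j0$strandL,
                 contigR = j0$contigR, posR = j0$posR, strandR = j0$strandR,
                 donor = j0$donor, acceptor = j0$acceptor,
                 nFwd = sum(vapply(js, function(j)
                   j$orientation == "forward", logical(1))),
                 nRev = sum(vapply(js, function(j)
                   j$orientation == "reverse", logical(1))),
                 nUnique = length(unique(vapply(js, function(j) {
                   s <- j$seq; r <- revComp(s); if (s <= r) s else r
                 }, character(1)))),
                 uniqueBasesAvg = uba,
                 reads = paste(vapply(js, `[[`, character(1), "name"),
                               collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out$junctions <- do.call(rbind, rows)
    rownames(out$junctions) <- NULL
    out$junctions <- out$junctions[order(out$junctions$contigL,
                                         out$junctions$posL,
                                         out$junctions$posR), , drop = FALSE]
  }
  if (length(poly)) {
    pd <- do.call(rbind, poly)
    key <- paste(pd$contig, pd$pos, pd$sense)
    rows <- lapply(split(pd, key), function(p) {
      data.frame(contig = p$contig[1], pos = p$pos[1], sense = p$sense[1],
                 tailLen = max(p$tailLen),
                 nFwd = sum(p$orientation == "forward"),
                 nRev = sum(p$orientation == "reverse"),
                 reads = paste(p$name, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out$polyA <- do.call(rbind, rows)
    rownames(out$polyA) <- NULL
  }
  if (length(plc)) out$placements <- do.call(rbind, plc)
  if (length(unres)) out$unresolved <- do.call(rbind, unres)
  out
}

#' Write a junction table as TSV
#'
#' One row per junction event; the flat relational schema (left/right locus,
#' splice dinucleotides, orientation counts, unique reads, unique-base
#' average, supporting read names) is the on-disk mirror of the in-memory
#' result.
#' @param junctions the \code{junctions} element of \code{callJunctions()}.
#' @param path output TSV.
#' @export
writeJunctionTable <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
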