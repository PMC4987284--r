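# Synthetic fixture generator.
#
# Builds a small self-contained study system: a two-contig genome (one gene
# contig plus a mitochondrial decoy), a five-gene annotation with canonical
# GT..AG introns, engineered aberrant transcripts of every event class with
# reads tiling their junctions in both orientations, discordant read pairs
# over a fusion breakpoint, X-chromosome SNP allele counts drawn from the
# phase-mixture binomial model, and cohort rank data from the
# uniform + top-rank point-mass mixture.  Every generated signal is logged
# in a truth table so end-to-end recovery can be scored exactly.

#' Fixture specification
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param readLength read length in bp (75, the nominal short-read length
#'   the mapper is tuned for).
#' @param depth junction-spanning reads planted per event.
#' @param errorRate per-base substitution error rate (default 0; errors are
#'   substitutions only, honouring the mapper's mismatch rule).
#' @param events character vector of event classes to plant.
#' @param xci list(nSnps, piValues, weights, meanDepth) for the X-SNP
#'   allele-count generator.
#' @param rank list(theta, n, m) for the cohort rank generator.
#' @return a fixture spec list.
#' @export
fixtureSpec <- function(seed = 1L,
                        readLength = 75L,
                        depth = 10L,
                        errorRate = 0,
                        events = c("exon_skip", "exon_skip_cryptic",
                                   "exon_reusage", "alt_donor",
                                   "alt_acceptor", "early_polyA",
                                   "fusion_same_orientation",
                                   "fusion_5to5_antisense",
                                   "gene_to_intergenic", "exon_skip_minus"),
                        xci = list(nSnps = 300L, piValues = c(0.9, 0.1),
                                   weights = c(0.8, 0.2), meanDepth = 50L),
                        rank = list(theta = 0.116, n = 23L, m = 4234L)) {
  list(seed = as.integer(seed), readLength = as.integer(readLength),
       depth = as.integer(depth), errorRate = errorRate, events = events,
       xci = xci, rank = rank)
}

.substrRight <- function(s, n) substr(s, nchar(s) - n + 1L, nchar(s))

#' Build the fixture genome and annotation
#'
#' Five genes on "chr1" (A, B, E coding on the plus strand; C a
#' processed transcript on the minus strand; D coding on the plus strand with
#' a latent antisense exon planted in its second intron), all introns edged
#' GT..AG strand-aware, coding exon bodies free of T so no reading frame can
#' hit a premature stop before the planted terminal TAA, plus a 600-bp
#' mitochondrial decoy contig.  Cryptic/alternative splice motifs and the
#' premature-polyA junction context are planted at fixed offsets and
#' recorded in the returned layout.
#'
#' @param spec a \code{fixtureSpec()}.
#' @return list(genome, models, layout).
#' @export
makeGenomeAndAnnotation <- function(spec = fixtureSpec()) {
  set.seed(spec$seed)
  plan <- list(
    geneA = list(strand = "+", nEx = 5L, exLen = 120L, intron = 300L,
                 biotype = "protein_coding"),
    geneB = list(strand = "+", nEx = 4L, exLen = 120L, intron = 250L,
                 biotype = "protein_coding"),
    geneC = list(strand = "-", nEx = 3L, exLen = 120L, intron = 200L,
                 biotype = "processed_transcript"),
    geneD = list(strand = "+", nEx = 3L, exLen = 120L, intron = 400L,
                 biotype = "protein_coding"),
    geneE = list(strand = "+", nEx = 3L, exLen = 120L, intron = 200L,
                 biotype = "protein_coding"))
  gaps <- c(200L, 500L, 400L, 400L, 300L, 300L)

  spans <- vapply(plan, function(g) g$nEx * g$exLen + (g$nEx - 1L) * g$intron,
                  integer(1))
  total <- sum(spans) + sum(gaps)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)

  cursor <- 0L
  exTabs <- list()
  for (nm in names(plan)) {
    g <- plan[[nm]]
    cursor <- cursor + gaps[match(nm, names(plan))]
    starts <- cursor + (seq_len(g$nEx) - 1L) * (g$exLen + g$intron)
    ends <- starts + g$exLen
    exTabs[[nm]] <- data.frame(geneId = nm, contig = "chr1",
                               strand = g$strand, start = starts, end = ends,
                               biotype = g$biotype, stringsAsFactors = FALSE)
    cursor <- cursor + spans[[nm]]
  }

  plant <- function(pos0, s) {
    for (i in seq_len(nchar(s)))
      chars[pos0 + i] <<- substr(s, i, i)
  }

  # T-free exon bodies for coding genes: no stop codon in any frame
  for (nm in names(plan)) {
    e <- exTabs[[nm]]
    if (e$biotype[1] != "protein_coding") next
    for (i in seq_len(nrow(e))) {
      w <- e$end[i] - e$start[i]
      chars[(e$start[i] + 1L):e$end[i]] <- sample(c("A", "C", "G"), w,
                                                  replace = TRUE)
    }
  }

  # canonical GT..AG intron edges, strand-aware
  for (nm in names(plan)) {
    e <- exTabs[[nm]]; s <- e$strand[1]
    for (i in seq_len(nrow(e) - 1L)) {
      iStart <- e$end[i]; iEnd <- e$start[i + 1L]
      if (s == "+") { plant(iStart, "GT"); plant(iEnd - 2L, "AG") }
      else          { plant(iStart, "CT"); plant(iEnd - 2L, "AC") }
    }
  }

  # transcript tables with CDS (30-bp UTR each side, length forced to 0 mod 3)
  exRows <- list(); txRows <- list()
  for (nm in names(plan)) {
    e <- exTabs[[nm]]
    ord <- if (e$strand[1] == "+") order(e$start) else order(-e$start)
    e <- e[ord, ]
    e$exonRank <- seq_len(nrow(e))
    e$txId <- paste0(nm, ".t1")
    txLen <- sum(e$end - e$start)
    coding <- e$biotype[1] == "protein_coding"
    if (coding) {
      cdsTxStart <- 30L
      cdsTxEnd <- cdsTxStart + 3L * ((txLen - 60L) %/% 3L)
      gmap <- .txToGenome(e)
      atg <- gmap[cdsTxStart + 1L]        # genomic pos of first CDS base
      stopPos <- gmap[(cdsTxEnd - 3L + 1L):cdsTxEnd]
      if (e$strand[1] == "+") {
        for (i in 0:2) plant(atg + i, substr("ATG", i + 1L, i + 1L))
        for (i in 0:2) plant(stopPos[1] + i, substr("TAA", i + 1L, i + 1L))
        cdsStart <- atg; cdsEnd <- stopPos[3] + 1L
      } else {
        # minus strand: a codon at transcript coords occupies descending
        # genomic positions; write its reverse complement ascending
        plantRC <- function(gposHigh, s) {
          rc <- revComp(s)
          for (i in seq_len(nchar(s)))
            chars[gposHigh - nchar(s) + 1L + i] <<- substr(rc, i, i)
        }
        plantRC(atg, "ATG")
        plantRC(stopPos[1], "TAA")
        cdsStart <- stopPos[3]; cdsEnd <- atg + 1L
      }
    } else {
      cdsStart <- NA_integer_; cdsEnd <- NA_integer_
    }
    exRows[[nm]] <- e
    txRows[[nm]] <- data.frame(geneId = nm, txId = e$txId[1],
                               biotype = e$biotype[1], contig = "chr1",
                               strand = e$strand[1], cdsStart = cdsStart,
                               cdsEnd = cdsEnd, stringsAsFactors = FALSE)
  }
  ex <- do.call(rbind, exRows); rownames(ex) <- NULL

  eA <- exRows$geneA[order(exRows$geneA$exonRank), ]
  eD <- exRows$geneD
  # engineered motifs (all positions 0-based genomic)
  crypticDonor <- eA$end[1] - 10L                 # GT 10 bp inside exon 1
  plant(crypticDonor, "GTCC")                     # T never at codon start risk
  altDonor <- eA$end[2] + 6L                      # GT 6 bp into intron 2
  plant(altDonor, "GT")
  altAcceptor <- eA$start[4] - 7L                 # AG ending 7 bp before exon 4
  plant(altAcceptor - 2L, "AG")
  polyASite <- eA$end[5] - 50L                    # junction 50 bp from tx end
  plant(polyASite, "CCC")                         # resist templated A-matching
  # latent antisense exon in intron 2 of geneD (minus strand: AC / CT edges)
  dIntron2Start <- eD$end[2]
  asStart <- dIntron2Start + 125L
  asEnd <- asStart + 150L
  plant(asStart - 2L, "AC")
  plant(asEnd, "CT")

  chrM <- paste(sample(c("A", "C", "G", "T"), 600L, replace = TRUE),
                collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = ""),
                                       chrM = chrM))
  models <- TranscriptSet(
    ex[, c("geneId", "txId", "biotype", "contig", "strand", "exonRank",
           "start", "end")],
    do.call(rbind, txRows))
  layout <- list(plan = plan, exons = exRows,
                 crypticDonor = crypticDonor, altDonor = altDonor,
                 altAcceptor = altAcceptor, polyASite = polyASite,
                 antisenseExon = c(start = asStart, end = asEnd))
  list(genome = genome, models = models, layout = layout)
}

# genomic coordinate (0-based) of each transcript position, transcription order
.txToGenome <- function(exonsTx) {
  unlist(lapply(seq_len(nrow(exonsTx)), function(i) {
    s <- exonsTx$start[i]; e <- exonsTx$end[i]
    if (exonsTx$strand[i] == "+") s:(e - 1L) else (e - 1L):s
  }))
}

#' Somatic rearrangements matching the default event plan
#'
#' One BEDPE-style record per planted structural event: the same-orientation
#' fusion (deletion joining geneA intron 2 to geneB intron 1), the inward
#' 5'-to-5' inversion into geneD intron 2, the geneA-to-intergenic deletion
#' whose downstream sense gene is geneE, a deletion confined to one intron of
#' geneC and a cross-intron deletion in geneE.
#' @param fixture result of \code{makeGenomeAndAnnotation()}.
#' @return rearrangement data.frame (see \code{readBedpe}).
#' @export
makeRearrangements <- function(fixture) {
  ex <- fixture$layout$exons
  eA <- ex$geneA; eB <- ex$geneB; eD <- ex$geneD; eE <- ex$geneE
  eC <- ex$geneC[order(ex$geneC$start), ]
  asEnd <- fixture$layout$antisenseExon[["end"]]
  gapDE <- c(max(eD$end), min(eE$start))
  data.frame(
    id = c("r_fusion", "r_5to5", "r_g2i", "r_withinC", "r_crossE"),
    contigA = "chr1",
    posA = c(eA$end[2] + 150L, eA$end[1] + 150L, eA$end[1] + 170L,
             eC$end[1] + 20L, eE$end[1] + 100L),
    orientA = c("+", "+", "+", "+", "+"),
    contigB = "chr1",
    posB = c(eB$end[1] + 125L, asEnd + 25L, (gapDE[1] + gapDE[2]) %/% 2L,
             eC$end[1] + 120L, eE$end[2] + 100L),
    orientB = c("-", "+", "-", "-", "-"),
    type = c("deletion", "inversion", "deletion", "deletion", "deletion"),
    stringsAsFactors = FALSE)
}

# build sense-strand sequence of an exon run (transcription order indices)
.exonSeq <- function(fixture, gene, ranks) {
  e <- fixture$layout$exons[[gene]]
  e <- e[order(e$exonRank), ]
  paste(vapply(ranks, function(r) {
    s <- genomeSlice(fixture$genome, "chr1", e$start[r], e$end[r])
    if (e$strand[r] == "-") revComp(s) else s
  }, character(1)), collapse = "")
}

#' Generate reads carrying the planted events, plus a truth table
#'
#' Junction-spanning reads are tiled so each side keeps at least one intact
#' 13-bp k-mer, alternating forward / reverse-complement orientation so the
#' two-orientation category rules are satisfiable.  Premature-polyA reads end
#' in a 14-base non-templated A run; the 5'-to-5' antisense fusion transcript
#' is tiled end to end (with stacked edge windows) so the antisense exon gets
#' plateau coverage.  Background reads tile every annotated transcript and
#' are pre-filter fodder.  With \code{errorRate = 0} and a fixed seed the
#' output is byte-identical across runs.
#'
#' @param fixture result of \code{makeGenomeAndAnnotation()}.
#' @param spec the \code{fixtureSpec()} used to build it.
#' @return list(reads = data.frame(name, seq1, seq2), truth = data.frame).
#' @export
makeReads <- function(fixture, spec = fixtureSpec()) {
  set.seed(spec$seed + 1L)
  L <- spec$readLength
  lay <- fixture$layout
  ex <- lay$exons
  eA <- ex$geneA[order(ex$geneA$exonRank), ]
  eE <- ex$geneE[order(ex$geneE$exonRank), ]
  eC <- ex$geneC[order(ex$geneC$exonRank), ]
  g <- fixture$genome

  addErr <- function(s) {
    if (spec$errorRate <= 0) return(s)
    n <- nchar(s)
    hit <- which(stats::runif(n) < spec$errorRate)
    if (!length(hit)) return(s)
    v <- strsplit(s, "")[[1]]
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
  }

  reads <- list(); truth <- list()
  emit <- function(name, s) {
    reads[[length(reads) + 1L]] <<- data.frame(
      name = name, seq1 = addErr(s), seq2 = NA_character_,
      stringsAsFactors = FALSE)
  }
  emitTruth <- function(...) {
    truth[[length(truth) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  }

  junctionReads <- function(tag, leftCtx, rightCtx, depth = spec$depth) {
    offs <- round(seq(16, 42, length.out = depth))
    for (j in seq_len(depth)) {
      o <- offs[j]
      s <- paste0(.substrRight(leftCtx, o), substr(rightCtx, 1L, L - o))
      if (j %% 2L == 0L) s <- revComp(s)
      emit(sprintf("%s_%02d", tag, j), s)
    }
  }

  plans <- list(
    exon_skip = function() {
      junctionReads("skip", .exonSeq(fixture, "geneA", 1L),
                    .exonSeq(fixture, "geneA", 3:4))
      emitTruth(class = "exon_skip", contigL = "chr1", posL = eA$end[1],
                strandL = "+", contigR = "chr1", posR = eA$start[3],
                strandR = "+", gene = "geneA", note = "exonsLost=1")
    },
    exon_skip_cryptic = function() {
      leftCtx <- substr(.exonSeq(fixture, "geneA", 1L), 1L, 110L)
      junctionReads("skipcr", leftCtx, .exonSeq(fixture, "geneA", 4:5))
      emitTruth(class = "exon_skip", contigL = "chr1",
                posL = lay$crypticDonor, strandL = "+", contigR = "chr1",
                posR = eA$start[4], strandR = "+", gene = "geneA",
                note = "cryptic;exonsLost=2")
    },
    exon_reusage = function() {
      junctionReads("reuse", .exonSeq(fixture, "geneA", 2:4),
                    .exonSeq(fixture, "geneA", 2:3))
      emitTruth(class = "exon_reusage", contigL = "chr1", posL = eA$end[4],
                strandL = "+", contigR = "chr1", posR = eA$start[2],
                strandR = "+", gene = "geneA", note = "exonsReused=3")
    },
    alt_donor = function() {
      leftCtx <- paste0(.exonSeq(fixture, "geneA", 2L),
                        genomeSlice(g, "chr1", eA$end[2], eA$end[2] + 6L))
      junctionReads("altd", leftCtx, .exonSeq(fixture, "geneA", 3L))
      emitTruth(class = "alt_donor", contigL = "chr1", posL = lay$altDonor,
                strandL = "+", contigR = "chr1", posR = eA$start[3],
                strandR = "+", gene = "geneA", note = "exon-extension 6bp")
    },
    alt_acceptor = function() {
      rightCtx <- paste0(genomeSlice(g, "chr1", eA$start[4] - 7L, eA$start[4]),
                         .exonSeq(fixture, "geneA", 4L))
      junctionReads("alta", .exonSeq(fixture, "geneA", 3L), rightCtx)
      emitTruth(class = "alt_acceptor", contigL = "chr1", posL = eA$end[3],
                strandL = "+", contigR = "chr1", posR = lay$altAcceptor,
                strandR = "+", gene = "geneA", note = "exon-extension 7bp")
    },
    early_polyA = function() {
      leftCtx <- genomeSlice(g, "chr1", eA$start[5], lay$polyASite)
      for (j in seq_along(10:14)) {
        t <- (10:14)[j]
        s <- paste0(.substrRight(leftCtx, L - t), strrep("A", t))
        if (j %% 2L == 0L) s <- revComp(s)
        emit(sprintf("polya_%02d", j), s)
      }
      emitTruth(class = "early_polyA", contigL = "chr1",
                posL = lay$polyASite, strandL = "+", contigR = NA_character_,
                posR = NA_integer_, strandR = NA_character_, gene = "geneA",
                note = "coding-exon;dist=50")
    },
    fusion_same_orientation = function() {
      junctionReads("fus", .exonSeq(fixture, "geneA", 1:2),
                    .exonSeq(fixture, "geneB", 2:3))
      eB <- ex$geneB[order(ex$geneB$exonRank), ]
      emitTruth(class = "fusion_same_orientation", contigL = "chr1",
                posL = eA$end[2], strandL = "+", contigR = "chr1",
                posR = eB$start[2], strandR = "+", gene = "geneA:geneB",
                note = "in_frame")
    },
    fusion_5to5_antisense = function() {
      asS <- lay$antisenseExon[["start"]]; asE <- lay$antisenseExon[["end"]]
      fusTx <- paste0(.exonSeq(fixture, "geneA", 1L),
                      revComp(genomeSlice(g, "chr1", asS, asE)))
      juncOff <- 120L  # first fully-antisense window starts at the junction
      offs <- c(seq(0L, nchar(fusTx) - L, by = 15L),
                0L, 0L, juncOff, juncOff,
                nchar(fusTx) - L, nchar(fusTx) - L)
      for (j in seq_along(offs)) {
        s <- substr(fusTx, offs[j] + 1L, offs[j] + L)
        if (j %% 2L == 0L) s <- revComp(s)
        emit(sprintf("anti_%02d", j), s)
      }
      # guaranteed junction spanners in both orientations
      emit("anti_jf", substr(fusTx, 91L, 91L + L - 1L))
      emit("anti_jr", revComp(substr(fusTx, 81L, 81L + L - 1L)))
      emitTruth(class = "fusion_5to5_antisense", contigL = "chr1",
                posL = eA$end[1], strandL = "+", contigR = "chr1",
                posR = asE, strandR = "-", gene = "geneA:geneD",
                note = sprintf("antisense_exon=%d-%d", asS, asE))
    },
    gene_to_intergenic = function() {
      junctionReads("g2i", .exonSeq(fixture, "geneA", 1L),
                    .exonSeq(fixture, "geneE", 2:3))
      emitTruth(class = "gene_to_intergenic_fusion", contigL = "chr1",
                posL = eA$end[1], strandL = "+", contigR = "chr1",
                posR = eE$start[2], strandR = "+", gene = "geneA:geneE",
                note = "exon2-entry")
    },
    exon_skip_minus = function() {
      junctionReads("skipm", .exonSeq(fixture, "geneC", 1L),
                    .exonSeq(fixture, "geneC", 3L))
      emitTruth(class = "exon_skip", contigL = "chr1", posL = eC$start[1],
                strandL = "-", contigR = "chr1", posR = eC$end[3],
                strandR = "-", gene = "geneC", note = "minus-strand;exonsLost=1")
    })

  for (ev in spec$events) {
    if (!ev %in% names(plans)) stop("unknown event class: ", ev)
    plans[[ev]]()
  }

  # background reads over every canonical transcript (pre-filter fodder)
  for (id in transcriptTable(fixture$models)$txId) {
    s <- splicedSequence(fixture$models, g, id)
    offs <- seq(0L, nchar(s) - L, by = 40L)
    for (j in seq_along(offs)) {
      r <- substr(s, offs[j] + 1L, offs[j] + L)
      if (j %% 2L == 0L) r <- revComp(r)
      emit(sprintf("bg_%s_%02d", id, j), r)
    }
  }

  truthDf <- if (length(truth)) do.call(rbind, truth) else NULL
  list(reads = do.call(rbind, reads), truth = truthDf)
}

#' Generate discordant read pairs over the geneA-geneB fusion breakpoint
#'
#' End 1 falls 5' of the geneA breakpoint on the forward strand; end 2 is the
#' reverse complement of sequence 3' of the geneB breakpoint, giving a
#' consistent cluster.  \code{nInconsistent} pairs get a flipped second end.
#' @param fixture result of \code{makeGenomeAndAnnotation()}.
#' @param n number of pairs.
#' @param nInconsistent how many of them carry an aberrant orientation.
#' @param seed RNG seed.
#' @param readLength read length in bp.
#' @return data.frame(name, seq1, seq2).
#' @export
makeDiscordantPairs <- function(fixture, n = 8L, nInconsistent = 0L,
                                seed = 1L, readLength = 75L) {
  set.seed(seed + 4L)
  ex <- fixture$layout$exons
  eA <- ex$geneA[order(ex$geneA$exonRank), ]
  eB <- ex$geneB[order(ex$geneB$exonRank), ]
  breakA <- eA$end[2] + 150L
  breakB <- eB$end[1] + 125L
  g <- fixture$genome
  out <- lapply(seq_len(n), function(i) {
    sA <- breakA - readLength - sample(0:225, 1L)
    sB <- breakB + 20L + sample(0:205, 1L)
    s1 <- genomeSlice(g, "chr1", sA, sA + readLength)
    s2 <- revComp(genomeSlice(g, "chr1", sB, sB + readLength))
    if (i <= nInconsistent) s2 <- revComp(s2)
    data.frame(name = sprintf("dp_%02d", i), seq1 = s1, seq2 = s2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Draw X-chromosome SNP allele counts from the phase-mixture model
#'
#' Each SNP gets a cluster (tumor transcript fraction pi) by the mixture
#' weights, a phase indicator lambda ~ Bern(0.5), a read depth n_i ~
#' Poisson(meanDepth) (floored at 1), and a reference count
#' y_i ~ Bin(n_i, lambda * pi + (1 - pi) / 2).
#' @param nSnps number of SNPs.
#' @param piValues,weights cluster tumor fractions and mixture weights.
#' @param meanDepth mean read depth per SNP.
#' @param seed RNG seed.
#' @return list(counts = data.frame(snpId, n, y), truth = data.frame).
#' @export
makeXciCounts <- function(nSnps = 300L, piValues = c(0.9, 0.1),
                          weights = c(0.8, 0.2), meanDepth = 50L, seed = 1L) {
  stopifnot(all(piValues >= 0 & piValues <= 1))
  set.seed(seed + 2L)
  cl <- sample(seq_along(piValues), nSnps, replace = TRUE, prob = weights)
  pi <- piValues[cl]
  lam <- stats::rbinom(nSnps, 1L, 0.5)
  n <- pmax(1L, stats::rpois(nSnps, meanDepth))
  p <- lam * pi + (1 - pi) / 2
  y <- stats::rbinom(nSnps, n, p)
  list(counts = data.frame(snpId = sprintf("snp%04d", seq_len(nSnps)),
                           n = n, y = y, stringsAsFactors = FALSE),
       truth = data.frame(snpId = sprintf("snp%04d", seq_len(nSnps)),
                          cluster = cl, pi = pi, lambda = lam,
                          stringsAsFactors = FALSE))
}

#' Draw cohort aberrance ranks from the uniform + top-rank mixture
#'
#' Each of \code{m} rearrangements ranks top (rank \code{n}) with probability
#' \code{theta}, otherwise uniformly on 1..n.
#' @param theta excess fraction in [0, 1].
#' @param n number of samples (ranks run 1..n).
#' @param m number of rearrangements.
#' @param seed RNG seed.
#' @return list(ranks = integer vector, theta = theta).
#' @export
makeRankData <- function(theta = 0.116, n = 23L, m = 4234L, seed = 1L) {
  stopifnot(theta >= 0, theta <= 1)
  set.seed(seed + 3L)
  top <- stats::rbinom(m, 1L, theta)
  ranks <- ifelse(top == 1L, n, sample.int(n, m, replace = TRUE))
  list(ranks = as.integer(ranks), theta = theta, n = as.integer(n))
}

#' Write reads as FASTQ
#' @param reads data.frame(name, seq1, seq2); paired ends go to _1/_2 names
#'   in one file.
#' @param path output FASTQ.
#' @export
writeReadsFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$name[i], "/1"), reads$seq1[i], "+",
                 strrep("I", nchar(reads$seq1[i]))), con)
    if (!is.na(reads$seq2[i]))
      writeLines(c(paste0("@", reads$name[i], "/2"), reads$seq2[i], "+",
                   strrep("I", nchar(reads$seq2[i]))), con)
  }
  invisible(path)
}
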