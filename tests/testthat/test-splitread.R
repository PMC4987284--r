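test_that("read shattering yields floor(L/k) k-mers plus a short 3' k-mer", {
  km <- shatterRead(strrep("A", 75), 13L)
  expect_equal(nrow(km), 6L)
  expect_equal(km$len, c(rep(13L, 5), 10L))
  expect_equal(km$off, c(0L, 13L, 26L, 39L, 52L, 65L))
  expect_false(attr(km, "short"))

  km13 <- shatterRead(strrep("A", 13), 13L)
  expect_equal(nrow(km13), 1L)
  expect_equal(km13$len, 13L)

  km100 <- shatterRead(strrep("A", 100), 13L)
  expect_equal(km100$len, c(rep(13L, 7), 9L))
  expect_equal(km100$off[8], 91L)

  short <- shatterRead("ACGT", 13L)
  expect_true(attr(short, "short"))
  expect_equal(short$len, 4L)
})

.idxModels <- function(starts, ends, contig = "c1") {
  n <- length(starts)
  exdf <- data.frame(geneId = paste0("g", seq_len(n)),
                     txId = paste0("g", seq_len(n), ".t1"),
                     biotype = "protein_coding", contig = contig,
                     strand = "+", exonRank = 1L,
                     start = starts, end = ends, stringsAsFactors = FALSE)
  txdf <- exdf[, c("geneId", "txId", "biotype", "contig", "strand")]
  txdf$cdsStart <- NA_integer_; txdf$cdsEnd <- NA_integer_
  TranscriptSet(exdf, txdf)
}

test_that("exon index word counts follow the sliding window", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  idx <- buildExonIndex(.idxModels(10L, 19L), genome, 9L)
  expect_equal(length(ls(idx$words)), 1L)  # exon of length 9 -> one word
  idx2 <- buildExonIndex(.idxModels(10L, 50L), genome, 9L)
  expect_equal(sum(vapply(ls(idx2$words), function(w)
    nrow(idx2$words[[w]]), numeric(1))), 40L - 8L)  # L - 8 positions
})

test_that("an identical 9-mer in two exons gives one key with two positions", {
  motif <- "ACGTACGTA"
  seq <- paste0(strrep("C", 20), motif, strrep("G", 20), motif,
                strrep("T", 20))
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  ts <- .idxModels(c(20L, 49L), c(29L, 58L))
  idx <- buildExonIndex(ts, genome, 9L)
  expect_equal(nrow(idx$words[[motif]]), 2L)
  expect_equal(sort(as.integer(idx$words[[motif]][, 2])), c(20L, 49L))
})

test_that("exons shorter than the word size contribute no words, with warning", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 30)))
  ts <- .idxModels(c(10L, 40L), c(15L, 60L))
  expect_warning(idx <- buildExonIndex(ts, genome, 9L), "no words")
  pos <- unlist(lapply(ls(idx$words), function(w) idx$words[[w]][, 2]))
  expect_true(all(as.integer(pos) >= 40L))
})

test_that("k-mer hits never disagree with the reference (exact-match seeding)", {
  fx <- fxDefault()
  idx <- buildExonIndex(fx$models, fx$genome, 9L)
  reads <- fxReads()$reads
  jr <- reads[grepl("^skip_|^fus_", reads$name), ]
  for (i in seq_len(min(6L, nrow(jr)))) {
    hits <- SomaticTx:::kmerScan(jr$seq1[i], idx, fx$genome, 13L)
    for (q in seq_len(nrow(hits))) {
      h <- hits[q, ]
      refseq <- genomeSlice(fx$genome, h$contig, h$refStart,
                            h$refStart + h$len)
      readPart <- substr(jr$seq1[i], h$readStart + 1L, h$readStart + h$len)
      if (h$strand == "-") readPart <- revComp(readPart)
      if (h$strand == "-") {
        expect_equal(revComp(refseq), revComp(readPart))
      } else {
        expect_equal(refseq, readPart)
      }
    }
  }
})

test_that("pre-filter removes transcriptome-explained, N-rich and chrM reads", {
  fx <- fxDefault()
  tx1 <- splicedSequence(fx$models, fx$genome, "geneA.t1")
  contained <- substr(tx1, 50, 124)              # inside the transcriptome
  adjacent <- substr(tx1, 90, 164)               # spans exon1/exon2 splice
  skipRead <- paste0(substr(tx1, 91, 120), substr(tx1, 241, 285))  # e1->e3
  nRead <- paste0("NN", substr(skipRead, 3, 75))
  oneN <- paste0("N", substr(skipRead, 2, 75))
  chrM <- as.character(Biostrings::subseq(fx$genome[["chrM"]], 11, 85))
  pairs <- data.frame(
    name = c("contained", "adjacent", "skip", "nn", "onen", "mito"),
    seq1 = c(contained, adjacent, skipRead, nRead, oneN, skipRead),
    seq2 = c(NA, NA, NA, NA, NA, chrM),
    stringsAsFactors = FALSE)
  kept <- prefilterReads(pairs, fx$models, fx$genome)
  expect_false(any(grepl("contained|adjacent|nn|mito", kept$name)))
  expect_true("skip/1" %in% kept$name)
  expect_true("onen/1" %in% kept$name)   # single N is tolerated

  # independent containment oracle: retained reads are exactly those not
  # found (either orientation) in any spliced transcript
  txs <- vapply(transcriptTable(fx$models)$txId, function(id)
    splicedSequence(fx$models, fx$genome, id), character(1))
  for (nm in c("contained", "adjacent", "skip")) {
    s <- pairs$seq1[pairs$name == nm]
    inTx <- any(vapply(txs, function(t)
      grepl(s, t, fixed = TRUE) || grepl(revComp(s), t, fixed = TRUE),
      logical(1)))
    expect_equal(!inTx, paste0(nm, "/1") %in% kept$name)
  }
})

test_that("a two-gene split read resolves to the exact junction loci", {
  fx <- fxDefault()
  eA <- exons(fx$models); eA <- eA[eA$geneId == "geneA", ]
  eB <- exons(fx$models); eB <- eB[eB$geneId == "geneB", ]
  # 40 bp of geneA exon2 end + 35 bp of geneB exon2 start
  posL <- eA$end[eA$exonRank == 2][1]
  posR <- eB$start[eB$exonRank == 2][1]
  read <- paste0(genomeSlice(fx$genome, "chr1", posL - 40L, posL),
                 genomeSlice(fx$genome, "chr1", posR, posR + 35L))
  idx <- buildExonIndex(fx$models, fx$genome, 9L)
  r <- resolveRead(read, idx, fx$genome, runConfig())
  expect_equal(r$status, "junction")
  expect_equal(r$junction$posL, posL)
  expect_equal(r$junction$posR, posR)
  # exhaustive all-split-position oracle agrees
  o <- oracleSplitAlign(read, fx$genome)
  expect_true(SomaticTx:::junctionKey(r$junction) %in% o$key)

  # a SNP 5 bp past the junction on the B side: same junction, mismatch
  snpRead <- read
  base <- substr(snpRead, 45, 45)
  swap <- setdiff(c("A", "C", "G", "T"), base)[1]
  substr(snpRead, 45, 45) <- swap
  r2 <- resolveRead(snpRead, idx, fx$genome, runConfig())
  expect_equal(r2$status, "junction")
  expect_equal(r2$junction$posL, posL)
  expect_equal(r2$junction$posR, posR)
  expect_true(length(r2$mismatches) >= 1L)
})

test_that("fully transcript-concordant reads merge into one fragment, no junction", {
  fx <- fxDefault()
  eA <- exons(fx$models); eA <- eA[eA$geneId == "geneA", ]
  s <- eA$start[eA$exonRank == 1][1]
  read <- genomeSlice(fx$genome, "chr1", s + 5L, s + 80L)
  idx <- buildExonIndex(fx$models, fx$genome, 9L)
  r <- resolveRead(read, idx, fx$genome, runConfig())
  expect_equal(r$status, "contiguous")
  expect_equal(r$refStart, s + 5L)
  expect_equal(r$refEnd, s + 80L)
})

.microGenome <- function(exonAEnd2, intronStart2, intronEnd2, exonBStart2) {
  set.seed(23)
  chars <- sample(c("A", "C", "G", "T"), 400, TRUE)
  put <- function(pos0, s) for (i in seq_len(nchar(s)))
    chars[pos0 + i] <<- substr(s, i, i)
  put(128, exonAEnd2)    # last 2 bases of exon A  [128,130)
  put(130, intronStart2) # first 2 intron bases    [130,132)
  put(178, intronEnd2)   # last 2 intron bases     [178,180)
  put(180, exonBStart2)  # first 2 bases of exon B [180,182)
  genome <- Biostrings::DNAStringSet(c(ctg = paste(chars, collapse = "")))
  exdf <- data.frame(geneId = "gM", txId = "gM.t1",
                     biotype = "protein_coding", contig = "ctg",
                     strand = "+", exonRank = 1:2,
                     start = c(50L, 180L), end = c(130L, 260L),
                     stringsAsFactors = FALSE)
  txdf <- data.frame(geneId = "gM", txId = "gM.t1",
                     biotype = "protein_coding", contig = "ctg",
                     strand = "+", cdsStart = NA_integer_,
                     cdsEnd = NA_integer_, stringsAsFactors = FALSE)
  list(genome = genome, models = TranscriptSet(exdf, txdf))
}

test_that("microhomology resolves to the GT-AG placement when one exists", {
  # exon A ends "AG", intron GT..AG, exon B starts "GT": both junction
  # flanks are echoed across the breakpoint, giving a +-2 bp homology range
  m <- .microGenome("AG", "GT", "AG", "GT")
  read <- paste0(genomeSlice(m$genome, "ctg", 93L, 130L),
                 genomeSlice(m$genome, "ctg", 180L, 218L))
  idx <- buildExonIndex(m$models, m$genome, 9L)
  r <- resolveRead(read, idx, m$genome, runConfig())
  expect_equal(r$status, "junction")
  expect_equal(r$junction$posL, 130L)
  expect_equal(r$junction$posR, 180L)
  expect_equal(r$junction$donor, "GT")
  expect_equal(r$junction$acceptor, "AG")
})

test_that("without any GT-AG option the leftmost placement wins deterministically", {
  m <- .microGenome("CC", "AC", "CC", "AC")
  read <- paste0(genomeSlice(m$genome, "ctg", 93L, 130L),
                 genomeSlice(m$genome, "ctg", 180L, 218L))
  idx <- buildExonIndex(m$models, m$genome, 9L)
  r <- resolveRead(read, idx, m$genome, runConfig())
  expect_equal(r$status, "junction")
  # equivalent placements all shift both loci together; the leftmost left
  # locus is chosen, which can only sit at or left of the canonical split
  expect_equal(r$junction$posR - r$junction$posL, 50L)
  expect_lte(r$junction$posL, 130L)
  expect_false(r$junction$donor == "GT" && r$junction$acceptor == "AG")
  r2 <- resolveRead(read, idx, m$genome, runConfig())
  expect_identical(r, r2)
})

test_that("junction tables are byte-identical across repeated runs", {
  fx <- fxDefault()
  reads <- fxReads()$reads
  sub <- reads[grepl("^skip_|^fus_|^anti_", reads$name), ]
  r1 <- callJunctions(sub, fx$models, fx$genome, runConfig())
  r2 <- callJunctions(sub, fx$models, fx$genome, runConfig())
  expect_identical(r1$junctions, r2$junctions)
  f1 <- tempfile(); f2 <- tempfile()
  writeJunctionTable(r1$junctions, f1)
  writeJunctionTable(r2$junctions, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("resolved junction reads partition their bases between two fragments", {
  fx <- fxDefault()
  idx <- buildExonIndex(fx$models, fx$genome, 9L)
  reads <- fxReads()$reads
  jr <- reads[grepl("^reuse_|^altd_", reads$name), ]
  for (i in seq_len(nrow(jr))) {
    r <- resolveRead(jr$seq1[i], idx, fx$genome, runConfig())
    expect_equal(r$status, "junction")
    L <- nchar(jr$seq1[i])
    s <- r$split
    expect_true(s >= 1L && s <= L - 1L)  # both sides non-empty, disjoint
  }
})

test_that("an empty read set yields an empty junction table", {
  fx <- fxDefault()
  res <- callJunctions(
    data.frame(name = character(0), seq1 = character(0),
               seq2 = character(0), stringsAsFactors = FALSE),
    fx$models, fx$genome, runConfig())
  expect_equal(nrow(res$junctions), 0L)
  expect_equal(nrow(res$polyA), 0L)
})
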