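test_that("planted events are categorised with their structural details", {
  ev <- fxEvents()
  truth <- fxReads()$truth
  acc <- ev[ev$accepted, ]

  # each truth junction appears exactly once, correctly categorised
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    hit <- if (tr$class == "early_polyA") {
      acc[acc$category == "early_polyA" & acc$posL == tr$posL, ]
    } else {
      acc[!is.na(acc$posR) & acc$posL == tr$posL & acc$posR == tr$posR, ]
    }
    expect_equal(nrow(hit), 1L, info = tr$class)
    expect_equal(hit$category, tr$class, info = tr$class)
  }

  skip1 <- acc[acc$category == "exon_skip" & acc$geneL == "geneA" &
               acc$canonicalEdges %in% TRUE, ]
  expect_equal(skip1$exonsLost, 1L)
  cryptic <- acc[acc$category == "exon_skip" & acc$crypticSide %in% "5p", ]
  expect_equal(cryptic$exonsLost, 2L)
  expect_false(cryptic$canonicalEdges)
  reuse <- acc[acc$category == "exon_reusage", ]
  expect_equal(reuse$exonsReused, 3L)
  fus <- acc[acc$category == "fusion_same_orientation", ]
  expect_equal(fus$frame, "in_frame")
  g2i <- acc[acc$category == "gene_to_intergenic_fusion", ]
  expect_equal(g2i$exonEntry, 2L)
  expect_false(g2i$novelExon)
  polya <- acc[acc$category == "early_polyA", ]
  expect_equal(polya$crypticSide, "coding_exon")  # subclass slot
})

test_that("the organoid novelty filter rejects junctions at two reads", {
  fx <- fxDefault()
  jt <- fxMapResult()$junctions
  skipRow <- jt[jt$posL == 320L & jt$posR == 1040L, ]
  key <- SomaticTx:::junctionKey(as.list(skipRow))
  cfg <- runConfig()
  ev1 <- classifyJunction(skipRow, fx$models, fx$genome,
                          organoid = setNames(1L, key), cfg)
  expect_true(ev1$accepted)   # fewer than two reads: still novel
  ev2 <- classifyJunction(skipRow, fx$models, fx$genome,
                          organoid = setNames(2L, key), cfg)
  expect_false(ev2$accepted)
  expect_match(ev2$reason, "organoid")
})

test_that("annotated junctions are never emitted regardless of read support", {
  fx <- fxDefault()
  eA <- exons(fx$models); eA <- eA[eA$geneId == "geneA", ]
  j <- data.frame(contigL = "chr1", posL = eA$end[eA$exonRank == 1][1],
                  strandL = "+", contigR = "chr1",
                  posR = eA$start[eA$exonRank == 2][1], strandR = "+",
                  donor = "GT", acceptor = "AG", nFwd = 500L, nRev = 500L,
                  stringsAsFactors = FALSE)
  ev <- classifyJunction(j, fx$models, fx$genome)
  expect_false(ev$accepted)
  expect_match(ev$reason, "annotated")
})

test_that("exon skips and reusages need both split-read orientations", {
  fx <- fxDefault()
  jt <- fxMapResult()$junctions
  skipRow <- jt[jt$posL == 320L & jt$posR == 1040L, ]
  skipRow$nRev <- 0L
  ev <- classifyJunction(skipRow, fx$models, fx$genome)
  expect_false(ev$accepted)
  expect_match(ev$reason, "forward and a reverse")
})

test_that("alternative donors/acceptors demand GT-AG context", {
  fx <- fxDefault()
  jt <- fxMapResult()$junctions
  alt <- jt[jt$posL == 746L, ]
  alt$donor <- "CA"  # simulate a non-canonical context
  ev <- classifyJunction(alt, fx$models, fx$genome)
  expect_false(ev$accepted)
  expect_match(ev$reason, "GT-AG")
})

test_that("junctions with no gene on either side are rejected with a reason", {
  fx <- fxDefault()
  j <- data.frame(contigL = "chr1", posL = 10L, strandL = "+",
                  contigR = "chr1", posR = 60L, strandR = "+",
                  donor = "GT", acceptor = "AG", nFwd = 2L, nRev = 2L,
                  stringsAsFactors = FALSE)
  ev <- classifyJunction(j, fx$models, fx$genome)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "intergenic-both-sides")
})

test_that("premature polyA calls respect templating and the edge distance", {
  fx <- fxDefault()
  cfg <- runConfig()
  lay <- fx$layout
  eA <- lay$exons$geneA
  ok <- detectEarlyPolyA(list(contig = "chr1", pos = lay$polyASite,
                              sense = "+", tailLen = 14L),
                         fx$models, fx$genome, cfg)
  expect_true(ok$accepted)
  expect_equal(ok$subclass, "coding_exon")
  expect_equal(ok$distance, 50L)

  # a junction 5 bp from the canonical UTR edge is too close
  near <- detectEarlyPolyA(list(contig = "chr1", pos = eA$end[5] - 5L,
                                sense = "+", tailLen = 14L),
                           fx$models, fx$genome, cfg)
  expect_false(near$accepted)
  expect_match(near$reason, "canonical edge")

  # an A-run templated in the genome is no polyA signal: plant one
  g2 <- fx$genome
  pos <- eA$end[5] - 40L
  s <- as.character(g2[["chr1"]])
  substr(s, pos + 1L, pos + cfg$polyAMinRun) <- strrep("A", cfg$polyAMinRun)
  g2 <- Biostrings::DNAStringSet(c(chr1 = s, chrM = as.character(g2[["chrM"]])))
  tmpl <- detectEarlyPolyA(list(contig = "chr1", pos = pos, sense = "+",
                                tailLen = 14L), fx$models, g2, cfg)
  expect_false(tmpl$accepted)
  expect_match(tmpl$reason, "templated")
})

test_that("frame prediction agrees with the codon-walking oracle", {
  fx <- fxDefault()
  eA <- exons(fx$models); eA <- eA[eA$geneId == "geneA", ]
  eB <- exons(fx$models); eB <- eB[eB$geneId == "geneB", ]
  endOf <- function(e, r) e$end[e$exonRank == r][1]
  startOf <- function(e, r) e$start[e$exonRank == r][1]
  cases <- list(
    list(posA = endOf(eA, 2), posB = startOf(eB, 2)),   # planted in-frame
    list(posA = endOf(eA, 2), posB = startOf(eB, 2) + 1L),
    list(posA = endOf(eA, 2) - 1L, posB = startOf(eB, 2)),
    list(posA = endOf(eA, 3), posB = startOf(eB, 3) + 2L),
    list(posA = endOf(eA, 1), posB = startOf(eB, 3)))
  for (cs in cases) {
    got <- predictFrame(fx$models, "geneA.t1", cs$posA, "geneB.t1", cs$posB)
    want <- oracleFrame(fx$models, fx$genome, "geneA.t1", cs$posA,
                        "geneB.t1", cs$posB)
    expect_equal(got$frame, want,
                 info = sprintf("posA=%d posB=%d", cs$posA, cs$posB))
  }
})

test_that("UTR breakpoints give utr_involved, noncoding partners noncoding", {
  fx <- fxDefault()
  eA <- exons(fx$models); eA <- eA[eA$geneId == "geneA", ]
  eB <- exons(fx$models); eB <- eB[eB$geneId == "geneB", ]
  utrPos <- eA$start[eA$exonRank == 1][1] + 10L   # inside geneA's 5' UTR
  bStart <- eB$start[eB$exonRank == 1][1] + 5L    # before geneB's ATG
  fr <- predictFrame(fx$models, "geneA.t1", utrPos, "geneB.t1", bStart)
  expect_equal(fr$frame, "utr_involved")
  expect_true(fr$potentiallyProductive)  # acceptor keeps its own ATG
  frC <- predictFrame(fx$models, "geneA.t1", eA$end[1], "geneC.t1", 4300L)
  expect_equal(frC$frame, "noncoding")
})

test_that("antisense exons are delimited by depth plateaus with GT-AG edges", {
  fx <- fxDefault()
  ae <- detectAntisenseExons(fxEvents(), fxMapResult()$placements,
                             fx$models, fx$genome, runConfig())
  expect_equal(nrow(ae), 1L)
  expect_equal(ae$start, fx$layout$antisenseExon[["start"]])
  expect_equal(ae$end, fx$layout$antisenseExon[["end"]])
  expect_true(ae$donorCanonical)
  expect_true(ae$acceptorCanonical)
  expect_gte(ae$maxDepth, runConfig()$antisenseMinDepth)

  # no reads past the junction: empty exon list
  none <- detectAntisenseExons(fxEvents(),
                               fxMapResult()$placements[0, ],
                               fx$models, fx$genome, runConfig())
  expect_equal(nrow(none), 0L)
})

test_that("reciprocal 5'-to-5' pairs are flagged on both events", {
  ev <- fxEvents()
  tmpl <- ev[ev$accepted & ev$category == "fusion_5to5_antisense", ][1, ]
  other <- tmpl
  other$geneL <- tmpl$geneR; other$geneR <- tmpl$geneL
  both <- rbind(tmpl, other)
  both$reciprocal <- FALSE
  # rerun the pairing rule as classifyEvents applies it
  anti <- which(both$accepted & both$category == "fusion_5to5_antisense")
  for (i in anti) for (k in anti) {
    if (i != k && both$geneL[i] == both$geneR[k] &&
        both$geneR[i] == both$geneL[k])
      both$reciprocal[c(i, k)] <- TRUE
  }
  expect_true(all(both$reciprocal))
  expect_false(any(fxEvents()$reciprocal))  # single event in the fixture
})
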