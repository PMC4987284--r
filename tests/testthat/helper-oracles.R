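# Independent oracles, implemented from first principles (no reuse of the
# mapper / sampler / estimator internals they check).

# --- exhaustive all-split-position aligner --------------------------------

.oraclePlacements <- function(part, genome) {
  hits <- list()
  p <- Biostrings::DNAString(part)
  rc <- Biostrings::reverseComplement(p)
  for (contig in names(genome)) {
    m <- Biostrings::matchPattern(p, genome[[contig]])
    for (st in Biostrings::start(m))
      hits[[length(hits) + 1L]] <- list(contig = contig, pos = st - 1L,
                                        strand = "+")
    m <- Biostrings::matchPattern(rc, genome[[contig]])
    for (st in Biostrings::start(m))
      hits[[length(hits) + 1L]] <- list(contig = contig, pos = st - 1L,
                                        strand = "-")
  }
  hits
}

.oracleDinuc <- function(genome, contig, a, b, rc = FALSE) {
  if (a < 0L || b > length(genome[[contig]])) return("NN")
  d <- as.character(Biostrings::subseq(genome[[contig]], a + 1L, b))
  if (rc) as.character(Biostrings::reverseComplement(Biostrings::DNAString(d)))
  else d
}

.oracleNormalize <- function(j) {
  rcs <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  flip <- list(contigL = j$contigR, posL = j$posR,
               strandL = if (j$strandR == "+") "-" else "+",
               contigR = j$contigL, posR = j$posL,
               strandR = if (j$strandL == "+") "-" else "+",
               donor = rcs(j$acceptor), acceptor = rcs(j$donor))
  canon <- function(x) x$donor == "GT" && x$acceptor == "AG"
  key <- function(x) paste(x$contigL, x$posL, x$strandL,
                           x$contigR, x$posR, x$strandR, sep = ":")
  pick <- if (canon(j) && !canon(flip)) j
  else if (canon(flip) && !canon(j)) flip
  else if (j$strandL == "+" && flip$strandL != "+") j
  else if (flip$strandL == "+" && j$strandL != "+") flip
  else if (key(j) <= key(flip)) j else flip
  c(pick, list(key = key(pick), canonical = canon(pick)))
}

# every exact full-coverage split placement of a read, as normalized keys
oracleSplitAlign <- function(seq, genome, minSide = 13L) {
  L <- nchar(seq)
  out <- list()
  for (s in seq(minSide, L - minSide)) {
    left <- substr(seq, 1L, s)
    right <- substr(seq, s + 1L, L)
    hl <- .oraclePlacements(left, genome)
    if (!length(hl)) next
    hr <- .oraclePlacements(right, genome)
    if (!length(hr)) next
    for (a in hl) for (b in hr) {
      if (a$strand == "+") {
        posL <- a$pos + s
        donor <- .oracleDinuc(genome, a$contig, posL, posL + 2L)
      } else {
        posL <- a$pos
        donor <- .oracleDinuc(genome, a$contig, posL - 2L, posL, rc = TRUE)
      }
      if (b$strand == "+") {
        posR <- b$pos
        acceptor <- .oracleDinuc(genome, b$contig, posR - 2L, posR)
      } else {
        posR <- b$pos + (L - s)
        acceptor <- .oracleDinuc(genome, b$contig, posR, posR + 2L,
                                 rc = TRUE)
      }
      j <- .oracleNormalize(list(
        contigL = a$contig, posL = posL, strandL = a$strand,
        contigR = b$contig, posR = posR, strandR = b$strand,
        donor = donor, acceptor = acceptor))
      # drop "splits" that are really one contiguous placement
      if (j$contigL == j$contigR && j$posL == j$posR &&
          j$strandL == j$strandR) next
      out[[length(out) + 1L]] <- j
    }
  }
  if (!length(out)) return(NULL)
  keys <- vapply(out, `[[`, character(1), "key")
  canon <- vapply(out, `[[`, logical(1), "canonical")
  data.frame(key = keys, canonical = canon,
             stringsAsFactors = FALSE)[!duplicated(keys), , drop = FALSE]
}

# --- dense-integration posterior for the 2-cluster DP model ---------------

# per-SNP posterior mean of pi under the truncated (C = 2) model with the
# concentration alpha held fixed, by grid integration over (pi1, pi2, V1)
oracleGridPosterior <- function(y, n, alphaFix,
                                grid = seq(0.005, 0.995, by = 0.01)) {
  N <- length(y)
  G <- length(grid)
  # M[i, g] = sum_lambda 0.5 * Bin(y_i; n_i, lambda pi + (1 - pi)/2)
  M <- sapply(grid, function(pi)
    0.5 * stats::dbinom(y, n, (1 + pi) / 2) +
    0.5 * stats::dbinom(y, n, (1 - pi) / 2))
  M <- matrix(M, nrow = N)
  vGrid <- grid
  vPrior <- stats::dbeta(vGrid, 1, alphaFix)
  denom <- 0
  numer <- numeric(N)
  for (g1 in seq_len(G)) for (g2 in seq_len(G)) {
    # L[i, v] and A[i, v] for all stick values at once
    L <- outer(M[, g1], vGrid) + outer(M[, g2], 1 - vGrid)
    A <- outer(M[, g1] * grid[g1], vGrid) +
         outer(M[, g2] * grid[g2], 1 - vGrid)
    logProd <- colSums(log(L))
    wv <- vPrior * exp(logProd - max(logProd))
    scale <- exp(max(logProd))
    denom <- denom + sum(wv) * scale
    numer <- numer + as.vector((A / L) %*% wv) * scale
  }
  numer / denom
}

# --- grid-search MLE for the top-rank excess fraction ---------------------

oracleGridTheta <- function(ranks, n, grid = seq(0, 1, by = 1e-3)) {
  k <- sum(ranks == n)
  m <- length(ranks)
  ll <- vapply(grid, function(th) {
    pTop <- th + (1 - th) / n
    pOther <- (1 - th) / n
    if (k > 0 && pTop <= 0) return(-Inf)
    if (m - k > 0 && pOther <= 0) return(-Inf)
    k * log(pTop) + (m - k) * log(pOther)
  }, numeric(1))
  grid[which.max(ll)]
}

# --- codon-walking frame oracle -------------------------------------------

# translate the spliced fusion CDS; in frame iff translation runs clean to a
# single terminal stop (fixture CDS bodies are stop-free in every frame)
oracleFrame <- function(models, genome, txA, posA, txB, posB) {
  len5 <- function(tx, pos) {
    e <- exonsOf(models, tx)
    if (e$strand[1] == "+") sum(pmax(0L, pmin(e$end, pos) - e$start))
    else sum(pmax(0L, e$end - pmax(e$start, pos)))
  }
  tt <- transcriptTable(models)
  rowA <- tt[tt$txId == txA, ]; rowB <- tt[tt$txId == txB, ]
  sA <- splicedSequence(models, genome, txA)
  sB <- splicedSequence(models, genome, txB)
  cdsLoA <- if (rowA$strand == "+") rowA$cdsStart else rowA$cdsEnd
  cdsHiB <- if (rowB$strand == "+") rowB$cdsEnd else rowB$cdsStart
  aFrom <- len5(txA, cdsLoA)  # tx offset of A's ATG
  aTo <- len5(txA, posA)
  bFrom <- len5(txB, posB)
  bTo <- len5(txB, cdsHiB)
  fused <- paste0(substr(sA, aFrom + 1L, aTo), substr(sB, bFrom + 1L, bTo))
  if (nchar(fused) %% 3L != 0L) return("out_of_frame")
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(fused)))
  stops <- gregexpr("*", pep, fixed = TRUE)[[1]]
  if (length(stops) == 1L && stops[1] == nchar(pep)) "in_frame"
  else "out_of_frame"
}
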