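test_that("the phase-mixture mean has the right limits", {
  expect_equal(mixtureMean(0, 0), 0.5)   # pure stroma: 50% either phase
  expect_equal(mixtureMean(0, 1), 0.5)
  expect_equal(mixtureMean(1, 1), 1.0)   # pure tumor, reference on Xa
  expect_equal(mixtureMean(1, 0), 0.0)
  expect_equal(mixtureMean(0.8, 0), 0.1) # (1 - pi) / 2
  expect_equal(mixtureMean(0.8, 1), 0.9)
  expect_error(mixtureMean(1.2, 1), "\\[0, 1\\]")
  expect_error(mixtureMean(0.5, 2), "0 or 1")
})

.mkState <- function(S, V, pi, lambda, alpha = 1) {
  list(S = S, V = V, pi = pi, lambda = lambda, alpha = alpha)
}

test_that("allocation is certain with one cluster and follows the binomial odds with two", {
  y <- rep(19L, 2000L); n <- rep(20L, 2000L)
  s1 <- .mkState(rep(1L, 2000L), V = 1, pi = 0.7, lambda = rep(1L, 2000L))
  set.seed(1)
  out <- gibbsAllocate(s1, y, n)
  expect_true(all(out$S == 1L))

  # two clusters, equal stick weights 0.5/0.5, pi = (0.9, 0.1), lambda = 1:
  # Pr(S = 1) is the normalized product of the two binomial terms
  s2 <- .mkState(rep(1L, 2000L), V = c(0.5, 1), pi = c(0.9, 0.1),
                 lambda = rep(1L, 2000L))
  set.seed(2)
  out2 <- gibbsAllocate(s2, y, n)
  pExp <- dbinom(19, 20, 0.95) / (dbinom(19, 20, 0.95) + dbinom(19, 20, 0.55))
  expect_equal(mean(out2$S == 1L), pExp, tolerance = 0.05)

  # equal locations: symmetry gives 0.5 / 0.5
  s3 <- .mkState(rep(1L, 2000L), V = c(0.5, 1), pi = c(0.4, 0.4),
                 lambda = rep(1L, 2000L))
  set.seed(3)
  out3 <- gibbsAllocate(s3, y, n)
  expect_equal(mean(out3$S == 1L), 0.5, tolerance = 0.05)
})

test_that("stick updates draw from the conjugate beta posteriors", {
  # 3 SNPs in cluster 1, 5 beyond it, alpha = 2 -> V1 ~ Beta(4, 7);
  # clusters with nothing at or beyond them fall back to the Beta(1, alpha)
  # prior; checked by seed-matched draws with independently derived shapes
  S <- c(rep(1L, 3L), rep(2L, 2L), rep(3L, 3L))
  C <- 5L
  st <- .mkState(S, V = rep(0.5, C), pi = runif(C), lambda = rep(0L, 8L),
                 alpha = 2)
  set.seed(42)
  out <- gibbsSticks(st, rep(1L, 8L), rep(2L, 8L))
  cnt <- tabulate(S, C)
  beyond <- rev(cumsum(rev(cnt)))
  set.seed(42)
  expected <- rbeta(C - 1L, 1 + cnt[1:(C - 1L)], 2 + beyond[2:C])
  expect_equal(out$V, c(expected, 1))
  expect_equal(cnt[1] + 1, 4)       # the example's Beta(4, 7)
  expect_equal(beyond[2] + 2, 7)
})

test_that("all SNPs in cluster 1 gives V1 ~ Beta(1 + N, alpha)", {
  N <- 12L
  st <- .mkState(rep(1L, N), V = c(0.5, 0.5, 1), pi = c(0.2, 0.5, 0.9),
                 lambda = rep(0L, N), alpha = 3)
  set.seed(9)
  out <- gibbsSticks(st, rep(1L, N), rep(2L, N))
  set.seed(9)
  expected <- rbeta(2L, c(1 + N, 1), c(3, 3))
  expect_equal(out$V[1:2], expected)
})

test_that("phase updates match an independent Bayes-rule computation", {
  # flat Bern(0.5) prior, two binomial likelihoods at (1+pi)/2 and (1-pi)/2
  y <- c(5L, 9L, 0L, 10L, 7L)
  n <- c(10L, 10L, 10L, 20L, 14L)
  pi <- c(0.8, 0.8, 0.3, 0, 0.6)
  st <- .mkState(seq_len(5L), V = c(rep(0.2, 4), 1), pi = pi,
                 lambda = rep(0L, 5L))
  pBayes <- dbinom(y, n, (1 + pi) / 2) /
    (dbinom(y, n, (1 + pi) / 2) + dbinom(y, n, (1 - pi) / 2))
  set.seed(5)
  out <- gibbsLambda(st, y, n)
  set.seed(5)
  expected <- rbinom(5L, 1L, pBayes)
  expect_equal(out$lambda, expected)
  expect_equal(pBayes[1], 0.5)  # y = n/2 -> exponent 0
  expect_equal(pBayes[4], 0.5)  # pi = 0 -> ratio 1
  # printed closed form for pi = 0.8, n = 10, y = 9
  expect_equal(pBayes[2], 1 / (1 + (1 / 9)^8))
})

test_that("pi = 1 phase updates hit the degenerate limits without errors", {
  st <- .mkState(c(1L, 1L, 1L), V = 1, pi = 1, lambda = c(0L, 0L, 0L))
  y <- c(9L, 1L, 5L); n <- c(10L, 10L, 10L)
  set.seed(8)
  out <- gibbsLambda(st, y, n)
  expect_equal(out$lambda[1], 1L)  # 2y - n > 0 -> certainly on Xa
  expect_equal(out$lambda[2], 0L)  # 2y - n < 0 -> certainly on Xi
})

test_that("concentration updates follow the printed gamma posterior", {
  # C = 2, V1 = 1 - exp(-1), prior Gamma(1, 1) -> Gamma(2, 2)
  st <- .mkState(c(1L, 2L), V = c(1 - exp(-1), 1), pi = c(0.5, 0.5),
                 lambda = c(0L, 0L))
  set.seed(13)
  out <- gibbsAlpha(st, c(1L, 1L), c(2L, 2L), A = 1, B = 1)
  set.seed(13)
  expect_equal(out$alpha, rgamma(1, shape = 2, rate = 2))

  # sticks near zero: posterior approaches Gamma(C + A - 1, B)
  C <- 40L
  st0 <- .mkState(rep(1L, 5L), V = c(rep(1e-12, C - 1L), 1),
                  pi = runif(C), lambda = rep(0L, 5L))
  draws <- vapply(1:3000, function(i)
    gibbsAlpha(st0, 1L, 2L, A = 0.01, B = 0.01)$alpha, numeric(1))
  expect_equal(mean(draws), (C + 0.01 - 1) / 0.01, tolerance = 0.05)
})

test_that("an empty cluster's location wanders over the flat base measure", {
  st <- .mkState(1L, V = c(0.9, 1), pi = c(0.5, 0.5), lambda = 1L)
  draws <- numeric(4000L)
  set.seed(17)
  for (i in seq_along(draws)) {
    st <- gibbsPi(st, 10L, 20L, d = 5)
    draws[i] <- st$pi[2]
  }
  expect_equal(mean(draws), 0.5, tolerance = 0.05)
  expect_equal(sd(draws), sqrt(1 / 12), tolerance = 0.1)
})

test_that("a monoallelic cluster's location concentrates at its analytic posterior", {
  # single SNP, lambda = 1, y = n = 10: target ((1+pi)/2)^10; compare the
  # chain mean to dense numerical integration of the same density
  st <- .mkState(1L, V = 1, pi = 0.5, lambda = 1L)
  draws <- numeric(6000L)
  set.seed(19)
  for (i in seq_along(draws)) {
    st <- gibbsPi(st, 10L, 10L, d = 10)
    draws[i] <- st$pi[1]
  }
  grid <- seq(0.0005, 0.9995, by = 0.001)
  w <- ((1 + grid) / 2)^10
  expect_equal(mean(draws[-(1:500)]), sum(grid * w) / sum(w),
               tolerance = 0.03)
})

test_that("stick weights sum to one in every kept draw", {
  xc <- makeXciCounts(nSnps = 40L, seed = 3L)
  fit <- runXciSampler(xc$counts, C = 10L, iters = 400L, burnIn = 100L,
                       thin = 5L, seed = 7L)
  expect_true(all(abs(rowSums(fit@draws$weights) - 1) < 1e-9))
})

test_that("pure-tumor and pure-stroma limits are recovered", {
  set.seed(31)
  n <- rep(40L, 20L)
  mono <- data.frame(n = n, y = ifelse(runif(20) < 0.5, 0L, 40L))
  fitT <- runXciSampler(mono, C = 10L, iters = 1500L, burnIn = 500L,
                        thin = 2L, seed = 11L)
  expect_gt(overallTumorFraction(fitT)[["mean"]], 0.95)

  bal <- data.frame(n = n, y = rbinom(20L, n, 0.5))
  fitS <- runXciSampler(bal, C = 10L, iters = 1500L, burnIn = 500L,
                        thin = 2L, seed = 12L)
  expect_lt(overallTumorFraction(fitS)[["mean"]], 0.1)
})

test_that("sampler posterior means match dense grid integration (C = 2)", {
  y <- c(28L, 3L, 20L, 30L, 10L)
  n <- c(30L, 25L, 40L, 35L, 20L)
  oracle <- oracleGridPosterior(y, n, alphaFix = 1)
  fit <- runXciSampler(data.frame(n = n, y = y), C = 2L, iters = 8000L,
                       burnIn = 2000L, thin = 2L, d = 10, alpha = 1,
                       seed = 21L)
  expect_true(all(abs(snpPosterior(fit)$postPi - oracle) < 0.02))
})

test_that("flipping reference and variant counts leaves the pi posterior unchanged", {
  xc <- makeXciCounts(nSnps = 60L, seed = 5L)
  a <- runXciSampler(xc$counts, C = 10L, iters = 2000L, burnIn = 500L,
                     thin = 2L, seed = 31L)
  flipped <- xc$counts
  flipped$y <- flipped$n - flipped$y
  b <- runXciSampler(flipped, C = 10L, iters = 2000L, burnIn = 500L,
                     thin = 2L, seed = 31L)
  expect_equal(overallTumorFraction(a)[["mean"]],
               overallTumorFraction(b)[["mean"]], tolerance = 0.03)
  expect_equal(mean(abs(snpPosterior(a)$postPi - snpPosterior(b)$postPi)),
               0, tolerance = 0.04)
})

test_that("the pi density is invariant to cluster relabelling", {
  xc <- makeXciCounts(nSnps = 40L, seed = 13L)
  fit <- runXciSampler(xc$counts, C = 6L, iters = 500L, burnIn = 100L,
                       thin = 5L, seed = 41L)
  piM <- fit@draws$pi
  wM <- fit@draws$weights
  perm <- sample(ncol(piM))
  d1 <- SomaticTx:::.weightedPiDensity(piM, wM, seq(0, 1, 0.01))
  d2 <- SomaticTx:::.weightedPiDensity(piM[, perm], wM[, perm],
                                       seq(0, 1, 0.01))
  expect_equal(d1, d2)
})

test_that("the sampler is reproducible given a seed and validates input", {
  xc <- makeXciCounts(nSnps = 25L, seed = 2L)
  f1 <- runXciSampler(xc$counts, C = 5L, iters = 300L, burnIn = 100L,
                      seed = 99L)
  f2 <- runXciSampler(xc$counts, C = 5L, iters = 300L, burnIn = 100L,
                      seed = 99L)
  expect_identical(snpPosterior(f1), snpPosterior(f2))
  expect_identical(overallTumorFraction(f1), overallTumorFraction(f2))
  bad <- data.frame(n = c(10L, 5L), y = c(11L, 2L))
  expect_error(runXciSampler(bad, iters = 100L, burnIn = 10L))
})
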