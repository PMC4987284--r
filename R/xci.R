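# Tumor/stroma transcript deconvolution from X-inactivation.
#
# X inactivation is clonal in a tumor but mosaic in stroma, so at a
# heterozygous X-chromosome SNP the reference-allele read fraction is
# (1 + pi) / 2 or (1 - pi) / 2 in tumor-derived transcripts (depending on
# which allele sits on the active X) and 1/2 in stromal transcripts, where
# pi is the fraction of transcripts derived from tumor cells.  Counts
# y_i ~ Bin(n_i, lambda_i * pi_i + (1 - pi_i) / 2) are modelled with a
# Dirichlet-process mixture over pi (truncated stick-breaking
# representation, C clusters), phase indicators lambda_i ~ Bern(0.5), base
# measure U(0, 1) and concentration alpha ~ Gamma(0.01, 0.01), sampled by
# a five-step Gibbs scheme with a Metropolis-Hastings update for the
# cluster locations.

#' Expected reference-allele read fraction under the phase mixture
#'
#' f(pi) = lambda * pi + (1 - pi) / 2: with the reference allele on the
#' active X (lambda = 1) this is (1 + pi) / 2, otherwise (1 - pi) / 2; at
#' pi = 0 (pure stromal expression) both phases give 1/2.
#'
#' @param pi tumor-derived transcript fraction in [0, 1] (vectorised).
#' @param lam phase indicator in {0, 1} (vectorised).
#' @return expected reference-allele fraction.
#' @export
mixtureMean <- function(pi, lam) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  if (!all(lam %in% c(0, 1))) stop("lam must be 0 or 1")
  lam * pi + (1 - pi) / 2
}

.stickWeights <- function(V) {
  # omega_h = V_h * prod_{l<h} (1 - V_l)
  C <- length(V)
  V * cumprod(c(1, 1 - V[-C]))
}

.newDPState <- function(N, C, rng = NULL) {
  list(S = sample.int(C, N, replace = TRUE),
       V = c(stats::rbeta(C - 1L, 1, 1), 1),
       pi = stats::runif(C),
       lambda = stats::rbinom(N, 1L, 0.5),
       alpha = 1)
}

#' Gibbs step 1: allocate each SNP to a cluster
#'
#' Draws S_i from the categorical posterior proportional to (stick weight)
#' times the binomial likelihood at p_hi = lambda_i pi_h + (1 - pi_h)/2,
#' computed in log space so underflow can never zero every cluster.
#' @param state DP state list (S, V, pi, lambda, alpha).
#' @param y,n reference and total counts per SNP.
#' @return updated state.
#' @export
gibbsAllocate <- function(state, y, n) {
  C <- length(state$V)
  logw <- log(pmax(.stickWeights(state$V), 1e-300))
  # N x C matrix of log Bin(y; n, p_hi)
  piMat <- matrix(state$pi, nrow = length(y), ncol = C, byrow = TRUE)
  lamMat <- matrix(state$lambda, nrow = length(y), ncol = C)
  p <- lamMat * piMat + (1 - piMat) / 2
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- stats::dbinom(y, n, p, log = TRUE) +
    matrix(logw, nrow = length(y), ncol = C, byrow = TRUE)
  ll <- ll - apply(ll, 1, max)
  pr <- exp(ll)
  # vectorised categorical draw: row-wise cumulative sums by matmul
  cs <- pr %*% upper.tri(diag(C), diag = TRUE)
  u <- stats::runif(nrow(pr)) * cs[, C]
  state$S <- 1L + as.integer(rowSums(cs < u))
  state
}

#' Gibbs step 2: stick-breaking fractions
#'
#' V_h ~ Beta(1 + #assigned to h, alpha + #assigned beyond h) for h < C;
#' V_C = 1 closes the stick.
#' @inheritParams gibbsAllocate
#' @return updated state.
#' @export
gibbsSticks <- function(state, y, n) {
  C <- length(state$V)
  cnt <- tabulate(state$S, nbins = C)
  beyond <- rev(cumsum(rev(cnt)))  # beyond[h] = count at >= h
  nAt <- cnt[seq_len(C - 1L)]
  nBeyond <- beyond[seq_len(C - 1L) + 1L]
  state$V <- c(stats::rbeta(C - 1L, 1 + nAt, state$alpha + nBeyond), 1)
  state
}

.piLogTarget <- function(pi, aExp, bExp) {
  # log of ((1+pi)/2)^aExp * ((1-pi)/2)^bExp
  aExp * log((1 + pi) / 2) + bExp * log((1 - pi) / 2)
}

#' Gibbs step 3: cluster tumor fractions (Metropolis-Hastings)
#'
#' One MH update per cluster with proposal Beta(x' d, d (1 - x')) around the
#' current location x'; the target exponents are
#' a = sum(2 lambda y - lambda n + n - y) and b = sum(y - 2 lambda y +
#' lambda n) over the cluster's SNPs (an empty cluster reduces to the flat
#' base measure).  Boundary proposals (0 or 1) are rejected outright since
#' the proposal density is undefined there.
#' @inheritParams gibbsAllocate
#' @param d proposal scale.
#' @return updated state; attribute \code{accept} carries the per-cluster
#'   acceptance indicator.
#' @export
gibbsPi <- function(state, y, n, d = 20) {
  stopifnot(d > 0)
  C <- length(state$V)
  acc <- logical(C)
  for (h in seq_len(C)) {
    ix <- which(state$S == h)
    lam <- state$lambda[ix]; yy <- y[ix]; nn <- n[ix]
    aExp <- sum(2 * lam * yy - lam * nn + nn - yy)
    bExp <- sum(yy - 2 * lam * yy + lam * nn)
    x0 <- min(max(state$pi[h], 1e-9), 1 - 1e-9)
    x1 <- stats::rbeta(1, x0 * d, d * (1 - x0))
    if (x1 <= 0 || x1 >= 1) next  # reject boundary draw
    logR <- .piLogTarget(x1, aExp, bExp) - .piLogTarget(x0, aExp, bExp) +
      stats::dbeta(x0, x1 * d, d * (1 - x1), log = TRUE) -
      stats::dbeta(x1, x0 * d, d * (1 - x0), log = TRUE)
    if (log(stats::runif(1)) < logR) {
      state$pi[h] <- x1
      acc[h] <- TRUE
    }
  }
  attr(state, "accept") <- acc
  state
}

#' Gibbs step 4: phase indicators
#'
#' Pr(lambda_i = 1 | -) = 1 / (1 + ((1 - pi_h) / (1 + pi_h))^(2 y_i - n_i))
#' with pi_h the location of SNP i's cluster; computed through the log ratio
#' so pi_h = 1 degenerates to the correct 0/1/0.5 limits without division
#' errors.
#' @inheritParams gibbsAllocate
#' @return updated state.
#' @export
gibbsLambda <- function(state, y, n) {
  pih <- state$pi[state$S]
  pih <- pmin(pih, 1 - 1e-12)  # only log(1 - pi) can degenerate
  logRatio <- (2 * y - n) * (log(1 - pih) - log(1 + pih))
  pr1 <- stats::plogis(-logRatio)
  state$lambda <- stats::rbinom(length(y), 1L, pr1)
  state
}

#' Gibbs step 5: Dirichlet-process concentration
#'
#' (alpha | -) ~ Gamma(C + A - 1, B - sum_{l<C} log(1 - V_l)) under the
#' Gamma(A, B) prior; V_l is clipped below 1 by 1e-12 before the log.
#' @inheritParams gibbsAllocate
#' @param A,B Gamma prior shape and rate (defaults 0.01, 0.01).
#' @return updated state.
#' @export
gibbsAlpha <- function(state, y, n, A = 0.01, B = 0.01) {
  C <- length(state$V)
  V <- pmin(state$V[seq_len(C - 1L)], 1 - 1e-12)
  state$alpha <- stats::rgamma(1, shape = C + A - 1,
                               rate = B - sum(log(1 - V)))
  state
}

#' XciFit: posterior summary of the X-inactivation deconvolution
#'
#' Holds the kept posterior draws and the derived summaries: per-SNP
#' posterior mean tumor fraction, the overall (read-weighted) tumor-derived
#' transcript fraction with a credible interval, and a density of cluster
#' locations weighted by stick weights (the distribution of per-gene tumor
#' fractions).
#'
#' @slot snp data.frame(snpId, n, y, postPi).
#' @slot overall numeric: mean, lower, upper (95 percent credible interval).
#' @slot density data.frame(pi, density) on a fixed grid.
#' @slot draws list of kept draws (pi matrix, weights matrix, alpha vector).
#' @slot settings the sampler configuration used.
#' @export
setClass("XciFit",
  representation(snp = "data.frame", overall = "numeric",
                 density = "data.frame", draws = "list",
                 settings = "list"))

setMethod("show", "XciFit", function(object) {
  cat(sprintf(paste0("XciFit: %d SNPs, %d kept draws\n",
                     "overall tumor-derived transcript fraction: ",
                     "%.3f (95%% CI %.3f-%.3f)\n"),
              nrow(object@snp), length(object@draws$alpha),
              object@overall[1], object@overall[2], object@overall[3]))
})

#' @describeIn XciFit per-SNP posterior summary table
#' @param x an \code{XciFit}.
#' @export
snpPosterior <- function(x) x@snp

#' @describeIn XciFit overall tumor fraction (mean, lower, upper)
#' @export
overallTumorFraction <- function(x) x@overall

#' @describeIn XciFit density of per-gene tumor fractions
#' @export
piDensity <- function(x) x@density

#' Run the Dirichlet-process Gibbs sampler
#'
#' Cycles allocation, stick, location, phase and concentration updates.
#' The proposal scale is auto-adjusted during burn-in toward a 20-50
#' percent acceptance rate.  The overall tumor-derived transcript fraction
#' is the read-weighted posterior mean of pi over SNPs.  A split-half
#' rhat on the overall fraction traces above 1.1 raises a warning, never a
#' failure.
#'
#' @param counts data.frame with columns \code{n} (total reads) and
#'   \code{y} (reference-allele reads), one row per heterozygous X SNP;
#'   non-diploid regions are assumed excluded upstream.
#' @param C maximum number of clusters (default 40).
#' @param iters,burnIn,thin chain settings.
#' @param d initial Metropolis-Hastings proposal scale.
#' @param alpha fix the DP concentration at this value instead of sampling
#'   it (NULL, the default, samples alpha with its Gamma(0.01, 0.01) prior).
#' @param seed RNG seed for full reproducibility.
#' @return an \code{XciFit}.
#' @export
runXciSampler <- function(counts, C = 40L, iters = 5000L, burnIn = 2000L,
                          thin = 5L, d = 20, alpha = NULL, seed = 1L) {
  stopifnot(nrow(counts) >= 1L, iters > burnIn,
            all(counts$y >= 0), all(counts$y <= counts$n),
            all(counts$n >= 1))
  set.seed(seed)
  y <- as.integer(counts$y); n <- as.integer(counts$n)
  N <- length(y)
  state <- .newDPState(N, C)
  if (!is.null(alpha)) state$alpha <- alpha

  keptPi <- list(); keptW <- list(); keptAlpha <- numeric(0)
  keptSnpPi <- 0; kept <- 0L
  accWin <- 0L; totWin <- 0L
  overallTrace <- numeric(0)

  for (it in seq_len(iters)) {
    state <- gibbsAllocate(state, y, n)
    state <- gibbsSticks(state, y, n)
    state <- gibbsPi(state, y, n, d)
    acc <- attr(state, "accept")
    accWin <- accWin + sum(acc); totWin <- totWin + length(acc)
    state <- gibbsLambda(state, y, n)
    if (is.null(alpha)) state <- gibbsAlpha(state, y, n)

    if (it <= burnIn && it %% 100L == 0L && totWin > 0L) {
      rate <- accWin / totWin
      if (rate < 0.20) d <- d * 1.5       # smaller steps
      else if (rate > 0.50) d <- d / 1.5  # larger steps
      accWin <- 0L; totWin <- 0L
    }
    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      kept <- kept + 1L
      keptPi[[kept]] <- state$pi
      keptW[[kept]] <- .stickWeights(state$V)
      keptAlpha[kept] <- state$alpha
      snpPi <- state$pi[state$S]
      keptSnpPi <- keptSnpPi + snpPi
      overallTrace[kept] <- sum(n * snpPi) / sum(n)
    }
  }

  postPi <- keptSnpPi / kept
  ci <- stats::quantile(overallTrace, c(0.025, 0.975), names = FALSE)
  overall <- c(mean = mean(overallTrace), lower = ci[1], upper = ci[2])

  if (kept >= 20L) {
    half <- floor(kept / 2)
    rhat <- .splitRhat(overallTrace[seq_len(half)],
                       overallTrace[(kept - half + 1L):kept])
    if (is.finite(rhat) && rhat > 1.1)
      warning(sprintf("split-half rhat %.2f on the overall fraction; ",
                      rhat), "consider a longer chain")
  }

  piMat <- do.call(rbind, keptPi)
  wMat <- do.call(rbind, keptW)
  grid <- seq(0, 1, by = 0.01)
  dens <- .weightedPiDensity(piMat, wMat, grid)

  snp <- data.frame(counts, postPi = postPi, stringsAsFactors = FALSE)
  methods::new("XciFit", snp = snp, overall = overall,
               density = data.frame(pi = grid, density = dens),
               draws = list(pi = piMat, weights = wMat, alpha = keptAlpha),
               settings = list(C = C, iters = iters, burnIn = burnIn,
                               thin = thin, d = d, alpha = alpha,
                               seed = seed))
}

.splitRhat <- function(a, b) {
  m <- length(a)
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- m * stats::var(c(mean(a), mean(b)))
  if (W <= 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

.weightedPiDensity <- function(piMat, wMat, grid, bw = 0.02) {
  # gaussian-kernel density over cluster locations weighted by stick
  # weights, invariant to cluster relabelling
  dens <- numeric(length(grid))
  for (r in seq_len(nrow(piMat))) {
    K <- stats::dnorm(outer(grid, piMat[r, ], "-"), sd = bw)
    dens <- dens + as.vector(K %*% wMat[r, ])
  }
  dens / nrow(piMat)
}
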