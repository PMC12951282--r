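#' @include AllClasses.R
NULL

#' Cosine similarity of two binned latency profiles
#'
#' \code{S = <a, b> / (||a||_2 * ||b||_2)} for nonnegative latency-count
#' vectors. The L2 normalization makes the statistic independent of the
#' overall spiking frequency: S is 1 iff the two profiles express an
#' identical normalized spiking pattern, 0 for disjoint support. If either
#' vector is all-zero, S is 0 by convention (a silent bin reads as maximally
#' dissimilar rather than undefined).
#'
#' @param a,b nonnegative numeric vectors of equal length.
#' @return Similarity in \code{[0, 1]}.
#' @examples
#' sttrpSimilarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
sttrpSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (any(a < 0) || any(b < 0)) stop("profiles must be nonnegative")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(a * b) / (na * nb))
}

#' Overall similarity to the initial phase
#'
#' For each time bin t, averages over all 16 (trigger electrode i,
#' observation electrode j) pairs the cosine similarity between the bin's
#' latency profile and a reference profile pooled (counts summed) over the
#' initial-phase bins \code{omegaInit}. All-zero pairs contribute 0.
#'
#' @param binned a \linkS4class{BinnedSttrp} (4 x 4 x T x L).
#' @param omegaInit integer vector of 0-based time-bin indices forming the
#'   initial phase (e.g. \code{0:10} for the first 22 min at 2-min bins).
#' @param pooled if FALSE, average per-bin similarities over
#'   \code{omegaInit} instead of pooling counts before comparison.
#' @return data.frame with \code{t_bin} (0-based) and \code{similarity}.
#' @export
overallSimilarity <- function(binned, omegaInit, pooled = TRUE) {
  stopifnot(is(binned, "BinnedSttrp"))
  d <- dim(binned@counts)
  nT <- d[3]
  if (length(omegaInit) == 0L) stop("omegaInit must be nonempty")
  if (any(omegaInit < 0) || any(omegaInit >= nT))
    stop("omegaInit indices out of range")
  oi <- omegaInit + 1L
  nPairs <- d[1] * d[2]
  sims <- numeric(nT)
  for (t in seq_len(nT)) {
    acc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      prof <- binned@counts[i, j, t, ]
      s <- if (pooled) {
        ref <- if (length(oi) > 1L) colSums(binned@counts[i, j, oi, ])
               else binned@counts[i, j, oi, ]
        sttrpSimilarity(ref, prof)
      } else {
        mean(vapply(oi, function(t0)
          sttrpSimilarity(binned@counts[i, j, t0, ], prof), numeric(1)))
      }
      acc <- acc + s
    }
    sims[t] <- acc / nPairs
  }
  data.frame(t_bin = 0:(nT - 1L), similarity = sims)
}

#' Mann-Kendall trend test
#'
#' Classic non-seasonal two-sided Mann-Kendall test: S is the number of
#' concordant minus discordant pairs, the variance is tie-corrected, and the
#' p-value uses the continuity-corrected normal approximation.
#'
#' @param series numeric vector, length >= 3.
#' @return list with \code{S}, \code{varS}, \code{tau}, \code{z} and
#'   \code{p} (two-sided).
#' @examples
#' mannKendall(1:10)$S  # 45
#' @export
mannKendall <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L) stop("series must have length >= 3")
  if (any(!is.finite(series))) stop("series must be finite")
  d <- sign(outer(series, series, "-"))
  S <- sum(d[lower.tri(d)])
  ties <- table(series)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
           sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  tau <- S / (n * (n - 1) / 2)
  if (varS <= 0 || S == 0) {
    z <- 0
  } else {
    z <- (S - sign(S)) / sqrt(varS)
  }
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(S = S, varS = varS, tau = tau, z = z, p = p)
}

#' Fisher's method for combining p-values
#'
#' \code{X = -2 * sum(log(p_i))} referred to the upper tail of a chi-square
#' distribution with \code{2k} degrees of freedom.
#'
#' @param pvals p-values in \code{(0, 1]}.
#' @return The combined p-value.
#' @examples
#' fisherCombine(c(0.1, 0.1))  # ~0.0561
#' @export
fisherCombine <- function(pvals) {
  if (length(pvals) == 0L) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pvals))
  stats::pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}
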