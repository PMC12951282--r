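#' @include AllClasses.R AllGenerics.R
NULL

#' Causal Butterworth high-pass filter
#'
#' Per-electrode third-order (by default) Butterworth IIR high-pass with a
#' 300 Hz cutoff, removing the local-field/DC component before spike
#' detection. Filtering is causal (forward-only) by default, matching a
#' real-time detection chain; set \code{zeroPhase = TRUE} for offline
#' forward-backward filtering.
#'
#' @param block a \linkS4class{VoltageBlock}.
#' @param cutoffHz high-pass cutoff in Hz; must be below Nyquist.
#' @param order filter order (>= 1).
#' @param zeroPhase if TRUE use zero-phase \code{filtfilt} instead of causal
#'   filtering.
#' @return A \linkS4class{VoltageBlock} of the same shape.
#' @examples
#' vb <- VoltageBlock(sin(2 * pi * 1000 * (0:1999) / 17361))
#' hp <- highpassFilter(vb)
#' @export
highpassFilter <- function(block, cutoffHz = 300, order = 3,
                           zeroPhase = FALSE) {
  stopifnot(is(block, "VoltageBlock"))
  if (order < 1) stop("order must be >= 1")
  fs <- samplingRate(block)
  if (cutoffHz <= 0 || cutoffHz >= fs / 2)
    stop("cutoffHz must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "high")
  x <- samples(block)
  y <- apply(x, 2, function(col) {
    if (zeroPhase) signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
  if (is.null(dim(y))) y <- matrix(y, ncol = ncol(x))
  VoltageBlock(y, fs = fs, electrodeIds = electrodeIds(block))
}

#' Five-point Savitzky-Golay smoothing
#'
#' Removes high-frequency fluctuations with a 5-element, degree-2
#' Savitzky-Golay filter applied per electrode. Polynomials of degree <= 2
#' pass through unchanged.
#'
#' @param block a \linkS4class{VoltageBlock} with at least 5 samples.
#' @param p polynomial degree (default 2).
#' @param n window length (default 5).
#' @return A \linkS4class{VoltageBlock} of the same shape.
#' @export
savgolSmooth <- function(block, p = 2, n = 5) {
  stopifnot(is(block, "VoltageBlock"))
  if (nSamples(block) < n) stop("trace shorter than the smoothing window")
  x <- samples(block)
  y <- apply(x, 2, signal::sgolayfilt, p = p, n = n)
  if (is.null(dim(y))) y <- matrix(y, ncol = ncol(x))
  VoltageBlock(y, fs = samplingRate(block),
               electrodeIds = electrodeIds(block))
}

#' Smoothed nonlinear energy operator (sNEO)
#'
#' Computes \code{psi[n] = x[n]^2 - x[n-k] * x[n+k]} per electrode and
#' smooths it with a unit-peak Bartlett (triangular) window of length
#' \code{4k + 1}. The operator emphasizes transient high-frequency events
#' such as extracellular spikes. Boundary samples where psi or the
#' convolution is undefined are set to 0.
#'
#' With \code{normalize = "peak"} (default) the Bartlett window has unit
#' peak, so a unit impulse in psi maps to the window itself; with
#' \code{"area"} the window has unit DC gain, so the sNEO of a sinusoid
#' \code{A sin(wn)} converges to the constant \code{A^2 sin^2(kw)} in the
#' interior. The two conventions differ only by the fixed factor \code{2k}
#' and hence only rescale detection thresholds.
#'
#' @param block a \linkS4class{VoltageBlock} with more than \code{2k}
#'   samples.
#' @param k integer sample spacing of the operator (3 or 4 typical).
#' @param normalize Bartlett normalization, \code{"peak"} or \code{"area"}.
#' @return A \linkS4class{VoltageBlock} holding the smoothed energy trace.
#' @export
sneo <- function(block, k = 3L, normalize = c("peak", "area")) {
  stopifnot(is(block, "VoltageBlock"))
  normalize <- match.arg(normalize)
  k <- as.integer(k)
  if (k <= 0L) stop("k must be a positive integer")
  n <- nSamples(block)
  if (n <= 2L * k) stop("trace shorter than 2k + 1 samples")
  w <- signal::bartlett(4L * k + 1L)  # unit peak
  if (normalize == "area") w <- w / sum(w)
  x <- samples(block)
  y <- apply(x, 2, function(col) {
    psi <- numeric(n)
    idx <- (k + 1L):(n - k)
    psi[idx] <- col[idx]^2 - col[idx - k] * col[idx + k]
    sm <- stats::filter(psi, w, method = "convolution", sides = 2)
    sm[is.na(sm)] <- 0
    as.numeric(sm)
  })
  if (is.null(dim(y))) y <- matrix(y, ncol = ncol(x))
  VoltageBlock(y, fs = samplingRate(block),
               electrodeIds = electrodeIds(block))
}

#' MAD-based detection threshold
#'
#' Returns \code{X} times the raw median absolute deviation of the series
#' (no Gaussian consistency factor), the robust noise scale used for
#' thresholding.
#'
#' @param series numeric vector (one electrode's detection trace).
#' @param X positive threshold multiplier.
#' @return The threshold, in the units of \code{series}.
#' @examples
#' madThreshold(c(-2, -1, 0, 1, 2), X = 6)  # 6
#' @export
madThreshold <- function(series, X) {
  if (length(series) == 0L) stop("series must be nonempty")
  if (X <= 0) stop("X must be positive")
  X * stats::median(abs(series - stats::median(series)))
}
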