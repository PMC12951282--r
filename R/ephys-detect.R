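#' @include AllClasses.R ephys-filter.R
NULL

# event-walk over one electrode's detection trace
# det: series compared against thr; amp: filtered trace for amplitude/peak
walkDetection <- function(det, amp, thr, peakWin, blockWin) {
  hits <- which(det > thr)
  if (!length(hits)) return(integer(0))
  n <- length(det)
  peaks <- integer(0)
  i <- 1L
  while (i <= length(hits)) {
    c0 <- hits[i]
    win <- c0:min(c0 + peakWin - 1L, n)
    # earliest absolute maximum of the filtered trace inside the window
    p <- win[which.max(abs(amp[win]))]
    peaks <- c(peaks, p)
    resume <- c0 + peakWin + blockWin
    # skip crossings inside the peak window and the dead time
    i <- i + 1L
    while (i <= length(hits) && hits[i] < resume) i <- i + 1L
  }
  peaks
}

#' Threshold-based spike detection
#'
#' Detects spikes on a conditioned voltage block (high-pass + Savitzky-Golay
#' filtered). In \code{"direct"} mode the absolute filtered value is compared
#' against \code{X} times the electrode's raw MAD; in \code{"sneo"} mode the
#' smoothed nonlinear energy operator of the trace is thresholded (its own
#' MAD scale) while amplitude and timestamp are read from the filtered
#' trace. At the first crossing a peak-search window (1 ms default) opens;
#' the sample index of the maximum absolute filtered value is recorded (ties
#' broken by earliest sample) and detection is suppressed for a further
#' dead time (2 ms default) measured from the crossing.
#'
#' Per electrode the MAD is computed over the whole recording (optionally a
#' subrange via \code{madRange}); sneo boundary samples (first and last
#' \code{3k}) are excluded from threshold estimation. If a trace's MAD is
#' degenerate (zero up to numerical dust, e.g. noise-free synthetic data)
#' the threshold falls back to 5\% of the trace's maximum absolute value so
#' that silence stays silent and injected transients are still found.
#'
#' @param block a conditioned \linkS4class{VoltageBlock}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @param thresholds optional numeric vector of per-electrode thresholds
#'   overriding the MAD rule.
#' @param madRange optional integer range (1-based sample indices) over
#'   which to estimate the MAD.
#' @return A spike-event data.frame with columns \code{electrode},
#'   \code{t_sample} (0-based sample index of the peak), \code{t_ms},
#'   \code{amplitude_uV} and \code{detector}, sorted by \code{t_sample}.
#' @export
detectSpikes <- function(block, cfg = DetectionConfig(), thresholds = NULL,
                         madRange = NULL) {
  stopifnot(is(block, "VoltageBlock"), is(cfg, "DetectionConfig"))
  validObject(cfg)
  fs <- samplingRate(block)
  peakWin <- msToSamples(cfg@peakWindowMs, fs)
  blockWin <- msToSamples(cfg@blockMs, fs)
  amp <- samples(block)
  if (cfg@mode == "sneo") {
    det <- samples(sneo(block, cfg@kNeo))
    edge <- 3L * cfg@kNeo
  } else {
    det <- abs(amp)
    edge <- 0L
  }
  n <- nrow(amp)
  out <- vector("list", ncol(amp))
  for (e in seq_len(ncol(amp))) {
    if (is.null(thresholds)) {
      est <- if (!is.null(madRange)) madRange
             else if (edge > 0L && n > 2L * edge) (edge + 1L):(n - edge)
             else seq_len(n)
      base <- if (cfg@mode == "sneo") det[est, e] else amp[est, e]
      thr <- madThreshold(base, cfg@X)
      # degenerate noise floor (e.g. noise-free synthetic data): fall back
      # to 5% of the trace maximum, above the causal filter's ringing (~4%
      # of a transient peak) but far below any real spike
      if (thr <= 1e-9 * max(abs(amp[, e])))
        thr <- 0.05 * max(abs(amp[, e]))
    } else thr <- thresholds[e]
    peaks <- walkDetection(det[, e], amp[, e], thr, peakWin, blockWin)
    out[[e]] <- if (length(peaks)) {
      data.frame(electrode = electrodeIds(block)[e],
                 t_sample = peaks - 1L,
                 t_ms = (peaks - 1L) / fs * 1000,
                 amplitude_uV = amp[peaks, e],
                 detector = cfg@mode, stringsAsFactors = FALSE)
    } else emptyEvents()
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$t_sample, ev$electrode), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
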