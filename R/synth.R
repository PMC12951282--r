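#' @include AllClasses.R utils.R
NULL

# Poisson process with a refractory floor on [0, durationS], times in s
poissonRefractory <- function(rateHz, durationS, refractoryS) {
  # draw in chunks until past the horizon
  t <- 0; out <- numeric(0)
  repeat {
    gaps <- stats::rexp(max(16L, ceiling(rateHz * durationS * 0.5)),
                        rate = rateHz) + refractoryS
    tt <- t + cumsum(gaps)
    out <- c(out, tt[tt <= durationS])
    t <- tt[length(tt)]
    if (t > durationS) break
  }
  out
}

#' Generate a ground-truthed synthetic spike-event stream
#'
#' Emulates one 4-electrode network: homogeneous Poisson trigger spikes
#' (with a refractory floor), follower spikes on band electrodes emitted
#' with the band's fidelity at latency \code{base + slope * (T(t) - 37) +
#' jitter} (plus any drift-profile modifiers), and uncorrelated background
#' spikes on every electrode. Fully reproducible under a seed.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param durationS stream duration (s).
#' @param temperature function(t_s) -> degC, or a single number (default
#'   37).
#' @param seed optional RNG seed.
#' @param fs sampling rate used to derive integer \code{t_sample} stamps.
#' @return list with \code{events} (canonical spike-event table) and
#'   \code{truth} (list: \code{triggers}, \code{followers},
#'   \code{background} data.frames).
#' @export
generateEventStream <- function(spec, durationS, temperature = 37,
                                seed = NULL, fs = 17361) {
  stopifnot(is(spec, "NetworkSpec"))
  if (durationS <= 0) stop("durationS must be positive")
  tempFun <- if (is.function(temperature)) temperature
             else function(t) temperature
  withSeed(seed, {
    trig <- poissonRefractory(spec@triggerRateHz, durationS,
                              spec@refractoryMs / 1000)
    followers <- list()
    for (b in spec@bands) {
      stopifnot(is(b, "BandSpec"))
      for (t0 in trig) {
        fid <- b@fidelity
        if (!is.null(b@fidelityProfile))
          fid <- fid * max(0, min(1, b@fidelityProfile(t0)))
        if (stats::runif(1) >= fid) next
        Tnow <- tempFun(t0)
        lat <- b@baseLatencyMs + b@tempSlopeMsPerK * (Tnow - 37)
        if (!is.null(b@latencyShiftMs)) lat <- lat + b@latencyShiftMs(t0)
        lat <- lat + stats::rnorm(1, 0, b@jitterSdMs)
        lat <- max(lat, 0.01)              # latencies clipped below at 10 us
        followers[[length(followers) + 1L]] <-
          data.frame(electrode = b@electrode, t_ms = t0 * 1000 + lat,
                     trigger_t_ms = t0 * 1000, latency_ms = lat,
                     stringsAsFactors = FALSE)
      }
    }
    fol <- if (length(followers)) do.call(rbind, followers)
           else data.frame(electrode = character(0), t_ms = numeric(0),
                           trigger_t_ms = numeric(0), latency_ms = numeric(0))
    bg <- list()
    if (spec@backgroundRateHz > 0) {
      for (el in spec@electrodes) {
        nbg <- stats::rpois(1, spec@backgroundRateHz * durationS)
        if (nbg > 0)
          bg[[length(bg) + 1L]] <-
            data.frame(electrode = el,
                       t_ms = sort(stats::runif(nbg, 0, durationS * 1000)),
                       stringsAsFactors = FALSE)
      }
    }
    bgDf <- if (length(bg)) do.call(rbind, bg)
            else data.frame(electrode = character(0), t_ms = numeric(0))
    ev <- rbind(
      data.frame(electrode = rep(spec@triggerElectrode, length(trig)),
                 t_ms = trig * 1000, stringsAsFactors = FALSE),
      fol[, c("electrode", "t_ms")],
      bgDf)
    ev <- ev[order(ev$t_ms), , drop = FALSE]
    ev$t_sample <- as.integer(round(ev$t_ms * fs / 1000))
    ev$amplitude_uV <- rep(-spec@spikeAmplitudeUv, nrow(ev))
    ev$detector <- rep("synthetic", nrow(ev))
    ev <- ev[, c("electrode", "t_sample", "t_ms", "amplitude_uV", "detector")]
    rownames(ev) <- NULL
    list(events = ev,
         truth = list(triggers = data.frame(t_ms = trig * 1000),
                      followers = fol, background = bgDf))
  })
}

# biphasic extracellular spike template: sharp negative phase (~0.3 ms)
# followed by a smaller positive rebound; peak normalized to -1 at index
# `peakAt` (1-based)
spikeTemplate <- function(fs = 17361, negMs = 0.3) {
  sigma1 <- negMs / 2.355 / 1000 * fs          # FWHM = neg phase width
  sigma2 <- 2 * sigma1
  L <- ceiling(8 * sigma2)
  i <- seq_len(L)
  c1 <- 2.5 * sigma1; c2 <- c1 + 2.2 * sigma1
  w <- -exp(-(i - c1)^2 / (2 * sigma1^2)) + 0.35 * exp(-(i - c2)^2 / (2 * sigma2^2))
  w <- w / max(abs(w))
  list(w = w, peakAt = which.max(abs(w)))
}

#' Generate a synthetic voltage recording with ground truth
#'
#' Places scaled biphasic spike templates at ground-truth event samples on
#' top of seeded Gaussian noise, for end-to-end testing of the detection
#' chain. The ground-truth \code{t_sample} of each event is the sample of
#' the template's absolute extremum.
#'
#' @param spec a \linkS4class{NetworkSpec}; \code{noiseSdUv} and
#'   \code{spikeAmplitudeUv} set the SNR (peak amplitude / noise sd).
#' @param durationS recording duration (s).
#' @param fs sampling rate (Hz).
#' @param events optional precomputed event table (defaults to
#'   \code{generateEventStream}).
#' @param temperature,seed passed to the event generator; the seed also
#'   drives the noise.
#' @return list with \code{block} (\linkS4class{VoltageBlock}),
#'   \code{events} (ground-truth table) and \code{truth}.
#' @export
generateRecording <- function(spec, durationS, fs = 17361, events = NULL,
                              temperature = 37, seed = NULL) {
  stopifnot(is(spec, "NetworkSpec"))
  withSeed(seed, {
    truth <- NULL
    if (is.null(events)) {
      es <- generateEventStream(spec, durationS, temperature, seed = NULL,
                                fs = fs)
      events <- es$events
      truth <- es$truth
    }
    n <- ceiling(durationS * fs)
    tmpl <- spikeTemplate(fs)
    if (length(tmpl$w) > n) stop("template longer than the trace")
    x <- matrix(if (spec@noiseSdUv > 0)
                  stats::rnorm(n * length(spec@electrodes), 0, spec@noiseSdUv)
                else 0,
                n, length(spec@electrodes))
    colnames(x) <- spec@electrodes
    keep <- logical(nrow(events))
    for (r in seq_len(nrow(events))) {
      e <- match(events$electrode[r], spec@electrodes)
      if (is.na(e)) next
      p <- events$t_sample[r] + 1L           # 1-based peak sample
      i0 <- p - tmpl$peakAt + 1L
      i1 <- i0 + length(tmpl$w) - 1L
      if (i0 < 1L || i1 > n) next
      x[i0:i1, e] <- x[i0:i1, e] + spec@spikeAmplitudeUv * tmpl$w
      keep[r] <- TRUE
    }
    events <- events[keep, , drop = FALSE]
    rownames(events) <- NULL
    list(block = VoltageBlock(x, fs = fs, electrodeIds = spec@electrodes),
         events = events, truth = truth)
  })
}

#' Build a drift scenario on top of a network spec
#'
#' Applies time-varying fidelity and latency modifiers to every band of the
#' spec and generates the event stream: the programmed analogue of a
#' spiking pattern fading and shifting under uncontrolled evaporation, with
#' optional recovery.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param durationS stream duration (s).
#' @param fidelityProfile function(t_s) -> multiplicative fidelity factor
#'   in [0, 1].
#' @param latencyShiftMs optional function(t_s) -> additive latency shift
#'   (ms).
#' @param temperature,seed,fs passed to \code{\link{generateEventStream}}.
#' @return As \code{\link{generateEventStream}}.
#' @export
driftScenario <- function(spec, durationS, fidelityProfile,
                          latencyShiftMs = NULL, temperature = 37,
                          seed = NULL, fs = 17361) {
  stopifnot(is(spec, "NetworkSpec"), is.function(fidelityProfile))
  spec@bands <- lapply(spec@bands, function(b) {
    b@fidelityProfile <- fidelityProfile
    if (!is.null(latencyShiftMs)) b@latencyShiftMs <- latencyShiftMs
    b
  })
  generateEventStream(spec, durationS, temperature, seed = seed, fs = fs)
}

#' Staircase temperature schedule
#'
#' Step schedule holding each level for a fixed duration, e.g. the
#' 35.5-37 degC staircase in 250 mK steps used for latency-temperature
#' experiments.
#'
#' @param levelsC temperature levels (degC), in presentation order.
#' @param holdS hold duration per level (s).
#' @return function(t_s) -> degC.
#' @export
temperatureStaircase <- function(levelsC = seq(35.5, 37, by = 0.25),
                                 holdS = 1200) {
  force(levelsC); force(holdS)
  function(t_s) {
    i <- pmin(length(levelsC), pmax(1, floor(t_s / holdS) + 1))
    levelsC[i]
  }
}
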