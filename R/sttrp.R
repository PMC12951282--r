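#' @include AllClasses.R utils.R
NULL

# number of elements of a sorted numeric vector strictly less than x
nLess <- function(sorted, x) {
  i <- findInterval(x, sorted)
  while (i > 0L && sorted[i] >= x) i <- i - 1L
  i
}

#' Find valid triggering spikes
#'
#' A spike on the trigger electrode is a valid trigger iff no spike occurred
#' in the preceding exclusion window \code{[t - exclusionMs, t)}, counted on
#' the trigger electrode alone or on all electrodes depending on the rule's
#' scope.
#'
#' @param events spike-event table (columns \code{electrode}, \code{t_ms}).
#' @param rule a \linkS4class{TriggerRule}.
#' @param electrodes optional vector of known electrode ids; if supplied, a
#'   trigger electrode outside it raises an error (a silent but known
#'   electrode just yields no triggers).
#' @return Numeric vector of valid trigger times (ms), increasing.
#' @examples
#' ev <- data.frame(electrode = "E1", t_ms = c(5, 12, 40))
#' findValidTriggers(ev, TriggerRule("E1", exclusionMs = 10))  # 5, 40
#' @export
findValidTriggers <- function(events, rule, electrodes = NULL) {
  stopifnot(is(rule, "TriggerRule"))
  events <- asEvents(events)
  if (!is.null(electrodes) && !rule@triggerElectrode %in% electrodes)
    stop("unknown trigger electrode: ", rule@triggerElectrode)
  if (!nrow(events)) return(numeric(0))
  tt <- events$t_ms[events$electrode == rule@triggerElectrode]
  if (!length(tt)) return(numeric(0))
  scope <- if (rule@exclusionScope == "all_electrodes") sort(events$t_ms)
           else sort(tt)
  keep <- vapply(tt, function(t) {
    i <- nLess(scope, t)
    i == 0L || scope[i] < t - rule@exclusionMs
  }, logical(1))
  sort(tt[keep])
}

#' Build a spike-time-triggered raster plot
#'
#' Opens a fixed-length segment \code{[t, t + segmentMs)} at each trigger
#' time and collects every network spike inside it as (electrode, latency).
#' The trigger spike itself appears at latency 0.
#'
#' @param events spike-event table.
#' @param triggerTimes trigger times (ms), e.g. from
#'   \code{\link{findValidTriggers}}.
#' @param triggerElectrode id of the triggering electrode.
#' @param segmentMs segment length in ms.
#' @param electrodes observation electrodes; defaults to all electrodes in
#'   \code{events}.
#' @return An \linkS4class{Sttrp}.
#' @export
buildSttrp <- function(events, triggerTimes, triggerElectrode,
                       segmentMs = 5, electrodes = NULL) {
  events <- asEvents(events)
  if (is.null(electrodes))
    electrodes <- sort(unique(as.character(events$electrode)))
  events <- events[events$electrode %in% electrodes, , drop = FALSE]
  triggerTimes <- sort(unique(triggerTimes))
  ts <- events$t_ms
  segs <- lapply(triggerTimes, function(t0) {
    lo <- nLess(ts, t0)
    hi <- nLess(ts, t0 + segmentMs)
    if (hi > lo) {
      idx <- (lo + 1L):hi
      data.frame(electrode = as.character(events$electrode[idx]),
                 latency_ms = ts[idx] - t0, stringsAsFactors = FALSE)
    } else data.frame(electrode = character(0), latency_ms = numeric(0),
                      stringsAsFactors = FALSE)
  })
  new("Sttrp", triggerElectrode = as.character(triggerElectrode),
      triggers = as.numeric(triggerTimes), segments = segs,
      segmentMs = segmentMs, electrodes = as.character(electrodes))
}

#' Bin an STTRP into latency-profile counts
#'
#' Half-open binning \code{[k*delta, (k+1)*delta)} of segment latencies
#' (default 0.1 ms) and trigger times (default 120 s), yielding the
#' latency-profile tensor compared by the similarity statistic.
#'
#' @param sttrp an \linkS4class{Sttrp}.
#' @param latencyBinMs latency bin width (ms).
#' @param timeBinS trigger-time bin width (s).
#' @param durationS recording duration (s) fixing the number of time bins;
#'   defaults to the last trigger time rounded up to a full bin.
#' @return A \linkS4class{BinnedSttrp} with a single trigger-electrode
#'   layer.
#' @export
binSttrp <- function(sttrp, latencyBinMs = 0.1, timeBinS = 120,
                     durationS = NULL) {
  stopifnot(is(sttrp, "Sttrp"))
  if (latencyBinMs <= 0 || timeBinS <= 0) stop("bin widths must be positive")
  if (is.null(durationS))
    durationS <- if (length(sttrp@triggers)) max(sttrp@triggers) / 1000 else timeBinS
  nT <- max(1L, as.integer(ceiling(durationS / timeBinS - 1e-9)))
  nL <- as.integer(ceiling(sttrp@segmentMs / latencyBinMs - 1e-9))
  counts <- array(0, c(1L, length(sttrp@electrodes), nT, nL))
  jIdx <- stats::setNames(seq_along(sttrp@electrodes), sttrp@electrodes)
  for (s in seq_along(sttrp@triggers)) {
    tbin <- min(nT - 1L, floor(sttrp@triggers[s] / 1000 / timeBinS + 1e-9))
    seg <- sttrp@segments[[s]]
    if (!nrow(seg)) next
    lbin <- pmin(nL - 1L, floor(seg$latency_ms / latencyBinMs + 1e-9))
    for (r in seq_len(nrow(seg))) {
      j <- jIdx[[seg$electrode[r]]]
      counts[1L, j, tbin + 1L, lbin[r] + 1L] <-
        counts[1L, j, tbin + 1L, lbin[r] + 1L] + 1
    }
  }
  new("BinnedSttrp", counts = counts, latencyBinMs = latencyBinMs,
      timeBinS = timeBinS, triggerElectrodes = sttrp@triggerElectrode,
      obsElectrodes = sttrp@electrodes)
}

#' Build the full network STTRP tensor
#'
#' Runs trigger finding, segment building and binning with each network
#' electrode in turn as the trigger electrode, stacking the results into the
#' 4-d (i, j, t, l) latency-profile tensor used by
#' \code{\link{overallSimilarity}}.
#'
#' @param events spike-event table of one network.
#' @param electrodes the network electrodes (trigger set = observation set).
#' @param exclusionMs,exclusionScope trigger-validity rule (see
#'   \linkS4class{TriggerRule}).
#' @param segmentMs segment length (ms).
#' @param latencyBinMs,timeBinS bin widths.
#' @param durationS recording duration (s).
#' @return A \linkS4class{BinnedSttrp}.
#' @export
buildNetworkSttrp <- function(events, electrodes, exclusionMs = 5,
                              exclusionScope = "trigger_only",
                              segmentMs = 10, latencyBinMs = 0.1,
                              timeBinS = 120, durationS = NULL) {
  events <- asEvents(events)
  if (is.null(durationS))
    durationS <- if (nrow(events)) max(events$t_ms) / 1000 else timeBinS
  parts <- lapply(electrodes, function(el) {
    rule <- TriggerRule(el, exclusionMs = exclusionMs,
                        exclusionScope = exclusionScope,
                        segmentMs = segmentMs)
    st <- buildSttrp(events, findValidTriggers(events, rule), el,
                     segmentMs = segmentMs, electrodes = electrodes)
    binSttrp(st, latencyBinMs, timeBinS, durationS)
  })
  d <- dim(parts[[1]]@counts)
  counts <- array(0, c(length(electrodes), d[2], d[3], d[4]))
  for (i in seq_along(parts)) counts[i, , , ] <- parts[[i]]@counts[1, , , ]
  new("BinnedSttrp", counts = counts, latencyBinMs = latencyBinMs,
      timeBinS = timeBinS, triggerElectrodes = as.character(electrodes),
      obsElectrodes = as.character(electrodes))
}

#' Latency and transmission fidelity of a band
#'
#' For one observation electrode and latency band \code{[lo, hi)}, collects
#' the in-band latencies of every trigger segment and computes the
#' transmission fidelity: the probability that a valid trigger is followed
#' by at least one in-band spike. Also returns the per-time-bin mean latency
#' (30 s bins by default) used for trend views against temperature.
#'
#' @param sttrp an \linkS4class{Sttrp}.
#' @param band a \linkS4class{Band} within the segment.
#' @param timeBinS bin width for the latency-over-time summary (s).
#' @return A list with \code{latencies} (numeric vector of in-band
#'   latencies), \code{fidelity}, \code{medianLatency}, \code{nTriggers} and
#'   \code{byTime} (data.frame \code{t_bin}, \code{t_s}, \code{meanLatency},
#'   \code{n}).
#' @export
bandMetrics <- function(sttrp, band, timeBinS = 30) {
  stopifnot(is(sttrp, "Sttrp"), is(band, "Band"))
  if (band@latencyHiMs > sttrp@segmentMs)
    stop("band must lie within the segment")
  nTrig <- length(sttrp@triggers)
  if (nTrig == 0L) stop("transmission fidelity undefined: zero triggers")
  lat <- vector("list", nTrig)
  hit <- logical(nTrig)
  for (s in seq_len(nTrig)) {
    seg <- sttrp@segments[[s]]
    l <- seg$latency_ms[seg$electrode == band@electrode &
                        seg$latency_ms >= band@latencyLoMs &
                        seg$latency_ms < band@latencyHiMs]
    lat[[s]] <- l
    hit[s] <- length(l) > 0L
  }
  perTrig <- lapply(seq_len(nTrig), function(s)
    if (length(lat[[s]])) data.frame(t_ms = sttrp@triggers[s],
                                     latency_ms = lat[[s]]) else NULL)
  flat <- do.call(rbind, perTrig)
  byTime <- if (!is.null(flat) && nrow(flat)) {
    bin <- floor(flat$t_ms / 1000 / timeBinS)
    agg <- stats::aggregate(flat$latency_ms, list(t_bin = bin),
                            function(v) c(mean(v), length(v)))
    data.frame(t_bin = agg$t_bin, t_s = agg$t_bin * timeBinS,
               meanLatency = agg$x[, 1], n = agg$x[, 2])
  } else data.frame(t_bin = integer(0), t_s = numeric(0),
                    meanLatency = numeric(0), n = numeric(0))
  all_lat <- unlist(lat, use.names = FALSE)
  list(latencies = all_lat,
       fidelity = mean(hit),
       medianLatency = if (length(all_lat)) stats::median(all_lat) else NA_real_,
       nTriggers = nTrig,
       byTime = byTime)
}

#' Per-bin mean spike rate
#'
#' Spike counts per time bin, divided by bin duration and electrode count:
#' the average firing rate (Hz per electrode) over time.
#'
#' @param events spike-event table.
#' @param binS bin width in seconds (default 120).
#' @param nElectrodes number of electrodes averaged over; defaults to the
#'   number of distinct electrodes in the table.
#' @param durationS duration fixing the number of bins.
#' @return data.frame with \code{t_bin}, \code{t_s} and \code{rate_hz}.
#' @export
spikeRate <- function(events, binS = 120, nElectrodes = NULL,
                      durationS = NULL) {
  events <- asEvents(events)
  if (is.null(nElectrodes))
    nElectrodes <- max(1L, length(unique(events$electrode)))
  if (is.null(durationS))
    durationS <- if (nrow(events)) max(events$t_ms) / 1000 else binS
  nB <- max(1L, as.integer(ceiling(durationS / binS - 1e-9)))
  bins <- if (nrow(events))
    pmin(nB - 1L, floor(events$t_ms / 1000 / binS + 1e-9)) else integer(0)
  counts <- tabulate(bins + 1L, nbins = nB)
  data.frame(t_bin = 0:(nB - 1L), t_s = (0:(nB - 1L)) * binS,
             rate_hz = counts / binS / nElectrodes)
}

#' Stimulus-response spike counts and PSTH
#'
#' Assigns every spike to the most recent stimulus and counts, per
#' electrode, spikes with post-stimulus latency in \code{(minLatencyMs,
#' windowMs]} -- the synaptically mediated response, excluding directly
#' evoked spikes below the cutoff. Also returns a post-stimulus time
#' histogram per electrode including latencies from 0.
#'
#' @param events spike-event table.
#' @param stimTimesMs sorted stimulus times (ms).
#' @param minLatencyMs latency cutoff excluding direct responses (default
#'   5 ms).
#' @param windowMs response window end (ms after stimulus).
#' @param psthBinMs PSTH bin width (ms).
#' @return list with \code{meanSpikes} (named per-electrode mean spikes per
#'   stimulus) and \code{psth} (data.frame \code{electrode},
#'   \code{latency_lo_ms}, \code{count}).
#' @export
stimResponseCount <- function(events, stimTimesMs, minLatencyMs = 5,
                              windowMs = 250, psthBinMs = 1) {
  events <- asEvents(events)
  if (length(stimTimesMs) == 0L) stop("no stimuli supplied")
  stim <- sort(stimTimesMs)
  if (length(stim) > 1L && min(diff(stim)) < windowMs)
    warning("stimulus spacing shorter than the response window; ",
            "spikes assigned to the most recent stimulus")
  idx <- findInterval(events$t_ms, stim)
  keep <- idx >= 1L
  lat <- events$t_ms[keep] - stim[idx[keep]]
  el <- as.character(events$electrode[keep])
  electrodes <- sort(unique(as.character(events$electrode)))
  inResp <- lat > minLatencyMs & lat <= windowMs
  meanSpikes <- vapply(electrodes, function(e)
    sum(inResp & el == e) / length(stim), numeric(1))
  inPsth <- lat >= 0 & lat <= windowMs
  psth <- if (any(inPsth)) {
    b <- floor(lat[inPsth] / psthBinMs)
    tab <- stats::aggregate(rep(1L, sum(inPsth)),
                            list(electrode = el[inPsth], bin = b), sum)
    data.frame(electrode = tab$electrode,
               latency_lo_ms = tab$bin * psthBinMs, count = tab$x)
  } else data.frame(electrode = character(0), latency_lo_ms = numeric(0),
                    count = integer(0))
  list(meanSpikes = meanSpikes, psth = psth)
}

#' Plot an STTRP raster
#'
#' Base-graphics raster of segment latencies (x) against trigger time (y),
#' one color per observation electrode.
#'
#' @param x an \linkS4class{Sttrp}.
#' @param ... passed to \code{plot}.
#' @return Invisibly, NULL.
#' @export
plotSttrp <- function(x, ...) {
  stopifnot(is(x, "Sttrp"))
  cols <- grDevices::hcl.colors(max(4L, length(x@electrodes)), "Dark 3")
  plot(NA, xlim = c(0, x@segmentMs),
       ylim = range(c(0, x@triggers / 1000)), xlab = "latency [ms]",
       ylab = "trigger time [s]",
       main = paste("STTRP, trigger", x@triggerElectrode), ...)
  for (s in seq_along(x@triggers)) {
    seg <- x@segments[[s]]
    if (!nrow(seg)) next
    ci <- match(seg$electrode, x@electrodes)
    graphics::points(seg$latency_ms, rep(x@triggers[s] / 1000, nrow(seg)),
                     pch = "|", col = cols[ci], cex = 0.5)
  }
  invisible(NULL)
}
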