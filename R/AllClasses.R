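#' @import methods
NULL

#' Multi-electrode voltage block
#'
#' Container for a window of raw or filtered multi-electrode voltage data:
#' a numeric matrix (samples in rows, electrodes in columns, microvolts),
#' the sampling rate and the ordered electrode identifiers.
#'
#' @slot samples numeric matrix, \code{n_samples x n_electrodes}, in uV.
#' @slot fs sampling rate in Hz (default 17361, the acquisition rate of the
#'   recording hardware this package models).
#' @slot electrodeIds character vector of electrode identifiers, one per
#'   column of \code{samples}.
#' @export
setClass("VoltageBlock",
  representation(samples = "matrix", fs = "numeric", electrodeIds = "character"),
  prototype(samples = matrix(numeric(0), 0, 0), fs = 17361,
            electrodeIds = character(0))
)

setValidity("VoltageBlock", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  else if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (ncol(object@samples) != length(object@electrodeIds))
    msg <- c(msg, "electrodeIds length must match the number of columns")
  if (anyDuplicated(object@electrodeIds))
    msg <- c(msg, "electrodeIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a VoltageBlock
#'
#' @param samples numeric matrix (samples x electrodes) or a vector for a
#'   single electrode, in uV.
#' @param fs sampling rate in Hz.
#' @param electrodeIds electrode identifiers; defaults to \code{"E1"...}.
#' @return A \linkS4class{VoltageBlock}.
#' @examples
#' vb <- VoltageBlock(matrix(rnorm(100), 50, 2), fs = 17361)
#' nSamples(vb)
#' @export
VoltageBlock <- function(samples, fs = 17361, electrodeIds = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(electrodeIds)) electrodeIds <- paste0("E", seq_len(ncol(samples)))
  new("VoltageBlock", samples = samples, fs = as.numeric(fs),
      electrodeIds = as.character(electrodeIds))
}

#' Spike detection configuration
#'
#' Parameters of the threshold-based spike detector. In \code{"direct"} mode
#' the MAD threshold is applied to the absolute filtered trace; in
#' \code{"sneo"} mode it is applied to the smoothed nonlinear energy operator
#' of the trace while amplitude and timestamp are still read from the
#' filtered trace.
#'
#' @slot mode \code{"direct"} or \code{"sneo"}.
#' @slot X threshold multiplier on the raw median absolute deviation
#'   (defaults: 6 direct, 12.5 sneo).
#' @slot kNeo integer sample spacing of the energy operator (3 or 4 typical).
#' @slot peakWindowMs length of the peak-search window opened at a threshold
#'   crossing (ms).
#' @slot blockMs dead time after the peak window during which the electrode
#'   is blocked for detection (ms).
#' @slot hpCutoffHz high-pass cutoff used upstream (Hz); stored for
#'   provenance.
#' @slot hpOrder high-pass filter order.
#' @export
setClass("DetectionConfig",
  representation(mode = "character", X = "numeric", kNeo = "integer",
                 peakWindowMs = "numeric", blockMs = "numeric",
                 hpCutoffHz = "numeric", hpOrder = "integer"),
  prototype(mode = "direct", X = 6, kNeo = 3L, peakWindowMs = 1,
            blockMs = 2, hpCutoffHz = 300, hpOrder = 3L)
)

setValidity("DetectionConfig", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("direct", "sneo"))
    msg <- c(msg, "mode must be 'direct' or 'sneo'")
  if (object@X <= 0) msg <- c(msg, "X must be positive")
  if (object@kNeo <= 0L) msg <- c(msg, "kNeo must be a positive integer")
  if (object@peakWindowMs <= 0 || object@blockMs <= 0)
    msg <- c(msg, "peakWindowMs and blockMs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionConfig
#'
#' @param mode \code{"direct"} or \code{"sneo"}.
#' @param X MAD multiplier. Defaults to 6 in direct mode, 12.5 in sneo mode.
#' @param kNeo energy-operator spacing in samples.
#' @param peakWindowMs,blockMs peak-search window and post-window dead time
#'   in ms.
#' @param hpCutoffHz,hpOrder upstream high-pass parameters (provenance).
#' @return A \linkS4class{DetectionConfig}.
#' @export
DetectionConfig <- function(mode = c("direct", "sneo"), X = NULL, kNeo = 3L,
                            peakWindowMs = 1, blockMs = 2,
                            hpCutoffHz = 300, hpOrder = 3L) {
  mode <- match.arg(mode)
  if (is.null(X)) X <- if (mode == "direct") 6 else 12.5
  new("DetectionConfig", mode = mode, X = as.numeric(X),
      kNeo = as.integer(kNeo), peakWindowMs = peakWindowMs, blockMs = blockMs,
      hpCutoffHz = hpCutoffHz, hpOrder = as.integer(hpOrder))
}

#' Spike-time-triggered raster plot (STTRP)
#'
#' Per-trigger segments of relative spike latencies: each valid trigger spike
#' on the trigger electrode opens a fixed-length segment, and every spike of
#' the network falling inside it is stored as (electrode, latency).
#'
#' @slot triggerElectrode identifier of the triggering electrode.
#' @slot triggers numeric vector of trigger times (ms from recording start),
#'   strictly increasing.
#' @slot segments list parallel to \code{triggers}; each element a
#'   data.frame with columns \code{electrode} and \code{latency_ms} in
#'   \code{[0, segmentMs)}.
#' @slot segmentMs segment length in ms.
#' @slot electrodes observation electrodes of the network.
#' @export
setClass("Sttrp",
  representation(triggerElectrode = "character", triggers = "numeric",
                 segments = "list", segmentMs = "numeric",
                 electrodes = "character"),
  prototype(triggerElectrode = NA_character_, triggers = numeric(0),
            segments = list(), segmentMs = 5, electrodes = character(0))
)

setValidity("Sttrp", function(object) {
  msg <- character(0)
  if (object@segmentMs <= 0) msg <- c(msg, "segmentMs must be positive")
  if (length(object@triggers) != length(object@segments))
    msg <- c(msg, "one segment per trigger required")
  if (is.unsorted(object@triggers, strictly = TRUE) && length(object@triggers) > 1)
    msg <- c(msg, "triggers must be strictly increasing")
  for (seg in object@segments) {
    if (!all(c("electrode", "latency_ms") %in% names(seg))) {
      msg <- c(msg, "segments need electrode and latency_ms columns"); break
    }
    if (nrow(seg) && (min(seg$latency_ms) < 0 ||
                      max(seg$latency_ms) >= object@segmentMs)) {
      msg <- c(msg, "latencies must lie in [0, segmentMs)"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Binned STTRP tensor
#'
#' Latency-profile counts indexed (trigger electrode i, observation
#' electrode j, time bin t, latency bin l). The latency profile at fixed
#' (i, j, t) is the vector compared by \code{\link{sttrpSimilarity}}.
#'
#' @slot counts 4-d array of nonnegative counts, dim
#'   \code{(i, j, t, l)}.
#' @slot latencyBinMs latency bin width (ms, default 0.1).
#' @slot timeBinS trigger-time bin width (s, default 120).
#' @slot triggerElectrodes,obsElectrodes electrode identifiers along the
#'   first two dimensions.
#' @export
setClass("BinnedSttrp",
  representation(counts = "array", latencyBinMs = "numeric",
                 timeBinS = "numeric", triggerElectrodes = "character",
                 obsElectrodes = "character"),
  prototype(counts = array(0, c(0, 0, 0, 0)), latencyBinMs = 0.1,
            timeBinS = 120)
)

setValidity("BinnedSttrp", function(object) {
  msg <- character(0)
  if (length(dim(object@counts)) != 4L)
    msg <- c(msg, "counts must be a 4-d array (i, j, t, l)")
  else {
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (dim(object@counts)[1] != length(object@triggerElectrodes) ||
        dim(object@counts)[2] != length(object@obsElectrodes))
      msg <- c(msg, "electrode labels must match counts dimensions")
  }
  if (object@latencyBinMs <= 0 || object@timeBinS <= 0)
    msg <- c(msg, "bin widths must be positive")
  if (length(msg)) msg else TRUE
})

#' Camera frame of the laser-reflection level sensor
#'
#' 8-bit grayscale frame (600 rows x 800 columns) as captured by the
#' level-sensor camera, with its physical pixel pitch.
#'
#' @slot pixels integer matrix, 600 x 800, values in [0, 255]. Row 1 of the
#'   matrix is sensor row 0.
#' @slot pixelPitchUm physical pixel pitch in micrometres (4.5).
#' @export
setClass("SensorImage",
  representation(pixels = "matrix", pixelPitchUm = "numeric"),
  prototype(pixels = matrix(0L, 600, 800), pixelPitchUm = 4.5)
)

setValidity("SensorImage", function(object) {
  msg <- character(0)
  if (!identical(dim(object@pixels), c(600L, 800L)))
    msg <- c(msg, "pixels must be a 600 x 800 matrix")
  if (any(object@pixels < 0) || any(object@pixels > 255))
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (object@pixelPitchUm <= 0) msg <- c(msg, "pixelPitchUm must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorImage
#'
#' @param pixels 600 x 800 numeric matrix of 8-bit intensities (rounded and
#'   clipped to [0, 255]).
#' @param pixelPitchUm pixel pitch in um.
#' @return A \linkS4class{SensorImage}.
#' @export
SensorImage <- function(pixels = matrix(0L, 600, 800), pixelPitchUm = 4.5) {
  storage.mode(pixels) <- "integer"
  new("SensorImage", pixels = pixels, pixelPitchUm = pixelPitchUm)
}

#' Level-sensor reading
#'
#' Integer level value in tenths of a sensor row (0--5990 valid); the code
#' 6000 marks an invalid measurement (no credible laser reflection found).
#'
#' @slot value integer reading.
#' @slot valid logical; \code{FALSE} iff \code{value == 6000}.
#' @export
setClass("LevelReading",
  representation(value = "integer", valid = "logical"),
  prototype(value = 6000L, valid = FALSE)
)

setValidity("LevelReading", function(object) {
  msg <- character(0)
  if ((object@value == 6000L) == object@valid)
    msg <- c(msg, "value 6000 must coincide with valid == FALSE")
  if (object@valid && (object@value < 0L || object@value > 5990L))
    msg <- c(msg, "valid readings lie in [0, 5990]")
  if (length(msg)) msg else TRUE
})

LevelReading <- function(value) {
  value <- as.integer(value)
  new("LevelReading", value = value, valid = value != 6000L)
}

#' Well geometry of the level sensor
#'
#' @slot betaDeg laser angle of incidence in degrees (default 60).
#' @slot wellDiameterMm inner well diameter in mm (default 19).
#' @slot pixelPitchUm camera pixel pitch in um (default 4.5).
#' @export
setClass("WellGeometry",
  representation(betaDeg = "numeric", wellDiameterMm = "numeric",
                 pixelPitchUm = "numeric"),
  prototype(betaDeg = 60, wellDiameterMm = 19, pixelPitchUm = 4.5)
)

setValidity("WellGeometry", function(object) {
  msg <- character(0)
  if (object@betaDeg <= 0 || object@betaDeg >= 90)
    msg <- c(msg, "betaDeg must lie in (0, 90)")
  if (object@wellDiameterMm <= 0) msg <- c(msg, "wellDiameterMm must be positive")
  if (object@pixelPitchUm <= 0) msg <- c(msg, "pixelPitchUm must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname WellGeometry-class
#' @param betaDeg,wellDiameterMm,pixelPitchUm see slots.
#' @return A \linkS4class{WellGeometry}.
#' @export
WellGeometry <- function(betaDeg = 60, wellDiameterMm = 19, pixelPitchUm = 4.5) {
  new("WellGeometry", betaDeg = betaDeg, wellDiameterMm = wellDiameterMm,
      pixelPitchUm = pixelPitchUm)
}

#' State of one MEA well for the environment simulators
#'
#' @slot volumeUl medium volume in uL.
#' @slot concentrations named numeric vector of solute concentrations (mM).
#' @slot temperatureC medium temperature in degrees C.
#' @slot upperThreshold,lowerThreshold level-sensor thresholds (level units);
#'   NA until calibrated.
#' @export
setClass("WellState",
  representation(volumeUl = "numeric", concentrations = "numeric",
                 temperatureC = "numeric", upperThreshold = "numeric",
                 lowerThreshold = "numeric"),
  prototype(volumeUl = 1000, concentrations = c(Mg = 0.81),
            temperatureC = 37, upperThreshold = NA_real_,
            lowerThreshold = NA_real_)
)

setValidity("WellState", function(object) {
  msg <- character(0)
  if (object@volumeUl <= 0) msg <- c(msg, "volumeUl must be positive")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be nonnegative")
  if (length(object@concentrations) && is.null(names(object@concentrations)))
    msg <- c(msg, "concentrations must be named")
  if (length(msg)) msg else TRUE
})

#' @rdname WellState-class
#' @param volumeUl,concentrations,temperatureC,upperThreshold,lowerThreshold
#'   see slots.
#' @return A \linkS4class{WellState}.
#' @export
WellState <- function(volumeUl = 1000, concentrations = c(Mg = 0.81),
                      temperatureC = 37, upperThreshold = NA_real_,
                      lowerThreshold = NA_real_) {
  new("WellState", volumeUl = volumeUl, concentrations = concentrations,
      temperatureC = temperatureC, upperThreshold = upperThreshold,
      lowerThreshold = lowerThreshold)
}

#' Latency band of one observation electrode
#'
#' @slot electrode observation electrode id.
#' @slot latencyLoMs,latencyHiMs band limits in ms, half-open
#'   \code{[lo, hi)}.
#' @export
setClass("Band",
  representation(electrode = "character", latencyLoMs = "numeric",
                 latencyHiMs = "numeric"),
  prototype(electrode = NA_character_, latencyLoMs = 3.25, latencyHiMs = 4.5)
)

setValidity("Band", function(object) {
  if (object@latencyLoMs < 0 || object@latencyLoMs >= object@latencyHiMs)
    "band limits must satisfy 0 <= lo < hi" else TRUE
})

#' @rdname Band-class
#' @param electrode,latencyLoMs,latencyHiMs see slots.
#' @return A \linkS4class{Band}.
#' @export
Band <- function(electrode, latencyLoMs = 3.25, latencyHiMs = 4.5) {
  new("Band", electrode = as.character(electrode), latencyLoMs = latencyLoMs,
      latencyHiMs = latencyHiMs)
}

#' Trigger-validity rule for STTRP construction
#'
#' A trigger-electrode spike is a valid trigger iff no spike occurred in the
#' preceding \code{exclusionMs} window, on the trigger electrode alone
#' (\code{"trigger_only"}) or on any electrode (\code{"all_electrodes"}).
#'
#' @slot triggerElectrode id of the triggering electrode.
#' @slot exclusionMs exclusion window before the trigger (ms, >= 0).
#' @slot exclusionScope \code{"trigger_only"} or \code{"all_electrodes"}.
#' @slot segmentMs segment length opened at each valid trigger (ms).
#' @export
setClass("TriggerRule",
  representation(triggerElectrode = "character", exclusionMs = "numeric",
                 exclusionScope = "character", segmentMs = "numeric"),
  prototype(triggerElectrode = NA_character_, exclusionMs = 10,
            exclusionScope = "trigger_only", segmentMs = 5)
)

setValidity("TriggerRule", function(object) {
  msg <- character(0)
  if (object@exclusionMs < 0) msg <- c(msg, "exclusionMs must be >= 0")
  if (object@segmentMs <= 0) msg <- c(msg, "segmentMs must be positive")
  if (!object@exclusionScope %in% c("trigger_only", "all_electrodes"))
    msg <- c(msg, "exclusionScope must be trigger_only or all_electrodes")
  if (length(msg)) msg else TRUE
})

#' @rdname TriggerRule-class
#' @param triggerElectrode,exclusionMs,exclusionScope,segmentMs see slots.
#' @return A \linkS4class{TriggerRule}.
#' @export
TriggerRule <- function(triggerElectrode, exclusionMs = 10,
                        exclusionScope = c("trigger_only", "all_electrodes"),
                        segmentMs = 5) {
  new("TriggerRule", triggerElectrode = as.character(triggerElectrode),
      exclusionMs = exclusionMs, exclusionScope = match.arg(exclusionScope),
      segmentMs = segmentMs)
}

#' Synthetic network specification
#'
#' Describes one 4-electrode network of the synthetic event-stream
#' generator: Poisson trigger activity on a trigger electrode, follower
#' bands on observation electrodes, and optional uncorrelated background
#' spiking.
#'
#' @slot electrodes ids of the 4 network electrodes.
#' @slot triggerElectrode id of the trigger electrode (one of
#'   \code{electrodes}).
#' @slot triggerRateHz mean trigger rate in Hz.
#' @slot bands list of \linkS4class{BandSpec}.
#' @slot backgroundRateHz rate of uncorrelated background spikes per
#'   non-trigger electrode (Hz).
#' @slot refractoryMs refractory floor of the trigger process (ms).
#' @slot noiseSdUv voltage noise s.d. for rendered recordings (uV).
#' @slot spikeAmplitudeUv peak template amplitude for rendered recordings
#'   (uV, negative phase).
#' @export
setClass("NetworkSpec",
  representation(electrodes = "character", triggerElectrode = "character",
                 triggerRateHz = "numeric", bands = "list",
                 backgroundRateHz = "numeric", refractoryMs = "numeric",
                 noiseSdUv = "numeric", spikeAmplitudeUv = "numeric"),
  prototype(electrodes = c("E1", "E2", "E3", "E4"), triggerElectrode = "E1",
            triggerRateHz = 2, bands = list(), backgroundRateHz = 0.2,
            refractoryMs = 10, noiseSdUv = 5, spikeAmplitudeUv = 40)
)

setValidity("NetworkSpec", function(object) {
  msg <- character(0)
  if (!object@triggerElectrode %in% object@electrodes)
    msg <- c(msg, "triggerElectrode must be one of electrodes")
  if (object@triggerRateHz <= 0) msg <- c(msg, "triggerRateHz must be positive")
  if (object@backgroundRateHz < 0)
    msg <- c(msg, "backgroundRateHz must be >= 0")
  for (b in object@bands)
    if (!is(b, "BandSpec")) { msg <- c(msg, "bands must be BandSpec objects"); break }
  if (length(msg)) msg else TRUE
})

#' Follower-band specification for the synthetic generator
#'
#' @slot electrode observation electrode carrying the band.
#' @slot baseLatencyMs latency at the 37 degC reference temperature (ms).
#' @slot jitterSdMs Gaussian latency jitter s.d. (ms).
#' @slot fidelity probability that a trigger is followed by a band spike.
#' @slot tempSlopeMsPerK latency change per kelvin (<= 0 mimics the
#'   physiological speed-up with warming).
#' @slot fidelityProfile optional function(t_s) -> multiplicative fidelity
#'   modifier in [0, 1] (drift scenarios).
#' @slot latencyShiftMs optional function(t_s) -> additive latency shift in
#'   ms (drift scenarios).
#' @export
setClass("BandSpec",
  representation(electrode = "character", baseLatencyMs = "numeric",
                 jitterSdMs = "numeric", fidelity = "numeric",
                 tempSlopeMsPerK = "numeric", fidelityProfile = "ANY",
                 latencyShiftMs = "ANY"),
  prototype(electrode = NA_character_, baseLatencyMs = 4, jitterSdMs = 0.1,
            fidelity = 0.9, tempSlopeMsPerK = 0, fidelityProfile = NULL,
            latencyShiftMs = NULL)
)

setValidity("BandSpec", function(object) {
  msg <- character(0)
  if (object@fidelity < 0 || object@fidelity > 1)
    msg <- c(msg, "fidelity must lie in [0, 1]")
  if (object@jitterSdMs < 0) msg <- c(msg, "jitterSdMs must be >= 0")
  if (object@baseLatencyMs < 0) msg <- c(msg, "baseLatencyMs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BandSpec-class
#' @param electrode,baseLatencyMs,jitterSdMs,fidelity,tempSlopeMsPerK,fidelityProfile,latencyShiftMs
#'   see slots.
#' @return A \linkS4class{BandSpec}.
#' @export
BandSpec <- function(electrode, baseLatencyMs = 4, jitterSdMs = 0.1,
                     fidelity = 0.9, tempSlopeMsPerK = 0,
                     fidelityProfile = NULL, latencyShiftMs = NULL) {
  new("BandSpec", electrode = as.character(electrode),
      baseLatencyMs = baseLatencyMs, jitterSdMs = jitterSdMs,
      fidelity = fidelity, tempSlopeMsPerK = tempSlopeMsPerK,
      fidelityProfile = fidelityProfile, latencyShiftMs = latencyShiftMs)
}

#' @rdname NetworkSpec-class
#' @param electrodes,triggerElectrode,triggerRateHz,bands,backgroundRateHz,refractoryMs,noiseSdUv,spikeAmplitudeUv
#'   see slots.
#' @return A \linkS4class{NetworkSpec}.
#' @export
NetworkSpec <- function(electrodes = c("E1", "E2", "E3", "E4"),
                        triggerElectrode = electrodes[1], triggerRateHz = 2,
                        bands = list(), backgroundRateHz = 0.1 * triggerRateHz,
                        refractoryMs = 10, noiseSdUv = 5,
                        spikeAmplitudeUv = 40) {
  new("NetworkSpec", electrodes = as.character(electrodes),
      triggerElectrode = as.character(triggerElectrode),
      triggerRateHz = triggerRateHz, bands = bands,
      backgroundRateHz = backgroundRateHz, refractoryMs = refractoryMs,
      noiseSdUv = noiseSdUv, spikeAmplitudeUv = spikeAmplitudeUv)
}

#' PI-controlled thermal plant of one MEA well
#'
#' First-order lumped plant \code{tau * dT/dt = -(T - Tenv) + u} with PI
#' actuation \code{u} (kelvin of steady-state authority), anti-windup
#' clamping, instantaneous-mixing bolus disturbances and RTD output
#' quantization.
#'
#' @slot setpointC temperature setpoint (degC).
#' @slot kp,ki PI gains (u in K, error in K, integral in K s).
#' @slot tauS plant time constant (s).
#' @slot envC ambient temperature seen by the plant (degC).
#' @slot mediumVolumeUl medium volume used for bolus mixing (uL).
#' @slot rtdLsbK RTD quantization step (K, default 0.032).
#' @slot uMin,uMax actuation clamp (K).
#' @export
setClass("ThermalPlant",
  representation(setpointC = "numeric", kp = "numeric", ki = "numeric",
                 tauS = "numeric", envC = "numeric",
                 mediumVolumeUl = "numeric", rtdLsbK = "numeric",
                 uMin = "numeric", uMax = "numeric"),
  prototype(setpointC = 37, kp = 20, ki = 1, tauS = 30, envC = 22,
            mediumVolumeUl = 1000, rtdLsbK = 0.032, uMin = -15, uMax = 40)
)

setValidity("ThermalPlant", function(object) {
  msg <- character(0)
  if (object@kp < 0 || object@ki < 0) msg <- c(msg, "gains must be >= 0")
  if (object@tauS <= 0) msg <- c(msg, "tauS must be positive")
  if (object@rtdLsbK <= 0) msg <- c(msg, "rtdLsbK must be positive")
  if (object@uMin >= object@uMax) msg <- c(msg, "uMin must be < uMax")
  if (length(msg)) msg else TRUE
})

#' @rdname ThermalPlant-class
#' @param setpointC,kp,ki,tauS,envC,mediumVolumeUl,rtdLsbK,uMin,uMax see
#'   slots.
#' @return A \linkS4class{ThermalPlant}.
#' @export
ThermalPlant <- function(setpointC = 37, kp = 20, ki = 1, tauS = 30,
                         envC = 22, mediumVolumeUl = 1000, rtdLsbK = 0.032,
                         uMin = -15, uMax = 40) {
  new("ThermalPlant", setpointC = setpointC, kp = kp, ki = ki, tauS = tauS,
      envC = envC, mediumVolumeUl = mediumVolumeUl, rtdLsbK = rtdLsbK,
      uMin = uMin, uMax = uMax)
}

#' Syringe-pump model for the level-control simulator
#'
#' @slot stepPerUl motor steps per uL (informational).
#' @slot hysteresisUl pump hysteresis bound (uL, <= 10 per the hardware
#'   characterization this model follows).
#' @slot incrementUl water-addition quantum (uL, default 2).
#' @slot rateUlPerS pumping speed (uL/s).
#' @export
setClass("PumpModel",
  representation(stepPerUl = "numeric", hysteresisUl = "numeric",
                 incrementUl = "numeric", rateUlPerS = "numeric"),
  prototype(stepPerUl = 100, hysteresisUl = 5, incrementUl = 2,
            rateUlPerS = 0.2)
)

setValidity("PumpModel", function(object) {
  msg <- character(0)
  if (object@stepPerUl <= 0 || object@incrementUl <= 0 ||
      object@rateUlPerS <= 0 || object@hysteresisUl < 0)
    msg <- c(msg, "pump parameters must be positive")
  if (object@hysteresisUl > 10)
    msg <- c(msg, "hysteresisUl must be <= 10")
  if (length(msg)) msg else TRUE
})

#' @rdname PumpModel-class
#' @param stepPerUl,hysteresisUl,incrementUl,rateUlPerS see slots.
#' @return A \linkS4class{PumpModel}.
#' @export
PumpModel <- function(stepPerUl = 100, hysteresisUl = 5, incrementUl = 2,
                      rateUlPerS = 0.2) {
  new("PumpModel", stepPerUl = stepPerUl, hysteresisUl = hysteresisUl,
      incrementUl = incrementUl, rateUlPerS = rateUlPerS)
}
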