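#' @include AllClasses.R
NULL

#' Accessors for meaflow classes
#'
#' Small accessor generics exposing the slots of the core containers without
#' reaching into them directly.
#'
#' @param x a meaflow object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))
#' @rdname accessors
#' @export
setGeneric("triggers", function(x) standardGeneric("triggers"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("levelValue", function(x) standardGeneric("levelValue"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname accessors
#' @export
setMethod("samples", "VoltageBlock", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "VoltageBlock", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("electrodeIds", "VoltageBlock", function(x) x@electrodeIds)
#' @rdname accessors
#' @export
setMethod("nSamples", "VoltageBlock", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("nElectrodes", "VoltageBlock", function(x) ncol(x@samples))

#' @rdname accessors
#' @export
setMethod("triggers", "Sttrp", function(x) x@triggers)
#' @rdname accessors
#' @export
setMethod("segments", "Sttrp", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("electrodeIds", "Sttrp", function(x) x@electrodes)

#' @rdname accessors
#' @export
setMethod("binCounts", "BinnedSttrp", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("pixels", "SensorImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("levelValue", "LevelReading", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("isValid", "LevelReading", function(x) x@valid)

setMethod("show", "VoltageBlock", function(object) {
  cat(sprintf("VoltageBlock: %d samples x %d electrodes @ %.0f Hz (%.2f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              nrow(object@samples) / object@fs))
})

setMethod("show", "Sttrp", function(object) {
  n_sp <- sum(vapply(object@segments, nrow, integer(1)))
  cat(sprintf(
    "Sttrp: trigger %s, %d triggers, %d segment spikes, segment %.1f ms\n",
    object@triggerElectrode, length(object@triggers), n_sp, object@segmentMs))
})

setMethod("show", "BinnedSttrp", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "BinnedSttrp: %d x %d electrodes, %d time bins (%.0f s), %d latency bins (%.1f ms), %d spikes\n",
    d[1], d[2], d[3], object@timeBinS, d[4], object@latencyBinMs,
    sum(object@counts)))
})

setMethod("show", "SensorImage", function(object) {
  cat(sprintf("SensorImage: 600 x 800, 8-bit, pitch %.1f um, max %d\n",
              object@pixelPitchUm, max(object@pixels)))
})

setMethod("show", "LevelReading", function(object) {
  cat(if (object@valid) sprintf("LevelReading: %d (valid)\n", object@value)
      else "LevelReading: 6000 (invalid)\n")
})

setMethod("show", "WellState", function(object) {
  cat(sprintf("WellState: %.1f uL, %.2f degC, [%s]\n", object@volumeUl,
              object@temperatureC,
              paste(sprintf("%s=%.3g mM", names(object@concentrations),
                            object@concentrations), collapse = ", ")))
})
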