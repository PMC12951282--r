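#' @include AllClasses.R utils.R
NULL

#' Write a raw recording (int16 binary + sidecar)
#'
#' Samples are quantized at the declared gain (uV per LSB), clamped to the
#' int16 range, and written little-endian in sample-major interleaved
#' order (all electrodes of sample 0, then sample 1, ...). A structured-
#' text (YAML) sidecar at \code{<path>.yaml} declares the sampling rate,
#' gain and electrode ids. Both writes are atomic.
#'
#' @param block a \linkS4class{VoltageBlock}.
#' @param path output path of the binary file.
#' @param gainUvPerLsb gain in uV per least-significant bit.
#' @return Invisibly, \code{path}.
#' @export
writeRecording <- function(block, path, gainUvPerLsb = 0.195) {
  stopifnot(is(block, "VoltageBlock"))
  q <- round(samples(block) / gainUvPerLsb)
  q <- pmin(pmax(q, -32768), 32767)   # q first so the matrix dim survives
  atomicWrite(path, function(tmp) {
    con <- file(tmp, "wb"); on.exit(close(con))
    writeBin(as.integer(t(q)), con, size = 2L, endian = "little")
  })
  sidecar <- list(format = "meaflow-raw-int16",
                  fs_hz = samplingRate(block),
                  gain_uV_per_lsb = gainUvPerLsb,
                  n_samples = nSamples(block),
                  electrode_ids = as.list(electrodeIds(block)))
  atomicWrite(paste0(path, ".yaml"), function(tmp)
    yaml::write_yaml(sidecar, tmp))
  invisible(path)
}

#' Read a raw recording (int16 binary + sidecar)
#'
#' Streams the binary in fixed-size chunks and reassembles the voltage
#' matrix at the sidecar's gain. The file size must be an exact multiple of
#' the electrode stride, and must match the sidecar's sample count.
#'
#' @param path path of the binary file (sidecar at \code{<path>.yaml}).
#' @param chunkSamples samples per streamed chunk.
#' @return A \linkS4class{VoltageBlock}.
#' @export
readRecording <- function(path, chunkSamples = 65536L) {
  sc <- paste0(path, ".yaml")
  if (!file.exists(sc)) stop("missing sidecar: ", sc)
  meta <- yaml::read_yaml(sc)
  ids <- as.character(unlist(meta$electrode_ids))
  nEl <- length(ids)
  nBytes <- file.size(path)
  if (nBytes %% (2L * nEl) != 0)
    stop("stride mismatch: file size not a multiple of the electrode count")
  nSamp <- nBytes / (2L * nEl)
  if (!is.null(meta$n_samples) && meta$n_samples != nSamp)
    stop("sidecar sample count does not match file size")
  con <- file(path, "rb"); on.exit(close(con))
  chunks <- list()
  remaining <- nSamp
  while (remaining > 0) {
    take <- min(chunkSamples, remaining)
    v <- readBin(con, "integer", n = take * nEl, size = 2L, signed = TRUE,
                 endian = "little")
    chunks[[length(chunks) + 1L]] <- matrix(v, ncol = nEl, byrow = TRUE)
    remaining <- remaining - take
  }
  x <- do.call(rbind, chunks) * meta$gain_uV_per_lsb
  VoltageBlock(x, fs = meta$fs_hz, electrodeIds = ids)
}

#' Read/write spike-event tables as CSV
#'
#' Canonical columns: \code{electrode}, \code{t_sample}, \code{t_ms},
#' \code{amplitude_uV}, \code{detector}. Writing is atomic; reading
#' restores column types and preserves row order.
#'
#' @param events event data.frame.
#' @param path CSV path.
#' @return \code{writeEvents}: invisibly, the path. \code{readEvents}: the
#'   event data.frame.
#' @export
writeEvents <- function(events, path) {
  atomicWrite(path, function(tmp)
    utils::write.csv(events, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("no such event file: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("electrode", "t_ms") %in% names(ev)))
    stop("malformed event file: required columns missing")
  ev$electrode <- as.character(ev$electrode)
  ev
}

#' Read/write 8-bit binary PGM (P5) images
#'
#' Only the binary P5 dialect with maxval <= 255 is supported; ASCII (P2)
#' files raise an unsupported-dialect error. Pixel row 1 of the matrix is
#' the top image row (sensor row 0).
#'
#' @param image a \linkS4class{SensorImage} (write) / path (read).
#' @param path file path.
#' @return \code{writePGM}: invisibly, the path. \code{readPGM}: a
#'   \linkS4class{SensorImage}.
#' @export
writePGM <- function(image, path) {
  stopifnot(is(image, "SensorImage"))
  px <- pixels(image)
  atomicWrite(path, function(tmp) {
    con <- file(tmp, "wb"); on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con,
              eos = NULL)
    writeBin(as.raw(as.integer(t(px))), con)
  })
  invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  readToken <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("malformed PGM: truncated header")
      if (ch == "#") {                      # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- readToken()
  if (magic == "P2") stop("unsupported PGM dialect: ASCII (P2)")
  if (magic != "P5") stop("malformed PGM: bad magic '", magic, "'")
  w <- as.integer(readToken()); h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  if (is.na(w) || is.na(h) || is.na(maxval)) stop("malformed PGM header")
  if (maxval > 255) stop("unsupported PGM: maxval > 255")
  raw <- readBin(con, "raw", n = w * h)
  if (length(raw) != w * h) stop("malformed PGM: truncated pixel data")
  SensorImage(matrix(as.integer(raw), nrow = h, ncol = w, byrow = TRUE))
}

#' Package run-configuration defaults
#'
#' The default analysis and simulation parameters: 300 Hz third-order
#' high-pass, 5-point Savitzky-Golay, MAD multipliers 6 (direct) / 12.5
#' (sneo), sNEO spacing 3, 1 ms peak window + 2 ms dead time, 10 ms trigger
#' exclusion, 5 ms segment, 0.1 ms / 2 min STTRP bins, 5 ms stimulus
#' cutoff.
#'
#' @return Nested list of defaults.
#' @export
meaflowDefaults <- function() {
  list(
    seed = 1L,
    detection = list(mode = "direct", X = 6, X_sneo = 12.5, kNeo = 3L,
                     peakWindowMs = 1, blockMs = 2, hpCutoffHz = 300,
                     hpOrder = 3L),
    trigger = list(exclusionMs = 10, exclusionScope = "trigger_only",
                   segmentMs = 5),
    band = list(latencyLoMs = 3.25, latencyHiMs = 4.5),
    binning = list(latencyBinMs = 0.1, timeBinS = 120),
    stimulus = list(minLatencyMs = 5, windowMs = 250),
    sensor = list(rowSumMin = 2550, pixelMin = 200, betaDeg = 60,
                  wellDiameterMm = 19, pixelPitchUm = 4.5),
    level = list(incrementUl = 2, exchangeUl = 50, cycles = 3L,
                 settleS = 20, nMeas = 30L),
    thermal = list(setpointC = 37, kp = 20, ki = 1, tauS = 30, envC = 22,
                   rtdLsbK = 0.032)
  )
}

#' Read a structured-text run configuration
#'
#' Reads a YAML configuration, validates it against the known parameter
#' blocks, and injects package defaults for anything missing (each
#' injection is reported via message).
#'
#' @param path YAML file path; NULL returns the pure defaults.
#' @param defaults default tree (see \code{\link{meaflowDefaults}}).
#' @param quiet suppress injection messages.
#' @return Nested configuration list.
#' @export
readConfig <- function(path = NULL, defaults = meaflowDefaults(),
                       quiet = FALSE) {
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config: top level must be a mapping")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  for (blk in names(defaults)) {
    if (is.null(cfg[[blk]])) {
      if (!quiet) message("config: block '", blk, "' missing, defaults used")
      next
    }
    if (is.list(defaults[[blk]])) {
      missing <- setdiff(names(defaults[[blk]]), names(cfg[[blk]]))
      if (length(missing) && !quiet)
        message("config: ", blk, ".", paste(missing, collapse = ", "),
                " missing, defaults injected")
      merged[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]])
    } else merged[[blk]] <- cfg[[blk]]
  }
  merged
}
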