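#' @include AllClasses.R utils.R
NULL

#' Subpixel laser-spot detection
#'
#' Locates the laser reflection on a sensor frame by integrating pixel
#' values per row. The row with the maximal integral is the spot center
#' candidate; the frame is invalid (code 6000) unless that integral exceeds
#' \code{rowSumMin} (strictly) and the brightest pixel of the frame exceeds
#' \code{pixelMin} (strictly). For subpixel resolution a weighted mean of
#' 0-based row indices is taken over the 20-row window \code{{m-10, ...,
#' m+9}} around the maximum (clipped at the sensor borders), with the raw
#' row integrals as weights, multiplied by 10 and rounded half-away-from-
#' zero to an integer. A one-row (4.5 um) spot shift therefore changes the
#' reading by exactly 10 units.
#'
#' @param image a \linkS4class{SensorImage}.
#' @param rowSumMin minimum winning row integral (default \code{10 * 255}).
#' @param pixelMin minimum brightest-pixel value (default 200).
#' @return A \linkS4class{LevelReading} (0--5990 valid, 6000 invalid).
#' @examples
#' detectSpot(SensorImage())  # all dark -> invalid, 6000
#' @export
detectSpot <- function(image, rowSumMin = 10 * 255, pixelMin = 200) {
  stopifnot(is(image, "SensorImage"))
  px <- pixels(image)
  rs <- rowSums(px)
  m1 <- which.max(rs)                      # 1-based row, earliest tie
  if (rs[m1] <= rowSumMin || max(px) <= pixelMin) return(LevelReading(6000L))
  m <- m1 - 1L                             # 0-based sensor row
  win <- max(0L, m - 10L):min(599L, m + 9L)
  w <- rs[win + 1L]
  centroid <- sum(win * w) / sum(w)
  LevelReading(as.integer(roundHalfAway(10 * centroid)))
}

#' Convert level units to liquid-height change
#'
#' The reflection displacement on the sensor is \code{dx = 2 sin(beta) dh},
#' and 10 level units equal one pixel pitch, so
#' \code{dh = (units / 10 * pitch) / (2 sin beta)}.
#'
#' @param deltaUnits change in level-sensor reading (units).
#' @param geom a \linkS4class{WellGeometry}.
#' @return Height change in micrometres.
#' @examples
#' unitsToHeight(10, WellGeometry())  # 4.5/sqrt(3) ~ 2.598 um
#' @export
unitsToHeight <- function(deltaUnits, geom = WellGeometry()) {
  stopifnot(is(geom, "WellGeometry"))
  (deltaUnits / 10 * geom@pixelPitchUm) /
    (2 * sin(geom@betaDeg * pi / 180))
}

#' Liquid-height change to level units (inverse of unitsToHeight)
#'
#' @param deltaHeightUm height change in um.
#' @param geom a \linkS4class{WellGeometry}.
#' @return Change in level units (not rounded).
#' @export
heightToUnits <- function(deltaHeightUm, geom = WellGeometry()) {
  stopifnot(is(geom, "WellGeometry"))
  10 * 2 * sin(geom@betaDeg * pi / 180) * deltaHeightUm / geom@pixelPitchUm
}

#' Theoretical sensor slope per unit volume
#'
#' For a cylindrical well of diameter d, one microlitre changes the liquid
#' height by \code{1000 / (pi (d/2)^2)} um, which the reflection geometry
#' magnifies by \code{2 sin(beta)} on the sensor. With beta = 60 deg and
#' d = 19 mm the slope is about 6.11 um per uL.
#'
#' @param geom a \linkS4class{WellGeometry}.
#' @return Sensor displacement per volume, in um/uL.
#' @examples
#' theoreticalSlope(WellGeometry())  # ~6.11
#' @export
theoreticalSlope <- function(geom = WellGeometry()) {
  stopifnot(is(geom, "WellGeometry"))
  if (geom@wellDiameterMm <= 0) stop("well diameter must be positive")
  area_mm2 <- pi * (geom@wellDiameterMm / 2)^2
  2 * sin(geom@betaDeg * pi / 180) * 1000 / area_mm2
}

#' Render a synthetic laser-spot frame
#'
#' Draws a Gaussian intensity spot on the sensor at a row offset encoding a
#' liquid-height change through the reflection geometry, optionally with
#' seeded Gaussian pixel noise, clipped to [0, 255]. This is the synthetic
#' stand-in for camera frames used for round-trip testing of the detector.
#' The default spot is a bright, horizontally elongated reflection streak
#' (peak 255, sigma 4 rows x 20 columns): the row-integral signal must
#' dominate the clipped-noise baseline for the raw-sum subpixel centroid to
#' be accurate, as it does for a laser reflection on a dark frame.
#'
#' @param heightOffsetUm liquid-height offset relative to the spot's base
#'   position (um).
#' @param geom a \linkS4class{WellGeometry}.
#' @param spot list with \code{rowCenter} (0-based base row), \code{col}
#'   (0-based column center), \code{widthRows}, \code{widthCols} (Gaussian
#'   sigmas in pixels) and \code{peak} intensity.
#' @param noiseSd pixel-noise s.d. at peak intensity (counts). Noise is
#'   shot-noise-like: its s.d. scales with the square root of the local
#'   intensity, and the dark frame stays black-level clamped at 0, as on
#'   the 8-bit camera this emulates. A zero-mean additive dark noise would
#'   be clipped at 0 and bias the raw-sum centroid; the real sensor's dark
#'   pixels read 0.
#' @param seed optional RNG seed for the noise.
#' @return A \linkS4class{SensorImage}.
#' @export
renderSpot <- function(heightOffsetUm = 0, geom = WellGeometry(),
                       spot = list(rowCenter = 300, col = 400,
                                   widthRows = 4, widthCols = 20,
                                   peak = 255),
                       noiseSd = 0, seed = NULL) {
  stopifnot(is(geom, "WellGeometry"))
  r0 <- spot$rowCenter + heightToUnits(heightOffsetUm, geom) / 10
  if (r0 < 0 || r0 > 599 || spot$col < 0 || spot$col > 799)
    stop("spot center off the sensor")
  rows <- 0:599; cols <- 0:799
  gr <- exp(-(rows - r0)^2 / (2 * spot$widthRows^2))
  gc <- exp(-(cols - spot$col)^2 / (2 * spot$widthCols^2))
  img <- spot$peak * outer(gr, gc)
  if (noiseSd > 0)
    img <- img + withSeed(seed, matrix(stats::rnorm(600 * 800, 0, noiseSd),
                                       600, 800)) * sqrt(img / spot$peak)
  SensorImage(matrix(pmin(255L, pmax(0L, as.integer(round(img)))), 600, 800))
}

#' Empirical sensor slope from a rendered volume sweep
#'
#' Renders frames for a sweep of well volumes, runs the spot detector, and
#' regresses the reading (converted to um on the sensor) on volume. Used to
#' cross-check the closed-form \code{\link{theoreticalSlope}}.
#'
#' @param volumesUl volumes to sweep (uL).
#' @param baseVolumeUl volume at which the spot sits at its base row.
#' @param geom a \linkS4class{WellGeometry}.
#' @param spot,noiseSd,seed passed to \code{\link{renderSpot}}.
#' @return list with \code{slopeUmPerUl}, \code{readings} and the
#'   \code{fit}.
#' @export
empiricalSlope <- function(volumesUl = seq(970, 1000, by = 2),
                           baseVolumeUl = 985, geom = WellGeometry(),
                           spot = list(rowCenter = 300, col = 400,
                                       widthRows = 4, widthCols = 20,
                                       peak = 255),
                           noiseSd = 0, seed = NULL) {
  area_mm2 <- pi * (geom@wellDiameterMm / 2)^2
  readings <- vapply(seq_along(volumesUl), function(i) {
    dh <- (volumesUl[i] - baseVolumeUl) * 1000 / area_mm2
    s <- if (is.null(seed)) NULL else seed + i
    r <- detectSpot(renderSpot(dh, geom, spot, noiseSd, s))
    if (!isValid(r)) stop("invalid reading during slope sweep")
    levelValue(r)
  }, numeric(1))
  sensor_um <- readings / 10 * geom@pixelPitchUm
  fit <- stats::lm(sensor_um ~ volumesUl)
  list(slopeUmPerUl = unname(stats::coef(fit)[2]),
       readings = data.frame(volume_uL = volumesUl, reading = readings),
       fit = fit)
}
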