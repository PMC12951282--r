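#' @include AllClasses.R utils.R
NULL

#' Partial medium exchange (replace semantics)
#'
#' Replacing a fraction f of the medium with fresh medium moves every solute
#' concentration to \code{(1 - f) * conc + f * fresh}; the volume is
#' unchanged. n half-exchanges against a fixed fresh concentration converge
#' geometrically: \code{(c0 - fresh) / 2^n + fresh}.
#'
#' @param conc current concentration(s), mM (may be a named vector).
#' @param fraction exchanged fraction in \code{[0, 1]}.
#' @param fresh fresh-medium concentration(s), mM (scalar or matching
#'   vector).
#' @return New concentration(s), mM.
#' @examples
#' applyExchange(3.81, 0.5, 0.81)  # 2.31
#' @export
applyExchange <- function(conc, fraction, fresh) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  (1 - fraction) * conc + fraction * fresh
}

#' Concentrated-stock addition (additive v/v convention)
#'
#' Adding \code{vvFraction} (v/v) of a stock at \code{stock} mM raises the
#' concentration by \code{vvFraction * stock} under the additive convention
#' (0.81 mM + 0.5\% of 1 M = 5.81 mM). The exact-dilution model, which also
#' accounts for the volume added (giving ~5.78 mM for the same numbers), is
#' available with \code{exact = TRUE}.
#'
#' @param conc current concentration, mM.
#' @param vvFraction volume fraction of stock added (>= 0).
#' @param stock stock concentration, mM.
#' @param exact use the exact dilution \code{(conc + vv*stock)/(1 + vv)}.
#' @return New concentration, mM.
#' @examples
#' applyStockAddition(0.81, 0.005, 1000)  # 5.81
#' @export
applyStockAddition <- function(conc, vvFraction, stock, exact = FALSE) {
  if (vvFraction < 0 || any(conc < 0) || stock < 0)
    stop("inputs must be nonnegative")
  if (exact) (conc + vvFraction * stock) / (1 + vvFraction)
  else conc + vvFraction * stock
}

#' Simulate the evaporation-compensation level-control loop
#'
#' Event-driven simulation of one well: evaporation removes water
#' continuously (concentrating solutes); whenever the sensor reading falls
#' to or below the control threshold and the shared syringe pump is free,
#' one increment of ultrapure water is added (conserving solute mass,
#' diluting concentrations). Pump-busy intervals (e.g. medium exchanges on
#' other wells) suppress additions and are logged.
#'
#' The default threshold corresponds to one increment below the starting
#' volume, so the controlled volume ripples within about one increment of
#' the start (plus the sensor deadband).
#'
#' @param state a \linkS4class{WellState}.
#' @param pump a \linkS4class{PumpModel}.
#' @param evapRateUlPerMin evaporation rate (uL/min, >= 0).
#' @param sensor function(volumeUl) -> level units (may be noisy or
#'   quantized); a \linkS4class{LevelReading}-style 6000 is treated as
#'   invalid and skipped.
#' @param durationS simulated duration (s).
#' @param dtS time step (s).
#' @param threshold control threshold in level units; defaults to
#'   \code{sensor(V0 - increment)} evaluated once.
#' @param busyIntervals optional data.frame \code{t0_s}, \code{t1_s} of
#'   pump-busy windows.
#' @param controlEnabled disable to observe free evaporation.
#' @param seed optional RNG seed (for noisy sensors).
#' @return list with \code{trace} (t_s, volume_uL, reading, solute
#'   concentrations) and \code{events} (t_s, type, volume_uL).
#' @export
simulateLevelControl <- function(state, pump, evapRateUlPerMin, sensor,
                                 durationS, dtS = 1, threshold = NULL,
                                 busyIntervals = NULL,
                                 controlEnabled = TRUE, seed = NULL) {
  stopifnot(is(state, "WellState"), is(pump, "PumpModel"))
  if (durationS <= 0) stop("durationS must be positive")
  if (evapRateUlPerMin < 0) stop("evapRateUlPerMin must be >= 0")
  withSeed(seed, {
    V0 <- state@volumeUl
    if (is.null(threshold)) threshold <- sensor(V0 - pump@incrementUl)
    amounts <- state@concentrations * V0   # nmol-equivalents, conserved
    V <- V0
    times <- seq(dtS, durationS, by = dtS)
    nrec <- length(times) + 1L
    trace <- data.frame(t_s = c(0, times), volume_uL = NA_real_,
                        reading = NA_real_)
    concTrace <- matrix(NA_real_, nrec, length(amounts),
                        dimnames = list(NULL, names(amounts)))
    trace$volume_uL[1] <- V
    trace$reading[1] <- sensor(V)
    concTrace[1, ] <- amounts / V
    events <- list()
    pumpBusy <- function(t) {
      !is.null(busyIntervals) &&
        any(t >= busyIntervals$t0_s & t <= busyIntervals$t1_s)
    }
    for (s in seq_along(times)) {
      t <- times[s]
      V <- V - evapRateUlPerMin * dtS / 60
      if (V <= 0) stop("well ran dry")
      reading <- sensor(V)
      if (controlEnabled && reading != 6000 &&
          reading <= threshold + 1e-9) {
        if (pumpBusy(t)) {
          events[[length(events) + 1L]] <-
            data.frame(t_s = t, type = "add_skipped_pump_busy",
                       volume_uL = V)
        } else {
          V <- V + pump@incrementUl   # pure water: solute mass conserved
          events[[length(events) + 1L]] <-
            data.frame(t_s = t, type = "water_add", volume_uL = V)
          reading <- sensor(V)
        }
      }
      trace$volume_uL[s + 1L] <- V
      trace$reading[s + 1L] <- reading
      concTrace[s + 1L, ] <- amounts / V
    }
    trace <- cbind(trace, as.data.frame(concTrace))
    list(trace = trace,
         events = if (length(events)) do.call(rbind, events)
                  else data.frame(t_s = numeric(0), type = character(0),
                                  volume_uL = numeric(0)))
  })
}

#' Calibrate the medium-exchange level thresholds
#'
#' Mirrors the hardware calibration routine: in each of 3 cycles the pump
#' removes \code{exchangeUl} of medium, waits for the surface to settle,
#' takes the median of \code{nMeas} sensor readings as the cycle's lower
#' threshold, then adds the volume back and takes the median again as the
#' upper threshold. The final thresholds are the means over cycles.
#'
#' @param state a \linkS4class{WellState}.
#' @param pump a \linkS4class{PumpModel}.
#' @param sensor function(volumeUl) -> level units; must never return 6000
#'   during calibration.
#' @param cycles number of cycles (default 3).
#' @param settleS settling pause before measuring (s; recorded, no effect
#'   on the noiseless model).
#' @param nMeas readings per median (default 30).
#' @param exchangeUl exchanged volume per cycle (uL, default 50).
#' @param seed optional RNG seed.
#' @return list with \code{upper}, \code{lower} (level units) and
#'   \code{perCycle} data.frame.
#' @export
calibrateThresholds <- function(state, pump, sensor, cycles = 3,
                                settleS = 20, nMeas = 30, exchangeUl = 50,
                                seed = NULL) {
  stopifnot(is(state, "WellState"), is(pump, "PumpModel"))
  withSeed(seed, {
    V <- state@volumeUl
    med <- function(vol) {
      r <- vapply(seq_len(nMeas), function(i) sensor(vol), numeric(1))
      if (any(r == 6000)) stop("calibration failure: invalid sensor reading")
      stats::median(r)
    }
    lo <- hi <- numeric(cycles)
    for (cy in seq_len(cycles)) {
      V <- V - exchangeUl
      if (V <= 0) stop("calibration failure: well ran dry")
      lo[cy] <- med(V)
      V <- V + exchangeUl
      hi[cy] <- med(V)
    }
    list(upper = mean(hi), lower = mean(lo),
         perCycle = data.frame(cycle = seq_len(cycles), lower = lo,
                               upper = hi))
  })
}

#' Run a perfusion protocol over multiple wells
#'
#' Executes an ordered list of steps against a list of well states. Steps
#' are lists with a \code{well} index, an \code{action} of
#' \code{"add_stock"} (fields \code{vv}, \code{stock_mM}, \code{solute}),
#' \code{"half_exchange"} (fields \code{fraction}, \code{fresh_mM}: scalar
#' or named vector) or \code{"hold"} (field \code{duration_s}), and an
#' optional requested start time \code{at_s}. A single shared pump serves
#' all wells: pumped steps occupy it for \code{volume / rate} seconds, and
#' a step requesting the pump before it is free raises a scheduling error.
#' Evaporation (water only) acts on all wells while time advances.
#'
#' @param plan list of step lists (see Details above).
#' @param states list of \linkS4class{WellState} objects.
#' @param evapRateUlPerMin evaporation rate applied to every well.
#' @param exchangeUl volume moved per half-exchange bookkeeping (uL), used
#'   for pump-busy accounting (replace semantics keep well volume fixed).
#' @param pumpRateUlPerS pump speed (uL/s).
#' @return list with \code{states} (final), \code{timeline} (one row per
#'   step and well: t_s, well, action, volume_uL, one column per solute)
#'   and \code{pumpBusy} (data.frame t0_s, t1_s of pump occupancy).
#' @export
runPerfusionProtocol <- function(plan, states, evapRateUlPerMin = 0,
                                 exchangeUl = 50, pumpRateUlPerS = 0.2) {
  stopifnot(is.list(states), all(vapply(states, is, logical(1), "WellState")))
  now <- 0
  pumpFree <- 0
  busy <- list()
  rows <- list()
  evap <- function(st, dt) {
    if (dt <= 0 || evapRateUlPerMin == 0) return(st)
    amt <- st@concentrations * st@volumeUl
    st@volumeUl <- st@volumeUl - evapRateUlPerMin * dt / 60
    if (st@volumeUl <= 0) stop("well ran dry during protocol")
    st@concentrations <- amt / st@volumeUl
    st
  }
  record <- function(t, w, action) {
    st <- states[[w]]
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(t_s = t, well = w, action = action,
                 volume_uL = st@volumeUl),
      as.data.frame(as.list(st@concentrations)))
  }
  for (w in seq_along(states)) record(0, w, "init")
  for (step in plan) {
    if (is.null(step$action)) stop("step without action")
    wantsPump <- step$action %in% c("add_stock", "half_exchange")
    t0 <- if (!is.null(step$at_s)) step$at_s else max(now, pumpFree)
    if (wantsPump && t0 < pumpFree)
      stop("scheduling error: concurrent pump request at t=", t0)
    dt <- t0 - now
    if (dt < 0) stop("steps must be ordered in time")
    states <- lapply(states, evap, dt = dt)
    now <- t0
    w <- if (!is.null(step$well)) step$well else 1L
    st <- states[[w]]
    if (step$action == "add_stock") {
      sol <- if (!is.null(step$solute)) step$solute else names(st@concentrations)[1]
      st@concentrations[[sol]] <-
        applyStockAddition(st@concentrations[[sol]], step$vv, step$stock_mM)
      pumpDur <- (step$vv * st@volumeUl) / pumpRateUlPerS
      pumpFree <- now + pumpDur
      busy[[length(busy) + 1L]] <- c(now, pumpFree)
    } else if (step$action == "half_exchange") {
      fresh <- step$fresh_mM
      if (is.null(names(fresh)) && length(fresh) == 1L)
        fresh <- stats::setNames(rep(fresh, length(st@concentrations)),
                                 names(st@concentrations))
      st@concentrations <- applyExchange(st@concentrations, step$fraction,
                                         fresh[names(st@concentrations)])
      pumpDur <- 2 * exchangeUl / pumpRateUlPerS  # remove + add
      pumpFree <- now + pumpDur
      busy[[length(busy) + 1L]] <- c(now, pumpFree)
    } else if (step$action == "hold") {
      states <- lapply(states, evap, dt = step$duration_s)
      now <- now + step$duration_s
      states[[w]] <- states[[w]]
      record(now, w, "hold")
      next
    } else stop("unknown action: ", step$action)
    states[[w]] <- st
    record(now, w, step$action)
  }
  busyDf <- if (length(busy)) {
    m <- do.call(rbind, busy)
    data.frame(t0_s = m[, 1], t1_s = m[, 2])
  } else data.frame(t0_s = numeric(0), t1_s = numeric(0))
  timeline <- do.call(rbind, rows)
  rownames(timeline) <- NULL
  list(states = states, timeline = timeline, pumpBusy = busyDf)
}

#' Simulate the PI-controlled medium temperature
#'
#' First-order lumped plant \code{tau dT/dt = -(T - Tenv) + u} under PI
#' control with anti-windup (conditional integration at the actuation
#' clamp). Medium boluses mix instantaneously:
#' \code{T <- (V0 T + V Tin) / (V0 + V)} (the well volume is restored
#' afterwards, matching a remove-then-add exchange). The returned trace
#' carries both the true temperature and the RTD-quantized readout
#' (nearest multiple of the LSB).
#'
#' The integrator is initialized for steady state at the initial setpoint,
#' so an undisturbed run holds the setpoint exactly.
#'
#' @param plant a \linkS4class{ThermalPlant}.
#' @param setpoint function(t_s) -> degC, or a single number.
#' @param boluses optional data.frame \code{t_s}, \code{volume_uL},
#'   \code{temp_C} of medium additions.
#' @param durationS simulated duration (s).
#' @param dtS integration step (s).
#' @return data.frame \code{t_s}, \code{setpoint_C}, \code{T_true_C},
#'   \code{T_rtd_C}, \code{u}; attribute \code{"diverged"} flags runaway
#'   error under unstable gains.
#' @export
simulateThermal <- function(plant, setpoint = NULL, boluses = NULL,
                            durationS = 600, dtS = 0.1) {
  stopifnot(is(plant, "ThermalPlant"))
  if (durationS <= 0) stop("durationS must be positive")
  spFun <- if (is.null(setpoint)) function(t) plant@setpointC
           else if (is.function(setpoint)) setpoint
           else function(t) setpoint
  T <- spFun(0)
  integ <- if (plant@ki > 0) (T - plant@envC) / plant@ki else 0
  times <- seq(0, durationS, by = dtS)
  n <- length(times)
  out <- data.frame(t_s = times, setpoint_C = NA_real_, T_true_C = NA_real_,
                    T_rtd_C = NA_real_, u = NA_real_)
  bolusIdx <- if (!is.null(boluses)) order(boluses$t_s) else integer(0)
  nextBolus <- 1L
  for (s in seq_len(n)) {
    t <- times[s]
    while (nextBolus <= length(bolusIdx) &&
           boluses$t_s[bolusIdx[nextBolus]] <= t) {
      b <- boluses[bolusIdx[nextBolus], ]
      T <- (plant@mediumVolumeUl * T + b$volume_uL * b$temp_C) /
        (plant@mediumVolumeUl + b$volume_uL)
      nextBolus <- nextBolus + 1L
    }
    sp <- spFun(t)
    e <- sp - T
    uRaw <- plant@kp * e + plant@ki * (integ + e * dtS)
    if (uRaw >= plant@uMin && uRaw <= plant@uMax) {
      integ <- integ + e * dtS            # integrate only when unsaturated
      u <- uRaw
    } else u <- min(plant@uMax, max(plant@uMin, uRaw))
    out$setpoint_C[s] <- sp
    out$T_true_C[s] <- T
    out$T_rtd_C[s] <- round(T / plant@rtdLsbK) * plant@rtdLsbK
    out$u[s] <- u
    T <- T + dtS * (-(T - plant@envC) + u) / plant@tauS
  }
  err <- abs(out$setpoint_C - out$T_true_C)
  lastTenth <- err[times > 0.9 * durationS]
  attr(out, "diverged") <- length(lastTenth) > 0 &&
    stats::median(lastTenth) > max(1, 2 * stats::median(err[seq_len(min(n, 50))]))
  out
}
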