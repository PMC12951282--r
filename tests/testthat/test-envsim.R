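# environment simulators: dilution arithmetic, level control, calibration,
# perfusion scheduling, thermal control

test_that("exchange arithmetic is exact and contracts toward fresh", {
  expect_identical(applyExchange(3.81, 0, 0.81), 3.81)
  expect_identical(applyExchange(3.81, 1, 0.81), 0.81)
  w <- 3.81
  for (i in 1:3) w <- applyExchange(w, 0.5, 0.81)
  expect_equal(round(w, 2), 1.19)
  # contraction identity: n half-exchanges give (c0-fresh)/2^n + fresh
  expect_equal(w, (3.81 - 0.81) / 8 + 0.81)
  for (f in c(0.2, 0.5, 0.9)) {
    c1 <- applyExchange(5, f, 1)
    expect_equal(abs(c1 - 1), (1 - f) * abs(5 - 1))
  }
  expect_error(applyExchange(1, 1.2, 0), "\\[0, 1\\]")
})

test_that("stock addition follows the additive v/v convention (exact model optional)", {
  expect_identical(applyStockAddition(0.81, 0, 1000), 0.81)
  expect_equal(applyStockAddition(0.81, 0.005, 1000), 5.81)
  # three +1 mM steps with 1 M stock
  cc <- 0.81
  for (i in 1:3) cc <- applyStockAddition(cc, 0.001, 1000)
  expect_equal(cc, 3.81)
  # exact dilution is slightly lower
  expect_lt(applyStockAddition(0.81, 0.005, 1000, exact = TRUE), 5.81)
  expect_error(applyStockAddition(0.81, -0.1, 1000), "nonnegative")
})

test_that("level control counts additions and conserves solute mass", {
  st <- WellState(volumeUl = 1000)
  pm <- PumpModel(incrementUl = 2)
  lin <- function(v) 6.74 * v
  # zero evaporation -> nothing happens
  r0 <- simulateLevelControl(st, pm, 0, lin, durationS = 600)
  expect_identical(nrow(r0$events), 0L)
  expect_true(all(r0$trace$volume_uL == 1000))

  # 10 uL/h compensated with 2 uL increments over 1 h -> 5 additions
  r <- simulateLevelControl(st, pm, 10 / 60, lin, durationS = 3600)
  expect_identical(sum(r$events$type == "water_add"), 5L)
  # ripple bounded by the increment (+ integration step)
  expect_lte(max(r$trace$volume_uL) - min(r$trace$volume_uL), 4)
  # pure-water additions conserve solute amount while diluting
  amount <- r$trace$Mg * r$trace$volume_uL
  expect_equal(max(abs(amount - amount[1])), 0, tolerance = 1e-9)

  # free evaporation at the printed rate: 0.18 uL/min for 4 h = 43.2 uL
  r2 <- simulateLevelControl(st, pm, 0.18, lin, 4 * 3600,
                             controlEnabled = FALSE)
  expect_equal(1000 - min(r2$trace$volume_uL), 43.2, tolerance = 1e-9)
  expect_identical(nrow(r2$events), 0L)
  # evaporation concentrates the solute
  expect_gt(max(r2$trace$Mg), 0.81)

  # pump-busy intervals suppress additions and are logged
  busy <- data.frame(t0_s = 0, t1_s = 3600)
  rb <- simulateLevelControl(st, pm, 10 / 60, lin, 3600,
                             busyIntervals = busy)
  expect_identical(sum(rb$events$type == "water_add"), 0L)
  expect_gt(sum(rb$events$type == "add_skipped_pump_busy"), 0L)
  expect_error(simulateLevelControl(st, pm, 1, lin, -5), "positive")
})

test_that("quantized sensing keeps the volume ripple within 4 uL", {
  st <- WellState(volumeUl = 1000)
  pm <- PumpModel(incrementUl = 2)
  qsens <- function(v) round(2 * v)   # slope 2 units/uL, 1-unit quantization
  r <- simulateLevelControl(st, pm, 10 / 60, qsens, 2 * 3600)
  expect_lte(max(r$trace$volume_uL) - min(r$trace$volume_uL), 4)
})

test_that("threshold calibration reproduces the slope-times-volume separation", {
  st <- WellState(volumeUl = 1000)
  pm <- PumpModel()
  lin <- function(v) 6.74 * v
  cal <- calibrateThresholds(st, pm, lin)
  # noiseless: identical across cycles, separation = 50 uL x slope
  expect_true(all(cal$perCycle$lower == cal$perCycle$lower[1]))
  expect_true(all(cal$perCycle$upper == cal$perCycle$upper[1]))
  expect_equal(cal$upper - cal$lower, 337)

  # noisy sensor: each threshold within 3 sigma/sqrt(n) of noiseless
  set.seed(205)
  for (rep in 1:50) {
    c2 <- calibrateThresholds(st, pm, function(v) lin(v) + rnorm(1, 0, 5))
    expect_lt(abs(c2$upper - cal$upper), 3 * 5 / sqrt(30))
    expect_lt(abs(c2$lower - cal$lower), 3 * 5 / sqrt(30))
  }
  expect_error(calibrateThresholds(st, pm, function(v) 6000),
               "calibration failure")
})

test_that("the magnesium staircase and washout reproduce the printed sequence", {
  plan <- c(lapply(1:3, function(i)
              list(well = 1L, action = "add_stock", vv = 0.001,
                   stock_mM = 1000, solute = "Mg")),
            lapply(1:3, function(i)
              list(well = 1L, action = "half_exchange", fraction = 0.5,
                   fresh_mM = c(Mg = 0.81))))
  res <- runPerfusionProtocol(plan, list(WellState()))
  cc <- res$timeline$Mg[res$timeline$well == 1]
  expect_equal(round(cc, 2), c(0.81, 1.81, 2.81, 3.81, 2.31, 1.56, 1.19))
  expect_equal(res$states[[1]]@volumeUl, 1000)  # replace semantics
})

test_that("the shared pump serializes steps; conflicting requests are errors", {
  # empty plan -> states unchanged
  res0 <- runPerfusionProtocol(list(), list(WellState(), WellState()))
  expect_equal(res0$states[[1]]@concentrations, c(Mg = 0.81))

  # four wells, equidistant phase-shifted exchanges -> busy intervals
  # never overlap
  plan <- lapply(0:3, function(k)
    list(well = k + 1L, action = "half_exchange", fraction = 0.5,
         fresh_mM = 0.81, at_s = k * 600))
  res <- runPerfusionProtocol(plan, replicate(4, WellState(), simplify = FALSE),
                              pumpRateUlPerS = 0.5)
  pb <- res$pumpBusy[order(res$pumpBusy$t0_s), ]
  expect_true(all(diff(as.vector(t(pb))) >= 0))

  # a request while the pump is busy is a scheduling error
  plan2 <- list(
    list(well = 1L, action = "half_exchange", fraction = 0.5,
         fresh_mM = 0.81, at_s = 0),
    list(well = 2L, action = "half_exchange", fraction = 0.5,
         fresh_mM = 0.81, at_s = 10))
  expect_error(runPerfusionProtocol(plan2, replicate(2, WellState(), simplify = FALSE),
                                    pumpRateUlPerS = 0.5),
               "scheduling error")
})

test_that("thermal control holds setpoint, settles 2 K steps, and mixes boluses", {
  pl <- ThermalPlant()
  # start at setpoint, no disturbance -> constant trace
  tr <- simulateThermal(pl, 37, durationS = 120)
  expect_equal(max(abs(tr$T_true_C - 37)), 0)

  # 2 K setpoint step settles within 5 min
  tr2 <- simulateThermal(pl, function(t) ifelse(t < 60, 37, 35),
                         durationS = 60 + 300)
  afterSettle <- tr2$T_true_C[tr2$t_s >= 60 + 300 - 1]
  expect_lt(max(abs(afterSettle - 35)), 0.1)
  tr3 <- simulateThermal(pl, function(t) ifelse(t < 60, 37, 39),
                         durationS = 60 + 300)
  expect_lt(max(abs(tr3$T_true_C[tr3$t_s >= 359] - 39)), 0.1)

  # 100 uL bolus at 35.755 degC into 1000 uL at 37.185 degC: -130 mK
  plB <- ThermalPlant(setpointC = 37.185)
  trB <- simulateThermal(plB, 37.185,
                         boluses = data.frame(t_s = 30, volume_uL = 100,
                                              temp_C = 35.755),
                         durationS = 240)
  drop <- min(trB$T_true_C) - 37.185
  expect_equal(drop * 1000, -130, tolerance = 1e-6)
  # recovery well within 3 min
  late <- trB$T_true_C[trB$t_s >= 30 + 180]
  expect_lt(max(abs(late - 37.185)), 0.032)

  # RTD quantizer stays within half an LSB of the true temperature
  expect_lte(max(abs(trB$T_rtd_C - trB$T_true_C)), pl@rtdLsbK / 2)
  expect_error(simulateThermal(pl, 37, durationS = -1), "positive")
})
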