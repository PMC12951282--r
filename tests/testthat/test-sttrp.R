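# STTRP construction: trigger validity, segments, binning, band metrics

test_that("trigger validity honors the exclusion window and scope", {
  ev <- makeEvents("E1", c(5, 12, 40))
  rule <- TriggerRule("E1", exclusionMs = 10)
  expect_equal(findValidTriggers(ev, rule), c(5, 40))

  # scope all_electrodes: a spike on another electrode also disqualifies
  ev2 <- rbind(ev, makeEvents("E2", 35))
  expect_equal(findValidTriggers(ev2, TriggerRule("E1", 10, "all_electrodes")),
               5)
  expect_equal(findValidTriggers(ev2, TriggerRule("E1", 10, "trigger_only")),
               c(5, 40))

  noEv <- makeEvents(character(0), numeric(0))
  expect_identical(findValidTriggers(noEv, rule), numeric(0))
  expect_error(findValidTriggers(ev, TriggerRule("E9"), electrodes = paste0("E", 1:4)),
               "unknown")
})

test_that("a network burst pattern yields exactly its hand-enumerated valid triggers", {
  # three network volleys separated by quiet periods, plus two trigger
  # spikes disqualified by preceding activity on other electrodes
  ev <- rbind(
    makeEvents("E1", c(100, 300, 500)),          # clean volley starts
    makeEvents("E2", c(103.5, 303.6, 503.4)),    # followers
    makeEvents("E3", c(104, 304.2, 504.1)),
    makeEvents("E2", 195), makeEvents("E1", 200),  # E1@200 fouled by E2@195
    makeEvents("E1", 402), makeEvents("E1", 406))  # E1@406 fouled by E1@402
  rule <- TriggerRule("E1", exclusionMs = 10, exclusionScope = "all_electrodes",
                      segmentMs = 5)
  valid <- findValidTriggers(ev, rule)
  expect_equal(valid, c(100, 300, 402, 500))  # E1@402 clean on all electrodes
  # with trigger-only scope, E1@200 becomes valid again
  expect_equal(findValidTriggers(ev, TriggerRule("E1", 10, "trigger_only")),
               c(100, 200, 300, 402, 500))
})

test_that("segments collect spikes half-open and include the trigger at latency 0", {
  ev <- rbind(makeEvents("E1", 100), makeEvents("E2", 104),
              makeEvents("E3", 105))   # exactly at segment end -> excluded
  st <- buildSttrp(ev, 100, "E1", segmentMs = 5,
                   electrodes = paste0("E", 1:4))
  expect_identical(length(triggers(st)), 1L)
  seg <- segments(st)[[1]]
  expect_setequal(seg$electrode, c("E1", "E2"))
  expect_equal(sort(seg$latency_ms), c(0, 4))
})

test_that("binning is half-open, conserves counts, and covers the full duration", {
  # 388-minute recording at 2-min bins -> time bins 0..193
  ev <- makeEvents("E1", c(1000, 388 * 60 * 1000 - 1))
  st <- buildSttrp(ev, ev$t_ms, "E1", segmentMs = 5,
                   electrodes = paste0("E", 1:4))
  b <- binSttrp(st, durationS = 388 * 60)
  expect_identical(dim(binCounts(b))[3], 194L)

  # latencies 0.04 and 0.14 ms -> latency bins 0 and 1; 0.05 -> bin 0
  ev2 <- rbind(makeEvents("E1", 100),
               makeEvents("E2", c(100.04, 100.14, 100.05)))
  st2 <- buildSttrp(ev2, 100, "E1", segmentMs = 5,
                    electrodes = paste0("E", 1:4))
  b2 <- binSttrp(st2, durationS = 1)
  j2 <- which(paste0("E", 1:4) == "E2")
  prof <- binCounts(b2)[1, j2, 1, ]
  expect_identical(prof[1], 2)   # 0.04 and 0.05
  expect_identical(prof[2], 1)   # 0.14
  # count conservation: all segment spikes appear exactly once
  nSeg <- sum(vapply(segments(st2), nrow, integer(1)))
  expect_identical(sum(binCounts(b2)), as.numeric(nSeg))

  expect_error(binSttrp(st2, latencyBinMs = 0), "positive")
})

test_that("band metrics count fidelity per trigger and bin latency over time", {
  # 4 triggers; 3 followed by an in-band E2 spike, one of them twice
  trig <- c(1000, 2000, 3000, 4000)
  ev <- rbind(makeEvents("E1", trig),
              makeEvents("E2", c(1003.6, 2003.9, 2004.2, 3004.4)),
              makeEvents("E2", 4005))   # outside [3.25, 4.5)
  st <- buildSttrp(ev, trig, "E1", segmentMs = 10,
                   electrodes = paste0("E", 1:4))
  bm <- bandMetrics(st, Band("E2", 3.25, 4.5))
  expect_equal(bm$fidelity, 0.75)
  expect_identical(length(bm$latencies), 4L)
  expect_equal(bm$medianLatency, median(c(3.6, 3.9, 4.2, 4.4)))
  expect_equal(bm$byTime$meanLatency, mean(c(3.6, 3.9, 4.2, 4.4)))

  # narrowing the band can only lower fidelity
  bmN <- bandMetrics(st, Band("E2", 3.5, 4.2))
  expect_lte(bmN$fidelity, bm$fidelity)

  # all triggers followed -> 1; none -> 0
  expect_equal(bandMetrics(st, Band("E2", 3, 5))$fidelity, 0.75)
  expect_equal(bandMetrics(st, Band("E3", 3, 5))$fidelity, 0)
  expect_error(bandMetrics(buildSttrp(ev[0, ], numeric(0), "E1", 10),
                           Band("E2", 3.25, 4.5)), "zero triggers")
  expect_error(bandMetrics(st, Band("E2", 3, 12)), "within the segment")
})

test_that("spike rate is counts per bin per electrode", {
  # 240 spikes on one electrode in one 2-min bin -> 2 Hz
  ev <- makeEvents("E1", seq(0, 120000 - 1, length.out = 240))
  r <- spikeRate(ev, binS = 120, nElectrodes = 1, durationS = 120)
  expect_equal(r$rate_hz, 2)
  # empty table -> zeros
  r0 <- spikeRate(makeEvents(character(0), numeric(0)), durationS = 240)
  expect_true(all(r0$rate_hz == 0))
  # Poisson process recovers its rate
  set.seed(77)
  lam <- 5
  tt <- cumsum(rexp(3000, lam))
  tt <- tt[tt < 300]
  rp <- spikeRate(makeEvents("E1", tt * 1000), binS = 300, nElectrodes = 1,
                  durationS = 300)
  se <- sqrt(lam / 300)
  expect_lt(abs(rp$rate_hz - lam), 3 * se)
})

test_that("stimulus-response counting applies the 5 ms cutoff", {
  stim <- seq(0, 9000, by = 1000)
  ev <- makeEvents("E2", stim + 7)          # one spike at 7 ms latency each
  out <- stimResponseCount(ev, stim, minLatencyMs = 5, windowMs = 250)
  expect_equal(unname(out$meanSpikes["E2"]), 1)
  # spikes at 3 ms only -> excluded by the cutoff but present in the PSTH
  ev3 <- makeEvents("E2", stim + 3)
  out3 <- stimResponseCount(ev3, stim, minLatencyMs = 5, windowMs = 250)
  expect_equal(unname(out3$meanSpikes["E2"]), 0)
  expect_equal(sum(out3$psth$count), 10)
  expect_error(stimResponseCount(ev, numeric(0)), "no stimuli")
  expect_warning(stimResponseCount(ev, c(0, 100), windowMs = 250), "spacing")
})
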