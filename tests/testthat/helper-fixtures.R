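# shared fixtures, built in code

# minimal event table from electrode/time pairs (times in ms)
makeEvents <- function(electrode, t_ms) {
  t_ms <- as.numeric(t_ms)
  data.frame(electrode = as.character(electrode), t_ms = t_ms,
             t_sample = as.integer(round(t_ms * 17361 / 1000)),
             amplitude_uV = rep(-40, length(t_ms)),
             detector = rep("fixture", length(t_ms)),
             stringsAsFactors = FALSE)[order(t_ms), ]
}

# 4-electrode network spec with one strong band, used across tests
defaultTestSpec <- function(fidelity = 0.9, jitter = 0.1, slope = 0,
                            rate = 2) {
  NetworkSpec(triggerRateHz = rate,
              bands = list(BandSpec("E2", baseLatencyMs = 4,
                                    jitterSdMs = jitter,
                                    fidelity = fidelity,
                                    tempSlopeMsPerK = slope)))
}

# match detected events against ground truth within a sample tolerance;
# returns c(recall, nFalsePositives)
matchEvents <- function(detected, truth, tolSamples = 18L) {
  hit <- vapply(seq_len(nrow(truth)), function(r) {
    d <- detected$t_sample[detected$electrode == truth$electrode[r]]
    any(abs(d - truth$t_sample[r]) <= tolSamples)
  }, logical(1))
  fp <- vapply(seq_len(nrow(detected)), function(r) {
    g <- truth$t_sample[truth$electrode == detected$electrode[r]]
    !any(abs(g - detected$t_sample[r]) <= tolSamples)
  }, logical(1))
  c(recall = mean(hit), fp = sum(fp))
}
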