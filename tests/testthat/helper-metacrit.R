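# Shared fixtures: the unbiased d' = 2 observer used throughout, and a
# Monte-Carlo 3-standard-error comparison helper for rate estimates.

p_unbiased <- function() sdt_params(2, 0, 0.5)

expect_within_3se <- function(p_hat, p_true, n_den, label = "rate") {
  se <- sqrt(pmax(p_true * (1 - p_true), 1e-12) / n_den)
  expect_lt(abs(p_hat - p_true), 3 * se + 1e-12,
            label = sprintf("%s: |%.5f - %.5f| vs 3*SE", label, p_hat, p_true))
}

# empirical type 2 cell rates from a simulated trial table
empirical_t2 <- function(trials) {
  hi <- trials$confidence == "high"
  list(
    HR2  = mean(hi[trials$correct]),
    FAR2 = mean(hi[!trials$correct]),
    HR2_S2 = mean(hi[trials$correct & trials$response == "S2"]),
    FAR2_S2 = mean(hi[!trials$correct & trials$response == "S2"]),
    p_high = mean(hi)
  )
}
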