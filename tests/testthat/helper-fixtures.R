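# Shared fixtures: curves, small burdens and an independent OLS oracle.

fluor100 <- function() calibration_curve(slope = 100, intercept = 0,
                                         modality = "fluorescence")

# Independent least-squares oracle: solve the normal equations directly.
ols_brute <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# A burden with known colony signals (cells = signal / 100 under fluor100()).
burden_from_signals <- function(signals, harvest_hours = 240,
                                mouse_id = "m1", clone_id = "cl",
                                n_injected = 2e6, diameters = NA_real_) {
  cols <- if (length(signals)) {
    data.frame(colony_id = seq_along(signals), diameter_mm = diameters,
               fluor_signal = signals)
  } else {
    data.frame(colony_id = integer(0), diameter_mm = numeric(0),
               fluor_signal = numeric(0))
  }
  liver_burden(mouse_id, clone_id, n_injected, harvest_hours, cols)
}
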