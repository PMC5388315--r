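# Shared fixtures, built in code.

# Mean developmental rates of the whole immature stage (egg to adult) over
# the usable temperature range of the bundled rearing study.
immature_rates <- function(with_descending = TRUE) {
  temps <- c(20, 24, 28, 30, 32)
  durs <- c(46.62, 29.34, 24.47, 22.04, 22.43)
  keep <- if (with_descending) seq_along(temps) else 1:4
  data.frame(temperature = temps[keep], rate = 1 / durs[keep])
}

immature_durations <- function() {
  data.frame(temperature = c(20, 24, 28, 30),
             duration = c(46.62, 29.34, 24.47, 22.04))
}

# Closed-form simple-OLS oracle (normal equations), independent of lm().
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = b, intercept = mean(y) - b * mean(x))
}

# Printed SSI parameter sets for the five composite stages of the bundled
# study (rho_phi, t_opt, t_l, t_h, dh_a, dh_l, dh_h).
published_ssi_params <- function() {
  list(
    egg = ssi_params(0.2866211, 28.2088, 11.13197, 32.451, 13292.41,
                     -76643.64, 786228.6),
    larva = ssi_params(0.06756835, 24.3899, 12.97607, 32.8627, 15236.67,
                       -138159.7, 122641.5),
    prepupa = ssi_params(0.3332183, 22.663, 16.9636, 31.4021, 20317.41,
                         -127233.6, 76757.69),
    pupa = ssi_params(0.1108385, 23.654, 9.950553, 35.0202, 12144.71,
                      -143849.7, 92395.43),
    immature = ssi_params(0.03337244, 24.6338, 13.0422, 34.0533, 13205.04,
                          -73234.83, 103394))
}
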