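# Shared fixtures: scaled-down configurations so unit tests stay fast while
# keeping the default sampling rates and protocol structure.

fast_config <- function(...) {
  sim_config(cycle_duration_mean_s = 4, cycle_duration_sd_s = 0.3,
             rest_s = 2, ...)
}

# fully deterministic pair: no measurement noise, one latent source
noiseless_emg_config <- function(...) {
  fast_config(device_noise_sd_counts = 0, reference_noise_sd_counts = 0,
              ecg_artifact_amplitude_mv = 0, shared_fraction = 1, ...)
}

noiseless_kin_config <- function(...) {
  fast_config(orientation_noise_deg = 0, imu_orientation_noise_deg = 0, ...)
}

# independent ANOVA route for ICC(2,1): mean squares from stats::aov
aov_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# independent unwrap route: accumulate complex-argument steps
arg_unwrap <- function(x) {
  if (length(x) < 2) return(x)
  steps <- Arg(exp(1i * diff(x) * pi / 180)) * 180 / pi
  x[1] + cumsum(c(0, steps))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
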