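# shared fixtures, built in code

biweekly <- seq(0, 224, by = 14)

# noiseless or noisy trajectory data frame from classical-form parameters
make_traj <- function(BWa = 2500, b = 3.4, k = 0.015, times = biweekly,
                      noise_cv = 0) {
  w <- BWa * exp(-b * exp(-k * times))
  if (noise_cv > 0) w <- w * (1 + stats::rnorm(length(times), 0, noise_cv))
  data.frame(age = times, weight = w)
}

# random valid classical-form parameter sets for property loops
random_g1 <- function(n) {
  data.frame(BWa = stats::runif(n, 1500, 7000),
             b = stats::runif(n, 1.5, 6),
             k = stats::runif(n, 0.008, 0.05))
}

# small flock design for fast end-to-end tests
small_design <- function(n = 12, noise_cv = 0.05, cv = 0.08, ...) {
  flock_design(groups = data.frame(breed = c("BS", "BS", "BP", "BP"),
                                   sex = c("F", "M", "F", "M"),
                                   n = n,
                                   BWa = c(2184, 3074, 2012, 2745),
                                   b = c(3.32, 3.55, 2.99, 3.25),
                                   k = c(0.014, 0.014, 0.016, 0.015)),
               noise_cv = noise_cv,
               cv = c(BWa = cv, b = cv, k = cv),
               ...)
}
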