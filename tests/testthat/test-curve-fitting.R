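test_that("noiseless trajectories are recovered to high relative precision", {
  d <- make_traj(2500, 3.4, 0.015)
  f <- gompertz_fit(weight ~ age, d)
  expect_true(f$converged)
  expect_lt(max(abs(coef(f) - c(2500, 3.4, 0.015)) / c(2500, 3.4, 0.015)), 1e-6)
  expect_equal(f$r2_adj, 1)
  expect_identical(f$aic, -Inf)
  # lag-time form on its own generating curve
  q <- convert_g1_to_g2(g1_params(2500, 3.4, 0.015))
  f2 <- gompertz_fit(weight ~ age, d, model = "G2")
  expect_true(f2$converged)
  expect_lt(max(abs(coef(f2) - unlist(q)) / abs(unlist(q))), 1e-5)
})

test_that("three noiseless points are interpolated exactly", {
  for (i in 1:5) {
    set.seed(i)
    pars <- random_g1(1)
    d <- make_traj(pars$BWa, pars$b, pars$k, times = c(30, 90, 170))
    f <- gompertz_fit(weight ~ age, d, control = gompertz_control(min_obs = 3))
    expect_true(f$converged)
    expect_lt(f$rss, 1e-12 * mean(d$weight)^2)
  }
})

test_that("default starting values are sane and close enough to converge", {
  d <- make_traj(2500, 3.4, 0.015, noise_cv = 0)
  ini <- default_init(d$age, d$weight)
  expect_equal(ini$BWa, 1.2 * max(d$weight), tolerance = 1e-12)
  truth <- c(2500, 3.4, 0.015)
  expect_true(all(abs(unlist(ini) - truth) / truth < 0.5))
  f <- gompertz_fit(weight ~ age, d, init = ini)
  expect_true(f$converged)
  # definition check on the asymptote start
  d2 <- d; d2$weight[which.max(d2$weight)] <- 2000
  d2$weight <- pmin(d2$weight, 2000)
  expect_equal(default_init(d2$age, d2$weight)$BWa, 2400)
  # degenerate (decreasing) input falls back to fixed defaults
  fb <- default_init(seq(0, 60, 15), c(500, 400, 300, 200, 100))
  expect_equal(unlist(fb), c(BWa = 2500, b = 3.5, k = 0.015))
})

test_that("goodness of fit: formulas, perfect-fit sentinel and guard", {
  set.seed(3)
  d <- make_traj(2500, 3.4, 0.015, noise_cv = 0.05)
  f <- gompertz_fit(weight ~ age, d)
  g <- goodness(f)
  n <- 17; p <- 3
  tss <- sum((d$weight - mean(d$weight))^2)
  r2 <- 1 - f$rss / tss
  expect_equal(g$r2_adj, 1 - (1 - r2) * (n - 1) / (n - p - 1), tolerance = 1e-12)
  expect_equal(g$aic, n * log(f$rss / n) + 2 * (p + 1), tolerance = 1e-12)
  # 4 points fit (interpolation regime): adjusted r2 undefined
  d4 <- make_traj(times = c(20, 60, 120, 200))
  f4 <- gompertz_fit(weight ~ age, d4, control = gompertz_control(min_obs = 4))
  expect_error(goodness(f4), "undefined")
  expect_true(is.na(f4$r2_adj))
})

test_that("refitting from a fit's own parameters is a fixed point", {
  set.seed(5)
  d <- make_traj(2800, 3.1, 0.017, noise_cv = 0.05)
  f <- gompertz_fit(weight ~ age, d)
  f2 <- gompertz_fit(weight ~ age, d, init = f$params)
  expect_lt(max(abs(coef(f2) - coef(f)) / abs(coef(f))), 1e-6)
})

test_that("degenerate trajectories are rejected, never fitted silently", {
  d <- data.frame(age = biweekly, weight = rep(40, 17))
  expect_error(gompertz_fit(weight ~ age, d), "no growth signal")
  expect_error(gompertz_fit(weight ~ age, make_traj(times = c(0, 14, 28, 42))),
               "at least 5")
  d2 <- make_traj(); d2$age[2] <- 0
  expect_error(gompertz_fit(weight ~ age, d2), "duplicate")
})

test_that("per-age actual-fitted correlations handle zero-variance columns", {
  set.seed(9)
  fl <- simulate_flock(small_design(n = 15), seed = 9, with_markers = FALSE)
  ff <- fit_flock(fl$data, model = "G1")
  act <- weights_matrix(fl$data)
  fitmat <- act
  for (id in rownames(act)) {
    p <- ff[ff$bird_id == id & ff$model == "G1", ]
    fitmat[id, ] <- predict_g1(g1_params(p$BWa, p$b, p$k),
                               as.numeric(colnames(act)))
  }
  r <- weekly_correlation(act, fitmat)
  expect_true(all(r[colnames(act) >= 28] > 0.9, na.rm = TRUE))
  # identical matrices correlate perfectly
  expect_equal(unname(weekly_correlation(fitmat, fitmat)),
               rep(1, ncol(fitmat)), tolerance = 1e-12)
  # a constant column (hatch recorded identically) is undefined, not an error
  act0 <- act; act0[, 1] <- 39
  expect_true(is.na(weekly_correlation(act0, fitmat)[1]))
  expect_error(weekly_correlation(act[, -1], fitmat), "identical dimensions")
})

test_that("parameter correlation matrix: trivial entries and expected signs", {
  fl <- simulate_flock(small_design(n = 20), seed = 21, with_markers = FALSE)
  ff <- fit_flock(fl$data, model = "G1")
  pc <- parameter_correlations(ff)
  expect_equal(pc["BWip", "BWa"], 1, tolerance = 1e-12)
  expect_equal(pc, t(pc))
  expect_equal(unname(diag(pc)), rep(1, ncol(pc)))
  # faster growth reaches the inflection earlier: corr(k, Tip) < 0
  expect_lt(pc["k", "Tip"], 0)
  expect_error(parameter_correlations(ff[1:2, ]), "at least 3")
})

test_that("simulated groups are recovered without material bias", {
  # scaled-down recovery check (the full calibration lives in the
  # acceptance suite): three replicates averaged, 25 birds/group, 5% noise
  truth <- small_design(n = 25)$groups
  est <- array(0, c(3, nrow(truth), 2))
  for (r in 1:3) {
    fl <- simulate_flock(small_design(n = 25), seed = 30 + r, with_markers = FALSE)
    ff <- fit_flock(fl$data, model = "G1")
    for (i in seq_len(nrow(truth))) {
      sel <- ff$breed == truth$breed[i] & ff$sex == truth$sex[i] & ff$converged
      est[r, i, ] <- c(mean(ff$BWa[sel]), mean(ff$k[sel]))
    }
  }
  for (i in seq_len(nrow(truth))) {
    expect_lt(abs(mean(est[, i, 1]) - truth$BWa[i]) / truth$BWa[i], 0.05)
    expect_lt(abs(mean(est[, i, 2]) - truth$k[i]) / truth$k[i], 0.1)
  }
})
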