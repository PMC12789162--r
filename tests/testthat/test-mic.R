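test_that("anchor dichotomization reproduces printed count arithmetic", {
  # knee-cohort TRs response counts, worst to best category
  counts <- c(5, 9, 3, 17, 36, 180, 161)
  trs7 <- rep(1:7, times = counts)
  d <- dichotomize_trs(trs7, cutpoint = 6)
  expect_equal(d$prop_improved, (180 + 161) / 411)
  expect_equal(round(d$prop_improved, 2), 0.83)
  d5 <- dichotomize_trs(trs7, cutpoint = 5)
  expect_equal(d5$prop_improved, (36 + 180 + 161) / 411)
  expect_error(dichotomize_trs(trs7, cutpoint = 1), "cutpoint")
  expect_error(dichotomize_trs(trs7, cutpoint = 8), "cutpoint")
  expect_warning(dichotomize_trs(rep(7, 10), cutpoint = 6), "undefined")
})

test_that("predictive-modeling MIC solves the likelihood-ratio-1 identity", {
  # perfectly symmetric toy data: intercept 0, so the MIC is 0
  delta <- rep(c(1, 1, -1, -1), times = c(30, 20, 20, 30))
  imp <- rep(c(1, 0, 1, 0), times = c(30, 20, 20, 30))
  pm <- predictive_modeling_mic(delta, imp)
  expect_equal(pm$mic_pm, 0, tolerance = 1e-8)

  # defining identity holds to machine precision for arbitrary fits
  set.seed(211)
  for (k in 1:5) {
    d <- rnorm(400, 0.5, 1.3)
    y <- rbinom(400, 1, plogis(-0.4 + 1.1 * d))
    if (length(unique(y)) < 2) next
    pm <- predictive_modeling_mic(d, y)
    expect_equal(pm$b0 + pm$b1 * pm$mic_pm, logodds(mean(y)),
                 tolerance = 1e-10)
  }

  expect_error(predictive_modeling_mic(rnorm(50), rep(1, 50)), "single class")
  # anchor anti-correlated with the change score: slope must be positive
  set.seed(213)
  d <- rnorm(300)
  y <- rbinom(300, 1, plogis(-2 * d))
  expect_error(predictive_modeling_mic(d, y), "non-positive")
})

test_that("predictive-modeling MIC matches a density-crossing oracle", {
  # the MIC is where the within-group densities of the change score cross
  # (likelihood ratio 1); locate that crossing from kernel estimates
  set.seed(217)
  n <- 5000
  d <- rnorm(n, 0.6, 1.4)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d))
  pm <- predictive_modeling_mic(d, y)
  xs <- seq(-2, 3, length.out = 1200)
  f1 <- approx(density(d[y == 1], bw = "SJ"), xout = xs)$y
  f0 <- approx(density(d[y == 0], bw = "SJ"), xout = xs)$y
  ok <- which(is.finite(f1) & is.finite(f0) & f0 > 1e-4 & f1 > 1e-4)
  cross <- xs[ok][which.min(abs(log(f1[ok] / f0[ok])))]
  expect_lt(abs(pm$mic_pm - cross), 0.2)
})

test_that("the APM adjustment follows its formula and boundary behaviour", {
  # worked example: logodds(0.7311) is 1 to four decimals
  expect_equal(apm_adjustment(1.0, 0.8, 1.38, 0.46, 0.7311),
               1.0 - 0.5 * 1.38 * 0.46 * logodds(0.7311), tolerance = 1e-12)
  expect_equal(apm_adjustment(1.0, 0.8, 1.38, 0.46, 0.7311), 0.6826,
               tolerance = 1e-3)
  # reliability 0.8 gives adjustment coefficient exactly 0.5
  expect_equal(0.8 / 0.8 - 0.5, 0.5)
  # a balanced anchor leaves the predictive-modeling MIC untouched
  set.seed(219)
  for (k in 1:5) {
    mic_pm <- rnorm(1); sd_d <- runif(1, 0.5, 2); r <- runif(1, 0.1, 0.7)
    rel <- runif(1, 0.4, 1)
    expect_identical(apm_adjustment(mic_pm, rel, sd_d, r, 0.5), mic_pm)
  }
  expect_error(apm_adjustment(1, 0, 1.4, 0.4, 0.6), "rel_trs")
  expect_error(apm_adjustment(1, 0.7, 1.4, 0.4, 1), "undefined")
  expect_error(apm_adjustment(1, 0.7, 0, 0.4, 0.6), "positive")
})

test_that("the LCFA MIC rescaling is exact and degree-1 in the SIM SD", {
  expect_equal(lcfa_mic(1, 1, 0.73), 0.73)
  expect_equal(lcfa_mic(4 * 1.9, 0.85, 0.8), 2 * lcfa_mic(1.9, 0.85, 0.8))
  # printed real-data ingredients on the 0-10 scale, back-transformed x10
  mic10 <- lcfa_mic(1.85^2, 0.899, 0.98)
  expect_equal(mic10 * 10, 17.0, tolerance = 0.3)
  expect_error(lcfa_mic(0, 0.9, 0.8), "positive")
  expect_error(lcfa_mic(1, 0, 0.8), "rel_sim")
})

test_that("continuous SIMs map onto a 12-point ordinal scale", {
  # endpoints of a 0-100 scale
  r <- rescale_continuous(c(0, 100, 50), 0, 100)
  expect_identical(r$scores, c(1L, 12L, 7L)) # 0.51, 12.49, 6.5 -> half away
  expect_equal(r$transform$t_factor, 11.98 / 100)
  # every declared range lands on 0.51..12.49 and exactly 12 categories
  for (rng in list(c(0, 100), c(1, 5), c(-50, 50))) {
    v <- seq(rng[1], rng[2], length.out = 10000)
    rr <- rescale_continuous(v, rng[1], rng[2])
    tv <- rr$transform$t_factor * v + rr$transform$r_shift
    expect_equal(range(tv), c(0.51, 12.49), tolerance = 1e-12)
    expect_identical(sort(unique(rr$scores)), 1:12)
  }
  expect_error(rescale_continuous(c(0, 101), 0, 100), "outside")
  expect_error(rescale_continuous(1, 5, 5), "exceed")
})

test_that("MIC back-transformation undoes the scale factor only", {
  t100 <- rescale_continuous(c(0, 100), 0, 100)$transform
  expect_equal(backtransform_mic(1.2, t100), 1.2 / 0.1198)
  expect_equal(backtransform_mic(1.70, t100), 14.190, tolerance = 1e-3)
  # an 11.98-wide range has unit transform
  tid <- rescale_continuous(c(0.51, 12.49), 0.51, 12.49)$transform
  expect_equal(tid$t_factor, 1)
  expect_equal(backtransform_mic(0.8, tid), 0.8)
})

test_that("the full pipeline populates estimates per model contract", {
  p <- easy_panel(n = 2000, seed = 907, psb = 0.4)
  eC <- estimate_all(p$observed, model = "C")
  expect_true(eC$converged)
  expect_true(is.finite(eC$mic_apm))
  expect_true(is.finite(eC$mic_lcfa))
  expect_equal(eC$mic_lcfa,
               sqrt(eC$var_sim_t1 * eC$rel_sim_t1) * eC$mic_theta)
  eA <- estimate_all(p$observed, model = "A")
  expect_true(is.finite(eA$mic_apm))
  expect_true(is.na(eA$mic_lcfa))
  # structured non-convergence: no numbers, no crash
  bad <- p$observed
  bad$trs_improved <- 1L
  eBad <- estimate_all(bad, model = "C")
  expect_false(eBad$converged)
  expect_true(is.na(eBad$mic_apm))
  expect_true(is.na(eBad$mic_lcfa))
})
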