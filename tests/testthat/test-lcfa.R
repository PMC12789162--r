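# The fitting engine is checked against (i) an analytically constructed
# population moment structure, whose generating parameters must be returned
# to optimizer tolerance, and (ii) simulated data whose recovery error must
# shrink with the sample size.

test_that("model specifications enforce their structure", {
  a <- build_model("A")
  expect_identical(a$aux_mode, "single_item")
  expect_identical(unname(a$treatments["sim_t1"]), "continuous")
  expect_identical(unname(a$treatments["aux_t1"]), "ordered")
  expect_identical(a$identification, "fix_lambda_sim")
  b <- build_model("B")
  expect_identical(unname(b$treatments["aux_t1"]), "continuous")
  cc <- build_model("C")
  expect_identical(unname(cc$treatments["sim_t1"]), "ordered")
  expect_true(cc$invariance)
  expect_identical(cc$parameterization, "theta")
  expect_identical(cc$identification, "standardize_theta_t1")
  expect_error(build_model("A", "sum_score"), "requires")
  expect_error(build_model("B", "single_item"), "requires")
  expect_error(build_model("C", "single_item"), "requires")
})

test_that("model C returns an analytic population structure's parameters", {
  # truth, and its implied moments written out independently of the package
  ls <- 1.5; lx1 <- 0.55; lx2 <- 0.6; lr1 <- -0.25; lr2 <- 0.75
  p12 <- 0.65; V2 <- 1.4; M2 <- 0.9; phi2 <- 1.2; cs <- 0.15; cx <- 0.25
  tau_s <- c(-3.0, -2.0, -1.1, -0.3, 0.5, 1.3, 2.2, 3.1)
  tau_r <- 0.6
  v1 <- ls^2 + 1
  v2 <- ls^2 * V2 + phi2
  vR <- lr1^2 + lr2^2 * V2 + 2 * lr1 * lr2 * p12 + 1
  corr <- c(
    (ls^2 * p12 + cs * sqrt(phi2)) / sqrt(v1 * v2),
    ls * lx1 / sqrt(v1),
    ls * lx2 * p12 / sqrt(v1),
    ls * (lr1 + lr2 * p12) / sqrt(v1 * vR),
    ls * lx1 * p12 / sqrt(v2),
    ls * lx2 * V2 / sqrt(v2),
    ls * (lr1 * p12 + lr2 * V2) / sqrt(v2 * vR),
    lx1 * lx2 * p12 + cx * sqrt((1 - lx1^2) * (1 - lx2^2 * V2)),
    lx1 * (lr1 + lr2 * p12) / sqrt(vR),
    lx2 * (lr1 * p12 + lr2 * V2) / sqrt(vR))
  vars <- c("sim_t1", "sim_t2", "aux_t1", "aux_t2", "trs")
  R <- diag(5); dimnames(R) <- list(vars, vars)
  R[micaux:::.LCFA_PAIRS] <- corr
  R[micaux:::.LCFA_PAIRS[, 2:1]] <- corr
  m <- length(tau_s)
  corstr <- structure(list(
    R = R, avar = matrix(1e-6, 5, 5, dimnames = list(vars, vars)),
    thresholds = list(trs = (tau_r - lr2 * M2) / sqrt(vR)),
    threshold_avar = list(trs = 1e-6),
    treatments = build_model("C")$treatments, n = 1e6), class = "mic_corstr")
  sim_th <- list(categories = 0:m, n_boundaries = m,
                 t1 = list(keep = 1:m, tau = tau_s / sqrt(v1),
                           avar = rep(1e-6, m)),
                 t2 = list(keep = 1:m, tau = (tau_s - ls * M2) / sqrt(v2),
                           avar = rep(1e-6, m)))
  core <- micaux:::.fit_c(corstr, build_model("C"), sim_th)
  expect_true(core$converged)
  expect_equal(core$par$lambda_sim, ls, tolerance = 1e-3)
  expect_equal(core$par$lambda_trs_t2, lr2, tolerance = 1e-3)
  expect_equal(core$par$lambda_trs_t1, lr1, tolerance = 1e-2)
  expect_equal(core$par$psi12, p12, tolerance = 1e-3)
  expect_equal(core$par$V2, V2, tolerance = 1e-3)
  expect_equal(core$par$M2, M2, tolerance = 1e-3)
  expect_equal(core$par$resvar_sim_t2, phi2, tolerance = 1e-2)
  expect_equal(core$par$tau_sim, tau_s, tolerance = 1e-3)
  expect_equal(core$mic_theta, tau_r / lr2, tolerance = 1e-3)
  expect_equal(core$psb_hat, 1 + lr1 / lr2, tolerance = 1e-2)
  expect_equal(core$r2_trs, (vR - 1) / vR, tolerance = 1e-3)
  expect_equal(core$r2_sim_t1, ls^2 / (ls^2 + 1), tolerance = 1e-3)
})

test_that("closed-form variance ratios behave at the corners", {
  # both TRs loadings zero: no explained anchor variance
  imp0 <- micaux:::.implied_c(c(1, 0.5, 0.5, 0, 0, 0.5, 1, 0, 1, 0, 0,
                                seq(-2, 2, length.out = 8), 0.4), 8)
  expect_equal((imp0$vR - 1) / imp0$vR, 0)
  # lambda_T1 = 0, lambda_T2 = 1, V2 = 1, unit residual: R^2 = 1/2
  imp1 <- micaux:::.implied_c(c(1, 0.5, 0.5, 0, 1, 0.5, 1, 0, 1, 0, 0,
                                seq(-2, 2, length.out = 8), 0.4), 8)
  expect_equal((imp1$vR - 1) / imp1$vR, 0.5)
  # theta parameterization, lambda_SIM = 1, V1 = 1: SIM R^2 = 1/2
  expect_equal(1^2 / (1^2 + 1), 0.5)
})

test_that("recovery error shrinks with sample size (monotone consistency)", {
  sizes <- c(2000, 20000, 200000)
  seeds <- 1:20
  err <- sapply(sizes, function(n) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_subjects = n, seed = 5000 + s, psb = 0.4,
                        rel_trs = 0.7, rel_sim_t1 = 0.8,
                        cor_theta_t1_delta = -0.5, strength_theta_b = 0.5)
      p <- simulate_dataset(cfg, keep_latent = FALSE)
      f <- fit_model(panel_indicators(p$observed, build_model("C")),
                     build_model("C"))
      if (f$converged) abs(f$mic_theta - 0.8) else NA_real_
    }, numeric(1))
  })
  med <- apply(err, 2, median, na.rm = TRUE)
  expect_true(all(diff(med) < 0))
})

test_that("fits are deterministic and degenerate inputs are flagged, not thrown", {
  p <- easy_panel(n = 1200, seed = 515)
  spec <- build_model("B")
  d <- panel_indicators(p$observed, spec)
  f1 <- fit_model(d, spec)
  f2 <- fit_model(d, spec)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$fit_indices, f2$fit_indices)

  # constant anchor: structured non-convergence
  d_bad <- d
  d_bad$trs <- 1L
  f_bad <- fit_model(d_bad, spec)
  expect_false(f_bad$converged)
  expect_match(f_bad$reason, "categories")
  expect_error(trs_reliability(f_bad), "converged")
  expect_error(fit_indices(f_bad), "converged")

  expect_error(fit_model(d[1:50, ], spec), "at least 100")
  expect_warning(fit_model(d[1:150, ], spec), "fewer than 200")
  expect_error(fit_model(d[, -1], spec), "sim_t1")
})

test_that("fit indices follow their defining arithmetic", {
  # zero discrepancy: perfect fit on every index
  idx <- micaux:::.fit_index_set(0, 4, 900, 10, 2000, rep(0, 10))
  expect_equal(unname(idx["cfi"]), 1)
  expect_equal(unname(idx["rmsea"]), 0)
  expect_equal(unname(idx["srmr"]), 0)
  # fitted discrepancy as bad as the baseline: CFI hits its floor
  idx0 <- micaux:::.fit_index_set(900, 10, 900, 10, 2000,
                                  rep(0.2, 10))
  expect_equal(unname(idx0["cfi"]), 0)
  # SRMR is the root mean square of the residual correlations
  resid <- c(0.02, -0.01, 0.03, 0, 0.01, -0.02, 0.005, 0.015, -0.03, 0.01)
  idx2 <- micaux:::.fit_index_set(12, 8, 900, 10, 2000, resid)
  expect_equal(unname(idx2["srmr"]), sqrt(mean(resid^2)))
  # RMSEA definition
  expect_equal(unname(idx2["rmsea"]), sqrt((12 - 8) / (8 * 1999)))
})

test_that("latent MIC extraction guards its preconditions", {
  p <- easy_panel(n = 2000, seed = 881, psb = 0.4)
  fC <- fit_model(panel_indicators(p$observed, build_model("C")),
                  build_model("C"))
  expect_true(fC$converged)
  expect_equal(latent_mic(fC), fC$par$tau_trs / fC$par$lambda_trs_t2)
  expect_gt(sim_reliability_t1(fC), 0)
  fB <- fit_model(panel_indicators(p$observed, build_model("B")),
                  build_model("B"))
  expect_error(latent_mic(fB), "model C")
  expect_error(sim_reliability_t1(fB), "model C")
  # arithmetic of the ratio at a zero threshold
  fake <- fC
  fake$par$tau_trs <- 0
  fake$mic_theta <- 0 / fake$par$lambda_trs_t2
  expect_equal(latent_mic(fake), 0)
})
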