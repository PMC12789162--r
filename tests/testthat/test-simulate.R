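# Moment, calibration and degenerate-limit checks of the generative model.
# Monte-Carlo tolerances are stated as multiples of the MC standard error.

test_that("latent moments match their configured values", {
  n <- 50000
  for (m in c(-1, 0)) for (rho in c(-0.5, 0)) {
    cfg <- sim_config(mean_theta_t1 = m, cor_theta_t1_delta = rho,
                      sd_delta_theta = 1.15, strength_theta_b = 1,
                      n_subjects = n, seed = 31 + 10 * (m + 2) + rho)
    lat <- draw_latent_states(cfg)
    expect_lt(abs(mean(lat$theta_t1) - m), 3 / sqrt(n))
    expect_lt(abs(sd(lat$theta_t1) - 1), 4 / sqrt(2 * n))
    expect_lt(abs(sd(lat$delta_theta) - 1.15), 4 / sqrt(2 * n))
    expect_lt(abs(cor(lat$theta_t1, lat$delta_theta) - rho), 4 / sqrt(n))
    expect_equal(lat$delta_theta,
                 (lat$theta_a_t2 + lat$theta_b_t2) -
                   (lat$theta_a_t1 + lat$theta_b_t1))
  }
})

test_that("the mean latent change calibrates the proportion improved", {
  n <- 50000
  for (p in c(0.2, 0.5, 0.8)) {
    cfg <- sim_config(prop_improved = p, n_subjects = n, seed = 100 + p * 10)
    lat <- draw_latent_states(cfg)
    mc_se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(lat$improved_true) - p), 4 * mc_se)
  }
  # closed-form solve agrees with 1-D root finding on the mixture probability
  for (p in c(0.2, 0.5, 0.8)) {
    s <- sqrt(1.15^2 + 0.2^2)
    f <- function(mu) pnorm((mu - 0.8) / s) - p
    root <- uniroot(f, c(-10, 10), tol = 1e-12)$root
    expect_equal(micaux:::solve_mean_delta(p, 1.15, 0.8, 0.2), root,
                 tolerance = 1e-8)
  }
})

test_that("degenerate limits collapse the intended components", {
  cfg <- sim_config(psb = 0, strength_theta_b = 0, strength_xi = 0,
                    n_subjects = 20000, seed = 9)
  panel <- simulate_dataset(cfg)
  lat <- panel$latent
  # psb = 0: weighted change is the plain change
  expect_equal(lat$delta_theta_w, lat$delta_theta)
  # strength_theta_b = 0: theta is theta^A alone
  expect_true(all(lat$theta_b_t1 == 0))
  expect_equal(lat$theta_t1, lat$theta_a_t1)
  # strength_xi = 0: AUX carries no xi information beyond theta^A
  r_aux_xi <- cor(resid(lm(panel$observed$aux_sum_t1 ~ lat$theta_a_t1)),
                  resid(lm(lat$xi_t1 ~ lat$theta_a_t1)))
  expect_lt(abs(r_aux_xi), 4 / sqrt(nrow(lat)))
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- sim_config(n_subjects = 500, seed = 77)
  p1 <- simulate_dataset(cfg)
  p2 <- simulate_dataset(cfg)
  expect_identical(p1$observed, p2$observed)
  expect_identical(p1$latent, p2$latent)
  p3 <- simulate_dataset(sim_config(n_subjects = 500, seed = 78))
  expect_false(identical(p1$observed$sim_t1, p3$observed$sim_t1))
})

test_that("SIM scores carry the configured construct share", {
  n <- 50000
  cfg <- sim_config(rel_sim_t1 = 0.8, n_subjects = n, seed = 13)
  lat <- draw_latent_states(cfg)
  attr(lat, "strength_theta_b") <- cfg$strength_theta_b
  sim <- generate_sim_scores(lat, 0.8, seed = 14)
  r2 <- cor(sim$sim_cont_t1, sim$sim_sys_t1)^2
  expect_lt(abs(r2 - 0.8), 0.01)
  sim5 <- generate_sim_scores(lat, 0.5, seed = 15)
  r2_5 <- cor(sim5$sim_cont_t1, sim5$sim_sys_t1)^2
  expect_lt(abs(r2_5 - 0.5), 0.01)
  # perfect reliability: measurement error vanishes, so the error seed is moot
  s_a <- generate_sim_scores(lat, 1, seed = 16)
  s_b <- generate_sim_scores(lat, 1, seed = 17)
  expect_identical(s_a$sim_t1, s_b$sim_t1)
  # integer range
  expect_true(all(sim$sim_t1 >= 0 & sim$sim_t1 <= 10))
})

test_that("baseline SIM mean sits in the printed envelope at zero trait mean", {
  cfg <- sim_config(mean_theta_t1 = 0, n_subjects = 20000, seed = 19)
  p <- simulate_dataset(cfg)
  expect_gt(mean(p$observed$sim_t1), 4.44)
  expect_lt(mean(p$observed$sim_t1), 6.58)
})

test_that("AUX responses are deterministic and alpha lands in the envelope", {
  cfg <- sim_config(n_subjects = 2000, seed = 23)
  lat <- draw_latent_states(cfg)
  attr(lat, "strength_theta_b") <- cfg$strength_theta_b
  a1 <- generate_aux_items(lat, 0.2, seed = 3)
  a2 <- generate_aux_items(lat, 0.2, seed = 3)
  expect_identical(a1$items_t1, a2$items_t1)
  alpha <- cronbach_alpha(a1$items_t1)
  expect_gt(alpha, 0.76)
  expect_lt(alpha, 0.90)
  expect_error(generate_aux_items(lat, 0.2, seed = 3, n_items = 2))
})

test_that("transition ratings track true improvement when unbiased and noise-free", {
  n <- 50000
  cfg <- sim_config(psb = 0, rel_trs = 1, sd_mic = 0, prop_improved = 0.8,
                    n_subjects = n, seed = 29)
  p <- simulate_dataset(cfg)
  # rel_trs = 1 with degenerate individual MICs: the anchor equals the truth
  expect_equal(p$observed$trs_improved, as.integer(p$latent$improved_true))
  expect_lt(abs(mean(p$observed$trs_improved) - 0.8),
            4 * sqrt(0.8 * 0.2 / n))
})

test_that("full present-state bias makes the anchor blind to change given T2 state", {
  n <- 50000
  cfg <- sim_config(psb = 1, n_subjects = n, seed = 37)
  p <- simulate_dataset(cfg)
  lat <- p$latent
  pc_resid <- resid(lm(lat$perceived_change ~ lat$theta_t2))
  d_resid <- resid(lm(lat$delta_theta ~ lat$theta_t2))
  expect_lt(abs(cor(pc_resid, d_resid)), 4 / sqrt(n))
})

test_that("observed summaries fall inside the reference envelopes across the grid", {
  grid <- build_parameter_grid(n_subjects = 2000, seed = 41)
  set.seed(43)
  idx <- sample(nrow(grid), 24)
  inside <- vapply(idx, function(i) {
    o <- simulate_dataset(grid_config(grid, i))$observed
    items1 <- as.matrix(o[, grep("^aux\\d+_t1$", names(o))])
    dsim <- o$sim_t2 - o$sim_t1
    pb <- suppressWarnings(cor(dsim, o$trs_improved))
    prop <- mean(o$trs_improved)
    bis <- pb * sqrt(prop * (1 - prop)) / dnorm(qnorm(prop))
    all(mean(o$sim_t1) >= 4.44, mean(o$sim_t1) <= 6.58,
        sd(o$sim_t1) >= 1.11, sd(o$sim_t1) <= 1.51,
        mean(o$sim_t2) >= 4.27, mean(o$sim_t2) <= 8.30,
        sd(o$sim_t2) >= 1.04, sd(o$sim_t2) <= 1.89,
        mean(dsim) >= -0.27, mean(dsim) <= 1.86,
        sd(dsim) >= 1.01, sd(dsim) <= 1.80,
        mean(o$aux_sum_t1) >= 8.4, mean(o$aux_sum_t1) <= 21.5,
        sd(o$aux_sum_t1) >= 5.5, sd(o$aux_sum_t1) <= 8.0,
        cronbach_alpha(items1) >= 0.76, cronbach_alpha(items1) <= 0.90,
        cor(o$sim_t1, o$aux_sum_t1) >= 0.35,
        cor(o$sim_t1, o$aux_sum_t1) <= 0.82,
        cor(o$sim_t2, o$aux_sum_t2) >= 0.28,
        cor(o$sim_t2, o$aux_sum_t2) <= 0.89,
        bis >= 0.11, bis <= 0.77,
        mean(o$sim_t1 == 0) <= 0.04, mean(o$sim_t1 == 10) <= 0.03)
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
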