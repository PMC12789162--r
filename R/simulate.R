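# Generative model for two-wave SIM / AUX / transition-rating panels.
#
# Four independent latent constructs underlie the observables: theta^A and
# theta^B together form the construct of interest theta = theta^A + theta^B
# (total variance standardized to 1 at baseline); eta is a SIM-specific
# nuisance construct; xi is an AUX-specific construct. The SIM measures
# theta + eta, the AUX items measure theta^A + xi (graded responses), and the
# transition-rating anchor reflects a present-state-biased weighting of the
# latent change, perceived with noise and compared against each subject's
# individual MIC.

# Weight of eta in the SIM score: eta carries 10% of the construct variance
# at baseline (c^2 = 0.1 * var(theta_T1)). Reliability targets count only
# theta as true score, so eta is off-target variance on a par with
# measurement error; this reading reproduces the observed-score envelopes of
# the reference design (see the methods vignette).
.ETA_WEIGHT <- sqrt(0.1)

# Cross-wave correlation of the SIM measurement errors: a stable error
# component (rater/style effects that persist over follow-up). Part of the
# observed-score calibration -- the printed baseline-SD and change-score-SD
# envelopes are only jointly attainable with correlated wave errors. The
# LCFA models absorb it, like the stable off-target construct eta, through
# the cross-wave residual correlation of the SIM indicators.
.SIM_ERR_STABILITY <- 0.25

# AUX graded-response calibration (8 items, 5 categories). Mean discrimination
# 1.5 (logistic metric), mild log-normal spread; category boundaries equally
# spaced on the latent scale with deterministic item shifts. Chosen so that,
# across the default design grid, the AUX sum score lands on a 0-32 scale
# with baseline mean ~15, SD 6-7.5 and Cronbach's alpha between 0.78 and 0.88.
.AUX_DEFAULTS <- list(n_items = 8L, n_categories = 5L,
                      mean_slope = 1.5, sdlog_slope = 0.2,
                      spread = 1.0, shift = 0.25, item_shift_range = 0.6)

# Mean latent change required for P(delta_theta > individual MIC) = prop.
# delta_theta - MIC_i is normal, so the root is available in closed form.
solve_mean_delta <- function(prop_improved, sd_delta_theta, true_mic, sd_mic) {
  s <- sqrt(sd_delta_theta^2 + sd_mic^2)
  mu <- true_mic + qnorm(prop_improved) * s
  if (!is.finite(mu)) {
    stop("infeasible proportion improved: cannot solve for the mean latent change",
         call. = FALSE)
  }
  mu
}

# Population moments of theta implied by a configuration (used by the anchor
# calibration and by oracle tests).
theta_moments <- function(cfg) {
  rho <- cfg$cor_theta_t1_delta
  sdd <- cfg$sd_delta_theta
  mu_delta <- solve_mean_delta(cfg$prop_improved, sdd, cfg$true_mic, cfg$sd_mic)
  var_t2 <- 1 + sdd^2 + 2 * rho * sdd
  cov_t1t2 <- 1 + rho * sdd
  list(mu_t1 = cfg$mean_theta_t1, mu_delta = mu_delta,
       mu_t2 = cfg$mean_theta_t1 + mu_delta,
       var_t1 = 1, var_t2 = var_t2, cov_t1t2 = cov_t1t2,
       var_delta = sdd^2)
}

#' Draw the latent part of a subject panel
#'
#' Generates theta^A, theta^B, xi, eta at both waves plus the latent change,
#' the individual MICs, and the true improvement status. theta^A and theta^B
#' are independent normals whose variances split the unit baseline variance of
#' theta in proportion to \code{strength_theta_b}^2; the latent change has the
#' configured SD and correlation with baseline theta, and its mean is solved
#' so that the probability of a change exceeding the individual MIC equals
#' \code{prop_improved}. The change is apportioned to theta^A and theta^B by
#' their variance shares.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional seed overriding the stage seed derived from
#'   \code{cfg$seed}.
#' @return \code{data.frame} with one row per subject: \code{theta_a_t1},
#'   \code{theta_b_t1}, \code{xi_t1}, \code{eta_t1}, the same at T2,
#'   \code{theta_t1}, \code{theta_t2}, \code{delta_theta},
#'   \code{individual_mic}, \code{improved_true}.
#' @export
draw_latent_states <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_subjects
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 4L)[1]
  set.seed(seed)

  r2 <- cfg$strength_theta_b^2
  p_a <- 1 / (1 + r2)
  p_b <- r2 / (1 + r2)
  m <- cfg$mean_theta_t1

  theta_a_t1 <- rnorm(n, m * p_a, sqrt(p_a))
  theta_b_t1 <- if (p_b > 0) rnorm(n, m * p_b, sqrt(p_b)) else numeric(n)
  theta_t1 <- theta_a_t1 + theta_b_t1

  mu_delta <- solve_mean_delta(cfg$prop_improved, cfg$sd_delta_theta,
                               cfg$true_mic, cfg$sd_mic)
  rho <- cfg$cor_theta_t1_delta
  z1 <- theta_t1 - m # standardized baseline deviation (unit variance)
  delta_theta <- mu_delta +
    cfg$sd_delta_theta * (rho * z1 + sqrt(1 - rho^2) * rnorm(n))

  theta_a_t2 <- theta_a_t1 + p_a * delta_theta
  theta_b_t2 <- theta_b_t1 + p_b * delta_theta

  cw <- function(r) { # bivariate standard normal pair with correlation r
    u <- rnorm(n); v <- r * u + sqrt(1 - r^2) * rnorm(n); cbind(u, v)
  }
  xi <- cw(cfg$cor_xi)
  eta <- cw(cfg$cor_eta)

  individual_mic <- rnorm(n, cfg$true_mic, cfg$sd_mic)

  data.frame(
    theta_a_t1 = theta_a_t1, theta_b_t1 = theta_b_t1,
    xi_t1 = xi[, 1], eta_t1 = eta[, 1],
    theta_a_t2 = theta_a_t2, theta_b_t2 = theta_b_t2,
    xi_t2 = xi[, 2], eta_t2 = eta[, 2],
    theta_t1 = theta_t1, theta_t2 = theta_a_t2 + theta_b_t2,
    delta_theta = delta_theta,
    individual_mic = individual_mic,
    improved_true = delta_theta > individual_mic
  )
}

#' Generate SIM scores from a latent panel
#'
#' The SIM measures theta + c*eta plus independent normal error (one latent
#' unit maps to one SIM unit, so the true MIC keeps its value in the SIM
#' metric). The baseline reliability target is the share of variance carried
#' by the construct theta; the off-target construct eta counts against
#' reliability together with measurement error, so the error variance is
#' \code{(1 - rel)/rel - c^2} (floored at zero: beyond \code{rel = 1/(1+c^2)}
#' the off-target variance alone caps the attainable reliability). The two
#' waves' errors share a stable component (correlation 0.25). Scores are
#' shifted by 5.5, rounded half away from zero and clamped to the 0-10
#' integer scale.
#'
#' @param panel latent panel from \code{\link{draw_latent_states}}.
#' @param rel_sim_t1 target reliability of the SIM at baseline.
#' @param seed RNG seed for the measurement errors.
#' @return list with integer vectors \code{sim_t1}, \code{sim_t2} and the
#'   pre-discretization continuous scores \code{sim_cont_t1},
#'   \code{sim_cont_t2}, \code{sim_sys_t1}, \code{sim_sys_t2} (for oracle
#'   checks).
#' @export
generate_sim_scores <- function(panel, rel_sim_t1, seed) {
  stopifnot(rel_sim_t1 > 0, rel_sim_t1 <= 1)
  n <- nrow(panel)
  set.seed(seed)
  c_eta <- .ETA_WEIGHT
  err_sd <- sqrt(max(0, (1 - rel_sim_t1) / rel_sim_t1 - c_eta^2))
  re <- .SIM_ERR_STABILITY
  u1 <- rnorm(n)
  e1 <- err_sd * u1
  e2 <- err_sd * (re * u1 + sqrt(1 - re^2) * rnorm(n))
  cont1 <- panel$theta_t1 + c_eta * panel$eta_t1 + e1
  cont2 <- panel$theta_t2 + c_eta * panel$eta_t2 + e2
  list(
    sim_t1 = as.integer(clamp(round_half_away(cont1 + 5.5), 0, 10)),
    sim_t2 = as.integer(clamp(round_half_away(cont2 + 5.5), 0, 10)),
    sim_cont_t1 = cont1, sim_cont_t2 = cont2,
    sim_sys_t1 = panel$theta_t1, sim_sys_t2 = panel$theta_t2
  )
}

#' Generate AUX item responses and sum scores
#'
#' Items follow a graded-response mechanism: item i loads on the shared trait
#' component theta^A (discrimination \code{a_i}, log-normal around the mean
#' slope) and on the AUX-specific construct xi with slope
#' \code{strength_xi * a_i}; category boundaries are equally spaced on the
#' latent scale and shifted per item. theta^A enters standardized by its
#' baseline SD so that discriminations keep their meaning across conditions.
#' The same item parameters apply at both waves.
#'
#' @param panel latent panel from \code{\link{draw_latent_states}}.
#' @param strength_xi ratio of the mean xi slope to the mean theta^A slope.
#' @param seed RNG seed (item parameters and response draws).
#' @param n_items,n_categories test length and response categories per item.
#' @return list with matrices \code{items_t1}, \code{items_t2} (subjects x
#'   items, scored 0..K-1), vectors \code{aux_sum_t1}, \code{aux_sum_t2}, and
#'   the drawn \code{slopes}.
#' @export
generate_aux_items <- function(panel, strength_xi, seed,
                               n_items = .AUX_DEFAULTS$n_items,
                               n_categories = .AUX_DEFAULTS$n_categories) {
  stopifnot(n_items >= 3, n_categories >= 2, strength_xi >= 0)
  n <- nrow(panel)
  set.seed(seed)
  au <- .AUX_DEFAULTS
  a <- exp(rnorm(n_items, log(au$mean_slope), au$sdlog_slope))
  a <- a * au$mean_slope / mean(a) # keep the mean slope ratio exact
  bx <- strength_xi * a
  item_shift <- seq(-au$item_shift_range, au$item_shift_range,
                    length.out = n_items) + au$shift
  k_mid <- n_categories / 2 # centers the K-1 boundaries around item_shift
  bounds <- lapply(seq_len(n_items), function(i) {
    au$spread * (seq_len(n_categories - 1L) - k_mid) + item_shift[i]
  })

  sd_a1 <- aux_theta_a_sd(panel)
  draw_wave <- function(theta_a, xi) {
    za <- theta_a / sd_a1
    out <- matrix(0L, n, n_items)
    for (i in seq_len(n_items)) {
      u <- runif(n)
      x <- integer(n)
      for (k in seq_len(n_categories - 1L)) {
        p_ge <- plogis(a[i] * (za - bounds[[i]][k]) + bx[i] * xi)
        x <- x + as.integer(u < p_ge)
      }
      out[, i] <- x
    }
    out
  }
  items_t1 <- draw_wave(panel$theta_a_t1, panel$xi_t1)
  items_t2 <- draw_wave(panel$theta_a_t2, panel$xi_t2)
  colnames(items_t1) <- paste0("aux", seq_len(n_items), "_t1")
  colnames(items_t2) <- paste0("aux", seq_len(n_items), "_t2")
  list(items_t1 = items_t1, items_t2 = items_t2,
       aux_sum_t1 = as.integer(rowSums(items_t1)),
       aux_sum_t2 = as.integer(rowSums(items_t2)),
       slopes = a)
}

# Baseline SD of theta^A: from the generating SD ratio when the panel carries
# it, otherwise estimated from the panel itself.
aux_theta_a_sd <- function(panel) {
  sb <- attr(panel, "strength_theta_b")
  if (!is.null(sb)) sqrt(1 / (1 + sb^2)) else stats::sd(panel$theta_a_t1)
}

#' Generate transition ratings with present-state bias
#'
#' The anchor reflects the weighted latent change
#' \eqn{\Delta\theta_w = (1 - psb)\,\Delta\theta + psb\,(\theta_{T2} -
#' \bar\theta_{T1})}. A perceived-change variable adds normal noise whose
#' variance is calibrated (together with the individual-MIC dispersion, which
#' also attenuates the binary anchor) so that the dichotomous item attains the
#' target reliability; the subject rates "improved" when the perceived change
#' exceeds their individual MIC.
#'
#' @param panel latent panel (including \code{individual_mic}).
#' @param psb present-state bias in \[0, 1\].
#' @param rel_trs target reliability of the dichotomous anchor.
#' @param seed RNG seed for the perception noise.
#' @param cfg the generating \code{\link{sim_config}} (population moments of
#'   theta are needed for the calibration).
#' @return list with \code{trs_improved} (integer 0/1), \code{trs7} (ordered
#'   1..7, a cosmetic mapping whose top-two categories correspond exactly to
#'   \code{trs_improved == 1}), \code{delta_theta_w} and \code{perceived}.
#' @export
generate_transition_ratings <- function(panel, psb, rel_trs, seed, cfg) {
  stopifnot(psb >= 0, psb <= 1, rel_trs > 0, rel_trs <= 1)
  n <- nrow(panel)
  set.seed(seed)
  mom <- theta_moments(cfg)
  var_dw <- mom$var_t2 + (1 - psb)^2 * mom$var_t1 -
    2 * (1 - psb) * mom$cov_t1t2
  noise_var <- var_dw * (1 - rel_trs) / rel_trs - cfg$sd_mic^2
  if (noise_var < 0) {
    stop(sprintf(
      "rel_trs = %.2f is not attainable: individual-MIC dispersion alone leaves reliability below the target",
      rel_trs), call. = FALSE)
  }
  dw <- (1 - psb) * panel$delta_theta +
    psb * (panel$theta_t2 - cfg$mean_theta_t1)
  perceived <- dw + rnorm(n, 0, sqrt(noise_var))
  rel_pc <- perceived - panel$individual_mic
  trs_improved <- as.integer(rel_pc > 0)
  breaks <- c(-Inf, -2.4, -1.6, -0.8, -0.3, 0, 0.8, Inf)
  trs7 <- as.integer(cut(rel_pc, breaks = breaks, labels = FALSE,
                         right = TRUE))
  list(trs_improved = trs_improved, trs7 = trs7,
       delta_theta_w = dw, perceived = perceived)
}

#' Labels of the 7-level transition-rating item
#' @return character vector of length 7 (worst to best).
#' @export
trs7_labels <- function() {
  c("Very much deteriorated", "Much deteriorated", "A little deteriorated",
    "Not changed", "A little improved", "Much improved",
    "Very much improved")
}

#' Simulate a complete SIM/AUX/TRs dataset
#'
#' Composes the latent, SIM, AUX and transition-rating generators using
#' independent RNG substreams derived from the configuration's master seed,
#' so the same configuration always yields a bit-identical panel.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param keep_latent keep the latent table for oracle checks (default TRUE).
#' @return object of class \code{sim_panel}: a list with \code{observed}
#'   (data.frame of SIM scores, AUX items and sums, \code{trs7},
#'   \code{trs_improved}), \code{latent} (or NULL) and \code{config}.
#' @export
simulate_dataset <- function(cfg, keep_latent = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  res <- tryCatch({
    latent <- draw_latent_states(cfg, seed = seeds[1])
    attr(latent, "strength_theta_b") <- cfg$strength_theta_b
    sim <- generate_sim_scores(latent, cfg$rel_sim_t1, seeds[2])
    aux <- generate_aux_items(latent, cfg$strength_xi, seeds[3])
    trs <- generate_transition_ratings(latent, cfg$psb, cfg$rel_trs,
                                       seeds[4], cfg)
    observed <- data.frame(sim_t1 = sim$sim_t1, sim_t2 = sim$sim_t2,
                           aux$items_t1, aux$items_t2,
                           aux_sum_t1 = aux$aux_sum_t1,
                           aux_sum_t2 = aux$aux_sum_t2,
                           trs7 = trs$trs7,
                           trs_improved = trs$trs_improved)
    latent$sim_cont_t1 <- sim$sim_cont_t1
    latent$sim_cont_t2 <- sim$sim_cont_t2
    latent$sim_sys_t1 <- sim$sim_sys_t1
    latent$sim_sys_t2 <- sim$sim_sys_t2
    latent$delta_theta_w <- trs$delta_theta_w
    latent$perceived_change <- trs$perceived
    list(observed = observed,
         latent = if (keep_latent) latent else NULL,
         config = cfg)
  }, error = function(e) {
    stop(sprintf("simulate_dataset failed for config (seed %d): %s",
                 cfg$seed, conditionMessage(e)), call. = FALSE)
  })
  structure(res, class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated two-wave panel: %d subjects\n", nrow(x$observed)))
  cat(sprintf("  mean theta T1 %.2f, SD(delta) %.2f, prop improved %.2f, PSB %.2f\n",
              cfg$mean_theta_t1, cfg$sd_delta_theta, cfg$prop_improved,
              cfg$psb))
  cat(sprintf("  rel(SIM T1) %.2f, rel(TRs) %.2f, true MIC %.2f\n",
              cfg$rel_sim_t1, cfg$rel_trs, cfg$true_mic))
  cat(sprintf("  observed: mean SIM T1 %.2f, mean SIM T2 %.2f, improved %.2f\n",
              mean(x$observed$sim_t1), mean(x$observed$sim_t2),
              mean(x$observed$trs_improved)))
  invisible(x)
}

#' Cronbach's alpha of an item matrix
#'
#' @param items numeric matrix, subjects x items.
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  k <- ncol(items)
  v_items <- sum(apply(items, 2, stats::var))
  v_total <- stats::var(rowSums(items))
  k / (k - 1) * (1 - v_items / v_total)
}
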