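# MIC estimators: predictive modeling, its adjusted version (APM), and the
# LCFA-based estimator, plus the rescaling recipe for continuous SIMs.

#' Dichotomize a transition-ratings item
#'
#' Splits the ordered anchor into improved / not-improved at a cutpoint:
#' category \code{cutpoint} and above count as improved. With the default 7
#' response levels (\code{\link{trs7_labels}}), \code{cutpoint = 6} places
#' the threshold between "A little improved" and "Much improved".
#'
#' @param trs7 integer vector of ordered categories (1-based).
#' @param cutpoint first category counted as improved.
#' @param n_levels number of categories of the item.
#' @return list with \code{improved} (integer 0/1) and \code{prop_improved}.
#' @export
dichotomize_trs <- function(trs7, cutpoint = 6L, n_levels = 7L) {
  if (cutpoint < 2L || cutpoint > n_levels) {
    stop(sprintf("cutpoint must lie in 2..%d (between two adjacent levels)",
                 n_levels), call. = FALSE)
  }
  if (any(trs7 < 1L | trs7 > n_levels, na.rm = TRUE)) {
    stop("transition ratings outside the declared category range",
         call. = FALSE)
  }
  improved <- as.integer(trs7 >= cutpoint)
  prop <- mean(improved, na.rm = TRUE)
  if (prop %in% c(0, 1)) {
    warning("all subjects on one side of the cutpoint; MIC_PM/MIC_APM undefined",
            call. = FALSE)
  }
  list(improved = improved, prop_improved = prop)
}

#' Predictive-modeling MIC
#'
#' Logistic regression of the improvement anchor on the SIM change score;
#' the MIC is the change score at which improvement is as likely as not
#' relative to the base rate -- where the fitted log-odds equals the marginal
#' log-odds of improvement, so the likelihood ratio between the improved and
#' not-improved groups is 1:
#' \deqn{MIC_{PM} = (logodds(p) - b_0)/b_1.}
#'
#' @param delta_sim SIM change scores (T2 - T1).
#' @param improved binary anchor (0/1).
#' @return list with \code{mic_pm}, intercept \code{b0}, slope \code{b1} and
#'   \code{prop_improved}.
#' @export
predictive_modeling_mic <- function(delta_sim, improved) {
  ok <- !is.na(delta_sim) & !is.na(improved)
  delta_sim <- delta_sim[ok]; improved <- improved[ok]
  if (length(unique(improved)) < 2L) {
    stop("anchor has a single class; predictive-modeling MIC undefined",
         call. = FALSE)
  }
  fit <- suppressWarnings(glm(improved ~ delta_sim, family = binomial()))
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  if (!is.finite(b0) || !is.finite(b1)) {
    stop("logistic fit failed (separation?)", call. = FALSE)
  }
  if (abs(b1) > 50) {
    stop("logistic slope diverged: (quasi-)complete separation", call. = FALSE)
  }
  if (b1 <= 0) {
    stop("non-positive logistic slope: anchor uninformative about the change score",
         call. = FALSE)
  }
  prop <- mean(improved)
  list(mic_pm = (logodds(prop) - b0) / b1, b0 = b0, b1 = b1,
       prop_improved = prop)
}

#' Adjusted predictive-modeling MIC
#'
#' Corrects the predictive-modeling MIC for the bias caused by the proportion
#' improved, using the reliability of the transition ratings:
#' \deqn{MIC_{APM} = MIC_{PM} - (0.8/Rel_{TRs} - 0.5) \cdot SD(\Delta SIM)
#'   \cdot Cor \cdot logodds(p)}
#' with \code{Cor} the point-biserial correlation between the change score
#' and the dichotomous anchor and natural-log odds.
#'
#' @param mic_pm predictive-modeling MIC.
#' @param rel_trs reliability of the transition ratings, in (0, 1].
#' @param sd_delta_sim SD of the SIM change score.
#' @param cor_pb point-biserial correlation between change score and anchor.
#' @param prop_improved proportion improved, strictly inside (0, 1).
#' @return the adjusted MIC.
#' @export
apm_adjustment <- function(mic_pm, rel_trs, sd_delta_sim, cor_pb,
                           prop_improved) {
  if (!is.finite(rel_trs) || rel_trs <= 0 || rel_trs > 1) {
    stop("rel_trs must lie in (0, 1]", call. = FALSE)
  }
  if (sd_delta_sim <= 0) stop("sd_delta_sim must be positive", call. = FALSE)
  if (prop_improved <= 0 || prop_improved >= 1) {
    stop("proportion improved of 0 or 1 gives infinite log-odds; MIC_APM undefined",
         call. = FALSE)
  }
  mic_pm - (0.8 / rel_trs - 0.5) * sd_delta_sim * cor_pb *
    logodds(prop_improved)
}

#' LCFA-based MIC in SIM units
#'
#' Rescales the latent MIC by the SD of the SIM's true score,
#' \eqn{\sqrt{var(SIM_{T1}) \cdot Rel_{SIM.T1}}}, i.e. the SD of the baseline
#' factor expressed in SIM units.
#'
#' @param var_sim_t1 observed variance of the SIM at baseline.
#' @param rel_sim_t1 baseline reliability of the SIM (model C R-squared).
#' @param mic_theta latent MIC from model C.
#' @return MIC in SIM change units.
#' @export
lcfa_mic <- function(var_sim_t1, rel_sim_t1, mic_theta) {
  if (var_sim_t1 <= 0) stop("var_sim_t1 must be positive", call. = FALSE)
  if (rel_sim_t1 <= 0 || rel_sim_t1 > 1) {
    stop("rel_sim_t1 must lie in (0, 1]", call. = FALSE)
  }
  sqrt(var_sim_t1 * rel_sim_t1) * mic_theta
}

#' Rescale a continuous SIM to a 12-point ordinal scale
#'
#' Maps a continuous bounded scale onto 0.51-12.49 (factor
#' \code{T = 11.98/range}, shift \code{R = 0.51 - T*min}) and rounds to
#' integers 1..12, so the result can serve as an ordered indicator in the
#' invariance model. Keep the returned transform to map the estimated MIC
#' back to the original units.
#'
#' @param values continuous scores within the declared range.
#' @param scale_min,scale_max declared bounds of the scale.
#' @return list with \code{scores} (integers 1..12) and \code{transform}
#'   (class \code{rescale_transform}: \code{t_factor}, \code{r_shift},
#'   \code{back_factor}).
#' @export
rescale_continuous <- function(values, scale_min, scale_max) {
  if (scale_max <= scale_min) stop("scale_max must exceed scale_min",
                                   call. = FALSE)
  bad <- which(values < scale_min | values > scale_max)
  if (length(bad)) {
    stop("values outside the declared range at position(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  t_factor <- 11.98 / (scale_max - scale_min)
  r_shift <- 0.51 - t_factor * scale_min
  scores <- round_half_away(t_factor * values + r_shift)
  transform <- structure(list(t_factor = t_factor, r_shift = r_shift,
                              back_factor = 1 / t_factor),
                         class = "rescale_transform")
  list(scores = as.integer(scores), transform = transform)
}

#' Back-transform a MIC from the rescaled to the original metric
#'
#' Change scores are unaffected by the shift, so only the scale factor is
#' undone: \code{mic / t_factor}.
#'
#' @param mic MIC on the transformed (1..12) scale.
#' @param transform a \code{rescale_transform}.
#' @return MIC in original scale units.
#' @export
backtransform_mic <- function(mic, transform) {
  stopifnot(inherits(transform, "rescale_transform"))
  mic * transform$back_factor
}

#' Estimate all MICs for a two-wave dataset
#'
#' End-to-end pipeline: dichotomizes the anchor if needed, fits the requested
#' LCFA model, and computes the predictive-modeling, APM and (for model C)
#' LCFA MICs. A non-convergent LCFA fit yields a structured result with
#' \code{converged = FALSE} and missing estimates rather than an error.
#'
#' @param data observed-data table (simulated panel's \code{observed} or a
#'   mapped dataset read with \code{\link{read_mic_data}}).
#' @param model LCFA model id: \code{"A"}, \code{"B"} or \code{"C"} (model C
#'   is required for the LCFA-based MIC).
#' @param aux_item AUX item used when \code{model = "A"}.
#' @param trs_cut cutpoint applied to a 7-level \code{trs7} column when no
#'   binary \code{trs_improved} column is present.
#' @return object of class \code{mic_estimates}.
#' @export
estimate_all <- function(data, model = "C", aux_item = 1L, trs_cut = 6L) {
  if ("trs_improved" %in% names(data)) {
    improved <- data$trs_improved
    prop <- mean(improved, na.rm = TRUE)
  } else if ("trs7" %in% names(data)) {
    d <- dichotomize_trs(data$trs7, trs_cut)
    improved <- d$improved
    prop <- d$prop_improved
    data$trs_improved <- improved
  } else {
    stop("data needs a 'trs_improved' or 'trs7' column", call. = FALSE)
  }
  delta_sim <- data$sim_t2 - data$sim_t1
  sd_delta <- sd(delta_sim, na.rm = TRUE)
  cor_pb <- suppressWarnings(cor(delta_sim, improved,
                                 use = "complete.obs"))

  spec <- build_model(model)
  fit <- fit_model(panel_indicators(data, spec, aux_item = aux_item), spec)

  pm <- tryCatch(predictive_modeling_mic(delta_sim, improved),
                 error = function(e) NULL)

  out <- list(
    model = model,
    converged = fit$converged,
    reason = fit$reason,
    prop_improved = prop,
    sd_delta_sim = sd_delta,
    cor_pb = cor_pb,
    b0 = pm$b0 %||% NA_real_,
    b1 = pm$b1 %||% NA_real_,
    mic_pm = pm$mic_pm %||% NA_real_,
    rel_trs = NA_real_, mic_apm = NA_real_,
    rel_sim_t1 = NA_real_, var_sim_t1 = var(data$sim_t1, na.rm = TRUE),
    mic_theta = NA_real_, mic_lcfa = NA_real_,
    psb_hat = NA_real_,
    fit = fit
  )
  if (fit$converged) {
    out$rel_trs <- trs_reliability(fit)
    if (!is.null(pm) && prop > 0 && prop < 1 && out$rel_trs > 0) {
      out$mic_apm <- apm_adjustment(pm$mic_pm, out$rel_trs, sd_delta,
                                    cor_pb, prop)
    }
    if (model == "C") {
      out$rel_sim_t1 <- sim_reliability_t1(fit)
      out$mic_theta <- tryCatch(latent_mic(fit), error = function(e) NA_real_)
      out$psb_hat <- fit$psb_hat
      if (is.finite(out$mic_theta) && out$rel_sim_t1 > 0) {
        out$mic_lcfa <- lcfa_mic(out$var_sim_t1, out$rel_sim_t1,
                                 out$mic_theta)
      }
    }
  }
  structure(out, class = "mic_estimates")
}

#' @export
print.mic_estimates <- function(x, digits = 3, ...) {
  cat(sprintf("MIC estimates (LCFA model %s, n = %d)%s\n", x$model,
              x$fit$n_obs,
              if (x$converged) "" else " - MODEL DID NOT CONVERGE"))
  cat(sprintf("  proportion improved %.3f | SD(dSIM) %.3f | point-biserial %.3f\n",
              x$prop_improved, x$sd_delta_sim, x$cor_pb))
  fmt <- function(v) if (is.na(v)) "   --" else formatC(v, digits = digits,
                                                        format = "f")
  cat("  MIC_PM  ", fmt(x$mic_pm),
      " | MIC_APM ", fmt(x$mic_apm),
      " (Rel_TRs ", fmt(x$rel_trs), ")\n", sep = "")
  if (x$model == "C") {
    cat("  MIC_theta ", fmt(x$mic_theta),
        " | MIC_LCFA ", fmt(x$mic_lcfa),
        " (Rel_SIM.T1 ", fmt(x$rel_sim_t1),
        ", PSB ", fmt(x$psb_hat), ")\n", sep = "")
  }
  invisible(x)
}
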