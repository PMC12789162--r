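# Monte-Carlo performance study over the simulation grid, and nonparametric
# bootstrap confidence intervals for single-dataset MIC estimates.

#' Bias and RMSE of a vector of MIC estimates
#'
#' Bias is the mean estimate minus the true value; RMSE the root mean squared
#' deviation from it. Monte-Carlo standard errors: bias by SD/sqrt(K), RMSE
#' by leave-one-out jackknife.
#'
#' @param estimates numeric vector of estimates (non-finite values dropped
#'   with a count).
#' @param true_mic the simulated true MIC.
#' @param method optional label stored in the result.
#' @return object of class \code{performance_summary} (one-row data.frame
#'   with \code{method}, \code{n_converged}, \code{mean_estimate},
#'   \code{bias}, \code{bias_mcse}, \code{rmse}, \code{rmse_mcse},
#'   \code{true_mic}).
#' @export
summarize_performance <- function(estimates, true_mic = 0.8,
                                  method = NA_character_) {
  est <- estimates[is.finite(estimates)]
  k <- length(est)
  if (k < 2L) stop("need at least 2 converged estimates", call. = FALSE)
  bias <- mean(est) - true_mic
  rmse <- sqrt(mean((est - true_mic)^2))
  # jackknife over leave-one-out RMSEs
  ss <- sum((est - true_mic)^2)
  loo <- sqrt((ss - (est - true_mic)^2) / (k - 1))
  rmse_mcse <- sqrt((k - 1) / k * sum((loo - mean(loo))^2))
  out <- data.frame(method = method, n_converged = k,
                    mean_estimate = mean(est), bias = bias,
                    bias_mcse = sd(est) / sqrt(k),
                    rmse = rmse, rmse_mcse = rmse_mcse,
                    true_mic = true_mic)
  class(out) <- c("performance_summary", "data.frame")
  out
}

# All four estimators on one simulated panel. Fits are reused across
# methods: the APM ingredients (MIC_PM, SD, point-biserial, proportion) are
# shared, only Rel_TRs differs by model.
condition_estimates <- function(panel, methods = c("APM-A", "APM-B", "APM-C",
                                                   "LCFA-C")) {
  obs <- panel$observed
  delta_sim <- obs$sim_t2 - obs$sim_t1
  improved <- obs$trs_improved
  prop <- mean(improved)
  sd_delta <- sd(delta_sim)
  cor_pb <- suppressWarnings(cor(delta_sim, improved))
  pm <- tryCatch(predictive_modeling_mic(delta_sim, improved),
                 error = function(e) NULL)

  model_ids <- unique(c(sub("APM-", "", grep("^APM-", methods, value = TRUE)),
                        if ("LCFA-C" %in% methods) "C"))
  fits <- lapply(setNames(model_ids, model_ids), function(mid) {
    spec <- build_model(mid)
    tryCatch(fit_model(panel_indicators(obs, spec), spec),
             error = function(e) NULL)
  })

  out <- list(prop_improved = prop, sd_delta_sim = sd_delta,
              cor_pb = cor_pb, mic_pm = pm$mic_pm %||% NA_real_,
              mean_sim_t1 = mean(obs$sim_t1), sd_sim_t1 = sd(obs$sim_t1))
  for (mid in c("A", "B", "C")) {
    apm_name <- paste0("mic_apm_", mid)
    conv_name <- paste0("converged_", mid)
    fit <- fits[[mid]]
    conv <- !is.null(fit) && isTRUE(fit$converged)
    out[[conv_name]] <- conv
    out[[apm_name]] <- if (conv && !is.null(pm) && prop > 0 && prop < 1) {
      tryCatch(apm_adjustment(pm$mic_pm, trs_reliability(fit), sd_delta,
                              cor_pb, prop), error = function(e) NA_real_)
    } else NA_real_
  }
  fit_c <- fits[["C"]]
  out$mic_lcfa <- if (!is.null(fit_c) && isTRUE(fit_c$converged)) {
    mt <- tryCatch(latent_mic(fit_c), error = function(e) NA_real_)
    if (is.finite(mt)) {
      lcfa_mic(var(obs$sim_t1), sim_reliability_t1(fit_c), mt)
    } else NA_real_
  } else NA_real_
  out
}

#' Run the Monte-Carlo performance study
#'
#' Simulates one dataset per grid condition, fits the requested LCFA models,
#' computes the APM MIC (with each model's TRs reliability) and the LCFA MIC
#' (model C), and aggregates bias/RMSE per method over conditions.
#' Non-converged fits are excluded from (and counted against) the affected
#' method only.
#'
#' @param grid a \code{mic_grid} (possibly a \code{\link{subset_grid}} of the
#'   full design).
#' @param methods estimators to evaluate.
#' @param true_mic true MIC of the generating process.
#' @param progress print a dot every 25 conditions.
#' @return list of class \code{mic_study}: \code{summary} (one
#'   \code{performance_summary} row per method), \code{details} (one row per
#'   condition) and \code{n_attempted}.
#' @export
run_study <- function(grid, methods = c("APM-A", "APM-B", "APM-C", "LCFA-C"),
                      true_mic = 0.8, progress = FALSE) {
  stopifnot(nrow(grid) >= 1)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid_config(grid, i)
    est <- tryCatch(
      condition_estimates(simulate_dataset(cfg, keep_latent = FALSE),
                          methods),
      error = function(e) NULL)
    rows[[i]] <- c(list(condition = grid$condition[i]), est %||% list())
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  cols <- c("condition", "prop_improved", "sd_delta_sim", "cor_pb",
            "mic_pm", "mean_sim_t1", "sd_sim_t1", "mic_apm_A", "mic_apm_B",
            "mic_apm_C", "mic_lcfa", "converged_A", "converged_B",
            "converged_C")
  details <- do.call(rbind, lapply(rows, function(r) {
    row <- lapply(setNames(cols, cols), function(cl) r[[cl]] %||% NA)
    as.data.frame(row)
  }))
  column_of <- c("APM-A" = "mic_apm_A", "APM-B" = "mic_apm_B",
                 "APM-C" = "mic_apm_C", "LCFA-C" = "mic_lcfa")
  summaries <- lapply(methods, function(m) {
    tryCatch(summarize_performance(details[[column_of[[m]]]], true_mic,
                                   method = m),
             error = function(e) {
               data.frame(method = m,
                          n_converged = sum(is.finite(details[[column_of[[m]]]])),
                          mean_estimate = NA_real_, bias = NA_real_,
                          bias_mcse = NA_real_, rmse = NA_real_,
                          rmse_mcse = NA_real_, true_mic = true_mic)
             })
  })
  structure(list(summary = do.call(rbind, summaries), details = details,
                 n_attempted = nrow(grid), true_mic = true_mic),
            class = "mic_study")
}

#' @export
print.mic_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo performance study: %d conditions, true MIC %.2f\n",
              x$n_attempted, x$true_mic))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s N %5d  mean %.3f  bias %+.3f (%.3f)  RMSE %.3f (%.3f)\n",
                s$method[i], s$n_converged[i], s$mean_estimate[i],
                s$bias[i], s$bias_mcse[i], s$rmse[i], s$rmse_mcse[i]))
  }
  invisible(x)
}

#' Nonparametric bootstrap CIs for single-dataset MIC estimates
#'
#' Resamples subjects with replacement, refits the chosen LCFA model and the
#' logistic anchor regression per replicate, and returns percentile 95%
#' intervals over the converged replicates. The anchor dichotomization of the
#' original dataset is kept fixed.
#'
#' @param data observed-data table (with \code{trs_improved}, or \code{trs7}
#'   plus \code{trs_cut}).
#' @param B number of bootstrap replications (>= 100).
#' @param model LCFA model id.
#' @param seed RNG seed.
#' @param trs_cut anchor cutpoint used if dichotomization is needed.
#' @return object of class \code{mic_bootstrap}: point estimates, percentile
#'   CIs, convergence counts and the replicate table.
#' @export
bootstrap_mic <- function(data, B = 2000L, model = "C", seed = 1L,
                          trs_cut = 6L) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (!"trs_improved" %in% names(data)) {
    if (!"trs7" %in% names(data)) {
      stop("data needs a 'trs_improved' or 'trs7' column", call. = FALSE)
    }
    data$trs_improved <- dichotomize_trs(data$trs7, trs_cut)$improved
  }
  point <- estimate_all(data, model = model)
  stat_names <- c("rel_trs", "mic_theta", "mic_apm", "mic_lcfa", "psb_hat")
  reps <- matrix(NA_real_, B, length(stat_names),
                 dimnames = list(NULL, stat_names))
  boot_seeds <- derive_seeds(seed, B)
  n <- nrow(data)
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(estimate_all(data[idx, , drop = FALSE], model = model),
                    error = function(e) NULL)
    if (!is.null(est) && est$converged) {
      reps[b, ] <- unlist(est[stat_names])
    }
  }
  conv <- is.finite(reps[, "rel_trs"])
  if (mean(conv) < 0.05) {
    stop(sprintf(
      "only %d of %d bootstrap replicates converged; intervals would be uninterpretable",
      sum(conv), B), call. = FALSE)
  }
  ci <- apply(reps[conv, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(point = point, ci = ci, replicates = reps,
                 n_requested = B, n_converged = sum(conv), seed = seed),
            class = "mic_bootstrap")
}

#' @export
print.mic_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d of %d replicates converged\n",
              x$n_converged, x$n_requested))
  pt <- unlist(x$point[colnames(x$ci)])
  for (nm in colnames(x$ci)) {
    cat(sprintf("  %-10s %6.3f (%6.3f, %6.3f)\n", nm, pt[[nm]],
                x$ci[1, nm], x$ci[2, nm]))
  }
  invisible(x)
}
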