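# Auxiliary-enriched longitudinal CFA models for two-wave SIM data.
#
# Three model layouts share the same indicator set {sim_t1, sim_t2, aux_t1,
# aux_t2, trs}: two correlated trait factors (baseline, follow-up), the
# transition-rating anchor loading on both, and cross-wave residual
# correlations for the repeated indicators.
#
#   A: AUX enters as a single ordered item; SIMs continuous; identified by
#      fixing both SIM loadings to 1.
#   B: as A but with the AUX sum score as a continuous indicator.
#   C: as B plus measurement invariance for the SIM: both SIMs ordered with
#      loadings and thresholds constrained equal over time, the baseline
#      factor standardized, theta parameterization (unit residual variances
#      for sim_t1 and trs), and free follow-up factor mean/variance and
#      sim_t2 residual variance. Model C identifies the latent change metric
#      and hence the latent MIC.
#
# Estimation is two-stage: thresholds and polychoric/polyserial/Pearson
# correlations first, then diagonally weighted least squares (weights = the
# inverse asymptotic variances of the first-stage estimates) on the model's
# implied moments.

.LCFA_VARS <- c("sim_t1", "sim_t2", "aux_t1", "aux_t2", "trs")
.LCFA_PAIRS <- cbind(i = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
                     j = c(2, 3, 4, 5, 3, 4, 5, 4, 5, 5))

#' Specify an auxiliary-enriched LCFA model
#'
#' @param model_id \code{"A"}, \code{"B"} or \code{"C"}.
#' @param aux_mode \code{"single_item"} (model A) or \code{"sum_score"}
#'   (models B and C). The pairing is fixed by the model definitions; a
#'   mismatch is rejected.
#' @return object of class \code{lcfa_spec} with the indicator treatments and
#'   identification rule.
#' @export
build_model <- function(model_id = c("A", "B", "C"),
                        aux_mode = c("single_item", "sum_score")) {
  model_id <- match.arg(model_id)
  aux_given <- !missing(aux_mode)
  aux_mode <- match.arg(aux_mode,
                        choices = c("single_item", "sum_score"),
                        several.ok = FALSE)
  required <- switch(model_id, A = "single_item", B = "sum_score",
                     C = "sum_score")
  if (aux_given && aux_mode != required) {
    stop(sprintf("model %s requires aux_mode = '%s'", model_id, required),
         call. = FALSE)
  }
  aux_mode <- required
  treatments <- switch(model_id,
    A = c(sim_t1 = "continuous", sim_t2 = "continuous",
          aux_t1 = "ordered", aux_t2 = "ordered", trs = "ordered"),
    B = c(sim_t1 = "continuous", sim_t2 = "continuous",
          aux_t1 = "continuous", aux_t2 = "continuous", trs = "ordered"),
    C = c(sim_t1 = "ordered", sim_t2 = "ordered",
          aux_t1 = "continuous", aux_t2 = "continuous", trs = "ordered"))
  structure(list(
    model_id = model_id,
    aux_mode = aux_mode,
    treatments = treatments,
    identification = if (model_id == "C") "standardize_theta_t1"
                     else "fix_lambda_sim",
    parameterization = if (model_id == "C") "theta" else "delta",
    invariance = model_id == "C"
  ), class = "lcfa_spec")
}

#' @export
print.lcfa_spec <- function(x, ...) {
  cat(sprintf("LCFA model %s (AUX as %s)\n", x$model_id,
              gsub("_", " ", x$aux_mode)))
  cat("  treatments:",
      paste(names(x$treatments), x$treatments, sep = "=", collapse = ", "),
      "\n")
  cat("  identification:", x$identification,
      "| parameterization:", x$parameterization, "\n")
  invisible(x)
}

# ---- implied moments ------------------------------------------------------

# Models A/B: correlation metric. par = (V1, V2, psi12, lx1, lx2, lr1, lr2,
# cs, cx). Returns the 10 implied correlations (pair order .LCFA_PAIRS) or
# NULL when the point is inadmissible.
.implied_ab <- function(par) {
  V1 <- par[1]; V2 <- par[2]; p12 <- par[3]
  lx1 <- par[4]; lx2 <- par[5]; lr1 <- par[6]; lr2 <- par[7]
  cs <- par[8]; cx <- par[9]
  rs1 <- 1 - V1; rs2 <- 1 - V2
  rx1 <- 1 - lx1^2 * V1; rx2 <- 1 - lx2^2 * V2
  rr <- 1 - (lr1^2 * V1 + lr2^2 * V2 + 2 * lr1 * lr2 * p12)
  if (rs1 < 0 || rs2 < 0 || rx1 < 0 || rx2 < 0 || rr < 0 ||
      p12^2 > V1 * V2) return(NULL)
  c(p12 + cs * sqrt(rs1 * rs2),                 # sim_t1 - sim_t2
    lx1 * V1,                                   # sim_t1 - aux_t1
    lx2 * p12,                                  # sim_t1 - aux_t2
    lr1 * V1 + lr2 * p12,                       # sim_t1 - trs
    lx1 * p12,                                  # sim_t2 - aux_t1
    lx2 * V2,                                   # sim_t2 - aux_t2
    lr1 * p12 + lr2 * V2,                       # sim_t2 - trs
    lx1 * lx2 * p12 + cx * sqrt(rx1 * rx2),     # aux_t1 - aux_t2
    lx1 * (lr1 * V1 + lr2 * p12),               # aux_t1 - trs
    lx2 * (lr1 * p12 + lr2 * V2))               # aux_t2 - trs
}

# Model C: theta parameterization. par = (ls, lx1, lx2, lr1, lr2, psi12, V2,
# M2, phi2, cs, cx, tau_s[1..m], tau_r). Returns list(corr, tau1, tau2,
# tau_r, v1, v2, vR) or NULL when inadmissible.
.implied_c <- function(par, m) {
  ls <- par[1]; lx1 <- par[2]; lx2 <- par[3]; lr1 <- par[4]; lr2 <- par[5]
  p12 <- par[6]; V2 <- par[7]; M2 <- par[8]; phi2 <- par[9]
  cs <- par[10]; cx <- par[11]
  tau_s <- par[12:(11 + m)]
  tau_r <- par[12 + m]
  if (V2 <= 0 || phi2 <= 0 || p12^2 > V2) return(NULL)
  v1 <- ls^2 + 1
  v2 <- ls^2 * V2 + phi2
  vR <- lr1^2 + lr2^2 * V2 + 2 * lr1 * lr2 * p12 + 1
  rx1 <- 1 - lx1^2
  rx2 <- 1 - lx2^2 * V2
  if (rx1 < 0 || rx2 < 0 || vR <= 0) return(NULL)
  corr <- c(
    (ls^2 * p12 + cs * sqrt(phi2)) / sqrt(v1 * v2),
    ls * lx1 / sqrt(v1),
    ls * lx2 * p12 / sqrt(v1),
    ls * (lr1 + lr2 * p12) / sqrt(v1 * vR),
    ls * lx1 * p12 / sqrt(v2),
    ls * lx2 * V2 / sqrt(v2),
    ls * (lr1 * p12 + lr2 * V2) / sqrt(v2 * vR),
    lx1 * lx2 * p12 + cx * sqrt(rx1 * rx2),
    lx1 * (lr1 + lr2 * p12) / sqrt(vR),
    lx2 * (lr1 * p12 + lr2 * V2) / sqrt(vR))
  list(corr = corr,
       tau1 = tau_s / sqrt(v1),
       tau2 = (tau_s - ls * M2) / sqrt(v2),
       tau_r = (tau_r - lr2 * M2) / sqrt(vR),
       v1 = v1, v2 = v2, vR = vR)
}

# ---- fitting --------------------------------------------------------------

# Shared boundary thresholds of the two SIM waves for the invariance model:
# boundaries are defined on the union of observed categories; for each wave,
# only boundaries with cumulative proportion strictly inside (0, 1) yield a
# finite sample threshold.
.sim_threshold_stats <- function(x1, x2) {
  cats <- sort(union(unique(x1), unique(x2)))
  if (length(cats) < 3L) {
    stop("invariance model needs at least 3 SIM categories", call. = FALSE)
  }
  n_b <- length(cats) - 1L
  wave <- function(x) {
    cnt <- as.numeric(table(factor(x, levels = cats)))
    cum <- cumsum(cnt)[-length(cnt)] / length(x)
    keep <- cum > 0 & cum < 1
    tau <- qnorm(cum[keep])
    list(keep = which(keep), tau = tau,
         avar = cum[keep] * (1 - cum[keep]) / (length(x) * dnorm(tau)^2))
  }
  list(categories = cats, n_boundaries = n_b,
       t1 = wave(x1), t2 = wave(x2))
}

.fit_ab <- function(corstr, spec) {
  r <- corstr$R[.LCFA_PAIRS]
  w <- corstr$avar[.LCFA_PAIRS]
  obj <- function(par) {
    sig <- .implied_ab(par)
    if (is.null(sig)) return(1e12)
    sum((r - sig)^2 / w)
  }
  start <- c(V1 = 0.55, V2 = 0.55, p12 = clamp(r[1], -0.9, 0.9) * 0.9,
             lx1 = 0.6, lx2 = 0.6, lr1 = 0.1,
             lr2 = sign(r[7]) * 0.5, cs = 0.1, cx = 0.2)
  lower <- c(1e-4, 1e-4, -1, -0.999, -0.999, -3, -3, -0.995, -0.995)
  upper <- c(0.999, 0.999, 1, 0.999, 0.999, 3, 3, 0.995, 0.995)
  fit <- .minimize_multistart(obj, start, lower, upper)
  par <- fit$par
  V1 <- par[1]; V2 <- par[2]; p12 <- par[3]
  sysR <- par[6]^2 * V1 + par[7]^2 * V2 + 2 * par[6] * par[7] * p12
  admissible <- fit$converged &&
    V1 > 1e-3 && V2 > 1e-3 && V1 < 0.999 && V2 < 0.999 &&
    abs(p12) < sqrt(V1 * V2) - 1e-6 &&
    sysR >= 0 && sysR < 1 &&
    abs(par[8]) < 0.99 && abs(par[9]) < 0.99
  list(par = as.list(setNames(par, c("V1", "V2", "psi12", "lambda_aux_t1",
                                     "lambda_aux_t2", "lambda_trs_t1",
                                     "lambda_trs_t2", "rescor_sim",
                                     "rescor_aux"))),
       implied = .implied_ab(par), discrepancy = fit$value,
       converged = admissible,
       reason = if (admissible) "" else fit$reason %||% "inadmissible solution",
       r2_trs = sysR, r2_sim_t1 = V1,
       n_stats = 10L, n_par = 9L,
       mean_latent_change = NA_real_,
       sd_latent_change = sqrt(max(0, V1 + V2 - 2 * p12)),
       mic_theta = NA_real_, psb_hat = NA_real_)
}

.fit_c <- function(corstr, spec, sim_th) {
  r <- corstr$R[.LCFA_PAIRS]
  w_r <- corstr$avar[.LCFA_PAIRS]
  t1 <- sim_th$t1; t2 <- sim_th$t2
  m <- sim_th$n_boundaries
  tau_r_hat <- corstr$thresholds$trs
  tau_r_avar <- corstr$threshold_avar$trs
  stats <- c(t1$tau, t2$tau, tau_r_hat, r)
  wts <- c(t1$avar, t2$avar, tau_r_avar, w_r)

  obj <- function(par) {
    imp <- .implied_c(par, m)
    if (is.null(imp)) return(1e12)
    sig <- c(imp$tau1[t1$keep], imp$tau2[t2$keep], imp$tau_r, imp$corr)
    sum((stats - sig)^2 / wts)
  }

  # data-informed starting values
  ls0 <- 1.2; V20 <- 1.2; phi20 <- 1; lr10 <- -0.2; lr20 <- 0.7
  p120 <- clamp(r[1], -0.9, 0.9) * sqrt(V20)
  tau0 <- rep(NA_real_, m)
  tau0[t1$keep] <- t1$tau * sqrt(ls0^2 + 1)
  v20 <- ls0^2 * V20 + phi20
  common <- intersect(t1$keep, t2$keep)
  M20 <- if (length(common)) {
    mean(tau0[common] - t2$tau[match(common, t2$keep)] * sqrt(v20)) / ls0
  } else 0
  miss <- which(is.na(tau0))
  if (length(miss)) { # boundaries unseen at T1: back out from T2
    tau0[miss] <- ifelse(miss %in% t2$keep,
                         t2$tau[match(miss, t2$keep)] * sqrt(v20) + ls0 * M20,
                         seq(-2, 2, length.out = m)[miss] * sqrt(ls0^2 + 1))
  }
  vR0 <- lr10^2 + lr20^2 * V20 + 2 * lr10 * lr20 * p120 + 1
  taur0 <- tau_r_hat * sqrt(vR0) + lr20 * M20
  start <- c(ls0, 0.6, 0.6, lr10, lr20, p120, V20, M20, phi20, 0.1, 0.2,
             tau0, taur0)
  lower <- c(0.05, -0.999, -3, -6, -6, -10, 1e-3, -10, 1e-3, -0.995, -0.995,
             rep(-12, m), -12)
  upper <- c(10, 0.999, 3, 6, 6, 10, 50, 10, 50, 0.995, 0.995,
             rep(12, m), 12)
  fit <- .minimize_multistart(obj, start, lower, upper)
  par <- fit$par
  imp <- .implied_c(par, m)
  tau_s <- par[12:(11 + m)]
  lx2 <- par[3]; V2 <- par[7]; p12 <- par[6]
  admissible <- fit$converged && !is.null(imp) &&
    V2 > 2e-3 && par[9] > 2e-3 &&
    abs(p12) < sqrt(V2) - 1e-6 &&
    abs(par[2]) < 0.995 && lx2^2 * V2 < 1 &&
    abs(par[10]) < 0.99 && abs(par[11]) < 0.99 &&
    all(diff(tau_s) > 0) && abs(par[5]) > 1e-4
  list(par = c(as.list(setNames(par[1:11],
                c("lambda_sim", "lambda_aux_t1", "lambda_aux_t2",
                  "lambda_trs_t1", "lambda_trs_t2", "psi12", "V2", "M2",
                  "resvar_sim_t2", "rescor_sim", "rescor_aux"))),
               list(tau_sim = tau_s, tau_trs = par[12 + m])),
       implied = if (is.null(imp)) NULL else imp$corr,
       discrepancy = fit$value,
       converged = admissible,
       reason = if (admissible) "" else fit$reason %||% "inadmissible solution",
       r2_trs = if (is.null(imp)) NA_real_ else (imp$vR - 1) / imp$vR,
       r2_sim_t1 = par[1]^2 / (par[1]^2 + 1),
       n_stats = length(stats), n_par = 12L + m,
       mean_latent_change = par[8],
       sd_latent_change = sqrt(max(0, 1 + V2 - 2 * p12)),
       mic_theta = par[12 + m] / par[5],
       psb_hat = 1 + par[4] / par[5])
}

# nlminb with a few deterministic jittered restarts; returns the best point.
# Leaves the caller's RNG state untouched.
.minimize_multistart <- function(obj, start, lower, upper, tries = 4L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best <- NULL
  for (k in seq_len(tries)) {
    s <- start
    if (k > 1L) {
      set.seed(1000 + k)
      s <- clamp(start * runif(length(start), 0.7, 1.3) +
                   runif(length(start), -0.1, 0.1), lower, upper)
    }
    res <- tryCatch(
      nlminb(s, obj, lower = lower, upper = upper,
             control = list(iter.max = 1000, eval.max = 4000,
                            rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (best$objective < 1e11 && best$convergence == 0) break
  }
  if (is.null(best)) {
    return(list(par = start, value = Inf, converged = FALSE,
                reason = "optimizer failure"))
  }
  list(par = best$par, value = best$objective,
       converged = best$objective < 1e11,
       reason = if (best$objective >= 1e11) "no admissible solution found"
                else "")
}

#' Fit an auxiliary-enriched LCFA model
#'
#' Two-stage estimation: mixed correlations/thresholds with asymptotic
#' variances, then a diagonally weighted least-squares fit of the model's
#' implied moments. Estimation problems (degenerate indicators,
#' non-convergence, inadmissible solutions) are reported through the
#' \code{converged} flag and \code{reason} field, never as an exception.
#'
#' @param data data.frame with columns \code{sim_t1}, \code{sim_t2},
#'   \code{aux_t1}, \code{aux_t2}, \code{trs} (see
#'   \code{\link{panel_indicators}} for assembling them from a simulated
#'   panel).
#' @param spec an \code{\link{lcfa_spec}}.
#' @return object of class \code{lcfa_fit}.
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "lcfa_spec"))
  missing_cols <- setdiff(.LCFA_VARS, names(data))
  if (length(missing_cols)) {
    stop("data lacks indicator column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, .LCFA_VARS]
  data <- data[complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  if (n < 100) stop("fit_model needs at least 100 complete rows", call. = FALSE)
  if (n < 200) warning("fewer than 200 rows; estimates will be unstable",
                       call. = FALSE)

  failed <- function(reason) {
    structure(list(model_id = spec$model_id, spec = spec, n_obs = n,
                   converged = FALSE, reason = reason, par = NULL,
                   r2_trs = NA_real_, r2_sim_t1 = NA_real_,
                   mic_theta = NA_real_, psb_hat = NA_real_,
                   mean_latent_change = NA_real_,
                   sd_latent_change = NA_real_,
                   discrepancy = NA_real_, df = NA_integer_,
                   fit_indices = c(cfi = NA_real_, tli = NA_real_,
                                   rmsea = NA_real_, srmr = NA_real_)),
              class = "lcfa_fit")
  }

  corstr <- tryCatch(estimate_correlations(data, spec$treatments),
                     error = function(e) conditionMessage(e))
  if (is.character(corstr)) return(failed(corstr))

  core <- tryCatch({
    if (spec$model_id == "C") {
      sim_th <- .sim_threshold_stats(data$sim_t1, data$sim_t2)
      .fit_c(corstr, spec, sim_th)
    } else {
      .fit_ab(corstr, spec)
    }
  }, error = function(e) conditionMessage(e))
  if (is.character(core)) return(failed(core))

  df <- core$n_stats - core$n_par
  resid <- corstr$R[.LCFA_PAIRS] - (core$implied %||% rep(NA_real_, 10))
  base_T <- sum(corstr$R[.LCFA_PAIRS]^2 / corstr$avar[.LCFA_PAIRS])
  indices <- .fit_index_set(core$discrepancy, df, base_T, 10L, n, resid)

  structure(list(model_id = spec$model_id, spec = spec, n_obs = n,
                 converged = core$converged, reason = core$reason,
                 par = core$par,
                 r2_trs = core$r2_trs, r2_sim_t1 = core$r2_sim_t1,
                 mic_theta = core$mic_theta, psb_hat = core$psb_hat,
                 mean_latent_change = core$mean_latent_change,
                 sd_latent_change = core$sd_latent_change,
                 discrepancy = core$discrepancy, df = as.integer(df),
                 residuals = resid, corstr = corstr,
                 fit_indices = indices),
            class = "lcfa_fit")
}

.fit_index_set <- function(T_m, df_m, T_b, df_b, n, resid) {
  num <- max(T_m - df_m, 0)
  den <- max(T_b - df_b, T_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (T_b > df_b) {
    (T_b / df_b - T_m / df_m) / (T_b / df_b - 1)
  } else NA_real_
  rmsea <- sqrt(max(0, (T_m - df_m) / (df_m * (n - 1))))
  srmr <- sqrt(mean(resid^2))
  c(cfi = cfi, tli = min(tli, 1), rmsea = rmsea, srmr = srmr)
}

#' @export
print.lcfa_fit <- function(x, ...) {
  cat(sprintf("LCFA model %s fit (n = %d): %s\n", x$model_id, x$n_obs,
              if (x$converged) "converged" else
                paste("NOT converged -", x$reason)))
  if (x$converged) {
    fi <- x$fit_indices
    cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.3f  SRMR %.3f (T = %.2f, df = %d)\n",
                fi["cfi"], fi["tli"], fi["rmsea"], fi["srmr"],
                x$discrepancy, x$df))
    cat(sprintf("  R2(TRs) = %.3f   R2(SIM T1) = %.3f\n",
                x$r2_trs, x$r2_sim_t1))
    if (x$model_id == "C") {
      cat(sprintf("  latent MIC = %.3f   mean latent change = %.3f (SD %.3f)   PSB = %.3f\n",
                  x$mic_theta, x$mean_latent_change, x$sd_latent_change,
                  x$psb_hat))
    }
  }
  invisible(x)
}

#' Fit indices of a converged LCFA fit
#'
#' Standard (unscaled) CFI, TLI, RMSEA and SRMR computed from the DWLS
#' discrepancy of the fitted model against the independence baseline
#' (correlations zero, thresholds free); SRMR is the root mean square of the
#' residual correlations.
#'
#' @param fit an \code{lcfa_fit}.
#' @return named numeric vector \code{cfi}, \code{tli}, \code{rmsea},
#'   \code{srmr}.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "lcfa_fit"))
  if (!fit$converged) stop("fit indices require a converged fit", call. = FALSE)
  fit$fit_indices
}

#' Reliability of the transition ratings from an LCFA fit
#'
#' The model R-squared of the TRs item: the share of the latent-response
#' variance of the anchor explained by the two trait factors jointly.
#'
#' @param fit a converged \code{lcfa_fit} (any model).
#' @return reliability in \[0, 1\].
#' @export
trs_reliability <- function(fit) {
  stopifnot(inherits(fit, "lcfa_fit"))
  if (!fit$converged) stop("TRs reliability requires a converged fit",
                           call. = FALSE)
  fit$r2_trs
}

#' Latent MIC from a model C fit
#'
#' The threshold of the transition-rating item divided by its loading on the
#' follow-up factor, in latent-change units.
#'
#' @param fit a converged model C \code{lcfa_fit}.
#' @return latent MIC.
#' @export
latent_mic <- function(fit) {
  stopifnot(inherits(fit, "lcfa_fit"))
  if (fit$model_id != "C") stop("the latent MIC is defined by model C",
                                call. = FALSE)
  if (!fit$converged) stop("latent MIC requires a converged fit",
                           call. = FALSE)
  if (abs(fit$par$lambda_trs_t2) < 1e-8) {
    stop("latent MIC undefined: TRs loading on the follow-up factor is zero",
         call. = FALSE)
  }
  fit$mic_theta
}

#' Baseline reliability of the SIM from a model C fit
#'
#' The model R-squared of sim_t1 on the baseline factor.
#'
#' @param fit a converged model C \code{lcfa_fit}.
#' @return reliability in \[0, 1\].
#' @export
sim_reliability_t1 <- function(fit) {
  stopifnot(inherits(fit, "lcfa_fit"))
  if (fit$model_id != "C") {
    stop("sim_reliability_t1 is defined for model C", call. = FALSE)
  }
  if (!fit$converged) stop("requires a converged fit", call. = FALSE)
  fit$r2_sim_t1
}

#' Assemble the five LCFA indicator columns from a dataset
#'
#' @param data observed-data table (e.g. \code{sim_panel$observed} or a
#'   mapped user dataset) with SIM scores, AUX items and/or sums, and a
#'   binary \code{trs_improved} column.
#' @param spec an \code{\link{lcfa_spec}}; decides whether \code{aux_t1/t2}
#'   are a single item or the sum score.
#' @param aux_item which AUX item to use for model A (default the first).
#' @return data.frame with columns \code{sim_t1}, \code{sim_t2},
#'   \code{aux_t1}, \code{aux_t2}, \code{trs}.
#' @export
panel_indicators <- function(data, spec, aux_item = 1L) {
  stopifnot(inherits(spec, "lcfa_spec"))
  if (spec$aux_mode == "single_item") {
    a1 <- paste0("aux", aux_item, "_t1")
    a2 <- paste0("aux", aux_item, "_t2")
    if (!all(c(a1, a2) %in% names(data))) {
      stop(sprintf("AUX item columns '%s'/'%s' not found", a1, a2),
           call. = FALSE)
    }
    aux1 <- data[[a1]]; aux2 <- data[[a2]]
  } else {
    if (!all(c("aux_sum_t1", "aux_sum_t2") %in% names(data))) {
      stop("AUX sum score columns 'aux_sum_t1'/'aux_sum_t2' not found",
           call. = FALSE)
    }
    aux1 <- data$aux_sum_t1; aux2 <- data$aux_sum_t2
  }
  trs <- if ("trs_improved" %in% names(data)) data$trs_improved else data$trs
  data.frame(sim_t1 = data$sim_t1, sim_t2 = data$sim_t2,
             aux_t1 = aux1, aux_t2 = aux2, trs = trs)
}
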