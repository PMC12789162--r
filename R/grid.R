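# Simulation design grid: one row per combination of the generative
# parameters, mirroring the factorial design of the Monte-Carlo study.

#' Default factor levels of the simulation design
#'
#' The full factorial crossing of these levels defines the 15,552-condition
#' design: mean latent trait at baseline (3) x SD of latent change (2) x
#' baseline-change correlation (2) x SIM reliability (2) x transition-rating
#' reliability (2) x present-state bias (3) x proportion improved (3) x
#' relative strength of the AUX-specific factor xi (3) x relative strength of
#' the SIM-specific trait component theta^B (3) x cross-wave correlation of xi
#' (2) x cross-wave correlation of eta (2).
#'
#' @return named list of numeric level vectors, in design order.
#' @export
default_grid_levels <- function() {
  list(
    mean_theta_t1      = c(-1, 0, 1),
    sd_delta_theta     = c(0.85, 1.15),
    cor_theta_t1_delta = c(-0.50, 0.00),
    rel_sim_t1         = c(0.50, 0.80),
    rel_trs            = c(0.40, 0.70),
    psb                = c(0, 0.4, 0.8),
    prop_improved      = c(0.2, 0.5, 0.8),
    strength_xi        = c(0, 0.2, 0.5),
    strength_theta_b   = c(0, 0.5, 1),
    cor_xi             = c(0.50, 0.90),
    cor_eta            = c(0.50, 0.90)
  )
}

.grid_domains <- list(
  mean_theta_t1      = c(-Inf, Inf),
  sd_delta_theta     = c(1e-8, Inf),
  cor_theta_t1_delta = c(-1, 1),
  rel_sim_t1         = c(1e-8, 1),
  rel_trs            = c(1e-8, 1),
  psb                = c(0, 1),
  prop_improved      = c(1e-8, 1 - 1e-8),
  strength_xi        = c(0, Inf),
  strength_theta_b   = c(0, Inf),
  cor_xi             = c(-1, 1),
  cor_eta            = c(-1, 1)
)

#' Construct a single simulation configuration
#'
#' @param mean_theta_t1 mean of the latent trait theta at baseline.
#' @param sd_delta_theta SD of the latent change delta-theta.
#' @param cor_theta_t1_delta correlation between theta at T1 and delta-theta.
#' @param rel_sim_t1 reliability of the SIM at baseline.
#' @param rel_trs reliability of the (dichotomous) transition ratings.
#' @param psb present-state bias: proportion of theta_T2 - mean(theta_T1)
#'   entering the weighted latent change that drives the anchor.
#' @param prop_improved proportion of subjects whose true latent change
#'   exceeds their individual MIC.
#' @param strength_xi ratio of the mean AUX slope on xi to the mean slope on
#'   theta^A.
#' @param strength_theta_b ratio of SD(theta^B) to SD(theta^A).
#' @param cor_xi,cor_eta cross-wave correlations of the wave-specific
#'   constructs xi (AUX-only) and eta (SIM-only).
#' @param n_subjects sample size of the simulated panel.
#' @param seed master seed of the configuration.
#' @param true_mic mean of the individual MIC distribution (latent change
#'   units; the true value the estimators target).
#' @param sd_mic SD of the individual MICs around \code{true_mic}.
#' @return object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(mean_theta_t1 = 0, sd_delta_theta = 1.15,
                       cor_theta_t1_delta = 0, rel_sim_t1 = 0.8,
                       rel_trs = 0.7, psb = 0, prop_improved = 0.5,
                       strength_xi = 0.2, strength_theta_b = 0.5,
                       cor_xi = 0.9, cor_eta = 0.9,
                       n_subjects = 2000L, seed = 1L,
                       true_mic = 0.8, sd_mic = 0.2) {
  cfg <- list(
    mean_theta_t1 = mean_theta_t1, sd_delta_theta = sd_delta_theta,
    cor_theta_t1_delta = cor_theta_t1_delta, rel_sim_t1 = rel_sim_t1,
    rel_trs = rel_trs, psb = psb, prop_improved = prop_improved,
    strength_xi = strength_xi, strength_theta_b = strength_theta_b,
    cor_xi = cor_xi, cor_eta = cor_eta,
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    true_mic = true_mic, sd_mic = sd_mic
  )
  for (nm in names(.grid_domains)) {
    dom <- .grid_domains[[nm]]
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < dom[1] || v > dom[2]) {
      stop(sprintf("sim_config: '%s' = %s outside its domain [%g, %g]",
                   nm, format(v), dom[1], dom[2]), call. = FALSE)
    }
  }
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (cfg$sd_mic < 0) stop("sd_mic must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Build the full factorial parameter grid
#'
#' Returns the Cartesian product of the supplied levels, one configuration per
#' row, ordered lexicographically with the first parameter varying slowest
#' (design order as in \code{\link{default_grid_levels}}). Per-condition seeds
#' are derived reproducibly from \code{seed}.
#'
#' @param levels named list of level vectors; defaults to the full design.
#' @param n_subjects sample size attached to every condition.
#' @param seed master seed from which per-condition seeds are derived.
#' @param true_mic,sd_mic individual-MIC distribution shared by all
#'   conditions.
#' @return a \code{data.frame} of class \code{mic_grid} with one row per
#'   condition, including \code{condition}, \code{n_subjects} and \code{seed}
#'   columns.
#' @export
build_parameter_grid <- function(levels = default_grid_levels(),
                                 n_subjects = 2000L, seed = 1L,
                                 true_mic = 0.8, sd_mic = 0.2) {
  full <- default_grid_levels()
  if (!all(names(levels) %in% names(full))) {
    stop("unknown parameter(s): ",
         paste(setdiff(names(levels), names(full)), collapse = ", "),
         call. = FALSE)
  }
  lv <- full
  lv[names(levels)] <- levels
  for (nm in names(lv)) {
    if (length(lv[[nm]]) < 1L) {
      stop(sprintf("parameter '%s' needs at least one level", nm),
           call. = FALSE)
    }
    dom <- .grid_domains[[nm]]
    bad <- lv[[nm]] < dom[1] | lv[[nm]] > dom[2]
    if (any(bad)) {
      stop(sprintf("parameter '%s' has level(s) outside [%g, %g]: %s",
                   nm, dom[1], dom[2],
                   paste(lv[[nm]][bad], collapse = ", ")), call. = FALSE)
    }
  }
  # expand.grid varies the first factor fastest; reverse to get the first
  # parameter varying slowest, then restore column order.
  g <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  g$condition <- seq_len(nrow(g))
  g$n_subjects <- as.integer(n_subjects)
  g$seed <- derive_seeds(seed, nrow(g))
  g$true_mic <- true_mic
  g$sd_mic <- sd_mic
  class(g) <- c("mic_grid", "data.frame")
  g
}

#' Extract one grid row as a simulation configuration
#'
#' @param grid a \code{mic_grid}.
#' @param i row index.
#' @return a \code{\link{sim_config}}.
#' @export
grid_config <- function(grid, i) {
  stopifnot(i >= 1, i <= nrow(grid))
  row <- as.list(grid[i, setdiff(names(grid), "condition")])
  do.call(sim_config, row)
}

#' Balanced stratified subset of a design grid
#'
#' Draws a seeded subset with equal counts from every stratum defined by the
#' joint levels of \code{stratify_by} (by default present-state bias and
#' proportion improved, the two parameters that drive the APM bias pattern).
#' Within strata, conditions are sampled without replacement.
#'
#' @param grid a \code{mic_grid}.
#' @param fraction target fraction of the grid to keep (0, 1].
#' @param seed sampling seed.
#' @param stratify_by character vector of grid columns defining strata.
#' @return a \code{mic_grid} with approximately \code{fraction * nrow(grid)}
#'   rows, balanced over the strata.
#' @export
subset_grid <- function(grid, fraction, seed = 1L,
                        stratify_by = c("psb", "prop_improved")) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(grid)
  strata <- interaction(grid[, stratify_by, drop = FALSE], drop = TRUE)
  per <- max(1L, as.integer(round(fraction * nrow(grid) / nlevels(strata))))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(grid)), strata), function(idx) {
    sample(idx, min(per, length(idx)))
  }), use.names = FALSE)
  out <- grid[sort(keep), , drop = FALSE]
  class(out) <- c("mic_grid", "data.frame")
  out
}
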