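# Thresholds and polychoric / polyserial / Pearson correlations, with the
# asymptotic variances that feed the diagonal DWLS weight matrix.
#
# Ordered indicators are modeled as discretized standard normal latent
# responses: thresholds come from the inverse-normal of cumulative category
# proportions; ordinal-ordinal correlations by two-step maximum likelihood on
# the contingency table (thresholds fixed at their univariate estimates);
# ordinal-continuous by two-step ML on the conditional likelihood. Asymptotic
# variances are 1/observed information of the profiled correlation, which is
# what a diagonally weighted fit needs.

.COR_CLAMP <- 1 - 1e-6

#' Thresholds of an ordered indicator
#'
#' Inverse-normal of the cumulative category proportions, skipping the last
#' category. Categories are the sorted unique observed values.
#'
#' @param x integer-valued vector.
#' @return list with \code{thresholds}, their asymptotic variances
#'   (\code{avar}, delta method on the multinomial proportions),
#'   \code{categories} and the category \code{counts}.
#' @export
poly_thresholds <- function(x) {
  x <- x[!is.na(x)]
  categories <- sort(unique(x))
  if (length(categories) < 2L) {
    stop("ordered indicator has fewer than 2 observed categories",
         call. = FALSE)
  }
  counts <- as.numeric(table(factor(x, levels = categories)))
  n <- length(x)
  cum <- cumsum(counts)[-length(counts)] / n
  tau <- qnorm(cum)
  list(thresholds = tau,
       avar = cum * (1 - cum) / (n * dnorm(tau)^2),
       categories = categories, counts = counts)
}

# Log-likelihood of a two-way table under the bivariate-normal discretization
# with fixed thresholds. tab is a K1 x K2 count matrix.
.polychor_loglik <- function(rho, tab, tau1, tau2) {
  b1 <- c(-Inf, tau1, Inf)
  b2 <- c(-Inf, tau2, Inf)
  k1 <- length(b1); k2 <- length(b2)
  cdf <- matrix(pbvnorm(rep(b1, times = k2), rep(b2, each = k1), rho), k1, k2)
  p <- cdf[-1, -1, drop = FALSE] - cdf[-k1, -1, drop = FALSE] -
    cdf[-1, -k2, drop = FALSE] + cdf[-k1, -k2, drop = FALSE]
  p <- pmax(p, 1e-300)
  sum(tab * log(p))
}

#' Polychoric correlation of two ordered indicators
#'
#' Two-step maximum likelihood: thresholds fixed at the univariate estimates,
#' then the latent correlation maximizes the contingency-table likelihood.
#' An estimate at the admissibility boundary is clamped to +/-(1 - 1e-6) with
#' a warning (perfect association).
#'
#' @param x,y integer-valued vectors of equal length.
#' @return list with \code{rho}, \code{avar} (inverse observed information of
#'   the profiled correlation), and both threshold sets.
#' @export
polychoric_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tx <- poly_thresholds(x)
  ty <- poly_thresholds(y)
  tab <- table(factor(x, levels = tx$categories),
               factor(y, levels = ty$categories))
  opt <- optimize(function(r) -.polychor_loglik(r, tab, tx$thresholds,
                                                ty$thresholds),
                  interval = c(-.COR_CLAMP, .COR_CLAMP), tol = 1e-9)
  rho <- opt$minimum
  clamped <- abs(rho) > .COR_CLAMP - 1e-4
  if (clamped) {
    warning("polychoric correlation at the boundary; clamped (perfect association?)",
            call. = FALSE)
    rho <- sign(rho) * .COR_CLAMP
  }
  avar <- Inf
  if (!clamped) {
    h <- 1e-4
    info <- -(.polychor_loglik(rho + h, tab, tx$thresholds, ty$thresholds) -
                2 * .polychor_loglik(rho, tab, tx$thresholds, ty$thresholds) +
                .polychor_loglik(rho - h, tab, tx$thresholds, ty$thresholds)) / h^2
    if (info > 0) avar <- 1 / info
  }
  list(rho = rho, avar = avar,
       tau_x = tx$thresholds, tau_y = ty$thresholds)
}

# Conditional log-likelihood of the ordinal y given standardized continuous z.
.polyserial_loglik <- function(rho, z, ycat, tau) {
  b <- c(-Inf, tau, Inf)
  s <- sqrt(1 - rho^2)
  upper <- pnorm((b[ycat + 1L] - rho * z) / s)
  lower <- pnorm((b[ycat] - rho * z) / s)
  sum(log(pmax(upper - lower, 1e-300)))
}

#' Polyserial correlation of a continuous and an ordered indicator
#'
#' Two-step ML: the continuous variable is standardized by its sample
#' moments, ordinal thresholds are fixed at the univariate estimates, and the
#' latent correlation maximizes the conditional likelihood of the ordinal
#' responses given the continuous scores.
#'
#' @param x continuous vector.
#' @param y integer-valued ordinal vector.
#' @return list with \code{rho}, \code{avar}, and the ordinal thresholds
#'   \code{tau_y}.
#' @export
polyserial_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0) stop("continuous indicator has zero variance", call. = FALSE)
  z <- (x - mean(x)) / sd(x)
  ty <- poly_thresholds(y)
  ycat <- match(y, ty$categories)
  opt <- optimize(function(r) -.polyserial_loglik(r, z, ycat, ty$thresholds),
                  interval = c(-.COR_CLAMP, .COR_CLAMP), tol = 1e-9)
  rho <- opt$minimum
  clamped <- abs(rho) > .COR_CLAMP - 1e-4
  if (clamped) {
    warning("polyserial correlation at the boundary; clamped (perfect association?)",
            call. = FALSE)
    rho <- sign(rho) * .COR_CLAMP
  }
  avar <- Inf
  if (!clamped) {
    h <- 1e-4
    info <- -(.polyserial_loglik(rho + h, z, ycat, ty$thresholds) -
                2 * .polyserial_loglik(rho, z, ycat, ty$thresholds) +
                .polyserial_loglik(rho - h, z, ycat, ty$thresholds)) / h^2
    if (info > 0) avar <- 1 / info
  }
  list(rho = rho, avar = avar, tau_y = ty$thresholds)
}

#' Correlation structure of a mixed ordinal/continuous indicator set
#'
#' Builds the input of the DWLS stage: pairwise correlations estimated by the
#' method the pair calls for (polychoric, polyserial or Pearson), thresholds
#' for every ordered indicator, and asymptotic variances of all estimates.
#'
#' @param data data.frame of indicator columns.
#' @param treatments named character vector, one of \code{"ordered"} /
#'   \code{"continuous"} per column of \code{data}.
#' @return object of class \code{mic_corstr}: list with the correlation
#'   matrix \code{R}, matching \code{avar} matrix, per-indicator
#'   \code{thresholds} and \code{threshold_avar}, \code{treatments}, and
#'   \code{n}.
#' @export
estimate_correlations <- function(data, treatments) {
  stopifnot(is.data.frame(data), all(names(data) %in% names(treatments)) ||
              all(names(treatments) %in% names(data)))
  vars <- names(data)
  treatments <- treatments[vars]
  if (any(is.na(treatments))) {
    stop("every column needs a treatment ('ordered' or 'continuous')",
         call. = FALSE)
  }
  p <- length(vars)
  n <- nrow(data)
  thresholds <- threshold_avar <- setNames(vector("list", p), vars)
  for (v in vars) {
    if (treatments[[v]] == "ordered") {
      th <- tryCatch(poly_thresholds(data[[v]]), error = function(e) {
        stop(sprintf("indicator '%s': %s", v, conditionMessage(e)),
             call. = FALSE)
      })
      thresholds[[v]] <- th$thresholds
      threshold_avar[[v]] <- th$avar
    } else if (sd(data[[v]], na.rm = TRUE) == 0) {
      stop(sprintf("continuous indicator '%s' has zero variance", v),
           call. = FALSE)
    }
  }
  R <- diag(p)
  avar <- matrix(0, p, p)
  dimnames(R) <- dimnames(avar) <- list(vars, vars)
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    ti <- treatments[[i]]; tj <- treatments[[j]]
    est <- if (ti == "ordered" && tj == "ordered") {
      polychoric_cor(data[[i]], data[[j]])
    } else if (ti == "continuous" && tj == "continuous") {
      r <- cor(data[[i]], data[[j]], use = "complete.obs")
      list(rho = r, avar = (1 - r^2)^2 / n)
    } else if (ti == "continuous") {
      polyserial_cor(data[[i]], data[[j]])
    } else {
      polyserial_cor(data[[j]], data[[i]])
    }
    R[i, j] <- R[j, i] <- est$rho
    avar[i, j] <- avar[j, i] <- est$avar
  }
  structure(list(R = R, avar = avar, thresholds = thresholds,
                 threshold_avar = threshold_avar,
                 treatments = treatments, n = n),
            class = "mic_corstr")
}

#' @export
print.mic_corstr <- function(x, ...) {
  cat(sprintf("Mixed correlation structure (%d observations)\n", x$n))
  print(round(x$R, 3))
  ord <- names(x$thresholds)[!vapply(x$thresholds, is.null, logical(1))]
  if (length(ord)) cat("ordered indicators:", paste(ord, collapse = ", "), "\n")
  invisible(x)
}
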