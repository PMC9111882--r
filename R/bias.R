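#' Egger's regression-based test for funnel-plot asymmetry
#'
#' Tests for small-study bias by regressing the change score on its
#' standard error. The default variant (\code{"se"}) is a mixed-effects
#' meta-regression \eqn{d_i = \beta_0 + \beta_1 se_i + u_i + e_i} with
#' \eqn{\tau^2} re-estimated by REML under the bias model; the statistic
#' is \eqn{t = \hat\beta_1 / SE(\hat\beta_1)} on Student t with k - 2
#' degrees of freedom, and asymmetry is flagged at p < 0.05. A positive
#' slope means small (large-se) studies report more positive change
#' scores than large studies.
#'
#' The classical variant (\code{"precision"}) is the original unweighted
#' regression of the standardised effect \eqn{d_i/se_i} on precision
#' \eqn{1/se_i}, testing the intercept; it is retained for cross-checks.
#'
#' @param fit a \code{"meta_change"} fit carrying its data (from
#'   \code{\link{pool_changes}}), or an effects data frame with columns
#'   \code{d} and \code{se}.
#' @param variant \code{"se"} (default) or \code{"precision"}.
#' @param alpha flag threshold, default 0.05.
#' @return Object of class \code{"egger_test"}: \code{t}, \code{df},
#'   \code{p}, \code{slope}, \code{slope_se}, \code{intercept},
#'   \code{intercept_se}, \code{variant}, \code{asymmetric}.
#' @export
egger_test <- function(fit, variant = c("se", "precision"), alpha = 0.05) {
  variant <- match.arg(variant)
  ef <- if (is.data.frame(fit)) fit else fit$data
  if (is.null(ef)) ef <- data.frame(d = fit$yi, se = fit$sei)
  stopifnot(all(c("d", "se") %in% names(ef)))
  ef <- ef[ef$se > 0, , drop = FALSE]
  k <- nrow(ef)
  if (k < 3) stop("Egger's test requires at least 3 estimates")
  if (stats::sd(ef$se) == 0)
    stop("degenerate predictor: all standard errors are equal")

  if (variant == "se") {
    mfit <- meta_change(d ~ se, data = ef, se = "se", method = "REML")
    slope <- mfit$beta[2]; slope_se <- mfit$se_beta[2]
    intercept <- mfit$beta[1]; intercept_se <- mfit$se_beta[1]
    tval <- slope / slope_se
  } else {
    lfit <- stats::lm(I(d / se) ~ I(1 / se), data = ef)
    sm <- summary(lfit)$coefficients
    intercept <- sm[1, 1]; intercept_se <- sm[1, 2]
    slope <- sm[2, 1]; slope_se <- sm[2, 2]
    tval <- intercept / intercept_se  # classical test is on the intercept
  }
  df <- k - 2
  p <- 2 * stats::pt(-abs(tval), df = df)
  structure(list(t = unname(tval), df = df, p = unname(p),
                 slope = unname(slope), slope_se = unname(slope_se),
                 intercept = unname(intercept),
                 intercept_se = unname(intercept_se),
                 k = k, variant = variant, alpha = alpha,
                 asymmetric = unname(p < alpha)),
            class = "egger_test")
}

#' @export
print.egger_test <- function(x, digits = 4, ...) {
  cat("Egger's regression-based test (", x$variant, " variant), k = ",
      x$k, "\n", sep = "")
  cat("t = ", format(x$t, digits = digits), " (df = ", x$df, "), p = ",
      format.pval(x$p, digits = digits), "\n", sep = "")
  cat(if (x$asymmetric) "Funnel asymmetry flagged"
      else "No indication of funnel asymmetry",
      " at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Funnel-plot data table
#'
#' Returns the (change score, standard error) points of a fitted
#' meta-analysis together with the pseudo-confidence contour
#' \eqn{\hat\mu \pm 1.959964\, se} over the observed se range, suitable
#' for plotting (se conventionally drawn on an inverted y axis). At
#' se = 0 the contour collapses to the pooled estimate.
#'
#' @param fit an intercept-only \code{"meta_change"} fit.
#' @param n_contour number of contour grid points (default 50).
#' @param level contour level; defaults to the fit's confidence level.
#' @return List with \code{points} (estimate_id if available, d, se),
#'   \code{contour} (se, lo, hi) spanning se = 0 to max(se), and
#'   \code{centre} (the pooled estimate).
#' @export
funnel_data <- function(fit, n_contour = 50, level = NULL) {
  stopifnot(inherits(fit, "meta_change"))
  if (fit$p != 1) stop("funnel data is defined for intercept-only fits")
  if (is.null(level)) level <- fit$level
  crit <- stats::qnorm(1 - (1 - level) / 2)
  ids <- if (!is.null(fit$data$estimate_id)) fit$data$estimate_id
         else paste0("estimate_", seq_len(fit$k))
  se_grid <- seq(0, max(fit$sei), length.out = n_contour)
  list(points = data.frame(estimate_id = ids, d = fit$yi, se = fit$sei,
                           stringsAsFactors = FALSE),
       contour = data.frame(se = se_grid,
                            lo = fit$beta - crit * se_grid,
                            hi = fit$beta + crit * se_grid),
       centre = unname(fit$beta))
}
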