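#' @export
print.meta_change <- function(x, digits = 4, ...) {
  cat("Random-effects meta-", if (x$p > 1) "regression" else "analysis",
      " of change scores (", x$method, ")\n", sep = "")
  cat("k = ", x$k, " estimates; tau^2 = ", format(x$tau2, digits = digits),
      "; I^2 = ", format(x$I2, digits = digits), "%\n", sep = "")
  if (x$p == 1) {
    cat("Pooled change score: ", format(x$beta, digits = digits),
        " [", format(x$ci.lb, digits = digits), ", ",
        format(x$ci.ub, digits = digits), "], p = ",
        format.pval(x$pval, digits = digits), "\n", sep = "")
  } else {
    cat("Coefficients:\n")
    print(round(stats::coef(x), digits))
  }
  invisible(x)
}

#' Summarise a fitted change-score meta-analysis
#'
#' @param object a \code{"meta_change"} fit.
#' @param ... unused.
#' @return The fit augmented with a coefficient table, printed with
#'   heterogeneity and moderator tests.
#' @export
summary.meta_change <- function(object, ...) {
  ct <- cbind(estimate = object$beta, se = object$se_beta,
              ci.lb = object$ci.lb, ci.ub = object$ci.ub,
              zval = object$zval, pval = object$pval)
  rownames(ct) <- colnames(object$X)
  object$coef_table <- ct
  class(object) <- c("summary.meta_change", class(object))
  object
}

#' @export
print.summary.meta_change <- function(x, digits = 4, ...) {
  cat("Random-effects model (", x$method, "), k = ", x$k, "\n\n", sep = "")
  cat("tau^2 = ", format(x$tau2, digits = digits),
      ";  I^2 = ", format(x$I2, digits = digits),
      "% (tau^2-based), ", format(x$I2_Q, digits = digits),
      "% (Q-based)\n", sep = "")
  cat("Cochran's Q = ", format(x$QE, digits = digits), " (df = ", x$QE_df,
      "), p ", format.pval(x$QE_p, digits = digits), "\n", sep = "")
  if (!is.na(x$QM))
    cat("Moderator test QM = ", format(x$QM, digits = digits), " (df = ",
        x$QM_df, "), p ", format.pval(x$QM_p, digits = digits), "\n", sep = "")
  cat("\nCoefficients (Wald z, ", round(100 * x$level), "% CI):\n", sep = "")
  stats::printCoefmat(x$coef_table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE, cs.ind = 1:4, tst.ind = 5)
  invisible(x)
}

#' @export
coef.meta_change <- function(object, ...) {
  stats::setNames(object$beta, colnames(object$X))
}

#' @export
vcov.meta_change <- function(object, ...) {
  structure(object$vb, dimnames = list(colnames(object$X), colnames(object$X)))
}

#' @export
confint.meta_change <- function(object, parm, level = NULL, ...) {
  if (is.null(level)) level <- object$level
  crit <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - crit * object$se_beta,
              object$beta + crit * object$se_beta)
  dimnames(ci) <- list(colnames(object$X),
                       paste0(format(100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2)), " %"))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Fitted change scores and level means
#'
#' For an intercept-only fit returns the pooled estimate; for a
#' meta-regression, fitted values for \code{newdata} (e.g. one row per
#' moderator level, giving the per-level mean change score) with Wald
#' confidence intervals. With \code{interval = "prediction"} the
#' between-study variance \eqn{\tau^2} is added, giving the interval for
#' a single new study's true effect.
#'
#' @param object a \code{"meta_change"} fit.
#' @param newdata data frame of moderator values; defaults to the
#'   estimation data (fitted values).
#' @param interval \code{"confidence"} (default) or \code{"prediction"}.
#' @param level confidence level; defaults to the fit's.
#' @param ... unused.
#' @return Data frame with \code{fit}, \code{se}, \code{ci.lb}, \code{ci.ub}.
#' @export
predict.meta_change <- function(object, newdata = NULL,
                                interval = c("confidence", "prediction"),
                                level = NULL, ...) {
  interval <- match.arg(interval)
  if (is.null(level)) level <- object$level
  X0 <- if (is.null(newdata)) {
    object$X
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    stats::model.matrix(tt, mf)
  }
  fit <- drop(X0 %*% object$beta)
  se <- sqrt(rowSums((X0 %*% object$vb) * X0))
  if (interval == "prediction") se <- sqrt(se^2 + object$tau2)
  crit <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = fit, se = se, ci.lb = fit - crit * se,
             ci.ub = fit + crit * se)
}

#' @export
fitted.meta_change <- function(object, ...) drop(object$X %*% object$beta)

#' Residuals from a change-score meta-analysis
#'
#' @param object a \code{"meta_change"} fit.
#' @param type \code{"response"} (raw \eqn{d_i - \hat d_i}) or
#'   \code{"standardized"} (divided by \eqn{\sqrt{se_i^2 + \tau^2}}).
#' @param ... unused.
#' @export
residuals.meta_change <- function(object,
                                  type = c("response", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$yi - fitted(object)
  if (type == "standardized") r <- r / sqrt(object$vi + object$tau2)
  r
}

#' Simulate new effect-size vectors from a fitted model
#'
#' Draws \eqn{d_i^* \sim N(x_i'\hat\beta, \; se_i^2 + \hat\tau^2)},
#' i.e. parametric-bootstrap replicates of the observed effects table.
#'
#' @param object a \code{"meta_change"} fit.
#' @param nsim number of replicate vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Data frame with \code{nsim} columns, \code{k} rows.
#' @export
simulate.meta_change <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sd <- sqrt(object$vi + object$tau2)
  out <- as.data.frame(replicate(nsim, stats::rnorm(object$k, mu, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
weights.meta_change <- function(object, ...) {
  w <- 1 / (object$vi + object$tau2)
  100 * w / sum(w)
}

#' Forest or funnel plot of a fitted meta-analysis
#'
#' @param x a \code{"meta_change"} fit.
#' @param type \code{"forest"} (default) or \code{"funnel"}.
#' @param labels optional estimate labels for the forest plot.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.meta_change <- function(x, type = c("forest", "funnel"),
                             labels = NULL, ...) {
  type <- match.arg(type)
  crit <- stats::qnorm(1 - (1 - x$level) / 2)
  if (type == "forest") {
    lo <- x$yi - crit * x$sei
    hi <- x$yi + crit * x$sei
    k <- x$k
    ord <- seq_len(k)
    graphics::plot(x$yi, rev(ord), xlim = range(c(lo, hi, 0)),
                   ylim = c(0, k + 1), pch = 15, yaxt = "n",
                   xlab = "Change score", ylab = "", ...)
    graphics::segments(lo, rev(ord), hi, rev(ord))
    if (!is.null(labels))
      graphics::axis(2, at = rev(ord), labels = labels, las = 1, cex.axis = 0.6)
    if (x$p == 1) {
      graphics::abline(v = x$beta, lty = 2)
      graphics::abline(v = 0, col = "grey")
    }
  } else {
    fd <- funnel_data(x)
    graphics::plot(fd$points$d, fd$points$se, ylim = rev(range(fd$points$se)),
                   xlab = "Change score", ylab = "Standard error", pch = 19, ...)
    graphics::lines(fd$contour$lo, fd$contour$se, lty = 2)
    graphics::lines(fd$contour$hi, fd$contour$se, lty = 2)
    graphics::abline(v = fd$centre, lty = 3)
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the random-effects model k times, omitting one estimate each
#' time, and flags omissions that move the pooled estimate outside the
#' full-model confidence interval or change its statistical significance
#' at \code{alpha}.
#'
#' @param fit an intercept-only \code{"meta_change"} fit carrying its
#'   data (as returned by \code{\link{pool_changes}}), or an effects
#'   data frame with columns \code{d} and \code{se}.
#' @param alpha significance level for the significance-flip flag.
#' @param method,level passed to refits; default to the original fit's.
#' @return Data frame with one row per omitted estimate: pooled estimate,
#'   CI, \code{tau2}, \code{I2}, p-value, and logical flags
#'   \code{outside_ci} and \code{sig_flip}; the full-model values are
#'   attached as attributes.
#' @export
leave_one_out <- function(fit, alpha = 0.05, method = NULL, level = NULL) {
  if (is.data.frame(fit)) {
    fit <- pool_changes(fit, method = if (is.null(method)) "REML" else method,
                        level = if (is.null(level)) 0.95 else level)
  }
  stopifnot(inherits(fit, "meta_change"))
  if (fit$p != 1) stop("leave-one-out is defined for intercept-only fits")
  k <- fit$k
  if (k < 3) stop("leave-one-out requires at least 3 estimates")
  if (is.null(method)) method <- fit$method
  if (is.null(level)) level <- fit$level
  ids <- if (!is.null(fit$data$estimate_id)) fit$data$estimate_id
         else paste0("estimate_", seq_len(k))
  full_sig <- fit$pval < alpha
  rows <- lapply(seq_len(k), function(i) {
    sub <- data.frame(d = fit$yi[-i], se = fit$sei[-i])
    f <- meta_change(d ~ 1, data = sub, method = method, level = level)
    data.frame(omitted = ids[i], pooled = f$beta, se = f$se_beta,
               ci.lb = f$ci.lb, ci.ub = f$ci.ub, pval = f$pval,
               tau2 = f$tau2, I2 = f$I2,
               outside_ci = f$beta < fit$ci.lb | f$beta > fit$ci.ub,
               sig_flip = (f$pval < alpha) != full_sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- c(pooled = unname(fit$beta), ci.lb = unname(fit$ci.lb),
                         ci.ub = unname(fit$ci.ub), pval = unname(fit$pval))
  out
}
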