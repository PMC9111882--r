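#' Random-effects meta-analysis and meta-regression of change scores
#'
#' Fits the random-effects model
#' \deqn{d_i = x_i'\beta + u_i + e_i, \quad u_i \sim N(0, \tau^2),
#'   \quad e_i \sim N(0, se_i^2)}
#' to study-level change scores by weighted least squares with weights
#' \eqn{w_i = 1/(se_i^2 + \tau^2)}. With an intercept-only formula
#' (\code{d ~ 1}) this is the plain random-effects pooled estimate; with a
#' categorical moderator on the right-hand side it is a single-moderator
#' mixed-effects meta-regression.
#'
#' The between-study variance \eqn{\tau^2} is estimated by restricted
#' maximum likelihood (Fisher scoring on the restricted log-likelihood,
#' convergence tolerance \code{1e-8}, at most 200 iterations, constrained
#' to be non-negative) or by the DerSimonian-Laird moment estimator.
#' Inference on the coefficients uses Wald z statistics and normal-theory
#' confidence intervals. Heterogeneity is summarised by Cochran's Q
#' (fixed-effect weighted residual sum of squares on \eqn{\chi^2_{k-p}}),
#' and I-squared in its \eqn{\tau^2}-based form
#' \eqn{I^2 = 100\,\tau^2/(\tau^2 + s^2)} where \eqn{s^2} is the typical
#' within-study variance \eqn{(k-p)/\mathrm{tr}(P)}; the Q-based form
#' \eqn{\max(0, 100 (Q - df)/Q)} is also reported. For models with
#' moderators the omnibus moderator test QM is the Wald chi-square on all
#' non-intercept coefficients.
#'
#' @param formula model formula, e.g. \code{d ~ 1} or \code{d ~ period}.
#' @param data data frame holding the effect sizes and moderators,
#'   typically from \code{\link{compute_effects}}.
#' @param se standard error of each effect size: a column name in
#'   \code{data} (default \code{"se"}) or a numeric vector.
#' @param method \code{"REML"} (default) or \code{"DL"}.
#' @param level confidence level, default 0.95.
#' @param control list: \code{tol} (default \code{1e-8}), \code{maxit}
#'   (default 200), \code{tau2_max} upper bound used by the fallback
#'   optimiser (default \code{100 * max(se^2)}).
#' @return An object of class \code{"meta_change"}; see
#'   \code{\link{summary.meta_change}}. Key components: \code{beta},
#'   \code{se_beta}, \code{ci.lb}, \code{ci.ub}, \code{zval}, \code{pval},
#'   \code{tau2}, \code{QE}, \code{QE_p}, \code{I2}, \code{QM},
#'   \code{QM_p}, \code{k}.
#' @examples
#' ef <- data.frame(d = c(-0.12, -0.05, 0.02, -0.08, -0.03),
#'                  se = c(0.03, 0.05, 0.04, 0.02, 0.06))
#' fit <- meta_change(d ~ 1, data = ef)
#' summary(fit)
#' @export
meta_change <- function(formula, data, se = "se",
                        method = c("REML", "DL"), level = 0.95,
                        control = list()) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  k <- length(y)
  p <- ncol(X)

  sev <- if (is.character(se)) {
    if (!se %in% names(data)) stop("column '", se, "' not found in data")
    data[[se]]
  } else se
  if (length(sev) != k) stop("'se' must match the number of estimates")
  if (any(!is.finite(sev)) || any(sev < 0)) stop("standard errors must be finite and >= 0")
  if (any(sev == 0))
    stop("degenerate estimate(s) with se = 0 cannot enter inverse-variance ",
         "pooling; filter them first (see pool_changes)")
  if (k < 2) stop("at least two estimates are required")
  if (k <= p) stop("model has as many coefficients as estimates (k = ", k,
                   ", p = ", p, "); no residual information")
  if (qr(X)$rank < p) stop("degenerate design: moderator matrix is rank-deficient")

  ctl <- list(tol = 1e-8, maxit = 200L, tau2_max = max(100 * max(sev^2), 1))
  ctl[names(control)] <- control
  vi <- sev^2

  tfit <- switch(method,
                 REML = .tau2_reml(y, X, vi, ctl),
                 DL = .tau2_dl(y, X, vi))
  tau2 <- tfit$tau2

  w <- 1 / (vi + tau2)
  fit <- .wls(y, X, w)
  vb <- fit$vb
  beta <- fit$beta
  se_beta <- sqrt(diag(vb))
  crit <- stats::qnorm(1 - (1 - level) / 2)
  zval <- beta / se_beta
  pval <- 2 * stats::pnorm(-abs(zval))

  # heterogeneity on fixed-effect weights
  wfe <- 1 / vi
  fe <- .wls(y, X, wfe)
  QE <- sum(wfe * (y - X %*% fe$beta)^2)
  QE_df <- k - p
  QE_p <- stats::pchisq(QE, df = QE_df, lower.tail = FALSE)
  # typical within-study variance s^2 = (k - p) / tr(P), P from FE weights
  trP <- .trP(X, wfe, fe$vb_unscaled)
  s2 <- QE_df / trP
  I2 <- 100 * tau2 / (tau2 + s2)
  I2_Q <- max(0, 100 * (QE - QE_df) / QE)

  # omnibus moderator test on non-intercept coefficients
  has_int <- "(Intercept)" %in% colnames(X)
  mod_idx <- if (has_int) setdiff(seq_len(p), which(colnames(X) == "(Intercept)")) else seq_len(p)
  if (p > has_int) {
    bm <- beta[mod_idx]
    QM <- drop(t(bm) %*% solve(vb[mod_idx, mod_idx, drop = FALSE]) %*% bm)
    QM_df <- length(mod_idx)
    QM_p <- stats::pchisq(QM, df = QM_df, lower.tail = FALSE)
  } else {
    QM <- QM_df <- QM_p <- NA_real_
  }

  structure(list(
    call = cl, formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    yi = y, vi = vi, sei = sev, X = X, k = k, p = p,
    method = method, level = level,
    tau2 = tau2, converged = tfit$converged, iterations = tfit$iterations,
    beta = drop(beta), vb = vb, se_beta = se_beta,
    zval = drop(zval), pval = drop(pval),
    ci.lb = drop(beta - crit * se_beta), ci.ub = drop(beta + crit * se_beta),
    QE = QE, QE_df = QE_df, QE_p = QE_p,
    I2 = I2, I2_Q = I2_Q, s2 = s2,
    QM = QM, QM_df = QM_df, QM_p = QM_p
  ), class = "meta_change")
}

# tr(P) with P = W - WX(X'WX)^{-1}X'W; Ainv = (X'WX)^{-1}
.trP <- function(X, w, Ainv) {
  Xw <- X * w
  sum(w) - sum(diag(Ainv %*% (t(Xw) %*% Xw)))
}

# weighted least squares; returns beta, vb = (X'WX)^{-1} and that matrix unscaled
.wls <- function(y, X, w) {
  XtW <- t(X * w)
  A <- XtW %*% X
  Ainv <- solve(A)
  beta <- Ainv %*% (XtW %*% y)
  list(beta = beta, vb = Ainv, vb_unscaled = Ainv)
}

# restricted log-likelihood of tau2 (constants dropped where harmless)
.reml_ll <- function(tau2, y, X, vi) {
  w <- 1 / (vi + tau2)
  A <- t(X * w) %*% X
  beta <- solve(A, t(X * w) %*% y)
  r <- y - X %*% beta
  -0.5 * (sum(log(vi + tau2)) + determinant(A, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

# REML via Fisher scoring with step-halving; optimise() fallback
.tau2_reml <- function(y, X, vi, ctl) {
  tau2 <- max(.tau2_dl(y, X, vi)$tau2, 1e-4)  # moment start
  conv <- FALSE
  iter <- 0L
  ll_old <- .reml_ll(tau2, y, X, vi)
  while (iter < ctl$maxit) {
    iter <- iter + 1L
    w <- 1 / (vi + tau2)
    A <- t(X * w) %*% X
    Ainv <- solve(A)
    H <- X %*% Ainv %*% t(X * w)        # hat matrix under W
    Pd <- w * (diag(length(y)) - H)     # P = W(I - H)
    r <- y - H %*% y
    score <- -0.5 * sum(diag(Pd)) + 0.5 * sum((w * r)^2)
    info <- 0.5 * sum(Pd * t(Pd))       # tr(P P)
    if (info <= 0) break
    step <- score / info
    tau2_new <- max(tau2 + step, 0)
    # step-halve if the restricted likelihood would decrease
    h <- 0L
    while (h < 20L) {
      ll_new <- .reml_ll(tau2_new, y, X, vi)
      if (ll_new >= ll_old - 1e-12) break
      step <- step / 2
      tau2_new <- max(tau2 + step, 0)
      h <- h + 1L
    }
    if (abs(tau2_new - tau2) < ctl$tol * (1 + tau2)) {
      tau2 <- tau2_new
      conv <- TRUE
      break
    }
    tau2 <- tau2_new
    ll_old <- .reml_ll(tau2, y, X, vi)
  }
  if (!conv) {
    opt <- stats::optimize(function(t2) .reml_ll(t2, y, X, vi),
                           interval = c(0, ctl$tau2_max), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    # honour the boundary: the maximum may sit at tau2 = 0
    if (.reml_ll(0, y, X, vi) >= opt$objective) {
      tau2 <- 0
    } else {
      tau2 <- opt$maximum
    }
    conv <- TRUE
  }
  # boundary polish: scoring can stall just above zero
  if (tau2 < 1e-10 || .reml_ll(0, y, X, vi) >= .reml_ll(tau2, y, X, vi))
    tau2 <- 0
  list(tau2 = tau2, converged = conv, iterations = iter)
}

# DerSimonian-Laird moment estimator (generalised to a moderator matrix)
.tau2_dl <- function(y, X, vi) {
  w <- 1 / vi
  fe <- .wls(y, X, w)
  Q <- sum(w * (y - X %*% fe$beta)^2)
  df <- length(y) - ncol(X)
  trP <- .trP(X, w, fe$vb_unscaled)
  list(tau2 = max(0, (Q - df) / trP), converged = TRUE, iterations = 0L)
}

#' Pool a set of change-score estimates
#'
#' Convenience wrapper around \code{\link{meta_change}} for plain
#' (intercept-only) random-effects pooling of an effects table. Estimates
#' with zero sampling variance are excluded with a warning before
#' fitting, and the number of independent studies contributing is
#' recorded alongside the number of estimates.
#'
#' @param effects effects table from \code{\link{compute_effects}}, or any
#'   data frame with columns \code{d} and \code{se} (optionally
#'   \code{study_id}).
#' @param method,level,control passed to \code{\link{meta_change}}.
#' @return A \code{"meta_change"} fit with an extra \code{n_studies}
#'   component and the filtered effects table attached as \code{data}.
#' @export
pool_changes <- function(effects, method = c("REML", "DL"), level = 0.95,
                         control = list()) {
  stopifnot(is.data.frame(effects), all(c("d", "se") %in% names(effects)))
  drop <- effects$se == 0
  if (any(drop)) {
    warning("excluding ", sum(drop),
            " degenerate estimate(s) with se = 0 from pooling")
    effects <- effects[!drop, , drop = FALSE]
  }
  fit <- meta_change(d ~ 1, data = effects, se = "se", method = method,
                     level = level, control = control)
  fit$n_studies <- if ("study_id" %in% names(effects))
    length(unique(effects$study_id)) else fit$k
  fit$data <- effects
  fit
}
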