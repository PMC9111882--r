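#' Bonferroni-corrected significance threshold
#'
#' Divides the nominal significance level by the number of moderator
#' models fitted on the same set of studies. With the four pre-specified
#' moderators (study timing, age oversampling, sampling weights,
#' European sub-region) and alpha = 0.05 the corrected threshold is
#' 0.0125.
#'
#' @param alpha nominal significance level, in (0, 1).
#' @param m number of models (tests), a positive integer.
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("'m' must be a positive integer")
  alpha / m
}

# reference levels for the pre-specified moderators
.moderator_refs <- c(period = "P1", age_profile = "general",
                     weighted = "FALSE", sub_region = "Western")

#' Single-moderator random-effects meta-regression
#'
#' Fits \code{d ~ moderator} by mixed-effects meta-regression (REML
#' \eqn{\tau^2}, Wald inference; see \code{\link{meta_change}}) with
#' dummy coding against a fixed reference level: period = P1 (March-June
#' 2020), age_profile = general, weighted = FALSE, sub_region = Western.
#' The omnibus moderator test QM (Wald chi-square on the non-intercept
#' coefficients) is judged against a Bonferroni-corrected threshold
#' \code{alpha / m}, reflecting m single-moderator models fitted to the
#' same studies.
#'
#' Empty moderator levels are dropped with a warning; a moderator that is
#' constant in the data is a degenerate design and an error.
#'
#' @param effects effects table (see \code{\link{compute_effects}}); rows
#'   with \code{se == 0} are excluded with a warning.
#' @param moderator one of \code{"period"}, \code{"age_profile"},
#'   \code{"weighted"}, \code{"sub_region"}, or any factor-like column
#'   of \code{effects}.
#' @param method,level passed to \code{\link{meta_change}}.
#' @param alpha nominal significance level (default 0.05).
#' @param m number of moderator models for the Bonferroni divisor
#'   (default 4, the pre-specified set).
#' @return Object of class \code{"meta_change_mr"} (inherits
#'   \code{"meta_change"}) with extra components: \code{moderator},
#'   \code{reference_level}, \code{level_means} (fitted change score per
#'   level with CI), \code{alpha_corrected}, and \code{significant}
#'   (QM_p < alpha_corrected).
#' @export
fit_meta_regression <- function(effects, moderator,
                                method = c("REML", "DL"), level = 0.95,
                                alpha = 0.05, m = 4) {
  stopifnot(is.data.frame(effects), moderator %in% names(effects))
  drop0 <- effects$se == 0
  if (any(drop0)) {
    warning("excluding ", sum(drop0), " degenerate estimate(s) with se = 0")
    effects <- effects[!drop0, , drop = FALSE]
  }
  x <- effects[[moderator]]
  if (is.logical(x)) x <- factor(x, levels = c("FALSE", "TRUE"))
  if (!is.factor(x)) x <- factor(x)
  obs <- droplevels(x)
  if (nlevels(obs) < nlevels(x))
    warning("dropping empty level(s) of '", moderator, "': ",
            paste(setdiff(levels(x), levels(obs)), collapse = ", "))
  x <- obs
  if (nlevels(x) < 2)
    stop("degenerate design: moderator '", moderator,
         "' has a single observed level")
  ref <- .moderator_refs[moderator]
  if (!is.na(ref) && ref %in% levels(x)) x <- stats::relevel(x, ref = ref)
  effects$.mod <- x
  if (nrow(effects) < nlevels(x) + 1)
    stop("too few estimates (k = ", nrow(effects), ") for ",
         nlevels(x), " moderator levels")

  fit <- meta_change(d ~ .mod, data = effects, se = "se",
                     method = match.arg(method), level = level)
  # restore readable coefficient names
  nm <- colnames(fit$X)
  colnames(fit$X) <- sub("^\\.mod", paste0(moderator, ""), nm)

  lv <- levels(x)
  lm_tab <- predict(fit, newdata = data.frame(.mod = factor(lv, levels = lv)))
  lm_tab <- cbind(level = lv, lm_tab)
  rownames(lm_tab) <- NULL

  fit$moderator <- moderator
  fit$reference_level <- levels(x)[1]
  fit$level_means <- lm_tab
  fit$alpha_corrected <- bonferroni_alpha(alpha, m)
  fit$significant <- fit$QM_p < fit$alpha_corrected
  fit$data <- effects
  class(fit) <- c("meta_change_mr", class(fit))
  fit
}

#' @export
print.meta_change_mr <- function(x, digits = 4, ...) {
  cat("Meta-regression on moderator '", x$moderator, "' (reference: ",
      x$reference_level, ")\n", sep = "")
  cat("QM = ", format(x$QM, digits = digits), " (df = ", x$QM_df, "), p = ",
      format.pval(x$QM_p, digits = digits),
      if (x$significant) "  * significant" else "  n.s.",
      " at Bonferroni-corrected alpha = ", x$alpha_corrected, "\n", sep = "")
  cat("Residual tau^2 = ", format(x$tau2, digits = digits), "\n", sep = "")
  cat("\nLevel means:\n")
  print(x$level_means, digits = digits)
  invisible(x)
}
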