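#' Paired-proportion change score with closed-form standard error
#'
#' Computes, for each study, the difference between the proportion of
#' drinkers reporting an increase and the proportion reporting a decrease
#' in alcohol use, \eqn{d = (n_{inc} - n_{dec}) / n}, together with its
#' standard error
#' \deqn{SE = \frac{1}{n}\sqrt{n_{inc} + n_{dec} - \frac{(n_{inc}-n_{dec})^2}{n}}}
#' which is the delta-method standard error of the difference of two
#' paired (multinomial) proportions.
#'
#' The SE is exactly zero in two degenerate situations: no respondent
#' changed at all (\code{n_inc + n_dec == 0}), or every respondent changed
#' in the same direction (\code{|n_inc - n_dec| == n}). Such estimates
#' carry no sampling variance on this scale and must be excluded from
#' inverse-variance pooling (see \code{\link{pool_changes}}).
#'
#' @param n number of current drinkers (denominator), positive integer(s).
#' @param n_inc number of respondents reporting increased use.
#' @param n_dec number of respondents reporting decreased use.
#' @return A data frame with one row per input: \code{d}, \code{se},
#'   \code{n}, \code{n_inc}, \code{n_dec}.
#' @examples
#' change_score(100, 30, 20)   # d = 0.10, se = 0.07
#' change_score(200, 20, 60)   # d = -0.20
#' @export
change_score <- function(n, n_inc, n_dec) {
  stopifnot(length(n_inc) == length(n), length(n_dec) == length(n))
  if (any(!is.finite(n)) || any(n < 1))
    stop("change score undefined: drinker denominator 'n' must be >= 1")
  if (any(n_inc < 0) || any(n_dec < 0))
    stop("counts 'n_inc' and 'n_dec' must be non-negative")
  if (any(n_inc + n_dec > n))
    stop("inconsistent counts: n_inc + n_dec exceeds n for row(s) ",
         paste(which(n_inc + n_dec > n), collapse = ", "))
  d <- (n_inc - n_dec) / n
  # clamp tiny negative float residue inside the sqrt
  arg <- pmax(n_inc + n_dec - (n_inc - n_dec)^2 / n, 0)
  se <- sqrt(arg) / n
  data.frame(d = d, se = se, n = n, n_inc = n_inc, n_dec = n_dec)
}

#' Before/during difference in the prevalence of alcohol use
#'
#' Effect size for studies reporting the prevalence of current alcohol
#' use before versus during the pandemic. Two reporting formats are
#' supported, tried in this order:
#' \itemize{
#'   \item \emph{Discordant counts}: numbers of respondents who started
#'     (\code{n_start}) and stopped (\code{n_stop}) drinking. The change
#'     score machinery applies directly with
#'     \code{(n_inc, n_dec) = (n_start, n_stop)}:
#'     \code{d = (n_start - n_stop)/n} with the paired-proportion SE.
#'   \item \emph{Marginal prevalences}: \code{p_before} and
#'     \code{p_during} only. Then \code{d = p_during - p_before} and
#'     \code{se = sqrt((p_during + p_before - d^2)/n)}, the same formula
#'     evaluated on the proportion scale. Without the discordant counts
#'     this is an approximation (it ignores the before/during covariance),
#'     so such rows are flagged \code{approx = TRUE} in the output.
#' }
#'
#' @param n number of respondents the prevalences refer to.
#' @param n_start,n_stop counts of respondents who started / stopped
#'   drinking (optional; both needed to use the count route).
#' @param p_before,p_during prevalence of alcohol use before / during the
#'   pandemic, fractions in \[0, 1\] (optional; both needed otherwise).
#' @return Data frame with columns \code{d}, \code{se}, \code{n},
#'   \code{approx}.
#' @examples
#' prevalence_difference(100, n_start = 5, n_stop = 12)
#' prevalence_difference(400, p_before = 0.70, p_during = 0.60)
#' @export
prevalence_difference <- function(n, n_start = NA, n_stop = NA,
                                  p_before = NA, p_during = NA) {
  len <- max(length(n), length(n_start), length(n_stop),
             length(p_before), length(p_during))
  n        <- rep_len(n, len)
  n_start  <- rep_len(n_start, len)
  n_stop   <- rep_len(n_stop, len)
  p_before <- rep_len(p_before, len)
  p_during <- rep_len(p_during, len)

  have_counts <- !is.na(n_start) & !is.na(n_stop)
  have_prev   <- !is.na(p_before) & !is.na(p_during)
  if (any(!have_counts & !have_prev))
    stop("insufficient data: need (n_start, n_stop) or (p_before, p_during) ",
         "for row(s) ", paste(which(!have_counts & !have_prev), collapse = ", "))
  if (any(have_prev & (p_before < 0 | p_before > 1 | p_during < 0 | p_during > 1)))
    stop("prevalences must lie in [0, 1]")

  out <- data.frame(d = NA_real_, se = NA_real_, n = n,
                    approx = !have_counts)
  if (any(have_counts)) {
    cs <- change_score(n[have_counts], n_start[have_counts], n_stop[have_counts])
    out$d[have_counts] <- cs$d
    out$se[have_counts] <- cs$se
  }
  mp <- !have_counts
  if (any(mp)) {
    d <- p_during[mp] - p_before[mp]
    arg <- pmax(p_during[mp] + p_before[mp] - d^2, 0)
    out$d[mp] <- d
    out$se[mp] <- sqrt(arg / n[mp])
  }
  out
}

#' Build the effects table from prepared study records
#'
#' Converts validated study records into per-estimate effect sizes: the
#' paired-proportion change score for the consumption-change indicators,
#' and the prevalence difference for \code{indicator == "prevalence"}.
#' Records must already carry a drinker denominator (see
#' \code{\link{estimate_drinker_n}}) and have starters/stoppers folded in
#' where applicable (see \code{\link{fold_start_stop}}).
#'
#' @param records a study-record data frame (see \code{\link{read_studies}}).
#' @return Data frame with one row per estimate: \code{estimate_id},
#'   \code{study_id}, \code{indicator}, \code{stratum}, \code{d},
#'   \code{se}, \code{n}, the moderator columns (\code{period},
#'   \code{age_profile}, \code{weighted}, \code{sub_region},
#'   \code{convenience_sample}), a \code{degenerate} flag (\code{se == 0},
#'   unusable for inverse-variance pooling) and an \code{approx} flag for
#'   prevalence rows computed from marginal prevalences.
#' @export
compute_effects <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  prev <- !is.na(records$indicator) & records$indicator == "prevalence"
  d <- se <- rep(NA_real_, nrow(records))
  approx <- rep(FALSE, nrow(records))

  if (any(!prev)) {
    r <- records[!prev, ]
    if (any(is.na(r$n_drinkers)))
      stop("missing drinker denominator; run estimate_drinker_n() first")
    cs <- change_score(r$n_drinkers, r$n_inc, r$n_dec)
    d[!prev] <- cs$d
    se[!prev] <- cs$se
  }
  if (any(prev)) {
    r <- records[prev, ]
    pd <- prevalence_difference(r$n_drinkers,
                                n_start = r$n_start, n_stop = r$n_stop,
                                p_before = r$p_before, p_during = r$p_during)
    d[prev] <- pd$d
    se[prev] <- pd$se
    approx[prev] <- pd$approx
  }

  out <- data.frame(
    estimate_id = records$estimate_id,
    study_id = records$study_id,
    indicator = records$indicator,
    stratum = records$stratum,
    d = d, se = se, n = records$n_drinkers,
    period = records$period,
    age_profile = records$age_profile,
    weighted = records$weighted,
    sub_region = records$sub_region,
    convenience_sample = records$convenience_sample,
    degenerate = se == 0,
    approx = approx,
    stringsAsFactors = FALSE
  )
  if (any(out$degenerate))
    warning(sum(out$degenerate), " estimate(s) have zero sampling variance ",
            "(no changers, or all changed one way) and will be excluded ",
            "from pooling: ",
            paste(out$estimate_id[out$degenerate], collapse = ", "))
  out
}
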