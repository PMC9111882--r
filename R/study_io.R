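#' @title Study-table schema
#' @description Column definitions for the study-level input table (one
#'   row per estimate). Mandatory columns: \code{study_id},
#'   \code{estimate_id}, \code{country}, \code{sub_region} (Northern /
#'   Western / Southern / Eastern), \code{period} (P1 = March-June 2020,
#'   P2 = July-September 2020, P3 = October 2020 or later), \code{design}
#'   (cross-sectional / repeated cross-sectional / longitudinal),
#'   \code{population} (general / AUD), \code{stratum} (total / women /
#'   men), \code{indicator} (overall_use / frequency / quantity / HED /
#'   prevalence), \code{n_total}, \code{weighted}, \code{age_profile}
#'   (general / younger / older), \code{convenience_sample}. Optional:
#'   \code{prop_drinkers}, \code{prop_women}, \code{n_drinkers},
#'   \code{n_inc}, \code{n_dec}, \code{n_start}, \code{n_stop},
#'   \code{p_before}, \code{p_during}. The prevalence indicator refers to
#'   the share of respondents drinking at least weekly or monthly.
#' @return Data frame describing each column (name, mandatory, type).
#' @export
study_schema <- function() {
  data.frame(
    column = c("study_id", "estimate_id", "country", "sub_region", "period",
               "design", "population", "stratum", "indicator", "n_total",
               "weighted", "age_profile", "convenience_sample",
               "prop_drinkers", "prop_women", "n_drinkers", "n_inc", "n_dec",
               "n_start", "n_stop", "p_before", "p_during"),
    mandatory = c(rep(TRUE, 13), rep(FALSE, 9)),
    type = c("text", "text", "text", "enum", "enum", "enum", "enum", "enum",
             "enum", "count", "logical", "enum", "logical",
             "proportion", "proportion", "count", "count", "count",
             "count", "count", "proportion", "proportion"),
    stringsAsFactors = FALSE
  )
}

.enums <- list(
  sub_region = c("Northern", "Western", "Southern", "Eastern"),
  period = c("P1", "P2", "P3"),
  design = c("cross-sectional", "repeated cross-sectional", "longitudinal"),
  population = c("general", "AUD"),
  stratum = c("total", "women", "men"),
  indicator = c("overall_use", "frequency", "quantity", "HED", "prevalence"),
  age_profile = c("general", "younger", "older")
)
.count_cols <- c("n_total", "n_drinkers", "n_inc", "n_dec", "n_start", "n_stop")
.prop_cols <- c("prop_drinkers", "prop_women", "p_before", "p_during")

#' Read and validate a study-level table
#'
#' Reads a UTF-8 CSV or TSV file (dialect inferred from the extension,
#' override with \code{sep}) against the schema of
#' \code{\link{study_schema}}, normalises proportion columns given as
#' percentages ("45" or "45\%") to fractions when
#' \code{proportions = "percent"}, and validates every row. With
#' \code{strict = TRUE} (default) any invariant violation is an error
#' naming the offending rows; with \code{strict = FALSE} invalid rows are
#' dropped and reported in the \code{"validation"} attribute.
#'
#' @param path path to the CSV/TSV file.
#' @param proportions \code{"fraction"} (default) or \code{"percent"}.
#' @param sep field separator; \code{NULL} infers from extension.
#' @param strict stop on invalid rows (default) or drop them.
#' @return Data frame of validated study records; attribute
#'   \code{"validation"} holds the issue table (row, column, message).
#' @export
read_studies <- function(path, proportions = c("fraction", "percent"),
                         sep = NULL, strict = TRUE) {
  proportions <- match.arg(proportions)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(study_schema()$column[study_schema()$mandatory],
                          names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in intersect(study_schema()$column, names(df))) {
    type <- study_schema()$type[study_schema()$column == col]
    if (type %in% c("count", "proportion") && is.logical(df[[col]]))
      df[[col]] <- as.numeric(df[[col]])  # all-NA columns read as logical
    if (type %in% c("count", "proportion") && is.character(df[[col]])) {
      raw <- sub("%$", "", trimws(df[[col]]))
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(df[[col]]) & is.na(num))
      if (length(bad))
        stop("parse error: non-numeric value in '", col, "' at row(s) ",
             paste(bad, collapse = ", "))
      df[[col]] <- num
    }
    if (type == "logical" && !is.logical(df[[col]])) {
      v <- trimws(tolower(as.character(df[[col]])))
      lg <- rep(NA, length(v))
      lg[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
      lg[v %in% c("false", "f", "0", "no", "n")] <- FALSE
      df[[col]] <- lg
    }
  }
  if (proportions == "percent")
    for (col in intersect(.prop_cols, names(df)))
      df[[col]] <- df[[col]] / 100
  for (col in setdiff(study_schema()$column, names(df))) df[[col]] <- NA
  validate_studies(df, strict = strict)
}

#' Validate study records against the schema invariants
#'
#' Checks enum membership, non-negative integer counts, proportions in
#' \[0, 1\], uniqueness of \code{estimate_id},
#' \code{n_inc + n_dec <= n_drinkers} where all three are present, and
#' that prevalence rows carry either both prevalences or both
#' start/stop counts.
#'
#' @param records study-record data frame.
#' @param strict stop on violations (default) or drop offending rows.
#' @return The (possibly filtered) records with a \code{"validation"}
#'   attribute: a data frame of issues (row, column, message).
#' @export
validate_studies <- function(records, strict = TRUE) {
  issues <- list()
  note <- function(rows, column, message) {
    if (length(rows))
      issues[[length(issues) + 1]] <<- data.frame(
        row = rows, column = column, message = message,
        stringsAsFactors = FALSE)
  }
  for (col in names(.enums)) {
    bad <- which(!is.na(records[[col]]) & !records[[col]] %in% .enums[[col]])
    note(bad, col, paste0("value outside {",
                          paste(.enums[[col]], collapse = ", "), "}"))
  }
  for (col in .count_cols) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    note(bad, col, "count must be a non-negative integer")
  }
  for (col in .prop_cols) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    note(bad, col, "proportion must lie in [0, 1]")
  }
  dup <- which(duplicated(records$estimate_id) |
                 duplicated(records$estimate_id, fromLast = TRUE))
  note(dup, "estimate_id", "estimate_id must be unique")
  ok3 <- !is.na(records$n_inc) & !is.na(records$n_dec) & !is.na(records$n_drinkers)
  bad <- which(ok3 & records$n_inc + records$n_dec > records$n_drinkers)
  note(bad, "n_inc", "n_inc + n_dec exceeds n_drinkers")
  prev <- !is.na(records$indicator) & records$indicator == "prevalence"
  has_p <- !is.na(records$p_before) & !is.na(records$p_during)
  has_c <- !is.na(records$n_start) & !is.na(records$n_stop)
  note(which(prev & !has_p & !has_c), "indicator",
       "prevalence rows need (p_before, p_during) or (n_start, n_stop)")

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(), message = character(),
               stringsAsFactors = FALSE)
  if (nrow(issues) && strict)
    stop("validation failed for row(s) ",
         paste(sort(unique(issues$row)), collapse = ", "), ":\n",
         paste(sprintf("  row %d [%s]: %s", issues$row, issues$column,
                       issues$message), collapse = "\n"))
  if (nrow(issues)) records <- records[-sort(unique(issues$row)), , drop = FALSE]
  attr(records, "validation") <- issues
  records
}

#' Write study records back to CSV
#'
#' @param records study-record data frame.
#' @param path output path; \code{.tsv} extension switches to tabs.
#' @export
write_studies <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  cols <- intersect(study_schema()$column, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# round-half-up; reconstructed denominators must stay integral
.round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct the drinker denominator of each record
#'
#' Where \code{n_drinkers} is not reported it is estimated as the total
#' sample size times the proportion of current drinkers, additionally
#' times the proportion of women (or its complement for men) for
#' gender-stratified rows; rounded half-up to the nearest integer. When
#' the proportion of current drinkers is unknown the total sample size
#' itself is used, under the assumption that the study reported changes
#' among drinkers only.
#'
#' @param records study-record data frame with \code{n_total} present.
#' @return The records with \code{n_drinkers} filled in and a logical
#'   \code{n_drinkers_estimated} column flagging reconstructed values.
#' @examples
#' r <- data.frame(n_total = 1000, prop_drinkers = 0.8, prop_women = 0.5,
#'                 stratum = "women", n_drinkers = NA)
#' estimate_drinker_n(r)$n_drinkers  # 400
#' @export
estimate_drinker_n <- function(records) {
  stopifnot(all(!is.na(records$n_total)))
  est <- is.na(records$n_drinkers)
  strat <- records$stratum %in% c("women", "men")
  unresolved <- est & strat & is.na(records$prop_women)
  if (any(unresolved))
    stop("unresolvable denominator: gender-stratified row(s) ",
         paste(which(unresolved), collapse = ", "),
         " lack both n_drinkers and prop_women")
  base <- ifelse(is.na(records$prop_drinkers), records$n_total,
                 records$n_total * records$prop_drinkers)
  gfac <- ifelse(records$stratum == "women", records$prop_women,
                 ifelse(records$stratum == "men", 1 - records$prop_women, 1))
  gfac[is.na(gfac)] <- 1
  records$n_drinkers[est] <- .round_half_up(base[est] * gfac[est])
  records$n_drinkers_estimated <- est
  records
}

#' Fold starters and stoppers into the change counts
#'
#' For the few studies reporting respondents who started or stopped
#' drinking during the pandemic, the drinker denominator is enlarged by
#' both groups and starters are counted as increases, stoppers as
#' decreases: \code{n_drinkers + n_start + n_stop},
#' \code{n_inc + n_start}, \code{n_dec + n_stop}. Absent counts are
#' treated as zero (one-sided folding). Original values are preserved in
#' the \code{"prefold"} attribute and a \code{folded} flag is set.
#'
#' @param records study-record data frame with \code{n_drinkers} present
#'   on the rows to fold.
#' @return The records with updated counts.
#' @export
fold_start_stop <- function(records) {
  has <- (!is.na(records$n_start) & records$n_start > 0) |
         (!is.na(records$n_stop) & records$n_stop > 0)
  records$folded <- has
  if (!any(has)) return(records)
  if (any(has & is.na(records$n_drinkers)))
    stop("cannot fold starters/stoppers for row(s) lacking n_drinkers: ",
         paste(which(has & is.na(records$n_drinkers)), collapse = ", "))
  pre <- records[has, c("estimate_id", "n_drinkers", "n_inc", "n_dec",
                        "n_start", "n_stop")]
  add_start <- ifelse(is.na(records$n_start), 0, records$n_start)
  add_stop <- ifelse(is.na(records$n_stop), 0, records$n_stop)
  records$n_drinkers[has] <- records$n_drinkers[has] + add_start[has] + add_stop[has]
  records$n_inc[has] <- records$n_inc[has] + add_start[has]
  records$n_dec[has] <- records$n_dec[has] + add_stop[has]
  attr(records, "prefold") <- pre
  records
}

#' Pandemic period of a date
#'
#' Maps calendar dates to the three pre-defined pandemic periods:
#' P1 = March-June 2020, P2 = July-September 2020, P3 = October 2020 or
#' later. Dates before March 2020 are an error. A study whose fieldwork
#' spans two periods is assigned by the midpoint of its window:
#' \code{pandemic_period(start, end)}.
#'
#' @param date a \code{Date} (or "YYYY-MM-DD" / "YYYY-MM" string).
#' @param end optional end of the fieldwork window; when given the
#'   midpoint of \code{[date, end]} is classified.
#' @return Character vector of \code{"P1"}, \code{"P2"}, \code{"P3"}.
#' @export
pandemic_period <- function(date, end = NULL) {
  to_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    x <- as.character(x)
    x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-15"), x)
    as.Date(x)
  }
  d <- to_date(date)
  if (!is.null(end)) d <- d + floor(as.numeric(to_date(end) - d) / 2)
  if (any(d < as.Date("2020-03-01")))
    stop("dates before March 2020 are outside the pandemic periods")
  ifelse(d <= as.Date("2020-06-30"), "P1",
         ifelse(d <= as.Date("2020-09-30"), "P2", "P3"))
}

#' Average monthly waves into pandemic-period records
#'
#' For a study reporting monthly change proportions, collapses the waves
#' into at most one record per pandemic period: the unweighted arithmetic
#' mean of \code{p_inc} and \code{p_dec} over the period's months, with
#' counts rebuilt as \code{round(mean p x n)} using the period-mean
#' drinker denominator.
#'
#' @param waves data frame with columns \code{study_id}, \code{month}
#'   (Date or "YYYY-MM"), \code{n_drinkers}, \code{p_inc}, \code{p_dec}.
#' @return Data frame with one row per (study_id, period): \code{period},
#'   \code{n_drinkers}, \code{p_inc}, \code{p_dec}, \code{n_inc},
#'   \code{n_dec}, \code{n_waves}.
#' @export
average_periods <- function(waves) {
  stopifnot(is.data.frame(waves))
  if (nrow(waves) == 0) stop("empty wave list")
  need <- c("study_id", "month", "n_drinkers", "p_inc", "p_dec")
  missing_cols <- setdiff(need, names(waves))
  if (length(missing_cols))
    stop("missing wave column(s): ", paste(missing_cols, collapse = ", "))
  if (any(waves$p_inc + waves$p_dec > 1 + 1e-12))
    stop("p_inc + p_dec exceeds 1 in wave row(s) ",
         paste(which(waves$p_inc + waves$p_dec > 1 + 1e-12), collapse = ", "))
  waves$period <- pandemic_period(waves$month)
  agg <- lapply(split(waves, list(waves$study_id, waves$period), drop = TRUE),
                function(g) {
    n_bar <- .round_half_up(mean(g$n_drinkers))
    data.frame(study_id = g$study_id[1], period = g$period[1],
               n_drinkers = n_bar,
               p_inc = mean(g$p_inc), p_dec = mean(g$p_dec),
               n_inc = .round_half_up(mean(g$p_inc) * n_bar),
               n_dec = .round_half_up(mean(g$p_dec) * n_bar),
               n_waves = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$study_id, out$period), , drop = FALSE]
}

#' Assemble analysis subsets from prepared records
#'
#' Groups general-population records by (indicator, stratum) into the
#' pre-specified meta-analysis subsets and flags each subset eligible
#' when at least \code{min_studies} independent studies contribute (a
#' study with several estimate rows counts once). For the change
#' indicators, gender-stratified rows form the women/men subsets while
#' all strata enter the total-sample analysis as separate estimates.
#'
#' @param records prepared study-record data frame.
#' @param min_studies eligibility threshold (default 5 independent
#'   studies).
#' @return A list of subsets, each a list with \code{label},
#'   \code{indicator}, \code{stratum}, \code{records},
#'   \code{n_estimates}, \code{n_studies}, \code{eligible}.
#' @export
build_subsets <- function(records, min_studies = 5) {
  if (nrow(records) == 0) return(list())
  gen <- records[!is.na(records$population) & records$population == "general", ,
                 drop = FALSE]
  subsets <- list()
  add <- function(label, indicator, stratum, recs) {
    subsets[[label]] <<- list(
      label = label, indicator = indicator, stratum = stratum,
      records = recs, n_estimates = nrow(recs),
      n_studies = length(unique(recs$study_id)),
      eligible = length(unique(recs$study_id)) >= min_studies)
  }
  for (ind in intersect(.enums$indicator, unique(gen$indicator))) {
    gi <- gen[gen$indicator == ind, , drop = FALSE]
    if (ind == "overall_use") {
      # total-sample analysis takes every estimate row, incl. stratified ones
      add("overall_use/total", ind, "total", gi)
      for (st in c("women", "men")) {
        gs <- gi[gi$stratum == st, , drop = FALSE]
        if (nrow(gs)) add(paste0("overall_use/", st), ind, st, gs)
      }
    } else {
      add(paste0(ind, "/total"), ind, "total", gi)
    }
  }
  subsets
}
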