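test_that("a well-formed table round-trips bit-identically", {
  rec <- make_records(3, prop_drinkers = c(0.8, NA, 0.9),
                      prop_women = c(0.5, NA, 0.45))
  path <- write_study_csv(rec)
  back <- read_studies(path)
  expect_equal(nrow(back), 3)
  cols <- intersect(study_schema()$column, names(rec))
  for (col in cols) expect_equal(back[[col]], rec[[col]], label = col)
  # second round trip reproduces the file
  path2 <- write_study_csv(back)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema and invariant violations are reported with row numbers", {
  rec <- make_records(2)
  path <- write_study_csv(rec[, setdiff(names(rec), "n_total")])
  expect_error(read_studies(path), "missing mandatory column.*n_total")

  bad <- make_records(2)
  bad$n_inc[2] <- -2
  expect_error(validate_studies(bad), "row 2")
  lax <- validate_studies(bad, strict = FALSE)
  expect_equal(nrow(lax), 1)
  expect_equal(attr(lax, "validation")$row, 2)

  dup <- make_records(2)
  dup$estimate_id <- "same"
  expect_error(validate_studies(dup), "unique")

  over <- make_records(1, n_drinkers = 100, n_inc = 70, n_dec = 40)
  expect_error(validate_studies(over), "exceeds")

  prev <- make_records(1, indicator = "prevalence")
  prev$n_inc <- prev$n_dec <- NA_real_
  expect_error(validate_studies(prev), "prevalence")
})

test_that("percent-dialect proportions are normalised to fractions", {
  rec <- make_records(1)
  rec$prop_drinkers <- "45%"
  path <- write_study_csv(rec)
  got <- read_studies(path, proportions = "percent")
  expect_equal(got$prop_drinkers, 0.45)
})

test_that("drinker denominators are reconstructed as documented", {
  r <- make_records(4, n_drinkers = rep(NA_real_, 4),
                    stratum = c("total", "total", "women", "men"))
  r$n_total <- rep(1000, 4)
  r$prop_drinkers <- c(0.8, NA, 0.8, 0.8)
  r$prop_women <- c(NA, NA, 0.5, 0.4)
  r$n_inc <- r$n_dec <- rep(10, 4)
  out <- estimate_drinker_n(r)
  expect_equal(out$n_drinkers, c(800, 1000, 400, 480))
  expect_true(all(out$n_drinkers_estimated))

  # reported denominators are never overwritten
  r2 <- make_records(1, n_drinkers = 777)
  expect_equal(estimate_drinker_n(r2)$n_drinkers, 777)
  expect_false(estimate_drinker_n(r2)$n_drinkers_estimated)

  # gender stratum without prop_women is unresolvable
  r3 <- make_records(1, n_drinkers = NA_real_, stratum = "women")
  expect_error(estimate_drinker_n(r3), "unresolvable")
})

test_that("reconstructed denominators are monotone in their inputs", {
  base <- function(n_total, prop) {
    r <- make_records(1, n_drinkers = NA_real_)
    r$n_total <- n_total; r$prop_drinkers <- prop
    estimate_drinker_n(r)$n_drinkers
  }
  ns <- seq(100, 2000, by = 137)
  expect_true(all(diff(vapply(ns, base, numeric(1), prop = 0.7)) >= 0))
  ps <- seq(0.1, 1, by = 0.07)
  expect_true(all(diff(vapply(ps, base, numeric(1), n_total = 997)) >= 0))
})

test_that("starters and stoppers fold into counts and denominator", {
  r <- make_records(1, n_drinkers = 100, n_inc = 10, n_dec = 20,
                    n_start = 5, n_stop = 10)
  out <- fold_start_stop(r)
  expect_equal(out$n_drinkers, 115)
  expect_equal(out$n_inc, 15)
  expect_equal(out$n_dec, 30)
  expect_true(out$folded)
  # conservation of the original counts
  pre <- attr(out, "prefold")
  expect_equal(out$n_inc - pre$n_start, pre$n_inc)
  expect_equal(out$n_dec - pre$n_stop, pre$n_dec)

  # zero counts leave the record unchanged
  r0 <- make_records(1, n_drinkers = 100, n_inc = 10, n_dec = 20,
                     n_start = 0, n_stop = 0)
  out0 <- fold_start_stop(r0)
  expect_equal(out0$n_drinkers, 100)
  expect_equal(out0$n_inc, 10)
  expect_false(out0$folded)

  # one-sided folding: only stoppers reported
  r1 <- make_records(1, n_drinkers = 100, n_inc = 10, n_dec = 20,
                     n_stop = 8)
  out1 <- fold_start_stop(r1)
  expect_equal(out1$n_drinkers, 108)
  expect_equal(out1$n_inc, 10)
  expect_equal(out1$n_dec, 28)

  # folding without a denominator is an error
  r2 <- make_records(1, n_drinkers = NA_real_, n_start = 5, n_stop = 2)
  expect_error(fold_start_stop(r2), "n_drinkers")
})

test_that("calendar dates map to the three pandemic periods", {
  expect_equal(pandemic_period(c("2020-03-01", "2020-06-30")), c("P1", "P1"))
  expect_equal(pandemic_period("2020-07-15"), "P2")
  expect_equal(pandemic_period(c("2020-10-01", "2021-02-11")), c("P3", "P3"))
  expect_error(pandemic_period("2020-02-15"), "outside")
  # spanning studies classify by the fieldwork midpoint
  expect_equal(pandemic_period("2020-06-20", end = "2020-07-20"), "P2")
  expect_equal(pandemic_period("2020-05-01", end = "2020-07-01"), "P1")
})

test_that("monthly waves average within periods", {
  waves <- data.frame(study_id = "s1",
                      month = c("2020-03", "2020-04"),
                      n_drinkers = c(200, 220),
                      p_inc = c(0.2, 0.3), p_dec = c(0.1, 0.1))
  out <- average_periods(waves)
  expect_equal(nrow(out), 1)
  expect_equal(out$period, "P1")
  expect_equal(out$p_inc, 0.25)
  expect_equal(out$n_drinkers, 210)
  expect_equal(out$n_inc, 53)  # 0.25 * 210 = 52.5, rounded half-up

  # a single wave is returned as-is
  one <- average_periods(data.frame(study_id = "s1", month = "2020-11",
                                    n_drinkers = 150, p_inc = 0.3,
                                    p_dec = 0.2))
  expect_equal(one$period, "P3")
  expect_equal(one$p_inc, 0.3)
  expect_equal(one$n_inc, 45)

  # waves on both sides of a period boundary stay separate
  span <- average_periods(data.frame(study_id = "s1",
                                     month = c("2020-06", "2020-07"),
                                     n_drinkers = 100,
                                     p_inc = c(0.2, 0.4), p_dec = 0.1))
  expect_equal(sort(span$period), c("P1", "P2"))
  expect_equal(span$p_inc[span$period == "P1"], 0.2)
  expect_equal(span$p_inc[span$period == "P2"], 0.4)

  expect_error(average_periods(waves[0, ]), "empty")
})

test_that("subsets gate on five independent studies and partition records", {
  # 4 studies of one indicator: ineligible
  r4 <- make_records(4, indicator = "frequency")
  s4 <- build_subsets(r4)
  expect_false(s4[["frequency/total"]]$eligible)

  # 6 overall-use studies, 2 contributing an extra stratified row each:
  # total-sample subset holds 8 estimates from 6 studies
  r6 <- make_records(6)
  extra <- rbind(
    make_records(1, study_id = r6$study_id[1], stratum = "women"),
    make_records(1, study_id = r6$study_id[2], stratum = "men"))
  extra$estimate_id <- paste0(extra$study_id, "_", extra$stratum)
  all <- rbind(r6, extra)
  ss <- build_subsets(all)
  expect_equal(ss[["overall_use/total"]]$n_estimates, 8)
  expect_equal(ss[["overall_use/total"]]$n_studies, 6)
  expect_true(ss[["overall_use/total"]]$eligible)
  expect_false(ss[["overall_use/women"]]$eligible)  # 1 study only

  # empty input
  expect_equal(build_subsets(make_records(0)), list())

  # partition: each record appears exactly once in its (indicator, stratum)
  mixed <- rbind(make_records(3, indicator = "quantity"),
                 make_records(3, study_id = sprintf("hed_%d", 1:3),
                              indicator = "HED"))
  sm <- build_subsets(mixed)
  ids <- unlist(lapply(sm, function(s) s$records$estimate_id))
  expect_setequal(ids, mixed$estimate_id)
  expect_equal(anyDuplicated(ids), 0)
})
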