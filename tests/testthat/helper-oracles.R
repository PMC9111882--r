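# Independent oracles and fixture builders used across the suite.

# Brute-force REML for the intercept-only model: two-stage grid search on
# the restricted log-likelihood over tau2 in [0, 1], final resolution 1e-6.
# Uses only the closed-form likelihood below -- independent of the
# Fisher-scoring path in the package.
reml_grid_oracle <- function(y, vi, upper = 1) {
  rll <- function(t2) {
    vapply(t2, function(t) {
      w <- 1 / (vi + t)
      mu <- sum(w * y) / sum(w)
      -0.5 * (sum(log(vi + t)) + log(sum(w)) + sum(w * (y - mu)^2))
    }, numeric(1))
  }
  coarse <- seq(0, upper, by = 1e-3)
  t0 <- coarse[which.max(rll(coarse))]
  fine <- seq(max(0, t0 - 2e-3), min(upper, t0 + 2e-3), by = 1e-6)
  tau2 <- fine[which.max(rll(fine))]
  w <- 1 / (vi + tau2)
  list(tau2 = tau2, pooled = sum(w * y) / sum(w),
       se_pooled = 1 / sqrt(sum(w)))
}

# Minimal valid study-record data frame (all schema columns present).
make_records <- function(n_rows = 3,
                         study_id = sprintf("study_%02d", seq_len(n_rows)),
                         n_drinkers = rep(500, n_rows),
                         n_inc = rep(100, n_rows),
                         n_dec = rep(150, n_rows),
                         indicator = "overall_use",
                         stratum = "total", ...) {
  if (n_rows == 0) {
    out <- make_records(1)[0, ]
    return(out)
  }
  out <- data.frame(
    study_id = study_id,
    estimate_id = paste0(study_id, "_e1"),
    country = "DE", sub_region = "Western", period = "P1",
    design = "cross-sectional", population = "general",
    stratum = stratum, indicator = indicator,
    n_total = ifelse(is.na(n_drinkers), 1000, n_drinkers + 100),
    weighted = FALSE, age_profile = "general",
    convenience_sample = FALSE,
    prop_drinkers = NA_real_, prop_women = NA_real_,
    n_drinkers = n_drinkers, n_inc = n_inc, n_dec = n_dec,
    n_start = NA_real_, n_stop = NA_real_,
    p_before = NA_real_, p_during = NA_real_,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Write records to a temporary CSV and return the path.
write_study_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write_studies(records, path)
  path
}

# Small heterogeneous effects table with a fixed layout (deterministic).
toy_effects <- function() {
  data.frame(
    estimate_id = paste0("e", 1:7),
    study_id = paste0("s", 1:7),
    d = c(-0.12, -0.05, 0.02, -0.08, -0.03, -0.15, 0.04),
    se = c(0.030, 0.050, 0.040, 0.020, 0.060, 0.035, 0.045),
    stringsAsFactors = FALSE
  )
}
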