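# Effect sizes for paired urban/non-urban summaries. The urban arm is always
# the numerator, so positive values mean a larger urban estimate.

effect_size_row <- function(record, measure, yi, vi) {
  data.frame(
    record_id = record$record_id, study_id = record$study_id,
    population_pair_id = record$population_pair_id, species = record$species,
    trait = record$trait, season = as.character(record$season),
    measure = measure, yi = yi, vi = vi,
    effective_n = effective_sample_size(record$n_urban, record$n_nonurban),
    publication_year = record$publication_year,
    stringsAsFactors = FALSE)
}

check_arms <- function(record, need_means = TRUE, need_sds = TRUE, need_n2 = TRUE) {
  id <- record$record_id
  if (need_means && (record$mean_urban <= 0 || record$mean_nonurban <= 0))
    stop("non-positive mean in record ", id)
  if (need_sds && (record$sd_urban <= 0 || record$sd_nonurban <= 0))
    stop("non-positive SD in record ", id)
  if (need_n2 && (record$n_urban < 2 || record$n_nonurban < 2))
    stop("per-arm n < 2 in record ", id)
}

#' Two-group effective sample size
#'
#' `4 n1 n2 / (n1 + n2)`, the harmonic-mean-based effective n used as the
#' precision proxy in small-study publication-bias moderators.
#'
#' @param n_urban,n_nonurban Per-arm sample sizes.
#' @return Effective sample size.
#' @export
effective_sample_size <- function(n_urban, n_nonurban) {
  4 * n_urban * n_nonurban / (n_urban + n_nonurban)
}

#' Log response ratio (lnRR) for one comparison
#'
#' `yi = ln(mean_urban / mean_nonurban)` with sampling variance
#' `sd_u^2/(n_u mean_u^2) + sd_n^2/(n_n mean_n^2)`. The plain log-ratio is
#' used (no small-sample bias-correction term); set `bias_correct = TRUE`
#' for the Taylor-expansion corrected variant.
#'
#' @param record One comparison record (single-row `data.frame` or list).
#' @param bias_correct Add the second-order small-sample correction to `yi`
#'   and `vi`.
#' @return One effect-size row (`data.frame`): ids, `measure`, `yi`, `vi`,
#'   `effective_n`, `publication_year`.
#' @export
compute_lnRR <- function(record, bias_correct = FALSE) {
  check_arms(record, need_sds = FALSE, need_n2 = FALSE)
  cv2_u <- (record$sd_urban / record$mean_urban)^2
  cv2_n <- (record$sd_nonurban / record$mean_nonurban)^2
  yi <- log(record$mean_urban / record$mean_nonurban)
  vi <- cv2_u / record$n_urban + cv2_n / record$n_nonurban
  if (bias_correct) {
    yi <- yi + 0.5 * (cv2_u / record$n_urban - cv2_n / record$n_nonurban)
    vi <- vi + 0.5 * (cv2_u^2 / record$n_urban^2 + cv2_n^2 / record$n_nonurban^2)
  }
  effect_size_row(record, "lnRR", yi, vi)
}

#' Log coefficient of variation ratio (lnCVR) for one comparison
#'
#' With `CV = sd/mean`:
#' `yi = ln(CV_u/CV_n) + 1/(2(n_u-1)) - 1/(2(n_n-1))` and
#' `vi = sd_u^2/(n_u mean_u^2) + 1/(2(n_u-1)) + sd_n^2/(n_n mean_n^2) +
#' 1/(2(n_n-1))`. The mean-variance correlation term is treated as zero by
#' default; supply `mvcor` to include it (subtracts
#' `2 rho [cv/sqrt(n)] ...` cross terms per arm).
#'
#' @param record One comparison record.
#' @param mvcor Optional assumed correlation between log mean and log SD
#'   within an arm (default 0).
#' @return One effect-size row.
#' @export
compute_lnCVR <- function(record, mvcor = 0) {
  check_arms(record)
  cv_u <- record$sd_urban / record$mean_urban
  cv_n <- record$sd_nonurban / record$mean_nonurban
  cu <- 1 / (2 * (record$n_urban - 1))
  cn <- 1 / (2 * (record$n_nonurban - 1))
  yi <- log(cv_u / cv_n) + cu - cn
  vi <- cv_u^2 / record$n_urban + cu + cv_n^2 / record$n_nonurban + cn -
    2 * mvcor * (sqrt(cv_u^2 / record$n_urban * cu) +
                 sqrt(cv_n^2 / record$n_nonurban * cn))
  effect_size_row(record, "lnCVR", yi, vi)
}

#' Log total variation ratio (lnVR) for one comparison
#'
#' `yi = ln(sd_u/sd_n) + 1/(2(n_u-1)) - 1/(2(n_n-1))`;
#' `vi = 1/(2(n_u-1)) + 1/(2(n_n-1))`.
#'
#' @param record One comparison record.
#' @return One effect-size row.
#' @export
compute_lnVR <- function(record) {
  check_arms(record, need_means = FALSE)
  cu <- 1 / (2 * (record$n_urban - 1))
  cn <- 1 / (2 * (record$n_nonurban - 1))
  effect_size_row(record, "lnVR", log(record$sd_urban / record$sd_nonurban) + cu - cn,
                  cu + cn)
}

#' Heteroscedastic standardised mean difference (SMDH) for one comparison
#'
#' Bonett-type standardised mean difference allowing unequal population
#' variances: `d = (mean_u - mean_n) / s` with `s = sqrt((sd_u^2 +
#' sd_n^2)/2)`, multiplied by the exact small-sample bias correction
#' `J(m) = Gamma(m/2) / (sqrt(m/2) Gamma((m-1)/2))` at `m = n_u + n_n - 2`
#' (approximately `1 - 3/(4m - 1)`); the sampling variance is the matching
#' heteroscedastic expression evaluated at the corrected estimate.
#'
#' @param record One comparison record.
#' @return One effect-size row.
#' @export
compute_SMDH <- function(record) {
  check_arms(record, need_means = FALSE)
  nu <- record$n_urban; nn <- record$n_nonurban
  s2 <- (record$sd_urban^2 + record$sd_nonurban^2) / 2
  m <- nu + nn - 2
  cm <- exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
  yi <- cm * (record$mean_urban - record$mean_nonurban) / sqrt(s2)
  vi <- yi^2 * (record$sd_urban^4 / (nu - 1) + record$sd_nonurban^4 / (nn - 1)) /
    (8 * s2^2) +
    (record$sd_urban^2 / (nu - 1) + record$sd_nonurban^2 / (nn - 1)) / s2
  effect_size_row(record, "SMDH", yi, vi)
}

#' Compute effect sizes for a whole comparison table
#'
#' Vectorised driver over [compute_lnRR()], [compute_lnCVR()],
#' [compute_lnVR()] and [compute_SMDH()].
#'
#' @param records Comparison `data.frame` (already filtered; see
#'   [apply_exclusions()]).
#' @param measure One of `"lnRR"`, `"lnCVR"`, `"lnVR"`, `"SMDH"`.
#' @param ... Passed to the per-record function.
#' @return Effect-size `data.frame`, one row per record.
#' @export
compute_effect_sizes <- function(records, measure = c("lnRR", "lnCVR", "lnVR", "SMDH"),
                                 ...) {
  measure <- match.arg(measure)
  fun <- switch(measure, lnRR = compute_lnRR, lnCVR = compute_lnCVR,
                lnVR = compute_lnVR, SMDH = compute_SMDH)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    fun(records[i, , drop = FALSE], ...)
  }))
  rownames(out) <- NULL
  out
}

#' Arm-level (lnSD, lnMean) rows for the arm-based variance model
#'
#' Each comparison yields two rows, one per habitat, with
#' `ln_sd = ln(sd)`, `ln_mean = ln(mean)` and sampling variance
#' `v_ln_sd = 1/(2(n - 1))`.
#'
#' @param record One comparison record.
#' @return Two-row `data.frame` with columns `record_id`, `study_id`,
#'   `population_pair_id`, `species`, `trait`, `habitat`, `ln_sd`,
#'   `ln_mean`, `v_ln_sd`, `n`.
#' @export
arm_rows <- function(record) {
  check_arms(record)
  data.frame(
    record_id = rep(record$record_id, 2), study_id = rep(record$study_id, 2),
    population_pair_id = rep(record$population_pair_id, 2),
    species = rep(record$species, 2), trait = rep(record$trait, 2),
    habitat = c("urban", "nonurban"),
    ln_sd = log(c(record$sd_urban, record$sd_nonurban)),
    ln_mean = log(c(record$mean_urban, record$mean_nonurban)),
    v_ln_sd = 1 / (2 * (c(record$n_urban, record$n_nonurban) - 1)),
    n = c(record$n_urban, record$n_nonurban),
    stringsAsFactors = FALSE)
}

#' Arm-level rows for a whole comparison table
#'
#' @param records Comparison `data.frame`.
#' @return `data.frame` with two rows per record; see [arm_rows()].
#' @export
compute_arm_rows <- function(records) {
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    arm_rows(records[i, , drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Back-transform a log-ratio to a percent difference
#'
#' `100 * (exp(|yi|) - 1)`, the magnitude of the implied percent change,
#' with the sign of `yi` reported alongside.
#'
#' @param yi A log-ratio effect size (lnRR, lnCVR or lnVR scale).
#' @return A list with `percent` (magnitude, in %) and `direction`
#'   (+1, 0 or -1, the sign of `yi`).
#' @export
percent_difference <- function(yi) {
  stopifnot(is.finite(yi))
  list(percent = 100 * (exp(abs(yi)) - 1), direction = sign(yi))
}

#' Write an effect-size table to CSV
#'
#' @param effects Effect-size `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE, na = "")
  invisible(path)
}
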