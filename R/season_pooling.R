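# Pooling of per-breeding-season summaries into among-season means and
# variances. The among-season variance is the n-weighted sum of the
# within-season variances plus the n-weighted variance of the season means
# about the pooled mean.

#' Pool per-season summaries into an among-season mean and variance
#'
#' Given g seasons with mean `xbar_i`, variance `s2_i` and sample size
#' `n_i` (N = sum of `n_i`):
#' \deqn{\bar{x} = \sum_i \bar{x}_i n_i / N}
#' \deqn{S^2 = \sum_i (n_i/N) s_i^2 + \sum_i (n_i/N) (\bar{x}_i - \bar{x})^2}
#' When the `s2_i` are population variances (denominator `n_i`) of raw
#' samples, `S^2` equals the population variance of the concatenated raw
#' samples exactly; for sample variances (denominator `n_i - 1`, the usual
#' literature convention) it is the corresponding close approximation.
#'
#' @param seasons A `data.frame` (or list) with columns/elements `mean`,
#'   `var` and `n`, one entry per season.
#' @return A list with `mean`, `var` (among-season variance, >= 0), `n`
#'   (total N) and `g` (number of seasons).
#' @export
pool_seasons <- function(seasons) {
  seasons <- as.data.frame(seasons)
  if (nrow(seasons) == 0) stop("no seasons to pool")
  stopifnot(all(c("mean", "var", "n") %in% names(seasons)))
  if (any(seasons$n < 2)) stop("per-season n must be at least 2")
  if (any(seasons$var < 0)) stop("negative per-season variance")
  N <- sum(seasons$n)
  w <- seasons$n / N
  xbar <- sum(w * seasons$mean)
  s2 <- sum(w * seasons$var) + sum(w * (seasons$mean - xbar)^2)
  list(mean = xbar, var = s2, n = N, g = nrow(seasons))
}

#' Build the inter-annual (among-season) comparison dataset
#'
#' Groups single-season records by (study, population pair, trait), checks
#' that the urban and non-urban arms cover the same seasons, and pools each
#' arm with [pool_seasons()] into one `season = "pooled"` record per group
#' (SD re-enters as `sqrt(S^2)`, n as the summed N). Records already
#' reported as multi-season in the source (`n_seasons > 1`) pass through
#' unchanged. Groups whose arms were not sampled in the same seasons are
#' skipped with a warning, mirroring the matched-season inclusion
#' criterion.
#'
#' @param records Comparison `data.frame`.
#' @param min_seasons Minimum number of matched seasons for a group to be
#'   pooled (default 2; single-season groups are not inter-annual
#'   information).
#' @return Comparison `data.frame` of pooled plus passthrough multi-season
#'   records, with `season = "pooled"` and `n_seasons = g` on pooled rows.
#' @export
build_interannual_dataset <- function(records, min_seasons = 2) {
  single <- split_intra_annual(records)
  passthrough <- records[records$season == "pooled" |
                           (!is.na(records$n_seasons) & records$n_seasons > 1), ,
                         drop = FALSE]
  key <- interaction(single$study_id, single$population_pair_id, single$trait,
                     drop = TRUE)
  pooled <- lapply(split(single, key), function(grp) {
    if (nrow(grp) < min_seasons) return(NULL)
    if (anyDuplicated(grp$season)) {
      warning("duplicate seasons within group ", grp$study_id[1], "/",
              grp$trait[1], "; group skipped")
      return(NULL)
    }
    pu <- pool_seasons(data.frame(mean = grp$mean_urban, var = grp$sd_urban^2,
                                  n = grp$n_urban))
    pn <- pool_seasons(data.frame(mean = grp$mean_nonurban, var = grp$sd_nonurban^2,
                                  n = grp$n_nonurban))
    out <- grp[1, , drop = FALSE]
    out$record_id <- paste0(grp$study_id[1], "_", grp$population_pair_id[1], "_",
                            grp$trait[1], "_pooled")
    out$season <- "pooled"
    out$n_seasons <- nrow(grp)
    out$mean_urban <- pu$mean; out$sd_urban <- sqrt(pu$var); out$n_urban <- pu$n
    out$mean_nonurban <- pn$mean; out$sd_nonurban <- sqrt(pn$var)
    out$n_nonurban <- pn$n
    out
  })
  out <- rbind(passthrough, do.call(rbind, pooled))
  rownames(out) <- NULL
  out
}

#' Extract the intra-annual (single-season) comparisons
#'
#' @param records Comparison `data.frame`.
#' @return The subset with a single-season `season` (not `"pooled"`, and
#'   not flagged as multi-season in the source).
#' @export
split_intra_annual <- function(records) {
  keep <- records$season != "pooled" &
    (is.na(records$n_seasons) | records$n_seasons == 1)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
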