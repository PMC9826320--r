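# Pipeline orchestration: a registry of the ten standard models (intercept
# and per-trait means for lnRR/lnCVR, intra-/inter-annual subsets, spatial
# meta-regression, SMDH/lnVR sensitivity models and the arm-based lnSD
# model), a single-config driver, and a reproduction mode for a deposited
# dataset.

#' Registry of the standard meta-models
#'
#' @return `data.frame` describing models 1-10: response measure, fixed
#'   part, data subset and type.
#' @export
model_registry <- function() {
  data.frame(
    model = 1:10,
    measure = c("lnRR", "lnRR", "lnCVR", "lnCVR", "lnCVR", "lnCVR", "lnCVR",
                "SMDH", "lnVR", "lnSD"),
    fixed = c("intercept", "trait", "intercept", "trait", "trait", "trait",
              "trait+spatial", "trait", "trait", "arm"),
    subset = c("all", "all", "all", "all", "intra_annual", "inter_annual",
               "georeferenced", "all", "all", "per_trait"),
    description = c(
      "overall mean difference (lnRR), univariate",
      "mean difference per trait (lnRR), trivariate",
      "overall variation difference (lnCVR), univariate",
      "variation difference per trait (lnCVR), trivariate",
      "intra-annual variation difference (lnCVR)",
      "inter-annual variation difference (lnCVR, pooled seasons)",
      "lnCVR meta-regression on urban-index and heterogeneity differences",
      "sensitivity: heteroscedastic SMD per trait",
      "sensitivity: total variation ratio per trait",
      "arm-based lnSD model per trait"),
    stringsAsFactors = FALSE)
}

fit_to_list <- function(fit) {
  list(beta = fit$beta, sigma2 = as.list(fit$sigma2),
       correlations = if (is.matrix(fit$correlations))
         as.data.frame(fit$correlations) else as.list(fit$correlations),
       logLik = fit$logLik, AIC = fit$AIC, k = fit$k, method = fit$method,
       convergence = fit$convergence[c("converged", "message", "starts_tried")])
}

fit_one_model <- function(id, records, A, method = "REML", moderators = NULL,
                          control = list()) {
  reg <- model_registry()
  row <- reg[reg$model == id, ]
  if (nrow(row) == 0) stop("unknown model id: ", id)
  dat <- switch(row$subset,
                all = records,
                intra_annual = split_intra_annual(records),
                inter_annual = build_interannual_dataset(records),
                georeferenced = records,
                per_trait = records)
  if (row$measure == "lnSD") {
    arms <- compute_arm_rows(dat)
    fits <- lapply(split(arms, arms$trait), function(a) {
      fit_arm_based(a, A = A, method = method, control = control)
    })
    return(fits)
  }
  effects <- compute_effect_sizes(dat, row$measure)
  if (row$fixed == "trait+spatial") {
    if (is.null(moderators))
      stop("model 7 needs spatial moderators (d_urban_index, d_heterogeneity)")
    effects <- merge(effects, moderators, by = "population_pair_id")
    spec <- meta_spec(fixed = "trait",
                      moderators = c("d_urban_index", "d_heterogeneity"),
                      vcv_structure = "diagonal", method = method)
  } else {
    spec <- meta_spec(fixed = row$fixed,
                      vcv_structure = if (row$fixed == "trait") "diagonal"
                      else "single_var_zero_cov",
                      obs_by_trait = row$fixed == "trait", method = method)
  }
  if (is.null(A)) spec$random <- setdiff(spec$random, "phylogeny")
  fit_meta(effects, spec, A = A, control = control)
}

#' Run the full meta-analytic pipeline from one configuration
#'
#' Stages, in dependency order: load (or simulate) the comparison table,
#' apply exclusion filters (logged), compute effect sizes, fit the
#' requested models, and write per-model JSON fits plus a temporal-scale
#' summary table to the output directory.
#'
#' @param config A list (or path to a JSON/YAML file holding one) with
#'   elements: `comparisons` (CSV path) or `simulate = TRUE`, `tree`
#'   (Newick path, optional), `models` (integer vector, default 1:6),
#'   `outdir`, `seed`, `method` (`"REML"`/`"ML"`), optional `moderators`
#'   (CSV of pair-level spatial moderators at one radius for model 7), and
#'   optional `sim_params` overrides.
#' @return List of fitted models (named `model_<id>`), with the exclusion
#'   log and file paths as attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  outdir <- config$outdir %||% tempfile("urbanvar_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  method <- config$method %||% "REML"
  models <- config$models %||% 1:6

  if (7 %in% models && is.null(config$moderators) && !isTRUE(config$simulate))
    stop("configuration error: model 7 requested without spatial moderators")

  if (isTRUE(config$simulate)) {
    params <- do.call(sim_params, config$sim_params %||% list())
    sim <- simulate_dataset(params, seed = seed)
    records <- sim$records
    A <- sim$A
  } else {
    if (is.null(config$comparisons)) stop("config needs 'comparisons' or simulate=TRUE")
    records <- read_comparisons(config$comparisons)
    A <- NULL
  }
  if (!is.null(config$tree)) {
    tree <- read_newick(file = config$tree)
    A <- phylo_correlation(grafen_lengths(tree))
  }
  moderators <- if (!is.null(config$moderators))
    utils::read.csv(config$moderators, stringsAsFactors = FALSE) else NULL

  filtered <- apply_exclusions(records)
  write_exclusion_log(filtered$log, file.path(outdir, "exclusions.json"))
  write_comparisons(filtered$kept, file.path(outdir, "comparisons_filtered.csv"))

  fits <- list()
  for (id in models) {
    fit <- fit_one_model(id, filtered$kept, A, method = method,
                         moderators = moderators,
                         control = config$control %||% list())
    fits[[paste0("model_", id)]] <- fit
    out <- if (inherits(fit, "meta_fit")) fit_to_list(fit) else
      lapply(fit, fit_to_list)
    jsonlite::write_json(out, file.path(outdir, sprintf("model_%02d.json", id)),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (all(c(4, 5, 6) %in% models)) {
    tab <- render_temporal_table(fits$model_4, fits$model_5, fits$model_6)
    utils::write.csv(tab, file.path(outdir, "temporal_scale_summary.csv"),
                     row.names = FALSE)
  }
  attr(fits, "exclusion_log") <- filtered$log
  attr(fits, "outdir") <- outdir
  attr(fits, "seed") <- seed
  fits
}

read_config <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Summary table of variation differences by temporal scale
#'
#' Renders per-trait lnCVR estimates with 95% CIs for the overall,
#' intra-annual and inter-annual fits as one table (rows = temporal scale,
#' columns = traits).
#'
#' @param fit_overall,fit_intra,fit_inter `meta_fit` objects from the
#'   per-trait lnCVR models on the full, single-season and pooled-season
#'   datasets.
#' @return `data.frame` with formatted `estimate [ci_lower, ci_upper]`
#'   cells and a `k` column.
#' @export
render_temporal_table <- function(fit_overall, fit_intra, fit_inter) {
  fmt_row <- function(fit) {
    b <- fit$beta
    cells <- sprintf("%.3f [%.3f, %.3f]", b$estimate, b$ci_lower, b$ci_upper)
    names(cells) <- b$term
    c(cells, k = as.character(fit$k))
  }
  rows <- rbind(overall = fmt_row(fit_overall),
                intra_annual = fmt_row(fit_intra),
                inter_annual = fmt_row(fit_inter))
  data.frame(temporal_scale = rownames(rows), rows, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Re-run the standard models on a deposited dataset
#'
#' Runs models 1-6 and 8-10 on a user-supplied comparison table and tree
#' and reports fitted values side by side with reference estimates (when
#' given), with absolute differences; without references the printed
#' column reads `"n/a"`.
#'
#' @param comparisons_csv Path to the comparison table.
#' @param tree_path Path to the Newick tree (models needing the phylogeny
#'   are skipped with a warning when absent).
#' @param reference Optional `data.frame` with columns `label` and `value`
#'   of published point estimates to compare against (e.g. the overall
#'   lnRR intercept or the per-trait lnCVR means).
#' @param models Model ids to run (default `c(1:6, 8:10)`).
#' @param control Optimiser control.
#' @return List with `fits` and `report` (`data.frame`: label, fitted,
#'   reference, abs_difference).
#' @export
reproduce_analysis <- function(comparisons_csv, tree_path = NULL,
                               reference = NULL, models = c(1:6, 8:10),
                               control = list()) {
  records <- apply_exclusions(read_comparisons(comparisons_csv))$kept
  A <- NULL
  if (!is.null(tree_path)) {
    A <- phylo_correlation(grafen_lengths(read_newick(file = tree_path)))
  } else {
    warning("no tree supplied; fitting without the phylogenetic term")
  }
  fits <- list()
  for (id in models) {
    fits[[paste0("model_", id)]] <- fit_one_model(id, records, A,
                                                  control = control)
  }
  labels <- list()
  grab <- function(fit, term) {
    if (is.null(fit)) return(NA_real_)
    fit$beta$estimate[fit$beta$term == term]
  }
  if (!is.null(fits$model_1))
    labels[["lnRR_overall"]] <- grab(fits$model_1, "intercept")
  if (!is.null(fits$model_3))
    labels[["lnCVR_overall"]] <- grab(fits$model_3, "intercept")
  if (!is.null(fits$model_4))
    labels[["lnCVR_laying_date"]] <- grab(fits$model_4, "laying_date")
  if (!is.null(fits$model_5))
    labels[["lnCVR_laying_date_intra"]] <- grab(fits$model_5, "laying_date")
  if (!is.null(fits$model_9))
    labels[["lnVR_laying_date"]] <- grab(fits$model_9, "laying_date")
  if (!is.null(fits$model_10))
    labels[["lnSD_urban_effect_laying_date"]] <-
      grab(fits$model_10$laying_date, "habitat_urban")
  fitted <- unlist(labels)
  report <- data.frame(label = names(fitted), fitted = unname(fitted),
                       reference = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    idx <- match(report$label, reference$label)
    report$reference <- reference$value[idx]
  }
  report$abs_difference <- abs(report$fitted - report$reference)
  report$reference_printed <- ifelse(is.na(report$reference), "n/a",
                                     format(report$reference))
  list(fits = fits, report = report)
}
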