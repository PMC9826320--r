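# Arm-based model of the log phenotypic standard deviation: instead of a
# contrast per comparison, each habitat arm contributes one lnSD row,
# regressed on habitat and (log) mean, with arms within a study correlated.

#' Fit the arm-based lnSD model for one trait
#'
#' Models `ln_sd ~ beta0 + beta1 * urban + beta2 * ln_mean` with known
#' sampling variances `1/(2(n - 1))`, random intercepts for study,
#' population pair, phylogeny (when `A` supplied) and species, plus an
#' effect-size-level random term whose entries within a study share an
#' estimated correlation (arms from the same study are not independent).
#' A `beta1` away from zero indicates a habitat difference in phenotypic
#' variation; `beta2` is the mean-variance (Taylor's-law-style) slope.
#'
#' @param arms Arm-level `data.frame` from [compute_arm_rows()], restricted
#'   to one trait, both habitats present, `>= 2` studies.
#' @param A Optional species correlation matrix.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control Passed to the optimiser (see [fit_meta()]).
#' @return A `meta_fit` with coefficient rows `intercept`,
#'   `habitat_urban`, `ln_mean`; `correlations` holds the within-study
#'   arm correlation.
#' @export
fit_arm_based <- function(arms, A = NULL, method = c("REML", "ML"),
                          control = list()) {
  method <- match.arg(method)
  if (length(unique(arms$trait)) != 1)
    stop("fit one trait at a time")
  if (length(unique(arms$habitat)) < 2)
    stop("both habitats must be represented")
  if (length(unique(arms$study_id)) < 2)
    stop("need at least 2 studies")
  n <- nrow(arms)
  X <- cbind(intercept = 1,
             habitat_urban = as.numeric(arms$habitat == "urban"),
             ln_mean = arms$ln_mean)

  terms <- list()
  par_names <- character()
  pos <- 0
  add_par <- function(nm) {
    par_names <<- c(par_names, nm)
    pos <<- pos + length(nm)
    seq.int(pos - length(nm) + 1, pos)
  }
  terms$study <- list(type = "iid",
                      C = outer(arms$study_id, arms$study_id, "==") * 1,
                      idx = add_par("sigma2_study"))
  if ("population_pair_id" %in% names(arms)) {
    terms$population <- list(type = "iid",
                             C = outer(arms$population_pair_id,
                                       arms$population_pair_id, "==") * 1,
                             idx = add_par("sigma2_pop"))
  }
  if (!is.null(A)) {
    missing_sp <- setdiff(unique(arms$species), rownames(A))
    if (length(missing_sp) > 0)
      stop("species missing from A: ", paste(missing_sp, collapse = ", "))
    C <- A[arms$species, arms$species]
    dimnames(C) <- NULL
    terms$phylogeny <- list(type = "iid", C = C, idx = add_par("sigma2_phylo"))
  }
  terms$species <- list(type = "iid",
                        C = outer(arms$species, arms$species, "==") * 1,
                        idx = add_par("sigma2_species"))
  # effect-size-level term, compound-symmetric within study
  S <- outer(arms$study_id, arms$study_id, "==") * 1
  diag(S) <- 0
  max_block <- max(table(arms$study_id))
  lo <- max(-1 / (max_block - 1) + 1e-6, -0.99)
  terms$effect_size <- list(type = "arm_cs", S = S, lo = lo,
                            idx = add_par(c("sigma2_es", "z_rho")))

  design <- structure(list(y = arms$ln_sd, X = X, vi = arms$v_ln_sd,
                           terms = terms, par_names = par_names, n_par = pos,
                           traits = unique(arms$trait), m = 1,
                           spec = list(method = method)),
                      class = "meta_design")

  reml <- method == "REML"
  best <- optimise_design(design, reml, control)
  theta <- best$par
  ll <- profile_loglik(theta, design, reml)

  sigma2 <- c(study = exp(theta[terms$study$idx]),
              if (!is.null(terms$population))
                c(population = exp(theta[terms$population$idx])),
              if (!is.null(terms$phylogeny))
                c(phylogeny = exp(theta[terms$phylogeny$idx])),
              species = exp(theta[terms$species$idx]),
              effect_size = exp(theta[terms$effect_size$idx[1]]))
  rho <- bounded_rho(theta[terms$effect_size$idx[2]], lo, 1 - 1e-6)

  se <- sqrt(diag(ll$vcov_beta))
  ci <- wald_ci(ll$beta, se)
  beta_tab <- data.frame(term = colnames(X), estimate = ll$beta, se = se,
                         ci_lower = ci$lower, ci_upper = ci$upper,
                         stringsAsFactors = FALSE)
  aic <- if (reml) -2 * ll$ll + 2 * design$n_par else
    -2 * ll$ll + 2 * (design$n_par + ncol(X))
  structure(list(beta = beta_tab, sigma2 = sigma2,
                 correlations = c(within_study_arm = rho),
                 logLik = ll$ll, AIC = aic, k = n, method = method,
                 design = design, theta = theta, vcov_beta = ll$vcov_beta,
                 convergence = list(converged = best$converged,
                                    message = best$message,
                                    starts_tried = best$starts_tried,
                                    objective = best$objective)),
            class = "meta_fit")
}
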