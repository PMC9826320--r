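test_that("marginal covariance assembly matches a brute-force oracle", {
  A <- four_species_A()
  eff <- random_small_effects(8, seed = 1)
  spec <- meta_spec(fixed = "trait", vcv_structure = "unstructured")
  design <- build_design(eff, spec, A)
  set.seed(2)
  for (rep in 1:10) {
    theta <- rnorm(design$n_par)
    V <- urbanvar:::assemble_V(theta, design)
    # reconstruct the same parameters into explicit component matrices
    traits <- design$traits
    obs_idx <- design$terms$observation$idx
    st <- design$terms$study_trait
    Sigma <- urbanvar:::study_trait_sigma(theta[st$idx], st$structure, st$m)
    Vb <- brute_force_V(eff, exp(theta[obs_idx]), Sigma,
                        exp(theta[design$terms$population$idx]),
                        exp(theta[design$terms$phylogeny$idx]),
                        exp(theta[design$terms$species$idx]), A)
    expect_equal(V, Vb, tolerance = 1e-10)
  }
})

test_that("profiled logLik equals direct multivariate-normal evaluation", {
  A <- four_species_A()
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(5:8, 1)
    eff <- random_small_effects(k, seed = 100 + rep)
    spec <- meta_spec(fixed = "intercept", vcv_structure = "compound_symmetric",
                      obs_by_trait = FALSE)
    design <- build_design(eff, spec, A)
    theta <- rnorm(design$n_par)
    V <- urbanvar:::assemble_V(theta, design)
    for (reml in c(FALSE, TRUE)) {
      mine <- urbanvar:::profile_loglik(theta, design, reml)$ll
      oracle <- brute_force_loglik(eff$yi, design$X, V, reml)
      expect_equal(mine, as.numeric(oracle), tolerance = 1e-8)
    }
  }
})

test_that("balanced-case REML matches the closed-form solution", {
  set.seed(4)
  for (rep in 1:5) {
    k <- sample(15:40, 1)
    v <- runif(1, 0.01, 0.2)
    y <- rnorm(k, 0.3, sqrt(runif(1, 0.05, 0.5)))
    eff <- random_small_effects(k, seed = rep)
    eff$yi <- y; eff$vi <- v
    fit <- fit_meta(eff, meta_spec(fixed = "intercept", random = "observation",
                                   obs_by_trait = FALSE))
    expect_equal(fit$beta$estimate, mean(y), tolerance = 1e-6)
    expect_equal(unname(fit$sigma2), max(0, var(y) - v), tolerance = 1e-5)
  }
})

test_that("with variance components forced to zero the GLS limit is the inverse-variance weighted mean", {
  eff <- random_small_effects(20, seed = 9)
  spec <- meta_spec(fixed = "intercept", random = "observation",
                    obs_by_trait = FALSE)
  design <- build_design(eff, spec)
  out <- urbanvar:::profile_loglik(-50, design, reml = FALSE)
  expect_equal(out$beta, sum(eff$yi / eff$vi) / sum(1 / eff$vi),
               tolerance = 1e-8)
})

test_that("full multilevel REML fit agrees with metafor::rma.mv", {
  skip_if_not_installed("metafor")
  sim <- simulate_dataset(sim_params(n_studies = 25, n_pairs = 20,
                                     n_species = 12), seed = 13)
  kept <- apply_exclusions(sim$records)$kept
  eff <- compute_effect_sizes(kept, "lnCVR")
  A <- sim$A[unique(eff$species), unique(eff$species)]
  fit <- fit_meta(eff, meta_spec(fixed = "trait", vcv_structure = "diagonal"),
                  A = A, control = list(n_starts = 2))
  eff$obs <- seq_len(nrow(eff))
  eff$species2 <- eff$species
  mf <- metafor::rma.mv(yi, vi, mods = ~ 0 + trait,
                        random = list(~ trait | study_id,
                                      ~ 1 | population_pair_id,
                                      ~ 1 | species, ~ 1 | species2,
                                      ~ trait | obs),
                        struct = c("DIAG", "DIAG"), R = list(species = A),
                        data = eff, method = "REML",
                        control = list(optimizer = "optim",
                                       optmethod = "BFGS"))
  ord <- match(sort(unique(eff$trait)), sub("trait", "", rownames(mf$beta)))
  expect_equal(fit$beta$estimate, as.numeric(mf$beta)[ord], tolerance = 5e-4)
  expect_equal(fit$beta$se, mf$se[ord], tolerance = 5e-3)
  expect_equal(unname(fit$sigma2[paste0("obs_", sort(unique(eff$trait)))]),
               mf$gamma2, tolerance = 1e-3)
})

test_that("REML is invariant to a constant shift of the response", {
  eff <- random_small_effects(40, seed = 17)
  spec <- meta_spec(fixed = "intercept", vcv_structure = "compound_symmetric",
                    obs_by_trait = FALSE)
  A <- four_species_A()
  f1 <- fit_meta(eff, spec, A, control = list(n_starts = 1))
  eff2 <- eff
  eff2$yi <- eff$yi + 5
  f2 <- fit_meta(eff2, spec, A, control = list(n_starts = 1))
  # comparisons across two optimiser runs: near-boundary components carry
  # small numerical noise, so absolute tolerances
  expect_lt(abs(f2$beta$estimate - (f1$beta$estimate + 5)), 1e-3)
  expect_lt(max(abs(f2$sigma2 - f1$sigma2)), 5e-3)
  expect_lt(abs(f2$logLik - f1$logLik), 5e-3)
})

test_that("AIC is invariant to row permutation", {
  eff <- random_small_effects(30, seed = 19)
  spec <- meta_spec(fixed = "trait", vcv_structure = "diagonal", method = "ML")
  A <- four_species_A()
  f1 <- fit_meta(eff, spec, A, control = list(n_starts = 1))
  set.seed(1)
  f2 <- fit_meta(eff[sample(nrow(eff)), ], spec, A, control = list(n_starts = 1))
  expect_equal(f2$AIC, f1$AIC, tolerance = 1e-5)
})

test_that("structure comparison respects likelihood nesting and parameter counts", {
  sim <- simulate_dataset(sim_params(n_studies = 18, n_pairs = 14,
                                     n_species = 8), seed = 23)
  kept <- apply_exclusions(sim$records)$kept
  eff <- compute_effect_sizes(kept, "lnCVR")
  A <- sim$A[unique(eff$species), unique(eff$species)]
  tab <- compare_vcv_structures(eff, A, control = list(n_starts = 1))
  expect_setequal(tab$structure, c("single_var_zero_cov", "compound_symmetric",
                                   "heteroscedastic_cs", "diagonal",
                                   "unstructured"))
  expect_equal(sort(tab$n_par_study), c(1, 2, 3, 4, 6))
  lls <- tab$logLik[match(c("unstructured", "diagonal", "heteroscedastic_cs",
                            "compound_symmetric", "single_var_zero_cov"),
                          tab$structure)]
  # the unstructured model nests all others
  expect_gte(lls[1] + 1e-4, max(lls[-1]))
  expect_equal(min(tab$delta_AIC), 0)
  # single-trait input: only the single-variance structure is estimable
  eff_ld <- eff[eff$trait == "laying_date", ]
  tab1 <- compare_vcv_structures(eff_ld, A, control = list(n_starts = 1))
  expect_equal(tab1$structure, "single_var_zero_cov")
  expect_error(fit_meta(eff_ld, meta_spec(fixed = "trait",
                                          vcv_structure = "unstructured"), A),
               ">= 2 traits")
})

test_that("heterogeneity decomposition follows the typical-sampling-variance formula", {
  eff <- random_small_effects(30, seed = 29)
  eff$vi <- 0.08  # equal vi: typical sampling variance equals v
  A <- four_species_A()
  spec <- meta_spec(fixed = "intercept",
                    vcv_structure = "single_var_zero_cov",
                    obs_by_trait = FALSE)
  fit <- fit_meta(eff, spec, A, control = list(n_starts = 1))
  dec <- i2_decomposition(fit)
  expect_equal(dec$typical_sampling_variance, 0.08, tolerance = 1e-12)
  expect_equal(sum(dec$I2), dec$I2_total, tolerance = 1e-9)
  expect_true(all(dec$I2 >= 0 & dec$I2 <= 100))
  # manufactured fits exercise the boundary identities
  fit0 <- fit
  fit0$sigma2[] <- 0
  expect_equal(i2_decomposition(fit0)$I2_total, 0)
  fit50 <- fit
  fit50$sigma2 <- c(total = i2_decomposition(fit)$typical_sampling_variance)
  expect_equal(i2_decomposition(fit50)$I2_total, 50)
})

test_that("marginal R2 reflects the moderator signal share", {
  set.seed(33)
  eff <- random_small_effects(80, seed = 33)
  eff$mod <- rnorm(80)
  eff$yi <- 0.3 * eff$mod + rnorm(80, 0, sqrt(eff$vi))
  spec <- meta_spec(fixed = "intercept", moderators = "mod",
                    random = "observation", obs_by_trait = FALSE)
  fit <- fit_meta(eff, spec)
  r2 <- r2_marginal(fit)
  expect_gt(r2, 50)  # nearly all non-sampling variance is the moderator
  # a null moderator explains nearly nothing
  eff$yi <- rnorm(80, 0, 0.4)
  fit0 <- fit_meta(eff, spec)
  expect_lt(r2_marginal(fit0), 15)
  fit_int <- fit_meta(eff, meta_spec(fixed = "intercept",
                                     random = "observation",
                                     obs_by_trait = FALSE))
  expect_error(r2_marginal(fit_int), "intercept-only")
})

test_that("Wald intervals use the 1.96 normal quantile", {
  ci <- wald_ci(0, 1)
  expect_equal(ci$lower, -1.959964, tolerance = 1e-6)
  expect_equal(ci$upper, 1.959964, tolerance = 1e-6)
  deg <- wald_ci(0.5, 0)
  expect_equal(deg$lower, 0.5)
  expect_equal(deg$upper, 0.5)
  # interval consistent with a reported estimate (SE back-solved from CI)
  ci2 <- wald_ci(0.176, 0.0469)
  expect_equal(round(ci2$lower, 3), 0.084)
  expect_equal(round(ci2$upper, 3), 0.268)
})

test_that("publication-bias moderators are built correctly and detect injected asymmetry", {
  sim <- simulate_dataset(sim_params(n_studies = 25, n_pairs = 20,
                                     n_species = 10), seed = 37)
  kept <- apply_exclusions(sim$records)$kept
  eff <- compute_effect_sizes(kept, "lnCVR")
  A <- sim$A[unique(eff$species), unique(eff$species)]
  spec <- meta_spec(vcv_structure = "single_var_zero_cov")
  out <- publication_bias_tests(eff, A, spec, control = list(n_starts = 1))
  expect_named(out$r2_marginal, c("small_study", "decline"))
  yr <- eff$publication_year - mean(eff$publication_year)
  expect_equal(mean(yr), 0, tolerance = 1e-12)
  slope <- out$small_study$beta[out$small_study$beta$term == "inv_sqrt_n", ]
  expect_true(is.finite(slope$estimate))
  # inject a funnel asymmetry: yi inflated proportional to sqrt(vi)
  eff2 <- eff
  eff2$yi <- eff2$yi + 3 * sqrt(eff2$vi)
  out2 <- publication_bias_tests(eff2, A, spec, control = list(n_starts = 1))
  slope2 <- out2$small_study$beta[out2$small_study$beta$term == "inv_sqrt_n", ]
  expect_gt(slope2$estimate, 0)
  expect_gt(slope2$ci_lower, 0)
  expect_error(publication_bias_tests(transform(eff, publication_year = 2000),
                                      A, spec),
               "constant moderator")
})

test_that("non-convergence is reported, never silent", {
  eff <- random_small_effects(12, seed = 41)
  fit <- fit_meta(eff, meta_spec(fixed = "intercept", random = "observation",
                                 obs_by_trait = FALSE),
                  control = list(n_starts = 1, max_iter = 1))
  expect_false(fit$convergence$converged)
  expect_type(fit$convergence$message, "character")
})
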