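test_that("simulated trees are reproducible pure-birth trees with labelled tips", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  t35a <- simulate_tree(35, seed = 7)
  t35b <- simulate_tree(35, seed = 7)
  expect_equal(ape::write.tree(t35a), ape::write.tree(t35b))
  expect_equal(ape::Ntip(t35a), 35)
  expect_equal(t35a$Nnode, 34)  # binary: n - 1 internal nodes
  expect_error(simulate_tree(1), "at least 2")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_dataset(sim_params(n_studies = 10, n_pairs = 8, n_species = 6),
                        seed = 3)
  b <- simulate_dataset(sim_params(n_studies = 10, n_pairs = 8, n_species = 6),
                        seed = 3)
  expect_identical(a$records, b$records)
  path_a <- withr::local_tempfile(fileext = ".csv")
  path_b <- withr::local_tempfile(fileext = ".csv")
  write_comparisons(a$records, path_a)
  write_comparisons(b$records, path_b)
  expect_identical(readLines(path_a), readLines(path_b))
})

test_that("records respect the schema invariants and truth covers every record", {
  sim <- simulate_dataset(sim_params(), seed = 5)
  rec <- sim$records
  expect_true(all(rec$n_urban >= 2 & rec$n_nonurban >= 2))
  expect_true(all(rec$sd_urban > 0 & rec$sd_nonurban > 0))
  counts <- rec[rec$trait %in% c("clutch_size", "n_fledglings"), ]
  expect_true(all(counts$mean_urban > 0 & counts$mean_nonurban > 0))
  ld <- rec[rec$trait == "laying_date", ]
  expect_true(all(ld$mean_urban >= 1 & ld$mean_urban <= 366))
  expect_setequal(sim$truth$per_record$record_id, rec$record_id)
  expect_true(all(rec$species %in% rownames(sim$A)))
})

test_that("a null generator concentrates effect sizes near zero", {
  params <- sim_params(
    n_studies = 20, n_pairs = 16, n_species = 8,
    mu_lnRR = c(laying_date = 0, clutch_size = 0, n_fledglings = 0),
    mu_lnCVR = c(laying_date = 0, clutch_size = 0, n_fledglings = 0),
    arm_n_meanlog = log(4000), arm_n_sdlog = 0.05, sigma_season = 0,
    sigma2 = list(
      lnRR = list(obs = c(0, 0, 0), study = c(0, 0, 0), rho_study = 0,
                  pop = 0, phylo = 0, species = 0),
      lnCVR = list(obs = c(0, 0, 0), study = c(0, 0, 0), rho_study = 0,
                   pop = 0, phylo = 0, species = 0)))
  sim <- simulate_dataset(params, seed = 11)
  for (ms in c("lnRR", "lnCVR")) {
    eff <- compute_effect_sizes(sim$records, ms)
    se <- sd(eff$yi) / sqrt(nrow(eff))
    expect_lt(abs(mean(eff$yi)), 3 * se + 1e-3)
    expect_lt(abs(mean(eff$yi)), 0.01)
  }
})

test_that("true effects are identifiable from large-n simulated arms", {
  params <- sim_params(n_studies = 40, n_pairs = 30, n_species = 10,
                       trait_prob = 1, p_multi_season = 0,
                       arm_n_meanlog = log(20000), arm_n_sdlog = 0.01,
                       sigma_season = 0)
  sim <- simulate_dataset(params, seed = 21)
  eff <- compute_effect_sizes(sim$records, "lnCVR")
  merged <- merge(eff, sim$truth$per_record, by = "record_id")
  # with huge arms, the computed lnCVR equals the generative truth
  expect_lt(max(abs(merged$yi - merged$true_lnCVR)), 0.05)
  expect_gt(cor(merged$yi, merged$true_lnCVR), 0.999)
  effr <- compute_effect_sizes(sim$records, "lnRR")
  mergedr <- merge(effr, sim$truth$per_record, by = "record_id")
  expect_lt(max(abs(mergedr$yi - mergedr$true_lnRR)), 0.05)
})

test_that("pooling simulated per-season rows ties to the season-pooling oracle", {
  params <- sim_params(n_studies = 16, n_pairs = 12, n_species = 6,
                       p_multi_season = 1, p_source_pooled = 0)
  sim <- simulate_dataset(params, seed = 31)
  inter <- build_interannual_dataset(sim$records)
  expect_true(all(inter$season == "pooled"))
  expect_true(all(inter$n_seasons >= 2))
  # pooled n equals the summed per-season n of its group
  grp <- sim$records[sim$records$study_id == inter$study_id[1] &
                       sim$records$trait == inter$trait[1], ]
  expect_equal(inter$n_urban[1], sum(grp$n_urban))
})

test_that("flaw injection yields the exact engineered exclusion breakdown", {
  rec <- simulate_dataset(sim_params(n_studies = 30, n_pairs = 24,
                                     n_species = 10), seed = 41)$records
  flawed <- inject_extraction_flaws(rec, c(3, 26, 11, 4), seed = 2)
  res <- apply_exclusions(flawed)
  expect_equal(unname(res$log$counts), c(3, 26, 11, 4))
  expect_equal(nrow(res$kept), nrow(rec) - 44)
})

test_that("the benchmark fixture reproduces the documented bookkeeping", {
  fx <- simulate_benchmark_fixture(seed = 1)
  expect_equal(nrow(fx), 443)
  res <- apply_exclusions(fx)
  expect_equal(nrow(res$kept), 399)
  expect_equal(unname(res$log$counts), c(3, 26, 11, 4))
  expect_equal(nrow(split_intra_annual(res$kept)), 363)
  expect_equal(sum(res$kept$season == "pooled"), 36)
})

test_that("synthetic land cover has an urban core and patchiness responds to smoothing", {
  sim <- simulate_landcover(n_categories = 5, seed = 3)
  expect_error(simulate_landcover(n_categories = 1), "n_categories")
  expect_error(simulate_landcover(width = 16), "32")
  counts_u <- buffer_extract(sim$grid, unlist(sim$sites[1, c("x", "y")]), 2000)
  expect_gt(urban_index(counts_u, "1"), 0.8)
  counts_n <- buffer_extract(sim$grid, unlist(sim$sites[2, c("x", "y")]), 2000)
  expect_lt(urban_index(counts_n, "1"), 0.2)
  # patchier fields carry more effective land covers at the same radius
  h_patchy <- mean(sapply(1:5, function(s) {
    g <- simulate_landcover(patch_scale = 1, seed = s)
    effective_landcovers(buffer_extract(g$grid,
                                        unlist(g$sites[2, c("x", "y")]), 3000))
  }))
  h_smooth <- mean(sapply(1:5, function(s) {
    g <- simulate_landcover(patch_scale = 12, seed = s)
    effective_landcovers(buffer_extract(g$grid,
                                        unlist(g$sites[2, c("x", "y")]), 3000))
  }))
  expect_gt(h_patchy, h_smooth)
})

test_that("a small recovery experiment is unbiased with near-nominal coverage", {
  params <- sim_params(n_studies = 20, n_pairs = 16, n_species = 8)
  out <- recovery_experiment(params, n_reps = 8, measure = "lnCVR", seed = 100,
                             control = list(n_starts = 1, rel_tol = 1e-6))
  expect_equal(nrow(out$summary), 3)
  ld <- out$summary[out$summary$term == "laying_date", ]
  expect_equal(ld$truth, 0.176)
  # MC tolerance at this replicate count is generous by design
  expect_lt(abs(ld$bias), 0.15)
  expect_true(all(out$summary$coverage >= 0.5))
})

test_that("components that are truly zero in the generator are estimated at the boundary", {
  zero_sigma <- sim_params(
    n_studies = 24, n_pairs = 20, n_species = 10,
    sigma2 = list(
      lnRR = list(obs = c(0.03, 0.03, 0.03), study = c(0.003, 0.003, 0.003),
                  rho_study = 0, pop = 0.001, phylo = 0.0006, species = 0.0055),
      lnCVR = list(obs = c(0.09, 0.09, 0.09), study = c(0, 0, 0),
                   rho_study = 0, pop = 0, phylo = 0.01, species = 0.005)))
  study_hat <- pop_hat <- c()
  for (r in 1:5) {
    sim <- simulate_dataset(zero_sigma, seed = 7000 + r)
    eff <- compute_effect_sizes(apply_exclusions(sim$records)$kept, "lnCVR")
    fit <- fit_meta(eff, meta_spec(fixed = "trait", vcv_structure = "diagonal"),
                    A = sim$A, control = list(n_starts = 1, rel_tol = 1e-6))
    study_hat <- c(study_hat,
                   fit$sigma2[paste0("study_", trait_levels())])
    pop_hat <- c(pop_hat, fit$sigma2["population"])
  }
  expect_lt(median(study_hat), 1e-3)
  expect_lt(median(pop_hat), 1e-3)
})

test_that("more phylogenetic variance in the generator raises estimated phylogenetic I2", {
  base <- list(obs = c(0.05, 0.05, 0.05), study = c(0.002, 0.002, 0.002),
               rho_study = 0, pop = 0.002, phylo = 0.002, species = 0.002)
  hi <- base; hi$phylo <- 0.08
  i2_phylo <- function(sig, seeds) {
    mean(sapply(seeds, function(s) {
      params <- sim_params(n_studies = 24, n_pairs = 20, n_species = 12,
                           sigma2 = list(lnRR = base, lnCVR = sig))
      sim <- simulate_dataset(params, seed = s)
      eff <- compute_effect_sizes(apply_exclusions(sim$records)$kept, "lnCVR")
      fit <- fit_meta(eff, meta_spec(fixed = "intercept",
                                     vcv_structure = "single_var_zero_cov",
                                     obs_by_trait = FALSE),
                      A = sim$A, control = list(n_starts = 1, rel_tol = 1e-6))
      i2_decomposition(fit)$I2["phylogeny"]
    }))
  }
  seeds <- 8000 + 1:4
  expect_gt(i2_phylo(hi, seeds), i2_phylo(base, seeds))
})
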