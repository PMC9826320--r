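# Shared fixtures and independent oracles for the test suite.

# A small, fully explicit comparison table (no generator involved).
tiny_records <- function(n = 3) {
  data.frame(
    record_id = paste0("r", seq_len(n)),
    study_id = paste0("s", rep(seq_len(max(1, n %/% 2)), length.out = n)),
    population_pair_id = paste0("p", rep(seq_len(max(1, n %/% 2)), length.out = n)),
    species = rep(c("Parus major", "Turdus merula"), length.out = n),
    trait = rep(c("laying_date", "clutch_size", "n_fledglings"), length.out = n),
    season = as.character(2000 + seq_len(n)), n_seasons = 1,
    mean_urban = 100 + seq_len(n), sd_urban = 5 + seq_len(n) / 10,
    n_urban = 20 + seq_len(n),
    mean_nonurban = 105 + seq_len(n), sd_nonurban = 4 + seq_len(n) / 10,
    n_nonurban = 25 + seq_len(n),
    lat_urban = 50.1, lon_urban = -4.2, lat_nonurban = 50.2, lon_nonurban = -4.1,
    publication_year = 2010, stringsAsFactors = FALSE)
}

# Brute-force marginal covariance of the multilevel model, assembled by
# explicit double loops over observation pairs (independent of the
# package's incidence-matrix assembly).
brute_force_V <- function(df, sigma2_obs, Sigma_study, sigma2_pop,
                          sigma2_phylo, sigma2_species, A) {
  n <- nrow(df)
  traits <- sort(unique(df$trait))
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ti <- match(df$trait[i], traits); tj <- match(df$trait[j], traits)
      if (i == j) V[i, j] <- V[i, j] + df$vi[i] + sigma2_obs[ti]
      if (df$study_id[i] == df$study_id[j]) V[i, j] <- V[i, j] + Sigma_study[ti, tj]
      if (df$population_pair_id[i] == df$population_pair_id[j])
        V[i, j] <- V[i, j] + sigma2_pop
      V[i, j] <- V[i, j] + sigma2_phylo * A[df$species[i], df$species[j]]
      if (df$species[i] == df$species[j]) V[i, j] <- V[i, j] + sigma2_species
    }
  }
  V
}

# Direct multivariate-normal log-density with beta profiled by GLS,
# written against the textbook formulas (generic solve/determinant, no
# Cholesky reuse).
brute_force_loglik <- function(y, X, V, reml = FALSE) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  ld <- determinant(V, logarithm = TRUE)$modulus
  if (reml) {
    ldx <- determinant(t(X) %*% Vi %*% X, logarithm = TRUE)$modulus
    -0.5 * ((n - p) * log(2 * pi) + ld + ldx + q)
  } else {
    -0.5 * (n * log(2 * pi) + ld + q)
  }
}

# Random small effect-size table over a fixed 4-species star-free tree.
random_small_effects <- function(k, seed) {
  set.seed(seed)
  data.frame(
    record_id = paste0("r", seq_len(k)),
    study_id = paste0("s", sample(1:3, k, replace = TRUE)),
    population_pair_id = paste0("p", sample(1:2, k, replace = TRUE)),
    species = sample(c("A", "B", "C", "D"), k, replace = TRUE),
    trait = sample(urbanvar::trait_levels(), k, replace = TRUE),
    season = "2000", measure = "lnCVR",
    yi = rnorm(k, 0.1, 0.4), vi = runif(k, 0.01, 0.1),
    effective_n = runif(k, 10, 80),
    publication_year = sample(1990:2020, k, replace = TRUE),
    stringsAsFactors = FALSE)
}

four_species_A <- function() {
  tr <- urbanvar::read_newick("((A,B),(C,D));")
  urbanvar::phylo_correlation(urbanvar::grafen_lengths(tr))
}
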