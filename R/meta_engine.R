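# Multilevel phylogenetic meta-analytic engine.
#
# The marginal model is y ~ Normal(X beta, V(theta)) with
#   V(theta) = sum_u sigma2_u Z_u G_u Z_u' + diag(vi),
# where the random terms u are: study x trait deviations with a structured
# among-trait variance-covariance matrix, population-pair, phylogenetic
# (G = A, the species correlation matrix), species, and observation-level
# deviations (one variance per trait in multi-trait fits). Variance
# components are optimised on the log scale; correlations through bounded
# logistic or spherical transforms, so V stays positive definite throughout.

VCV_STRUCTURES <- c("single_var_zero_cov", "compound_symmetric",
                    "heteroscedastic_cs", "diagonal", "unstructured")

#' Declare a multilevel meta-analytic model
#'
#' @param fixed `"intercept"` (one overall mean) or `"trait"` (one mean per
#'   trait, no global intercept).
#' @param moderators Character vector of effect-size table columns to add
#'   as continuous fixed moderators.
#' @param random Random terms to include, a subset of `"study_trait"`,
#'   `"population"`, `"phylogeny"`, `"species"`, `"observation"`.
#' @param vcv_structure Among-trait structure of the study-by-trait term:
#'   `"single_var_zero_cov"` (one variance, zero covariance),
#'   `"compound_symmetric"` (one variance, one correlation),
#'   `"heteroscedastic_cs"` (per-trait variances, one correlation),
#'   `"diagonal"` (per-trait variances, zero correlation) or
#'   `"unstructured"` (per-trait variances and pairwise correlations).
#' @param obs_by_trait One observation-level variance per trait (`TRUE`,
#'   default when `fixed = "trait"`) or a single variance.
#' @param method `"REML"` (default for final estimates) or `"ML"` (used for
#'   structure comparison by AIC).
#' @param ci `"wald"` (z intervals, matching the symmetric intervals this
#'   literature prints), `"kh"` (Knapp-Hartung-style adjustment: scaled
#'   SE and t quantiles) or `"adjusted"` (Kackar-Harville first-order
#'   propagation of variance-component uncertainty into the coefficient
#'   covariance).
#' @return A `meta_spec` list.
#' @export
meta_spec <- function(fixed = c("intercept", "trait"),
                      moderators = character(),
                      random = c("study_trait", "population", "phylogeny",
                                 "species", "observation"),
                      vcv_structure = "diagonal",
                      obs_by_trait = NULL,
                      method = c("REML", "ML"),
                      ci = c("wald", "kh", "adjusted")) {
  fixed <- match.arg(fixed)
  method <- match.arg(method)
  ci <- match.arg(ci)
  vcv_structure <- match.arg(vcv_structure, VCV_STRUCTURES)
  random <- match.arg(random, several.ok = TRUE)
  if (is.null(obs_by_trait)) obs_by_trait <- identical(fixed, "trait")
  structure(list(fixed = fixed, moderators = moderators, random = random,
                 vcv_structure = vcv_structure, obs_by_trait = obs_by_trait,
                 method = method, ci = ci),
            class = "meta_spec")
}

# ---- correlation transforms -------------------------------------------------

# z in R -> rho in (lo, hi)
bounded_rho <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

# Spherical parameterisation of an m x m correlation matrix from
# m(m-1)/2 unconstrained angles: R = L L' with unit-length lower-triangular
# rows, positive definite for any z.
spherical_corr <- function(z, m) {
  theta <- pi * stats::plogis(z)
  L <- diag(m)
  idx <- 0
  for (i in seq_len(m)[-1]) {
    prod_sin <- 1
    for (j in seq_len(i - 1)) {
      idx <- idx + 1
      L[i, j] <- cos(theta[idx]) * prod_sin
      prod_sin <- prod_sin * sin(theta[idx])
    }
    L[i, i] <- prod_sin
  }
  L %*% t(L)
}

# Build the among-trait Sigma for the study x trait term.
study_trait_sigma <- function(par, structure, m) {
  switch(structure,
    single_var_zero_cov = diag(exp(par[1]), m),
    compound_symmetric = {
      rho <- bounded_rho(par[2], -1 / (m - 1) + 1e-6, 1 - 1e-6)
      exp(par[1]) * ((1 - rho) * diag(m) + rho)
    },
    heteroscedastic_cs = {
      s <- sqrt(exp(par[seq_len(m)]))
      rho <- bounded_rho(par[m + 1], -1 / (m - 1) + 1e-6, 1 - 1e-6)
      R <- (1 - rho) * diag(m) + rho
      outer(s, s) * R
    },
    diagonal = diag(exp(par[seq_len(m)]), m),
    unstructured = {
      s <- sqrt(exp(par[seq_len(m)]))
      R <- spherical_corr(par[-seq_len(m)], m)
      outer(s, s) * R
    })
}

n_structure_par <- function(structure, m) {
  switch(structure,
    single_var_zero_cov = 1L,
    compound_symmetric = 2L,
    heteroscedastic_cs = m + 1L,
    diagonal = m,
    unstructured = m + m * (m - 1L) / 2L)
}

# ---- design assembly --------------------------------------------------------

#' Assemble the design of a multilevel meta-analytic model
#'
#' Builds the response, fixed-design matrix, sampling-variance vector and
#' the precomputed incidence structures from which the marginal covariance
#' `V(theta)` is assembled at each likelihood evaluation.
#'
#' @param effects Effect-size `data.frame` (one measure) with columns
#'   `yi`, `vi`, `trait`, `study_id`, `population_pair_id`, `species`, plus
#'   any moderator columns named in the spec.
#' @param spec A [meta_spec()].
#' @param A Species correlation matrix (required when `"phylogeny"` is in
#'   the random terms); all species in `effects` must appear in its
#'   dimnames.
#' @return A `meta_design` list (`y`, `X`, `vi`, random-term descriptors,
#'   parameter bookkeeping).
#' @export
build_design <- function(effects, spec, A = NULL) {
  stopifnot(inherits(spec, "meta_spec"))
  if (any(!is.finite(effects$vi)) || any(effects$vi <= 0))
    stop("all sampling variances must be positive and finite")
  n <- nrow(effects)
  traits <- sort(unique(as.character(effects$trait)))
  m <- length(traits)
  ti <- match(as.character(effects$trait), traits)

  # fixed part
  if (spec$fixed == "trait" && m > 1) {
    X <- stats::model.matrix(~ 0 + factor(effects$trait, levels = traits))
    colnames(X) <- traits
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  }
  for (mod in spec$moderators) {
    if (!mod %in% names(effects)) stop("moderator column not found: ", mod)
    x <- effects[[mod]]
    if (stats::sd(x) == 0) stop("constant moderator: ", mod)
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- mod
  }

  terms <- list()
  par_names <- character()
  index <- list()
  pos <- 0
  add_par <- function(nm) {
    par_names <<- c(par_names, nm)
    pos <<- pos + length(nm)
    seq.int(pos - length(nm) + 1, pos)
  }

  if ("observation" %in% spec$random) {
    per_trait <- spec$obs_by_trait && m > 1
    nm <- if (per_trait) paste0("sigma2_obs_", traits) else "sigma2_obs"
    terms$observation <- list(type = "obs", per_trait = per_trait, ti = ti,
                              m = m, idx = add_par(nm))
  }
  if ("study_trait" %in% spec$random) {
    if (m == 1 && spec$vcv_structure != "single_var_zero_cov")
      stop("multi-trait variance-covariance structures need >= 2 traits present")
    S <- outer(effects$study_id, effects$study_id, "==") * 1
    np <- n_structure_par(spec$vcv_structure, m)
    nm <- paste0("study_", seq_len(np))
    terms$study_trait <- list(type = "study_trait", S = S, ti = ti, m = m,
                              structure = spec$vcv_structure, idx = add_par(nm))
  }
  if ("population" %in% spec$random) {
    C <- outer(effects$population_pair_id, effects$population_pair_id, "==") * 1
    terms$population <- list(type = "iid", C = C, idx = add_par("sigma2_pop"))
  }
  if ("phylogeny" %in% spec$random) {
    if (is.null(A)) stop("phylogeny term requires a species correlation matrix A")
    missing_sp <- setdiff(unique(effects$species), rownames(A))
    if (length(missing_sp) > 0)
      stop("species missing from A: ", paste(missing_sp, collapse = ", "))
    C <- A[effects$species, effects$species]
    dimnames(C) <- NULL
    terms$phylogeny <- list(type = "iid", C = C, idx = add_par("sigma2_phylo"))
  }
  if ("species" %in% spec$random) {
    C <- outer(effects$species, effects$species, "==") * 1
    terms$species <- list(type = "iid", C = C, idx = add_par("sigma2_species"))
  }

  structure(list(y = effects$yi, X = X, vi = effects$vi, terms = terms,
                 par_names = par_names, n_par = pos, traits = traits, m = m,
                 spec = spec),
            class = "meta_design")
}

# Marginal covariance at transformed parameters theta.
assemble_V <- function(theta, design) {
  n <- length(design$y)
  V <- diag(design$vi, n)
  for (term in design$terms) {
    par <- theta[term$idx]
    if (term$type == "obs") {
      if (term$per_trait) {
        diag(V) <- diag(V) + exp(par)[term$ti]
      } else {
        diag(V) <- diag(V) + exp(par)
      }
    } else if (term$type == "iid") {
      V <- V + exp(par) * term$C
    } else if (term$type == "study_trait") {
      Sigma <- study_trait_sigma(par, term$structure, term$m)
      V <- V + term$S * Sigma[term$ti, term$ti, drop = FALSE]
    } else if (term$type == "arm_cs") {
      rho <- bounded_rho(par[2], term$lo, 1 - 1e-6)
      M <- term$S * rho
      diag(M) <- 1
      V <- V + exp(par[1]) * M
    }
  }
  V
}

# Profile log-likelihood of y ~ N(X beta, V(theta)) with beta profiled out
# by GLS. Returns logLik plus GLS by-products.
profile_loglik <- function(theta, design, reml) {
  V <- assemble_V(theta, design)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  a <- backsolve(ch, X, transpose = TRUE)   # solve(t(ch), X)
  b <- backsolve(ch, y, transpose = TRUE)
  XtViX <- crossprod(a)
  XtViy <- crossprod(a, b)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(list(ll = -Inf))
  beta <- backsolve(ch2, backsolve(ch2, XtViy, transpose = TRUE))
  q <- sum(b^2) - sum(XtViy * beta)
  logdetV <- 2 * sum(log(diag(ch)))
  if (reml) {
    ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV +
                    2 * sum(log(diag(ch2))) + q)
  } else {
    ll <- -0.5 * (n * log(2 * pi) + logdetV + q)
  }
  list(ll = ll, beta = drop(beta), vcov_beta = chol2inv(ch2), V = V, q = q)
}

# ---- fitting ----------------------------------------------------------------

default_start <- function(design) {
  v0 <- max(stats::var(design$y) - mean(design$vi), 0.01 * stats::var(design$y),
            1e-4)
  n_terms <- max(1, length(design$terms))
  start <- numeric(design$n_par)
  for (term in design$terms) {
    par <- rep(log(v0 / n_terms), length(term$idx))
    if (term$type == "study_trait") {
      nv <- switch(term$structure, single_var_zero_cov = 1, compound_symmetric = 1,
                   heteroscedastic_cs = term$m, diagonal = term$m,
                   unstructured = term$m)
      par <- c(rep(log(v0 / n_terms), nv), rep(0, length(term$idx) - nv))
    }
    if (term$type == "arm_cs") par <- c(log(v0 / n_terms), 0)
    start[term$idx] <- par
  }
  start
}

is_variance_par <- function(design) {
  flag <- logical(design$n_par)
  for (term in design$terms) {
    nv <- switch(term$type,
                 obs = length(term$idx),
                 iid = 1L,
                 arm_cs = 1L,
                 study_trait = switch(term$structure,
                                      single_var_zero_cov = 1L,
                                      compound_symmetric = 1L,
                                      heteroscedastic_cs = term$m,
                                      diagonal = term$m,
                                      unstructured = term$m))
    flag[term$idx[seq_len(nv)]] <- TRUE
  }
  flag
}

# Multi-start quasi-Newton maximisation of the profiled (restricted)
# likelihood over transformed variance parameters. Dispersed starts shift
# the log-variance entries; the best objective wins. Used by both
# fit_meta() and fit_arm_based().
optimise_design <- function(design, reml, control = list()) {
  ctrl <- utils::modifyList(list(n_starts = 5, rel_tol = 1e-8, max_iter = 500),
                            control)
  obj <- function(theta) {
    ll <- profile_loglik(theta, design, reml)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  start0 <- default_start(design)
  vflag <- is_variance_par(design)
  shifts <- c(0, +2, -2, +4, -4)
  best <- NULL
  tried <- 0
  for (s in shifts[seq_len(max(1, min(ctrl$n_starts, length(shifts))))]) {
    start <- start0
    start[vflag] <- start[vflag] + s
    fit <- tryCatch(
      stats::nlminb(start, obj,
                    lower = ifelse(vflag, -25, -12),
                    upper = ifelse(vflag, 12, 12),
                    control = list(rel.tol = ctrl$rel_tol,
                                   iter.max = ctrl$max_iter,
                                   eval.max = 4 * ctrl$max_iter)),
      error = function(e) NULL)
    tried <- tried + 1
    if (!is.null(fit) && is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective - 1e-10)) {
      best <- fit
    }
    # default start plus one dispersed confirmation is enough when clean
    if (!is.null(best) && best$convergence == 0 && tried >= 2) break
  }
  if (is.null(best)) stop("optimisation failed from all starts")
  best$converged <- best$convergence == 0 ||
    grepl("relative convergence", best$message %||% "")
  best$starts_tried <- tried
  best
}

#' Fit a multilevel (phylogenetic) meta-analytic model
#'
#' Maximises the (restricted) log-likelihood of
#' `y ~ Normal(X beta, V(theta))` over the variance components, with the
#' fixed effects profiled out by generalised least squares. Variances are
#' optimised on the log scale and correlations through bounded transforms;
#' optimisation restarts from several dispersed points before a
#' non-convergence is declared (flagged in the result, never silent).
#'
#' @param effects Effect-size `data.frame` (a single measure).
#' @param spec A [meta_spec()].
#' @param A Optional species correlation matrix (see [phylo_correlation()]).
#' @param control List: `n_starts` (default 5), `rel_tol` (default 1e-8),
#'   `max_iter` (default 500).
#' @return A `meta_fit` object: `beta` table (estimate, SE, Wald 95% CI),
#'   `sigma2` named variance components, `correlations` (study-by-trait
#'   among-trait correlation matrix, when estimated), `logLik`, `AIC`,
#'   `k`, `method`, `convergence` report.
#' @export
fit_meta <- function(effects, spec = meta_spec(), A = NULL, control = list()) {
  design <- build_design(effects, spec, A)
  reml <- spec$method == "REML"
  p <- ncol(design$X)
  if (nrow(effects) <= p) stop("k must exceed the number of fixed parameters")
  best <- optimise_design(design, reml, control)
  theta <- best$par
  converged <- best$converged
  ll <- profile_loglik(theta, design, reml)

  # back-transform components
  sigma2 <- list()
  correlations <- NULL
  for (nm in names(design$terms)) {
    term <- design$terms[[nm]]
    par <- theta[term$idx]
    if (term$type == "obs") {
      v <- exp(par)
      names(v) <- if (term$per_trait) paste0("obs_", design$traits) else "obs"
      sigma2 <- c(sigma2, as.list(v))
    } else if (term$type == "iid") {
      sigma2[[nm]] <- exp(par)
    } else if (term$type == "study_trait") {
      Sigma <- study_trait_sigma(par, term$structure, term$m)
      if (term$structure == "single_var_zero_cov") {
        # one shared variance: report it once, whatever the trait count
        sigma2[["study"]] <- Sigma[1, 1]
      } else {
        v <- diag(Sigma)
        names(v) <- paste0("study_", design$traits)
        sigma2 <- c(sigma2, as.list(v))
        correlations <- stats::cov2cor(Sigma)
        dimnames(correlations) <- list(design$traits, design$traits)
      }
    } else if (term$type == "arm_cs") {
      sigma2[["effect_size"]] <- exp(par[1])
      correlations <- bounded_rho(par[2], term$lo, 1 - 1e-6)
    }
  }
  sigma2 <- unlist(sigma2)

  ci_method <- spec$ci %||% "wald"
  vb <- ll$vcov_beta
  df <- NULL
  if (ci_method == "adjusted") {
    adj <- adjusted_vcov_beta(design, theta, reml, vb, nrow(effects), p)
    vb <- adj$vcov
    df <- adj$df
  }
  se <- sqrt(diag(vb))
  beta_tab <- beta_table(colnames(design$X), ll, se, nrow(effects), p,
                         ci = ci_method, df = df)
  if (!is.null(df)) beta_tab$df <- df
  n_theta <- design$n_par
  aic <- if (reml) -2 * ll$ll + 2 * n_theta else
    -2 * ll$ll + 2 * (n_theta + p)

  structure(list(beta = beta_tab, sigma2 = sigma2, correlations = correlations,
                 logLik = ll$ll, AIC = aic, k = nrow(effects),
                 method = spec$method, spec = spec, design = design,
                 theta = theta, vcov_beta = vb,
                 convergence = list(converged = converged,
                                    message = best$message,
                                    starts_tried = best$starts_tried,
                                    objective = best$objective)),
            class = "meta_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coefficient table under one of three interval constructions:
# "wald"     plain z intervals on the GLS covariance at theta-hat (matches
#            the symmetric intervals this literature prints);
# "kh"       Knapp-Hartung-style residual scaling, sqrt(max(1, q/(k-p)))
#            with t(k-p) quantiles;
# "adjusted" Kackar-Harville first-order correction: the GLS covariance is
#            inflated by G Cov(theta-hat) G' (G = d beta-hat / d theta,
#            Cov(theta-hat) from the curvature of the profiled restricted
#            likelihood), propagating variance-component uncertainty that
#            plain Wald z ignores.
beta_table <- function(terms, ll, se, k, p, ci = c("wald", "kh", "adjusted"),
                       df = NULL) {
  ci <- match.arg(ci)
  if (ci == "kh") {
    scale <- sqrt(max(1, ll$q / (k - p)))
    crit <- stats::qt(0.975, k - p)
    lower <- ll$beta - crit * se * scale
    upper <- ll$beta + crit * se * scale
  } else if (ci == "adjusted") {
    crit <- stats::qt(0.975, df %||% (k - p))
    lower <- ll$beta - crit * se
    upper <- ll$beta + crit * se
  } else {
    w <- wald_ci(ll$beta, se)
    lower <- w$lower
    upper <- w$upper
  }
  out <- data.frame(term = terms, estimate = ll$beta, se = se,
                    ci_lower = lower, ci_upper = upper,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Kackar-Harville / Satterthwaite small-sample machinery. Numeric central
# differences on the transformed parameter scale give the curvature of the
# profiled (restricted) likelihood (-> Cov(theta-hat)), the sensitivity of
# beta-hat to theta (-> variance inflation), and the sensitivity of the
# coefficient variances to theta (-> Satterthwaite degrees of freedom).
# Parameters with numerically zero curvature (components at the boundary)
# contribute nothing and are dropped.
adjusted_vcov_beta <- function(design, theta, reml, vcov_beta, k, p,
                               h = 1e-3) {
  q <- length(theta)
  f <- function(th) profile_loglik(th, design, reml)
  H <- matrix(0, q, q)
  G <- matrix(0, p, q)        # d beta-hat / d theta
  D <- matrix(0, p, q)        # d var(beta-hat_i) / d theta
  f0 <- f(theta)
  for (j in seq_len(q)) {
    ej <- replace(numeric(q), j, h)
    fp <- f(theta + ej); fm <- f(theta - ej)
    H[j, j] <- -(fp$ll - 2 * f0$ll + fm$ll) / h^2
    G[, j] <- (fp$beta - fm$beta) / (2 * h)
    D[, j] <- (diag(fp$vcov_beta) - diag(fm$vcov_beta)) / (2 * h)
  }
  fallback <- list(vcov = vcov_beta, df = rep(k - p, p))
  for (j in seq_len(q - 1)) {
    for (l in seq.int(j + 1, q)) {
      ej <- replace(numeric(q), j, h)
      el <- replace(numeric(q), l, h)
      fpp <- f(theta + ej + el); fpm <- f(theta + ej - el)
      fmp <- f(theta - ej + el); fmm <- f(theta - ej - el)
      H[j, l] <- H[l, j] <- -(fpp$ll - fpm$ll - fmp$ll + fmm$ll) / (4 * h^2)
    }
  }
  keep <- diag(H) > 1e-6
  if (!any(keep)) return(fallback)
  Hk <- H[keep, keep, drop = FALSE]
  covt <- tryCatch(solve(Hk), error = function(e) NULL)
  if (is.null(covt)) return(fallback)
  ev <- eigen(covt, symmetric = TRUE)
  covt <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(covt)) %*% t(ev$vectors)
  Gk <- G[, keep, drop = FALSE]
  Dk <- D[, keep, drop = FALSE]
  vadj <- vcov_beta + Gk %*% covt %*% t(Gk)
  # Satterthwaite: df_i = 2 var_i^2 / Var(var_i-hat)
  df <- vapply(seq_len(p), function(i) {
    v <- drop(Dk[i, ] %*% covt %*% Dk[i, ])
    if (v <= 0) return(k - p)
    min(max(2 * vcov_beta[i, i]^2 / v, 2), k - p)
  }, numeric(1))
  list(vcov = vadj, df = df)
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic fit (", x$method, "), k = ", x$k, "\n", sep = "")
  cat("logLik = ", format(x$logLik, digits = digits + 2),
      ", AIC = ", format(x$AIC, digits = digits + 2), "\n\n", sep = "")
  tab <- x$beta
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("\nVariance components:\n")
  print(round(x$sigma2, digits + 2))
  if (!is.null(x$correlations) && is.matrix(x$correlations)) {
    cat("\nAmong-trait correlations (study term):\n")
    print(round(x$correlations, digits))
  }
  if (!x$convergence$converged)
    cat("\nWARNING: optimisation did not report clean convergence:",
        x$convergence$message, "\n")
  invisible(x)
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile for the
#' requested level (1.959964 at 95%).
#'
#' @param estimate,se Point estimate(s) and standard error(s), `se >= 0`.
#' @param level Confidence level (default 0.95).
#' @return A list with `lower` and `upper`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  stopifnot(all(se >= 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = estimate - z * se, upper = estimate + z * se)
}

# ---- model comparison and summaries ----------------------------------------

#' Compare among-trait variance-covariance structures by ML + AIC
#'
#' Fits the trait-level multilevel model under each admissible constraint
#' on the study-by-trait variance-covariance matrix by maximum likelihood
#' and tabulates AIC differences. Ties in AIC (below `1e-6`) are broken
#' toward the structure with fewer parameters.
#'
#' @param effects Effect-size `data.frame` (one measure, >= 2 traits for
#'   the multi-trait structures).
#' @param A Optional species correlation matrix.
#' @param spec Base [meta_spec()]; its `vcv_structure` and `method` are
#'   overridden per row.
#' @param control Passed to [fit_meta()].
#' @return `data.frame` with structure, number of study-term parameters,
#'   logLik, AIC, delta_AIC and convergence flag, ordered by AIC (ties by
#'   parameter count); fits attached as attribute `"fits"`.
#' @export
compare_vcv_structures <- function(effects, A = NULL,
                                   spec = meta_spec(fixed = "trait", method = "ML"),
                                   control = list()) {
  m <- length(unique(effects$trait))
  structures <- if (m == 1) "single_var_zero_cov" else VCV_STRUCTURES
  fits <- list()
  rows <- lapply(structures, function(s) {
    sp <- spec
    sp$vcv_structure <- s
    sp$method <- "ML"
    fit <- fit_meta(effects, sp, A, control)
    fits[[s]] <<- fit
    data.frame(structure = s, n_par_study = n_structure_par(s, m),
               logLik = fit$logLik, AIC = fit$AIC,
               converged = fit$convergence$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab$delta_AIC[tab$delta_AIC < 1e-6] <- 0
  tab <- tab[order(tab$AIC, tab$n_par_study), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Heterogeneity (I-squared) decomposition
#'
#' Computes the typical sampling variance
#' `sigma2_m = (k - 1) sum(w) / (sum(w)^2 - sum(w^2))` with `w = 1/vi`,
#' and expresses total and per-level heterogeneity as percentages:
#' `I2_u = sigma2_u / (sum_u sigma2_u + sigma2_m)`.
#'
#' @param fit A `meta_fit` whose random terms each carry a single variance
#'   (an intercept-only univariate model).
#' @param vi Sampling-variance vector of the fitted effect sizes (defaults
#'   to the one stored in the fit design).
#' @return List: `I2_total` (%), `I2` named per-component vector (%),
#'   `typical_sampling_variance`.
#' @export
i2_decomposition <- function(fit, vi = fit$design$vi) {
  k <- length(vi)
  if (k < 2) stop("need at least 2 effect sizes")
  w <- 1 / vi
  s2m <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  sig <- fit$sigma2
  total <- sum(sig)
  denom <- total + s2m
  list(I2_total = 100 * total / denom,
       I2 = 100 * sig / denom,
       typical_sampling_variance = s2m)
}

#' Marginal R-squared of fixed moderators
#'
#' `R2 = var(X beta) / (var(X beta) + sum(sigma2))`, in percent: the share
#' of effect-size variance attributable to the fixed moderators relative
#' to moderators plus random heterogeneity.
#'
#' @param fit A `meta_fit` with at least one non-intercept fixed term.
#' @return Percent (0-100).
#' @export
r2_marginal <- function(fit) {
  X <- fit$design$X
  if (ncol(X) == 1 && all(X == 1))
    stop("marginal R2 is undefined for an intercept-only fit")
  fitted_fixed <- drop(X %*% fit$beta$estimate)
  vf <- stats::var(fitted_fixed) * (length(fitted_fixed) - 1) / length(fitted_fixed)
  100 * vf / (vf + sum(fit$sigma2))
}

#' Small-study and decline-effect meta-regressions
#'
#' Fits two uni-moderator multilevel models on the same random structure:
#' one with `sqrt(1 / effective_n)` (small-study effect) and one with the
#' mean-centred publication year (decline / time-lag effect), and reports
#' slope estimates with Wald CIs plus the marginal R-squared of each
#' moderator.
#'
#' @param effects Effect-size `data.frame` with `effective_n` and
#'   `publication_year` columns.
#' @param A Optional species correlation matrix.
#' @param spec Base [meta_spec()] (fixed part is forced to
#'   intercept + moderator).
#' @param control Passed to [fit_meta()].
#' @return List with `small_study` and `decline` fits, and `r2_marginal`, a
#'   named vector of percents.
#' @export
publication_bias_tests <- function(effects, A = NULL,
                                   spec = meta_spec(), control = list()) {
  if (!all(c("effective_n", "publication_year") %in% names(effects)))
    stop("effects must carry effective_n and publication_year")
  eff <- effects
  eff$inv_sqrt_n <- sqrt(1 / eff$effective_n)
  eff$year_centred <- eff$publication_year - mean(eff$publication_year)
  fit1 <- fit_meta(eff, utils::modifyList(spec, list(fixed = "intercept",
                                                     moderators = "inv_sqrt_n",
                                                     obs_by_trait = FALSE)),
                   A, control)
  fit2 <- fit_meta(eff, utils::modifyList(spec, list(fixed = "intercept",
                                                     moderators = "year_centred",
                                                     obs_by_trait = FALSE)),
                   A, control)
  list(small_study = fit1, decline = fit2,
       r2_marginal = c(small_study = r2_marginal(fit1),
                       decline = r2_marginal(fit2)))
}
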