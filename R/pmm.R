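#' MCMC settings for the phylogenetic mixed model
#'
#' Defaults follow the study design the bundled coefficients were derived
#' under: a single chain of 50,000 iterations, burn-in 5,000, sampling every
#' 50th iteration — hence exactly (50,000 - 5,000) / 50 = 900 retained
#' draws.
#'
#' @param iterations Total Gibbs iterations.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param burn_in Iterations discarded before sampling starts.
#' @param seed Optional integer seed.
#' @return List of class `"mcmc_control"`.
#' @export
mcmc_control <- function(iterations = 50000, thin = 50, burn_in = 5000,
                         seed = NULL) {
  stopifnot(iterations > burn_in, thin >= 1, burn_in >= 0)
  structure(list(iterations = as.integer(iterations), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "mcmc_control")
}

#' Specify a phylogenetic mixed model
#'
#' @param response Response trait (log scale), typically `toL` or `carL`.
#' @param predictors One or two predictor traits (log scale).
#' @param include_sex_interaction Add a sex main effect and a
#'   sex-by-first-predictor interaction (sex coded female = 0, male = 1).
#' @param mcmc An [mcmc_control()].
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(response, predictors,
                       include_sex_interaction = FALSE,
                       mcmc = mcmc_control()) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(predictors),
            length(predictors) %in% 1:2,
            inherits(mcmc, "mcmc_control"))
  if (!all(c(response, predictors) %in% trait_names())) {
    stop("unknown trait name(s); allowed: ",
         paste(trait_names(), collapse = ", "))
  }
  if (response %in% predictors) stop("response cannot be a predictor")
  if (anyDuplicated(predictors)) stop("duplicated predictor")
  structure(list(response = response, predictors = predictors,
                 include_sex_interaction = isTRUE(include_sex_interaction),
                 mcmc = mcmc),
            class = "model_spec")
}

# Assemble response vector, fixed-effect design matrix and species index
# from a log-scale trait matrix. Rows with a missing response or predictor
# are dropped.
.build_design <- function(data, tree, spec) {
  stopifnot(inherits(data, "trait_matrix"), inherits(tree, "phylo"),
            inherits(spec, "model_spec"))
  if (trait_scale(data) != "log") {
    stop("data must be on the log scale; call to_log() first")
  }
  need <- c(spec$response, spec$predictors)
  absent <- setdiff(need, names(data))
  if (length(absent) > 0L) {
    stop("trait(s) absent from data: ", paste(absent, collapse = ", "))
  }
  df <- as.data.frame(data)
  keep <- stats::complete.cases(df[need])
  df <- df[keep, , drop = FALSE]
  miss <- setdiff(unique(df$species), tree$tip.label)
  if (length(miss) > 0L) {
    stop("species absent from tree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  y <- df[[spec$response]]
  X <- matrix(1, nrow(df), 1L)
  for (p in spec$predictors) X <- cbind(X, df[[p]])
  colnames(X) <- c("(Intercept)", spec$predictors)
  if (spec$include_sex_interaction) {
    if (length(unique(df$sex)) < 2L) {
      stop("both sexes required for a sex-interaction model")
    }
    sexm <- as.numeric(df$sex == "male")
    X <- cbind(X, sexmale = sexm)
    X <- cbind(X, sexm * df[[spec$predictors[1]]])
    colnames(X)[ncol(X)] <- paste0("sexmale:", spec$predictors[1])
  }
  for (p in spec$predictors) {
    if (stats::sd(df[[p]]) == 0) stop("predictor ", p, " is constant")
  }
  species <- sort(unique(df$species))
  list(y = y, X = X, species = species,
       sp_idx = match(df$species, species), df = df)
}

#' Fit a Bayesian phylogenetic mixed linear model by Gibbs sampling
#'
#' Fits `y = X beta + u_phylo + u_species + e` on log-scale trait data with
#' one record per species and sex (repeated measures): `u_phylo ~ N(0,
#' sigma2_p * C)` with `C` the Brownian tip covariance of the tree,
#' `u_species ~ N(0, sigma2_s * I)` a species-level random intercept shared
#' by the two sex records, and i.i.d. residuals. Priors are diffuse normal
#' on the fixed effects (mean 0, variance 1e10) and weak inverse-gamma
#' (shape = rate = 0.001, i.e. V = 1, nu = 0.002) on each variance
#' component. All full conditionals are conjugate, so the sampler is a
#' Gibbs scheme with Gaussian block updates.
#'
#' Variance components are weakly identified when each species contributes
#' only two records (phylogenetic and species intercepts both act at the
#' species level); slopes and intercepts — the quantities the prediction
#' equations use — are unaffected.
#'
#' @param data A `"trait_matrix"` on the log scale.
#' @param tree A `"phylo"` tree containing all species in `data`.
#' @param spec A [model_spec()].
#' @return Object of class `"pmm_fit"`: `draws` (retained samples of fixed
#'   effects and variance components), `summary` (posterior mean, 95%
#'   credible bounds, effective sample size and pMCMC per fixed effect),
#'   `rmse_mm`, `spec`, and the design internals used for prediction.
#' @param prior_V,prior_nu Inverse-gamma hyperparameters of each variance
#'   component (shape `nu/2`, rate `nu * V / 2`); the defaults `V = 1`,
#'   `nu = 0.002` are the conventional weak choice.
#'
#' The fixed effects and the phylogenetic effect are updated jointly in one
#' Gaussian block (in the eigenbasis of `C`): when a predictor is itself
#' phylogenetically structured the two are strongly correlated a
#' posteriori, and separate one-at-a-time updates would mix far too slowly.
#' @seealso [fit_pgls_ml()] for the ML cross-check, [rmse_mm()],
#'   [rank_predictors()].
#' @export
fit_pmm <- function(data, tree, spec, prior_V = 1, prior_nu = 0.002) {
  d <- .build_design(data, tree, spec)
  ctrl <- spec$mcmc
  if (!is.null(ctrl$seed)) set.seed(ctrl$seed)
  y <- d$y
  X <- d$X
  sp <- d$sp_idx
  n_sp <- length(d$species)
  N <- length(y)
  p <- ncol(X)

  tree_f <- prune_tree(tree, d$species)
  C <- phylo_covariance(tree_f)[d$species, d$species]
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, max(eg$values) * 1e-12)
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    stop("phylogenetic covariance matrix is not positive semidefinite")
  }
  U <- eg$vectors
  counts <- tabulate(sp, n_sp)

  # joint (beta, v) block, v the phylogenetic effect in the eigenbasis of
  # C (u_phylo = U v): a predictor with phylogenetic structure makes beta
  # and u_phylo strongly correlated a posteriori, so they must be updated
  # together for the chain to mix
  XZ <- cbind(X, U[sp, , drop = FALSE])
  G <- crossprod(XZ)
  idx_b <- seq_len(p)
  idx_v <- p + seq_len(n_sp)
  pr_shape <- prior_nu / 2
  pr_rate <- prior_nu * prior_V / 2

  beta <- stats::coef(stats::lm.fit(X, y))
  beta[is.na(beta)] <- 0
  res0 <- y - drop(X %*% beta)
  s2 <- max(stats::var(res0), 1e-6)
  sigma2_p <- s2 / (3 * mean(diag(C)))
  sigma2_s <- s2 / 3
  sigma2_e <- s2 / 3
  u_s <- numeric(n_sp)    # species intercept

  n_keep <- (ctrl$iterations - ctrl$burn_in) %/% ctrl$thin
  pn <- c(colnames(X), "sigma2_phylo", "sigma2_species", "sigma2_resid")
  draws <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  kept <- 0L

  for (it in seq_len(ctrl$iterations)) {
    # joint fixed-effect + phylogenetic-effect draw
    r1 <- y - u_s[sp]
    P <- G / sigma2_e
    diag(P)[idx_b] <- diag(P)[idx_b] + 1e-10
    diag(P)[idx_v] <- diag(P)[idx_v] + 1 / (sigma2_p * lam)
    ch <- chol(P)
    b <- crossprod(XZ, r1) / sigma2_e
    theta <- backsolve(ch, forwardsolve(t(ch), b)) +
      backsolve(ch, stats::rnorm(p + n_sp))
    beta <- theta[idx_b]
    v <- theta[idx_v]
    u_sp <- drop(U %*% v)
    ss_p <- sum(v^2 / lam)
    xb <- drop(X %*% beta)
    # species intercept
    r2 <- y - xb - u_sp[sp]
    zr2 <- drop(rowsum(r2, sp, reorder = FALSE))
    prec_s <- counts / sigma2_e + 1 / sigma2_s
    u_s <- zr2 / sigma2_e / prec_s + stats::rnorm(n_sp) / sqrt(prec_s)
    # variance components
    resid <- r2 - u_s[sp]
    sigma2_p <- 1 / stats::rgamma(1, pr_shape + n_sp / 2,
                                  pr_rate + ss_p / 2)
    sigma2_s <- 1 / stats::rgamma(1, pr_shape + n_sp / 2,
                                  pr_rate + sum(u_s^2) / 2)
    sigma2_e <- 1 / stats::rgamma(1, pr_shape + N / 2,
                                  pr_rate + sum(resid^2) / 2)
    if (it > ctrl$burn_in && (it - ctrl$burn_in) %% ctrl$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(beta, sigma2_p, sigma2_s, sigma2_e)
    }
  }

  fit <- structure(list(draws = draws, spec = spec, design = d,
                        n_species = n_sp, n_records = N),
                   class = "pmm_fit")
  fit$summary <- .summarise_draws(draws, n_fixed = p)
  fit$rmse_mm <- rmse_mm(fit, data)
  fit
}

# posterior mean, 95% quantile credible bounds, ESS; pMCMC for fixed effects
.summarise_draws <- function(draws, n_fixed) {
  m <- nrow(draws)
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    lower = apply(draws, 2L, stats::quantile, 0.025),
                    upper = apply(draws, 2L, stats::quantile, 0.975),
                    ess = apply(draws, 2L, ess),
                    row.names = NULL)
  pm <- rep(NA_real_, ncol(draws))
  for (j in seq_len(n_fixed)) {
    pm[j] <- max(1 / m, 2 * min(mean(draws[, j] > 0),
                                mean(draws[, j] < 0)))
  }
  out$pMCMC <- pm
  out
}

#' Effective sample size of an MCMC chain
#'
#' Spectral estimate: the chain's variance divided by its spectral density
#' at frequency zero (from an AIC-selected autoregressive fit), times the
#' chain length; capped at the chain length.
#'
#' @param x Numeric vector of draws.
#' @return Scalar effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, n - 1L)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(n)
  s0 <- if (fit$order == 0L) fit$var.pred else
    fit$var.pred / (1 - sum(fit$ar))^2
  min(n, n * v / s0)
}

#' @export
print.pmm_fit <- function(x, digits = 3, ...) {
  cat("Phylogenetic mixed model:", x$spec$response, "~",
      paste(x$spec$predictors, collapse = " + "),
      if (x$spec$include_sex_interaction) "(+ sex interaction)" else "",
      "\n")
  cat(sprintf("%d species, %d records, %d retained draws, RMSE = %.2f mm\n",
              x$n_species, x$n_records, nrow(x$draws), x$rmse_mm))
  print(cbind(
    x$summary["parameter"],
    round(x$summary[c("mean", "lower", "upper", "ess", "pMCMC")], digits)))
  invisible(x)
}

#' Posterior-mean fixed effects of a fit
#' @param fit A `"pmm_fit"`.
#' @return Named numeric vector.
#' @export
fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "pmm_fit"))
  k <- ncol(fit$design$X)
  colMeans(fit$draws[, seq_len(k), drop = FALSE])
}

#' Root-mean-square error of back-transformed predictions, in mm
#'
#' Predictions use the posterior-mean fixed effects only (no BLUPs of the
#' random effects), back-transformed with a plain `exp()` — exactly the
#' published prediction equation `Y = exp(a + ln(x) b)`. The RMSE is taken
#' over all species-sex records of the training data, on the mm scale.
#'
#' @param fit A `"pmm_fit"`.
#' @param data The log-scale `"trait_matrix"` the model was fitted to.
#' @return RMSE in mm.
#' @export
rmse_mm <- function(fit, data) {
  stopifnot(inherits(fit, "pmm_fit"), inherits(data, "trait_matrix"))
  if (trait_scale(data) != "log") {
    stop("scale mismatch: data must be on the log scale")
  }
  d <- .build_design(data, NULL_tree_ok(fit), fit$spec)
  beta <- fixed_effects(fit)
  pred_mm <- exp(drop(d$X %*% beta))
  actual_mm <- exp(d$y)
  sqrt(mean((pred_mm - actual_mm)^2))
}

# rmse_mm rebuilds the design from data; the tree is only used for species
# checks, which the stored design already passed — reuse the fitted species.
NULL_tree_ok <- function(fit) {
  structure(list(tip.label = fit$design$species, Nnode = 1L),
            class = "phylo")
}

#' Maximum-likelihood GLS fit of the phylogenetic mixed model (oracle)
#'
#' Point estimates of the same model as [fit_pmm()] by direct maximum
#' likelihood: the marginal covariance `V = sigma2_p ZCZ' + sigma2_s ZZ' +
#' sigma2_e I` is parameterised by log variances and optimised numerically,
#' with the fixed effects profiled out by generalized least squares at each
#' evaluation. Used as an independent estimator to cross-check the Gibbs
#' sampler.
#'
#' @inheritParams fit_pmm
#' @return List with `beta` (ML/GLS fixed effects), `se_beta`, `sigma2_p`,
#'   `sigma2_s`, `sigma2_e`, `loglik`.
#' @export
fit_pgls_ml <- function(data, tree, spec) {
  d <- .build_design(data, tree, spec)
  y <- d$y
  X <- d$X
  N <- length(y)
  tree_f <- prune_tree(tree, d$species)
  C <- phylo_covariance(tree_f)[d$species, d$species]
  ZCZ <- C[d$sp_idx, d$sp_idx]
  ZZ <- outer(d$sp_idx, d$sp_idx, `==`) * 1

  nll <- function(lt) {
    s <- exp(lt)
    V <- s[1] * ZCZ + s[2] * ZZ + diag(s[3], N)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xi <- backsolve(ch, forwardsolve(t(ch), X))
    yi <- backsolve(ch, forwardsolve(t(ch), y))
    XtVX <- crossprod(X, Xi)
    beta <- solve(XtVX, crossprod(X, yi))
    r <- y - drop(X %*% beta)
    ri <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (2 * sum(log(diag(ch))) + sum(r * ri) + N * log(2 * pi))
  }
  s2 <- stats::var(y - drop(X %*% stats::coef(stats::lm.fit(X, y))))
  s2 <- max(s2, 1e-8)
  start <- log(c(s2 / (3 * mean(diag(C))), s2 / 3, s2 / 3))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  s <- exp(opt$par)
  V <- s[1] * ZCZ + s[2] * ZZ + diag(s[3], N)
  ch <- chol(V)
  Xi <- backsolve(ch, forwardsolve(t(ch), X))
  yi <- backsolve(ch, forwardsolve(t(ch), y))
  XtVX <- crossprod(X, Xi)
  beta <- drop(solve(XtVX, crossprod(X, yi)))
  names(beta) <- colnames(X)
  list(beta = beta, se_beta = sqrt(diag(solve(XtVX))),
       sigma2_p = s[1], sigma2_s = s[2], sigma2_e = s[3],
       loglik = -opt$value)
}

#' Test a sex-by-predictor interaction under phylogeny
#'
#' Refits the model with a sex main effect and a sex-by-predictor
#' interaction and reports the interaction's pMCMC (twice the smaller
#' posterior tail probability of its sign); the interaction is declared
#' significant below 0.05.
#'
#' @inheritParams fit_pmm
#' @return List with `fit` (the `"pmm_fit"`), `pMCMC`, `significant`.
#' @export
test_sex_interaction <- function(data, tree, spec) {
  spec2 <- model_spec(spec$response, spec$predictors,
                      include_sex_interaction = TRUE, mcmc = spec$mcmc)
  fit <- fit_pmm(data, tree, spec2)
  term <- paste0("sexmale:", spec$predictors[1])
  p <- fit$summary$pMCMC[fit$summary$parameter == term]
  list(fit = fit, pMCMC = p, significant = p < 0.05)
}

#' Rank candidate single predictors of a body-size trait by RMSE
#'
#' Fits one single-predictor phylogenetic mixed model per candidate and
#' orders them by ascending prediction RMSE (mm); ties break
#' alphabetically. The best predictor is the first row.
#'
#' @param data Log-scale `"trait_matrix"`.
#' @param tree A `"phylo"` tree.
#' @param response Response trait name.
#' @param candidates Character vector (length at least 2) of predictor
#'   trait names.
#' @param mcmc An [mcmc_control()].
#' @return List of class `"predictor_ranking"`: `table` (data frame with
#'   `predictor`, `rmse_mm`, `a`, `b`), `fits` (named list of
#'   `"pmm_fit"`s).
#' @export
rank_predictors <- function(data, tree, response, candidates,
                            mcmc = mcmc_control()) {
  stopifnot(length(candidates) >= 2L)
  fits <- list()
  rows <- list()
  for (p in candidates) {
    fit <- fit_pmm(data, tree, model_spec(response, p, mcmc = mcmc))
    fits[[p]] <- fit
    be <- fixed_effects(fit)
    rows[[p]] <- data.frame(predictor = p, rmse_mm = fit$rmse_mm,
                            a = be[["(Intercept)"]], b = be[[p]])
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$rmse_mm, tab$predictor), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, response = response),
            class = "predictor_ranking")
}

#' @export
print.predictor_ranking <- function(x, ...) {
  cat("Predictor ranking for", x$response, "(ascending RMSE):\n")
  print(transform(x$table, rmse_mm = round(rmse_mm, 3),
                  a = round(a, 3), b = round(b, 3)))
  invisible(x)
}

#' Fit a two-predictor phylogenetic mixed model
#'
#' Adds a secondary predictor to a single-predictor model; random structure
#' unchanged. Nearly collinear predictors (|r| > 0.999) trigger a warning.
#'
#' @inheritParams rank_predictors
#' @param primary,secondary Predictor trait names (`secondary != primary`).
#' @return A `"pmm_fit"`.
#' @export
fit_two_predictor <- function(data, tree, response, primary, secondary,
                              mcmc = mcmc_control()) {
  if (identical(primary, secondary)) {
    warning("secondary predictor duplicates the primary; ",
            "fitting the single-predictor model")
    return(fit_pmm(data, tree, model_spec(response, primary, mcmc = mcmc)))
  }
  df <- as.data.frame(data)
  if (all(c(primary, secondary) %in% names(df))) {
    cc <- stats::complete.cases(df[c(primary, secondary)])
    r <- stats::cor(df[[primary]][cc], df[[secondary]][cc])
    if (abs(r) > 0.999) {
      warning(sprintf("predictors nearly collinear (r = %.4f)", r))
    }
  }
  fit_pmm(data, tree, model_spec(response, c(primary, secondary),
                                 mcmc = mcmc))
}

#' Extract a coefficient set from a fitted model
#'
#' Packages the posterior-mean intercept and slope(s), with their 95%
#' credible bounds, in the form consumed by [predict_simple()] and
#' [predict_multi()].
#'
#' @param fit A `"pmm_fit"`.
#' @return A `"coefficient_set"`.
#' @export
as_coefficient_set <- function(fit) {
  stopifnot(inherits(fit, "pmm_fit"))
  sm <- fit$summary
  pick <- function(nm, col) sm[[col]][sm$parameter == nm]
  preds <- fit$spec$predictors
  coefficient_set(
    response = fit$spec$response, predictors = preds,
    a = pick("(Intercept)", "mean"), b = pick(preds[1], "mean"),
    b2 = if (length(preds) == 2L) pick(preds[2], "mean") else NULL,
    bounds = list(
      a = c(pick("(Intercept)", "lower"), pick("(Intercept)", "upper")),
      b = c(pick(preds[1], "lower"), pick(preds[1], "upper")),
      b2 = if (length(preds) == 2L)
        c(pick(preds[2], "lower"), pick(preds[2], "upper")) else NULL),
    rmse_mm = fit$rmse_mm, source = "fitted")
}
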