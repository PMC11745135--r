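# scenario with the response trait regenerated under a configured slope so
# fitting response ~ toL targets a known coefficient
slope_scenario <- function(n_species, b = 0.95, a = -1.5,
                           sigma2_resid = 6e-4, seed = 1) {
  tp <- default_trait_params()
  i <- tp$trait == "carL"
  tp$b[i] <- b
  tp$a[i] <- a
  tp$sigma2_resid[i] <- sigma2_resid
  allometry_scenario(n_species = n_species, trait_params = tp,
                     missing_fraction = 0, seed = seed)
}

test_that("retained-draw bookkeeping matches the sampling schedule", {
  sim <- simulate_traits(standard_scenario(n_species = 20, seed = 2))
  dat <- log_means(sim)
  fit <- fit_pmm(dat, sim$tree,
                 model_spec("toL", "met5L",
                            mcmc = mcmc_control(50000, 50, 5000, seed = 1)))
  expect_identical(nrow(fit$draws), 900L)
  expect_true(all(fit$summary$ess <= 900 + 1e-9))
  expect_true(all(fit$draws[, c("sigma2_phylo", "sigma2_species",
                                "sigma2_resid")] > 0))
  expect_true(all(fit$summary$lower <= fit$summary$mean &
                    fit$summary$mean <= fit$summary$upper))

  fit2 <- fit_pmm(dat, sim$tree,
                  model_spec("toL", "met5L",
                             mcmc = mcmc_control(1000, 10, 200, seed = 1)))
  expect_identical(nrow(fit2$draws), 80L)
})

test_that("the sampler is reproducible under a fixed seed", {
  sim <- simulate_traits(standard_scenario(n_species = 25, seed = 4))
  dat <- log_means(sim)
  spec <- model_spec("toL", "met5L", mcmc = mcmc_control(800, 4, 200,
                                                         seed = 7))
  f1 <- fit_pmm(dat, sim$tree, spec)
  f2 <- fit_pmm(dat, sim$tree, spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("noiseless log-linear data give exact ML coefficients", {
  sim <- simulate_traits(noiseless_scenario(n_species = 30, seed = 11))
  spec <- model_spec("carL", "toL")
  ml <- fit_pgls_ml(sim$truth, sim$tree, spec)
  tp <- sim$scenario$trait_params
  expect_equal(unname(ml$beta[1]), tp$a[tp$trait == "carL"],
               tolerance = 1e-8)
  expect_equal(unname(ml$beta[2]), tp$b[tp$trait == "carL"],
               tolerance = 1e-8)
})

test_that("without phylogenetic signal the ML fit matches ordinary OLS", {
  tr <- simulate_tree(120, 0.05, seed = 31)
  set.seed(32)
  x <- rnorm(240, 3, 0.5)
  y <- 1.2 + 0.8 * x + rnorm(240, 0, 0.1)
  dat <- trait_matrix(data.frame(
    species = rep(tr$tip.label, each = 2),
    sex = rep(c("female", "male"), 120), toL = y, met5L = x),
    scale = "log")
  spec <- model_spec("toL", "met5L")
  ml <- fit_pgls_ml(dat, tr, spec)
  ols <- unname(stats::coef(stats::lm(y ~ x)))
  expect_equal(unname(ml$beta), ols, tolerance = 0.01)

  # Gibbs posterior mean agrees with OLS within Monte-Carlo error
  fit <- fit_pmm(dat, tr, model_spec("toL", "met5L",
                                     mcmc = mcmc_control(4000, 4, 1000,
                                                         seed = 5)))
  psd <- apply(fit$draws[, 1:2], 2, stats::sd)
  expect_true(all(abs(fixed_effects(fit) - ols) < 2 * psd))
})

test_that("Gibbs posterior means track the ML oracle on synthetic data", {
  for (seed in c(3, 14)) {
    sim <- simulate_traits(slope_scenario(60, seed = seed))
    dat <- log_means(sim)
    spec <- model_spec("carL", "toL", mcmc = test_mcmc(seed))
    fit <- fit_pmm(dat, sim$tree, spec)
    ml <- fit_pgls_ml(dat, sim$tree, spec)
    psd <- apply(fit$draws[, 1:2], 2, stats::sd)
    expect_true(all(abs(fixed_effects(fit) - ml$beta) < 2 * psd))
  }
})

test_that("posterior credible intervals cover a configured slope", {
  rd <- recovery_data(100, b = 0.95, seed = 8)
  fit <- fit_pmm(rd$data, rd$tree,
                 model_spec("carL", "toL", mcmc = test_mcmc(1)))
  sm <- fit$summary
  expect_gt(sm$upper[sm$parameter == "toL"], 0.95)
  expect_lt(sm$lower[sm$parameter == "toL"], 0.95)
})

test_that("posterior is robust to the variance-prior strength", {
  sim <- simulate_traits(slope_scenario(50, seed = 6))
  dat <- log_means(sim)
  spec <- model_spec("carL", "toL", mcmc = test_mcmc(2))
  f1 <- fit_pmm(dat, sim$tree, spec)
  f2 <- fit_pmm(dat, sim$tree, spec, prior_nu = 0.02)
  psd <- stats::sd(f1$draws[, "toL"])
  expect_lt(abs(fixed_effects(f1)[["toL"]] - fixed_effects(f2)[["toL"]]),
            psd)
})

test_that("RMSE back-transforms to mm correctly", {
  # hand-built fit: a = 0, b = 1 predicts met5L itself
  spec <- model_spec("toL", "met5L")
  dat <- trait_matrix(data.frame(species = c("s1", "s2"), sex = "female",
                                 toL = log(c(12, 8)),
                                 met5L = log(c(10, 8))), scale = "log")
  draws <- matrix(rep(c(0, 1, 1e-6, 1e-6, 1e-6), 2), 2, byrow = TRUE)
  colnames(draws) <- c("(Intercept)", "met5L", "sigma2_phylo",
                       "sigma2_species", "sigma2_resid")
  fake <- structure(list(draws = draws, spec = spec,
                         design = list(X = cbind(1, log(c(10, 8))),
                                       species = c("s1", "s2"))),
                    class = "pmm_fit")
  expect_equal(rmse_mm(fake, dat), sqrt(4 / 2), tolerance = 1e-10)

  # log-perfect predictions give zero RMSE
  dat0 <- trait_matrix(data.frame(species = c("s1", "s2"), sex = "female",
                                  toL = log(c(10, 8)),
                                  met5L = log(c(10, 8))), scale = "log")
  expect_equal(rmse_mm(fake, dat0), 0)
  expect_error(rmse_mm(fake, to_mm(dat0)), "scale mismatch")
})

test_that("sex interactions are detected when present and not otherwise", {
  base <- simulate_traits(slope_scenario(100, seed = 41))
  dat <- log_means(base)
  spec <- model_spec("carL", "toL", mcmc = test_mcmc(3))

  # equal slopes (sex offset only): interaction non-significant
  res_null <- test_sex_interaction(dat, base$tree, spec)
  expect_false(res_null$significant)
  # the sex main effect is still in the model
  expect_true("sexmale" %in% res_null$fit$summary$parameter)

  # inject a male-specific slope difference of 0.3
  df <- as.data.frame(dat)
  male <- df$sex == "male"
  df$carL[male] <- df$carL[male] +
    0.3 * (df$toL[male] - mean(df$toL))
  dat_alt <- trait_matrix(df, scale = "log")
  res_alt <- test_sex_interaction(dat_alt, base$tree, spec)
  expect_true(res_alt$significant)
  term <- res_alt$fit$summary
  est <- term$mean[term$parameter == "sexmale:toL"]
  expect_lt(abs(est - 0.3), 0.1)

  single <- trait_matrix(df[df$sex == "female", ], scale = "log")
  expect_error(test_sex_interaction(single, base$tree, spec),
               "both sexes")
})

test_that("the generating predictor outranks a pure-noise trait", {
  tp <- default_trait_params()
  i <- tp$trait == "cheW"
  tp$b[i] <- 0          # cheW carries no size information
  tp$a[i] <- 1
  tp$sigma2_resid[i] <- 5e-3
  sim <- simulate_traits(allometry_scenario(n_species = 60,
                                            trait_params = tp,
                                            missing_fraction = 0,
                                            seed = 51))
  dat <- log_means(sim)
  rk <- rank_predictors(dat, sim$tree, "toL", c("cheW", "met5L"),
                        mcmc = mcmc_control(2000, 4, 500, seed = 1))
  expect_identical(rk$table$predictor[1], "met5L")
  expect_lt(rk$table$rmse_mm[1], rk$table$rmse_mm[2])
  expect_s3_class(rk$fits$met5L, "pmm_fit")
})

test_that("a no-information secondary predictor leaves RMSE unchanged", {
  tp <- default_trait_params()
  i <- tp$trait == "cheW"
  tp$b[i] <- 0
  tp$a[i] <- 1
  tp$sigma2_resid[i] <- 5e-3
  sim <- simulate_traits(allometry_scenario(n_species = 60,
                                            trait_params = tp,
                                            missing_fraction = 0,
                                            seed = 52))
  dat <- log_means(sim)
  ctrl <- mcmc_control(2000, 4, 500, seed = 2)
  single <- fit_pmm(dat, sim$tree, model_spec("toL", "met5L", mcmc = ctrl))
  double <- fit_two_predictor(dat, sim$tree, "toL", "met5L", "cheW",
                              mcmc = ctrl)
  expect_lt(abs(double$rmse_mm - single$rmse_mm), 0.25 * single$rmse_mm)
  expect_identical(colnames(double$draws)[2:3], c("met5L", "cheW"))

  expect_warning(fit_two_predictor(dat, sim$tree, "toL", "met5L", "met5L",
                                   mcmc = ctrl), "duplicates")
})

test_that("design guards reject malformed model requests", {
  sim <- simulate_traits(standard_scenario(n_species = 20, seed = 5))
  dat <- log_means(sim)
  expect_error(model_spec("toL", "toL"), "response")
  expect_error(model_spec("toL", c("a", "b", "c")))
  expect_error(model_spec("toL", "legL"), "unknown trait")
  expect_error(fit_pmm(species_means(sim$records), sim$tree,
                       model_spec("toL", "met5L")), "log scale")
  df <- as.data.frame(dat)
  df$met5L <- df$met5L[1]
  expect_error(fit_pmm(trait_matrix(df, scale = "log"), sim$tree,
                       model_spec("toL", "met5L", mcmc = test_mcmc())),
               "constant")
})

test_that("effective sample size behaves like a spectral estimate", {
  set.seed(9)
  iid <- rnorm(800)
  expect_gt(ess(iid), 0.6 * 800)
  expect_lte(ess(iid), 800)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.95), 800))
  expect_lt(ess(ar1), 200)
  expect_equal(ess(rep(2, 50)), 50)
})
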