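# Shared fixtures, all built in code.

# the worked 3-tip tree: ((A:1,B:1):1,C:2);
three_tip_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# a small noise-free scenario: exact log-linear relations
noiseless_scenario <- function(n_species = 40, seed = 11) {
  tp <- default_trait_params(sigma2_resid = 0, sex_offset = 0)
  allometry_scenario(n_species = n_species, trait_params = tp,
                     individual_sd = 0, missing_fraction = 0, seed = seed)
}

# a moderate-noise scenario used by model-fitting tests
standard_scenario <- function(n_species = 60, seed = 7, ...) {
  allometry_scenario(n_species = n_species, missing_fraction = 0,
                     seed = seed, ...)
}

# log species means from a simulated dataset
log_means <- function(sim) to_log(species_means(sim$records))

# short MCMC settings for tests (bookkeeping tests set their own)
test_mcmc <- function(seed = 1) mcmc_control(4000, 3, 1000, seed = seed)

# data drawn from the mixed model's own generative process: BM predictor,
# BM phylogenetic residual, species intercept, iid record noise. Used by
# parameter-recovery checks, where the model must be correctly specified
# (species means of noisy individuals would add predictor measurement
# error and attenuate the slope).
recovery_data <- function(n_species, b = 0.95, a = -1.5, sigma2_p = 6e-4,
                          sigma2_s = 1e-3, sigma2_e = 5e-4, seed = 1) {
  set.seed(seed)
  tree <- simulate_tree(n_species, 0.05)
  x <- simulate_bm(tree, 0.0015, log(50))
  up <- simulate_bm(tree, sigma2_p)
  us <- stats::rnorm(n_species, 0, sqrt(sigma2_s))
  sp <- tree$tip.label
  df <- data.frame(species = rep(sp, 2),
                   sex = rep(c("female", "male"), each = n_species))
  df$toL <- x[df$species]
  df$carL <- a + b * df$toL + up[df$species] + us[match(df$species, sp)] +
    stats::rnorm(nrow(df), 0, sqrt(sigma2_e))
  list(tree = tree, data = trait_matrix(df, scale = "log"))
}

# star phylogeny with unit branch lengths
star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}
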