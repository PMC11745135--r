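#' Default per-trait allometric parameters
#'
#' Intercepts and slopes of `ln(trait) = a + b * ln(toL)` matching the
#' bundled buthid coefficient sets (inverted to the trait-on-size
#' direction), with a small phylogenetic residual rate and a log-scale
#' male-female offset proportional to each trait's slope.
#'
#' @param sigma2_resid Brownian rate of the per-trait residual (log^2 per My).
#' @param sex_offset Log-scale size offset of males relative to females
#'   (negative = males smaller); each trait receives `sex_offset * b`.
#' @return Data frame with columns `trait`, `a`, `b`, `sigma2_resid`,
#'   `sex_offset`.
#' @export
default_trait_params <- function(sigma2_resid = 2e-4, sex_offset = -0.06) {
  tab <- data.frame(
    trait = c("toL", "carL", "cheL", "cheW", "met5L", "met5W", "teL", "teW"),
    a = c(0, -2.18 / 1.01, -2.27 / 0.72, -3.40 / 0.63, -2.13 / 0.95,
          -3.13 / 0.71, -2.32 / 0.90, -3.29 / 0.82),
    b = c(1, 1 / 1.01, 1 / 0.72, 1 / 0.63, 1 / 0.95, 1 / 0.71, 1 / 0.90,
          1 / 0.82)
  )
  tab$sigma2_resid <- ifelse(tab$trait == "toL", 0, sigma2_resid)
  tab$sex_offset <- sex_offset * tab$b
  tab
}

#' Define a synthetic allometry scenario
#'
#' Fixes every knob of the generator: a pure-birth time-calibrated tree, a
#' latent log body size (`ln toL`) evolving by Brownian motion, seven traits
#' scaling log-linearly with size with phylogenetically correlated (Brownian)
#' residuals, an additive log-scale sex offset, within-species individual
#' noise, and completely-at-random missingness on the predictor traits.
#'
#' Defaults emulate a buthid-scale study: 195 species, crown age near 100 My
#' (`birth_rate` 0.05 per My), tip standard deviation of `ln toL` near 0.37
#' (`sigma2_size` 0.0015 per My, root at 50 mm), two individuals per sex,
#' 3% individual noise, and 13% missingness (the maximum observed per-trait
#' rate in the empirical matrices the generator emulates).
#'
#' @param n_species Number of tips.
#' @param birth_rate Speciation rate (per My) of the pure-birth tree.
#' @param sigma2_size Brownian rate of latent `ln toL` (log^2 per My).
#' @param root_size_mm Total length at the root, mm.
#' @param trait_params Data frame as from [default_trait_params()].
#' @param individual_sd Log-scale SD of individual measurements around the
#'   species-sex mean.
#' @param n_individuals Individuals measured per species and sex.
#' @param missing_fraction Fraction of species-sex cells masked per
#'   predictor trait (MCAR), in `[0, 1)`.
#' @param seed Integer seed making the whole scenario reproducible.
#' @return List of class `"allometry_scenario"`.
#' @export
allometry_scenario <- function(n_species = 195,
                               birth_rate = 0.05,
                               sigma2_size = 0.0015,
                               root_size_mm = 50,
                               trait_params = default_trait_params(),
                               individual_sd = 0.03,
                               n_individuals = 2,
                               missing_fraction = 0.13,
                               seed = 42L) {
  stopifnot(n_species >= 2, birth_rate > 0, sigma2_size >= 0,
            root_size_mm > 0, individual_sd >= 0, n_individuals >= 1,
            missing_fraction >= 0, missing_fraction < 1)
  stopifnot(all(c("trait", "a", "b", "sigma2_resid", "sex_offset") %in%
                  names(trait_params)))
  stopifnot(all(trait_params$trait %in% trait_names()),
            "toL" %in% trait_params$trait,
            all(is.finite(trait_params$b)),
            all(trait_params$sigma2_resid >= 0))
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 sigma2_size = sigma2_size, root_size_mm = root_size_mm,
                 trait_params = trait_params, individual_sd = individual_sd,
                 n_individuals = n_individuals,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "allometry_scenario")
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule (pure-birth) process conditioned on the number of extant tips; all
#' tips end at the present, so the tree is exactly ultrametric. Tips are
#' labeled `sp001`, `sp002`, ...
#'
#' @param n_tips Number of tips (at least 2).
#' @param birth_rate Speciation rate per My.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.05, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate Brownian motion on a tree
#'
#' Draws independent Gaussian increments on every branch (variance
#' `sigma2 * branch length`) and accumulates them from the root, so tip
#' values are multivariate normal with mean `root_value` and covariance
#' `sigma2 * C` where `C` is [phylo_covariance()] at `lambda = 1`.
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, root_value = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- numeric(n_node)
  root <- n_tip + 1L
  vals[root] <- root_value
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (e in seq_len(nrow(tree$edge))) {
    vals[tree$edge[e, 2L]] <- vals[tree$edge[e, 1L]] + inc[e]
  }
  out <- vals[seq_len(n_tip)]
  names(out) <- tree$tip.label
  out
}

#' Simulate an allometric trait dataset with known ground truth
#'
#' Runs a full scenario: simulates the tree, the latent size axis, the
#' per-trait phylogenetic residuals, the sex offsets, individual records
#' with lognormal measurement noise, and MCAR missingness on the predictor
#' traits (missingness removes all individuals of a species-sex-trait cell,
#' as in real data where nobody measured that cell). `toL` and `carL`, the
#' response traits, are never masked.
#'
#' @param scenario An [allometry_scenario()].
#' @return List of class `"synthetic_traits"`:
#'   \describe{
#'     \item{tree}{the simulated `"phylo"` tree}
#'     \item{records}{individual records (long format, mm) after masking}
#'     \item{truth}{complete ground-truth `"trait_matrix"` of species-sex
#'       means, log scale}
#'     \item{latent_log_size}{named vector of latent `ln toL` per species
#'       (female baseline)}
#'     \item{masked}{data frame of masked species-sex-trait cells}
#'     \item{scenario}{the input scenario}
#'   }
#' @export
simulate_traits <- function(scenario) {
  stopifnot(inherits(scenario, "allometry_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  tree <- simulate_tree(sc$n_species, sc$birth_rate, seed = NULL)
  size <- simulate_bm(tree, sc$sigma2_size, log(sc$root_size_mm))
  tp <- sc$trait_params
  species <- tree$tip.label

  # species-sex latent log values, one column per trait
  grid <- expand.grid(species = species, sex = .SEXES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$sex), , drop = FALSE]
  lat <- matrix(NA_real_, nrow(grid), nrow(tp),
                dimnames = list(NULL, tp$trait))
  for (j in seq_len(nrow(tp))) {
    resid <- if (tp$sigma2_resid[j] > 0) {
      simulate_bm(tree, tp$sigma2_resid[j])
    } else {
      stats::setNames(numeric(length(species)), species)
    }
    base <- tp$a[j] + tp$b[j] * size + resid
    lat[, j] <- base[grid$species] +
      ifelse(grid$sex == "male", tp$sex_offset[j], 0)
  }
  truth <- trait_matrix(cbind(grid, as.data.frame(lat)), scale = "log")

  # individual records with lognormal noise
  k <- sc$n_individuals
  rec <- do.call(rbind, lapply(seq_len(nrow(tp)), function(j) {
    mu <- rep(lat[, j], each = k)
    data.frame(species = rep(grid$species, each = k),
               sex = rep(grid$sex, each = k),
               trait = tp$trait[j],
               value_mm = exp(mu + stats::rnorm(length(mu), 0,
                                                sc$individual_sd)))
  }))

  # MCAR masking of predictor-trait cells (drop all their individuals)
  maskable <- setdiff(tp$trait, c("toL", "carL"))
  masked <- list()
  if (sc$missing_fraction > 0 && length(maskable) > 0) {
    n_cells <- nrow(grid)
    n_mask <- round(sc$missing_fraction * n_cells)
    for (tr in maskable) {
      idx <- sample.int(n_cells, n_mask)
      masked[[tr]] <- data.frame(species = grid$species[idx],
                                 sex = grid$sex[idx], trait = tr)
    }
  }
  masked <- if (length(masked)) do.call(rbind, masked) else
    data.frame(species = character(), sex = character(), trait = character())
  rownames(masked) <- NULL
  if (nrow(masked) > 0) {
    key <- function(d) paste(d$species, d$sex, d$trait)
    rec <- rec[!(key(rec) %in% key(masked)), , drop = FALSE]
  }
  rownames(rec) <- NULL

  structure(list(tree = tree, records = rec, truth = truth,
                 latent_log_size = size, masked = masked, scenario = sc),
            class = "synthetic_traits")
}

#' @export
print.synthetic_traits <- function(x, ...) {
  cat("Synthetic allometry dataset:", x$scenario$n_species, "species,",
      nrow(x$records), "individual records,", nrow(x$masked),
      "masked cells (seed", x$scenario$seed, ")\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the tree (Newick), the individual records and ground-truth matrix
#' (CSV) and a JSON sidecar holding the scenario and latent size axis.
#'
#' @param x A `"synthetic_traits"` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_traits"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(x$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(x$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  write_trait_matrix(x$truth, file.path(dir, "truth_log.csv"))
  sidecar <- list(scenario = unclass(x$scenario)[setdiff(
    names(x$scenario), "trait_params")],
    trait_params = x$scenario$trait_params,
    latent_log_size = as.list(x$latent_log_size))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
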