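#' Subset a trait matrix to one sex
#'
#' Phylogenetic PCA and most comparative analyses operate on one row per
#' species; this helper extracts a single sex's rows.
#'
#' @param x A `"trait_matrix"`.
#' @param sex `"female"` or `"male"`.
#' @return A `"trait_matrix"` with that sex's rows only.
#' @export
sex_subset <- function(x, sex) {
  stopifnot(inherits(x, "trait_matrix"), sex %in% .SEXES)
  out <- as.data.frame(x)[x$sex == sex, , drop = FALSE]
  if (nrow(out) == 0L) stop("no rows for sex ", sex)
  trait_matrix(out, scale = trait_scale(x))
}

# species-by-trait numeric matrix from a single-sex complete trait matrix,
# aligned to the tree's tip order
.species_matrix <- function(x, tree) {
  stopifnot(inherits(x, "trait_matrix"), inherits(tree, "phylo"))
  if (anyDuplicated(x$species)) {
    stop("one row per species required; subset to a single sex first")
  }
  tcols <- intersect(trait_names(), names(x))
  X <- as.matrix(as.data.frame(x)[tcols])
  rownames(X) <- x$species
  if (anyNA(X)) stop("matrix must be complete (impute first)")
  miss <- setdiff(x$species, tree$tip.label)
  if (length(miss) > 0L) {
    stop("species absent from tree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  tips <- intersect(tree$tip.label, x$species)
  X[tips, , drop = FALSE]
}

# joint multivariate Brownian log-likelihood of the trait matrix under
# C(lambda), with the GLS mean vector and the full evolutionary trait
# covariance R concentrated out at their ML values:
# ll = -nm/2 log(2pi) - m/2 log|C| - n/2 log|R_ML| - nm/2
.lambda_loglik <- function(lambda, X, C) {
  n <- nrow(X)
  m <- ncol(X)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetC <- 2 * sum(log(diag(ch)))
  Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- drop(crossprod(X, Ci1)) / sum(Ci1)
  Xc <- sweep(X, 2L, mu)
  W <- backsolve(ch, forwardsolve(t(ch), Xc))
  R <- crossprod(Xc, W) / n
  ldR <- determinant(R, logarithm = TRUE)
  if (ldR$sign <= 0) return(-Inf)
  -n * m / 2 * log(2 * pi) - m / 2 * logdetC -
    n / 2 * as.numeric(ldR$modulus) - n * m / 2
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Estimates the phylogenetic-signal multiplier lambda shared by all trait
#' columns, by maximising the joint multivariate Brownian likelihood of the
#' (complete, log-scale, single-sex) trait matrix under the
#' lambda-transformed covariance `C(lambda)` (see [phylo_covariance()]).
#' Each trait's ancestral mean and Brownian rate are concentrated out at
#' their ML values, and lambda is found by one-dimensional optimisation on
#' `[0, 1]` to tolerance 1e-6 (lambda above 1 can break positive
#' definiteness on ultrametric trees and is not searched).
#'
#' @param x A complete `"trait_matrix"` on the log scale, one row per
#'   species (see [sex_subset()]).
#' @param tree A `"phylo"` tree containing all the matrix's species.
#' @return List with `lambda` (the ML estimate) and `loglik`.
#' @export
estimate_lambda <- function(x, tree) {
  X <- .species_matrix(x, tree)
  if (nrow(X) < 3L) stop("need at least 3 species")
  if (!is_ultrametric(tree)) {
    warning("tree is not ultrametric; lambda transform is still defined")
  }
  tree <- prune_tree(tree, rownames(X))
  C <- phylo_covariance(tree)[rownames(X), rownames(X)]
  # collinear trait columns make the trait covariance singular and carry no
  # extra information about lambda; search on an independent column subset
  qx <- qr(sweep(X, 2L, colMeans(X)))
  if (qx$rank < ncol(X)) {
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  opt <- stats::optimize(.lambda_loglik, c(0, 1), X = X, C = C,
                         maximum = TRUE, tol = 1e-6)
  # the interior optimum can miss a boundary maximum; check both ends
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, .lambda_loglik(0, X, C), .lambda_loglik(1, X, C))
  best <- which.max(lls)
  list(lambda = cand[best], loglik = lls[best])
}

#' Phylogenetic principal component analysis under Pagel's lambda
#'
#' Principal components of the evolutionary (rate) covariance matrix,
#' accounting for phylogenetic non-independence: with `C = C(lambda_hat)`
#' the ML lambda transform of the tree covariance, the ancestral (GLS) mean
#' of each trait is `mu = (1' C^-1 X) / (1' C^-1 1)`, the evolutionary
#' covariance is `R = (X - mu)' C^-1 (X - mu) / (n - 1)`, and the axes are
#' the eigenvectors of `R`. Scores are `(X - mu) V`; loadings are the
#' evolutionary correlations between traits and axes,
#' `V[t,k] * sqrt(eigval_k) / sqrt(R[t,t])`; the variance share of each axis
#' is its eigenvalue as a percentage of the total. Each axis is oriented so
#' its largest-magnitude loading is positive (the sign of a principal axis
#' is arbitrary; published tables with all-negative first-axis loadings are
#' the same result up to this reflection, so compare absolute values).
#'
#' @inheritParams estimate_lambda
#' @param lambda Optional fixed lambda; by default the ML estimate is used.
#' @return Object of class `"phylo_pca_result"`: `lambda`, `loglik`,
#'   `scores`, `loadings`, `variance_pct`, `eigenvalues`, `phylo_mean`,
#'   `evol_vcv`.
#' @export
phylo_pca <- function(x, tree, lambda = NULL) {
  X <- .species_matrix(x, tree)
  tree <- prune_tree(tree, rownames(X))
  if (is.null(lambda)) {
    est <- estimate_lambda(x, tree)
    lambda <- est$lambda
    loglik <- est$loglik
  } else {
    loglik <- NA_real_
  }
  C <- phylo_covariance(tree, lambda)[rownames(X), rownames(X)]
  n <- nrow(X)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("singular phylogenetic covariance matrix")
  })
  Cinv <- chol2inv(ch)
  one <- rep(1, n)
  mu <- drop(one %*% Cinv %*% X) / drop(one %*% Cinv %*% one)
  Xc <- sweep(X, 2L, mu)
  R <- t(Xc) %*% Cinv %*% Xc / (n - 1)
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  eval <- pmax(eig$values, 0)
  scores <- Xc %*% V
  sd_t <- sqrt(diag(R))
  loadings <- sweep(V, 2L, sqrt(eval), `*`) / sd_t
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  axes <- paste0("PC", seq_len(ncol(V)))
  dimnames(scores) <- list(rownames(X), axes)
  dimnames(loadings) <- list(colnames(X), axes)
  dimnames(V) <- list(colnames(X), axes)
  structure(list(lambda = lambda, loglik = loglik, scores = scores,
                 loadings = loadings,
                 variance_pct = 100 * eval / sum(eval),
                 eigenvalues = eval, phylo_mean = mu, evol_vcv = R,
                 rotation = V),
            class = "phylo_pca_result")
}

#' @export
print.phylo_pca_result <- function(x, digits = 3, ...) {
  cat(sprintf("Phylogenetic PCA (lambda = %.4f)\n", x$lambda))
  k <- min(4L, length(x$variance_pct))
  cat("Variance (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$variance_pct[seq_len(k)]),
            collapse = ", "), "\n")
  cat("Loadings (first two axes):\n")
  print(round(x$loadings[, seq_len(min(2L, ncol(x$loadings))), drop = FALSE],
              digits))
  invisible(x)
}
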