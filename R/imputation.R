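#' Phylogenetically informed random-forest imputation
#'
#' Fills missing cells of a log-scale trait matrix by iterative random-forest
#' regression (the missForest algorithm): missing cells are initialised with
#' column means, then each incomplete column in turn (least missing first) is
#' regressed on all other trait columns plus the phylogenetic eigenvectors,
#' re-filling its missing cells with out-of-matrix predictions. Iteration
#' stops as soon as the normalised change in imputed values increases (the
#' previous iteration's values are returned) or after `max_iter` passes.
#' Each sex is imputed separately; observed cells are never modified.
#'
#' @param x A `"trait_matrix"` on the log scale.
#' @param eigenvectors Optional `"eigenvector_set"` (see
#'   [phylo_eigenvectors()]) whose labels cover the species in `x`; its
#'   columns are appended as fixed predictors, injecting tree structure into
#'   the imputation. `NULL` imputes from trait columns alone.
#' @param seed Optional integer seed (forest growing is stochastic).
#' @param ntree Trees per forest (default 100).
#' @param max_iter Maximum number of refinement passes (default 10).
#' @return The completed `"trait_matrix"` (log scale, no missing cells).
#' @export
impute <- function(x, eigenvectors = NULL, seed = NULL, ntree = 100,
                   max_iter = 10) {
  stopifnot(inherits(x, "trait_matrix"))
  if (trait_scale(x) != "log") {
    stop("impute expects a log-scale matrix; call to_log() first")
  }
  if (!is.null(seed)) set.seed(seed)
  tcols <- intersect(trait_names(), names(x))
  out <- as.data.frame(x)
  for (s in unique(out$sex)) {
    rows <- which(out$sex == s)
    sub <- as.matrix(out[rows, tcols, drop = FALSE])
    rownames(sub) <- out$species[rows]
    E <- NULL
    if (!is.null(eigenvectors)) {
      stopifnot(inherits(eigenvectors, "eigenvector_set"))
      missing_sp <- setdiff(rownames(sub), eigenvectors$labels)
      if (length(missing_sp) > 0L) {
        stop("eigenvectors missing species: ",
             paste(utils::head(missing_sp, 5L), collapse = ", "))
      }
      E <- eigenvectors$vectors[rownames(sub), , drop = FALSE]
    }
    out[rows, tcols] <- .impute_one_sex(sub, E, ntree, max_iter)
  }
  trait_matrix(out, scale = "log")
}

.impute_one_sex <- function(X, E, ntree, max_iter) {
  n_miss <- colSums(is.na(X))
  if (any(n_miss == nrow(X))) {
    stop("entirely missing column(s): ",
         paste(colnames(X)[n_miss == nrow(X)], collapse = ", "))
  }
  if (all(n_miss == 0L)) return(X)
  mask <- is.na(X)
  # mean initialisation, then column-wise RF refits, least missing first
  for (j in which(n_miss > 0L)) {
    X[mask[, j], j] <- mean(X[!mask[, j], j])
  }
  order_j <- order(n_miss)
  order_j <- order_j[n_miss[order_j] > 0L]
  prev_diff <- Inf
  X_prev <- X
  for (iter in seq_len(max_iter)) {
    X_new <- X
    for (j in order_j) {
      preds <- cbind(X_new[, -j, drop = FALSE], E)
      obs <- !mask[, j]
      fit <- randomForest::randomForest(x = preds[obs, , drop = FALSE],
                                        y = X_new[obs, j], ntree = ntree)
      X_new[!obs, j] <- stats::predict(fit, preds[!obs, , drop = FALSE])
    }
    diff <- sum((X_new[mask] - X[mask])^2) / sum(X_new[mask]^2)
    if (diff >= prev_diff) return(X)  # stopping rule: first increase
    X_prev <- X
    X <- X_new
    prev_diff <- diff
  }
  X
}

#' Normalised root-mean-square error of imputed values
#'
#' `sqrt( mean((truth - imputed)^2) / mean((truth - mean(truth))^2) )` over
#' the masked cells only, i.e. the RMSE normalised by the standard deviation
#' of the true values (population moments). 0 means perfect imputation; the
#' statistic is invariant to rescaling truth and imputed by a common factor.
#'
#' @param truth,imputed Numeric vectors or matrices of identical shape.
#' @param mask Logical vector/matrix marking the cells to score (the cells
#'   that were imputed). Must select at least one cell.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(truth, imputed, mask) {
  truth <- as.numeric(as.matrix(truth)[as.logical(mask)])
  imputed <- as.numeric(as.matrix(imputed)[as.logical(mask)])
  if (length(truth) == 0L) stop("mask selects no cells")
  if (length(truth) != length(imputed)) stop("shape mismatch")
  v <- mean((truth - mean(truth))^2)
  if (v <= 0) stop("zero variance in truth over masked cells")
  sqrt(mean((truth - imputed)^2) / v)
}

#' Masked-reimputation accuracy protocol
#'
#' Assesses imputation accuracy on a complete (no missing cells) mm-scale
#' matrix: per replicate, a fixed fraction of cells in each trait column is
#' masked uniformly at random within each sex, the masked matrix is
#' log-transformed and imputed with the tree's phylogenetic eigenvectors,
#' predictions are back-transformed to mm, and the NRMSE over the masked
#' cells is scored on the mm scale.
#'
#' @param complete_matrix A `"trait_matrix"` on the mm scale with no missing
#'   cells (prune to complete-case species first).
#' @param tree A `"phylo"` tree covering the matrix's species (extra tips
#'   are pruned away); its first `k` eigenvectors are computed once and
#'   reused across replicates.
#' @param fraction Fraction masked per trait column (default 0.13).
#' @param reps Number of mask-impute replicates per sex (default 10).
#' @param seed Integer seed.
#' @param k Number of phylogenetic eigenvectors (default 10).
#' @param ntree Trees per forest, passed to [impute()].
#' @return Object of class `"imputation_report"`: `per_rep` (rep x sex
#'   overall NRMSE), `per_trait` (sex x trait NRMSE averaged over reps),
#'   `mean_nrmse` (named per sex), plus `fraction` and `reps`.
#' @export
validate_imputation <- function(complete_matrix, tree, fraction = 0.13,
                                reps = 10, seed = 1L, k = 10, ntree = 100) {
  stopifnot(inherits(complete_matrix, "trait_matrix"),
            inherits(tree, "phylo"))
  if (trait_scale(complete_matrix) != "mm") {
    stop("complete_matrix must be on the mm scale")
  }
  tcols <- intersect(trait_names(), names(complete_matrix))
  vals <- as.data.frame(complete_matrix)[tcols]
  if (anyNA(vals)) stop("complete_matrix must have no missing cells")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (reps < 1) stop("reps must be at least 1")
  set.seed(seed)

  species <- unique(complete_matrix$species)
  if (length(setdiff(species, tree$tip.label)) > 0L) {
    stop("tree is missing species present in the matrix")
  }
  if (length(setdiff(tree$tip.label, species)) > 0L) {
    tree <- prune_tree(tree, species)
  }
  eig <- phylo_eigenvectors(tree, k = k)

  df <- as.data.frame(complete_matrix)
  per_rep <- list()
  per_cell <- list()
  for (s in unique(df$sex)) {
    rows <- which(df$sex == s)
    truth_mm <- as.matrix(df[rows, tcols, drop = FALSE])
    n <- length(rows)
    n_mask <- max(1L, round(fraction * n))
    for (r in seq_len(reps)) {
      mask <- matrix(FALSE, n, length(tcols),
                     dimnames = list(NULL, tcols))
      for (j in seq_along(tcols)) {
        mask[sample.int(n, n_mask), j] <- TRUE
      }
      masked <- truth_mm
      masked[mask] <- NA_real_
      mm <- trait_matrix(cbind(df[rows, c("species", "sex")],
                               as.data.frame(masked)), scale = "mm")
      done <- to_mm(impute(to_log(mm), eig, ntree = ntree))
      imp_mm <- as.matrix(as.data.frame(done)[tcols])
      per_rep[[length(per_rep) + 1L]] <-
        data.frame(rep = r, sex = s,
                   nrmse = nrmse(truth_mm, imp_mm, mask))
      tr_scores <- vapply(seq_along(tcols), function(j) {
        nrmse(truth_mm[, j], imp_mm[, j], mask[, j])
      }, numeric(1))
      per_cell[[length(per_cell) + 1L]] <-
        data.frame(rep = r, sex = s, trait = tcols, nrmse = tr_scores)
    }
  }
  per_rep <- do.call(rbind, per_rep)
  per_cell <- do.call(rbind, per_cell)
  per_trait <- stats::aggregate(nrmse ~ sex + trait, data = per_cell,
                                FUN = mean)
  mean_nrmse <- tapply(per_rep$nrmse, per_rep$sex, mean)
  structure(list(per_rep = per_rep, per_trait = per_trait,
                 mean_nrmse = mean_nrmse, fraction = fraction, reps = reps),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("Masked-reimputation report:", x$reps, "reps, fraction",
      x$fraction, "\n")
  for (s in names(x$mean_nrmse)) {
    cat(sprintf("  %s: mean NRMSE = %.4f\n", s, x$mean_nrmse[[s]]))
  }
  invisible(x)
}
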