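#' Read a phylogenetic tree from a Newick string or file
#'
#' Parses a single Newick tree with branch lengths. Labels are expected to be
#' unquoted and unique across tips; internal node labels are tolerated and
#' ignored by downstream operations. Branch lengths are interpreted as time
#' (million years) throughout the package.
#'
#' @param text A Newick string (ending in `;`), or the path of a file holding
#'   one Newick tree.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_depths(tr)
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (is.null(tree$edge.length)) {
    stop("Newick tree has no branch lengths; branch lengths are required")
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

# Minimal structural scan so malformed input fails with a character offset
# instead of an opaque ape error.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unbalanced ')' at offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at offset ",
         length(chars))
  }
  if (!grepl(";\\s*$", text)) {
    stop("malformed Newick: missing terminal ';' at offset ", nchar(text))
  }
  invisible(TRUE)
}

#' Write a tree to a Newick string or file
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root-to-tip path lengths
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Named numeric vector of tip depths (time units).
#' @export
tree_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within a relative tolerance of the
#' tree depth (default 1e-6), appropriate for time-calibrated trees written
#' at limited precision.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on the spread of tip depths.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tree_depths(tree)
  diff(range(d)) <= tol * max(d)
}

#' Prune a tree to a set of tips
#'
#' Drops all tips outside `keep`, collapsing the resulting unary internal
#' nodes with branch lengths summed so that path lengths between retained
#' tips are unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"), is.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("labels not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Under Brownian motion the covariance of two tips equals the depth of their
#' most recent common ancestor; the diagonal holds root-to-tip depths.
#' Pagel's lambda rescales the off-diagonal (shared-history) entries:
#' `C(lambda)[i,j] = lambda * C[i,j]` for `i != j`, leaving the diagonal
#' untouched. `lambda = 1` gives the untransformed Brownian covariance,
#' `lambda = 0` the star phylogeny (independent tips).
#'
#' @param tree A `"phylo"` object with nonnegative branch lengths.
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames, units of time.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  C <- ape::vcv.phylo(tree)
  if (lambda != 1) {
    d <- diag(C)
    C <- lambda * C
    diag(C) <- d
  }
  C
}

#' Cophenetic (patristic) distance matrix
#'
#' Sum of branch lengths on the path between every pair of tips. For an
#' ultrametric tree `d[i,j] = 2 * (depth - depth of MRCA(i,j))`.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Labeled symmetric matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Principal coordinates of a distance matrix
#'
#' Classical metric scaling: eigendecompose the double-centred matrix
#' `-1/2 * J %*% d^2 %*% J`, retain the axes with positive eigenvalues and
#' scale each eigenvector by the square root of its eigenvalue. Each axis is
#' oriented so that its largest-magnitude coordinate is positive, making
#' results reproducible across linear-algebra backends. Negative eigenvalues
#' (possible for non-metric distances; tree distances produce none) are
#' dropped.
#'
#' @param d Symmetric distance matrix with zero diagonal, optionally labeled.
#' @param k Number of axes requested (default 10). If fewer positive
#'   eigenvalues exist, that many are returned with a warning.
#' @return List of class `"eigenvector_set"`: `vectors` (n x k coordinate
#'   matrix), `eigenvalues` (nonincreasing, length k), `labels`.
#' @export
pcoa_eigenvectors <- function(d, k = 10) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("d must be a symmetric matrix")
  }
  if (max(abs(diag(d))) > 1e-8) stop("d must have zero diagonal")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  G <- -0.5 * d^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  # row-centring of the column-centred matrix completes J G J
  eig <- eigen(G, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-10 & eig$values > 0)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalues; returning ",
            length(pos), " axes instead of ", k)
    k <- length(pos)
  }
  idx <- pos[seq_len(k)]
  vec <- eig$vectors[, idx, drop = FALSE]
  val <- eig$values[idx]
  scores <- sweep(vec, 2L, sqrt(val), `*`)
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- labels
  colnames(scores) <- paste0("PCo", seq_len(k))
  structure(list(vectors = scores, eigenvalues = val, labels = labels),
            class = "eigenvector_set")
}

#' Phylogenetic eigenvectors for a tree
#'
#' Convenience wrapper: principal coordinates of the cophenetic distance
#' matrix, the standard way of summarising tree structure as predictor
#' columns for trait imputation.
#'
#' @inheritParams cophenetic_distances
#' @param k Number of eigenvectors (default 10).
#' @return An `"eigenvector_set"`, see [pcoa_eigenvectors()].
#' @export
phylo_eigenvectors <- function(tree, k = 10) {
  pcoa_eigenvectors(cophenetic_distances(tree), k = k)
}

#' @export
print.eigenvector_set <- function(x, ...) {
  cat("Phylogenetic eigenvector set:", length(x$labels), "species,",
      ncol(x$vectors), "axes\n")
  cat("Eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Lognormal calibration prior from an age interval
#'
#' Finds the lognormal distribution whose `p_lo` and `p_hi` quantiles equal
#' a calibration point's minimum and maximum age, as used to build node-age
#' priors for divergence dating. The solution is closed form: on the log
#' scale the quantile conditions are linear in `meanlog` and `sdlog`, giving
#' `sdlog = (log(hi) - log(lo)) / (z(p_hi) - z(p_lo))` and
#' `meanlog = log(lo) - sdlog * z(p_lo)`. For the default symmetric
#' probabilities `meanlog = (log(lo) + log(hi)) / 2`, i.e. the prior median
#' is the geometric mean of the interval bounds.
#'
#' @param lo,hi Minimum and maximum age (same time units as the tree),
#'   `0 < lo < hi`.
#' @param p_lo,p_hi Probabilities attached to `lo` and `hi` (defaults 0.025
#'   and 0.975).
#' @return List of class `"lognormal_prior"` with `meanlog` and `sdlog`.
#' @examples
#' pr <- lognormal_from_quantiles(53, 63)
#' qlnorm(c(0.025, 0.975), pr$meanlog, pr$sdlog)  # 53, 63
#' @export
lognormal_from_quantiles <- function(lo, hi, p_lo = 0.025, p_hi = 0.975) {
  if (!(lo > 0 && hi > 0)) stop("ages must be positive")
  if (lo >= hi) stop("lo must be smaller than hi")
  if (!(p_lo > 0 && p_hi < 1 && p_lo < p_hi)) {
    stop("need 0 < p_lo < p_hi < 1")
  }
  z_lo <- stats::qnorm(p_lo)
  z_hi <- stats::qnorm(p_hi)
  sdlog <- (log(hi) - log(lo)) / (z_hi - z_lo)
  meanlog <- log(lo) - sdlog * z_lo
  structure(list(meanlog = meanlog, sdlog = sdlog),
            class = "lognormal_prior")
}

#' @export
print.lognormal_prior <- function(x, ...) {
  cat(sprintf("Lognormal prior: meanlog = %.6f, sdlog = %.6f\n",
              x$meanlog, x$sdlog))
  cat(sprintf("  2.5%% / 97.5%% quantiles: %.4f / %.4f\n",
              stats::qlnorm(0.025, x$meanlog, x$sdlog),
              stats::qlnorm(0.975, x$meanlog, x$sdlog)))
  invisible(x)
}

#' Batch lognormal priors from a calibration table
#'
#' @param calibrations Data frame with columns `node_label`, `min_age`,
#'   `max_age` (the CSV schema used by the `priors` CLI subcommand).
#' @return Data frame with `node_label`, `meanlog`, `sdlog`.
#' @export
calibration_priors <- function(calibrations) {
  need <- c("node_label", "min_age", "max_age")
  if (!all(need %in% names(calibrations))) {
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(calibrations)), function(i) {
    pr <- lognormal_from_quantiles(calibrations$min_age[i],
                                   calibrations$max_age[i])
    data.frame(node_label = calibrations$node_label[i],
               meanlog = pr$meanlog, sdlog = pr$sdlog)
  })
  do.call(rbind, out)
}
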