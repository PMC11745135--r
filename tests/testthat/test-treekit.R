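test_that("Newick parsing preserves structure and round-trips", {
  tr <- three_tip_tree()
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(unname(tree_depths(tr)), c(2, 2, 2))
  expect_true(is_ultrametric(tr))

  two <- read_newick("(A:1,B:1);")
  expect_length(two$tip.label, 2L)
  expect_true(is_ultrametric(two))

  rt <- read_newick(write_newick(tr))
  expect_equal(cophenetic_distances(rt), cophenetic_distances(tr))
})

test_that("a simulated large tree survives write/re-read", {
  tr <- simulate_tree(268, 0.05, seed = 5)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_length(back$tip.label, 268L)
  expect_true(is_ultrametric(back))
  lab <- tr$tip.label
  expect_equal(cophenetic_distances(back)[lab, lab],
               cophenetic_distances(tr), tolerance = 1e-8)
})

test_that("malformed Newick fails with an offset; missing lengths fail", {
  expect_error(read_newick("((A:1,B:1):1,C:2"), "offset")
  expect_error(read_newick("(A:1,B:1));"), "offset")
  expect_error(read_newick("(A,B);"), "branch length")
  expect_error(read_newick("(A:1,A:1);"), "duplicate")
})

test_that("pruning preserves path lengths and rejects unknown labels", {
  tr <- three_tip_tree()
  expect_identical(prune_tree(tr, c("A", "B", "C")), tr)

  pr <- prune_tree(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(cophenetic_distances(pr)["A", "C"], 4)
  expect_equal(unname(tree_depths(pr)), c(2, 2))

  expect_error(prune_tree(tr, c("A", "Z")), "Z")

  big <- simulate_tree(268, 0.05, seed = 9)
  keep <- sort(sample(big$tip.label, 195))
  pr2 <- prune_tree(big, keep)
  expect_setequal(pr2$tip.label, keep)
  expect_equal(cophenetic_distances(pr2),
               cophenetic_distances(big)[keep, keep], tolerance = 1e-10)
})

test_that("pruning preserves the cophenetic submatrix on random trees", {
  set.seed(42)
  for (i in 1:100) {
    tr <- simulate_tree(sample(5:12, 1), 0.2)
    keep <- sort(sample(tr$tip.label, sample(3:4, 1)))
    expect_equal(cophenetic_distances(prune_tree(tr, keep)),
                 cophenetic_distances(tr)[keep, keep], tolerance = 1e-10)
  }
})

test_that("phylogenetic covariance follows shared path lengths and lambda", {
  two <- read_newick("(A:1,B:1);")
  expect_equal(phylo_covariance(two),
               matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B"))))
  tr <- three_tip_tree()
  C <- phylo_covariance(tr)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)

  C0 <- phylo_covariance(tr, lambda = 0)
  expect_equal(unname(C0), diag(2, 3))

  Ch <- phylo_covariance(tr, lambda = 0.5)
  expect_equal(Ch["A", "B"], 0.5)
  expect_equal(unname(diag(Ch)), c(2, 2, 2))

  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(phylo_covariance(bad), "negative")
})

test_that("covariance matrices of simulated trees are PSD", {
  set.seed(3)
  for (i in 1:20) {
    C <- phylo_covariance(simulate_tree(sample(5:40, 1), 0.1))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
})

test_that("cophenetic distances are path sums obeying the four-point rule", {
  tr <- three_tip_tree()
  d <- cophenetic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(cophenetic_distances(read_newick("(A:1,B:1);"))["A", "B"], 2)

  set.seed(8)
  for (i in 1:20) {
    d <- cophenetic_distances(simulate_tree(6, 0.2))
    idx <- utils::combn(6, 4)
    for (j in seq_len(ncol(idx))) {
      q <- idx[, j]
      sums <- c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]])
      s <- sort(sums)
      expect_lte(s[3] - s[2], 1e-8)  # two largest sums equal
    }
  }
})

test_that("classical scaling recovers coordinates and distances", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  ax <- suppressWarnings(pcoa_eigenvectors(d2, k = 1))
  expect_equal(unname(sort(ax$vectors[, 1])), c(-1, 1))
  expect_gt(ax$vectors[which.max(abs(ax$vectors[, 1])), 1], 0)

  # tree distances are Euclidean-embeddable: full-rank axes reproduce them
  tr <- simulate_tree(8, 0.2, seed = 21)
  d <- cophenetic_distances(tr)
  ax <- suppressWarnings(pcoa_eigenvectors(d, k = 8))
  rec <- as.matrix(dist(ax$vectors))
  expect_equal(rec[rownames(d), colnames(d)], d, tolerance = 1e-7,
               ignore_attr = TRUE)

  # axis 1 separates the two cherries of a balanced 4-tip tree
  quartet <- read_newick("((A:1,B:1):2,(C:1,D:1):2);")
  ax4 <- suppressWarnings(pcoa_eigenvectors(cophenetic_distances(quartet),
                                            k = 3))
  s1 <- sign(ax4$vectors[c("A", "B", "C", "D"), 1])
  expect_equal(s1[["A"]], s1[["B"]])
  expect_equal(s1[["C"]], s1[["D"]])
  expect_true(s1[["A"]] != s1[["C"]])

  expect_warning(pcoa_eigenvectors(d2, k = 5), "positive eigenvalues")
  expect_equal(sort(diff(pcoa_eigenvectors(cophenetic_distances(tr),
                                           k = 7)$eigenvalues) <= 1e-9),
               rep(TRUE, 6))
})

test_that("lognormal priors match the requested quantiles", {
  pr <- lognormal_from_quantiles(10, 20)
  expect_equal(pr$meanlog, (log(10) + log(20)) / 2, tolerance = 1e-10)
  expect_equal(pr$meanlog, 2.649159, tolerance = 1e-6)
  expect_equal(pr$sdlog, log(2) / (2 * stats::qnorm(0.975)),
               tolerance = 1e-10)
  expect_equal(pr$sdlog, 0.176827, tolerance = 1e-5)
  expect_equal(exp(pr$meanlog), sqrt(10 * 20), tolerance = 1e-10)

  for (pair in list(c(10, 20), c(53, 63), c(0.5, 2), c(100, 400))) {
    pr <- lognormal_from_quantiles(pair[1], pair[2])
    q <- stats::qlnorm(c(0.025, 0.975), pr$meanlog, pr$sdlog)
    expect_equal(q, pair, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # asymmetric probabilities still round-trip
  pr <- lognormal_from_quantiles(5, 30, p_lo = 0.05, p_hi = 0.9)
  expect_equal(stats::qlnorm(c(0.05, 0.9), pr$meanlog, pr$sdlog), c(5, 30),
               tolerance = 1e-8)

  expect_error(lognormal_from_quantiles(20, 10), "smaller")
  expect_error(lognormal_from_quantiles(-1, 10), "positive")
  expect_error(lognormal_from_quantiles(1, 2, 0.9, 0.1), "p_lo")
})

test_that("batch calibration priors follow the CSV schema", {
  tab <- data.frame(node_label = c("crownA", "crownB"),
                    min_age = c(53, 39.7), max_age = c(63, 46.6))
  out <- calibration_priors(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(stats::qlnorm(0.975, out$meanlog[2], out$sdlog[2]), 46.6,
               tolerance = 1e-8)
  expect_error(calibration_priors(data.frame(x = 1)), "columns")
})
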