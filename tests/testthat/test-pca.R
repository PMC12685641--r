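random_score_matrix <- function(seed, n = 10, p = 6) {
  set.seed(seed)
  matrix(stats::rexp(n * p), n, p,
         dimnames = list(sprintf("sp%02d", 1:n), sprintf("in%02d", 1:p)))
}

test_that("rank-1 input explains all variance in one component", {
  A <- outer(1:8, c(2, 1, 0.5, 4))
  rownames(A) <- sprintf("sp%d", 1:8)
  p <- run_pca(A)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$explained_variance_ratio[-1]), 0, tolerance = 1e-12)
})

test_that("loadings are orthonormal and variance ratios sum to one", {
  p <- run_pca(random_score_matrix(3))
  G <- t(p$loadings) %*% p$loadings
  expect_equal(unname(G), diag(ncol(p$loadings)), tolerance = 1e-8)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
})

test_that("component scores match a covariance eigensolver up to sign", {
  A <- random_score_matrix(7)
  p <- run_pca(A)
  X <- scale(A, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  k <- ncol(p$component_scores)
  oracle_scores <- X %*% eg$vectors[, seq_len(k)]
  for (j in seq_len(k)) {
    same <- max(abs(p$component_scores[, j] - oracle_scores[, j]))
    flip <- max(abs(p$component_scores[, j] + oracle_scores[, j]))
    expect_lt(min(same, flip), 1e-8)
  }
  # eigenvalue ratios agree too
  expect_equal(p$explained_variance_ratio[seq_len(k)],
               (eg$values / sum(eg$values))[seq_len(k)],
               tolerance = 1e-10)
})

test_that("species scores are permutation-equivariant and scale-invariant", {
  A <- random_score_matrix(9)
  p1 <- run_pca(A)
  perm <- sample(nrow(A))
  p2 <- run_pca(A[perm, ])
  expect_equal(p2$species_score, p1$species_score[perm])
  p3 <- run_pca(A * 17)
  expect_equal(p3$explained_variance_ratio, p1$explained_variance_ratio,
               tolerance = 1e-12)
  expect_equal(p3$species_score, p1$species_score, tolerance = 1e-10)
})

test_that("key-species band is inclusive and ordered", {
  p <- run_pca(random_score_matrix(5))
  s <- p$species_score
  # unit-median rescaling puts the median species at exactly 1
  expect_equal(unname(stats::median(s)), 1)
  sel <- select_key_species(p, 0.8, 1.2)
  expect_true(all(s[sel] >= 0.8 & s[sel] <= 1.2))
  expect_true(!is.unsorted(rev(s[sel])))
  # boundary score is included
  lo <- min(s[s >= 0.8])
  expect_true(names(s)[s == lo][1] %in% select_key_species(p, lo, 1.2))
  expect_error(select_key_species(p, 2, 1), "lo")
})

test_that("degenerate inputs are rejected", {
  Z <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(run_pca(Z), "degenerate")
  expect_error(run_pca(matrix(1:3, 3, 1)), "at least 2")
})
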