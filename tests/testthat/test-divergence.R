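test_that("standardization yields exact zero-mean unit-variance columns", {
  set.seed(13)
  M <- matrix(rnorm(40, 10, 3), 8, 5)
  Z <- standardize_means(M)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, var) - 1) < 1e-12))
  expect_equal(unclass(standardize_means(Z)), unclass(Z),
               tolerance = 1e-12, ignore_attr = TRUE)
  M[, 2] <- 7
  colnames(M) <- paste0("t", 1:5)
  expect_error(standardize_means(M), "constant")
})

test_that("pooled residual covariance diagonal equals each trait's QMr", {
  set.seed(14)
  tab <- random_phenotype_table(g = 8, k = 4, traits = c("a", "b", "c"))
  pcov <- pooled_residual_covariance(tab)
  expect_equal(pcov$df_r, 8 * 3)
  for (tr in c("a", "b", "c")) {
    a <- anova_crd(tab, tr)
    expect_equal(pcov$Sigma[tr, tr], a$QMr, tolerance = 1e-10)
  }
  expect_equal(pcov$Sigma, t(pcov$Sigma))
})

test_that("D2 reduces to squared Euclidean under identity covariance", {
  set.seed(15)
  M <- matrix(rnorm(15), 5, 3, dimnames = list(LETTERS[1:5], NULL))
  D <- mahalanobis_d2(M, diag(3))
  expect_equal(unname(D), unname(as.matrix(dist(M))^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D), ignore_attr = TRUE)
})

test_that("univariate D2 matches hand arithmetic", {
  M <- matrix(c(1, 3), 2, 1, dimnames = list(c("A", "B"), "t"))
  D <- mahalanobis_d2(M, matrix(4))
  expect_equal(D["A", "B"], 1)
})

test_that("D2 is invariant under nonsingular trait recodings", {
  set.seed(16)
  for (i in 1:10) {
    M <- matrix(rnorm(24), 6, 4)
    W <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
    A <- matrix(rnorm(16), 4, 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
    D1 <- mahalanobis_d2(M, W)
    D2 <- mahalanobis_d2(M %*% A, t(A) %*% W %*% A)
    expect_equal(unname(D1), unname(D2), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("near-singular covariance falls back to the pseudo-inverse", {
  M <- matrix(rnorm(9), 3, 3)
  W <- tcrossprod(c(1, 1, 1)) + diag(3) * 1e-14
  expect_warning(D <- mahalanobis_d2(M, W), "pseudo-inverse")
  expect_true(all(is.finite(D)))
})

test_that("standardized Euclidean distances match the naive oracle", {
  set.seed(17)
  M <- matrix(rnorm(15, 50, 10), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("t", 1:3)))
  D <- standardized_euclidean(M)
  Z <- scale(M)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D[i, j], sqrt(sum((Z[i, ] - Z[j, ])^2)), tolerance = 1e-12)
  }
  Dm <- standardized_euclidean(M, mean_variant = TRUE)
  expect_equal(unname(Dm), unname(D) / sqrt(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical rows at distance zero
  M2 <- rbind(M, M[1, ])
  rownames(M2) <- c(rownames(M), "dup")
  expect_equal(standardized_euclidean(M2)["g1", "dup"], 0)
})

test_that("Euclidean variants satisfy the triangle inequality", {
  set.seed(18)
  for (rep in 1:5) {
    M <- matrix(rnorm(21), 7, 3)
    rownames(M) <- paste0("g", 1:7)
    D <- standardized_euclidean(M)
    for (i in 1:7) for (j in 1:7) for (l in 1:7)
      expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-12)
  }
})

test_that("permuting genotypes permutes the distance matrix consistently", {
  set.seed(19)
  M <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  D <- mahalanobis_d2(M, diag(4))
  p <- c(3, 1, 5, 2, 4)
  Dp <- mahalanobis_d2(M[p, ], diag(4))
  expect_equal(Dp, D[p, p], ignore_attr = TRUE)
})
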