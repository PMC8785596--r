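test_that("correlation matrices are validated and match hand arithmetic", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  R <- correlation_matrix(x)
  # hand-computed Pearson r on the 5 points
  num <- sum((x[, 1] - 3) * (x[, 2] - 3.2))
  den <- sqrt(sum((x[, 1] - 3)^2) * sum((x[, 2] - 3.2)^2))
  expect_equal(R["a", "b"], num / den)
  expect_equal(diag(R), c(a = 1, b = 1))

  dup <- cbind(x, c = x[, 1])
  expect_equal(correlation_matrix(dup)["a", "c"], 1)
  expect_error(correlation_matrix(cbind(a = 1:5, b = rep(2, 5))),
               "constant item.*b")
  set.seed(8)
  z <- matrix(rnorm(5000 * 4), ncol = 4)
  Rz <- correlation_matrix(z)
  expect_lt(max(abs(Rz[lower.tri(Rz)])), 0.05)
})

test_that("KMO is 1/2 for any correlated pair and matches the Schur oracle", {
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(kmo_msa(R2)$msa_overall, 0.5)

  lam <- rep(0.6, 14)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  got <- kmo_msa(R)
  # oracle: partial correlations via Schur complements, independent route
  p <- ncol(R)
  q2 <- r2 <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + 2 * R[i, j]^2
    q2 <- q2 + 2 * partial_cor_schur(R, i, j)^2
  }
  expect_equal(got$msa_overall, r2 / (r2 + q2), tolerance = 1e-12)
  expect_equal(unname(got$msa_per_item), rep(got$msa_overall, p))

  # pure-noise correlations: partial correlations inflate relative to the
  # raw ones and sampling adequacy drops below the 0.5 acceptability line
  set.seed(44)
  noise <- matrix(rnorm(40 * 14), 40)
  expect_lt(kmo_msa(correlation_matrix(noise))$msa_overall, 0.5)
  expect_gt(got$msa_overall, 0.8)  # coherent single factor is adequate
})

test_that("Bartlett's sphericity matches its closed form", {
  expect_equal(bartlett_sphericity(diag(5), 100)$chi2, 0)
  expect_equal(bartlett_sphericity(diag(5), 100)$p, 1)

  R <- matrix(0.5, 3, 3); diag(R) <- 1
  # hand evaluation: |R| = 1 + 2 r^3 - 3 r^2 = 0.5 at r = 0.5, p = 3
  got <- bartlett_sphericity(R, 100)
  expect_equal(got$chi2, -(100 - 1 - 11 / 6) * log(0.5))
  expect_equal(got$df, 3)
  expect_gt(bartlett_sphericity(R, 500)$chi2, got$chi2)  # grows with n
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2), 10),
               "positive definite")
})

test_that("principal-axis factoring recovers a population single factor", {
  lam <- c(0.45, 0.44, 0.42, 0.42, 0.38, 0.37, 0.36, 0.35, 0.35, 0.34,
           0.30, 0.29, 0.26, 0.23)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  efa <- principal_axis_efa(R, n_factors = 1)
  expect_lt(max(abs(drop(efa$loadings) - lam)), 0.01)
  expect_true(all(efa$communalities <= 1))
  expect_equal(kaiser_retention(efa$eigenvalues), 1)

  id <- principal_axis_efa(diag(6), n_factors = 1)
  expect_lt(max(abs(id$loadings)), 1e-6)
  expect_true(all(colSums(efa$loadings) >= 0))  # deterministic sign
  expect_error(principal_axis_efa(R, n_factors = 14), "between 1 and p-1")
})

test_that("factor loadings reproduce the off-diagonal correlations", {
  lam <- seq(0.25, 0.6, length.out = 8)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  efa <- principal_axis_efa(R, n_factors = 1)
  fitted <- tcrossprod(efa$loadings)
  off <- !diag(8)
  expect_lt(max(abs(R[off] - fitted[off])), 1e-4)
})

test_that("Kaiser retention counts eigenvalues strictly above one", {
  expect_equal(kaiser_retention(c(3.2, 0.9, 0.5)), 1)
  expect_equal(kaiser_retention(c(0.9, 0.8)), 0)
  expect_equal(kaiser_retention(c(1.0, 0.5)), 0)  # exactly 1 not retained
  expect_equal(kaiser_retention(c(2.5, 1.3, 0.2)), 2)
})

test_that("Cronbach's alpha follows both closed forms", {
  # standardized: k = 2, r = 0.5 => 2 * 0.5 / 1.5
  set.seed(3)
  z <- rnorm(4000)
  x <- cbind(z + rnorm(4000), z + rnorm(4000))
  a <- cronbach_alpha(x, standardized = TRUE)
  r <- cor(x)[1, 2]
  expect_equal(a, 2 * r / (1 + r))

  perf <- cbind(1:10, 2 * (1:10))
  expect_equal(cronbach_alpha(perf, standardized = TRUE), 1)

  set.seed(4)
  indep <- matrix(rnorm(6000), ncol = 3)
  expect_lt(abs(cronbach_alpha(indep, standardized = TRUE)), 0.1)

  # raw form equals its variance decomposition, hand-evaluated
  x5 <- cbind(c(1, 2, 3, 4, 5), c(2, 2, 4, 5, 5), c(1, 3, 3, 4, 6))
  raw <- cronbach_alpha(x5, standardized = FALSE)
  expect_equal(raw, (3 / 2) * (1 - sum(apply(x5, 2, var)) / var(rowSums(x5))))
  expect_error(cronbach_alpha(x5[, 1, drop = FALSE]), "at least 2")
})

test_that("weighted kappa matches a hand-computed 3x3 table to 1e-10", {
  # observed counts: rows rater A, columns rater B
  #   20  5  1
  #    4 15  6
  #    2  5 18        n = 76, row sums (26,25,25), col sums (26,25,25)
  # linear disagreement weights |i-j|/2:
  #   sum(w p)  = (2.5 + 1 + 2 + 3 + 2 + 2.5)/76 = 13/76
  #   sum(w e)  = (325 + 650 + 325 + 312.5 + 650 + 312.5)/76^2 = 2575/5776
  #   kappa     = 1 - (13/76)/(2575/5776) = 1 - 988/2575
  a <- rep(c("T1", "T1", "T1", "T2", "T2", "T2", "T3", "T3", "T3"),
           c(20, 5, 1, 4, 15, 6, 2, 5, 18))
  b <- rep(c("T1", "T2", "T3", "T1", "T2", "T3", "T1", "T2", "T3"),
           c(20, 5, 1, 4, 15, 6, 2, 5, 18))
  k <- weighted_kappa(a, b, scheme = "linear")
  expect_equal(k$kappa, 1 - 988 / 2575, tolerance = 1e-10)
  expect_gt(k$se, 0)
})

test_that("kappa is 1 for identical raters and 0 under independence", {
  x <- rep(c("T1", "T2", "T3"), times = c(10, 12, 9))
  expect_equal(weighted_kappa(x, x)$kappa, 1)
  # population table equal to the outer product of its marginals
  a <- rep(c("T1", "T2"), each = 10)
  b <- rep(rep(c("T1", "T2"), each = 5), 2)
  expect_equal(weighted_kappa(a, b)$kappa, 0)
  expect_error(weighted_kappa(rep("T1", 5), rep("T1", 5)), "single category")
})

test_that("quadratic weights reward near-diagonal disagreement more than linear", {
  a <- rep(c("T1", "T2", "T3"), times = c(12, 12, 12))
  b <- a
  b[c(1, 13, 25)] <- c("T2", "T3", "T2")  # adjacent-category slips only
  kl <- weighted_kappa(a, b, scheme = "linear")$kappa
  kq <- weighted_kappa(a, b, scheme = "quadratic")$kappa
  expect_gte(kq, kl)
})

test_that("psychometric statistics ignore observation order", {
  set.seed(31)
  z <- rnorm(200)
  x <- sapply(1:5, function(i) z + rnorm(200))
  perm <- sample(200)
  expect_equal(cronbach_alpha(x), cronbach_alpha(x[perm, ]))
  expect_equal(correlation_matrix(x), correlation_matrix(x[perm, ]))
  a <- sample(c("T1", "T2", "T3"), 200, replace = TRUE)
  b <- sample(c("T1", "T2", "T3"), 200, replace = TRUE)
  expect_equal(weighted_kappa(a, b)$kappa,
               weighted_kappa(a[perm], b[perm])$kappa)
})
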