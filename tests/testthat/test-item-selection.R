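make_selection_cohort <- function(n = 40) {
  set.seed(99)
  cov <- base_covariates(n)
  cov$age <- sample(55:75, n, replace = TRUE)
  cov$sex <- sample(c("female", "male"), n, replace = TRUE)
  cov$center <- sample(c("C01", "C02"), n, replace = TRUE)
  cov$energy_kcal <- round(runif(n, 1500, 3000))
  cov$pa_level <- sample(c("low", "medium", "high"), n, replace = TRUE)
  cov$bp_med <- sample(0:1, n, replace = TRUE)
  cov$dm_med <- sample(0:1, n, replace = TRUE)
  cov$working <- sample(0:1, n, replace = TRUE)
  cov$education <- sample(c("primary", "secondary", "college"), n,
                          replace = TRUE)
  cov$civil <- sample(c("married", "single", "widowed_divorced"), n,
                      replace = TRUE)
  cohort <- cbind(data.frame(participant_id = sprintf("s%02d", seq_len(n))),
                  cov,
                  itA = sample(0:8, n, replace = TRUE),
                  itB = sample(0:8, n, replace = TRUE),
                  itC = sample(0:8, n, replace = TRUE))
  cohort$tertile_agreement <- rep(c(0L, 1L), length.out = n)
  cohort
}

test_that("the design matrix matches a hand-encoded oracle column for column", {
  cohort <- make_selection_cohort()
  d <- build_design_matrix(cohort, tiny_config(), "gA")
  # hand encoding: intercept, predictor, continuous pass-through, dummies
  # against the alphabetically first level of each categorical covariate
  grid <- ffq_frequency_grid()$times_per_day
  expect_equal(unname(d$X[, "(Intercept)"]), rep(1, 40))
  expect_equal(unname(d$X[, "gA"]), grid[cohort$itA + 1])
  expect_equal(unname(d$X[, "age"]), cohort$age)
  expect_equal(unname(d$X[, "sexmale"]), as.numeric(cohort$sex == "male"))
  expect_equal(unname(d$X[, "centerC02"]), as.numeric(cohort$center == "C02"))
  expect_equal(unname(d$X[, "energy_kcal"]), cohort$energy_kcal)
  # pa_level reference is "high" (alphabetically first)
  expect_equal(unname(d$X[, "pa_levellow"]), as.numeric(cohort$pa_level == "low"))
  expect_equal(unname(d$X[, "pa_levelmedium"]),
               as.numeric(cohort$pa_level == "medium"))
  # education reference is "college"
  expect_equal(unname(d$X[, "educationprimary"]),
               as.numeric(cohort$education == "primary"))
  expect_equal(unname(d$X[, "educationsecondary"]),
               as.numeric(cohort$education == "secondary"))
  # civil reference is "married"
  expect_equal(unname(d$X[, "civilsingle"]), as.numeric(cohort$civil == "single"))
  expect_equal(unname(d$X[, "civilwidowed_divorced"]),
               as.numeric(cohort$civil == "widowed_divorced"))
  expect_equal(unname(d$X[, "bp_med"]), as.numeric(cohort$bp_med))
  expect_equal(ncol(d$X), 15L)
  expect_equal(d$y, cohort$tertile_agreement)
  expect_equal(nrow(d$X), 40L)
})

test_that("degenerate design matrices raise informative errors", {
  cohort <- make_selection_cohort()
  cohort$itA <- 0L  # all-never group => constant predictor
  expect_error(build_design_matrix(cohort, tiny_config(), "gA"),
               "constant column.*gA")
  cohort2 <- make_selection_cohort()
  cohort2$tertile_agreement <- NULL
  expect_error(build_design_matrix(cohort2, tiny_config(), "gA"),
               "tertile_agreement")
  expect_error(build_design_matrix(make_selection_cohort(), tiny_config(),
                                   "no_such_group"),
               "unknown predictor")
})

test_that("intercept-only logistic fits reproduce the closed form log(n1/n0)", {
  y <- rep(c(0, 1), c(10, 10))
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-10)  # logit(0.5) = 0
  y2 <- rep(c(0, 1), c(5, 15))
  expect_equal(unname(fit_logistic(X, y2)$beta), log(15 / 5), tolerance = 1e-8)
})

test_that("IRLS matches brute-force likelihood maximization on a toy dataset", {
  x <- c(1, 2, 2, 3, 3, 4)
  y <- c(0, 0, 1, 0, 1, 1)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_logistic(X, y)
  oracle <- gridsearch_logit(x, y)
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
})

test_that("IRLS agrees with glm on the fixture cohort", {
  cohort <- make_selection_cohort()
  d <- build_design_matrix(cohort, tiny_config(), "gA")
  fit <- fit_logistic(d)
  ref <- stats::glm.fit(d$X, d$y, family = stats::binomial())
  expect_equal(unname(fit$beta), unname(ref$coefficients), tolerance = 1e-6)
})

test_that("a predictor independent of the outcome stays null", {
  set.seed(314)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  fit <- fit_logistic(cbind(1, x), y)
  expect_lt(abs(fit$z[2]), 3)
  expect_gt(fit$p_raw[2], 0.001)
})

test_that("complete separation is reported as such", {
  x <- c(rep(0, 20), rep(5, 20))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(cbind(1, x), y), "separation")
})

test_that("Bonferroni caps at one and scales by the number of tests", {
  expect_equal(bonferroni_adjust(0.001, 33), 0.033)
  expect_equal(bonferroni_adjust(0.5, 33), 1)
  expect_equal(bonferroni_adjust(0, 33), 0)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("selection demands a positive coefficient and adjusted significance", {
  results <- data.frame(
    predictor = c("sugary_drinks", "semi_skimmed_dairy", "whole_dairy"),
    beta = c(3.90, -0.15, -0.01),
    p_bonf = c(1e-4, 1e-4, 1)
  )
  expect_equal(select_items(results), "sugary_drinks")
})

test_that("selection is invariant to candidate ordering", {
  synth <- generate_cohort(synthetic_config(n_participants = 800, seed = 21))
  filt <- apply_cohort_filters(synth$cohort, synth$config)
  fwd <- association_table(filt$cohort, synth$config)
  rev_config <- synth$config[rev(seq_len(nrow(synth$config))), ]
  bwd <- association_table(filt$cohort, rev_config)
  expect_setequal(select_items(fwd), select_items(bwd))
})
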