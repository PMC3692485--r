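test_that("OLS recovers a noiseless linear model exactly", {
  set.seed(1)
  X <- cbind(x1 = rnorm(50), x2 = rnorm(50))
  y <- 2 * X[, 1] - X[, 2] + 3
  fit <- fit_linear(X, y)
  expect_equal(unname(fit$coefficients),
               c(3, 2, -1), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$d, 3)
})

test_that("interaction designs carry all pairwise products", {
  set.seed(2)
  X <- matrix(rnorm(10 * 39), 10, 39,
              dimnames = list(NULL, sprintf("f%02d", 1:39)))
  D <- build_design(X, interactions = TRUE)
  expect_equal(ncol(D), 39 + choose(39, 2))
  expect_equal(choose(39, 2), 741)
  # product columns really are products
  expect_equal(D[, "f01:f02"], X[, "f01"] * X[, "f02"])
})

test_that("rank-deficient designs and undersized samples are rejected", {
  set.seed(3)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_linear(X, rnorm(30)), "collinear")
  expect_error(fit_linear(X[1:3, 1:2], rnorm(3)), "m <= d")
})

test_that("null responses give uniform p-values and no BH discoveries", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 8), 500, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rnorm(500)
    fit <- fit_linear(X, y)
    sum(fit$p_adj[-1] < 0.001)
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})

test_that("cross-validation is exact on noiseless data and near zero on null", {
  set.seed(4)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5) + 1
  cv <- cross_validate(X, y, seed = 1)
  expect_equal(cv$mean_r, 1, tolerance = 1e-9)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(length(cv$folds), 200)

  null_r <- vapply(1:5, function(s) {
    set.seed(s + 100)
    Xn <- matrix(rnorm(1000 * 5), 1000, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
    cross_validate(Xn, rnorm(1000), seed = s)$mean_r
  }, numeric(1))
  expect_true(all(abs(null_r) < 0.1))
})

test_that("cross-validated accuracy approaches the generator's closed form", {
  sc <- make_feature_scenario(m = 5000, seed = 11)
  X <- sc$data[, setdiff(colnames(sc$data), "exon_expr")]
  cv <- cross_validate(X, sc$data[, "exon_expr"], seed = 11)
  expect_equal(cv$mean_r, sc$truth$true_r, tolerance = 0.05)
})

test_that("CV accuracy is invariant to feature column order", {
  sc <- make_feature_scenario(m = 1000, seed = 5)
  X <- sc$data[, setdiff(colnames(sc$data), "exon_expr")]
  y <- sc$data[, "exon_expr"]
  r1 <- cross_validate(X, y, seed = 9)$mean_r
  r2 <- cross_validate(X[, rev(colnames(X))], y, seed = 9)$mean_r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("shuffled-input control collapses a strong model to chance", {
  # many mutually independent marks, one carrying the signal: any
  # derangement sends the informative column to an uninformative slot
  sc <- make_feature_scenario(
    v = 39, m = 1000, seed = 6,
    edges = data.frame(a = character(), b = character(),
                       pcor = numeric()),
    coef = c(gene_expr = 0, 1.0, 0), noise_sd = 0.35)
  X <- sc$data[, setdiff(colnames(sc$data), c("gene_expr", "exon_expr"))]
  y <- sc$data[, "exon_expr"]
  expect_gt(cross_validate(X, y, seed = 2)$mean_r, 0.9)
  shuf <- vapply(1:5, function(s) {
    shuffle_control(X, y, seed = s)$mean_r
  }, numeric(1))
  expect_true(all(abs(shuf) < 0.2))
  expect_error(shuffle_control(X[, 1, drop = FALSE], y), "at least 2")
  # the only derangement of two columns is the swap
  set.seed(1)
  expect_equal(histonet:::sample_derangement(2), c(2L, 1L))
})

test_that("improvement ratio follows its formula", {
  expect_equal(improvement_ratio(0.70, 0.68), 0.02857143,
               tolerance = 1e-6)
  expect_equal(improvement_ratio(0.5, 0.5), 0)
  expect_equal(improvement_ratio(0.5, 0.6), -0.2)
  expect_error(improvement_ratio(0, 0.5), "zero")
})

test_that("combination enumeration covers C(N,1)+C(N,2) models and ranks drivers", {
  set.seed(8)
  X <- matrix(rnorm(400 * 3), 400, 3, dimnames = list(NULL, c("A", "B", "C")))
  y <- X[, "A"] + X[, "B"] + rnorm(400, sd = 0.3)
  out <- enumerate_combination_models(X, y, seed = 1)
  expect_equal(nrow(out$combos), 3 + 3)
  expect_false(is.unsorted(out$combos$mean_r))
  best2 <- out$combos$features[out$combos$size == 2]
  expect_equal(best2[length(best2)], "A+B")
  best1 <- out$combos$features[out$combos$size == 1]
  expect_true(best1[length(best1)] %in% c("A", "B"))
})

test_that("transfer prediction reproduces in-sample accuracy on the training data", {
  set.seed(9)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X %*% c(1, 0.5, -0.5, 0) + rnorm(300, sd = 0.5)
  fit <- fit_linear(X, y)
  tp <- transfer_predict(fit, X, y)
  expect_equal(tp$r, stats::cor(y, fit$fitted), tolerance = 1e-12)
  expect_equal(transfer_predict(fit, X, fit$fitted)$r, 1, tolerance = 1e-12)
  expect_error(transfer_predict(fit, X[, 1:3], y), "missing feature")
})

test_that("model trained on one stratum transfers to another sharing coefficients", {
  set.seed(10)
  m <- 3000
  X <- matrix(rnorm(2 * m * 5), 2 * m, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- X %*% c(1, 0.8, 0, 0, -0.5) + rnorm(2 * m, sd = 0.6)
  train <- seq_len(m)
  fit <- fit_linear(X[train, ], y[train])
  within_r <- cross_validate(X[train, ], y[train], seed = 3)$mean_r
  transfer_r <- transfer_predict(fit, X[-train, ], y[-train])$r
  expect_equal(transfer_r, within_r, tolerance = 0.05)
})

test_that("BIC matches the brute-force Gaussian likelihood and its penalty", {
  set.seed(12)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(200, sd = 0.8)
  fit <- fit_linear(X, y)
  expect_equal(bic_of_fit(fit), brute_force_bic(fit$residuals, fit$d),
               tolerance = 1e-8)
  # one extra near-duplicate regressor with no fit gain costs about ln(m)
  X2 <- cbind(X, d = X[, "a"] + rnorm(200, sd = 1e-6))
  fit2 <- fit_linear(X2, y)
  expect_equal(bic_of_fit(fit2) - bic_of_fit(fit), log(200),
               tolerance = 0.2)
  # same d and data size, larger RSS: BIC increases
  fit_a <- fit_linear(X[, "a", drop = FALSE], y)
  fit_b <- fit_linear(X[, "b", drop = FALSE], y)
  expect_gt(fit_b$rss, fit_a$rss)
  expect_gt(bic_of_fit(fit_b), bic_of_fit(fit_a))
  expect_error(bic_of_fit(list(rss = 0, m = 10, d = 2)), "RSS")
})

test_that("OLS recovers generating coefficients within standard errors", {
  cover <- unlist(lapply(1:5, function(s) {
    sc <- make_feature_scenario(m = 2000, seed = s)
    X <- sc$data[, setdiff(colnames(sc$data), "exon_expr")]
    fit <- fit_linear(X, sc$data[, "exon_expr"])
    truth <- sc$truth$coef[names(fit$coefficients)[-1]]
    abs(fit$coefficients[-1] - truth) <= 3 * fit$se[-1]
  }))
  expect_gte(mean(cover), 0.95)
})
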