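test_that("the three-correlation closed form behaves at its fixed points", {
  # numerator cancels exactly: 0.4 - 0.8*0.5 = 0
  expect_equal(partial_correlation_triple(0.4, 0.8, 0.5), 0)
  # identical variables stay perfectly correlated given anything
  for (c in c(-0.9, 0, 0.6)) {
    expect_equal(partial_correlation_triple(1, c, c), 1)
  }
  expect_error(partial_correlation_triple(0.5, 1, 0.2), "degenerate")
})

test_that("the closed form equals the residual-correlation definition on toy data", {
  a <- c(1.2, -0.4, 0.8, 2.1, -1.0)
  b <- c(0.3, 0.9, -1.2, 1.4, 0.6)
  c <- c(-0.5, 1.1, 0.2, 0.9, -1.3)
  closed <- partial_correlation_triple(cor(a, b), cor(a, c), cor(b, c))
  expect_equal(closed, lm_residual_pcor(a, b, c), tolerance = 1e-12)
})

test_that("precision-matrix pcors equal double-residual-regression pcors", {
  set.seed(21)
  worst <- 0
  for (i in 1:20) {
    v <- sample(3:8, 1)
    m <- sample(30:200, 1)
    data <- matrix(rnorm(m * v), m, v,
                   dimnames = list(NULL, paste0("v", seq_len(v))))
    P <- pairwise_partial_correlations(data)
    for (a in 1:(v - 1)) for (b in (a + 1):v) {
      worst <- max(worst, abs(P[a, b] - pcor_residual(data, a, b)))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("for three variables the full conditional matches the closed form", {
  set.seed(22)
  for (i in 1:10) {
    data <- matrix(rnorm(60 * 3), 60, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
    P <- pairwise_partial_correlations(data)
    C <- cor(data)
    expect_equal(P["A", "B"],
                 partial_correlation_triple(C["A", "B"], C["A", "C"],
                                            C["B", "C"]),
                 tolerance = 1e-10)
  }
})

test_that("independent columns give near-zero pcors; collinearity is refused", {
  set.seed(23)
  null_max <- vapply(1:5, function(s) {
    set.seed(s)
    data <- matrix(rnorm(4000 * 6), 4000, 6,
                   dimnames = list(NULL, paste0("v", 1:6)))
    P <- pairwise_partial_correlations(data)
    max(abs(P[upper.tri(P)]))
  }, numeric(1))
  expect_true(all(null_max < 3 / sqrt(4000) * 1.5))

  data <- matrix(rnorm(100 * 3), 100, 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  data[, "z"] <- data[, "x"] + 1e-9 * rnorm(100)
  expect_error(pairwise_partial_correlations(data), "collinear")
  expect_error(pairwise_partial_correlations(data[1:2, ]), "m > V")
})

test_that("estimated pcors converge to the generating precision pattern", {
  sc <- make_ggm_scenario(m = 20000, seed = 24)
  P <- pairwise_partial_correlations(sc$data)
  expect_lt(max(abs(P - sc$truth$pcors)), 0.05)
})

test_that("network BIC rewards true edges and penalizes noise edges", {
  empty <- data.frame(a = character(), b = character())
  sc <- make_ggm_scenario(m = 2000, seed = 25)
  # empty network = sum of intercept-only scores
  base <- sum(vapply(colnames(sc$data), function(v) {
    y <- sc$data[, v]
    brute_force_bic(y - mean(y), 1)
  }, numeric(1)))
  expect_equal(network_bic(sc$data, empty), base, tolerance = 1e-8)

  true_edge <- sc$truth$edges[1, c("a", "b")]
  noise_improves <- vapply(1:10, function(s) {
    scs <- make_ggm_scenario(m = 2000, seed = s + 200)
    with_true <- network_bic(scs$data, true_edge)
    # a pair from different graph components: fully independent in the
    # generator, so the edge buys nothing and pays the BIC penalty
    null_pair <- data.frame(a = "H3K4me1", b = "H3K36me3")
    with_noise <- network_bic(scs$data, null_pair)
    base_s <- network_bic(scs$data, empty)
    as.numeric(c(with_true < base_s, with_noise > base_s))
  }, numeric(2))
  expect_true(all(noise_improves[1, ] == 1))
  expect_gte(mean(noise_improves[2, ]), 0.8)
})

test_that("threshold selection keeps pairs through the last large BIC drop", {
  trace <- data.frame(a = letters[1:5], b = LETTERS[1:5],
                      pcor = c(0.9, 0.7, 0.5, 0.3, 0.1),
                      bic = cumsum(-c(100, 50, 30, 15, 5)),
                      diff = c(100, 50, 30, 15, 5))
  sel <- select_threshold(trace, 0.2)
  expect_equal(sel$index, 3)
  expect_equal(sel$threshold, 0.5)
  expect_equal(nrow(sel$edges), 3)
  # all-equal differences: every pair qualifies
  trace$diff <- rep(10, 5)
  expect_equal(select_threshold(trace, 0.2)$index, 5)
  expect_warning(sel1 <- select_threshold(trace[1, ], 0.2), "single pair")
  expect_equal(sel1$threshold, 0.9)
})

test_that("BIC-threshold selection recovers the generating edge set", {
  f1 <- vapply(1:10, function(s) {
    sc <- make_ggm_scenario(m = 2000, seed = s)
    sel <- select_threshold(bic_trace(sc$data), 0.2)
    edge_f1(sel$edges, sc$truth$edges)
  }, numeric(1))
  expect_gte(mean(f1), 0.9)
})

test_that("the BIC trace has one difference per added pair and is internally consistent", {
  sc <- make_ggm_scenario(v = 5, m = 500,
                          edges = data.frame(a = "H3K36me3",
                                             b = "H4K20me1", pcor = 0.4),
                          seed = 26)
  tr <- bic_trace(sc$data)
  expect_equal(nrow(tr), choose(5, 2))
  expect_equal(tr$diff[1], attr(tr, "bic0") - tr$bic[1])
  expect_equal(tr$diff[-1], -diff(tr$bic))
  expect_true(all(diff(abs(tr$pcor)) <= 1e-12))
  # step BICs equal scoring the cumulative edge set from scratch
  i <- 3
  expect_equal(tr$bic[i],
               network_bic(sc$data, tr[seq_len(i), c("a", "b")]),
               tolerance = 1e-8)
})

test_that("permutation preserves marginals, breaks structure and scores the threshold", {
  sc <- make_ggm_scenario(m = 400, seed = 27)
  sel <- select_threshold(bic_trace(sc$data), 0.2)
  perm <- permutation_null(sc$data, n_perm = 30, seed = 1,
                           threshold = sel$threshold)
  expect_gt(perm$z, 5)
  expect_lt(perm$max_abs, sel$threshold)
  # independent columns: the observed scale is the null scale
  set.seed(28)
  nd <- matrix(rnorm(400 * 5), 400, 5,
               dimnames = list(NULL, paste0("v", 1:5)))
  P <- pairwise_partial_correlations(nd)
  pn <- permutation_null(nd, n_perm = 30, seed = 2,
                         threshold = max(abs(P[upper.tri(P)])))
  expect_lt(abs(pn$z), 5)
  # a derangement is a permutation without fixed points
  set.seed(29)
  for (n in c(2, 3, 10)) {
    p <- histonet:::sample_derangement(n)
    expect_setequal(p, seq_len(n))
    expect_true(all(p != seq_len(n)))
  }
})

test_that("network assembly thresholds, normalizes and wires the driver scenario", {
  sc <- make_ggm_scenario(m = 1000, seed = 30)
  P <- pairwise_partial_correlations(sc$data)
  nw_empty <- build_network(P, threshold = 1.01)
  expect_equal(nrow(nw_empty$edges), 0)
  nw <- build_network(P, threshold = 0.15)
  expect_equal(max(abs(nw$edges$norm_pcor)), 1)

  scf <- make_feature_scenario(m = 5000, seed = 31)
  sel <- select_threshold(bic_trace(scf$data), 0.2)
  nwf <- build_network(pairwise_partial_correlations(scf$data),
                       sel$threshold, exon_col = "exon_expr")
  expect_setequal(network_neighbors(nwf, "exon_expr"),
                  c("gene_expr", scf$truth$drivers))
})
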