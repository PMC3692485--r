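#' Build a regression design from a signal matrix
#'
#' With `interactions = TRUE` the design carries the N main effects plus all
#' C(N, 2) pairwise products, named `"A:B"`.
#'
#' @param X Numeric matrix with column names (rows = genes or exons).
#' @param interactions Add all pairwise product terms?
#' @return Numeric matrix of regressors (intercept not included).
#' @export
build_design <- function(X, interactions = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("signal matrix must have column names")
  if (interactions && ncol(X) >= 2L) {
    cmb <- utils::combn(colnames(X), 2L)
    inter <- matrix(NA_real_, nrow = nrow(X), ncol = ncol(cmb))
    for (i in seq_len(ncol(cmb))) {
      inter[, i] <- X[, cmb[1L, i]] * X[, cmb[2L, i]]
    }
    colnames(inter) <- paste(cmb[1L, ], cmb[2L, ], sep = ":")
    X <- cbind(X, inter)
  }
  X
}

#' Ordinary least squares fit of expression on chromatin features
#'
#' Fits `y = b + sum_i a_i x_i (+ sum_{i<j} a_ij x_i x_j) + e` by OLS, with
#' two-sided t-tests per coefficient and Benjamini-Hochberg adjustment
#' across the non-intercept coefficient family.
#'
#' @param X Signal matrix (rows = observations, named columns = features).
#' @param y Response vector (gene or exon expression).
#' @param interactions Include all pairwise products as regressors?
#' @return A `FitResult`: `coefficients` (named, `(Intercept)` first), `se`,
#'   `t`, `p`, `p_adj` (BH over non-intercept terms), `rss`, `m` (rows),
#'   `d` (regressors including intercept), `feature_names`, `interactions`,
#'   `fitted`, `residuals`.
#' @export
fit_linear <- function(X, y, interactions = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  D <- cbind(`(Intercept)` = 1, build_design(X, interactions))
  m <- nrow(D)
  d <- ncol(D)
  if (m <= d) stop("m <= d: ", m, " rows for ", d, " regressors")
  q <- qr(D)
  if (q$rank < d) {
    kept <- q$pivot[seq_len(q$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(D)[setdiff(seq_len(d), kept)], collapse = ", "))
  }
  coef <- qr.coef(q, y)
  fitted <- drop(D %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (m - d)
  xtx_inv <- matrix(NA_real_, d, d)
  xtx_inv[q$pivot, q$pivot] <- chol2inv(qr.R(q))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(D)
  tval <- coef / se
  p <- 2 * stats::pt(-abs(tval), df = m - d)
  p_adj <- rep(NA_real_, d)
  names(p_adj) <- colnames(D)
  p_adj[-1L] <- stats::p.adjust(p[-1L], method = "BH")
  structure(
    list(coefficients = coef, se = se, t = tval, p = p, p_adj = p_adj,
         rss = rss, m = m, d = d,
         feature_names = colnames(X), interactions = interactions,
         fitted = fitted, residuals = resid),
    class = "FitResult"
  )
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("<FitResult %d obs, %d regressors%s, RSS %.4g>\n",
              x$m, x$d, if (x$interactions) " (with interactions)" else "",
              x$rss))
  invisible(x)
}

#' Predict from a fitted model on new signal data
#'
#' @param fit A `FitResult`.
#' @param X_new Matrix carrying at least the model's feature columns.
#' @return Vector of predictions.
#' @export
predict_fit <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  miss <- setdiff(fit$feature_names, colnames(X_new))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  D <- cbind(1, build_design(X_new[, fit$feature_names, drop = FALSE],
                             fit$interactions))
  drop(D %*% fit$coefficients)
}

# coefficient table in supplementary-style layout
#' Coefficient table of a fit
#' @param fit A `FitResult`.
#' @return data.frame: term, coefficient, se, t, p, p_adj.
#' @export
coefficient_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             coefficient = unname(fit$coefficients),
             se = unname(fit$se), t = unname(fit$t),
             p = unname(fit$p), p_adj = unname(fit$p_adj),
             stringsAsFactors = FALSE)
}

sample_derangement <- function(n) {
  if (n < 2L) stop("no derangement exists for n = 1")
  if (n == 2L) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Ten-fold cross-validated prediction accuracy
#'
#' Rows are randomly grouped into `k` folds (seeded; remainder rows spread
#' one per fold); the model is fit on k-1 folds and predicts the held-out
#' fold; accuracy is the mean over folds of the Pearson correlation between
#' measured and predicted response.
#'
#' @param X Signal matrix.
#' @param y Response vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param interactions Include pairwise products?
#' @param shuffle_perm Optional derangement of the feature columns applied
#'   to held-out rows only (the shuffled-input control: the model is trained
#'   with every modification in the right place and asked to predict from
#'   inputs where none is).
#' @return A `CVResult`: `folds`, `fold_r`, `mean_r`, `k`, `seed`.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L, interactions = FALSE,
                           shuffle_perm = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  if (m < 2L * k) stop("need at least 2k rows for ", k, "-fold CV")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), m))
  fold_r <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    D_tr <- cbind(1, build_design(X[!test, , drop = FALSE], interactions))
    q <- qr(D_tr)
    coef <- qr.coef(q, y[!test])
    coef[is.na(coef)] <- 0  # dropped collinear columns predict as zero
    X_te <- X[test, , drop = FALSE]
    if (!is.null(shuffle_perm)) {
      X_te <- X_te[, shuffle_perm, drop = FALSE]
      colnames(X_te) <- colnames(X)
    }
    pred <- drop(cbind(1, build_design(X_te, interactions)) %*% coef)
    if (stats::sd(y[test]) == 0) {
      stop("constant response within fold ", f, "; use larger folds")
    }
    if (stats::sd(pred) == 0) {
      stop("constant predictions within fold ", f, "; use larger folds")
    }
    fold_r[f] <- stats::cor(y[test], pred)
  }
  structure(list(folds = folds, fold_r = fold_r, mean_r = mean(fold_r),
                 k = k, seed = seed),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult %d-fold, mean Pearson r = %.4f>\n", x$k, x$mean_r))
  invisible(x)
}

#' Shuffled-input control for cross-validated accuracy
#'
#' Feature columns of the held-out rows are reassigned by a seeded
#' derangement (no modification stays in its own place) before prediction,
#' so a model that has genuinely learned per-feature weights collapses
#' toward chance.
#'
#' @inheritParams cross_validate
#' @return A `CVResult` for the shuffled-input predictions.
#' @export
shuffle_control <- function(X, y, k = 10L, seed = 1L,
                            interactions = FALSE) {
  if (ncol(X) < 2L) stop("need at least 2 features to shuffle")
  set.seed(seed)
  perm <- sample_derangement(ncol(X))
  cross_validate(X, y, k = k, seed = seed, interactions = interactions,
                 shuffle_perm = perm)
}

#' Improvement ratio between singleton and interaction models
#'
#' `(P_singleton - P_interaction) / P_singleton`, where both inputs are
#' cross-validated Pearson correlations. Negative values mean the
#' interaction model predicts better.
#'
#' @param p_singleton,p_interaction Mean CV Pearson correlations.
#' @return Scalar ratio.
#' @export
improvement_ratio <- function(p_singleton, p_interaction) {
  if (p_singleton == 0) stop("P_singleton is zero")
  (p_singleton - p_interaction) / p_singleton
}

#' Cross-validated accuracy of every one- and two-feature model
#'
#' Generates all feature combinations of the requested sizes, scores each by
#' [cross_validate()], and reports them sorted ascending by accuracy with
#' the full-model accuracy alongside as the reference line.
#'
#' @inheritParams cross_validate
#' @param sizes Combination sizes (default 1 and 2).
#' @return List: `combos` (data.frame `features`, `size`, `mean_r`, sorted
#'   ascending by `mean_r`) and `full_model_r`.
#' @export
enumerate_combination_models <- function(X, y, sizes = c(1L, 2L), k = 10L,
                                         seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 features")
  rows <- list()
  for (s in sizes) {
    cmb <- utils::combn(colnames(X), s)
    for (i in seq_len(ncol(cmb))) {
      feats <- cmb[, i]
      cv <- cross_validate(X[, feats, drop = FALSE], y, k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        features = paste(feats, collapse = "+"), size = s,
        mean_r = cv$mean_r, stringsAsFactors = FALSE)
    }
  }
  combos <- do.call(rbind, rows)
  combos <- combos[order(combos$mean_r), , drop = FALSE]
  rownames(combos) <- NULL
  full <- cross_validate(X, y, k = k, seed = seed)
  list(combos = combos, full_model_r = full$mean_r)
}

#' Transfer a fitted model to new data
#'
#' Applies a trained model to a new stratum or cell type and reports the
#' Pearson correlation between measured and predicted response together
#' with its t-test (`t = r sqrt(m - 2) / sqrt(1 - r^2)`).
#'
#' @param model A `FitResult`.
#' @param X_new Signal matrix with the model's features.
#' @param y_new Measured response for the new rows.
#' @return List: `r`, `t`, `p`, `n`, `predictions`.
#' @export
transfer_predict <- function(model, X_new, y_new) {
  pred <- predict_fit(model, X_new)
  n <- length(y_new)
  r <- stats::cor(y_new, pred)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, t = tval, p = p, n = n, predictions = pred)
}

bic_gaussian <- function(rss, m, d) {
  if (rss <= 0) stop("RSS is zero: degenerate Gaussian likelihood")
  m * (log(2 * pi * rss / m) + 1) + d * log(m)
}

#' Bayesian information criterion of an OLS fit
#'
#' `BIC = -2 ln L + d ln m` with the Gaussian likelihood at its MLE variance
#' `RSS/m`; `d` counts regressors including the intercept. Lower is better.
#'
#' @param fit A `FitResult`.
#' @return Scalar BIC.
#' @export
bic_of_fit <- function(fit) {
  bic_gaussian(fit$rss, fit$m, fit$d)
}
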