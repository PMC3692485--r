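#' Median high/low binning of a modification pair
#'
#' Each exon is labelled H or L per feature by strict comparison with that
#' feature's empirical median (ties at the median count as L), giving the
#' four bins LL, HL, LH, HH with the first letter for `f1`.
#'
#' @param values_f1,values_f2 Signal vectors of equal length (>= 4).
#' @param names Optional feature names `c(f1, f2)`.
#' @return A `BinAssignment`: `bin` (factor LL/HL/LH/HH), `medians`,
#'   `features`.
#' @export
median_bins <- function(values_f1, values_f2, names = c("f1", "f2")) {
  stopifnot(length(values_f1) == length(values_f2),
            length(values_f1) >= 4L)
  if (stats::sd(values_f1) == 0 || stats::sd(values_f2) == 0) {
    stop("constant feature vector: median binning degenerate")
  }
  med <- c(stats::median(values_f1), stats::median(values_f2))
  h1 <- values_f1 > med[1L]
  h2 <- values_f2 > med[2L]
  lab <- paste0(ifelse(h1, "H", "L"), ifelse(h2, "H", "L"))
  structure(list(bin = factor(lab, levels = c("LL", "HL", "LH", "HH")),
                 medians = stats::setNames(med, names), features = names),
            class = "BinAssignment")
}

#' Per-bin response summaries with pairwise rank-sum tests
#'
#' @param bins A `BinAssignment`.
#' @param response Response vector (e.g. exon expression), same length.
#' @return List: `summary` (data.frame per bin: n, mean, median, q1, q3)
#'   and `tests` (data.frame of two-sided Wilcoxon rank-sum p-values for
#'   every bin pair).
#' @export
bin_summary <- function(bins, response) {
  stopifnot(inherits(bins, "BinAssignment"),
            length(response) == length(bins$bin))
  tab <- table(bins$bin)
  if (any(tab == 0L)) {
    stop("empty bin(s): ", paste(names(tab)[tab == 0L], collapse = ", "))
  }
  lv <- levels(bins$bin)
  summ <- do.call(rbind, lapply(lv, function(b) {
    x <- response[bins$bin == b]
    data.frame(bin = b, n = length(x), mean = mean(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  cmb <- utils::combn(lv, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- response[bins$bin == cmb[1L, i]]
    b <- response[bins$bin == cmb[2L, i]]
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(bin_a = cmb[1L, i], bin_b = cmb[2L, i], p = p,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}

#' Singleton-vs-interaction comparison for network combinations
#'
#' For every network node with at least two neighbors, fits its value on
#' the neighbors with and without pairwise interaction terms, scores both
#' by cross-validation, and reports the improvement ratio. Nodes with fewer
#' than two neighbors are skipped (logged).
#'
#' @param network A `NetworkModel`.
#' @param data Numeric matrix with columns for every node.
#' @param k,seed Cross-validation controls.
#' @return data.frame: `node`, `n_neighbors`, `p_singleton`,
#'   `p_interaction`, `improvement_ratio`.
#' @export
network_combination_tests <- function(network, data, k = 10L, seed = 1L) {
  data <- as.matrix(data)
  rows <- list()
  for (node in network$nodes) {
    nbrs <- network_neighbors(network, node)
    if (length(nbrs) < 2L) {
      message("node ", node, " skipped: ", length(nbrs), " neighbor(s)")
      next
    }
    X <- data[, nbrs, drop = FALSE]
    y <- data[, node]
    cv_s <- cross_validate(X, y, k = k, seed = seed, interactions = FALSE)
    cv_i <- cross_validate(X, y, k = k, seed = seed, interactions = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, n_neighbors = length(nbrs),
      p_singleton = cv_s$mean_r, p_interaction = cv_i$mean_r,
      improvement_ratio = improvement_ratio(cv_s$mean_r, cv_i$mean_r),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(node = character(), n_neighbors = integer(),
                      p_singleton = numeric(), p_interaction = numeric(),
                      improvement_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise BIC along the partial-correlation order
#'
#' Features are added to the response regression one at a time in the given
#' order (descending |partial correlation with the response| upstream) and
#' the BIC recorded at each size; a feature that adds no rank (collinear
#' with those already in) is dropped with a warning.
#'
#' @param data Numeric matrix with named columns.
#' @param response Response column name.
#' @param order Character vector of feature names, most associated first.
#' @return data.frame: `k`, `feature_added`, `bic`.
#' @export
stepwise_bic_by_pcor <- function(data, response, order) {
  stopifnot(length(order) >= 1L, response %in% colnames(data))
  data <- as.matrix(data)
  y <- data[, response]
  used <- character(0)
  rows <- list()
  for (f in order) {
    cand <- c(used, f)
    D <- cbind(1, data[, cand, drop = FALSE])
    if (qr(D)$rank < ncol(D)) {
      warning("feature ", f, " collinear with current model; dropped")
      next
    }
    fit <- fit_linear(data[, cand, drop = FALSE], y)
    used <- cand
    rows[[length(rows) + 1L]] <- data.frame(
      k = length(used), feature_added = f, bic = bic_of_fit(fit),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Response-ordered signal matrix with clustered feature order
#'
#' Rows are sorted by ascending response; features are ordered by
#' average-linkage hierarchical clustering on (1 - Pearson correlation)
#' distance. The exported matrix is ready for heatmap plotting.
#'
#' @param signals Numeric matrix (rows x features, >= 2 features).
#' @param response Response vector, one value per row.
#' @return List: `matrix` (reordered), `feature_order`, `hclust`.
#' @export
cluster_matrix_export <- function(signals, response) {
  signals <- as.matrix(signals)
  stopifnot(ncol(signals) >= 2L, nrow(signals) == length(response))
  d <- stats::as.dist(1 - stats::cor(signals))
  hc <- stats::hclust(d, method = "average")
  feats <- colnames(signals)[hc$order]
  m <- signals[order(response), feats, drop = FALSE]
  list(matrix = m, feature_order = feats, hclust = hc)
}
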