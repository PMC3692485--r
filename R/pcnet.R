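#' Partial correlation from three pairwise correlations
#'
#' Closed form for the first-order partial correlation of A and B given C:
#' `(P_AB - P_AC P_BC) / sqrt((1 - P_AC^2)(1 - P_BC^2))`.
#'
#' @param p_ab,p_ac,p_bc Pairwise Pearson correlations.
#' @return Scalar partial correlation in `[-1, 1]`.
#' @export
partial_correlation_triple <- function(p_ab, p_ac, p_bc) {
  stopifnot(abs(p_ab) <= 1, abs(p_ac) <= 1, abs(p_bc) <= 1)
  if (abs(p_ac) == 1 || abs(p_bc) == 1) {
    stop("degenerate conditioning: |correlation with C| = 1")
  }
  (p_ab - p_ac * p_bc) / sqrt((1 - p_ac^2) * (1 - p_bc^2))
}

#' Full-conditional partial correlation by double residual regression
#'
#' The definition-based route: regress each of A and B on all remaining
#' variables (with intercept) by OLS and correlate the two residual
#' vectors. Algebraically identical to the precision-matrix route of
#' [pairwise_partial_correlations()]; kept as an independent code path for
#' cross-checking.
#'
#' @param data Numeric matrix (rows = samples, named columns = variables).
#' @param a,b Column names or indices.
#' @return Scalar full-conditional partial correlation.
#' @export
pcor_residual <- function(data, a, b) {
  data <- as.matrix(data)
  if (is.character(a)) a <- match(a, colnames(data))
  if (is.character(b)) b <- match(b, colnames(data))
  stopifnot(!is.na(a), !is.na(b), a != b)
  cond <- setdiff(seq_len(ncol(data)), c(a, b))
  D <- cbind(1, data[, cond, drop = FALSE])
  r_a <- stats::lsfit(D, data[, a], intercept = FALSE)$residuals
  r_b <- stats::lsfit(D, data[, b], intercept = FALSE)$residuals
  stats::cor(r_a, r_b)
}

#' All pairwise full-conditional partial correlations
#'
#' For every pair of variables, the partial correlation conditional on all
#' remaining variables, computed from the inverse correlation matrix Omega
#' as `-Omega_AB / sqrt(Omega_AA Omega_BB)`.
#'
#' @param data Numeric matrix, rows = samples, named columns = variables;
#'   needs more rows than columns and non-constant columns.
#' @return Symmetric matrix of partial correlations (unit diagonal by
#'   convention) with attribute `m` = sample size.
#' @export
pairwise_partial_correlations <- function(data) {
  data <- as.matrix(data)
  m <- nrow(data)
  v <- ncol(data)
  if (m <= v) stop("need more samples than variables (m > V)")
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "))
  }
  C <- stats::cor(data)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) <= 0 || max(ev$values) / min(ev$values) > 1e10) {
    # columns loading most on the smallest eigenvector are the culprits
    load <- abs(ev$vectors[, v])
    sus <- colnames(data)[load > 0.3]
    stop("correlation matrix singular or near-singular; ",
         "near-collinear column(s): ", paste(sus, collapse = ", "))
  }
  omega <- solve(C)
  dd <- sqrt(diag(omega))
  P <- -omega / tcrossprod(dd)
  diag(P) <- 1
  dimnames(P) <- dimnames(C)
  attr(P, "m") <- m
  P
}

#' Sorted pair list of a partial-correlation matrix
#'
#' Upper-triangle pairs sorted by descending absolute partial correlation;
#' ties broken by lexicographic pair name so traces are deterministic.
#'
#' @param pcors Symmetric partial-correlation matrix with named dims.
#' @return data.frame: `a`, `b`, `pcor`, ordered.
#' @export
pcor_pairs <- function(pcors) {
  vars <- colnames(pcors)
  idx <- which(upper.tri(pcors), arr.ind = TRUE)
  out <- data.frame(a = vars[idx[, 1L]], b = vars[idx[, 2L]],
                    pcor = pcors[idx], stringsAsFactors = FALSE)
  key <- paste(pmin(out$a, out$b), pmax(out$a, out$b))
  out <- out[order(-abs(out$pcor), key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

node_bic <- function(data, node, neighbors) {
  y <- data[, node]
  m <- length(y)
  if (length(neighbors) == 0L) {
    rss <- sum((y - mean(y))^2)
    return(bic_gaussian(rss, m, 1L))
  }
  D <- cbind(1, data[, neighbors, drop = FALSE])
  fit <- stats::lsfit(D, y, intercept = FALSE)
  bic_gaussian(sum(fit$residuals^2), m, length(neighbors) + 1L)
}

#' BIC of a network hypothesis on the data
#'
#' Scores an undirected edge set as the sum over nodes of the Gaussian OLS
#' BIC of each node regressed on its current neighbors (intercept-only when
#' isolated). For a single response variable this degenerates to
#' [bic_of_fit()] of the ordinary regression model.
#'
#' @param data Numeric matrix with named columns.
#' @param edges data.frame with columns `a`, `b` naming data columns
#'   (zero rows = empty network).
#' @return Scalar network BIC.
#' @export
network_bic <- function(data, edges) {
  data <- as.matrix(data)
  vars <- colnames(data)
  nbrs <- stats::setNames(vector("list", length(vars)), vars)
  if (nrow(edges)) {
    bad <- setdiff(unique(c(edges$a, edges$b)), vars)
    if (length(bad)) stop("edge endpoint(s) not in data: ",
                          paste(bad, collapse = ", "))
    for (i in seq_len(nrow(edges))) {
      nbrs[[edges$a[i]]] <- union(nbrs[[edges$a[i]]], edges$b[i])
      nbrs[[edges$b[i]]] <- union(nbrs[[edges$b[i]]], edges$a[i])
    }
  }
  sum(vapply(vars, function(v) node_bic(data, v, nbrs[[v]]), numeric(1)))
}

#' BIC trace over nested networks of descending partial correlation
#'
#' Pairs are sorted by descending |partial correlation| and added one at a
#' time to a growing edge set; the network BIC is recorded at every step.
#' Step 0 is the empty network, so every added pair has a difference
#' `BIC_{i-1} - BIC_i` (positive when the new edge improves the score).
#'
#' @param data Numeric matrix with named columns.
#' @param pcors Optional precomputed matrix from
#'   [pairwise_partial_correlations()].
#' @return A `BICTrace`: data.frame `a`, `b`, `pcor`, `bic`, `diff`, with
#'   attributes `bic0` (empty-network BIC) and `m`.
#' @export
bic_trace <- function(data, pcors = NULL) {
  data <- as.matrix(data)
  if (is.null(pcors)) pcors <- pairwise_partial_correlations(data)
  pairs <- pcor_pairs(pcors)
  vars <- colnames(data)
  nbrs <- stats::setNames(vector("list", length(vars)), vars)
  bics <- stats::setNames(
    vapply(vars, function(v) node_bic(data, v, NULL), numeric(1)), vars)
  total <- sum(bics)
  bic0 <- total
  trace_bic <- numeric(nrow(pairs))
  trace_diff <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
    prev <- total
    for (v in c(a, b)) {  # only the touched nodes change
      total <- total - bics[[v]]
      bics[[v]] <- node_bic(data, v, nbrs[[v]])
      total <- total + bics[[v]]
    }
    trace_bic[i] <- total
    trace_diff[i] <- prev - total
  }
  out <- cbind(pairs, bic = trace_bic, diff = trace_diff)
  attr(out, "bic0") <- bic0
  attr(out, "m") <- nrow(data)
  class(out) <- c("BICTrace", class(out))
  out
}

#' Select the partial-correlation threshold from a BIC trace
#'
#' The BIC score is taken to change only over a small scale once the
#' per-step difference falls below `fraction` (default 20%) of the maximum
#' difference. The threshold is the |partial correlation| of the last pair
#' whose difference still reaches that cutoff; all pairs up to and
#' including it become edges.
#'
#' @param trace A `BICTrace`.
#' @param fraction Fraction of the maximum BIC difference (default 0.2).
#' @return List: `threshold`, `index`, `edges` (data.frame `a`, `b`,
#'   `pcor`), `fraction`, `max_diff`.
#' @export
select_threshold <- function(trace, fraction = 0.2) {
  if (nrow(trace) < 1L) stop("empty trace")
  if (nrow(trace) == 1L) {
    warning("single pair: kept, threshold equals its |pcor|")
    return(list(threshold = abs(trace$pcor[1L]), index = 1L,
                edges = trace[1L, c("a", "b", "pcor")],
                fraction = fraction, max_diff = trace$diff[1L]))
  }
  max_diff <- max(trace$diff)
  keep <- which(trace$diff >= fraction * max_diff)
  idx <- max(keep)
  list(threshold = abs(trace$pcor[idx]), index = idx,
       edges = trace[seq_len(idx), c("a", "b", "pcor")],
       fraction = fraction, max_diff = max_diff)
}

#' Permutation null distribution for partial correlations
#'
#' Each variable's column is independently permuted with a no-fixed-point
#' permutation (so no value stays with its own exon), the full pairwise
#' partial-correlation matrix is recomputed, and all pair values are pooled
#' across permutations. The z-score locates a threshold in this pooled
#' null.
#'
#' @param data Numeric matrix with named columns.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param threshold Optional threshold whose z-score is wanted.
#' @return A `PermutationResult`: `null_pcors` (pooled vector), `mean`,
#'   `sd`, `max_abs`, `z` (or `NA`), `n_perm`.
#' @export
permutation_null <- function(data, n_perm = 100L, seed = 1L,
                             threshold = NULL) {
  data <- as.matrix(data)
  m <- nrow(data)
  if (m < 2L) stop("need at least 2 rows to permute")
  set.seed(seed)
  vals <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    perm_data <- data
    for (j in seq_len(ncol(data))) {
      perm_data[, j] <- data[sample_derangement(m), j]
    }
    P <- pairwise_partial_correlations(perm_data)
    vals[[p]] <- P[upper.tri(P)]
  }
  pooled <- unlist(vals)
  mu <- mean(pooled)
  sdv <- stats::sd(pooled)
  z <- if (is.null(threshold)) NA_real_ else (threshold - mu) / sdv
  structure(list(null_pcors = pooled, mean = mu, sd = sdv,
                 max_abs = max(abs(pooled)), z = z, n_perm = n_perm),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "<PermutationResult %d perms, null mean %.4g sd %.4g, max |pcor| %.4f%s>\n",
    x$n_perm, x$mean, x$sd, x$max_abs,
    if (is.na(x$z)) "" else sprintf(", z = %.2f", x$z)))
  invisible(x)
}

#' Assemble the undirected interaction network
#'
#' Pairs whose |partial correlation| reaches the threshold become edges.
#' Edge weights are normalized by the absolute value of the maximum
#' coefficient so the strongest edge has weight 1; when `exon_col` is given
#' each node also carries its (equally normalized) partial correlation with
#' exon expression.
#'
#' @param pcors Partial-correlation matrix.
#' @param threshold Positive threshold from [select_threshold()].
#' @param exon_col Optional name of the exon-expression column.
#' @return A `NetworkModel`: `nodes`, `edges` (data.frame `a`, `b`, `pcor`,
#'   `norm_pcor`), `threshold`, `node_attr`.
#' @export
build_network <- function(pcors, threshold, exon_col = NULL) {
  stopifnot(threshold > 0)
  pairs <- pcor_pairs(pcors)
  edges <- pairs[abs(pairs$pcor) >= threshold, , drop = FALSE]
  scale <- if (nrow(edges)) max(abs(edges$pcor)) else NA_real_
  edges$norm_pcor <- if (nrow(edges)) edges$pcor / scale else numeric(0)
  node_attr <- NULL
  if (!is.null(exon_col)) {
    stopifnot(exon_col %in% colnames(pcors))
    node_attr <- pcors[, exon_col] / scale
  }
  structure(list(nodes = colnames(pcors), edges = edges,
                 threshold = threshold, node_attr = node_attr),
            class = "NetworkModel")
}

#' @export
print.NetworkModel <- function(x, ...) {
  cat(sprintf("<NetworkModel %d nodes, %d edges, threshold %.4f>\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Neighbors of a node in a network
#' @param network A `NetworkModel`.
#' @param node Node name.
#' @return Character vector of neighbor names.
#' @export
network_neighbors <- function(network, node) {
  e <- network$edges
  unique(c(e$b[e$a == node], e$a[e$b == node]))
}
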