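#' Fit an affine normalizer between two cell types
#'
#' OLS of the reference cell's values on the source cell's values gives a
#' per-variable line; rescaling the source by it turns that line into
#' `y = x`, putting both cell types on the reference scale.
#'
#' @param source Values in the cell type to be normalized.
#' @param reference Matched values in the reference cell type.
#' @param name Variable name carried in the map.
#' @return An `AffineMap`: `name`, `slope`, `intercept`, `n`.
#' @export
fit_affine_normalizer <- function(source, reference, name = "var") {
  ok <- stats::complete.cases(source, reference)
  source <- source[ok]; reference <- reference[ok]
  if (length(source) < 3L) stop("need at least 3 matched rows")
  if (stats::sd(source) == 0) stop("constant source values for ", name)
  fit <- stats::lm.fit(cbind(1, source), reference)
  structure(list(name = name, slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 n = length(source)),
            class = "AffineMap")
}

#' Apply an affine normalizer
#' @param map An `AffineMap`.
#' @param x Values on the source scale.
#' @return Values on the reference scale.
#' @export
apply_affine <- function(map, x) {
  map$intercept + map$slope * x
}

#' Exons changed at least k-fold between two cell types
#'
#' Keeps ids whose absolute log2 expression difference reaches
#' `log2(fold)`; the boundary is inclusive and the filter is symmetric in
#' the two cell types.
#'
#' @param expr_a,expr_b Named log2 expression vectors.
#' @param fold Fold-change cutoff (e.g. 2, 5, 10).
#' @return Character vector of selected ids.
#' @export
fold_change_filter <- function(expr_a, expr_b, fold) {
  stopifnot(fold >= 1)
  ids <- intersect(names(expr_a), names(expr_b))
  dropped <- setdiff(union(names(expr_a), names(expr_b)), ids)
  if (length(dropped)) {
    warning("unmatched id(s) skipped: ", length(dropped))
  }
  delta <- abs(expr_a[ids] - expr_b[ids])
  ids[delta >= log2(fold)]
}

#' Cross-cell-type transfer of the exon-expression model
#'
#' Affine-normalizes the training cell's shared variables (features and
#' expression) onto the reference cell's scale, fits the linear model in
#' the training cell, then predicts the reference cell's exon expression —
#' over all matched exons and over each subset whose expression changed at
#' least `folds`-fold between the cells.
#'
#' @param train List with `signals` (matrix, rownames = exon ids) and
#'   `expr` (named vector) for the training cell type.
#' @param reference Same structure for the reference (predicted) cell type.
#' @param shared_features Feature names present in both cell types.
#' @param folds Fold-change cutoffs (default `c(2, 5, 10)`).
#' @return List: `r_all`, `per_fold` (data.frame `fold`, `n`, `r`),
#'   `affine_maps`, `model`.
#' @export
cross_cell_pipeline <- function(train, reference, shared_features,
                                folds = c(2, 5, 10)) {
  stopifnot(length(shared_features) >= 1L)
  ids <- intersect(rownames(train$signals), rownames(reference$signals))
  ids <- intersect(ids, intersect(names(train$expr),
                                  names(reference$expr)))
  if (length(ids) < 10L) stop("too few matched exons: ", length(ids))

  tr_sig <- train$signals[ids, shared_features, drop = FALSE]
  rf_sig <- reference$signals[ids, shared_features, drop = FALSE]
  tr_expr <- train$expr[ids]
  rf_expr <- reference$expr[ids]

  maps <- list()
  for (f in shared_features) {
    maps[[f]] <- fit_affine_normalizer(tr_sig[, f], rf_sig[, f], f)
    tr_sig[, f] <- apply_affine(maps[[f]], tr_sig[, f])
  }
  maps[["expression"]] <- fit_affine_normalizer(tr_expr, rf_expr,
                                                "expression")
  tr_expr <- apply_affine(maps[["expression"]], tr_expr)

  model <- fit_linear(tr_sig, tr_expr)
  all_tp <- transfer_predict(model, rf_sig, rf_expr)

  per_fold <- do.call(rbind, lapply(folds, function(fd) {
    keep <- fold_change_filter(tr_expr, rf_expr, fd)
    if (length(keep) < 3L) {
      warning("fold ", fd, ": too few exons pass, reported as NA")
      return(data.frame(fold = fd, n = length(keep), r = NA_real_))
    }
    tp <- transfer_predict(model, rf_sig[keep, , drop = FALSE],
                           rf_expr[keep])
    data.frame(fold = fd, n = length(keep), r = tp$r)
  }))

  list(r_all = all_tp$r, per_fold = per_fold, affine_maps = maps,
       model = model)
}

#' Affine-map table for export
#' @param maps Named list of `AffineMap`s.
#' @return data.frame: `variable`, `slope`, `intercept`, `n`.
#' @export
affine_map_table <- function(maps) {
  do.call(rbind, lapply(maps, function(m) {
    data.frame(variable = m$name, slope = m$slope,
               intercept = m$intercept, n = m$n, stringsAsFactors = FALSE)
  }))
}
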