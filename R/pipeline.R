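#' Default pipeline configuration
#'
#' Stage constants default to the study's stated values: pseudocount 0.01,
#' 100-bp read extension, 4,001-bp promoter window, 10 CV folds, 100
#' permutations, 20% BIC-difference fraction, fold filters 2/5/10.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param preset Synthetic preset name, or `NULL` to use file inputs.
#' @return Named list of configuration values.
#' @export
default_config <- function(out_dir, seed = 1L, preset = "small") {
  list(preset = preset, seed = seed, out_dir = out_dir,
       pseudocount = 0.01, extend_len = 100L, promoter_window = 4001L,
       cv_folds = 10L, n_perm = 100L, bic_fraction = 0.2,
       fold_filters = c(2, 5, 10),
       annotation = NULL, annotation_format = "refFlat",
       alt_table = NULL, read_files = NULL)
}

validate_config <- function(config) {
  need <- c("seed", "out_dir", "pseudocount", "extend_len", "cv_folds",
            "n_perm", "bic_fraction", "fold_filters")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(config$preset)) {
    for (f in c("annotation", "alt_table")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("config: ", f, " path missing or not found")
      }
    }
    if (is.null(config$read_files) || !"rna" %in% names(config$read_files)) {
      stop("config: read_files must name an 'rna' entry")
    }
    for (p in config$read_files) {
      if (!file.exists(p)) stop("config: read file not found: ", p)
    }
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates quantification (for file inputs) or synthetic generation
#' (for presets), regression with cross-validation and the shuffled-input
#' control, interaction-vs-singleton comparison, the partial-correlation
#' network with BIC threshold and permutation z, combination and stepwise
#' analyses, and cross-cell transfer. Writes every table as TSV plus a
#' `report.json` with the headline numbers.
#'
#' @param config List from [default_config()] (possibly edited).
#' @return The report list, invisibly; all outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  feat <- NULL
  if (!is.null(config$preset)) {
    scen <- run_stage("simulate", synth_preset(config$preset, seed = seed))
    if (!"exon_expr" %in% colnames(scen$data)) {
      stop("preset '", config$preset,
           "' has no response column; use a feature preset")
    }
    data <- scen$data
  } else {
    q <- run_stage("quantify", {
      chip <- lapply(config$read_files[setdiff(names(config$read_files),
                                               "rna")], read_bed_reads)
      rna <- read_bed_reads(config$read_files[["rna"]])
      genes <- read_gene_models(config$annotation,
                                config$annotation_format)
      alt <- read_alt_table(config$alt_table)
      quantify_dataset(chip, rna, genes, alt,
                       pseudocount = config$pseudocount,
                       extend_len = config$extend_len,
                       promoter_window = config$promoter_window)
    })
    scen <- NULL
    keep <- q$exons$klass == "cassette"
    ids <- q$exons$exon_id[keep]
    data <- cbind(q$exon_signals[ids, , drop = FALSE],
                  gene_expr = q$gene_expr[q$exons$gene_id[keep]],
                  exon_expr = q$exon_expr[ids])
    rownames(data) <- ids
  }

  feats <- setdiff(colnames(data), c("gene_expr", "exon_expr"))
  X <- data[, feats, drop = FALSE]
  y <- data[, "exon_expr"]

  reg <- run_stage("regress", {
    fit <- fit_linear(X, y)
    cv <- cross_validate(X, y, k = config$cv_folds, seed = seed)
    shuf <- shuffle_control(X, y, k = config$cv_folds, seed = seed)
    cv_int <- cross_validate(X, y, k = config$cv_folds, seed = seed,
                             interactions = TRUE)
    list(fit = fit, cv = cv, shuffle = shuf, cv_int = cv_int,
         improvement = improvement_ratio(cv$mean_r, cv_int$mean_r))
  })
  write_tsv(coefficient_table(reg$fit),
            file.path(config$out_dir, "coefficients.tsv"))

  net <- run_stage("pcnet", {
    pc <- pairwise_partial_correlations(data)
    tr <- bic_trace(data, pc)
    sel <- select_threshold(tr, config$bic_fraction)
    perm <- permutation_null(data, n_perm = config$n_perm, seed = seed,
                             threshold = sel$threshold)
    nw <- build_network(pc, sel$threshold, exon_col = "exon_expr")
    list(pcors = pc, trace = tr, sel = sel, perm = perm, network = nw)
  })
  write_tsv(as.data.frame(net$trace),
            file.path(config$out_dir, "bic_trace.tsv"))
  write_tsv(net$network$edges, file.path(config$out_dir, "edges.tsv"))
  write_tsv(as.data.frame(net$pcors) |> cbind(variable = colnames(net$pcors)),
            file.path(config$out_dir, "pcor_matrix.tsv"))

  cmb <- run_stage("combos", {
    exon_node <- "exon_expr"
    nbrs <- network_neighbors(net$network, exon_node)
    drivers <- setdiff(nbrs, "gene_expr")
    if (length(drivers) < 2L) drivers <- feats[1:2]
    bins <- median_bins(data[, drivers[1L]], data[, drivers[2L]],
                        names = drivers[1:2])
    bs <- bin_summary(bins, y)
    nct <- network_combination_tests(net$network, data,
                                     k = config$cv_folds, seed = seed)
    ord <- feats[order(-abs(net$pcors[feats, exon_node]))]
    sw <- stepwise_bic_by_pcor(data, exon_node, ord)
    cl <- cluster_matrix_export(X, y)
    list(bins = bins, bin_summary = bs, combination_tests = nct,
         stepwise = sw, cluster = cl, drivers = drivers[1:2])
  })
  write_tsv(cmb$bin_summary$summary,
            file.path(config$out_dir, "bin_summary.tsv"))
  write_tsv(cmb$bin_summary$tests,
            file.path(config$out_dir, "bin_tests.tsv"))
  if (nrow(cmb$combination_tests)) {
    write_tsv(cmb$combination_tests,
              file.path(config$out_dir, "combination_tests.tsv"))
  }
  write_tsv(cmb$stepwise, file.path(config$out_dir, "stepwise_bic.tsv"))
  utils::write.table(cmb$cluster$matrix,
                     file.path(config$out_dir, "clustered_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  cross <- NULL
  if (!is.null(scen)) {
    cross <- run_stage("crosscell", {
      cell2 <- make_second_cell(scen, seed = seed + 1L)
      ids <- sprintf("exon%05d", seq_len(nrow(data)))
      tr <- list(signals = cell2$data[, feats, drop = FALSE],
                 expr = stats::setNames(cell2$data[, "exon_expr"], ids))
      rownames(tr$signals) <- ids
      rf <- list(signals = X, expr = stats::setNames(y, ids))
      rownames(rf$signals) <- ids
      cross_cell_pipeline(tr, rf, feats, folds = config$fold_filters)
    })
    write_tsv(affine_map_table(cross$affine_maps),
              file.path(config$out_dir, "affine_maps.tsv"))
    write_tsv(cross$per_fold,
              file.path(config$out_dir, "transfer_by_fold.tsv"))
  }

  report <- list(
    seed = seed,
    n_rows = nrow(data), n_features = length(feats),
    cv_r = reg$cv$mean_r,
    shuffle_r = reg$shuffle$mean_r,
    interaction_cv_r = reg$cv_int$mean_r,
    improvement_ratio = reg$improvement,
    threshold = net$sel$threshold,
    n_edges = nrow(net$network$edges),
    permutation_z = net$perm$z,
    max_null_pcor = net$perm$max_abs,
    driver_pair = cmb$drivers,
    transfer_r_all = if (is.null(cross)) NA else cross$r_all,
    transfer_r_by_fold = if (is.null(cross)) NULL else
      stats::setNames(cross$per_fold$r, paste0("fold", cross$per_fold$fold))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
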