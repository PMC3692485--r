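#' Build a precision matrix from a declared edge list
#'
#' Unit diagonal with `Omega[a, b] = -pcor` for every declared edge, so the
#' implied full-conditional partial correlation of a declared pair is
#' exactly its declared value and undeclared pairs are exactly
#' conditionally independent.
#'
#' @param vars Variable names.
#' @param edges data.frame with columns `a`, `b`, `pcor`.
#' @return Symmetric positive-definite precision matrix.
#' @export
make_precision <- function(vars, edges) {
  v <- length(vars)
  omega <- diag(v)
  dimnames(omega) <- list(vars, vars)
  if (!is.null(edges) && nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$a[i]; b <- edges$b[i]
      stopifnot(a %in% vars, b %in% vars, a != b)
      omega[a, b] <- omega[b, a] <- -edges$pcor[i]
    }
  }
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    stop("precision matrix not positive definite; min eigenvalue ", ev)
  }
  omega
}

#' True partial correlations implied by a precision matrix
#' @param omega Precision matrix.
#' @return Matrix of `-Omega_AB / sqrt(Omega_AA Omega_BB)` (unit diagonal).
#' @export
true_pcors <- function(omega) {
  dd <- sqrt(diag(omega))
  P <- -omega / tcrossprod(dd)
  diag(P) <- 1
  P
}

default_marks <- function(v) {
  marks <- c("H3K36me3", "H4K20me1", "H3K4me1", "H3K4me3", "H3K9me1",
             "H3K79me1", "H3K79me2", "H2BK5me1", "H3K9ac", "H3K27me3",
             "H3K4me2", "H3K9me3", "H3K27ac", "H2BK5ac", "H3K23ac",
             "H4K5ac", "H4K91ac", "H2AK5ac", "H3K14ac", "H4K8ac")
  if (v <= length(marks)) return(marks[seq_len(v)])
  c(marks, sprintf("mark%02d", seq_len(v - length(marks))))
}

default_ggm_edges <- function() {
  data.frame(
    a = c("H3K36me3", "H3K4me1", "H3K4me1", "H3K79me1", "H3K79me1",
          "H3K9ac", "H4K20me1", "H3K36me3"),
    b = c("H4K20me1", "H3K4me3", "H3K9me1", "H3K79me2", "H2BK5me1",
          "H3K27me3", "H3K9ac", "H3K79me1"),
    pcor = c(0.32, 0.40, 0.30, 0.38, 0.28, 0.25, 0.27, 0.26),
    stringsAsFactors = FALSE
  )
}

default_feature_edges <- function(vars) {
  e <- default_ggm_edges()
  e <- e[e$a %in% vars & e$b %in% vars, , drop = FALSE]
  rbind(e, data.frame(a = c("gene_expr", "gene_expr"),
                      b = c("H3K36me3", "H3K4me3"),
                      pcor = c(0.30, 0.30), stringsAsFactors = FALSE))
}

#' Pure Gaussian-graphical scenario
#'
#' Draws i.i.d. multivariate-normal rows whose precision matrix has the
#' declared sparsity pattern, for testing network recovery against known
#' conditional-independence structure.
#'
#' @param v Number of variables (default 10).
#' @param m Number of rows (default 2000).
#' @param edges data.frame `a`, `b`, `pcor` (defaults to an 8-edge pattern
#'   with true |pcor| between 0.25 and 0.40).
#' @param seed Integer seed.
#' @return List: `data` (m x v matrix), `truth` (`omega`, `pcors`,
#'   `edges`, `seed`).
#' @export
make_ggm_scenario <- function(v = 10L, m = 2000L,
                              edges = default_ggm_edges(), seed = 1L) {
  vars <- default_marks(v)
  edges <- edges[edges$a %in% vars & edges$b %in% vars, , drop = FALSE]
  omega <- make_precision(vars, edges)
  set.seed(seed)
  data <- MASS::mvrnorm(m, mu = rep(0, v), Sigma = solve(omega))
  colnames(data) <- vars
  list(data = data,
       truth = list(omega = omega, pcors = true_pcors(omega),
                    edges = edges, seed = seed))
}

#' Feature scenario: GGM marks + gene expression driving exon expression
#'
#' Chromatin-feature and gene-expression columns are drawn jointly from a
#' Gaussian graphical model with the declared precision pattern; exon
#' expression is a stated linear function of gene expression plus two
#' driver marks plus Gaussian noise, optionally with one product
#' (interaction) term between the drivers.
#'
#' @param v Number of chromatin features (default 10; `"gene_expr"` and
#'   `"exon_expr"` columns are added).
#' @param m Number of exons/rows (default 2000).
#' @param seed Integer seed.
#' @param edges GGM edge spec over features + `"gene_expr"`.
#' @param drivers The two marks wired directly into exon expression.
#' @param coef Named coefficients for `gene_expr` and the two drivers.
#' @param intercept Response intercept (default 0.5).
#' @param interaction_coef Coefficient of the driver product term
#'   (default 0: purely additive generator).
#' @param noise_sd Response noise standard deviation (default 0.6).
#' @return List: `data` (m x (v+2) matrix incl. `gene_expr`, `exon_expr`),
#'   `truth` (omega, pcors over the GGM block, `joint_pcors` over all
#'   columns when the generator is linear, coefficients, `noise_sd`,
#'   `true_r` = closed-form population correlation sqrt(R^2) attainable by
#'   the main-effects regression, `drivers`, `seed`).
#' @export
make_feature_scenario <- function(v = 10L, m = 2000L, seed = 1L,
                                  edges = NULL,
                                  drivers = c("H3K36me3", "H4K20me1"),
                                  coef = c(gene_expr = 1.0, 0.6, 0.5),
                                  intercept = 0.5,
                                  interaction_coef = 0,
                                  noise_sd = 0.6) {
  vars <- c(default_marks(v), "gene_expr")
  stopifnot(all(drivers %in% vars), noise_sd > 0)
  if (is.null(edges)) edges <- default_feature_edges(vars)
  omega <- make_precision(vars, edges)
  sigma <- solve(omega)

  w <- stats::setNames(rep(0, length(vars)), vars)
  w["gene_expr"] <- coef[["gene_expr"]]
  w[drivers[1L]] <- unname(coef[2L])
  w[drivers[2L]] <- unname(coef[3L])

  set.seed(seed)
  Z <- MASS::mvrnorm(m, mu = rep(0, length(vars)), Sigma = sigma)
  colnames(Z) <- vars
  y <- intercept + drop(Z %*% w) +
    interaction_coef * Z[, drivers[1L]] * Z[, drivers[2L]] +
    stats::rnorm(m, sd = noise_sd)
  data <- cbind(Z, exon_expr = y)

  # population R^2 of the main-effects regression (exact when the
  # generator is linear; the product term is uncorrelated with the main
  # effects under joint normality, so for interaction generators this is
  # the main-effects-only share)
  sig_var <- drop(t(w) %*% sigma %*% w)
  tot_var <- sig_var + noise_sd^2 +
    interaction_coef^2 * (sigma[drivers[1L], drivers[2L]]^2 +
                            sigma[drivers[1L], drivers[1L]] *
                            sigma[drivers[2L], drivers[2L]])
  true_r <- sqrt(sig_var / tot_var)

  joint_pcors <- NULL
  if (interaction_coef == 0) {
    # joint precision of (Z, y): parents pick up -w/sd^2 couplings
    k <- length(vars)
    oj <- matrix(0, k + 1L, k + 1L,
                 dimnames = list(c(vars, "exon_expr"),
                                 c(vars, "exon_expr")))
    oj[seq_len(k), seq_len(k)] <- omega + tcrossprod(w) / noise_sd^2
    oj[seq_len(k), k + 1L] <- -w / noise_sd^2
    oj[k + 1L, seq_len(k)] <- -w / noise_sd^2
    oj[k + 1L, k + 1L] <- 1 / noise_sd^2
    joint_pcors <- true_pcors(oj)
  }

  list(data = data,
       truth = list(omega = omega, pcors = true_pcors(omega),
                    joint_pcors = joint_pcors,
                    coef = w, intercept = intercept,
                    interaction_coef = interaction_coef,
                    noise_sd = noise_sd, true_r = true_r,
                    drivers = drivers, edges = edges, seed = seed))
}

#' Scenario presets
#'
#' `"small"` is the desk-scale default (10 features + gene + exon
#' expression, 2000 exons); `"paper-shape"` matches the real study's shape
#' (39 chromatin features incl. RNAPII + gene + exon expression, 17,713
#' exons); `"ggm10"` is the pure 10-node graphical model used for network
#' recovery.
#'
#' @param name One of `"small"`, `"paper-shape"`, `"ggm10"`.
#' @param seed Integer seed.
#' @return Scenario list as from the underlying generator.
#' @export
synth_preset <- function(name = c("small", "paper-shape", "ggm10"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
         small = make_feature_scenario(v = 10L, m = 2000L, seed = seed),
         `paper-shape` = make_feature_scenario(v = 39L, m = 17713L,
                                               seed = seed),
         ggm10 = make_ggm_scenario(v = 10L, m = 2000L, seed = seed))
}

#' Second cell type related by per-variable affine transforms
#'
#' Every variable (features, gene expression, exon expression) of the
#' scenario is mapped through its own affine transform with fresh
#' measurement noise; a designated fraction of exons additionally has its
#' expression shifted by at least `log2(fold)` (random sign, magnitude
#' 1.3-2.2 x the cutoff so shifted exons clear the fold filter despite
#' noise). Shifts are applied on the reference scale (inside the affine
#' map), so they survive affine re-normalization; model coefficients are
#' unchanged.
#'
#' @param scenario Output of [make_feature_scenario()].
#' @param seed Integer seed.
#' @param affine `"random"` (seeded slopes in 0.7-1.3, intercepts in
#'   -0.5-0.5), `"identity"`, or a data.frame
#'   `variable`, `slope`, `intercept`.
#' @param shift_frac Fraction of exons with shifted expression
#'   (default 0.1).
#' @param fold Fold-change floor of the shift (default 2).
#' @param noise_sd Measurement noise of the second cell type
#'   (default 0.1).
#' @return List: `data` (same columns as the scenario), `shifted_ids`
#'   (row indices), `affine` (data.frame), `fold`, `seed`.
#' @export
make_second_cell <- function(scenario, seed = 2L, affine = "random",
                             shift_frac = 0.1, fold = 2,
                             noise_sd = 0.1) {
  stopifnot(shift_frac >= 0, shift_frac <= 1)
  data <- scenario$data
  vars <- colnames(data)
  m <- nrow(data)
  set.seed(seed)
  if (identical(affine, "random")) {
    affine <- data.frame(variable = vars,
                         slope = stats::runif(length(vars), 0.7, 1.3),
                         intercept = stats::runif(length(vars), -0.5, 0.5),
                         stringsAsFactors = FALSE)
  } else if (identical(affine, "identity")) {
    affine <- data.frame(variable = vars, slope = 1, intercept = 0,
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(vars %in% affine$variable))

  n_shift <- round(shift_frac * m)
  shifted <- if (n_shift > 0) sample.int(m, n_shift) else integer(0)
  shift <- numeric(m)
  if (n_shift > 0) {
    shift[shifted] <- sample(c(-1, 1), n_shift, replace = TRUE) *
      log2(fold) * stats::runif(n_shift, 1.3, 2.2)
  }

  out <- data
  for (v in vars) {
    a <- affine[affine$variable == v, , drop = FALSE]
    x <- data[, v]
    if (v == "exon_expr") x <- x + shift
    out[, v] <- a$intercept + a$slope * x + stats::rnorm(m, sd = noise_sd)
  }
  list(data = out, shifted_ids = shifted, affine = affine, fold = fold,
       seed = seed)
}

#' Read-level toy genome realizing a signal matrix
#'
#' Inverts the quantification stage: builds a toy genome with one
#' three-exon gene per scenario row (the middle exon carries that row's
#' signals), draws per-region read counts as
#' `Poisson(region_bp * (2^signal - pseudocount))`, places 25-bp reads
#' uniformly inside each exon on random strands, and writes BED6 read
#' files, a refFlat annotation and a cassette-event table. Running the
#' quantification pipeline on these files recovers the generating log2
#' densities (up to Poisson noise).
#'
#' Signals are shifted by `density_offset` before conversion to read rates
#' so even low-signal regions receive enough reads; the returned
#' `expected` matrix records the shifted generating values the round trip
#' is compared against.
#'
#' @param scenario Output of [make_feature_scenario()]; chromatin-feature
#'   columns become ChIP read sets, `exon_expr` the RNA reads.
#' @param out_dir Directory for the generated files.
#' @param seed Integer seed.
#' @param exon_bp,intron_bp,flank_bp,gene_gap Toy-genome geometry in bp.
#' @param density_offset Added to every log2 signal before read generation
#'   (default 2).
#' @param cassette_frac Fraction of genes whose middle exon is annotated
#'   as a cassette event (default 0.5).
#' @param read_len Raw read length in bp before extension (default 25).
#' @param pseudocount Matches the quantification stage (default 0.01).
#' @return List: `annotation`, `alt_table`, `read_files` (named paths,
#'   `rna` included), `exon_ids` (middle-exon ids in row order),
#'   `expected` (matrix of generating log2 densities: features + `rna`),
#'   `gene_ids`.
#' @export
make_read_level <- function(scenario, out_dir, seed = 1L,
                            exon_bp = 200L, intron_bp = 300L,
                            flank_bp = 200L, gene_gap = 5000L,
                            density_offset = 2,
                            cassette_frac = 0.5,
                            read_len = 25L, pseudocount = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- scenario$data
  feat_cols <- setdiff(colnames(data), c("gene_expr", "exon_expr"))
  G <- nrow(data)
  gene_ids <- sprintf("gene%04d", seq_len(G))

  gene_len <- 2L * flank_bp + exon_bp + 2L * intron_bp
  gene_start <- 1000L + (seq_len(G) - 1L) * (gene_len + gene_gap)
  e1_s <- gene_start
  e1_e <- e1_s + flank_bp - 1L
  e2_s <- e1_e + intron_bp + 1L
  e2_e <- e2_s + exon_bp - 1L
  e3_s <- e2_e + intron_bp + 1L
  e3_e <- e3_s + flank_bp - 1L

  # refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
  #          exonCount exonStarts exonEnds (0-based half-open)
  ann <- sprintf("%s\t%s\tchrT\t+\t%d\t%d\t%d\t%d\t3\t%d,%d,%d,\t%d,%d,%d,",
                 gene_ids, gene_ids, e1_s - 1L, e3_e, e1_s - 1L, e3_e,
                 e1_s - 1L, e2_s - 1L, e3_s - 1L, e1_e, e2_e, e3_e)
  annotation <- file.path(out_dir, "genes.refflat")
  writeLines(ann, annotation)

  n_cass <- ceiling(cassette_frac * G)
  alt_table <- file.path(out_dir, "alt_events.bed")
  if (n_cass > 0) {
    idx <- seq_len(n_cass)
    writeLines(sprintf("chrT\t%d\t%d\t%s_cass\t0\t+\tcassetteExon",
                       e2_s[idx] - 1L, e2_e[idx],
                       gene_ids[idx]), alt_table)
  } else {
    writeLines(character(0), alt_table)
  }

  set.seed(seed)
  # vectorized read placement over many regions at once
  emit_reads <- function(lo, hi, dens_log2, path) {
    bp <- hi - lo + 1L
    lambda <- pmax(0, 2^dens_log2 - pseudocount) * bp
    n <- stats::rpois(length(lambda), lambda)
    tot <- sum(n)
    if (tot == 0L) {
      writeLines(character(0), path)
      return(invisible(NULL))
    }
    reg <- rep.int(seq_along(lo), n)
    # uniform raw-read starts fully inside each region
    s <- lo[reg] + floor(stats::runif(tot) * (bp[reg] - read_len + 1L))
    strand <- sample(c("+", "-"), tot, replace = TRUE)
    writeLines(sprintf("chrT\t%d\t%d\tr%07d\t0\t%s", s - 1L,
                       s + read_len - 1L, seq_len(tot), strand), path)
    invisible(NULL)
  }

  expected <- matrix(NA_real_, nrow = G, ncol = length(feat_cols) + 1L,
                     dimnames = list(gene_ids, c(feat_cols, "rna")))
  read_files <- character(0)
  all_lo <- c(rbind(e1_s, e2_s, e3_s))
  all_hi <- c(rbind(e1_e, e2_e, e3_e))

  for (f in feat_cols) {
    s <- data[, f] + density_offset
    expected[, f] <- s
    # flanks share the gene's signal so union density equals it too
    path <- file.path(out_dir, paste0("reads_", f, ".bed"))
    emit_reads(all_lo, all_hi, rep(s, each = 3L), path)
    read_files[f] <- path
  }

  # RNA: middle exon carries exon_expr; flanks carry densities chosen so
  # the exonic-union density realizes gene_expr
  e_dens <- data[, "exon_expr"] + density_offset
  g_dens <- data[, "gene_expr"] + density_offset
  expected[, "rna"] <- e_dens
  union_bp <- 2L * flank_bp + exon_bp
  flank_rate <- (2^g_dens * union_bp - 2^e_dens * exon_bp) /
    (2L * flank_bp)
  flank_dens <- log2(pmax(flank_rate, pseudocount))
  rna_path <- file.path(out_dir, "reads_rna.bed")
  emit_reads(all_lo, all_hi,
             c(rbind(flank_dens, e_dens, flank_dens)), rna_path)
  read_files["rna"] <- rna_path

  list(annotation = annotation, alt_table = alt_table,
       read_files = read_files,
       exon_ids = paste0(gene_ids, ":2"), gene_ids = gene_ids,
       expected = expected, density_offset = density_offset)
}
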