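#' Extend aligned reads in their strand direction
#'
#' Short ChIP/RNA reads mark only the 5' end of the sequenced fragment, so
#' each read is stretched to the expected fragment length before counting: a
#' + read becomes `[start, start + target_len)` and a - read
#' `[end - target_len, end)` (0-based half-open terms), clipped at the
#' chromosome origin.
#'
#' @param reads `GRanges` of raw reads; every read needs a `+`/`-` strand.
#' @param target_len Extended length in bp (default 100).
#' @return `GRanges` of extended reads.
#' @export
extend_reads <- function(reads, target_len = 100L) {
  stopifnot(target_len > 0)
  s <- as.character(GenomicRanges::strand(reads))
  bad <- which(!s %in% c("+", "-"))
  if (length(bad)) {
    id <- names(reads)[bad[1L]]
    if (is.null(id) || is.na(id) || !nzchar(id)) id <- paste0("#", bad[1L])
    stop("read without strand: ", id)
  }
  out <- GenomicRanges::resize(reads, width = as.integer(target_len),
                               fix = "start")
  # clip anything pushed past the chromosome origin
  IRanges::restrict(out, start = 1L)
}

count_region_reads <- function(reads, region) {
  region <- GenomicRanges::reduce(region, ignore.strand = TRUE)
  sum(IRanges::overlapsAny(reads, region, ignore.strand = TRUE))
}

#' Length-normalized log2 read density over a region union
#'
#' Counts reads whose (already extended) interval overlaps the union of the
#' region by at least 1 bp — each read at most once per region even when it
#' spans several exons of the union — divides by the region length, adds a
#' pseudocount, and takes log2.
#'
#' @param reads Extended reads (`GRanges`).
#' @param region `GRanges`; overlapping pieces are unioned.
#' @param region_bp Region length in bp; defaults to the union width.
#' @param pseudocount Added to the length-normalized sum before the log
#'   (default 0.01) so empty regions stay defined.
#' @return Scalar `log2(count / region_bp + pseudocount)`.
#' @export
region_signal <- function(reads, region, region_bp = NULL,
                          pseudocount = 0.01) {
  if (length(region) == 0L) stop("empty region")
  if (is.null(region_bp)) {
    region_bp <- sum(GenomicRanges::width(
      GenomicRanges::reduce(region, ignore.strand = TRUE)))
  }
  stopifnot(region_bp > 0)
  n <- count_region_reads(reads, region)
  log2(n / region_bp + pseudocount)
}

#' @rdname region_signal
#' @param gene A `GeneModel`; its exon union is the transcribed region.
#' @export
gene_expression <- function(reads, gene, pseudocount = 0.01) {
  stopifnot(inherits(gene, "GeneModel"))
  region_signal(reads, gene$exons, gene$exonic_bp, pseudocount)
}

#' @rdname region_signal
#' @param exon A single-interval `GRanges`.
#' @export
exon_expression <- function(reads, exon, pseudocount = 0.01) {
  region_signal(reads, exon, pseudocount = pseudocount)
}

#' @rdname region_signal
#' @param target A `GeneModel` or `GRanges` to quantify a chromatin feature
#'   over.
#' @export
feature_signal <- function(reads, target, pseudocount = 0.01) {
  if (inherits(target, "GeneModel")) {
    region_signal(reads, target$exons, target$exonic_bp, pseudocount)
  } else {
    region_signal(reads, target, pseudocount = pseudocount)
  }
}

#' Promoter signal in a fixed window around the TSS
#'
#' Counts extended reads overlapping the `window_bp`-wide window centered on
#' the strand-aware TSS (4,001 bp by default: 2,000 bp each side plus the TSS
#' base) and returns `log2(count + pseudocount)`. Unlike [region_signal()]
#' the raw read sum is logged without length normalization, since the window
#' has a fixed width for every gene; the pseudocount keeps empty windows
#' defined.
#'
#' @param reads Extended reads (`GRanges`).
#' @param gene A `GeneModel`.
#' @param window_bp Odd window width in bp (default 4001).
#' @param pseudocount Added to the count before the log (default 0.01).
#' @return Scalar log2 signal.
#' @export
promoter_signal <- function(reads, gene, window_bp = 4001L,
                            pseudocount = 0.01) {
  stopifnot(inherits(gene, "GeneModel"), window_bp %% 2L == 1L)
  half <- (window_bp - 1L) / 2L
  chrom <- as.character(GenomicRanges::seqnames(gene$exons))[1L]
  win <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = max(1L, gene$tss - half),
                              end = gene$tss + half)
  )
  n <- count_region_reads(reads, win)
  log2(n + pseudocount)
}

#' Exon inclusion value
#'
#' Log2 fold change of exon expression over the expression of its gene;
#' since both are log2 densities under the same normalization this is their
#' difference. Exons with negative inclusion are flagged as alternatively
#' spliced in the cell type at hand.
#'
#' @param exon_expr,gene_expr Log2 length-normalized densities.
#' @return Numeric inclusion value(s).
#' @export
inclusion_value <- function(exon_expr, gene_expr) {
  exon_expr - gene_expr
}

#' Classify internal exons as constitutive or cassette
#'
#' The first and last exon of every gene are dropped (they are dominated by
#' initiation/termination effects); genes with fewer than three exons yield
#' nothing. An internal exon overlapping only cassette events in the
#' alternative-event table is a cassette exon; one overlapping no event is
#' constitutive; one touching any non-cassette or conflicting event is
#' excluded from both sets (and logged).
#'
#' @param genes Named list of `GeneModel`s.
#' @param alt_table `GRanges` with `event_type` metadata
#'   (cassette encoded as `"cassetteExon"`), or `NULL` for none.
#' @return A data.frame with one row per analyzable exon:
#'   `exon_id, gene_id, chrom, start, end, strand, ordinal, klass`.
#' @export
classify_exons <- function(genes, alt_table = NULL) {
  rows <- list()
  for (gm in genes) {
    n <- length(gm$exons)
    if (n < 3L) next
    idx <- 2:(n - 1L)
    ex <- gm$exons[idx]
    for (j in seq_along(idx)) {
      klass <- "constitutive"
      if (!is.null(alt_table) && length(alt_table)) {
        hits <- IRanges::overlapsAny(alt_table, ex[j], ignore.strand = TRUE)
        if (any(hits)) {
          types <- unique(alt_table$event_type[hits])
          if (identical(types, "cassetteExon")) {
            klass <- "cassette"
          } else {
            message("exon ", gm$gene_id, ":", idx[j],
                    " excluded: event type(s) ",
                    paste(types, collapse = ","))
            next
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = paste0(gm$gene_id, ":", idx[j]),
        gene_id = gm$gene_id,
        chrom = as.character(GenomicRanges::seqnames(ex))[j],
        start = GenomicRanges::start(ex)[j],
        end = GenomicRanges::end(ex)[j],
        strand = gm$strand,
        ordinal = idx[j],
        klass = klass,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(exon_id = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      ordinal = integer(), klass = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$exon_id
  out
}

exon_granges <- function(exon_table) {
  gr <- GenomicRanges::GRanges(
    seqnames = exon_table$chrom,
    ranges = IRanges::IRanges(start = exon_table$start,
                              end = exon_table$end),
    strand = exon_table$strand
  )
  names(gr) <- exon_table$exon_id
  gr
}

#' Signal matrix over a set of regions
#'
#' Applies [region_signal()] for every (region, feature) pair, producing the
#' regions x features matrix of log2 length-normalized densities the
#' regression and network stages consume.
#'
#' @param read_sets Named list of extended-read `GRanges`, one per chromatin
#'   feature (RNAPII included).
#' @param regions Named list of `GRanges` (one union per row: a gene's exon
#'   union or a single exon).
#' @param region_bp Optional vector of region lengths (defaults to union
#'   widths).
#' @param pseudocount See [region_signal()].
#' @return Numeric matrix, `length(regions)` rows x `length(read_sets)`
#'   columns.
#' @export
signal_matrix <- function(read_sets, regions, region_bp = NULL,
                          pseudocount = 0.01) {
  stopifnot(length(read_sets) >= 1L, !is.null(names(read_sets)))
  if (is.null(region_bp)) {
    region_bp <- vapply(regions, function(r) {
      sum(GenomicRanges::width(GenomicRanges::reduce(r,
                                                     ignore.strand = TRUE)))
    }, numeric(1))
  }
  grl <- GenomicRanges::GRangesList(lapply(regions, function(r) {
    GenomicRanges::reduce(r, ignore.strand = TRUE)
  }))
  out <- matrix(NA_real_, nrow = length(regions), ncol = length(read_sets),
                dimnames = list(names(regions), names(read_sets)))
  for (f in names(read_sets)) {
    # one hit per (read, region) pair even when a read spans several exons
    counts <- GenomicRanges::countOverlaps(grl, read_sets[[f]],
                                           ignore.strand = TRUE)
    out[, f] <- log2(counts / region_bp + pseudocount)
  }
  out
}

#' Quantify a full dataset: gene, promoter and exon level
#'
#' Runs the whole quantification stage: extends reads, computes gene-body
#' (exon-union) signal and expression, promoter signal, classifies internal
#' exons, and computes per-exon signal, expression and inclusion.
#'
#' @param chip_reads Named list of raw read `GRanges`, one per chromatin
#'   feature.
#' @param rna_reads Raw RNA-seq read `GRanges`.
#' @param genes Named list of `GeneModel`s.
#' @param alt_table Alternative-event `GRanges` or `NULL`.
#' @param pseudocount,extend_len,promoter_window Stage constants
#'   (defaults 0.01, 100 bp, 4001 bp).
#' @return List with `gene_signals`, `gene_expr`, `promoter_signals`,
#'   `exons` (classification table incl. `inclusion`, `is_alternative`),
#'   `exon_signals`, `exon_expr`.
#' @export
quantify_dataset <- function(chip_reads, rna_reads, genes, alt_table = NULL,
                             pseudocount = 0.01, extend_len = 100L,
                             promoter_window = 4001L) {
  chip_ext <- lapply(chip_reads, extend_reads, target_len = extend_len)
  rna_ext <- extend_reads(rna_reads, target_len = extend_len)

  gene_regions <- lapply(genes, `[[`, "exons")
  gene_bp <- vapply(genes, `[[`, numeric(1), "exonic_bp")
  gene_signals <- signal_matrix(chip_ext, gene_regions, gene_bp, pseudocount)
  gene_expr <- drop(signal_matrix(list(rna = rna_ext), gene_regions,
                                  gene_bp, pseudocount))

  half <- (promoter_window - 1L) / 2L
  tss <- vapply(genes, `[[`, numeric(1), "tss")
  chroms <- vapply(genes, function(gm) {
    as.character(GenomicRanges::seqnames(gm$exons))[1L]
  }, character(1))
  windows <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = pmax(1, tss - half),
                              end = tss + half))
  names(windows) <- names(genes)
  promoter_signals <- matrix(
    NA_real_, nrow = length(genes), ncol = length(chip_ext),
    dimnames = list(names(genes), names(chip_ext)))
  for (f in names(chip_ext)) {
    counts <- GenomicRanges::countOverlaps(windows, chip_ext[[f]],
                                           ignore.strand = TRUE)
    promoter_signals[, f] <- log2(counts + pseudocount)
  }

  exons <- classify_exons(genes, alt_table)
  exon_signals <- NULL
  exon_expr <- NULL
  if (nrow(exons)) {
    gr <- exon_granges(exons)
    exon_regions <- split(gr, names(gr))[exons$exon_id]
    exon_bp <- exons$end - exons$start + 1L
    names(exon_bp) <- exons$exon_id
    exon_signals <- signal_matrix(chip_ext, exon_regions, exon_bp,
                                  pseudocount)
    exon_expr <- drop(signal_matrix(list(rna = rna_ext), exon_regions,
                                    exon_bp, pseudocount))
    exons$inclusion <- inclusion_value(exon_expr[exons$exon_id],
                                       gene_expr[exons$gene_id])
    exons$is_alternative <- exons$klass == "cassette" & exons$inclusion < 0
  }

  list(gene_signals = gene_signals, gene_expr = gene_expr,
       promoter_signals = promoter_signals, exons = exons,
       exon_signals = exon_signals, exon_expr = exon_expr)
}
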