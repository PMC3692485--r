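#' Read aligned reads from a BED6 file
#'
#' Reads are parsed as 0-based half-open BED intervals and returned as a
#' `GRanges` (1-based closed, the Bioconductor convention used throughout the
#' package). Strand is kept as given; records with strand "." become "*" and
#' are rejected later by [extend_reads()], which needs a direction.
#'
#' @param path Path to a BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand).
#' @return A `GRanges` of reads, named by the BED name column.
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  tab <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    comment.char = "#", quote = "",
    colClasses = c("character", "integer", "integer", "character",
                   "character", "character", rep("NULL", 6L))[
                     seq_len(max(6L, utils::count.fields(path,
                                                         sep = "\t")[1L]))])
  if (ncol(tab) < 6L) {
    stop("BED6 expected (6+ columns), got ", ncol(tab), " in ", path)
  }
  bad <- which(!(tab[[6]] %in% c("+", "-", ".")))
  if (length(bad)) {
    stop("malformed strand in ", path, " at line ", bad[1L])
  }
  strand <- ifelse(tab[[6]] == ".", "*", tab[[6]])
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges   = IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]]),
    strand   = strand
  )
  names(gr) <- as.character(tab[[4]])
  gr
}

#' Read an alternative-splicing event table (BED6+1)
#'
#' The seventh column carries the event type; cassette exons (exons totally
#' included or totally skipped across transcripts) are encoded as
#' `"cassetteExon"`, mirroring the UCSC KnownAlt vocabulary.
#'
#' @param path Path to a BED6+1 file.
#' @return A `GRanges` with metadata column `event_type`.
#' @export
read_alt_table <- function(path) {
  if (!file.exists(path)) stop("alt-event file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 7L) {
    stop("BED6+1 expected (event type in column 7) in ", path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges   = IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]]),
    strand   = ifelse(tab[[6]] == ".", "*", tab[[6]])
  )
  gr$event_type <- as.character(tab[[7]])
  names(gr) <- as.character(tab[[4]])
  gr
}

new_gene_model <- function(gene_id, strand, exons) {
  if (length(exons) == 0L) return(NULL)
  exons <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  GenomicRanges::strand(exons) <- strand
  tss <- if (strand == "+") min(GenomicRanges::start(exons)) else
    max(GenomicRanges::end(exons))
  structure(
    list(gene_id = gene_id, strand = strand, tss = tss, exons = exons,
         exonic_bp = sum(GenomicRanges::width(exons))),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<GeneModel %s (%s) %d exon(s), %d exonic bp, TSS %d>\n",
              x$gene_id, x$strand, length(x$exons), x$exonic_bp, x$tss))
  invisible(x)
}

parse_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed refFlat line ", i, ": ",
                              length(f), " fields (11 expected)")
    n_exon <- suppressWarnings(as.integer(f[9L]))
    starts <- suppressWarnings(as.integer(strsplit(f[10L], ",")[[1L]]))
    ends   <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    if (is.na(n_exon) || anyNA(starts) || anyNA(ends) ||
        length(starts) != n_exon || length(ends) != n_exon) {
      stop("malformed refFlat line ", i, ": exon block mismatch")
    }
    if (any(starts >= ends)) stop("malformed refFlat line ", i,
                                  ": exon start >= end")
    out[[i]] <- data.frame(
      gene_id = f[1L], chrom = f[3L], strand = f[4L],
      start = starts + 1L, end = ends, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

parse_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("BED12 blocks column missing in ", path)
  blocks <- gr$blocks
  n <- lengths(blocks)
  flat <- unlist(blocks)
  # block starts are relative to chromStart
  abs_start <- rep(GenomicRanges::start(gr), n) + IRanges::start(flat) - 1L
  abs_end   <- rep(GenomicRanges::start(gr), n) + IRanges::end(flat) - 1L
  data.frame(
    gene_id = rep(as.character(gr$name), n),
    chrom   = rep(as.character(GenomicRanges::seqnames(gr)), n),
    strand  = rep(as.character(GenomicRanges::strand(gr)), n),
    start   = abs_start, end = abs_end, stringsAsFactors = FALSE
  )
}

parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF ", path)
  gid <- as.character(gr$gene_id)
  data.frame(
    gene_id = gid,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = as.character(GenomicRanges::strand(gr)),
    start   = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read gene models with exon structure
#'
#' Multi-isoform genes are merged into one exon union per `gene_id`; the
#' transcribed region of a gene is operationalized as that union, so
#' `exonic_bp` is the non-redundant exonic length. The TSS is the leftmost
#' base on the + strand and the rightmost on the - strand.
#'
#' @param path Path to the annotation file.
#' @param format One of `"refFlat"`, `"BED12"`, `"GTF"`.
#' @return A named list of `GeneModel` objects
#'   (`gene_id`, `strand`, `tss`, `exons` as `GRanges`, `exonic_bp`).
#' @export
read_gene_models <- function(path, format = c("refFlat", "BED12", "GTF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- switch(format,
                refFlat = parse_refflat(path),
                BED12   = parse_bed12(path),
                GTF     = parse_gtf(path))
  models <- list()
  for (gid in unique(tab$gene_id)) {
    sub <- tab[tab$gene_id == gid, , drop = FALSE]
    strand <- sub$strand[1L]
    if (!strand %in% c("+", "-")) {
      message("gene ", gid, " rejected: no usable strand")
      next
    }
    exons <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start, end = sub$end)
    )
    gm <- new_gene_model(gid, strand, exons)
    if (is.null(gm)) {
      message("gene ", gid, " rejected: zero exons")
      next
    }
    models[[gid]] <- gm
  }
  models
}
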