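test_that("reads are extended in the strand direction and clipped at the origin", {
  # BED 0-based [100,125) on + becomes [100,200): 1-based [101,200]
  plus <- extend_reads(gr("chr1", 101, 125, "+"), 100)
  expect_equal(GenomicRanges::start(plus), 101)
  expect_equal(GenomicRanges::end(plus), 200)
  # BED [100,125) on - becomes [25,125): 1-based [26,125]
  minus <- extend_reads(gr("chr1", 101, 125, "-"), 100)
  expect_equal(GenomicRanges::start(minus), 26)
  expect_equal(GenomicRanges::end(minus), 125)
  # BED [10,35) on - clips at the origin: [0,35) -> 1-based [1,35]
  clipped <- extend_reads(gr("chr1", 11, 35, "-"), 100)
  expect_equal(GenomicRanges::start(clipped), 1)
  expect_equal(GenomicRanges::end(clipped), 35)
  expect_error(extend_reads(gr("chr1", 1, 25, "*")), "without strand")
})

test_that("region signal follows the pseudocount-floored log2 density formula", {
  region <- gr("chr1", 1001, 2000)
  expect_equal(region_signal(gr("chr1", 1, 1)[0], region), log2(0.01))
  reads <- gr("chr1", seq(1001, 1991, by = 10), seq(1001, 1991, by = 10) + 99,
              "+")
  expect_equal(length(reads), 100)
  expect_equal(region_signal(reads, region, 1000), log2(0.11))
  # a read spanning two exons of one region union is counted once
  two_exon <- gr("chr1", c(100, 300), c(200, 400))
  spanner <- gr("chr1", 150, 350, "+")
  expect_equal(region_signal(spanner, two_exon, 202),
               log2(1 / 202 + 0.01))
  expect_error(region_signal(reads, region[0]), "empty region")
})

test_that("gene and exon expression are density-based and scale invariant", {
  exons <- gr("chr1", c(1, 1001), c(1000, 2000))
  gene <- histonet:::new_gene_model("g1", "+", exons)
  expect_equal(gene$exonic_bp, 2000)
  reads <- gr("chr1", seq(1, 391, by = 10), seq(1, 391, by = 10) + 49, "+")
  expect_equal(length(reads), 40)
  expect_equal(gene_expression(reads, gene), log2(0.03))
  # doubling reads and region length leaves the density unchanged
  exons2 <- gr("chr1", c(1, 3001), c(2000, 5000))
  gene2 <- histonet:::new_gene_model("g2", "+", exons2)
  reads2 <- c(reads, gr("chr1", seq(3001, 3391, by = 10),
                        seq(3001, 3391, by = 10) + 49, "+"))
  expect_equal(gene_expression(reads2, gene2), log2(0.03))
  # single-exon gene: gene expression equals exon expression
  g <- histonet:::new_gene_model("g3", "+", gr("chr1", 1, 1000))
  expect_equal(gene_expression(reads, g),
               exon_expression(reads, g$exons))
})

test_that("promoter window is strand-aware, centered and 4001 bp wide", {
  gene_p <- histonet:::new_gene_model("gp", "+", gr("chr1", 5001, 6000))
  # TSS at 1-based 5001; window [3001, 7001]
  inside <- gr("chr1", c(3001, 7001), c(3001, 7001), "+")
  outside <- gr("chr1", c(3000, 7002), c(3000, 7002), "+")
  expect_equal(promoter_signal(inside, gene_p), log2(2.01))
  expect_equal(promoter_signal(outside, gene_p), log2(0.01))
  # minus-strand gene centers on its rightmost base
  gene_m <- histonet:::new_gene_model("gm", "-", gr("chr1", 5001, 6000))
  at_tss <- gr("chr1", 6000, 6000, "+")
  expect_equal(promoter_signal(at_tss, gene_m), log2(1.01))
  expect_error(promoter_signal(inside, gene_p, window_bp = 4000))
})

test_that("gene models merge isoforms into exon unions across formats", {
  tmp <- tempfile(fileext = ".refflat")
  writeLines(c(
    "gA\tgA.1\tchr1\t+\t0\t1000\t0\t1000\t3\t0,300,700,\t100,400,800,",
    "gA\tgA.2\tchr1\t+\t0\t1000\t0\t1000\t2\t50,300,\t150,500,",
    "gB\tgB.1\tchr1\t-\t0\t200\t0\t200\t1\t0,\t200,"
  ), tmp)
  models <- read_gene_models(tmp, "refFlat")
  expect_setequal(names(models), c("gA", "gB"))
  # gA union: [0,150) + [300,500) + [700,800) = 150 + 200 + 100
  expect_equal(models$gA$exonic_bp, 450)
  expect_equal(length(models$gA$exons), 3)
  expect_equal(models$gA$tss, 1)
  expect_equal(models$gB$tss, 200)

  bad <- tempfile(fileext = ".refflat")
  writeLines("gX\tgX.1\tchr1\t+\t0\t100\t0\t100\t2\t0,\t100,", bad)
  expect_error(read_gene_models(bad, "refFlat"), "line 1")

  # BED12 with 3 blocks
  b12 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t1100\tgC\t0\t+\t100\t1100\t0\t3\t100,200,100,\t0,400,900,",
             b12)
  mb <- read_gene_models(b12, "BED12")
  expect_equal(length(mb$gC$exons), 3)
  expect_equal(mb$gC$exonic_bp, 400)

  # GTF with out-of-order exons gets sorted
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t701\t800\t.\t+\t.\tgene_id \"gD\"; ",
           "transcript_id \"gD.1\";"),
    paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id \"gD\"; ",
           "transcript_id \"gD.1\";")
  ), gtf)
  mg <- read_gene_models(gtf, "GTF")
  expect_equal(GenomicRanges::start(mg$gD$exons), c(1, 701))
})

test_that("exon classification keeps internal exons and splits by event type", {
  exons <- gr("chr1", c(1, 201, 401, 601, 801),
              c(100, 300, 500, 700, 900))
  g5 <- histonet:::new_gene_model("g5", "+", exons)
  alt <- gr("chr1", 401, 500)
  alt$event_type <- "cassetteExon"
  out <- classify_exons(list(g5 = g5), alt)
  expect_setequal(out$ordinal[out$klass == "constitutive"], c(2, 4))
  expect_equal(out$ordinal[out$klass == "cassette"], 3)
  expect_false(any(out$ordinal %in% c(1, 5)))

  # two-exon gene yields nothing analyzable
  g2 <- histonet:::new_gene_model("g2", "+", gr("chr1", c(1, 201),
                                                c(100, 300)))
  expect_equal(nrow(classify_exons(list(g2 = g2), alt)), 0)

  # a retained-intron event excludes the exon from both classes
  ri <- gr("chr1", 201, 300)
  ri$event_type <- "retainedIntron"
  out2 <- suppressMessages(classify_exons(list(g5 = g5), ri))
  expect_false(any(out2$ordinal == 2))
  expect_setequal(out2$ordinal, c(3, 4))
})

test_that("inclusion value is the log2 exon/gene density ratio", {
  expect_equal(inclusion_value(-3, -3), 0)
  expect_equal(inclusion_value(log2(0.05), log2(0.1)), -1)
  # negative inclusion flags the alternative set downstream
  expect_true(inclusion_value(-4, -3) < 0)
})

test_that("per-region counts of disjoint regions conserve the total", {
  set.seed(7)
  starts <- sort(sample(1:9000, 200))
  reads <- extend_reads(gr("chr1", starts, starts + 24,
                           sample(c("+", "-"), 200, TRUE)))
  # three adjacent blocks jointly covering every extended read
  blocks <- list(gr("chr1", 1, 3000), gr("chr1", 3001, 6000),
                 gr("chr1", 6001, 10000))
  counted <- vapply(blocks, function(b) {
    sum(IRanges::overlapsAny(reads, b))
  }, numeric(1))
  # reads straddling a boundary appear in two blocks; count them once
  straddle <- sum(IRanges::overlapsAny(reads, gr("chr1", 3001, 3001))
                  & IRanges::overlapsAny(reads, gr("chr1", 1, 3000))) +
    sum(IRanges::overlapsAny(reads, gr("chr1", 6001, 6001)) &
          IRanges::overlapsAny(reads, gr("chr1", 1, 6000)))
  expect_equal(sum(counted) - straddle, 200)
})
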