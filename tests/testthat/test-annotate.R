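test_that("GFF3 and GTF encodings of the same gene load identically", {
  g3 <- load_gene_models(write_test_gff3(withr::local_tempfile(fileext = ".gff3")))
  gt <- load_gene_models(write_test_gtf(withr::local_tempfile(fileext = ".gtf")))
  expect_equal(g3$genes$gene_name, "GENEA")
  expect_equal(g3$genes[, c("gene_name", "chrom", "strand", "start", "end")],
               gt$genes[, c("gene_name", "chrom", "strand", "start", "end")])
  t3 <- g3$transcripts[[1]][[1]]
  tg <- gt$transcripts[[1]][[1]]
  expect_equal(unname(t3$exons), unname(tg$exons))
  expect_equal(unname(t3$cds), unname(tg$cds))
})

test_that("empty annotation input yields an empty model set", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p)
  m <- load_gene_models(p)
  expect_equal(nrow(m$genes), 0L)
  ctx <- classify_context(list(chrom = "chr1", pos = 5, end = 10,
                               svtype = "DEL"), m)
  expect_equal(ctx$context, "INTERGENIC")
})

models <- load_gene_models(write_test_gff3(tempfile(fileext = ".gff3")))
ctx_of <- function(pos, end, svtype = "DEL")
  classify_context(list(chrom = "chr1", pos = pos, end = end,
                        svtype = svtype), models)

test_that("context classification matches hand-built cases", {
  # model: exons [1000,2000] [5000,6000] [8000,9000];
  # CDS [1500,2000] [5000,6000] [8000,8400]; + strand
  within_intron <- ctx_of(3000, 4000)
  expect_equal(within_intron$context, "INTRONIC")
  expect_equal(within_intron$detail, "within intron 1")

  part_exon <- ctx_of(1800, 2600)
  expect_equal(part_exon$context, "EXONIC_CODING")
  expect_match(part_exon$detail, "partially exon 1")

  contained <- ctx_of(5100, 5200)
  expect_equal(contained$context, "EXONIC_CODING")
  expect_equal(contained$detail, "within exon 2")

  utr5 <- ctx_of(1100, 1300)   # exon 1 before CDS start on + strand
  expect_equal(utr5$context, "UTR5")
  utr3 <- ctx_of(8500, 8900)   # exon 3 after CDS end
  expect_equal(utr3$context, "UTR3")
  expect_match(utr3$detail, "3'UTR")

  expect_equal(ctx_of(20000, 21000)$context, "INTERGENIC")
  expect_length(ctx_of(20000, 21000)$genes, 0)

  # insertions classify by the single insertion point
  expect_equal(ctx_of(3000, 99999, svtype = "INS")$context, "INTRONIC")
  expect_equal(ctx_of(5100, 99999, svtype = "INS")$context, "EXONIC_CODING")

  # a span crossing exon/intron structure enumerates features in order
  multi <- ctx_of(1800, 5200)
  expect_equal(multi$context, "EXONIC_CODING")
  expect_match(multi$detail, "partially exon 1, intron 1, partially exon 2")
})

test_that("precedence agrees with a base-by-base oracle on random spans", {
  set.seed(31)
  for (i in 1:200) {
    p1 <- sample(500:9500, 1)
    p2 <- p1 + sample(0:3000, 1)
    got <- ctx_of(p1, p2)$context
    expect_equal(got, oracle_context(p1, p2),
                 info = sprintf("span %d-%d", p1, p2))
  }
})

test_that("minus-strand genes side their UTRs correctly", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t9000\t.\t-\t.\tID=g2;Name=GENEB",
    "chr1\ttest\tmRNA\t1000\t9000\t.\t-\t.\tID=g2t1;Parent=g2",
    "chr1\ttest\texon\t1000\t2000\t.\t-\t.\tID=e1;Parent=g2t1",
    "chr1\ttest\texon\t8000\t9000\t.\t-\t.\tID=e2;Parent=g2t1",
    "chr1\ttest\tCDS\t1500\t2000\t.\t-\t0\tID=c1;Parent=g2t1",
    "chr1\ttest\tCDS\t8000\t8400\t.\t-\t0\tID=c2;Parent=g2t1"), p)
  m <- load_gene_models(p)
  # genomically-left exon tail is the 3' end of a minus-strand gene
  left <- classify_context(list(chrom = "chr1", pos = 1100, end = 1300,
                                svtype = "DEL"), m)
  expect_equal(left$context, "UTR3")
  right <- classify_context(list(chrom = "chr1", pos = 8600, end = 8900,
                                 svtype = "DEL"), m)
  expect_equal(right$context, "UTR5")
  # exon numbering runs 5' -> 3', i.e. right to left on the minus strand
  expect_match(left$detail, "exon 2")
})

test_that("multi-gene overlaps report all genes with the max-precedence context", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t5000\t.\t+\t.\tID=ga;Name=GA",
    "chr1\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=gat;Parent=ga",
    "chr1\ttest\texon\t1000\t5000\t.\t+\t.\tID=gae;Parent=gat",
    "chr1\ttest\tCDS\t1000\t5000\t.\t+\t0\tID=gac;Parent=gat",
    "chr1\ttest\tgene\t4000\t9000\t.\t+\t.\tID=gb;Name=GB",
    "chr1\ttest\tmRNA\t4000\t9000\t.\t+\t.\tID=gbt;Parent=gb",
    "chr1\ttest\texon\t4000\t4100\t.\t+\t.\tID=gbe;Parent=gbt",
    "chr1\ttest\texon\t8000\t9000\t.\t+\t.\tID=gbe2;Parent=gbt",
    "chr1\ttest\tCDS\t8000\t9000\t.\t+\t0\tID=gbc;Parent=gbt"), p)
  m <- load_gene_models(p)
  ctx <- classify_context(list(chrom = "chr1", pos = 4500, end = 5000,
                               svtype = "DEL"), m)
  expect_setequal(ctx$genes, c("GA", "GB"))
  expect_equal(ctx$context, "EXONIC_CODING")  # coding in GA, intronic in GB
  expect_equal(ctx$primary_gene, "GA")
})
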