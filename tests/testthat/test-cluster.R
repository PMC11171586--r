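test_that("identical calls from two samples form one cluster", {
  r <- rbind(rec("S1", "chr1", 1000, 2000), rec("S2", "chr1", 1000, 2000))
  cl <- cluster_svs(r)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$carrier_samples[[1]], c("S1", "S2"))
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$pos, 1000L)
})

test_that("insufficient reciprocal overlap keeps calls apart", {
  # 10% overlap, far below the 50% default
  r <- rbind(rec("S1", "chr1", 1000, 2000), rec("S2", "chr1", 1900, 2900))
  expect_equal(nrow(cluster_svs(r)), 2L)
  # breakpoints beyond tolerance also split, even with high overlap
  r2 <- rbind(rec("S1", "chr1", 1000, 10000), rec("S2", "chr1", 1200, 10200))
  expect_equal(nrow(cluster_svs(r2)), 2L)
  expect_equal(nrow(cluster_svs(r2, match_params(breakpoint_tol = 250))), 1L)
  # different svtype never links
  r3 <- rbind(rec("S1", "chr1", 1000, 2000),
              rec("S2", "chr1", 1000, 2000, svtype = "DUP", svlen = 1000L))
  expect_equal(nrow(cluster_svs(r3)), 2L)
})

test_that("single linkage merges chains A~B~C even when A and C do not link", {
  # A [1000,2000], B [1040,2040], C [1080,2080]: A~B, B~C within 50 bp,
  # A-C breakpoints differ by 80 > 50. Brute-force pairwise check confirms.
  r <- rbind(rec("S1", "chr1", 1000, 2000),
             rec("S2", "chr1", 1040, 2040),
             rec("S3", "chr1", 1080, 2080))
  pair_links <- function(a, b, tol = 50) {
    ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
    w <- function(x) x[2] - x[1] + 1
    ov / w(a) >= .5 && ov / w(b) >= .5 &&
      abs(a[1] - b[1]) <= tol && abs(a[2] - b[2]) <= tol
  }
  ivs <- list(c(1000, 2000), c(1040, 2040), c(1080, 2080))
  expect_true(pair_links(ivs[[1]], ivs[[2]]))
  expect_true(pair_links(ivs[[2]], ivs[[3]]))
  expect_false(pair_links(ivs[[1]], ivs[[3]]))
  cl <- cluster_svs(r)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$carrier_samples[[1]], c("S1", "S2", "S3"))
  expect_equal(cl$pos, 1040L)  # median consensus
})

test_that("insertions match on breakpoint distance and length ratio", {
  r <- rbind(rec("S1", "chr1", 5000, 5000, svtype = "INS", svlen = 100L),
             rec("S2", "chr1", 5030, 5030, svtype = "INS", svlen = 80L),
             rec("S3", "chr1", 5030, 5030, svtype = "INS", svlen = 20L))
  cl <- cluster_svs(r)
  # S1~S2 (30 bp apart, ratio 0.8); S3 length ratio 0.2 < 0.5 stays apart
  expect_equal(nrow(cl), 2L)
  big <- cl[vapply(cl$carrier_samples, length, 1L) == 2, ]
  expect_setequal(big$carrier_samples[[1]], c("S1", "S2"))
})

test_that("clustering is permutation-invariant and conserves records", {
  set.seed(9)
  base <- do.call(rbind, lapply(1:40, function(i) {
    pos <- sample(1000:100000, 1)
    len <- sample(100:5000, 1)
    rec(sprintf("S%d", sample(1:6, 1)), sample(c("chr1", "chr2"), 1),
        pos, pos + len)
  }))
  cl1 <- cluster_svs(base)
  key <- function(cl) {
    k <- sprintf("%s:%d-%d:%s:%s", cl$chrom, cl$pos, cl$end, cl$svtype,
                 vapply(cl$carrier_samples, paste, "", collapse = "+"))
    sort(k)
  }
  for (i in 1:5) {
    shuf <- base[sample(nrow(base)), ]
    cl2 <- cluster_svs(shuf)
    expect_identical(key(cl2), key(cl1))
    expect_identical(cl2$cluster_id, cl1$cluster_id)
  }
  # conservation: member counts sum to the number of input records
  expect_equal(sum(cl1$n_members), nrow(base))
})

test_that("clustering consensus records is idempotent", {
  r <- rbind(rec("S1", "chr1", 1000, 2000), rec("S2", "chr1", 1040, 2040),
             rec("S1", "chr2", 5000, 9000), rec("S3", "chr2", 5010, 9010))
  cl <- cluster_svs(r)
  consensus <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i)
    rec(cl$cluster_id[i], cl$chrom[i], cl$pos[i], cl$end[i], cl$svtype[i],
        cl$svlen[i])))
  cl2 <- cluster_svs(consensus)
  expect_equal(nrow(cl2), nrow(cl))
  expect_equal(cl2[, c("chrom", "pos", "end", "svtype", "svlen")],
               cl[, c("chrom", "pos", "end", "svtype", "svlen")])
})

test_that("control_frequency uses the carrier-over-individuals convention", {
  ctl <- sprintf("CTRL%03d", 1:102)
  f1 <- control_frequency(list(carrier_samples = c("FAM1", ctl[1])), ctl)
  expect_equal(f1$n_carriers, 1L)
  expect_equal(f1$n_controls, 102L)
  expect_equal(round(f1$percent, 2), 0.98)
  f5 <- control_frequency(list(carrier_samples = ctl[1:5]), ctl)
  expect_equal(round(f5$percent, 2), 4.90)
  f0 <- control_frequency(list(carrier_samples = c("FAM1", "FAM2")), ctl)
  expect_equal(f0$percent, 0)
  expect_error(control_frequency(list(carrier_samples = "x"), character(0)),
               "non-empty")
})

test_that("tier boundaries are strict less-than", {
  expect_equal(assign_tier(0), "ABSENT")
  expect_equal(assign_tier(0.9999), "RARE")
  expect_equal(assign_tier(1.0), "UNCOMMON")
  expect_equal(assign_tier(4.9999), "UNCOMMON")
  expect_equal(assign_tier(5.0), "COMMON")
  ctl <- sprintf("C%d", 1:102)
  expect_equal(assign_tier(control_frequency(list(carrier_samples = ctl[1]), ctl)),
               "RARE")      # 0.98%
  expect_equal(assign_tier(control_frequency(list(carrier_samples = ctl[1:2]), ctl)),
               "UNCOMMON")  # 1.96%
  expect_equal(assign_tier(control_frequency(list(carrier_samples = ctl[1:6]), ctl)),
               "COMMON")    # 5.88%
})

test_that("cluster VCF export round-trips consensus genotypes", {
  r <- rbind(rec("S1", "chr1", 1000, 2000), rec("S2", "chr1", 1010, 2010),
             rec("S2", "chr1", 50000, 50000, svtype = "INS", svlen = 80L,
                 genotype = "1/1"))
  cl <- cluster_svs(r)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_cluster_vcf(cl, c("S1", "S2", "S3"), p, c(chr1 = 1000000L))
  back <- read_sv_vcf(p)
  expect_equal(nrow(back), 3L)  # S1+S2 for the DEL, S2 for the INS
  expect_equal(back$genotype[back$svtype == "INS"], "1/1")
  expect_setequal(back$sample_id[back$svtype == "DEL"], c("S1", "S2"))
})
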