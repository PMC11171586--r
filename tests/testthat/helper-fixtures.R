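# Shared fixtures and the independent brute-force gene-dropping oracle.

# founder couple + n genotyped children with given phenotypes
couple_ped <- function(phenos, family_code = "Z") {
  n <- length(phenos)
  pedigree(family_code, data.frame(
    id = c("F1", "F2", sprintf("C%d", seq_len(n))),
    father_id = c(NA, NA, rep("F1", n)),
    mother_id = c(NA, NA, rep("F2", n)),
    sex = c("male", "female", rep(c("male", "female"), length.out = n)),
    phenotype = c("UNKNOWN", "UNKNOWN", phenos),
    genotyped = c(FALSE, FALSE, rep(TRUE, n)),
    stringsAsFactors = FALSE))
}

# three-generation transmission chain: F1 x F2 -> C1 (x S1) -> G1 ... with
# n_chain genotyped descendants, each constraining one distinct meiosis
chain_ped <- function(n_chain, family_code = "Z") {
  ids <- c("F1", "F2"); fa <- c(NA, NA); mo <- c(NA, NA)
  parent <- "F1"; parent_mo <- "F2"
  for (i in seq_len(n_chain)) {
    kid <- sprintf("K%d", i)
    sp <- sprintf("S%d", i)
    ids <- c(ids, kid, sp)
    fa <- c(fa, parent, NA); mo <- c(mo, parent_mo, NA)
    parent <- kid; parent_mo <- sp
  }
  n <- length(ids)
  pedigree(family_code, data.frame(
    id = ids, father_id = fa, mother_id = mo,
    sex = rep(c("male", "female"), length.out = n),
    phenotype = ifelse(grepl("^K", ids), "GTS", "UNKNOWN"),
    genotyped = grepl("^K", ids),
    stringsAsFactors = FALSE))
}

# Independent oracle: full enumeration of all 2^(2 * n_nonfounders)
# transmission bit-vectors, one (paternal, maternal) bit per non-founder,
# weighted uniformly. Deliberately structured differently from the package's
# pruned depth-first engine.
oracle_p_seg <- function(ped, scheme) {
  ind <- ped$individuals
  ids <- ind$id
  fa <- match(ind$father_id, ids)
  mo <- match(ind$mother_id, ids)
  nonf <- which(!is.na(fa))
  # order non-founders so parents precede children
  repeat {
    ok <- TRUE
    for (pos in seq_along(nonf)) {
      i <- nonf[pos]
      for (p in c(fa[i], mo[i])) {
        pp <- match(p, nonf)
        if (!is.na(pp) && pp > pos) {
          nonf[c(pos, pp)] <- nonf[c(pp, pos)]
          ok <- FALSE
        }
      }
    }
    if (ok) break
  }
  nf <- length(nonf)
  m <- 2L * nf
  stopifnot(m <= 16L)  # oracle is for tiny pedigrees only
  car_idx <- match(scheme$obligate_carriers, ids)
  non_idx <- match(scheme$obligate_noncarriers, ids)
  fnd <- which(is.na(fa))
  outcomes <- 0:(2^m - 1)
  bits <- sapply(seq_len(m), function(b) bitwAnd(outcomes, 2^(b - 1)) > 0)
  if (m == 0L) bits <- matrix(logical(0), nrow = 1)
  n_out <- nrow(bits)
  per_founder <- sapply(fnd, function(origin) {
    # cnt: outcomes x individuals allele counts, filled in pedigree order
    cnt <- matrix(0L, nrow = n_out, ncol = length(ids))
    cnt[, origin] <- 1L
    for (pos in seq_along(nonf)) {
      i <- nonf[pos]
      pat <- (cnt[, fa[i]] == 2L) | (cnt[, fa[i]] == 1L & bits[, 2 * pos - 1])
      mat <- (cnt[, mo[i]] == 2L) | (cnt[, mo[i]] == 1L & bits[, 2 * pos])
      cnt[, i] <- pat + mat
    }
    ok <- rep(TRUE, n_out)
    for (i in car_idx) ok <- ok & cnt[, i] > 0L
    for (i in non_idx) ok <- ok & cnt[, i] == 0L
    mean(ok)
  })
  max(per_founder)
}

# random small pedigree (<= max_nonfounders) with a scheme realized from an
# actual latent gene drop, so the scheme is always satisfiable
random_ped_scheme <- function(seed, max_nonfounders = 6L) {
  set.seed(seed)
  repeat {
    n2 <- sample(1:3, 1)
    ind <- data.frame(id = c("F1", "F2"),
                      father_id = c(NA, NA), mother_id = c(NA, NA),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n2))
      ind <- rbind(ind, data.frame(id = sprintf("C%d", i),
                                   father_id = "F1", mother_id = "F2"))
    kid <- n2
    for (i in seq_len(n2)) {
      if (runif(1) < 0.5 && sum(!is.na(ind$father_id)) < max_nonfounders - 1) {
        sp <- sprintf("S%d", i)
        ind <- rbind(ind, data.frame(id = sp, father_id = NA, mother_id = NA))
        for (j in seq_len(sample(1:2, 1))) {
          if (sum(!is.na(ind$father_id)) >= max_nonfounders) break
          kid <- kid + 1
          ind <- rbind(ind, data.frame(id = sprintf("C%d", kid),
                                       father_id = sprintf("C%d", i),
                                       mother_id = sp))
        }
      }
    }
    n <- nrow(ind)
    ind$sex <- rep(c("male", "female"), length.out = n)
    ind$phenotype <- "UNKNOWN"
    ind$genotyped <- c(FALSE, FALSE, rep(TRUE, n - 2)) & runif(n) < 0.9
    ped <- pedigree("R", ind)
    g <- genotyped_ids(ped)
    if (length(g) < 2) next
    # realize carriers by one latent drop from F1
    fa <- match(ped$individuals$father_id, ped$individuals$id)
    mo <- match(ped$individuals$mother_id, ped$individuals$id)
    cnt <- integer(nrow(ped$individuals)); cnt[1] <- 1L
    for (i in which(!is.na(fa)))
      cnt[i] <- (if (cnt[fa[i]] == 1L) rbinom(1, 1, .5) else 0L) +
                (if (cnt[mo[i]] == 1L) rbinom(1, 1, .5) else 0L)
    carriers <- intersect(ped$individuals$id[cnt > 0], g)
    if (!length(carriers)) next
    sch <- seg_scheme("rand", obligate_carriers = carriers,
                      obligate_noncarriers = setdiff(g, carriers))
    return(list(ped = ped, scheme = sch))
  }
}

# tiny deterministic gene-model files for annotation tests
write_test_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t9000\t.\t+\t.\tID=g1;Name=GENEA",
    "chr1\ttest\tmRNA\t1000\t9000\t.\t+\t.\tID=g1t1;Parent=g1",
    "chr1\ttest\texon\t1000\t2000\t.\t+\t.\tID=g1e1;Parent=g1t1",
    "chr1\ttest\texon\t5000\t6000\t.\t+\t.\tID=g1e2;Parent=g1t1",
    "chr1\ttest\texon\t8000\t9000\t.\t+\t.\tID=g1e3;Parent=g1t1",
    "chr1\ttest\tCDS\t1500\t2000\t.\t+\t0\tID=g1c1;Parent=g1t1",
    "chr1\ttest\tCDS\t5000\t6000\t.\t+\t0\tID=g1c2;Parent=g1t1",
    "chr1\ttest\tCDS\t8000\t8400\t.\t+\t0\tID=g1c3;Parent=g1t1"), path)
  path
}

write_test_gtf <- function(path) {
  a <- "gene_id \"g1\"; transcript_id \"g1t1\"; gene_name \"GENEA\";"
  writeLines(c(
    sprintf("chr1\ttest\tgene\t1000\t9000\t.\t+\t.\tgene_id \"g1\"; gene_name \"GENEA\";"),
    sprintf("chr1\ttest\ttranscript\t1000\t9000\t.\t+\t.\t%s", a),
    sprintf("chr1\ttest\texon\t1000\t2000\t.\t+\t.\t%s", a),
    sprintf("chr1\ttest\texon\t5000\t6000\t.\t+\t.\t%s", a),
    sprintf("chr1\ttest\texon\t8000\t9000\t.\t+\t.\t%s", a),
    sprintf("chr1\ttest\tCDS\t1500\t2000\t.\t+\t0\t%s", a),
    sprintf("chr1\ttest\tCDS\t5000\t6000\t.\t+\t0\t%s", a),
    sprintf("chr1\ttest\tCDS\t8000\t8400\t.\t+\t0\t%s", a)), path)
  path
}

# brute-force per-base context oracle against the g1 model above
oracle_context <- function(p1, p2) {
  exons <- rbind(c(1000, 2000), c(5000, 6000), c(8000, 9000))
  cds <- rbind(c(1500, 2000), c(5000, 6000), c(8000, 8400))
  span <- p1:p2
  in_any <- function(iv, x) any(x >= iv[, 1] & x <= iv[, 2])
  lab <- vapply(span, function(x) {
    if (in_any(cds, x)) "EXONIC_CODING"
    else if (in_any(exons, x)) { if (x < 1500) "UTR5" else "UTR3" }
    else if (x >= 1000 && x <= 9000) "INTRONIC"
    else "INTERGENIC"
  }, character(1))
  prec <- c(EXONIC_CODING = 1, UTR5 = 2, UTR3 = 2, INTRONIC = 3, INTERGENIC = 4)
  names(sort(prec[unique(lab)]))[1]
}

# minimal sv_records builder for clustering tests
rec <- function(sample, chrom, pos, end, svtype = "DEL",
                svlen = if (svtype == "DEL") -(end - pos) else
                  if (svtype == "INS") 100L else end - pos,
                genotype = "0/1") {
  data.frame(sample_id = sample, chrom = chrom, pos = as.integer(pos),
             end = as.integer(end), svtype = svtype,
             svlen = as.integer(svlen), genotype = genotype,
             source_line = "test", stringsAsFactors = FALSE)
}
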