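#' Simulation configuration
#'
#' Defaults state the study design the simulator emulates: 17 multiplex
#' families with per-family genome counts drawn from the published family
#' sizes (4-14, mean 7.3, so 17 families average ~124 genomes), 102 unrelated
#' controls, 300 SVs per genome (the study averaged 2726; scaled down ~1/9 to
#' keep full-pipeline tests fast), and an SV type mix taken from the study's
#' uncommon-candidate counts (DEL/DUP/INV/INS = 154/34/11/7, normalized).
#' Background founder allele frequencies follow a rare-skewed Beta(0.2, 1.8)
#' spectrum (mean 0.1). Injected truth variants are heterozygous in all
#' obligate carriers of their family and absent everywhere else, including
#' controls.
#'
#' @param n_families number of families (default 17).
#' @param genomes_per_family integer range `c(min, max)` for genotyped
#'   genomes per family (default 4-14; drawn from the empirical study sizes
#'   truncated to this range).
#' @param n_controls unrelated controls (default 102).
#' @param svs_per_genome expected background SV calls per genome (default 300).
#' @param type_mix named proportions over DEL/DUP/INS/INV (normalized).
#' @param freq_spectrum function(n) drawing n founder allele frequencies.
#' @param n_injected number of injected co-segregating variants (default 5).
#' @param affected_fraction target fraction of genotyped members affected
#'   (default 80/124).
#' @param contigs named integer vector: the synthetic genome (default 5
#'   contigs of 10 Mb).
#' @param jitter_bp max per-file breakpoint jitter in bp (default 10),
#'   exercising fuzzy cross-sample matching.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 17L,
                       genomes_per_family = c(4L, 14L),
                       n_controls = 102L,
                       svs_per_genome = 300L,
                       type_mix = c(DEL = 154, DUP = 34, INS = 7, INV = 11),
                       freq_spectrum = function(n) rbeta(n, 0.2, 1.8),
                       n_injected = 5L,
                       affected_fraction = 80 / 124,
                       contigs = setNames(rep(10000000L, 5),
                                          paste0("chr", 1:5)),
                       jitter_bp = 10L) {
  stopifnot(n_families >= 1, n_controls >= 1, svs_per_genome >= 1,
            all(type_mix >= 0), sum(type_mix) > 0, n_injected >= 0,
            affected_fraction > 0, affected_fraction < 1)
  structure(list(n_families = as.integer(n_families),
                 genomes_per_family = as.integer(genomes_per_family),
                 n_controls = as.integer(n_controls),
                 svs_per_genome = as.integer(svs_per_genome),
                 type_mix = type_mix / sum(type_mix),
                 freq_spectrum = freq_spectrum,
                 n_injected = as.integer(n_injected),
                 affected_fraction = affected_fraction,
                 contigs = contigs,
                 jitter_bp = as.integer(jitter_bp)),
            class = "sim_config")
}

#' Generate a random multiplex-family pedigree
#'
#' Builds a 2-3 generation pedigree, drops a fully penetrant latent disease
#' allele from one founder to assign phenotypes (carriers affected, split
#' between full syndrome and other tic disorder; non-carriers healthy), and
#' marks as genotyped all affected members plus enough healthy members to
#' reach a genome count drawn from the published family sizes. Because
#' phenotypes are produced by an actual single-founder gene drop, the
#' family's default segregation scheme is always satisfiable
#' (`p_seg > 0`) and the family is multiplex (>= 2 affected).
#'
#' @param config a [sim_config()].
#' @param family_code family label.
#' @param seed integer seed; the same seed reproduces the same pedigree.
#' @return a [pedigree()].
#' @export
gen_pedigree <- function(config, family_code, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lo <- config$genomes_per_family[1]; hi <- config$genomes_per_family[2]
  sizes <- study_overview()$genomes
  sizes <- sizes[sizes >= lo & sizes <= hi]
  if (!length(sizes)) sizes <- lo:hi
  target <- sizes[sample.int(length(sizes), 1L)]  # sample() mis-handles length-1 x
  cap <- max(16L, target + 6L)  # structure must comfortably exceed target

  for (attempt in 1:400) {
    ind <- data.frame(id = c("F1", "F2"),
                      father_id = NA_character_, mother_id = NA_character_,
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
    n2 <- sample(max(2L, ceiling(target / 3)):5, 1)
    kid <- 0L
    gen2 <- character(0)
    for (i in seq_len(n2)) {
      kid <- kid + 1L
      id <- sprintf("C%d", kid)
      ind <- rbind(ind, data.frame(id = id, father_id = "F1", mother_id = "F2",
                                   sex = sample(c("male", "female"), 1)))
      gen2 <- c(gen2, id)
    }
    sp <- 0L
    for (id in gen2) {
      marry <- if (nrow(ind) < target + 2L) TRUE else runif(1) < 0.7
      if (marry && nrow(ind) < cap) {
        sp <- sp + 1L
        spouse <- sprintf("S%d", sp)
        sex_sp <- if (ind$sex[ind$id == id] == "male") "female" else "male"
        ind <- rbind(ind, data.frame(id = spouse, father_id = NA_character_,
                                     mother_id = NA_character_, sex = sex_sp))
        for (j in seq_len(sample(2:3, 1))) {
          if (nrow(ind) >= cap) break
          kid <- kid + 1L
          fa <- if (sex_sp == "female") id else spouse
          mo <- if (sex_sp == "female") spouse else id
          ind <- rbind(ind, data.frame(id = sprintf("C%d", kid), father_id = fa,
                                       mother_id = mo,
                                       sex = sample(c("male", "female"), 1)))
        }
      }
    }
    # latent fully penetrant disease allele from founder F1
    carrier <- drop_single_allele(ind, origin = "F1")
    n_aff <- sum(carrier)
    # accept multiplex drops that leave room for >= 1 genotyped healthy
    # member and can reach the drawn genome count exactly
    if (n_aff < 2 || n_aff > target - 1L ||
        sum(!carrier) < target - n_aff) next
    phen <- ifelse(carrier, sample(c("GTS", "TD"), nrow(ind), replace = TRUE),
                   "HEALTHY")
    aff_ids <- ind$id[carrier]
    healthy_ids <- ind$id[!carrier]
    n_healthy_geno <- max(1L, min(length(healthy_ids),
                                  target - length(aff_ids)))
    geno_ids <- c(aff_ids, healthy_ids[seq_len(n_healthy_geno)])
    ind$phenotype <- phen
    ind$genotyped <- ind$id %in% geno_ids
    # ids must be unique cohort-wide (they become VCF sample names)
    pre <- function(x) ifelse(is.na(x), x, sprintf("%s_%s", family_code, x))
    ind$id <- pre(ind$id)
    ind$father_id <- pre(ind$father_id)
    ind$mother_id <- pre(ind$mother_id)
    return(pedigree(family_code, ind))
  }
  stop("could not generate a multiplex pedigree for family ", family_code)
}

# one seeded gene drop of a single founder allele; returns carrier logical
drop_single_allele <- function(ind, origin) {
  n <- nrow(ind)
  fa <- match(ind$father_id, ind$id)
  mo <- match(ind$mother_id, ind$id)
  cnt <- integer(n)
  cnt[ind$id == origin] <- 1L
  for (i in seq_len(n)) {  # rows are built parents-first
    if (is.na(fa[i])) next
    pat <- if (cnt[fa[i]] == 2L) 1L else if (cnt[fa[i]] == 1L) rbinom(1, 1, 0.5) else 0L
    mat <- if (cnt[mo[i]] == 2L) 1L else if (cnt[mo[i]] == 1L) rbinom(1, 1, 0.5) else 0L
    cnt[i] <- pat + mat
  }
  cnt > 0L
}

#' Drop background genotypes down a pedigree
#'
#' Founder genotypes are drawn as Binomial(2, f) per locus from the given
#' allele frequencies; each parent-to-child transmission passes one allele,
#' alt with probability (parent count)/2. Returns allele counts.
#'
#' @param ped a [pedigree()].
#' @param freqs numeric vector of per-locus founder allele frequencies.
#' @param seed integer seed.
#' @return integer matrix individuals x loci (rownames = ids).
#' @export
drop_background <- function(ped, freqs, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ind <- ped$individuals
  n <- nrow(ind); L <- length(freqs)
  ord <- topo_order(ped)
  fa <- match(ind$father_id, ind$id)
  mo <- match(ind$mother_id, ind$id)
  cnt <- matrix(0L, nrow = n, ncol = L, dimnames = list(ind$id, NULL))
  for (i in ord) {
    if (is.na(fa[i])) {
      cnt[i, ] <- rbinom(L, 2L, freqs)
    } else {
      cnt[i, ] <- rbinom(L, 1L, cnt[fa[i], ] / 2) + rbinom(L, 1L, cnt[mo[i], ] / 2)
    }
  }
  cnt
}

#' Inject a co-segregating truth variant
#'
#' Produces genotypes that satisfy the scheme by construction: every obligate
#' carrier heterozygous (the minimal satisfying state), everyone else
#' (including unconstrained members and all controls) homozygous reference.
#'
#' @param ped a [pedigree()].
#' @param scheme a [seg_scheme()] for that family; must be satisfiable
#'   (`p_seg > 0`).
#' @param sv_template list/row with `chrom`, `pos`, `end`, `svtype`, `svlen`.
#' @return list with `genotypes` (named integer vector of allele counts over
#'   the family) and `truth` (one-row data.frame: chrom, pos, end, svtype,
#'   family_code, scheme_id, expected_tier).
#' @export
inject_coseg <- function(ped, scheme, sv_template) {
  sp <- suppressWarnings(p_seg(ped, scheme))
  if (sp$p_seg == 0)
    stop("scheme ", scheme$scheme_id, " is unsatisfiable in family ",
         ped$family_code)
  gt <- setNames(integer(nrow(ped$individuals)), ped$individuals$id)
  gt[scheme$obligate_carriers] <- 1L
  truth <- data.frame(chrom = sv_template$chrom, pos = sv_template$pos,
                      end = sv_template$end, svtype = sv_template$svtype,
                      family_code = ped$family_code,
                      scheme_id = scheme$scheme_id,
                      expected_tier = "ABSENT", stringsAsFactors = FALSE)
  list(genotypes = gt, truth = truth)
}

#' Simulate a full cohort with known truth
#'
#' Generates pedigrees and default schemes, a shared background SV panel
#' (loci, types, sizes, frequencies calibrated so the expected per-genome
#' call count matches `svs_per_genome`), family genotypes by gene dropping,
#' control genotypes by Hardy-Weinberg draws, synthetic gene models placed
#' so injected variants hit the configured contexts, and `n_injected`
#' co-segregating truth variants (one family each, cycling; absent from
#' controls and from background loci by at least 50 kb).
#'
#' @param config a [sim_config()].
#' @param seed master integer seed; all per-stage seeds derive from it.
#' @return object of class `sim_cohort`: list with `config`, `pedigrees`,
#'   `schemes`, `panel` (variant table with per-locus frequency), `fam_gt`
#'   (per family: allele-count matrix members x loci), `control_gt`,
#'   `control_ids`, `genes` (gene model table), `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed <- as.integer(seed)
  fam_codes <- make_family_codes(config$n_families)
  pedigrees <- lapply(seq_along(fam_codes), function(i)
    gen_pedigree(config, fam_codes[i], seed = seed * 1000L + i))
  names(pedigrees) <- fam_codes
  schemes <- lapply(pedigrees, function(p) list(default_scheme(p)))

  set.seed(seed + 777L)
  # calibrate panel size: expected calls/genome = sum of carrier
  # probabilities; trim the panel at the locus where the running expectation
  # reaches the target so the mean per-genome count is on target
  freqs <- numeric(0)
  while (sum(1 - (1 - freqs)^2) < config$svs_per_genome)
    freqs <- c(freqs, pmin(config$freq_spectrum(200L), 0.98))
  freqs <- freqs[seq_len(which(cumsum(1 - (1 - freqs)^2) >=
                                 config$svs_per_genome)[1])]
  L <- length(freqs)
  panel <- data.frame(
    chrom = sample(names(config$contigs), L, replace = TRUE),
    svtype = sample(names(config$type_mix), L, replace = TRUE,
                    prob = config$type_mix),
    freq = freqs, stringsAsFactors = FALSE)
  panel$pos <- as.integer(floor(runif(L, 1e5, config$contigs[panel$chrom] - 2e5)))
  len <- as.integer(pmax(60L, round(exp(runif(L, log(60), log(20000))))))
  panel$end <- ifelse(panel$svtype == "INS", panel$pos,
                      panel$pos + len)
  panel$svlen <- ifelse(panel$svtype == "INS",
                        pmin(len, 500L),
                        ifelse(panel$svtype == "DEL", -len, len))
  panel$end <- as.integer(panel$end); panel$svlen <- as.integer(panel$svlen)

  # injected truth variants: placed on a reserved stripe, in genes chosen to
  # hit the configured contexts
  inj_contexts <- rep(c("EXONIC_CODING", "UTR3", "INTRONIC", "INTRONIC",
                        "INTERGENIC"), length.out = config$n_injected)
  genes <- list(); truth <- list(); injected_panel <- list()
  inj_fams <- rep(fam_codes, length.out = config$n_injected)
  for (j in seq_len(config$n_injected)) {
    chrom <- names(config$contigs)[(j - 1L) %% length(config$contigs) + 1L]
    base <- 50000L + 40000L * ((j - 1L) %/% length(config$contigs))
    placed <- place_injected(chrom, base, inj_contexts[j], j)
    genes[[length(genes) + 1L]] <- placed$gene
    ped <- pedigrees[[inj_fams[j]]]
    inj <- inject_coseg(ped, schemes[[inj_fams[j]]][[1]], placed$sv)
    truth[[j]] <- cbind(inj$truth, data.frame(expected_context = inj_contexts[j],
                                              stringsAsFactors = FALSE))
    injected_panel[[j]] <- c(placed$sv, list(freq = 0, genotypes = inj$genotypes))
  }
  # keep background loci off the reserved injected stripe
  reserved <- panel$pos < 3e5
  panel$pos[reserved] <- panel$pos[reserved] + 3e5L
  panel$end[reserved] <- ifelse(panel$svtype[reserved] == "INS",
                                panel$pos[reserved],
                                panel$end[reserved] + 3e5L)

  # a few background genes away from both stripes, for realistic annotation
  for (k in 1:10) {
    chrom <- names(config$contigs)[(k - 1L) %% length(config$contigs) + 1L]
    s <- 4e5L + 500000L * k
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = sprintf("BGGENE%02d", k), gene_name = sprintf("BGG%02d", k),
      chrom = chrom, strand = "+", tx_start = s, tx_end = s + 20000L,
      cds_start = s + 2000L, cds_end = s + 18000L, n_exons = 3L,
      stringsAsFactors = FALSE)
  }
  gene_tab <- do.call(rbind, genes)

  # genotypes: families by gene dropping, controls by Hardy-Weinberg
  fam_gt <- list()
  for (i in seq_along(pedigrees)) {
    ped <- pedigrees[[i]]
    gt <- drop_background(ped, panel$freq, seed = seed * 100L + i)
    for (j in seq_len(config$n_injected)) {
      if (inj_fams[j] != names(pedigrees)[i]) {
        gt <- cbind(gt, 0L)
      } else {
        gt <- cbind(gt, injected_panel[[j]]$genotypes[rownames(gt)])
      }
    }
    fam_gt[[i]] <- gt
  }
  names(fam_gt) <- names(pedigrees)

  set.seed(seed + 999L)
  control_ids <- sprintf("CTRL%03d", seq_len(config$n_controls))
  control_gt <- matrix(rbinom(config$n_controls * L, 2L,
                              rep(panel$freq, each = config$n_controls)),
                       nrow = config$n_controls,
                       dimnames = list(control_ids, NULL))
  control_gt <- cbind(control_gt,
                      matrix(0L, nrow = config$n_controls,
                             ncol = config$n_injected))

  full_panel <- rbind(panel[, c("chrom", "pos", "end", "svtype", "svlen", "freq")],
                      do.call(rbind, lapply(injected_panel, function(x)
                        data.frame(chrom = x$chrom, pos = x$pos, end = x$end,
                                   svtype = x$svtype, svlen = x$svlen,
                                   freq = 0, stringsAsFactors = FALSE))))
  full_panel$id <- sprintf("sv%05d", seq_len(nrow(full_panel)))
  structure(list(config = config, pedigrees = pedigrees, schemes = schemes,
                 panel = full_panel, fam_gt = fam_gt,
                 control_gt = control_gt, control_ids = control_ids,
                 genes = gene_tab,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL),
            class = "sim_cohort")
}

make_family_codes <- function(n) {
  pool <- c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))
  pool[seq_len(n)]
}

# Build one gene + the injected SV so that the SV hits the requested context.
place_injected <- function(chrom, base, context, j) {
  gid <- sprintf("INJGENE%02d", j)
  gname <- sprintf("INJG%02d", j)
  # 3-exon plus-strand gene: exon1 [s, s+1000], exon2 [s+5000, s+6000],
  # exon3 [s+10000, s+11000]; CDS from s+200 to s+10500 (3' UTR tail in exon 3)
  s <- base
  gene <- data.frame(gene_id = gid, gene_name = gname, chrom = chrom,
                     strand = "+", tx_start = s, tx_end = s + 11000L,
                     cds_start = s + 200L, cds_end = s + 10500L, n_exons = 3L,
                     stringsAsFactors = FALSE)
  sv <- switch(context,
    EXONIC_CODING = list(pos = s + 300L, end = s + 700L),
    UTR3 = list(pos = s + 10600L, end = s + 10900L),
    INTRONIC = list(pos = s + 2000L, end = s + 3000L),
    INTERGENIC = list(pos = s + 25000L, end = s + 25400L))
  sv$chrom <- chrom
  sv$svtype <- "DEL"
  sv$svlen <- -(sv$end - sv$pos)
  list(gene = gene, sv = sv)
}

#' Write a simulated cohort to disk
#'
#' Writes one multi-sample VCF per family (`fam_<code>.vcf`, rows limited to
#' variants carried by at least one member), a control-cohort VCF
#' (`controls.vcf`), the PED file, schemes JSON, a truth TSV and a GFF3 of
#' the synthetic gene models. Per-file breakpoint jitter (at most
#' `jitter_bp`, derived deterministically from the seed embedded in the
#' cohort) is applied to background family variants so cross-sample
#' clustering is exercised; injected truth variants are never jittered.
#' All outputs are byte-deterministic given the cohort object.
#'
#' @param sim a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @param jitter_seed integer seed for the per-file jitter (default 1).
#' @return named list of paths (`family_vcfs`, `control_vcf`, `ped`,
#'   `schemes`, `truth`, `gff`), invisibly.
#' @export
write_cohort <- function(sim, out_dir, jitter_seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- sim$config$contigs
  panel <- sim$panel
  n_inj <- nrow(sim$truth %||% data.frame())
  n_bg <- nrow(panel) - n_inj
  fam_paths <- character(0)
  set.seed(as.integer(jitter_seed))
  for (fc in names(sim$pedigrees)) {
    ped <- sim$pedigrees[[fc]]
    gt <- sim$fam_gt[[fc]][genotyped_ids(ped), , drop = FALSE]
    keep <- colSums(gt) > 0L
    v <- panel[keep, c("chrom", "pos", "end", "svtype", "svlen", "id")]
    if (sim$config$jitter_bp > 0 && nrow(v)) {
      bg <- which(keep) <= n_bg
      jit <- sample(-sim$config$jitter_bp:sim$config$jitter_bp,
                    sum(bg), replace = TRUE)
      v$pos[bg] <- v$pos[bg] + jit
      v$end[bg] <- ifelse(v$svtype[bg] == "INS", v$pos[bg], v$end[bg] + jit)
    }
    gtm <- t(gt[, keep, drop = FALSE])
    gtc <- matrix(c("0/0", "0/1", "1/1")[gtm + 1L], nrow = nrow(gtm),
                  dimnames = list(NULL, rownames(gt)))
    p <- file.path(out_dir, sprintf("fam_%s.vcf", fc))
    write_sv_vcf(v, gtc, p, contigs)
    fam_paths <- c(fam_paths, p)
  }
  keep <- colSums(sim$control_gt) > 0L
  v <- panel[keep, c("chrom", "pos", "end", "svtype", "svlen", "id")]
  gtm <- t(sim$control_gt[, keep, drop = FALSE])
  gtc <- matrix(c("0/0", "0/1", "1/1")[gtm + 1L], nrow = nrow(gtm),
                dimnames = list(NULL, rownames(sim$control_gt)))
  ctl_path <- file.path(out_dir, "controls.vcf")
  write_sv_vcf(v, gtc, ctl_path, contigs)

  ped_path <- file.path(out_dir, "cohort.ped")
  write_ped(sim$pedigrees, ped_path)
  schemes_path <- file.path(out_dir, "schemes.json")
  write_schemes(sim$schemes, schemes_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(sim$truth %||% data.frame(), truth_path)
  gff_path <- file.path(out_dir, "genes.gff3")
  write_gene_gff3(sim$genes, gff_path)
  invisible(list(family_vcfs = fam_paths, control_vcf = ctl_path,
                 ped = ped_path, schemes = schemes_path, truth = truth_path,
                 gff = gff_path))
}

# GFF3 emitter for the simulator's simple gene table (uniform 3-exon genes).
write_gene_gff3 <- function(gene_tab, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gene_tab))) {
    g <- gene_tab[i, ]
    tx <- sprintf("%s.t1", g$gene_id)
    span <- g$tx_end - g$tx_start
    ex <- rbind(c(g$tx_start, g$tx_start + round(span * 0.09)),
                c(g$tx_start + round(span * 0.45), g$tx_start + round(span * 0.55)),
                c(g$tx_end - round(span * 0.09), g$tx_end))
    row <- function(type, s, e, id, parent)
      sprintf("%s\tsvcoseg_sim\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;Parent=%s",
              g$chrom, type, as.integer(s), as.integer(e), g$strand,
              if (type == "CDS") "0" else ".", id, parent)
    lines <- c(lines,
               sprintf("%s\tsvcoseg_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       g$chrom, g$tx_start, g$tx_end, g$strand, g$gene_id,
                       g$gene_name),
               sprintf("%s\tsvcoseg_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$tx_start, g$tx_end, g$strand, tx, g$gene_id))
    for (k in 1:3) {
      lines <- c(lines, row("exon", ex[k, 1], ex[k, 2],
                            sprintf("%s.e%d", tx, k), tx))
      cs <- max(ex[k, 1], g$cds_start); ce <- min(ex[k, 2], g$cds_end)
      if (cs <= ce)
        lines <- c(lines, row("CDS", cs, ce, sprintf("%s.c%d", tx, k), tx))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Assemble in-memory SV records from a simulated cohort
#'
#' Equivalent to [write_cohort()] followed by [read_sv_vcf()] on every file,
#' but without touching disk (no jitter applied); used by fast end-to-end
#' tests. Only carrier records are emitted, matching the reader's contract.
#'
#' @param sim a [simulate_cohort()] result.
#' @return an `sv_records` data.frame over all genotyped family members and
#'   controls.
#' @export
cohort_records <- function(sim) {
  panel <- sim$panel
  rows <- list()
  emit <- function(gt, label) {
    for (sid in rownames(gt)) {
      idx <- which(gt[sid, ] > 0L)
      if (!length(idx)) next
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, chrom = panel$chrom[idx], pos = panel$pos[idx],
        end = panel$end[idx], svtype = panel$svtype[idx],
        svlen = panel$svlen[idx],
        genotype = c("0/1", "1/1")[pmin(gt[sid, idx], 2L)],
        source_line = paste0(label, ":", panel$id[idx]),
        stringsAsFactors = FALSE)
    }
  }
  for (fc in names(sim$pedigrees)) {
    ped <- sim$pedigrees[[fc]]
    emit(sim$fam_gt[[fc]][genotyped_ids(ped), , drop = FALSE],
         sprintf("fam_%s", fc))
  }
  emit(sim$control_gt, "controls")
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$pos, res$end, res$sample_id), ]
  rownames(res) <- NULL
  class(res) <- c("sv_records", "data.frame")
  res
}
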