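#' Evaluate a segregation scheme against a cluster's carriers
#'
#' The acceptance rule: every obligate carrier contributes at least one
#' alternative allele, no obligate non-carrier contributes any; unconstrained
#' individuals are ignored. A genotyped family member with an explicitly
#' missing genotype fails an obligate position by default (strict reading);
#' with `missing_as_unknown = TRUE` missing obligate *non-carriers* are
#' treated as unconstrained (obligate carriers still fail).
#'
#' @param cluster one row of an `sv_clusters` data.frame, or any list with a
#'   `carrier_samples` element (or a bare character vector of carrier ids).
#' @param scheme a [seg_scheme()].
#' @param missing character vector of ids whose genotype is missing (`./.`).
#' @param missing_as_unknown relax missing obligate non-carriers only.
#' @return logical.
#' @export
evaluate_scheme <- function(cluster, scheme, missing = character(0),
                            missing_as_unknown = FALSE) {
  carriers <- if (is.character(cluster)) cluster else {
    cs <- cluster$carrier_samples
    if (is.list(cs)) cs[[1]] else cs
  }
  if (any(scheme$obligate_carriers %in% missing)) return(FALSE)
  non <- scheme$obligate_noncarriers
  if (missing_as_unknown) non <- setdiff(non, missing)
  else if (any(non %in% missing)) return(FALSE)
  all(scheme$obligate_carriers %in% carriers) && !any(non %in% carriers)
}

#' Find candidate co-segregating variants
#'
#' A cluster is a candidate when it passes at least one segregation scheme in
#' at least one family (schemes within a family combine by OR) and its
#' control-cohort tier is at or below `max_tier` (default `UNCOMMON`, i.e.
#' COMMON variants are excluded). Each candidate is annotated with its
#' genomic context, the families hit (with the scheme that passed), and its
#' tier.
#'
#' @param clusters an `sv_clusters` data.frame over family + control records.
#' @param pedigrees named list of [pedigree()] objects.
#' @param schemes named list (by family) of lists of [seg_scheme()]; families
#'   absent fall back to [default_scheme()].
#' @param control_ids character vector of control sample ids.
#' @param models a [load_gene_models()] result, or `NULL` to skip annotation
#'   (context reported as `NA`).
#' @param max_tier highest admissible tier (`"ABSENT"`, `"RARE"`,
#'   `"UNCOMMON"`).
#' @param missing_as_unknown passed to [evaluate_scheme()].
#' @return list with `candidates` (data.frame: `cluster_id`, `chrom`, `pos`,
#'   `end`, `svtype`, `tier`, `n_carriers_controls`, `maf_percent`,
#'   `context`, `genes`, `detail`, `families_hit`, `schemes_hit`,
#'   `n_families`), `summary` (type x nested-tier count matrix), and
#'   `family_hits` (long data.frame of every cluster/family/scheme
#'   evaluation that passed).
#' @export
find_candidates <- function(clusters, pedigrees, schemes = list(),
                            control_ids, models = NULL,
                            max_tier = "UNCOMMON",
                            missing_as_unknown = FALSE) {
  tier_rank <- c(ABSENT = 1, RARE = 2, UNCOMMON = 3, COMMON = 4)
  stopifnot(max_tier %in% names(tier_rank))
  fam_schemes <- lapply(names(pedigrees), function(fc)
    if (!is.null(schemes[[fc]])) schemes[[fc]] else list(default_scheme(pedigrees[[fc]])))
  names(fam_schemes) <- names(pedigrees)
  fam_members <- lapply(pedigrees, genotyped_ids)

  hits <- list()
  cand_rows <- list()
  for (i in seq_len(nrow(clusters))) {
    if (!clusters$clustered[i]) next
    carriers <- clusters$carrier_samples[[i]]
    passed_fams <- character(0); passed_schemes <- character(0)
    for (fc in names(pedigrees)) {
      for (sc in fam_schemes[[fc]]) {
        if (evaluate_scheme(carriers, sc,
                            missing_as_unknown = missing_as_unknown)) {
          passed_fams <- c(passed_fams, fc)
          passed_schemes <- c(passed_schemes, sc$scheme_id)
          hits[[length(hits) + 1L]] <- data.frame(
            cluster_id = clusters$cluster_id[i], family_code = fc,
            scheme_id = sc$scheme_id, stringsAsFactors = FALSE)
          break  # schemes OR within family; record first passing scheme
        }
      }
    }
    if (!length(passed_fams)) next
    freq <- control_frequency(list(carrier_samples = carriers), control_ids)
    tier <- assign_tier(freq)
    if (tier_rank[[tier]] > tier_rank[[max_tier]]) next
    ctx <- if (is.null(models)) NULL else classify_context(clusters[i, ], models)
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      cluster_id = clusters$cluster_id[i], chrom = clusters$chrom[i],
      pos = clusters$pos[i], end = clusters$end[i],
      svtype = clusters$svtype[i], tier = tier,
      n_carriers_controls = freq$n_carriers,
      n_controls = freq$n_controls,
      maf_percent = freq$percent,
      context = if (is.null(ctx)) NA_character_ else ctx$context,
      genes = if (is.null(ctx)) NA_character_ else
        paste(unique(ctx$genes), collapse = ","),
      detail = if (is.null(ctx)) NA_character_ else ctx$detail,
      families_hit = paste(passed_fams, collapse = ","),
      schemes_hit = paste(passed_schemes, collapse = ","),
      n_families = length(passed_fams),
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows)
    else data.frame(cluster_id = character(0), chrom = character(0),
                    pos = integer(0), end = integer(0), svtype = character(0),
                    tier = character(0), n_carriers_controls = integer(0),
                    n_controls = integer(0),
                    maf_percent = numeric(0), context = character(0),
                    genes = character(0), detail = character(0),
                    families_hit = character(0), schemes_hit = character(0),
                    n_families = integer(0), stringsAsFactors = FALSE)
  family_hits <- if (length(hits)) do.call(rbind, hits)
    else data.frame(cluster_id = character(0), family_code = character(0),
                    scheme_id = character(0), stringsAsFactors = FALSE)
  list(candidates = candidates,
       summary = candidate_summary(candidates),
       family_hits = family_hits)
}

#' Nested type-by-tier candidate counts
#'
#' Counts follow the nested reporting convention: `uncommon` includes rare
#' and absent variants, `rare` includes absent, `absent` (private) stands
#' alone, so `uncommon >= rare >= absent` per type.
#'
#' @param candidates candidate data.frame from [find_candidates()].
#' @return integer matrix, rows = DEL/DUP/INV/INS, columns
#'   `uncommon`/`rare`/`absent`.
#' @export
candidate_summary <- function(candidates) {
  types <- c("DEL", "DUP", "INV", "INS")
  m <- matrix(0L, nrow = length(types), ncol = 3,
              dimnames = list(types, c("uncommon", "rare", "absent")))
  for (ty in types) {
    tt <- candidates$tier[candidates$svtype == ty]
    m[ty, "uncommon"] <- sum(tt %in% c("ABSENT", "RARE", "UNCOMMON"))
    m[ty, "rare"] <- sum(tt %in% c("ABSENT", "RARE"))
    m[ty, "absent"] <- sum(tt == "ABSENT")
  }
  m
}

#' Attach P(obs) statistics to candidates
#'
#' Single-family exonic candidates get `p_obs_single(p_seg, p_exvar)`;
#' candidates hit in k >= 2 families get the Bonferroni-corrected
#' `p_obs_multi` with the control carrier fraction as P(var); single-family
#' non-exonic candidates get `NA`. The p_seg used per family is the one for
#' the scheme that passed.
#'
#' @param candidates candidate data.frame from [find_candidates()].
#' @param seg_probs data.frame with columns `family_code`, `scheme_id`,
#'   `p_seg` (see [seg_prob_table()]).
#' @param p_exvar study-wide exonic fraction (number or `exonic_fraction`).
#' @param n_families_total total number of study families F.
#' @param zero_maf_pvar passed to [p_obs_multi()].
#' @return `candidates` with columns `p_obs` and `p_obs_rounded` appended.
#' @export
attach_statistics <- function(candidates, seg_probs, p_exvar,
                              n_families_total, zero_maf_pvar = NA_real_) {
  pe <- if (inherits(p_exvar, "exonic_fraction")) p_exvar$p_exvar else p_exvar
  lookup <- function(fc, sc) {
    i <- which(seg_probs$family_code == fc & seg_probs$scheme_id == sc)
    if (!length(i))
      stop("no segregation probability for family ", fc, " scheme ", sc)
    seg_probs$p_seg[i[1]]
  }
  p_obs <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fams <- strsplit(candidates$families_hit[i], ",")[[1]]
    scs <- strsplit(candidates$schemes_hit[i], ",")[[1]]
    ps <- mapply(lookup, fams, scs)
    if (length(fams) >= 2L) {
      maf <- candidates$maf_percent[i] / 100
      p_obs[i] <- p_obs_multi(ps, maf, n_families_total,
                              zero_maf_pvar = zero_maf_pvar)$p_obs
    } else if (!is.na(candidates$context[i]) &&
               candidates$context[i] %in% c("EXONIC_CODING", "UTR5", "UTR3")) {
      p_obs[i] <- p_obs_single(ps[1], pe)$p_obs
    }
  }
  candidates$p_obs <- p_obs
  candidates$p_obs_rounded <- round_pobs(p_obs)
  candidates
}

#' Per-family, per-scheme segregation probability table
#'
#' @param pedigrees named list of [pedigree()] objects.
#' @param schemes named list of scheme lists (default schemes where absent).
#' @param max_meioses enumeration cap before Monte Carlo fallback.
#' @param n_draws,seed Monte Carlo parameters.
#' @return data.frame with `family_code`, `scheme_id`, `p_seg`,
#'   `origin_founder`, `method`.
#' @export
seg_prob_table <- function(pedigrees, schemes = list(), max_meioses = 22L,
                           n_draws = 100000L, seed = 1L) {
  rows <- list()
  for (fc in names(pedigrees)) {
    scs <- if (!is.null(schemes[[fc]])) schemes[[fc]]
           else list(default_scheme(pedigrees[[fc]]))
    for (sc in scs) {
      sp <- suppressWarnings(
        p_seg(pedigrees[[fc]], sc, max_meioses = max_meioses,
              n_draws = n_draws, seed = seed))
      rows[[length(rows) + 1L]] <- data.frame(
        family_code = fc, scheme_id = sc$scheme_id, p_seg = sp$p_seg,
        origin_founder = sp$origin_founder, method = sp$method,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Overlap SV candidate genes with SNV co-segregation gene lists
#'
#' Returns genes that both carry an SV co-segregating in at least
#' `sv_min_families` families at or below the SV tier ceiling, and appear in
#' the SNV list with at least `snv_min_families` co-segregating families.
#' Tier semantics are nested: `"ABSENT"` admits only private SVs,
#' `"RARE"` admits absent + rare, `"UNCOMMON"` admits all three.
#'
#' @param sv_genes data.frame with columns `gene`, `tier`, `n_families`
#'   (typically derived from annotated candidates).
#' @param snv_list data.frame with columns `gene`, `n_families` (and
#'   optionally `tier_label`, taken on trust from the input file).
#' @param sv_max_tier SV tier ceiling.
#' @param sv_min_families,snv_min_families inclusive thresholds.
#' @return character vector of gene names, sorted.
#' @export
snv_overlap <- function(sv_genes, snv_list, sv_max_tier = "ABSENT",
                        sv_min_families = 1L, snv_min_families = 2L) {
  tier_rank <- c(ABSENT = 1, RARE = 2, UNCOMMON = 3)
  stopifnot(sv_max_tier %in% names(tier_rank))
  sv_ok <- sv_genes$gene[
    tier_rank[sv_genes$tier] <= tier_rank[[sv_max_tier]] &
      sv_genes$n_families >= sv_min_families]
  snv_ok <- snv_list$gene[snv_list$n_families >= snv_min_families]
  sort(unique(intersect(sv_ok, snv_ok)))
}

#' Write report tables
#'
#' Emits four deterministic text files into `out_dir`: `family_overview.tsv`
#' (per family/scheme P(seg)), `exonic_candidates.tsv` (single-family exonic
#' rare candidates), `multifamily_candidates.tsv` (recurrent candidates with
#' corrected P(obs)), and `gene_list.txt` (unique candidate gene names for
#' external enrichment tools). Probabilities are rounded with
#' [round_pobs()]; positions are reported as `chrom:pos-end`.
#'
#' @param candidates candidate data.frame with statistics attached.
#' @param seg_probs data.frame from [seg_prob_table()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the paths written, invisibly.
#' @export
render_report <- function(candidates, seg_probs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("family_overview.tsv", "exonic_candidates.tsv",
                                "multifamily_candidates.tsv", "gene_list.txt"))
  fam <- seg_probs
  fam$p_seg <- round_pobs(fam$p_seg, 6L)
  write_tsv(fam, paths[1])

  type_names <- c(DEL = "deletion", DUP = "duplication", INS = "insertion",
                  INV = "inversion")
  fmt <- function(d) {
    if (!nrow(d)) return(data.frame(position = character(0), type = character(0),
                                    gene = character(0), location = character(0),
                                    maf_percent_controls = character(0),
                                    families = character(0), p_obs = numeric(0)))
    data.frame(position = ifelse(d$svtype == "INS",
                                 sprintf("%s:%d", d$chrom, d$pos),
                                 sprintf("%s:%d-%d", d$chrom, d$pos, d$end)),
               type = unname(type_names[d$svtype]),
               gene = d$genes, location = d$detail,
               maf_percent_controls = sprintf("%.2f (%d/%d)",
                                              d$maf_percent,
                                              d$n_carriers_controls,
                                              d$n_controls),
               families = d$families_hit,
               p_obs = d$p_obs_rounded, stringsAsFactors = FALSE)
  }
  exonic <- candidates[candidates$n_families == 1 & !is.na(candidates$context) &
                         candidates$context %in% c("EXONIC_CODING", "UTR5", "UTR3"), ,
                       drop = FALSE]
  multi <- candidates[candidates$n_families >= 2, , drop = FALSE]
  write_tsv(fmt(exonic), paths[2])
  write_tsv(fmt(multi), paths[3])

  genes <- unique(unlist(strsplit(candidates$genes[!is.na(candidates$genes) &
                                                     candidates$genes != ""], ",")))
  writeLines(sort(as.character(genes %||% character(0))), paths[4])
  invisible(paths)
}

write_tsv <- function(df, path) {
  con <- file(path, "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Run the full co-segregation pipeline
#'
#' Reads family and control SV VCFs, clusters all records jointly, computes
#' per-family segregation probabilities, filters clusters by scheme and
#' control tier, annotates genomic context, attaches P(obs) statistics, and
#' writes the report tables.
#'
#' @param family_vcfs character vector of family VCF paths (multi-sample;
#'   sample names must match pedigree individual ids).
#' @param control_vcfs character vector of control VCF paths.
#' @param ped_path PED file path.
#' @param out_dir output directory.
#' @param schemes_path optional JSON schemes file.
#' @param gff_path optional GFF3/GTF gene models.
#' @param params a [match_params()].
#' @param p_exvar exonic fraction; when `NULL` (default) it is estimated
#'   from the contexts of all clustered variants (requires `gff_path`).
#' @param n_families_total total families F for the Bonferroni factor;
#'   default = number of families in the PED file.
#' @param max_tier tier ceiling, default `"UNCOMMON"`.
#' @param max_meioses,n_draws,seed segregation-probability engine controls.
#' @param missing_as_unknown passed to [evaluate_scheme()].
#' @return list with `candidates`, `seg_probs`, `summary`, `family_hits`,
#'   `p_exvar`, `n_clusters`, `report_paths`.
#' @export
run_coseg <- function(family_vcfs, control_vcfs, ped_path, out_dir,
                      schemes_path = NULL, gff_path = NULL,
                      params = match_params(), p_exvar = NULL,
                      n_families_total = NULL, max_tier = "UNCOMMON",
                      max_meioses = 22L, n_draws = 100000L, seed = 1L,
                      missing_as_unknown = FALSE) {
  pedigrees <- read_ped(ped_path)
  schemes <- if (!is.null(schemes_path)) read_schemes(schemes_path) else list()
  models <- if (!is.null(gff_path)) load_gene_models(gff_path) else NULL

  fam_recs <- lapply(family_vcfs, read_sv_vcf)
  ctl_recs <- lapply(control_vcfs, read_sv_vcf)
  control_ids <- unique(unlist(lapply(control_vcfs, vcf_sample_names)))
  records <- do.call(rbind, c(fam_recs, ctl_recs))
  message(sprintf("[read] %d SV records from %d family + %d control VCF(s)",
                  if (is.null(records)) 0L else nrow(records),
                  length(family_vcfs), length(control_vcfs)))

  clusters <- cluster_svs(records, params)
  message(sprintf("[cluster] %d clusters", nrow(clusters)))

  seg_probs <- seg_prob_table(pedigrees, schemes, max_meioses = max_meioses,
                              n_draws = n_draws, seed = seed)
  if (is.null(p_exvar)) {
    if (is.null(models))
      stop("p_exvar not given and no gene models to estimate it from")
    ctxs <- vapply(seq_len(nrow(clusters)), function(i)
      classify_context(clusters[i, ], models)$context, character(1))
    p_exvar <- estimate_p_exvar(ctxs)
  }
  found <- find_candidates(clusters, pedigrees, schemes, control_ids, models,
                           max_tier = max_tier,
                           missing_as_unknown = missing_as_unknown)
  message(sprintf("[filter] %d candidate(s) passed scheme + tier",
                  nrow(found$candidates)))
  if (is.null(n_families_total)) n_families_total <- length(pedigrees)
  candidates <- attach_statistics(found$candidates, seg_probs, p_exvar,
                                  n_families_total)
  report_paths <- render_report(candidates, seg_probs, out_dir)
  message(sprintf("[report] wrote %d file(s) to %s", length(report_paths), out_dir))
  list(candidates = candidates, seg_probs = seg_probs,
       summary = found$summary, family_hits = found$family_hits,
       p_exvar = p_exvar, n_clusters = nrow(clusters),
       report_paths = report_paths)
}

# sample names of a VCF without parsing its body
vcf_sample_names <- function(path) {
  hdr <- VariantAnnotation::scanVcfHeader(path)
  VariantAnnotation::samples(hdr)
}
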