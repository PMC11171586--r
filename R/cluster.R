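#' Matching parameters for cross-sample SV clustering
#'
#' Two interval-type calls (DEL/DUP/INV) are considered the same variant when
#' they share chromosome and type, their reciprocal overlap is at least
#' `reciprocal_overlap`, and both breakpoints differ by at most
#' `breakpoint_tol` bp. Insertions match on breakpoint distance and length
#' ratio. Defaults follow common SV-merging practice (50% reciprocal overlap,
#' +/- 50 bp).
#'
#' @param reciprocal_overlap fraction in (0, 1], default 0.5.
#' @param breakpoint_tol non-negative bp tolerance, default 50.
#' @param ins_len_ratio min(len)/max(len) floor for insertions in (0, 1],
#'   default 0.5.
#' @return object of class `match_params`.
#' @export
match_params <- function(reciprocal_overlap = 0.5, breakpoint_tol = 50L,
                         ins_len_ratio = 0.5) {
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1,
            breakpoint_tol >= 0, ins_len_ratio > 0, ins_len_ratio <= 1)
  structure(list(reciprocal_overlap = reciprocal_overlap,
                 breakpoint_tol = as.integer(breakpoint_tol),
                 ins_len_ratio = ins_len_ratio),
            class = "match_params")
}

#' Cluster SV records across samples into equivalence classes
#'
#' Single-linkage clustering: two records link iff they satisfy the
#' [match_params()] criteria; a cluster is a connected component of the link
#' graph, so every record belongs to exactly one cluster and the result does
#' not depend on input order. Breakend records are never linked and form
#' singleton clusters flagged `clustered = FALSE`.
#'
#' Consensus coordinates are member medians (rounded); `carrier_samples` is
#' the set of samples contributing at least one member record.
#'
#' @param records an `sv_records` data.frame from [read_sv_vcf()] (rows from
#'   several files may be concatenated with `rbind`).
#' @param params a [match_params()].
#' @return data.frame of class `sv_clusters` with columns `cluster_id`,
#'   `chrom`, `pos`, `end`, `svtype`, `svlen`, `n_members`, `clustered`, and
#'   list-columns `carrier_samples` and `members` (row indices into the
#'   sorted input, returned as attribute `records`).
#' @export
cluster_svs <- function(records, params = match_params()) {
  records <- as.data.frame(records)
  if (!nrow(records)) {
    out <- data.frame(cluster_id = character(0), chrom = character(0),
                      pos = integer(0), end = integer(0), svtype = character(0),
                      svlen = integer(0), n_members = integer(0),
                      clustered = logical(0))
    out$carrier_samples <- list()
    out$members <- list()
    class(out) <- c("sv_clusters", "data.frame")
    attr(out, "records") <- records
    return(out)
  }
  # canonical internal order makes cluster ids permutation-invariant
  records <- records[order(records$chrom, records$svtype, records$pos,
                           records$end, records$svlen, records$sample_id), ]
  rownames(records) <- NULL
  n <- nrow(records)

  # identical calls always link; deduplicate to unique "sites" first so the
  # pairwise stage scales with distinct coordinates, not carrier counts.
  # BND records never link, not even to identical coordinates: each stays a
  # singleton site.
  site_key <- paste(records$chrom, records$svtype, records$pos, records$end,
                    records$svlen, sep = "\r")
  is_bnd <- records$svtype == "BND"
  site_key[is_bnd] <- paste0(site_key[is_bnd], "\rBND", seq_len(sum(is_bnd)))
  site_of_rec <- match(site_key, unique(site_key))
  us <- records[!duplicated(site_key),
                c("chrom", "svtype", "pos", "end", "svlen")]
  m <- nrow(us)
  parent <- seq_len(m)

  edges <- site_link_edges(us, params)
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, m - max(edges)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_len(m)

  comp_of_rec <- comp[site_of_rec]
  idx_by_comp <- split(seq_len(n), comp_of_rec)
  rows <- lapply(idx_by_comp, function(idx) {
    r <- records[idx, ]
    data.frame(chrom = r$chrom[1],
               pos = as.integer(round(median(r$pos))),
               end = as.integer(round(median(r$end))),
               svtype = r$svtype[1],
               svlen = as.integer(round(median(r$svlen))),
               n_members = length(idx),
               clustered = r$svtype[1] != "BND",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$carrier_samples <- lapply(idx_by_comp, function(idx)
    sort(unique(records$sample_id[idx])))
  out$members <- idx_by_comp
  ord <- order(out$chrom, out$pos, out$end, out$svtype)
  out <- out[ord, ]
  out$cluster_id <- sprintf("SVC%05d", seq_len(nrow(out)))
  out <- out[, c("cluster_id", "chrom", "pos", "end", "svtype", "svlen",
                 "n_members", "clustered", "carrier_samples", "members")]
  rownames(out) <- NULL
  class(out) <- c("sv_clusters", "data.frame")
  attr(out, "records") <- records
  out
}

# Edge list (site index pairs) of the single-linkage graph over unique sites.
site_link_edges <- function(us, params) {
  edges_list <- list()
  grp <- paste(us$chrom, us$svtype, sep = "\r")
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) < 2L || us$svtype[i[1]] == "BND") next
    sub <- us[i, ]
    if (sub$svtype[1] == "INS") {
      ir <- IRanges::IRanges(sub$pos, sub$pos)
      hits <- IRanges::findOverlaps(ir, maxgap = params$breakpoint_tol,
                                    drop.self = TRUE, drop.redundant = TRUE)
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      len_q <- abs(sub$svlen[q]); len_s <- abs(sub$svlen[s])
      ok <- abs(sub$pos[q] - sub$pos[s]) <= params$breakpoint_tol &
        pmin(len_q, len_s) / pmax(len_q, len_s) >= params$ins_len_ratio
    } else {
      ir <- IRanges::IRanges(sub$pos, sub$end)
      hits <- IRanges::findOverlaps(ir, maxgap = params$breakpoint_tol,
                                    drop.self = TRUE, drop.redundant = TRUE)
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ov <- pmin(sub$end[q], sub$end[s]) - pmax(sub$pos[q], sub$pos[s]) + 1L
      wq <- sub$end[q] - sub$pos[q] + 1L
      ws <- sub$end[s] - sub$pos[s] + 1L
      ok <- ov > 0L &
        ov / wq >= params$reciprocal_overlap &
        ov / ws >= params$reciprocal_overlap &
        abs(sub$pos[q] - sub$pos[s]) <= params$breakpoint_tol &
        abs(sub$end[q] - sub$end[s]) <= params$breakpoint_tol
    }
    if (any(ok))
      edges_list[[length(edges_list) + 1L]] <- cbind(i[q[ok]], i[s[ok]])
  }
  if (length(edges_list)) do.call(rbind, edges_list)
  else matrix(integer(0), ncol = 2)
}

#' Control-cohort carrier frequency of a cluster
#'
#' The frequency convention is carrier individuals over control individuals
#' (not alleles): a sample counts as a carrier if it contributes at least one
#' alternative allele. Control samples without a call count as non-carriers,
#' so the frequency is a lower bound.
#'
#' @param cluster one row of an `sv_clusters` data.frame (or anything with a
#'   `carrier_samples` character vector / list-column).
#' @param control_ids character vector of control sample ids (non-empty).
#' @return object of class `cohort_frequency`: list with `n_carriers`,
#'   `n_controls`, `percent`.
#' @export
control_frequency <- function(cluster, control_ids) {
  if (!length(control_ids)) stop("control_ids must be non-empty")
  cs <- cluster$carrier_samples
  if (is.list(cs)) cs <- cs[[1]]
  k <- length(intersect(cs, control_ids))
  structure(list(n_carriers = k, n_controls = length(control_ids),
                 percent = 100 * k / length(control_ids)),
            class = "cohort_frequency")
}

#' Assign a control-frequency tier
#'
#' `ABSENT` at exactly 0%, `RARE` below 1%, `UNCOMMON` from 1% up to (not
#' including) 5%, `COMMON` at 5% and above. The boundaries are strict
#' less-than: 1/102 = 0.98% is RARE, 5/102 = 4.90% is UNCOMMON, an exact 1%
#' or 5% falls in the next tier up. The nested report-time sets are unions:
#' private = ABSENT, rare = ABSENT+RARE, uncommon = ABSENT+RARE+UNCOMMON.
#'
#' @param freq a [control_frequency()] result, or a bare percent.
#' @return single string, one of `"ABSENT"`, `"RARE"`, `"UNCOMMON"`,
#'   `"COMMON"`.
#' @export
assign_tier <- function(freq) {
  pct <- if (inherits(freq, "cohort_frequency")) freq$percent else as.numeric(freq)
  stopifnot(length(pct) == 1L, pct >= 0)
  if (pct == 0) "ABSENT"
  else if (pct < 1) "RARE"
  else if (pct < 5) "UNCOMMON"
  else "COMMON"
}

#' Export clusters as a merged multi-sample VCF
#'
#' Writes consensus coordinates with per-sample genotypes (`0/1` for members,
#' `0/0` otherwise) for all non-breakend clusters.
#'
#' @param clusters an `sv_clusters` data.frame.
#' @param samples character vector of sample columns to emit.
#' @param path output path.
#' @param contigs named integer vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_cluster_vcf <- function(clusters, samples, path, contigs) {
  cl <- clusters[clusters$clustered, , drop = FALSE]
  gt <- matrix("0/0", nrow = nrow(cl), ncol = length(samples),
               dimnames = list(NULL, samples))
  recs <- attr(clusters, "records")
  for (i in seq_len(nrow(cl))) {
    mem <- recs[cl$members[[i]], ]
    gts <- tapply(mem$genotype, mem$sample_id, function(g)
      if (any(g == "1/1")) "1/1" else "0/1")
    hit <- intersect(names(gts), samples)
    gt[i, hit] <- gts[hit]
  }
  v <- cl[, c("chrom", "pos", "end", "svtype", "svlen")]
  v$id <- cl$cluster_id
  write_sv_vcf(v, gt, path, contigs)
}
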