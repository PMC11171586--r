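#' Load gene models from GFF3 or GTF
#'
#' Reads gene/transcript/exon/CDS features and builds an interval-searchable
#' set of gene models. UTRs are derived as exon minus CDS, sided by strand.
#' Format is chosen by file extension (`.gtf` vs anything else = GFF3);
#' features whose parent transcript or gene cannot be resolved are skipped
#' with a warning.
#'
#' @param path GFF3 or GTF file.
#' @return object of class `gene_models`: list with `genes` (data.frame
#'   `gene_id`, `gene_name`, `chrom`, `strand`, `start`, `end`) and
#'   `transcripts` (per-gene list of transcripts, each with sorted `exons`
#'   and `cds` interval matrices).
#' @export
load_gene_models <- function(path) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (!length(gr)) return(empty_gene_models())
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = type, stringsAsFactors = FALSE)
  if (fmt == "gtf") {
    df$gene_id <- as.character(md$gene_id)
    df$tx_id <- as.character(md$transcript_id)
    df$gene_name <- if ("gene_name" %in% names(md))
      as.character(md$gene_name) else NA_character_
  } else {
    first_chr <- function(x) vapply(x, function(v)
      if (length(v)) as.character(v)[1] else NA_character_, character(1))
    id <- as.character(md$ID)
    parent <- first_chr(md$Parent)
    nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
    # resolve transcript -> gene
    tx_rows <- type %in% c("mRNA", "transcript")
    tx2gene <- setNames(parent[tx_rows], id[tx_rows])
    df$gene_id <- ifelse(type == "gene", id,
                  ifelse(tx_rows, parent, unname(tx2gene[parent])))
    df$tx_id <- ifelse(tx_rows, id, ifelse(type == "gene", NA_character_, parent))
    df$gene_name <- nm
  }
  orphan <- df$type %in% c("exon", "CDS") &
    (is.na(df$gene_id) | is.na(df$tx_id))
  if (any(orphan)) {
    warning(sum(orphan), " exon/CDS feature(s) without resolvable parents skipped")
    df <- df[!orphan, ]
  }

  gene_rows <- df[df$type == "gene", ]
  gids <- if (nrow(gene_rows)) gene_rows$gene_id else unique(df$gene_id[!is.na(df$gene_id)])
  genes <- do.call(rbind, lapply(gids, function(gid) {
    sub <- df[!is.na(df$gene_id) & df$gene_id == gid, ]
    grow <- sub[sub$type == "gene", ]
    nm <- c(grow$gene_name, sub$gene_name)
    nm <- nm[!is.na(nm)]
    data.frame(gene_id = gid,
               gene_name = if (length(nm)) nm[1] else gid,  # ENSG fallback
               chrom = sub$chrom[1], strand = sub$strand[1],
               start = min(sub$start), end = max(sub$end),
               stringsAsFactors = FALSE)
  }))
  transcripts <- lapply(gids, function(gid) {
    sub <- df[!is.na(df$gene_id) & df$gene_id == gid & !is.na(df$tx_id), ]
    lapply(split(sub, sub$tx_id), function(tx) {
      ex <- tx[tx$type == "exon", c("start", "end")]
      cds <- tx[tx$type == "CDS", c("start", "end")]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      list(exons = as.matrix(ex), cds = as.matrix(cds),
           strand = tx$strand[1])
    })
  })
  names(transcripts) <- gids
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_models")
}

empty_gene_models <- function() {
  structure(list(genes = data.frame(gene_id = character(0),
                                    gene_name = character(0),
                                    chrom = character(0), strand = character(0),
                                    start = integer(0), end = integer(0)),
                 transcripts = list()),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes on %d contig(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Classify the genomic context of an SV
#'
#' Overlap is computed strand-agnostically on the inclusive span
#' `[pos, end]`; insertions are classified by their single insertion point.
#' Within each overlapped gene the representative transcript is the longest
#' one (by exonic bases); context precedence is
#' `EXONIC_CODING > UTR5/UTR3 > INTRONIC > INTERGENIC`, taken over all
#' overlapped genes. Exons of transcripts without any CDS count as
#' non-coding exonic and are reported as `UTR3`. `detail` names the
#' overlapped features of the primary (max-precedence) gene in genomic
#' order, with exons numbered 5' to 3' along the transcript strand.
#'
#' @param cluster one row of an `sv_clusters` data.frame, or any list with
#'   `chrom`, `pos`, `end`, `svtype`.
#' @param models a [load_gene_models()] result.
#' @return object of class `genomic_context`: list with `context`, `genes`
#'   (character, empty iff intergenic), `primary_gene`, `detail`.
#' @export
classify_context <- function(cluster, models) {
  stopifnot(inherits(models, "gene_models"))
  p1 <- as.integer(cluster$pos)
  p2 <- if (identical(as.character(cluster$svtype), "INS")) p1
        else as.integer(cluster$end)
  chrom <- as.character(cluster$chrom)
  g <- models$genes
  hit <- which(g$chrom == chrom & g$start <= p2 & g$end >= p1)
  if (!length(hit))
    return(structure(list(context = "INTERGENIC", genes = character(0),
                          primary_gene = NA_character_, detail = "intergenic"),
                     class = "genomic_context"))
  per_gene <- lapply(hit, function(i)
    classify_in_gene(p1, p2, models$transcripts[[g$gene_id[i]]], g$gene_name[i]))
  prec <- c(EXONIC_CODING = 1, UTR5 = 2, UTR3 = 2, INTRONIC = 3)
  ranks <- vapply(per_gene, function(x) prec[[x$context]], numeric(1))
  best <- which.min(ranks)
  structure(list(context = per_gene[[best]]$context,
                 genes = vapply(per_gene, `[[`, character(1), "gene"),
                 primary_gene = per_gene[[best]]$gene,
                 detail = per_gene[[best]]$detail),
            class = "genomic_context")
}

# Context of [p1, p2] within one gene, using its longest transcript.
classify_in_gene <- function(p1, p2, txs, gene_name) {
  exonic_bp <- vapply(txs, function(t)
    sum(t$exons[, "end"] - t$exons[, "start"] + 1), numeric(1))
  t <- txs[[which.max(exonic_bp)]]
  ex <- t$exons; cds <- t$cds
  minus <- identical(t$strand, "-")
  n_ex <- nrow(ex)
  ov <- function(iv) any(iv[, "start"] <= p2 & iv[, "end"] >= p1)

  context <- if (nrow(cds) && ov(cds)) "EXONIC_CODING"
  else if (ov(ex)) {
    if (!nrow(cds)) "UTR3"  # non-coding transcript: non-coding exonic
    else {
      cs <- min(cds[, "start"]); ce <- max(cds[, "end"])
      before <- p1 < cs; after <- p2 > ce
      side <- if (before && !after) "upstream" else if (after && !before) "downstream"
              else "both"
      if (side == "both") if (minus) "UTR3" else "UTR5"
      else if ((side == "upstream") != minus) "UTR5" else "UTR3"
    }
  } else "INTRONIC"

  # feature walk in genomic order: exon 1..n along transcript strand
  feat <- list()
  for (i in seq_len(n_ex)) {
    num <- if (minus) n_ex - i + 1L else i
    feat[[length(feat) + 1L]] <- list(s = ex[i, "start"], e = ex[i, "end"],
                                      name = sprintf("exon %d", num))
    if (i < n_ex) {
      inum <- if (minus) n_ex - i else i
      feat[[length(feat) + 1L]] <- list(s = ex[i, "end"] + 1L,
                                        e = ex[i + 1L, "start"] - 1L,
                                        name = sprintf("intron %d", inum))
    }
  }
  hits <- Filter(function(f) f$s <= p2 && f$e >= p1, feat)
  detail <- if (!length(hits)) "within gene span"
  else if (length(hits) == 1L) {
    f <- hits[[1]]
    if (p1 >= f$s && p2 <= f$e) sprintf("within %s", f$name)
    else sprintf("partially %s", f$name)
  } else {
    nm <- vapply(hits, `[[`, character(1), "name")
    f1 <- hits[[1]]; fn <- hits[[length(hits)]]
    if (p1 > f1$s) nm[1] <- paste("partially", nm[1])
    if (p2 < fn$e) nm[length(nm)] <- paste("partially", nm[length(nm)])
    paste(nm, collapse = ", ")
  }
  if (context %in% c("UTR5", "UTR3"))
    detail <- sprintf("%s, %s", detail, sub("UTR5", "5'UTR",
                                            sub("UTR3", "3'UTR", context)))
  list(context = context, gene = gene_name, detail = detail)
}
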