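#' Read structural variant records from a VCF
#'
#' Parses a VCF 4.x (plain or gzipped) carrying structural variants with
#' `SVTYPE` (INFO key or symbolic ALT such as `<DEL>`) and `END` and/or
#' `SVLEN`. One record is emitted per sample carrying at least one
#' alternative allele per VCF row; samples with `0/0` or missing genotypes
#' contribute no record. For deletions, duplications and inversions a missing
#' `END` is inferred as `pos + |SVLEN|`; insertions use `end = pos` and carry
#' the inserted length in `svlen`. Records with neither `END` nor `SVLEN`
#' (non-insertion) are skipped with a warning. Breakend (`BND`) records are
#' retained but flagged so the clustering step leaves them unclustered.
#'
#' @param path VCF file path.
#' @return data.frame of class `sv_records` with columns `sample_id`,
#'   `chrom`, `pos`, `end`, `svtype`, `svlen`, `genotype`, `source_line`.
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(empty_sv_records())
  inf <- VariantAnnotation::info(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)

  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE)
            else rep(NA_character_, n)
  if (anyNA(svtype)) {
    # fall back to symbolic ALT (<DEL>, <DUP>, ...); vectorized first-ALT
    alt <- VariantAnnotation::alt(vcf)
    nn <- S4Vectors::elementNROWS(alt)
    alt1 <- rep(NA_character_, n)
    alt1[nn > 0L] <- as.character(unlist(alt))[cumsum(nn) - nn + 1L][nn > 0L]
    sym_full <- rep(NA_character_, n)
    has_sym <- !is.na(alt1) & grepl("^<", alt1)
    sym_full[has_sym] <- sub("^<([A-Za-z]+).*", "\\1", alt1[has_sym])
    svtype <- ifelse(is.na(svtype), sym_full, svtype)
  }
  svtype <- toupper(svtype)

  end_info <- if ("END" %in% names(inf)) suppressWarnings(as.integer(inf$END))
              else rep(NA_integer_, n)
  svlen <- extract_svlen(inf, n)

  keep <- !is.na(svtype) & svtype %in% c("DEL", "DUP", "INS", "INV", "BND")
  no_span <- keep & svtype %in% c("DEL", "DUP", "INV") &
    is.na(end_info) & is.na(svlen)
  if (any(no_span)) {
    warning(sum(no_span), " record(s) in ", basename(path),
            " lack both END and SVLEN; skipped")
    keep <- keep & !no_span
  }

  end <- end_info
  span <- svtype %in% c("DEL", "DUP", "INV")
  end[span & is.na(end)] <- pos[span & is.na(end)] + abs(svlen[span & is.na(end)])
  end[svtype %in% c("INS", "BND")] <- pos[svtype %in% c("INS", "BND")]
  # infer svlen from the span when absent; deletions carry negative lengths
  svlen[span & is.na(svlen)] <-
    (end - pos)[span & is.na(svlen)] * ifelse(svtype[span & is.na(svlen)] == "DEL", -1L, 1L)
  svlen[svtype == "DEL" & !is.na(svlen)] <- -abs(svlen[svtype == "DEL" & !is.na(svlen)])

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF '", path, "' has no GT genotypes")
  samples <- colnames(gt)
  vids <- rownames(vcf)

  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    g <- gsub("|", "/", gt[, j], fixed = TRUE)
    carrier <- keep & grepl("1", g, fixed = TRUE)
    if (!any(carrier)) next
    idx <- which(carrier)
    out[[j]] <- data.frame(
      sample_id = samples[j], chrom = chrom[idx], pos = pos[idx],
      end = as.integer(end[idx]), svtype = svtype[idx],
      svlen = as.integer(svlen[idx]), genotype = g[idx],
      source_line = paste0(basename(path), ":", vids[idx]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_sv_records())
  res <- res[order(res$chrom, res$pos, res$end, res$sample_id), ]
  rownames(res) <- NULL
  class(res) <- c("sv_records", "data.frame")
  res
}

extract_svlen <- function(inf, n) {
  if (!"SVLEN" %in% names(inf)) return(rep(NA_integer_, n))
  sl <- inf$SVLEN
  if (is.list(sl) || is(sl, "List")) {
    nn <- S4Vectors::elementNROWS(sl)
    out <- rep(NA_integer_, n)
    out[nn > 0L] <-
      suppressWarnings(as.integer(unlist(sl)))[cumsum(nn) - nn + 1L][nn > 0L]
    out
  } else suppressWarnings(as.integer(sl))
}

empty_sv_records <- function() {
  res <- data.frame(sample_id = character(0), chrom = character(0),
                    pos = integer(0), end = integer(0), svtype = character(0),
                    svlen = integer(0), genotype = character(0),
                    source_line = character(0), stringsAsFactors = FALSE)
  class(res) <- c("sv_records", "data.frame")
  res
}

#' Write a multi-sample structural variant VCF
#'
#' Emits a minimal, byte-deterministic VCF 4.2 with `SVTYPE`/`END`/`SVLEN`
#' INFO fields, symbolic ALT alleles and per-sample GT, sorted by
#' (chromosome, position). Used by the synthetic-cohort writer and the
#' cluster exporter; [read_sv_vcf()] round-trips its output.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `end`, `svtype`,
#'   `svlen` and optionally `id`.
#' @param gt character matrix of genotypes (`"0/0"`, `"0/1"`, `"1/1"`,
#'   `"./."`), rows = variants, columns = samples (named).
#' @param path output path.
#' @param contigs named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(variants, gt, path, contigs) {
  stopifnot(nrow(variants) == nrow(gt), !is.null(colnames(gt)))
  ord <- order(variants$chrom, variants$pos, variants$end)
  variants <- variants[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  ids <- if ("id" %in% names(variants)) variants$id
         else sprintf("sv%05d", seq_len(nrow(variants)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svcoseg",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", variants$svtype,
                  as.integer(variants$end), as.integer(variants$svlen))
  body <- paste(variants$chrom, variants$pos, ids, "N",
                sprintf("<%s>", variants$svtype), ".", "PASS", info, "GT",
                sep = "\t")
  if (ncol(gt) > 0)
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
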