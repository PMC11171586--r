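#' Construct a pedigree
#'
#' A pedigree is one family's parent-child graph together with per-individual
#' phenotype labels and a flag saying whether a genome is available for that
#' individual. Individuals with exactly one recorded parent are completed with
#' a synthetic untyped founder spouse so that every non-founder has two
#' resolvable parents (keeps the transmission model uniform).
#'
#' @param family_code single string identifying the family (e.g. `"A"`).
#' @param individuals data.frame with columns `id`, `father_id`, `mother_id`
#'   (`NA` for founders), `sex` (`"male"`, `"female"`, `"unknown"`),
#'   `phenotype` (`"GTS"`, `"TD"`, `"HEALTHY"`, `"UNKNOWN"`) and `genotyped`
#'   (logical).
#' @return object of class `pedigree`, a list with elements `family_code` and
#'   `individuals` (the completed data.frame).
#' @export
pedigree <- function(family_code, individuals) {
  stopifnot(is.character(family_code), length(family_code) == 1L)
  req <- c("id", "father_id", "mother_id", "sex", "phenotype", "genotyped")
  missing_cols <- setdiff(req, names(individuals))
  if (length(missing_cols))
    stop("individuals is missing columns: ", paste(missing_cols, collapse = ", "))
  ind <- individuals[, req]
  ind$id <- as.character(ind$id)
  ind$father_id <- as.character(ind$father_id)
  ind$mother_id <- as.character(ind$mother_id)
  ind$father_id[!is.na(ind$father_id) & ind$father_id %in% c("", "0")] <- NA_character_
  ind$mother_id[!is.na(ind$mother_id) & ind$mother_id %in% c("", "0")] <- NA_character_
  ind$phenotype <- toupper(as.character(ind$phenotype))
  bad_phen <- setdiff(unique(ind$phenotype), c("GTS", "TD", "HEALTHY", "UNKNOWN"))
  if (length(bad_phen)) stop("unknown phenotype labels: ", paste(bad_phen, collapse = ", "))
  ind$genotyped <- as.logical(ind$genotyped)

  # complete single-parent records with a synthetic untyped founder spouse
  half <- which(is.na(ind$father_id) != is.na(ind$mother_id))
  for (i in half) {
    side <- if (is.na(ind$father_id[i])) "father" else "mother"
    sid <- sprintf("%s_%s", ind$id[i], side)
    if (!sid %in% ind$id) {
      ind <- rbind(ind, data.frame(
        id = sid, father_id = NA_character_, mother_id = NA_character_,
        sex = if (side == "father") "male" else "female",
        phenotype = "UNKNOWN", genotyped = FALSE,
        stringsAsFactors = FALSE))
    }
    if (side == "father") ind$father_id[i] <- sid else ind$mother_id[i] <- sid
  }
  rownames(ind) <- NULL
  structure(list(family_code = family_code, individuals = ind),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s: %d individuals (%d genotyped, %d founders)\n",
              x$family_code, nrow(x$individuals),
              sum(x$individuals$genotyped), length(founders(x))))
  invisible(x)
}

#' Founder ids of a pedigree (individuals with no recorded parents)
#' @param ped a [pedigree()].
#' @return character vector of ids.
#' @export
founders <- function(ped) {
  ind <- ped$individuals
  ind$id[is.na(ind$father_id) & is.na(ind$mother_id)]
}

#' Ids of genotyped individuals
#' @param ped a [pedigree()].
#' @return character vector of ids.
#' @export
genotyped_ids <- function(ped) ped$individuals$id[ped$individuals$genotyped]

# Topological order of individual indices (parents before children).
# Returns NULL when the parent-child graph has a cycle.
topo_order <- function(ped) {
  ind <- ped$individuals
  n <- nrow(ind)
  fa <- match(ind$father_id, ind$id)
  mo <- match(ind$mother_id, ind$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(ind$father_id) | (!is.na(fa) & placed[pmax(fa, 1L)] & !is.na(fa))) &
                     (is.na(ind$mother_id) | (!is.na(mo) & placed[pmax(mo, 1L)] & !is.na(mo))))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) return(NULL)
  ord
}

#' Check pedigree invariants
#'
#' Violations are returned, not thrown: duplicate ids, parent ids that do not
#' resolve within the family, individuals that are their own ancestors
#' (cycles), and pedigrees without founders.
#'
#' @param ped a [pedigree()].
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_pedigree <- function(ped) {
  ind <- ped$individuals
  v <- character(0)
  dup <- unique(ind$id[duplicated(ind$id)])
  if (length(dup))
    v <- c(v, sprintf("individual '%s': id duplicated within family", dup))
  unresolved <- FALSE
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(ind[[col]]) & !(ind[[col]] %in% ind$id)
    if (any(bad)) {
      unresolved <- TRUE
      v <- c(v, sprintf("individual '%s': %s '%s' not found in family",
                        ind$id[bad], col, ind[[col]][bad]))
    }
  }
  if (!length(founders(ped)))
    v <- c(v, sprintf("family '%s': no founder individual", ped$family_code))
  # cycle detection is only meaningful once ids and parents resolve
  if (!length(dup) && !unresolved && length(founders(ped)) &&
      is.null(topo_order(ped)))
    v <- c(v, sprintf("family '%s': parent-child graph contains a cycle",
                      ped$family_code))
  v
}

#' Phenotype labels counted as affected
#'
#' By default both full-syndrome and partial-phenotype patients (GTS and
#' non-GTS tic disorder) are collapsed into "affected" when deriving a
#' default segregation scheme.
#'
#' @param affected_labels character subset of
#'   `c("GTS", "TD", "HEALTHY", "UNKNOWN")`.
#' @return object of class `phenotype_collapse`.
#' @export
phenotype_collapse <- function(affected_labels = c("GTS", "TD")) {
  affected_labels <- toupper(affected_labels)
  bad <- setdiff(affected_labels, c("GTS", "TD", "HEALTHY", "UNKNOWN"))
  if (length(bad) || !length(affected_labels))
    stop("affected_labels must be a non-empty subset of GTS/TD/HEALTHY/UNKNOWN")
  structure(list(affected_labels = affected_labels), class = "phenotype_collapse")
}

#' Construct a segregation scheme
#'
#' A scheme partitions the genotyped members of one family into obligate
#' carriers (every one must carry at least one alternative allele), obligate
#' non-carriers (must carry none), and unconstrained individuals (genotyped
#' but permitted either state, e.g. an asymptomatic carrier).
#'
#' @param scheme_id single string.
#' @param obligate_carriers,obligate_noncarriers,unconstrained character
#'   vectors of individual ids; pairwise disjoint, carriers non-empty.
#' @param ped optional [pedigree()]; when given, the three sets must
#'   partition its genotyped individuals.
#' @return object of class `seg_scheme`.
#' @export
seg_scheme <- function(scheme_id, obligate_carriers,
                       obligate_noncarriers = character(0),
                       unconstrained = character(0), ped = NULL) {
  obligate_carriers <- unique(as.character(obligate_carriers))
  obligate_noncarriers <- unique(as.character(obligate_noncarriers))
  unconstrained <- unique(as.character(unconstrained))
  if (!length(obligate_carriers)) stop("obligate_carriers must be non-empty")
  all3 <- c(obligate_carriers, obligate_noncarriers, unconstrained)
  if (anyDuplicated(all3))
    stop("scheme sets are not pairwise disjoint: ",
         paste(unique(all3[duplicated(all3)]), collapse = ", "))
  if (!is.null(ped)) {
    g <- genotyped_ids(ped)
    if (!setequal(all3, g))
      stop("scheme sets must partition the genotyped individuals of family ",
           ped$family_code)
  }
  structure(list(scheme_id = as.character(scheme_id),
                 obligate_carriers = obligate_carriers,
                 obligate_noncarriers = obligate_noncarriers,
                 unconstrained = unconstrained),
            class = "seg_scheme")
}

#' Default segregation scheme of a family
#'
#' The default acceptance rule: every genotyped affected individual must carry
#' at least one alternative allele, every genotyped healthy individual must
#' carry none; genotyped individuals of unknown phenotype are unconstrained.
#'
#' @param ped a [pedigree()].
#' @param collapse a [phenotype_collapse()] giving the labels counted as
#'   affected (default GTS and TD).
#' @return a [seg_scheme()] with id `"<family>_default"`.
#' @export
default_scheme <- function(ped, collapse = phenotype_collapse()) {
  stopifnot(inherits(ped, "pedigree"), inherits(collapse, "phenotype_collapse"))
  ind <- ped$individuals[ped$individuals$genotyped, ]
  aff <- ind$id[ind$phenotype %in% collapse$affected_labels]
  if (!length(aff))
    stop("scheme undefinable: family ", ped$family_code,
         " has no genotyped affected individual")
  non <- ind$id[ind$phenotype == "HEALTHY" &
                  !ind$phenotype %in% collapse$affected_labels]
  unc <- setdiff(ind$id, c(aff, non))
  seg_scheme(sprintf("%s_default", ped$family_code),
             obligate_carriers = aff, obligate_noncarriers = non,
             unconstrained = unc, ped = ped)
}

# ---- PED dialect I/O --------------------------------------------------------

#' Read pedigrees from a PED file
#'
#' Seven tab-separated columns: family, id, father (0 = missing), mother,
#' sex (1 male / 2 female / 0 unknown), phenotype (1 HEALTHY / 2 GTS / 3 TD /
#' 0 UNKNOWN), genotyped (0/1). Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return named list of [pedigree()] objects, one per family code.
#' @export
read_ped <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("PED file must have 7 columns: ", path)
  names(df)[1:7] <- c("family", "id", "father", "mother", "sex", "phen", "geno")
  sex_map <- c("1" = "male", "2" = "female", "0" = "unknown")
  phen_map <- c("1" = "HEALTHY", "2" = "GTS", "3" = "TD", "0" = "UNKNOWN")
  out <- lapply(split(df, df$family), function(d) {
    pedigree(d$family[1], data.frame(
      id = d$id,
      father_id = ifelse(d$father == "0", NA_character_, d$father),
      mother_id = ifelse(d$mother == "0", NA_character_, d$mother),
      sex = unname(sex_map[d$sex]),
      phenotype = unname(phen_map[d$phen]),
      genotyped = d$geno == "1",
      stringsAsFactors = FALSE))
  })
  out[order(names(out))]
}

#' Write pedigrees to a PED file
#' @param peds named list of [pedigree()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  sex_map <- c(male = "1", female = "2", unknown = "0")
  phen_map <- c(HEALTHY = "1", GTS = "2", TD = "3", UNKNOWN = "0")
  rows <- lapply(peds, function(p) {
    d <- p$individuals
    data.frame(family = p$family_code, id = d$id,
               father = ifelse(is.na(d$father_id), "0", d$father_id),
               mother = ifelse(is.na(d$mother_id), "0", d$mother_id),
               sex = unname(sex_map[d$sex]),
               phen = unname(phen_map[d$phenotype]),
               geno = ifelse(d$genotyped, "1", "0"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# family\tid\tfather\tmother\tsex\tphenotype\tgenotyped", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-family segregation schemes from a JSON file
#'
#' The file maps family codes to a list of scheme entries, each with
#' `scheme_id`, `obligate_carriers`, `obligate_noncarriers`, `unconstrained`.
#' Families absent from the file fall back to [default_scheme()] at run time.
#'
#' @param path JSON file.
#' @return named list (by family code) of lists of [seg_scheme()] objects.
#' @export
read_schemes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(entries) {
    lapply(entries, function(e) {
      seg_scheme(e$scheme_id,
                 obligate_carriers = unlist(e$obligate_carriers),
                 obligate_noncarriers = unlist(e$obligate_noncarriers %||% list()),
                 unconstrained = unlist(e$unconstrained %||% list()))
    })
  })
}

#' Write per-family segregation schemes to a JSON file
#' @param schemes named list (by family) of lists of [seg_scheme()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schemes <- function(schemes, path) {
  obj <- lapply(schemes, function(lst) {
    lapply(lst, function(s) list(
      scheme_id = s$scheme_id,
      obligate_carriers = as.list(s$obligate_carriers),
      obligate_noncarriers = as.list(s$obligate_noncarriers),
      unconstrained = as.list(s$unconstrained)))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
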