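#' Fraction of variants that are exonic
#'
#' "Exonic" counts coding-exon and UTR overlaps (`EXONIC_CODING`, `UTR5`,
#' `UTR3`); intronic and intergenic variants are not exonic. The study-wide
#' fraction is the P(exvar) factor of the single-family statistic.
#'
#' @param contexts character vector of context labels, or a list of
#'   `genomic_context` objects from [classify_context()].
#' @return object of class `exonic_fraction`: list with `p_exvar`,
#'   `n_exonic`, `n_total`.
#' @export
estimate_p_exvar <- function(contexts) {
  if (is.list(contexts))
    contexts <- vapply(contexts, function(x)
      if (is.list(x)) x$context else as.character(x), character(1))
  if (!length(contexts)) stop("empty context list")
  bad <- setdiff(unique(contexts),
                 c("EXONIC_CODING", "UTR5", "UTR3", "INTRONIC", "INTERGENIC"))
  if (length(bad)) stop("unknown context labels: ", paste(bad, collapse = ", "))
  n_ex <- sum(contexts %in% c("EXONIC_CODING", "UTR5", "UTR3"))
  structure(list(p_exvar = n_ex / length(contexts),
                 n_exonic = n_ex, n_total = length(contexts)),
            class = "exonic_fraction")
}

#' Bonferroni factor over family combinations
#'
#' The multi-family statistic is corrected for the number of ways `k` of the
#' `F` study families could have shown the recurrence: the binomial
#' coefficient C(F, k).
#'
#' @param n_families_total total number of families F.
#' @param n_families_hit number of families k sharing the variant (1 <= k <= F).
#' @return integer C(F, k).
#' @export
bonferroni_factor <- function(n_families_total, n_families_hit) {
  F <- n_families_total; k <- n_families_hit
  stopifnot(length(F) == 1L, length(k) == 1L, F >= 1, k >= 1)
  if (k > F) stop("n_families_hit (", k, ") exceeds n_families_total (", F, ")")
  as.integer(round(choose(F, k)))
}

new_obs_probability <- function(p_obs, p_segs, p_exvar = NA_real_,
                                p_var = NA_real_, p_anyvar = 1,
                                bonferroni = 1L, n_families_total = 1L,
                                n_families_hit = 1L) {
  structure(list(p_obs = p_obs, p_segs = p_segs, p_exvar = p_exvar,
                 p_var = p_var, p_anyvar = p_anyvar,
                 bonferroni = as.integer(bonferroni),
                 n_families_total = as.integer(n_families_total),
                 n_families_hit = as.integer(n_families_hit)),
            class = "obs_probability")
}

#' @export
print.obs_probability <- function(x, ...) {
  cat(sprintf("<obs_probability> P(obs) = %s (%d famil%s)\n",
              ifelse(is.na(x$p_obs), "NA", format(x$p_obs, digits = 6)),
              x$n_families_hit, ifelse(x$n_families_hit == 1, "y", "ies")))
  invisible(x)
}

#' Single-family exonic P(obs)
#'
#' Probability of observing an exonic variant co-segregating in one given
#' family under the null: `p_obs = p_seg * p_exvar`.
#'
#' @param p_seg the family's null co-segregation probability, in `[0, 1]`
#'   (a number or a `seg_probability`).
#' @param p_exvar study-wide exonic fraction, in `[0, 1]` (a number or an
#'   `exonic_fraction`).
#' @return an `obs_probability`.
#' @export
p_obs_single <- function(p_seg, p_exvar) {
  ps <- if (inherits(p_seg, "seg_probability")) p_seg$p_seg else p_seg
  pe <- if (inherits(p_exvar, "exonic_fraction")) p_exvar$p_exvar else p_exvar
  stopifnot(length(ps) == 1L, ps >= 0, ps <= 1, length(pe) == 1L, pe >= 0, pe <= 1)
  new_obs_probability(ps * pe, p_segs = ps, p_exvar = pe)
}

#' Multi-family P(obs) with Bonferroni correction
#'
#' Probability of observing the same variant co-segregating in `k >= 2` of
#' the `F` study families under the null:
#' `p_obs = prod(p_segs) * p_anyvar * maf^(k-1) * C(F, k)`,
#' where `maf` is the control-cohort carrier fraction of the variant (the
#' chance of the variant being present and available to a further family)
#' and `p_anyvar` defaults to 1.
#'
#' When `maf = 0` the statistic is undefined under this null (the variant was
#' never seen in controls, so its recurrence probability has no frequency
#' estimate); the default policy reports `NA`. A substitute frequency can be
#' supplied via `zero_maf_pvar`.
#'
#' @param p_segs numeric vector of k >= 2 per-family co-segregation
#'   probabilities, each in (0, 1] (or a list of `seg_probability`).
#' @param maf control carrier fraction in `[0, 1)`.
#' @param n_families_total total number of study families F (>= k).
#' @param p_anyvar leading probability factor, default 1.
#' @param zero_maf_pvar replacement for `maf` when `maf == 0`; default `NA`
#'   (report `NA`).
#' @return an `obs_probability`.
#' @export
p_obs_multi <- function(p_segs, maf, n_families_total, p_anyvar = 1,
                        zero_maf_pvar = NA_real_) {
  if (is.list(p_segs))
    p_segs <- vapply(p_segs, function(x)
      if (inherits(x, "seg_probability")) x$p_seg else as.numeric(x), numeric(1))
  k <- length(p_segs)
  if (k < 2L) stop("p_obs_multi needs k >= 2 families; use p_obs_single()")
  stopifnot(all(p_segs > 0), all(p_segs <= 1), maf >= 0, maf < 1,
            k <= n_families_total)
  bf <- bonferroni_factor(n_families_total, k)
  pv <- if (maf == 0) zero_maf_pvar else maf
  p_obs <- if (is.na(pv)) NA_real_ else prod(p_segs) * p_anyvar * pv^(k - 1) * bf
  new_obs_probability(p_obs, p_segs = p_segs, p_var = pv, p_anyvar = p_anyvar,
                      bonferroni = bf, n_families_total = n_families_total,
                      n_families_hit = k)
}

#' Round a probability for reporting
#'
#' Half-away-from-zero rounding to `digits` decimal places; values that are
#' non-zero but below one unit at that precision are instead rounded to one
#' significant digit, matching the mixed precision conventional in published
#' co-segregation tables (e.g. 0.00485 -> 0.0049, 3.6e-5 -> 4e-5).
#'
#' @param x numeric vector of probabilities (NA passed through).
#' @param digits decimal places, default 4.
#' @return numeric vector.
#' @export
round_pobs <- function(x, digits = 4L) {
  half_away <- function(v, d) sign(v) * floor(abs(v) * 10^d + 0.5) / 10^d
  out <- half_away(x, digits)
  small <- !is.na(x) & x != 0 & abs(x) < 10^(-digits)
  if (any(small)) {
    d1 <- -floor(log10(abs(x[small])))  # one significant digit
    out[small] <- half_away(x[small], d1)
  }
  out
}
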