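#' Number of meioses in a pedigree
#'
#' Each non-founder receives one allele from each parent, so the pedigree has
#' two meioses per non-founder. Exhaustive enumeration of transmission
#' outcomes scales as 2^meioses.
#'
#' @param ped a [pedigree()].
#' @return integer.
#' @export
count_meioses <- function(ped) {
  2L * sum(!(ped$individuals$id %in% founders(ped)))
}

# Shared setup for the gene-dropping engines: index parents and scheme sets.
gd_setup <- function(ped, scheme) {
  viol <- validate_pedigree(ped)
  if (length(viol)) stop("invalid pedigree: ", paste(viol, collapse = "; "))
  ind <- ped$individuals
  ord <- topo_order(ped)
  ids <- ind$id
  miss <- setdiff(c(scheme$obligate_carriers, scheme$obligate_noncarriers,
                    scheme$unconstrained), ids)
  if (length(miss))
    stop("scheme names individuals not in family ", ped$family_code, ": ",
         paste(miss, collapse = ", "))
  list(ind = ind,
       ord = ord,
       nonfounders = ord[!(ids[ord] %in% founders(ped))],
       fa = match(ind$father_id, ids),
       mo = match(ind$mother_id, ids),
       carriers = match(scheme$obligate_carriers, ids),
       noncarriers = match(scheme$obligate_noncarriers, ids),
       founder_idx = match(founders(ped), ids))
}

#' Exact null co-segregation probability by enumeration
#'
#' Under the null model the variant enters the family through a single
#' heterozygous founder and every parent-to-child transmission passes the
#' allele independently with probability 1/2 (autosomal Mendelian gene
#' dropping). For each candidate origin founder the probability that the
#' resulting carrier set contains all obligate carriers and excludes all
#' obligate non-carriers is computed exactly; the reported P(seg) is the
#' maximum over founders (most favorable unknown origin), with the arg-max
#' founder recorded. Unconstrained individuals are ignored.
#'
#' @param ped a [pedigree()].
#' @param scheme a [seg_scheme()].
#' @param max_meioses enumeration cap; pedigrees with more than this many
#'   meioses (default 22, about 4M outcomes) must use [p_seg_montecarlo()].
#' @return object of class `seg_probability`: list with `family_code`,
#'   `scheme_id`, `p_seg`, `origin_founder`, `method = "enumeration"`,
#'   `per_founder` (named vector), `mc_stderr = NA`.
#' @export
p_seg_enumerate <- function(ped, scheme, max_meioses = 22L) {
  m <- count_meioses(ped)
  if (m > max_meioses)
    stop(sprintf(
      "pedigree %s has %d meioses (> cap %d); use p_seg_montecarlo()",
      ped$family_code, m, max_meioses))
  s <- gd_setup(ped, scheme)
  per_founder <- vapply(s$founder_idx, function(f)
    gd_enum_origin(s, f), numeric(1))
  names(per_founder) <- s$ind$id[s$founder_idx]
  finish_seg_prob(ped, scheme, per_founder, "enumeration", NA_real_)
}

# Exact probability for one origin founder: depth-first over the allele
# counts of non-founders in topological order, branching only on meioses
# from carrier parents, pruning as soon as an obligate constraint is
# decided and violated (an individual's count is final once assigned).
gd_enum_origin <- function(s, origin) {
  n <- nrow(s$ind)
  cnt0 <- integer(n)
  cnt0[origin] <- 1L
  is_car <- logical(n); is_car[s$carriers] <- TRUE
  is_non <- logical(n); is_non[s$noncarriers] <- TRUE
  # founders other than origin are non-carriers by conditioning; check
  # constraints on founders directly
  for (i in seq_len(n)) {
    if (i %in% s$nonfounders) next
    if (is_car[i] && cnt0[i] == 0L) return(0)
    if (is_non[i] && cnt0[i] > 0L) return(0)
  }
  nf <- s$nonfounders
  rec <- function(k, cnt) {
    if (k > length(nf)) return(1)
    i <- nf[k]
    tot <- 0
    for (pat in transmit_opts(cnt[s$fa[i]])) {
      for (mat in transmit_opts(cnt[s$mo[i]])) {
        ci <- pat[1] + mat[1]
        p <- pat[2] * mat[2]
        if (is_car[i] && ci == 0L) next
        if (is_non[i] && ci > 0L) next
        cnt[i] <- ci
        tot <- tot + p * rec(k + 1L, cnt)
      }
    }
    tot
  }
  rec(1L, cnt0)
}

# Possible (allele, probability) contributions from a parent with a given
# alt-allele count.
transmit_opts <- function(parent_cnt) {
  if (parent_cnt == 0L) list(c(0, 1))
  else if (parent_cnt == 1L) list(c(0, 0.5), c(1, 0.5))
  else list(c(1, 1))
}

finish_seg_prob <- function(ped, scheme, per_founder, method, stderr_best) {
  best <- which.max(per_founder)
  p <- unname(per_founder[best])
  if (p == 0)
    warning(sprintf(
      "family %s scheme %s: obligate carriers not reachable from any single founder; p_seg = 0",
      ped$family_code, scheme$scheme_id))
  structure(list(family_code = ped$family_code,
                 scheme_id = scheme$scheme_id,
                 p_seg = p,
                 origin_founder = names(per_founder)[best],
                 method = method,
                 mc_stderr = if (method == "monte_carlo") stderr_best else NA_real_,
                 per_founder = per_founder),
            class = "seg_probability")
}

#' @export
print.seg_probability <- function(x, ...) {
  cat(sprintf("<seg_probability> family %s scheme %s: P(seg) = %.6g (%s, origin %s)\n",
              x$family_code, x$scheme_id, x$p_seg, x$method, x$origin_founder))
  invisible(x)
}

#' Monte Carlo null co-segregation probability
#'
#' Unbiased estimate of the [p_seg_enumerate()] quantity by simulated gene
#' dropping, for pedigrees above the enumeration cap. For each candidate
#' origin founder, `n_draws` transmission outcomes are simulated and the
#' fraction matching the scheme recorded; the estimate is the maximum over
#' founders with its binomial standard error.
#'
#' @inheritParams p_seg_enumerate
#' @param n_draws number of simulated outcomes per founder (>= 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return a `seg_probability` with `method = "monte_carlo"` and `mc_stderr`.
#' @export
p_seg_montecarlo <- function(ped, scheme, n_draws = 100000L, seed = 1L) {
  if (n_draws < 1000L) stop("n_draws must be >= 1000")
  s <- gd_setup(ped, scheme)
  n <- nrow(s$ind)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  per_founder <- numeric(length(s$founder_idx))
  names(per_founder) <- s$ind$id[s$founder_idx]
  for (j in seq_along(s$founder_idx)) {
    f <- s$founder_idx[j]
    cnt <- matrix(0L, nrow = n_draws, ncol = n)
    cnt[, f] <- 1L
    for (i in s$nonfounders) {
      cf <- cnt[, s$fa[i]]
      cm <- cnt[, s$mo[i]]
      pat <- (cf == 2L) + (cf == 1L) * rbinom(n_draws, 1L, 0.5)
      mat <- (cm == 2L) + (cm == 1L) * rbinom(n_draws, 1L, 0.5)
      cnt[, i] <- pat + mat
    }
    ok <- rep(TRUE, n_draws)
    for (i in s$carriers) ok <- ok & cnt[, i] > 0L
    for (i in s$noncarriers) ok <- ok & cnt[, i] == 0L
    per_founder[j] <- mean(ok)
  }
  p <- max(per_founder)
  se <- sqrt(p * (1 - p) / n_draws)
  finish_seg_prob(ped, scheme, per_founder, "monte_carlo", se)
}

#' Null co-segregation probability, enumeration with Monte Carlo fallback
#'
#' Convenience wrapper used by the pipeline: exact enumeration when the
#' pedigree is at or below `max_meioses`, otherwise Monte Carlo.
#'
#' @inheritParams p_seg_montecarlo
#' @return a `seg_probability`.
#' @export
p_seg <- function(ped, scheme, max_meioses = 22L, n_draws = 100000L, seed = 1L) {
  if (count_meioses(ped) <= max_meioses) p_seg_enumerate(ped, scheme, max_meioses)
  else p_seg_montecarlo(ped, scheme, n_draws = n_draws, seed = seed)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
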