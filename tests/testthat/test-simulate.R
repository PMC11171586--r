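cfg_small <- sim_config(n_families = 3, n_controls = 12, svs_per_genome = 40,
                        n_injected = 2)

test_that("gen_pedigree is deterministic and respects genome bounds", {
  p1 <- gen_pedigree(cfg_small, "A", seed = 5)
  p2 <- gen_pedigree(cfg_small, "A", seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, gen_pedigree(cfg_small, "A", seed = 6)))
  for (seed in 1:15) {
    ped <- gen_pedigree(sim_config(), "Q", seed = seed)
    expect_length(validate_pedigree(ped), 0)
    g <- sum(ped$individuals$genotyped)
    expect_gte(g, 4L); expect_lte(g, 14L)
    aff <- sum(ped$individuals$phenotype %in% c("GTS", "TD") &
                 ped$individuals$genotyped)
    expect_gte(aff, 2L)  # multiplex by construction
    # generated phenotypes always admit a satisfiable default scheme
    # (constraint pruning keeps exact enumeration fast above the default cap)
    sp <- p_seg_enumerate(ped, default_scheme(ped), max_meioses = 40)
    expect_gt(sp$p_seg, 0)
  }
})

test_that("exact genome-count range is honored", {
  cfg4 <- sim_config(genomes_per_family = c(4L, 4L))
  for (seed in 1:5)
    expect_equal(sum(gen_pedigree(cfg4, "A", seed)$individuals$genotyped), 4L)
})

test_that("17 families at defaults total near the 124 genomes of the design", {
  totals <- vapply(1:20, function(seed) {
    sim <- lapply(1:17, function(i)
      gen_pedigree(sim_config(), LETTERS[i], seed * 100 + i))
    sum(vapply(sim, function(p) sum(p$individuals$genotyped), 1L))
  }, numeric(1))
  expect_true(all(totals >= 17 * 4 & totals <= 17 * 14))
  # family sizes are drawn from the published empirical sizes (mean 7.3),
  # so cohort totals concentrate around 124
  expect_gt(mean(totals), 105)
  expect_lt(mean(totals), 145)
})

test_that("drop_background obeys Mendelian and Hardy-Weinberg limits", {
  ped <- couple_ped(c("GTS", "TD", "HEALTHY", "HEALTHY"))
  g0 <- drop_background(ped, rep(0, 20), seed = 1)
  expect_true(all(g0 == 0L))
  g1 <- drop_background(ped, rep(1, 20), seed = 1)
  expect_true(all(g1 == 2L))
  # founder carrier rate at f = 0.2 within the binomial 99% CI of 1 - 0.8^2
  L <- 10000
  g <- drop_background(ped, rep(0.2, L), seed = 7)
  rate <- mean(g["F1", ] > 0)
  p <- 1 - 0.8^2
  ci <- p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / L)
  expect_gt(rate, ci[1]); expect_lt(rate, ci[2])
  # children inherit only from parents: a child allele count never exceeds
  # the number of carrier parents
  bound <- (g["F1", ] > 0) + (g["F2", ] > 0)
  for (kid in c("C1", "C2", "C3", "C4"))
    expect_true(all(g[kid, ] <= bound))
})

test_that("inject_coseg satisfies the scheme by construction", {
  ped <- gen_pedigree(cfg_small, "A", seed = 3)
  sch <- default_scheme(ped)
  tpl <- list(chrom = "chr1", pos = 100L, end = 500L, svtype = "DEL",
              svlen = -400L)
  inj <- inject_coseg(ped, sch, tpl)
  carriers <- names(inj$genotypes)[inj$genotypes > 0]
  expect_true(evaluate_scheme(carriers, sch))
  expect_setequal(carriers, sch$obligate_carriers)
  expect_true(all(inj$genotypes[carriers] == 1L))  # heterozygous carriers
  expect_equal(inj$truth$expected_tier, "ABSENT")

  # unsatisfiable scheme rejected
  bad <- pedigree("U", data.frame(
    id = c("F1", "F2", "C1"), father_id = c(NA, NA, "F1"),
    mother_id = c(NA, NA, "F2"), sex = c("male", "female", "male"),
    phenotype = c("HEALTHY", "HEALTHY", "GTS"), genotyped = TRUE))
  expect_error(suppressWarnings(inject_coseg(bad, default_scheme(bad), tpl)),
               "unsatisfiable")
})

test_that("simulated cohorts carry coherent truth and calibrated scale", {
  sim <- simulate_cohort(cfg_small, seed = 11)
  expect_equal(length(sim$pedigrees), 3L)
  expect_equal(nrow(sim$truth), 2L)
  expect_equal(length(sim$control_ids), 12L)
  # injected variants are absent from every control
  n_inj <- nrow(sim$truth)
  inj_cols <- seq(nrow(sim$panel) - n_inj + 1, nrow(sim$panel))
  expect_true(all(sim$control_gt[, inj_cols] == 0L))
  # per-genome background call count is near the configured expectation
  recs <- cohort_records(sim)
  per_genome <- table(recs$sample_id)
  expect_gt(mean(per_genome), cfg_small$svs_per_genome * 0.6)
  expect_lt(mean(per_genome), cfg_small$svs_per_genome * 1.6)
})

test_that("generated type mix matches the configured proportions", {
  # chi-square goodness of fit over 10 seeds at family-wise alpha = 0.01
  # (Bonferroni over the 10 seeds, since the draws are independent)
  pvals <- vapply(1:10, function(seed) {
    sim <- simulate_cohort(sim_config(n_families = 2, n_controls = 5,
                                      svs_per_genome = 150, n_injected = 0),
                           seed = seed)
    obs <- table(factor(sim$panel$svtype, levels = names(sim$config$type_mix)))
    suppressWarnings(chisq.test(obs, p = sim$config$type_mix)$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 0.01 / 10)
  expect_gt(mean(pvals > 0.01), 0.8)
})

test_that("write_cohort is byte-deterministic and round-trips records", {
  cfg0 <- sim_config(n_families = 2, n_controls = 8, svs_per_genome = 30,
                     n_injected = 1, jitter_bp = 0L)
  sim <- simulate_cohort(cfg0, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(sim, d1, jitter_seed = 4)
  p2 <- write_cohort(sim, d2, jitter_seed = 4)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
  # reading every VCF back reproduces the in-memory record multiset
  back <- do.call(rbind, lapply(c(p1$family_vcfs, p1$control_vcf), read_sv_vcf))
  mem <- cohort_records(sim)
  key <- function(d) sort(sprintf("%s|%s|%d|%d|%s|%d|%s", d$sample_id, d$chrom,
                                  d$pos, d$end, d$svtype, d$svlen, d$genotype))
  expect_identical(key(back), key(mem))
  # PED and schemes load back into valid objects
  peds <- read_ped(p1$ped)
  expect_named(peds, names(sim$pedigrees))
  expect_length(unlist(lapply(peds, validate_pedigree)), 0)
  sch <- read_schemes(p1$schemes)
  expect_equal(sch$A[[1]]$obligate_carriers,
               sim$schemes$A[[1]]$obligate_carriers)
})

test_that("the synthetic GFF3 places injected variants in their contexts", {
  sim <- simulate_cohort(sim_config(n_families = 5, n_controls = 5,
                                    svs_per_genome = 20, n_injected = 5),
                         seed = 2)
  d <- withr::local_tempdir()
  paths <- write_cohort(sim, d)
  models <- load_gene_models(paths$gff)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    ctx <- classify_context(list(chrom = tr$chrom[i], pos = tr$pos[i],
                                 end = tr$end[i], svtype = tr$svtype[i]),
                            models)
    expect_equal(ctx$context, tr$expected_context[i],
                 info = sprintf("injected variant %d", i))
  }
})
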