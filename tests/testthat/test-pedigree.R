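test_that("single-parent records are completed with a synthetic founder spouse", {
  ped <- pedigree("A", data.frame(
    id = c("M", "K"), father_id = c(NA, NA), mother_id = c(NA, "M"),
    sex = c("female", "male"), phenotype = c("HEALTHY", "GTS"),
    genotyped = c(TRUE, TRUE)))
  ind <- ped$individuals
  expect_equal(nrow(ind), 3L)
  spouse <- ind[ind$id == "K_father", ]
  expect_equal(spouse$sex, "male")
  expect_equal(spouse$phenotype, "UNKNOWN")
  expect_false(spouse$genotyped)
  expect_equal(ind$father_id[ind$id == "K"], "K_father")
  expect_length(validate_pedigree(ped), 0)
})

test_that("validate_pedigree reports violations instead of throwing", {
  trio <- pedigree("A", data.frame(
    id = c("F", "M", "K"), father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"), sex = c("male", "female", "male"),
    phenotype = c("HEALTHY", "HEALTHY", "GTS"), genotyped = TRUE))
  expect_identical(validate_pedigree(trio), character(0))

  # unresolved father id
  bad <- trio
  bad$individuals$father_id[3] <- "GHOST"
  v <- validate_pedigree(bad)
  expect_length(v, 1)
  expect_match(v, "GHOST")

  # cycle: an individual its own ancestor
  cyc <- pedigree("A", data.frame(
    id = c("X", "Y", "F0"), father_id = c("Y", "X", NA),
    mother_id = c("F0", "F0", NA), sex = "male",
    phenotype = "UNKNOWN", genotyped = FALSE))
  expect_match(paste(validate_pedigree(cyc), collapse = " "), "cycle")

  dup <- pedigree("A", data.frame(
    id = c("F", "F"), father_id = NA, mother_id = NA, sex = "male",
    phenotype = "UNKNOWN", genotyped = FALSE))
  expect_match(paste(validate_pedigree(dup), collapse = " "), "duplicated")
})

test_that("default_scheme follows the acceptance rule", {
  ped <- couple_ped(c("GTS", "GTS", "TD", "HEALTHY", "HEALTHY"))
  sch <- default_scheme(ped)
  expect_setequal(sch$obligate_carriers, c("C1", "C2", "C3"))
  expect_setequal(sch$obligate_noncarriers, c("C4", "C5"))
  expect_length(sch$unconstrained, 0)

  # degenerate: one genotyped GTS only
  one <- couple_ped("GTS")
  sch1 <- default_scheme(one)
  expect_equal(sch1$obligate_carriers, "C1")
  expect_length(sch1$obligate_noncarriers, 0)

  # unknown phenotype maps to unconstrained
  unk <- couple_ped(c("GTS", "GTS", "GTS", "UNKNOWN"))
  expect_equal(default_scheme(unk)$unconstrained, "C4")

  # collapse configurability: only GTS counted as affected
  sch_gts <- default_scheme(ped, phenotype_collapse("GTS"))
  expect_setequal(sch_gts$obligate_carriers, c("C1", "C2"))
  expect_true("C3" %in% sch_gts$unconstrained)

  healthy_only <- couple_ped(c("HEALTHY", "HEALTHY"))
  expect_error(default_scheme(healthy_only), "scheme undefinable")
})

test_that("default_scheme is deterministic and partitions the genotyped set", {
  cfg <- sim_config(n_families = 1)
  for (seed in 1:10) {
    ped <- gen_pedigree(cfg, "Q", seed = seed)
    s1 <- default_scheme(ped)
    s2 <- default_scheme(ped)
    expect_identical(s1, s2)
    all3 <- c(s1$obligate_carriers, s1$obligate_noncarriers, s1$unconstrained)
    expect_setequal(all3, genotyped_ids(ped))
    expect_equal(anyDuplicated(all3), 0L)
  }
})

test_that("seg_scheme enforces disjointness and pedigree partition", {
  expect_error(seg_scheme("s", character(0)), "non-empty")
  expect_error(seg_scheme("s", "A", obligate_noncarriers = "A"), "disjoint")
  ped <- couple_ped(c("GTS", "HEALTHY"))
  expect_error(
    seg_scheme("s", "C1", ped = ped),  # C2 unaccounted for
    "partition")
})

test_that("PED and schemes files round-trip", {
  peds <- list(A = couple_ped(c("GTS", "TD", "HEALTHY"), "A"),
               B = chain_ped(3, "B"))
  pf <- withr::local_tempfile(fileext = ".ped")
  write_ped(peds, pf)
  back <- read_ped(pf)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$individuals, peds$A$individuals)
  expect_equal(back$B$individuals, peds$B$individuals)

  schemes <- list(A = list(default_scheme(peds$A)),
                  B = list(default_scheme(peds$B),
                           seg_scheme("B_alt", "K1", "K2", "K3")))
  sf <- withr::local_tempfile(fileext = ".json")
  write_schemes(schemes, sf)
  back_s <- read_schemes(sf)
  expect_equal(back_s$A[[1]]$obligate_carriers,
               schemes$A[[1]]$obligate_carriers)
  expect_equal(back_s$B[[2]]$scheme_id, "B_alt")
  expect_equal(back_s$B[[2]]$unconstrained, "K3")
})
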