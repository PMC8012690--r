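test_that("built-in NAT2 definition set has three signature variants plus implicit *4", {
  defs <- load_allele_definitions("NAT2")
  expect_s3_class(defs, "nat2_definitions")
  expect_equal(nrow(defs$variants), 3)
  expect_setequal(defs$variants$allele, c("*5", "*6", "*7"))
  expect_setequal(defs$variants$rsid, c("rs1801280", "rs1799930", "rs1799931"))
  expect_equal(defs$alleles, c("*4", "*5", "*6", "*7"))
  expect_equal(defs$reference_allele, "*4")
})

test_that("definition loading rejects malformed tables and accepts extra alleles", {
  expect_error(load_allele_definitions(
    data.frame(rsid = character(), ref = character(), alt = character(),
               allele = character())), "no signature variants")
  base <- nat2kit:::nat2_signature_variants()
  dup_rs <- rbind(base, base[1, ])
  expect_error(load_allele_definitions(dup_rs), "duplicate rsid")
  two_per_allele <- base
  two_per_allele$allele[2] <- "*5"
  expect_error(load_allele_definitions(two_per_allele), "one named allele")
  # *14 (rs1801279) loads fine; its exclusion happens at the scoring stage
  with14 <- rbind(base, data.frame(rsid = "rs1801279", cdna_change = "c.191G>A",
                                   ref = "G", alt = "A", allele = "*14"))
  defs14 <- load_allele_definitions(with14)
  expect_true("*14" %in% defs14$alleles)
  expect_equal(defs14$alleles[1], "*4")
})

test_that("canonical diplotype labels sort alleles numerically", {
  expect_equal(canonical_diplotype("*6", "*4"), "*4/*6")
  expect_equal(canonical_diplotype("*4", "*6"), "*4/*6")
  expect_equal(canonical_diplotype("*14", "*5"), "*5/*14")
  expect_equal(canonical_diplotype(c("*7", "*5"), c("*4", "*5")),
               c("*4/*7", "*5/*5"))
})

test_that("EM puts all mass on the reference haplotype in a variant-free cohort", {
  defs <- load_allele_definitions("NAT2")
  calls <- data.frame(individual_id = paste0("s", 1:5),
                      rs1801280 = 0, rs1799930 = 0, rs1799931 = 0)
  hf <- em_haplotype_frequencies(calls, defs)
  expect_equal(unname(hf$frequencies["*4"]), 1.0, tolerance = 1e-9)
  expect_equal(sum(hf$frequencies), 1, tolerance = 1e-9)
})

test_that("EM equals direct gamete counting on unambiguous cohorts", {
  defs <- load_allele_definitions("NAT2")
  sites <- defs$variants$rsid
  # every individual het at <= 1 site: phase is forced, EM must agree with
  # simple counting
  calls <- data.frame(
    individual_id = paste0("s", 1:8),
    rs1801280 = c(0, 0, 2, 1, 0, 0, 0, 1),
    rs1799930 = c(0, 1, 0, 0, 2, 0, 0, 0),
    rs1799931 = c(0, 0, 0, 0, 0, 1, 2, 0))
  hf <- em_haplotype_frequencies(calls, defs)
  oracle <- counting_oracle(calls, sites)
  # map oracle bit-keys (site order = sites) onto EM labels
  key_to_label <- c("000" = "*4", "100" = "*5", "010" = "*6", "001" = "*7")
  for (key in names(oracle)) {
    expect_equal(unname(hf$frequencies[key_to_label[[key]]]),
                 unname(as.numeric(oracle[key])), tolerance = 1e-6,
                 label = paste("frequency of", key_to_label[[key]]))
  }
})

test_that("EM log-likelihood is monotone non-decreasing", {
  defs <- load_allele_definitions("NAT2")
  sim <- simulate_cohort_hwe(c("*4" = .55, "*5" = .05, "*6" = .25, "*7" = .15),
                             150, seed = 11, definitions = defs)
  hf <- em_haplotype_frequencies(sim$dosages, defs)
  expect_true(all(diff(hf$ll_trace) >= -1e-8))
  expect_gt(hf$iterations, 1)
})

test_that("EM recovers simulation truth within 3 standard errors", {
  defs <- load_allele_definitions("NAT2")
  truth <- c("*4" = .55, "*5" = .05, "*6" = .25, "*7" = .15)
  sim <- simulate_cohort_hwe(truth, 100, seed = 2023, definitions = defs)
  hf <- em_haplotype_frequencies(sim$dosages, defs)
  se <- sqrt(truth * (1 - truth) / 200)   # 2n gametes
  for (al in names(truth)) {
    expect_lt(abs(hf$frequencies[[al]] - truth[[al]]), 3 * se[[al]])
  }
})

test_that("EM drops all-missing sites and excludes incomplete individuals", {
  defs <- load_allele_definitions("NAT2")
  calls <- data.frame(individual_id = c("a", "b", "c"),
                      rs1801280 = c(0, 0, NA),
                      rs1799930 = c(1, 0, 0),
                      rs1799931 = NA_real_)
  expect_warning(expect_warning(
    hf <- em_haplotype_frequencies(calls, defs),
    "all genotypes missing"), "excluded from EM")
  expect_equal(hf$n_used, 2)
  expect_equal(hf$excluded_individuals, "c")
  expect_false("rs1799931" %in% hf$sites)
})

test_that("diplotype calls resolve forced phase and flag genuine ambiguity", {
  defs <- load_allele_definitions("NAT2")
  # a cohort rich enough that the EM assigns all mass to the four star
  # alleles (no compound support)
  cohort <- data.frame(
    individual_id = paste0("s", 1:10),
    rs1801280 = c(0, 0, 2, 0, 0, 0, 0, 1, 0, 0),
    rs1799930 = c(0, 1, 0, 0, 1, 2, 0, 0, 1, 0),
    rs1799931 = c(0, 0, 0, 1, 1, 0, 2, 0, 0, 0))
  hf <- em_haplotype_frequencies(cohort, defs)
  single_het <- data.frame(individual_id = "x", rs1801280 = 0,
                           rs1799930 = 1, rs1799931 = 0)
  d <- call_diplotypes(single_het, hf, defs)
  expect_equal(d$diplotype, "*4/*6")
  expect_false(d$ambiguous)
  expect_equal(d$posterior, 1)

  hom <- data.frame(individual_id = "y", rs1801280 = 2,
                    rs1799930 = 0, rs1799931 = 0)
  expect_equal(call_diplotypes(hom, hf, defs)$diplotype, "*5/*5")

  # double het: the compound 590+857 pattern has EM frequency 0, so the
  # *6/*7 configuration wins with posterior 1
  dh <- data.frame(individual_id = "z", rs1801280 = 0,
                   rs1799930 = 1, rs1799931 = 1)
  d2 <- call_diplotypes(dh, hf, defs)
  expect_equal(d2$diplotype, "*6/*7")
  expect_equal(d2$posterior, 1.0)
})

test_that("a selected compound haplotype is a hard error, not a silent rename", {
  defs <- load_allele_definitions("NAT2")
  # dosage 2 at two sites forces both haplotypes to carry both variants
  cohort <- data.frame(individual_id = c("a", "b"),
                       rs1801280 = c(2, 0), rs1799930 = c(2, 0),
                       rs1799931 = c(0, 0))
  hf <- em_haplotype_frequencies(cohort, defs)
  expect_error(call_diplotypes(cohort, hf, defs), "in cis")
})

test_that("calls with dosages at unknown rsids are rejected", {
  defs <- load_allele_definitions("NAT2")
  calls <- data.frame(individual_id = "a", rs1801280 = 0, rs1799930 = 0,
                      rs1799931 = 0, rs9999999 = 1)
  hf <- em_haplotype_frequencies(calls[, 1:4], defs)
  expect_error(call_diplotypes(calls, hf, defs), "unknown rsid")
})

test_that("allele frequencies come from gamete counting and sum to one", {
  expect_equal(estimate_allele_frequencies(c("*4/*4", "*4/*4"))[["*4"]], 1)
  f <- estimate_allele_frequencies("*5/*6")
  expect_equal(unname(f[c("*5", "*6")]), c(0.5, 0.5))
  # published Japanese cohort counts: freq(*4) = (2*480+23+260+125)/1980
  counts <- nat2_genotype_counts()
  jpn <- counts[counts$population == "JPN", ]
  f_jpn <- estimate_allele_frequencies(jpn)
  expect_equal(unname(f_jpn[["*4"]]), (2 * 480 + 23 + 260 + 125) / 1980,
               tolerance = 1e-12)
  expect_equal(unname(f_jpn[["*4"]]), 0.691, tolerance = 5e-4)
  expect_equal(sum(f_jpn), 1, tolerance = 1e-12)
})

test_that("simulated cohorts round-trip through the diplotype caller", {
  defs <- load_allele_definitions("NAT2")
  truth <- c("*4" = .55, "*5" = .05, "*6" = .25, "*7" = .15)
  sim <- simulate_cohort_hwe(truth, 200, seed = 31, definitions = defs)
  hf <- em_haplotype_frequencies(sim$dosages, defs)
  called <- call_diplotypes(sim$dosages, hf, defs)
  n_het <- rowSums(sim$dosages[, defs$variants$rsid] == 1)
  # phase-forced individuals must round-trip exactly
  expect_equal(called$diplotype[n_het <= 1], sim$diplotypes$diplotype[n_het <= 1])
  # double heterozygotes resolve to the star-allele pair because compound
  # haplotypes get (essentially) zero EM support in this cohort
  expect_true(all(called$diplotype == sim$diplotypes$diplotype))
})
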