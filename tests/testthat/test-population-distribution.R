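test_that("genotype frequencies are counts over cohort size", {
  counts <- nat2_genotype_counts()
  coh <- tabulate_genotype_frequencies(counts)
  g <- function(pop, geno) coh$frequency[coh$population == pop & coh$genotype == geno]
  expect_equal(round_half_up(g("JPN", "*4/*4"), 3), 0.485)
  expect_equal(g("EUR", "*7/*7"), 0)
  expect_equal(unique(coh$n[coh$population == "JPN"]), 990)
  # frequencies sum to 1 within each population
  sums <- tapply(coh$frequency, coh$population, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  one <- tabulate_genotype_frequencies(
    data.frame(population = "P", genotype = "*4/*6", count = 1))
  expect_equal(one$frequency, 1)
})

test_that("diplotype calls tabulate directly into a cohort", {
  d <- data.frame(individual_id = 1:3, diplotype = c("*4/*4", "*4/*4", "*4/*6"))
  class(d) <- c("nat2_diplotypes", "data.frame")
  coh <- tabulate_genotype_frequencies(d)
  expect_equal(coh$count[coh$genotype == "*4/*4"], 2)
  expect_equal(sum(coh$count), 3)
})

test_that("phenotype frequencies reproduce published SMZ ultra-slow percentages", {
  coh <- tabulate_genotype_frequencies(nat2_genotype_counts())
  asg <- cluster_phenotypes(reference_score_table())
  dist <- phenotype_frequencies(coh, asg)
  usa <- dist[dist$drug == "SMZ" & dist$phenotype == "USA", ]
  pct <- stats::setNames(usa$percent, usa$population)
  expect_equal(round_half_up(pct[["JPN"]], 2), 4.75)
  expect_equal(round_half_up(pct[["EAS"]], 2), 11.11)
  expect_equal(pct[["JPN"]], 100 * 47 / 990, tolerance = 1e-12)
  expect_equal(pct[["EAS"]], 100 * 56 / 504, tolerance = 1e-12)
  # conservation: per population x drug the phenotype frequencies sum to 1
  sums <- tapply(dist$frequency, list(dist$population, dist$drug), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("RA frequency equals the *4/*4 frequency when RA = {*4/*4}", {
  coh <- tabulate_genotype_frequencies(nat2_genotype_counts())
  asg <- cluster_phenotypes(reference_score_table())
  dist <- phenotype_frequencies(coh, asg)
  ra_sets <- tapply(asg$genotype[asg$phenotype == "RA"],
                    asg$drug[asg$phenotype == "RA"], identity)
  for (d in names(ra_sets)) {
    if (identical(unname(ra_sets[[d]]), "*4/*4")) {
      for (pop in unique(coh$population)) {
        expect_equal(
          dist$frequency[dist$population == pop & dist$drug == d &
                         dist$phenotype == "RA"],
          coh$frequency[coh$population == pop & coh$genotype == "*4/*4"],
          tolerance = 1e-12)
      }
    }
  }
})

test_that("unlabelled genotypes abort with the offending name", {
  coh <- tabulate_genotype_frequencies(
    data.frame(population = "P", genotype = c("*4/*4", "*4/*14"), count = c(1, 1)))
  asg <- cluster_phenotypes(reference_score_table())
  expect_error(phenotype_frequencies(coh, asg), "\\*4/\\*14")
})

test_that("range summaries reproduce published rapid-acetylator spans", {
  coh <- tabulate_genotype_frequencies(nat2_genotype_counts())
  asg <- cluster_phenotypes(reference_score_table())
  dist <- phenotype_frequencies(coh, asg)
  rr <- frequency_range_summary(dist, "RA")
  jpn <- rr[rr$population == "JPN", ]
  expect_equal(round_half_up(jpn$min_percent, 2), 48.48)
  expect_equal(round_half_up(jpn$max_percent, 2), 62.02)
  eur <- rr[rr$population == "EUR", ]
  expect_equal(round_half_up(c(eur$min_percent, eur$max_percent), 2),
               c(6.76, 7.95))
  one_drug <- frequency_range_summary(dist[dist$drug == "INH", ], "RA")
  expect_equal(one_drug$min_percent, one_drug$max_percent)
  expect_warning(out <- frequency_range_summary(dist, "XX"), "absent")
  expect_equal(nrow(out), 0)
})

test_that("simulated HWE cohorts reproduce expected phenotype frequencies", {
  counts <- nat2_genotype_counts()
  jpn_freq <- estimate_allele_frequencies(counts[counts$population == "JPN", ])
  sim <- simulate_cohort_hwe(jpn_freq, 5000, seed = 404)
  coh <- tabulate_genotype_frequencies(sim$diplotypes[, c("individual_id", "diplotype")] |>
    (\(d) { class(d) <- c("nat2_diplotypes", "data.frame"); d })())
  asg <- cluster_phenotypes(reference_score_table())
  dist <- phenotype_frequencies(coh, asg)
  # HWE closed form for the expected frequency of each phenotype class
  hwe_prob <- function(genos) {
    sum(vapply(genos, function(g) {
      al <- strsplit(g, "/", fixed = TRUE)[[1]]
      p <- jpn_freq[al[1]] * jpn_freq[al[2]]
      if (al[1] == al[2]) p else 2 * p
    }, numeric(1)))
  }
  for (d in c("SMZ", "INH")) {
    sub <- asg[asg$drug == d, ]
    for (ph in unique(sub$phenotype)) {
      expected <- hwe_prob(sub$genotype[sub$phenotype == ph])
      got_row <- dist[dist$drug == d & dist$phenotype == ph, ]
      got <- if (nrow(got_row)) got_row$frequency else 0
      ci99 <- 2.576 * sqrt(expected * (1 - expected) / 5000)
      expect_lt(abs(got - expected), max(ci99, 1e-3),
                label = paste(d, ph, "frequency"))
    }
  }
})
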