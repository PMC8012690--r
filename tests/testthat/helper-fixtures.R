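# Shared fixtures built in code.

# Reference score table coerced to the class build_score_table() emits, so
# clustering tests can run on the published (rounded) scores directly.
reference_score_table <- function() {
  as_score_table(nat2_reference_scores())
}

# Expand a (population, genotype, count) table into one diplotype row per
# individual — the counting oracle's input format.
expand_counts <- function(counts, population = NULL) {
  if (!is.null(population)) counts <- counts[counts$population == population, ]
  rep(counts$genotype, counts$count)
}

# Direct gamete-counting of haplotype frequencies for cohorts in which no
# individual is heterozygous at more than one site (phase is then forced).
# Independent of the EM implementation.
counting_oracle <- function(dosages, sites) {
  n <- nrow(dosages)
  pat <- matrix(0, nrow = 2 * n, ncol = length(sites),
                dimnames = list(NULL, sites))
  for (i in seq_len(n)) {
    g <- as.numeric(dosages[i, sites])
    stopifnot(sum(g == 1) <= 1)
    h1 <- as.numeric(g == 2); h2 <- h1
    h1 <- h1 + as.numeric(g == 1)        # put the single het on gamete 1
    pat[2 * i - 1, ] <- h1
    pat[2 * i, ] <- h2
  }
  key <- apply(pat, 1, paste, collapse = "")
  table(key) / (2 * n)
}

# Evaluate code under a fixed seed without disturbing global RNG state.
with_seed_local <- function(seed, code) nat2kit:::with_local_seed(seed, code)

# Truth table for kinetic simulations: published Km/Vmax per drug x allele.
kinetic_truth <- function() {
  kin <- nat2_reference_kinetics()
  kin[, c("drug", "allele", "km", "vmax")]
}
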