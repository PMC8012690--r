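# Synthetic inputs for every pipeline stage: diploid cohorts under
# Hardy-Weinberg equilibrium at given star-allele frequencies, with the
# implied signature-SNV dosage rows, and replicated Michaelis-Menten
# velocity data with multiplicative lognormal noise.

# Run code under a fixed seed without touching the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a diploid cohort under Hardy-Weinberg equilibrium
#'
#' Each individual draws two star alleles i.i.d. from the given frequency
#' vector; the true diplotype and the implied signature-variant dosages are
#' both returned, so the simulation doubles as a round-trip oracle for the
#' diplotype caller.
#'
#' @param allele_frequencies Named numeric vector (names = star alleles
#'   from the definition set, values summing to 1 within 1e-9).
#' @param n_individuals Number of individuals (>= 1).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param definitions A `nat2_definitions` object.
#' @return List with `diplotypes` (data frame `individual_id`, `diplotype`,
#'   `allele_a`, `allele_b`) and `dosages` (data frame `individual_id` plus
#'   one dosage column per signature rsID).
#' @examples
#' sim <- simulate_cohort_hwe(c("*4" = 0.7, "*6" = 0.3), 5, seed = 1)
#' sim$diplotypes
#' @export
simulate_cohort_hwe <- function(allele_frequencies, n_individuals, seed = NULL,
                                definitions = load_allele_definitions("NAT2")) {
  if (is.null(names(allele_frequencies)) || any(allele_frequencies < 0)) {
    stop("allele frequencies must be a named non-negative vector")
  }
  if (abs(sum(allele_frequencies) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1")
  }
  if (n_individuals < 1) stop("need at least one individual")
  unknown <- setdiff(names(allele_frequencies), definitions$alleles)
  if (length(unknown)) {
    stop("allele(s) not in the definition set: ", paste(unknown, collapse = ", "))
  }
  alleles <- names(allele_frequencies)
  draws <- with_local_seed(seed, {
    matrix(sample(alleles, 2 * n_individuals, replace = TRUE,
                  prob = allele_frequencies), ncol = 2)
  })
  ids <- sprintf("sim%05d", seq_len(n_individuals))
  diplotypes <- data.frame(
    individual_id = ids,
    diplotype = canonical_diplotype(draws[, 1], draws[, 2]),
    stringsAsFactors = FALSE
  )
  parts <- split_diplotype(diplotypes$diplotype)
  diplotypes$allele_a <- vapply(parts, `[`, character(1), 1)
  diplotypes$allele_b <- vapply(parts, `[`, character(1), 2)
  sites <- definitions$variants$rsid
  site_of <- stats::setNames(definitions$variants$rsid, definitions$variants$allele)
  dosages <- matrix(0, nrow = n_individuals, ncol = length(sites),
                    dimnames = list(NULL, sites))
  for (col in 1:2) {
    carried <- site_of[draws[, col]]
    hit <- !is.na(carried)
    idx <- cbind(which(hit), match(carried[hit], sites))
    dosages[idx] <- dosages[idx] + 1
  }
  dosages <- data.frame(individual_id = ids, dosages, check.names = FALSE,
                        stringsAsFactors = FALSE)
  list(diplotypes = diplotypes, dosages = dosages)
}

#' Per-drug substrate concentration designs
#'
#' The concentration series used in the in vitro incubations, in uM. The 0
#' row is a blank. Hydralazine's series is two orders of magnitude lower
#' (it is the highest-affinity substrate); diaminodiphenyl sulfone tops
#' out at 300 uM.
#'
#' @return Named list, drug code -> numeric vector of concentrations.
#' @export
nat2_concentration_designs <- function() {
  std <- c(0, 0.3, 1, 3, 10, 30, 100, 300, 1000)
  list(
    AGT = std,
    DDP = c(0, 0.1, 0.3, 1, 3, 10, 30, 100, 300),
    HLZ = c(0, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10),
    INH = std, PZ = std, PA = std, SMZ = std, SP = std
  )
}

#' Simulate a replicated Michaelis-Menten reaction dataset
#'
#' Velocities are v = Vmax \[S\] / (Km + \[S\]) times multiplicative
#' lognormal noise with mean 1 and coefficient of variation `cv_noise`
#' (velocities are positive peak-area ratios, so noise is multiplicative,
#' not additive). \[S\] = 0 rows emit velocity 0 (blanks).
#'
#' @param true_params Data frame with columns `drug`, `allele`, `km`,
#'   `vmax` (one row per drug x allele to simulate).
#' @param designs Named list drug -> concentration vector (uM); defaults to
#'   [nat2_concentration_designs()].
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates per drug x allele.
#' @param seed Integer seed.
#' @return Data frame with columns `drug`, `allele`, `replicate`,
#'   `conc_um`, `velocity` — the layout [fit_kinetics()] consumes.
#' @export
simulate_kinetic_dataset <- function(true_params,
                                     designs = nat2_concentration_designs(),
                                     cv_noise = 0.05, n_replicates = 4,
                                     seed = NULL) {
  required <- c("drug", "allele", "km", "vmax")
  missing_cols <- setdiff(required, names(true_params))
  if (length(missing_cols)) {
    stop("true_params lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (cv_noise < 0) stop("cv_noise must be >= 0")
  if (any(unlist(designs) < 0)) stop("negative concentrations in design")
  sdlog <- sqrt(log(1 + cv_noise^2))
  meanlog <- -sdlog^2 / 2     # so the multiplicative noise has mean 1
  with_local_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(true_params))) {
      d <- true_params$drug[i]
      if (is.null(designs[[d]])) stop("no concentration design for drug ", d)
      s <- designs[[d]]
      for (r in seq_len(n_replicates)) {
        v_true <- true_params$vmax[i] * s / (true_params$km[i] + s)
        noise <- if (cv_noise > 0) stats::rlnorm(length(s), meanlog, sdlog) else 1
        v <- ifelse(s == 0, 0, v_true * noise)
        rows[[length(rows) + 1L]] <- data.frame(
          drug = d, allele = true_params$allele[i], replicate = r,
          conc_um = s, velocity = v, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
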