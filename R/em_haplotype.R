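# EM estimation of haplotype frequencies over the signature sites, and
# maximum-likelihood diplotype calling for unphased genotype data.
#
# With k signature sites there are 2^k possible haplotype patterns; a
# pattern is represented internally as an integer bitmask (bit i set =
# carries the alt allele at site i). The all-zero pattern is the reference
# allele *4; a single-bit pattern is the star allele its signature variant
# defines; patterns with two or more variant sites in cis ("compound"
# haplotypes) are carried through the EM but are outside the supported
# allele universe and raise an error if a diplotype call selects one.

#' Estimate haplotype frequencies by expectation-maximization
#'
#' Standard multilocus EM for unphased diploid genotypes: each individual's
#' dosage vector is compatible with one or more (haplotype, haplotype)
#' pairs; the E-step distributes each individual over the compatible pairs
#' in proportion to the product of current haplotype frequencies, and the
#' M-step re-estimates frequencies from expected gamete counts. The
#' initialization is uniform over all 2^k patterns, so the result is
#' deterministic.
#'
#' @param calls A data frame of genotype calls: column `individual_id` plus
#'   one column per signature-site rsID holding alt-allele dosages in
#'   \{0, 1, 2\} (NA = missing).
#' @param definitions A `nat2_definitions` object (default: built-in NAT2).
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood gain falls below `tol`.
#' @return An object of class `nat2_hapfreq`: list with `frequencies`
#'   (named numeric over pattern labels, summing to 1), `pattern_bits`,
#'   `sites`, `log_likelihood`, `ll_trace`, `iterations`, `n_used` and
#'   `excluded_individuals`.
#' @examples
#' defs <- load_allele_definitions("NAT2")
#' calls <- data.frame(individual_id = c("a", "b"),
#'                     rs1801280 = c(0, 0), rs1799930 = c(1, 0),
#'                     rs1799931 = c(0, 0))
#' em_haplotype_frequencies(calls, defs)$frequencies
#' @export
em_haplotype_frequencies <- function(calls, definitions = load_allele_definitions("NAT2"),
                                     max_iter = 1000L, tol = 1e-10) {
  stopifnot(inherits(definitions, "nat2_definitions"))
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop("need at least one individual")
  }
  sites <- definitions$variants$rsid
  present <- intersect(sites, names(calls))
  if (length(present) == 0) stop("no signature-site columns in 'calls'")
  dos <- as.matrix(calls[, present, drop = FALSE])
  storage.mode(dos) <- "double"
  if (any(!is.na(dos) & !(dos %in% c(0, 1, 2)))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  # sites where every individual is missing are dropped, not imputed
  all_missing <- apply(dos, 2, function(x) all(is.na(x)))
  if (any(all_missing)) {
    warning("dropping site(s) with all genotypes missing: ",
            paste(present[all_missing], collapse = ", "))
    dos <- dos[, !all_missing, drop = FALSE]
    present <- present[!all_missing]
  }
  if (ncol(dos) == 0) stop("no usable signature sites")
  if (ncol(dos) > 8) stop("more than 8 signature sites not supported")
  # individuals with a missing dosage at a retained site are excluded
  incomplete <- apply(dos, 1, anyNA)
  excluded <- character(0)
  if (any(incomplete)) {
    excluded <- as.character(calls$individual_id[incomplete])
    warning(sum(incomplete), " individual(s) with missing dosages excluded from EM")
    dos <- dos[!incomplete, , drop = FALSE]
  }
  if (nrow(dos) == 0) stop("no individuals with complete dosages")

  k <- ncol(dos)
  n_pat <- 2L^k
  labels <- pattern_labels(k, present, definitions)

  # collapse identical genotype rows; EM cost scales with unique genotypes
  keys <- apply(dos, 1, paste, collapse = ",")
  tab <- table(keys)
  ugen <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  ugen <- matrix(as.numeric(ugen), ncol = k)
  wts <- as.numeric(tab)
  configs <- lapply(seq_len(nrow(ugen)), function(i) genotype_configs(ugen[i, ]))

  f <- rep(1 / n_pat, n_pat)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(n_pat)
    ll <- 0
    for (i in seq_along(configs)) {
      cf <- configs[[i]]
      w <- f[cf$h1 + 1L] * f[cf$h2 + 1L] * cf$mult
      tot <- sum(w)
      if (tot <= 0) {
        # degenerate support: spread expectation uniformly over configs
        w <- cf$mult
        tot <- sum(w)
        ll <- ll + wts[i] * log(.Machine$double.xmin)
      } else {
        ll <- ll + wts[i] * log(tot)
      }
      p <- wts[i] * w / tot
      for (j in seq_along(p)) {
        counts[cf$h1[j] + 1L] <- counts[cf$h1[j] + 1L] + p[j]
        counts[cf$h2[j] + 1L] <- counts[cf$h2[j] + 1L] + p[j]
      }
    }
    if (ll < ll_old - 1e-8) {
      stop("internal error: EM log-likelihood decreased")   # nocov
    }
    ll_trace <- c(ll_trace, ll)
    f <- counts / sum(counts)
    if ((ll - ll_old) < tol || iter >= max_iter) break
    ll_old <- ll
  }
  out <- list(
    frequencies = stats::setNames(f, labels),
    pattern_bits = seq_len(n_pat) - 1L,
    sites = present,
    log_likelihood = ll_trace[length(ll_trace)],
    ll_trace = ll_trace,
    iterations = iter,
    n_used = nrow(dos),
    excluded_individuals = excluded
  )
  class(out) <- "nat2_hapfreq"
  out
}

#' @export
print.nat2_hapfreq <- function(x, ...) {
  cat("EM haplotype frequencies over", length(x$sites), "signature sites",
      sprintf("(%d individuals, %d iterations, logLik %.4f)\n",
              x$n_used, x$iterations, x$log_likelihood))
  print(round(x$frequencies[x$frequencies > 0 | grepl("^\\*", names(x$frequencies))], 6))
  invisible(x)
}

# Label every bitmask pattern: reference allele for 0, the defining star
# allele for single-bit patterns, "rsX+rsY" for compound patterns.
pattern_labels <- function(k, sites, definitions) {
  vapply(seq_len(2L^k) - 1L, function(p) {
    bits <- bitwAnd(bitwShiftR(p, seq_len(k) - 1L), 1L) == 1L
    nb <- sum(bits)
    if (nb == 0) return(definitions$reference_allele)
    if (nb == 1) {
      rs <- sites[bits]
      al <- definitions$variants$allele[match(rs, definitions$variants$rsid)]
      if (!is.na(al)) return(al)
    }
    paste(sites[bits], collapse = "+")
  }, character(1))
}

# All unordered haplotype pairs compatible with a dosage vector.
# Returns integer bitmasks h1, h2 and the multiplicity (2 for heterozygous
# pairs, 1 for homozygous) entering P(g) = sum mult * f1 * f2.
genotype_configs <- function(g) {
  k <- length(g)
  hom <- sum(bitwShiftL(1L, which(g == 2) - 1L))
  het <- which(g == 1)
  h <- length(het)
  if (h == 0) {
    return(list(h1 = hom, h2 = hom, mult = 1))
  }
  # fix the first het site on haplotype 1 to enumerate unordered pairs once
  rest <- het[-1]
  n_cfg <- 2L^(h - 1L)
  h1 <- integer(n_cfg); h2 <- integer(n_cfg)
  for (s in seq_len(n_cfg) - 1L) {
    take <- if (h > 1) rest[bitwAnd(bitwShiftR(s, seq_len(h - 1L) - 1L), 1L) == 1L] else integer(0)
    a <- hom + bitwShiftL(1L, het[1] - 1L) + sum(bitwShiftL(1L, take - 1L))
    b <- hom + sum(bitwShiftL(1L, setdiff(het, c(het[1], take)) - 1L))
    h1[s + 1L] <- a
    h2[s + 1L] <- b
  }
  list(h1 = h1, h2 = h2, mult = rep(2, n_cfg))
}

#' Call star-allele diplotypes from genotype dosages
#'
#' Enumerates the phase configurations consistent with each individual's
#' dosages and selects the configuration with the maximum product of
#' haplotype frequencies. The phase posterior is the chosen configuration's
#' share of the summed products; a call is flagged ambiguous when more than
#' one configuration is consistent and the posterior is below 1. A selected
#' haplotype carrying two or more signature variants in cis is outside the
#' supported allele universe and raises an error rather than being renamed.
#'
#' @param calls Data frame of genotype calls (as for
#'   [em_haplotype_frequencies()]).
#' @param freqs A `nat2_hapfreq` object; if omitted it is estimated from
#'   `calls` by EM.
#' @param definitions A `nat2_definitions` object.
#' @return A data frame of class `nat2_diplotypes` with columns
#'   `individual_id`, `diplotype`, `allele_a`, `allele_b`, `ambiguous`,
#'   `posterior`.
#' @examples
#' defs <- load_allele_definitions("NAT2")
#' calls <- data.frame(individual_id = "s1", rs1801280 = 0,
#'                     rs1799930 = 1, rs1799931 = 0)
#' call_diplotypes(calls, definitions = defs)
#' @export
call_diplotypes <- function(calls, freqs = NULL,
                            definitions = load_allele_definitions("NAT2")) {
  if (is.null(freqs)) freqs <- em_haplotype_frequencies(calls, definitions)
  stopifnot(inherits(freqs, "nat2_hapfreq"))
  sites <- freqs$sites
  missing_sites <- setdiff(sites, names(calls))
  if (length(missing_sites)) {
    stop("calls lack signature-site column(s): ", paste(missing_sites, collapse = ", "))
  }
  extra <- setdiff(setdiff(names(calls), "individual_id"), definitions$variants$rsid)
  if (length(extra)) {
    stop("dosage at unknown rsid(s): ", paste(extra, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call_one_diplotype(calls$individual_id[i],
                       as.numeric(calls[i, sites]), freqs, definitions)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nat2_diplotypes", "data.frame")
  out
}

call_one_diplotype <- function(id, g, freqs, definitions) {
  if (all(is.na(g))) stop("individual ", id, ": no dosages at signature sites")
  if (anyNA(g)) {
    stop("individual ", id, ": missing dosage at a signature site; ",
         "missing data are excluded, not imputed")
  }
  cf <- genotype_configs(g)
  w <- freqs$frequencies[cf$h1 + 1L] * freqs$frequencies[cf$h2 + 1L]
  lab1 <- names(freqs$frequencies)[cf$h1 + 1L]
  lab2 <- names(freqs$frequencies)[cf$h2 + 1L]
  n_cfg <- length(w)
  if (sum(w) > 0) {
    posterior <- max(w) / sum(w)
    best <- which(w == max(w))
  } else {
    posterior <- 1 / n_cfg
    best <- seq_len(n_cfg)
  }
  if (length(best) > 1) {
    # deterministic tie-break: lexicographic order of the canonical label
    labs <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "/"),
                   lab1[best], lab2[best])
    best <- best[order(labs)][1]
  }
  a <- lab1[best]; b <- lab2[best]
  compound <- c(a, b)[!c(a, b) %in% definitions$alleles]
  if (length(compound)) {
    stop("individual ", id, ": selected haplotype carries multiple ",
         "signature variants in cis (", paste(unique(compound), collapse = ", "),
         "); not in the supported allele universe")
  }
  data.frame(
    individual_id = as.character(id),
    diplotype = canonical_diplotype(a, b),
    allele_a = ifelse(allele_number(a) <= allele_number(b), a, b),
    allele_b = ifelse(allele_number(a) <= allele_number(b), b, a),
    ambiguous = n_cfg > 1 && posterior < 1,
    posterior = posterior,
    stringsAsFactors = FALSE
  )
}

#' Gamete-counting allele frequencies from diplotype calls
#'
#' @param diplotypes A `nat2_diplotypes` data frame, or a character vector
#'   of canonical diplotype labels, or a data frame with columns `genotype`
#'   and `count` (expanded by count).
#' @return Named numeric vector of allele frequencies (sums to 1).
#' @examples
#' estimate_allele_frequencies(c("*4/*4", "*4/*6", "*5/*6"))
#' @export
estimate_allele_frequencies <- function(diplotypes) {
  if (is.data.frame(diplotypes) && all(c("genotype", "count") %in% names(diplotypes))) {
    labels <- rep(diplotypes$genotype, diplotypes$count)
  } else if (is.data.frame(diplotypes) && all(c("allele_a", "allele_b") %in% names(diplotypes))) {
    labels <- paste(diplotypes$allele_a, diplotypes$allele_b, sep = "/")
  } else if (is.character(diplotypes)) {
    labels <- diplotypes
  } else {
    stop("unsupported input to estimate_allele_frequencies()")
  }
  if (length(labels) == 0) stop("no diplotypes")
  alleles <- unlist(split_diplotype(labels))
  tab <- table(alleles)
  f <- as.numeric(tab) / length(alleles)
  stats::setNames(f, names(tab))[order(allele_number(names(tab)))]
}
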