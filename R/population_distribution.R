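# Combine per-population genotype counts with per-drug phenotype
# assignments into worldwide acetylator-phenotype frequency tables.

#' Tabulate genotype frequencies per population
#'
#' @param x Either a counts data frame with columns `population`,
#'   `genotype`, `count`, or a `nat2_diplotypes` data frame (optionally
#'   with a `population` column; otherwise one cohort named `"cohort"`).
#' @return Data frame of class `nat2_cohort` with columns `population`,
#'   `genotype`, `count`, `n`, `frequency`.
#' @examples
#' counts <- data.frame(population = "JPN",
#'                      genotype = c("*4/*4", "*4/*6"), count = c(480, 260))
#' tabulate_genotype_frequencies(counts)
#' @export
tabulate_genotype_frequencies <- function(x) {
  if (inherits(x, "nat2_diplotypes") ||
      (is.data.frame(x) && "diplotype" %in% names(x))) {
    pop <- if ("population" %in% names(x)) x$population else rep("cohort", nrow(x))
    tab <- as.data.frame(table(population = pop, genotype = x$diplotype),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "count"
    x <- tab[tab$count > 0, ]
  }
  required <- c("population", "genotype", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) stop("empty cohort table")
  if (any(x$count < 0)) stop("negative genotype count")
  out <- x[, required]
  n_by_pop <- tapply(out$count, out$population, sum)
  out$n <- as.numeric(n_by_pop[out$population])
  out$frequency <- out$count / out$n
  rownames(out) <- NULL
  class(out) <- c("nat2_cohort", "data.frame")
  out
}

#' Phenotype frequencies for one cohort and one drug assignment
#'
#' @param cohort A `nat2_cohort` table (any number of populations).
#' @param assignment A `nat2_phenotypes` object for one drug, or a
#'   `nat2_assignments` data frame (all drugs used).
#' @return Data frame of class `nat2_distribution` with columns
#'   `population`, `drug`, `phenotype`, `count`, `n`, `frequency`,
#'   `percent` (percent = 100 x frequency, full precision).
#' @export
phenotype_frequencies <- function(cohort, assignment) {
  cohort <- tabulate_genotype_frequencies(cohort)
  if (inherits(assignment, "nat2_phenotypes")) {
    amap <- data.frame(drug = assignment$drug %||% "drug",
                       genotype = names(assignment$labels),
                       phenotype = unname(assignment$labels),
                       stringsAsFactors = FALSE)
  } else if (is.data.frame(assignment) &&
             all(c("drug", "genotype", "phenotype") %in% names(assignment))) {
    amap <- assignment[, c("drug", "genotype", "phenotype")]
  } else {
    stop("unsupported 'assignment'")
  }
  rows <- list()
  for (d in unique(amap$drug)) {
    am <- amap[amap$drug == d, ]
    unlabelled <- setdiff(unique(cohort$genotype), am$genotype)
    if (length(unlabelled)) {
      stop("genotype(s) without a phenotype label for ", d, ": ",
           paste(unlabelled, collapse = ", "))
    }
    ph <- am$phenotype[match(cohort$genotype, am$genotype)]
    agg <- stats::aggregate(count ~ population + phenotype,
                            data = cbind(cohort, phenotype = ph), FUN = sum)
    agg$drug <- d
    rows[[d]] <- agg
  }
  out <- do.call(rbind, rows)
  n_by_pop <- tapply(cohort$count, cohort$population, sum)
  out$n <- as.numeric(n_by_pop[out$population])
  out$frequency <- out$count / out$n
  out$percent <- 100 * out$frequency
  out <- out[order(out$population, match(out$drug, nat2_drugs()),
                   match(out$phenotype, c("RA", "IA", "SA", "USA"))),
             c("population", "drug", "phenotype", "count", "n", "frequency", "percent")]
  rownames(out) <- NULL
  class(out) <- c("nat2_distribution", "data.frame")
  out
}

#' Range of a phenotype's percentage across drugs
#'
#' @param distributions A `nat2_distribution` data frame covering >= 1
#'   drug.
#' @param phenotype Phenotype label (`"RA"`, `"IA"`, `"SA"`, `"USA"`).
#' @return Data frame per population: `min_percent`, `max_percent`,
#'   `n_drugs` (number of drugs in which the phenotype occurs). A
#'   phenotype absent everywhere yields a zero-row result with a warning.
#' @export
frequency_range_summary <- function(distributions, phenotype) {
  stopifnot(is.data.frame(distributions))
  sub <- distributions[distributions$phenotype == phenotype, ]
  if (nrow(sub) == 0) {
    warning("phenotype ", phenotype, " absent for all drugs")
    return(data.frame(population = character(0), min_percent = numeric(0),
                      max_percent = numeric(0), n_drugs = integer(0)))
  }
  out <- do.call(rbind, lapply(split(sub, sub$population), function(g) {
    data.frame(population = g$population[1],
               min_percent = min(g$percent), max_percent = max(g$percent),
               n_drugs = length(unique(g$drug)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
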