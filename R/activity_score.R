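# Per-drug activity scores: allele CLint normalized to the reference
# allele *4 (score 1), and diploid genotype scores as the sum over both
# alleles, so *4/*4 scores exactly 2.

#' Round half away from zero
#'
#' Report-style rounding (0.0005 -> 0.001) as opposed to base R's
#' round-half-even. Used only when formatting reports; internal
#' computations keep full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Activity score of one allele
#'
#' The allele's intrinsic clearance as a fraction of the reference
#' allele's: a score of 0.5 means a 50% reduction in CLint.
#'
#' @param clint_allele CLint of the allele.
#' @param clint_ref CLint of the reference allele (*4).
#' @return Numeric score (reference allele scores exactly 1).
#' @examples
#' allele_activity_score(0.037, 0.593)   # AGT *6: ~0.062
#' @export
allele_activity_score <- function(clint_allele, clint_ref) {
  if (any(clint_ref <= 0)) stop("reference CLint must be positive")
  clint_allele / clint_ref
}

#' Build the per-drug activity-score table
#'
#' From per-allele CLint values (either a `nat2_kinetics` fit or any data
#' frame with columns `drug`, `allele`, `clint`), computes allele scores
#' (CLint ratio to *4) and all 10 diploid genotype scores (sum over both
#' alleles) for each drug.
#'
#' @param kinetic_params Data frame with columns `drug`, `allele`, `clint`.
#' @param reference_allele Reference allele name (score fixed at 1).
#' @return Data frame of class `nat2_scores` with columns `drug`,
#'   `genotype`, `activity_score` (full precision), plus attribute
#'   `allele_scores` (data frame drug x allele).
#' @examples
#' kp <- data.frame(drug = "AGT", allele = c("*4", "*5", "*6", "*7"),
#'                  clint = c(0.593, 0.105, 0.037, 0.029))
#' build_score_table(kp)
#' @export
build_score_table <- function(kinetic_params, reference_allele = "*4") {
  required <- c("drug", "allele", "clint")
  missing_cols <- setdiff(required, names(kinetic_params))
  if (length(missing_cols)) {
    stop("kinetic parameter table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- list()
  ascores <- list()
  for (d in unique(kinetic_params$drug)) {
    kp <- kinetic_params[kinetic_params$drug == d, ]
    if (anyDuplicated(kp$allele)) stop(d, ": duplicated allele rows")
    if (!reference_allele %in% kp$allele) {
      stop(d, ": missing reference allele ", reference_allele)
    }
    ref <- kp$clint[kp$allele == reference_allele]
    if (ref <= 0) stop(d, ": reference CLint must be positive")
    sc <- stats::setNames(allele_activity_score(kp$clint, ref), kp$allele)
    genos <- all_diplotypes(kp$allele)
    parts <- split_diplotype(genos)
    gs <- vapply(parts, function(p) sc[[p[1]]] + sc[[p[2]]], numeric(1))
    out[[d]] <- data.frame(drug = d, genotype = genos, activity_score = gs,
                           stringsAsFactors = FALSE)
    ascores[[d]] <- data.frame(drug = d, allele = names(sc),
                               allele_score = unname(sc),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "allele_scores") <- do.call(rbind, c(ascores, make.row.names = FALSE))
  attr(res, "reference_allele") <- reference_allele
  class(res) <- c("nat2_scores", "data.frame")
  res
}

#' Coerce a plain data frame of activity scores to a score table
#'
#' For clustering pre-computed scores (for instance the shipped reference
#' table) without refitting kinetics. The result supports
#' [cluster_phenotypes()]; per-allele lookups via
#' [genotype_activity_score()] require a table from [build_score_table()].
#'
#' @param x Data frame with columns `drug`, `genotype`, `activity_score`.
#' @return The same data frame with class `nat2_scores`.
#' @examples
#' as_score_table(nat2_reference_scores())
#' @export
as_score_table <- function(x) {
  required <- c("drug", "genotype", "activity_score")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("score table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(x)[, required]
  class(out) <- c("nat2_scores", "data.frame")
  out
}

#' Diploid activity score of one genotype
#'
#' @param diplotype Canonical diplotype label (e.g. `"*4/*5"`) or a one-row
#'   `nat2_diplotypes` data frame.
#' @param table A `nat2_scores` table from [build_score_table()].
#' @param drug Drug code (may be omitted when the table covers one drug).
#' @return Numeric score. Alleles without kinetic data (e.g. *14) raise an
#'   error rather than scoring 0, which would fabricate an ultra-slow call.
#' @export
genotype_activity_score <- function(diplotype, table, drug = NULL) {
  stopifnot(inherits(table, "nat2_scores"))
  if (is.data.frame(diplotype)) diplotype <- diplotype$diplotype
  al <- split_diplotype(diplotype)[[1]]
  ascores <- attr(table, "allele_scores")
  if (is.null(drug)) {
    drug <- unique(table$drug)
    if (length(drug) > 1) stop("table covers several drugs; give 'drug'")
  }
  ascores <- ascores[ascores$drug == drug, ]
  if (nrow(ascores) == 0) stop("no scores for drug ", drug)
  missing_al <- setdiff(al, ascores$allele)
  if (length(missing_al)) {
    stop("no kinetic data for allele(s) ", paste(missing_al, collapse = ", "),
         "; cannot score genotype ", diplotype)
  }
  sum(ascores$allele_score[match(al, ascores$allele)])
}

#' Report-ready activity-score table
#'
#' @param table A `nat2_scores` table.
#' @param digits Decimal places (half-up rounding).
#' @return Wide data frame, genotype rows x drug columns.
#' @export
score_report <- function(table, digits = 3) {
  stopifnot(inherits(table, "nat2_scores"))
  tab <- table
  tab$activity_score <- round_half_up(tab$activity_score, digits)
  wide <- stats::reshape(as.data.frame(tab), idvar = "genotype",
                         timevar = "drug", direction = "wide")
  names(wide) <- sub("^activity_score\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
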