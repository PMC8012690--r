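# Categorization of diploid genotypes into acetylator phenotypes by
# agglomerative hierarchical clustering of activity scores (Ward D2
# linkage on Euclidean distances), with a data-driven choice between 3
# clusters (RA/IA/SA) and 4 (RA/IA/SA/USA).

#' Ward-D2 dendrogram of genotype activity scores
#'
#' Agglomerative clustering with the Ward D2 criterion (Lance-Williams
#' update on squared Euclidean distances; merge heights on the D2 scale,
#' matching R's `ward.D2` convention). Deterministic for a given score
#' vector; merge heights are invariant to the input order of the leaves.
#'
#' @param scores Named numeric vector: genotype label -> activity score.
#' @return An `hclust` object with genotype leaf labels.
#' @export
ward_linkage <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 genotypes")
  if (any(!is.finite(scores))) stop("non-finite activity score")
  if (is.null(names(scores))) names(scores) <- paste0("g", seq_along(scores))
  # sort leaves so the linkage (and any tie-break inside hclust) never
  # depends on input order
  scores <- scores[order(names(scores))]
  stats::hclust(stats::dist(scores), method = "ward.D2")
}

#' Choose the number of phenotype clusters
#'
#' Two selection rules are provided.
#'
#' `"slow_split"` (default) walks the candidate counts in increasing order
#' and accepts a finer cut only when the additional split (i) subdivides
#' the current slowest cluster — i.e. carves out a candidate ultra-slow
#' group — and (ii) separates the two resulting cluster means by more than
#' `min_gap` activity-score units. The default `min_gap` of 0.2 is 10% of
#' the reference diploid score (2.0): a new phenotype category is only
#' warranted when it represents at least that much metabolic capacity.
#' A finer cut that instead subdivides a rapid or intermediate cluster is
#' rejected, because the extra category would not be a phenotype class.
#'
#' `"silhouette"` returns the candidate maximizing the mean silhouette
#' width (Euclidean); ties are broken by the Calinski-Harabasz index, then
#' by the smaller k.
#'
#' @param dendrogram `hclust` object from [ward_linkage()].
#' @param scores The named score vector that was clustered.
#' @param candidates Candidate cluster counts (default 3 and 4).
#' @param method `"slow_split"` or `"silhouette"`.
#' @param min_gap Minimum separation between the means of the two clusters
#'   produced by an accepted split (activity-score units).
#' @return The selected integer k.
#' @export
select_cluster_count <- function(dendrogram, scores, candidates = c(3L, 4L),
                                 method = c("slow_split", "silhouette"),
                                 min_gap = 0.2) {
  method <- match.arg(method)
  if (length(candidates) == 0) stop("empty candidate set")
  n <- length(scores)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 2 | candidates > n - 1)) {
    stop("candidates must lie in 2..(n_leaves - 1)")
  }
  scores <- scores[dendrogram$labels]
  if (method == "silhouette") {
    d <- stats::dist(scores)
    sil <- vapply(candidates, function(k) {
      mean(cluster::silhouette(stats::cutree(dendrogram, k), d)[, "sil_width"])
    }, numeric(1))
    best <- candidates[sil >= max(sil) - 1e-12]
    if (length(best) > 1) {
      ch <- vapply(best, function(k) calinski_harabasz(scores, stats::cutree(dendrogram, k)),
                   numeric(1))
      best <- best[ch >= max(ch) - 1e-12]
    }
    return(min(best))
  }
  k <- candidates[1]
  for (k_next in candidates[-1]) {
    cl <- stats::cutree(dendrogram, k)
    cl_next <- stats::cutree(dendrogram, k_next)
    if (k_next - k != 1L) break
    split_of <- which(vapply(seq_len(k), function(i) {
      length(unique(cl_next[cl == i])) == 2
    }, logical(1)))
    means <- tapply(scores, cl, mean)
    slowest <- as.integer(names(means)[which.min(means)])
    if (!identical(slowest, split_of[1]) || length(split_of) != 1) break
    sub_means <- tapply(scores[cl == slowest], cl_next[cl == slowest], mean)
    if (abs(diff(range(sub_means))) <= min_gap) break
    k <- k_next
  }
  k
}

calinski_harabasz <- function(x, cl) {
  k <- length(unique(cl))
  n <- length(x)
  gm <- mean(x)
  W <- sum(vapply(split(x, cl), function(g) sum((g - mean(g))^2), numeric(1)))
  B <- sum(vapply(split(x, cl), function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  (B / (k - 1)) / (W / (n - k))
}

#' Cut the dendrogram and label clusters as acetylator phenotypes
#'
#' Clusters are ordered by decreasing mean activity score and labelled
#' RA > IA > SA for k = 3, RA > IA > SA > USA for k = 4 (RA/SA for k = 2).
#'
#' @param dendrogram `hclust` object from [ward_linkage()].
#' @param k Number of clusters (2, 3 or 4).
#' @param scores The named score vector that was clustered.
#' @param drug Optional drug code recorded in the result.
#' @return Object of class `nat2_phenotypes`: list with `drug`, `k`,
#'   `labels` (named character vector genotype -> phenotype) and
#'   `cluster_means` (named by phenotype, decreasing).
#' @export
assign_phenotype_labels <- function(dendrogram, k, scores, drug = NULL) {
  label_sets <- list(`2` = c("RA", "SA"), `3` = c("RA", "IA", "SA"),
                     `4` = c("RA", "IA", "SA", "USA"))
  if (!as.character(k) %in% names(label_sets)) {
    stop("k must be 2, 3 or 4 for phenotype labelling")
  }
  scores <- scores[dendrogram$labels]
  cl <- stats::cutree(dendrogram, k)
  means <- tapply(scores, cl, mean)
  ord <- order(means, decreasing = TRUE)
  phen <- label_sets[[as.character(k)]]
  labels <- stats::setNames(phen[match(cl, as.integer(names(means))[ord])],
                            names(scores))
  out <- list(drug = drug, k = as.integer(k),
              labels = labels,
              cluster_means = stats::setNames(as.numeric(means)[ord], phen))
  class(out) <- "nat2_phenotypes"
  out
}

#' @export
print.nat2_phenotypes <- function(x, ...) {
  cat("Acetylator phenotype assignment",
      if (!is.null(x$drug)) paste0("(", x$drug, ")"), "- k =", x$k, "\n")
  for (p in names(x$cluster_means)) {
    cat(sprintf("  %-3s (mean AS %.3f): %s\n", p, x$cluster_means[[p]],
                paste(names(x$labels)[x$labels == p], collapse = ", ")))
  }
  invisible(x)
}

#' Cluster genotypes into phenotypes for every drug
#'
#' Runs [ward_linkage()], [select_cluster_count()] and
#' [assign_phenotype_labels()] per drug over an activity-score table.
#'
#' @param score_table A `nat2_scores` table from [build_score_table()].
#' @param candidates Candidate cluster counts.
#' @param method,min_gap Passed to [select_cluster_count()].
#' @return Data frame of class `nat2_assignments` with columns `drug`,
#'   `genotype`, `activity_score`, `phenotype`, `k`; attribute
#'   `assignments` holds the per-drug `nat2_phenotypes` objects.
#' @export
cluster_phenotypes <- function(score_table, candidates = c(3L, 4L),
                               method = c("slow_split", "silhouette"),
                               min_gap = 0.2) {
  stopifnot(inherits(score_table, "nat2_scores") || is.data.frame(score_table))
  method <- match.arg(method)
  rows <- list()
  per_drug <- list()
  for (d in unique(score_table$drug)) {
    sub <- score_table[score_table$drug == d, ]
    sc <- stats::setNames(sub$activity_score, sub$genotype)
    hc <- ward_linkage(sc)
    k <- select_cluster_count(hc, sc, candidates, method, min_gap)
    asg <- assign_phenotype_labels(hc, k, sc, drug = d)
    per_drug[[d]] <- asg
    rows[[d]] <- data.frame(drug = d, genotype = sub$genotype,
                            activity_score = sub$activity_score,
                            phenotype = unname(asg$labels[sub$genotype]),
                            k = k, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "assignments") <- per_drug
  class(out) <- c("nat2_assignments", "data.frame")
  out
}
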