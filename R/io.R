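# Readers and writers for the pipeline's tabular formats, accessors for
# the shipped reference tables, and the end-to-end pipeline driver.
# All tabular output is tab-separated UTF-8 with a single header row;
# genotype labels use the canonical "*a/*b" form.

#' Read genotype dosages at the signature sites from a VCF
#'
#' Matches VCF records to the signature variants by ID (rsID), computes
#' per-sample alt-allele dosages from the GT field (phasing separators are
#' ignored: phase is resolved statistically downstream), and ignores
#' non-signature records with a message. Multi-allelic records at a
#' signature site are rejected.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param definitions A `nat2_definitions` object.
#' @return Data frame with `individual_id` plus one dosage column per
#'   signature rsID found (NA where the GT is missing).
#' @export
read_vcf <- function(path, definitions = load_allele_definitions("NAT2")) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)   # always a matrix
  keep <- fix$ID %in% definitions$variants$rsid
  n_skip <- sum(!keep)
  if (n_skip > 0) message("ignoring ", n_skip, " non-signature VCF record(s)")
  if (!any(keep)) stop("no usable sites: VCF contains no signature variants")
  if (any(grepl(",", fix$ALT[keep], fixed = TRUE))) {
    stop("multi-allelic record at signature site(s): ",
         paste(fix$ID[keep][grepl(",", fix$ALT[keep], fixed = TRUE)], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  rs <- fix$ID[keep]
  dosage_of <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    if (any(!al %in% c("0", "1"))) stop("unsupported GT allele code: ", g)
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), dosage_of)
  out <- data.frame(individual_id = colnames(gt),
                    t(dos), check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- rs
  rownames(out) <- NULL
  out
}

#' Read a dosage matrix from TSV
#'
#' Rows are individuals (first column `individual_id`), remaining columns
#' are rsIDs holding alt-allele dosages.
#'
#' @param path TSV path.
#' @return Data frame of genotype calls.
#' @export
read_dosage_matrix <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(out)) {
    stop("dosage matrix needs an 'individual_id' column")
  }
  out
}

#' Read a kinetics reaction table from TSV
#'
#' @param path TSV with columns `drug`, `allele`, `replicate`, `conc_um`,
#'   `velocity`.
#' @return Data frame of reaction observations.
#' @export
read_reaction_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("drug", "allele", "replicate", "conc_um", "velocity")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("reaction table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out
}

#' Write a pipeline table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- shipped reference tables -------------------------------------------

extdata <- function(file) {
  p <- system.file("extdata", file, package = "nat2kit", mustWork = TRUE)
  p
}

#' Reference cohort genotype counts
#'
#' Diplotype counts for 990 Japanese individuals and the five continental
#' super-populations of the 1000 Genomes Project (AFR n=661, AMR n=347,
#' EAS n=504, EUR n=503, SAS n=489), as published for the study cohorts.
#'
#' @return Data frame with columns `population`, `genotype`, `count`.
#' @export
nat2_genotype_counts <- function() {
  utils::read.delim(extdata("nat2_genotype_counts.tsv"), stringsAsFactors = FALSE)
}

#' Reference kinetic parameters per allele and drug
#'
#' Published Km (uM), Vmax (relative peak area/min/mg protein) and CLint
#' (Vmax/Km) means with standard errors of four independent experiments,
#' for recombinant NAT2 *4/*5/*6/*7 against the eight substrate drugs.
#' CLint values are means of per-replicate Vmax/Km ratios, so they can
#' deviate by a few percent from the ratio of the tabulated mean Vmax to
#' the tabulated mean Km.
#'
#' @return Data frame with columns `drug`, `allele`, `km`, `km_se`,
#'   `vmax`, `vmax_se`, `clint`, `clint_se`.
#' @export
nat2_reference_kinetics <- function() {
  utils::read.delim(extdata("nat2_kinetic_params.tsv"), stringsAsFactors = FALSE)
}

#' Reference activity scores and phenotype categories
#'
#' Published per-drug diploid activity scores (3 decimals) and acetylator
#' phenotype categories for the 10 genotypes over *4/*5/*6/*7.
#'
#' @return Data frame with columns `drug`, `genotype`, `activity_score`,
#'   `phenotype`.
#' @export
nat2_reference_scores <- function() {
  utils::read.delim(extdata("nat2_reference_scores.tsv"), stringsAsFactors = FALSE)
}

# ---- configuration and pipeline driver ----------------------------------

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected.
#'
#' @param genotypes Path to a VCF (`.vcf`/`.vcf.gz`) or a dosage-matrix
#'   TSV, or a data frame of genotype calls; NULL to use `cohort_counts`.
#' @param cohort_counts Path to (or data frame of) per-population genotype
#'   counts (`population`, `genotype`, `count`); used for the population
#'   distribution stage. Defaults to the shipped reference counts.
#' @param kinetics Path to (or data frame of) a reaction table; NULL to
#'   score from the shipped reference kinetic parameters.
#' @param definition_set Definition-set name or path.
#' @param fitting_method `"lineweaver_burk"` or `"nls"`.
#' @param k_candidates Candidate phenotype cluster counts.
#' @param rounding Decimals for reported scores.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Output directory (created if needed); NULL = no files.
#' @return A validated list of class `nat2_config`.
#' @export
nat2_config <- function(genotypes = NULL, cohort_counts = NULL, kinetics = NULL,
                        definition_set = "NAT2",
                        fitting_method = c("lineweaver_burk", "nls"),
                        k_candidates = c(3L, 4L), rounding = 3L,
                        seed = 1L, out_dir = NULL) {
  cfg <- list(genotypes = genotypes, cohort_counts = cohort_counts,
              kinetics = kinetics, definition_set = definition_set,
              fitting_method = match.arg(fitting_method),
              k_candidates = as.integer(k_candidates),
              rounding = as.integer(rounding), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "nat2_config"
  cfg
}

validate_config <- function(config) {
  if (!inherits(config, "nat2_config")) {
    if (is.list(config)) {
      known <- names(formals(nat2_config))
      unknown <- setdiff(names(config), known)
      if (length(unknown)) {
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
      }
      config <- do.call(nat2_config, config)
    } else {
      stop("config must be an nat2_config or a named list")
    }
  }
  config
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline: call, fit, score, cluster, distribute
#'
#' Composes the five analysis stages. Genotype input (if any) is
#' diplotyped via EM; kinetics input (or the shipped reference parameters)
#' yields CLint, activity scores and phenotype assignments; cohort counts
#' (per-individual calls and/or count tables) yield the per-population
#' phenotype distribution. Reports are written as TSV (rounded) with a
#' full-precision JSON companion and a run log.
#'
#' @param config A `nat2_config` (or plain named list of its arguments).
#' @return List of class `nat2_report` with elements `diplotypes` (or
#'   NULL), `allele_frequencies`, `kinetics`, `scores`, `assignments`,
#'   `distribution`, `config`.
#' @export
run_pipeline <- function(config = nat2_config()) {
  config <- validate_config(config)
  defs <- pipeline_stage("definitions", load_allele_definitions(config$definition_set))

  diplos <- NULL
  freqs <- NULL
  if (!is.null(config$genotypes)) {
    calls <- pipeline_stage("genotype input", {
      g <- config$genotypes
      if (is.character(g)) {
        if (grepl("\\.vcf(\\.gz)?$", g)) read_vcf(g, defs) else read_dosage_matrix(g)
      } else g
    })
    hf <- pipeline_stage("em", em_haplotype_frequencies(calls, defs))
    diplos <- pipeline_stage("call", call_diplotypes(calls, hf, defs))
    freqs <- pipeline_stage("allele frequencies", estimate_allele_frequencies(diplos))
  }

  kin <- pipeline_stage("fit", {
    if (is.null(config$kinetics)) {
      nat2_reference_kinetics()
    } else {
      rx <- if (is.character(config$kinetics)) read_reaction_table(config$kinetics) else config$kinetics
      fit_kinetics(rx, method = config$fitting_method)
    }
  })
  scores <- pipeline_stage("score", build_score_table(kin))
  assign <- pipeline_stage("cluster",
                           cluster_phenotypes(scores, candidates = config$k_candidates))

  counts <- pipeline_stage("cohort counts", {
    cc <- config$cohort_counts
    if (is.null(cc) && !is.null(diplos)) {
      tabulate_genotype_frequencies(diplos)
    } else {
      if (is.null(cc)) cc <- nat2_genotype_counts()
      if (is.character(cc)) cc <- utils::read.delim(cc, stringsAsFactors = FALSE)
      tabulate_genotype_frequencies(cc)
    }
  })
  dist <- pipeline_stage("distribute", phenotype_frequencies(counts, assign))

  report <- list(diplotypes = diplos, allele_frequencies = freqs,
                 kinetics = kin, scores = scores, assignments = assign,
                 distribution = dist, config = config)
  class(report) <- "nat2_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) write_pipeline_tsv(x, file.path(config$out_dir, f))
    if (!is.null(diplos)) wr(diplos, "diplotype_calls.tsv")
    wr(as.data.frame(kin), "kinetic_params.tsv")
    rounded <- as.data.frame(scores)
    rounded$activity_score <- round_half_up(rounded$activity_score, config$rounding)
    wr(rounded, "activity_scores.tsv")
    wr(as.data.frame(assign), "phenotype_assignments.tsv")
    dist_out <- as.data.frame(dist)
    dist_out$percent <- round_half_up(dist_out$percent, 2)
    wr(dist_out, "phenotype_distribution.tsv")
    jsonlite::write_json(
      list(allele_frequencies = as.list(freqs %||% list()),
           scores = as.data.frame(scores),
           distribution = as.data.frame(dist)),
      file.path(config$out_dir, "results_full_precision.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(c(
      paste0("nat2kit ", as.character(utils::packageVersion("nat2kit"))),
      paste0("R ", R.version.string),
      paste0("seed ", config$seed),
      paste0("fitting_method ", config$fitting_method),
      paste0("timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    ), file.path(config$out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.nat2_report <- function(x, ...) {
  cat("nat2kit pipeline report\n")
  if (!is.null(x$diplotypes)) {
    cat("  diplotypes called:", nrow(x$diplotypes), "\n")
  }
  cat("  drugs scored:", length(unique(x$scores$drug)), "\n")
  cat("  populations:", paste(unique(x$distribution$population), collapse = ", "), "\n")
  invisible(x)
}
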