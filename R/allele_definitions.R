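#' Signature-variant definitions of NAT2 star alleles
#'
#' NAT2 star alleles are named haplotypes of the *NAT2* gene, each defined by
#' a single signature single-nucleotide variant: c.341T>C (rs1801280) defines
#' *5, c.590G>A (rs1799930) defines *6 and c.857G>A (rs1799931) defines *7.
#' The reference allele *4 is the haplotype carrying none of the signature
#' variants and is synthesized implicitly.
#'
#' @param definitions Either the name of a built-in definition set (currently
#'   `"NAT2"`) or the path to a tab-separated file with columns `rsid`,
#'   `ref`, `alt`, `allele` and optionally `cdna_change`.
#' @return An object of class `nat2_definitions`: a list with elements
#'   `variants` (data frame of signature variants), `alleles` (character
#'   vector of star-allele names, reference allele first) and
#'   `reference_allele`.
#' @examples
#' defs <- load_allele_definitions("NAT2")
#' defs$alleles
#' @export
load_allele_definitions <- function(definitions = "NAT2") {
  if (is.character(definitions) && length(definitions) == 1 &&
      definitions == "NAT2") {
    variants <- nat2_signature_variants()
  } else if (is.character(definitions) && length(definitions) == 1) {
    if (!file.exists(definitions)) {
      stop("definition table not found: ", definitions)
    }
    variants <- utils::read.delim(definitions, stringsAsFactors = FALSE)
  } else if (is.data.frame(definitions)) {
    variants <- definitions
  } else {
    stop("'definitions' must be a built-in name, a file path or a data frame")
  }
  required <- c("rsid", "ref", "alt", "allele")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("definition table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0) stop("no signature variants in definition table")
  if (anyDuplicated(variants$rsid)) {
    stop("duplicate rsid in definition table: ",
         paste(unique(variants$rsid[duplicated(variants$rsid)]), collapse = ", "))
  }
  if (anyDuplicated(variants$allele)) {
    stop("two signature variants map to one named allele (unsupported): ",
         paste(unique(variants$allele[duplicated(variants$allele)]), collapse = ", "))
  }
  if (!"cdna_change" %in% names(variants)) variants$cdna_change <- NA_character_
  variants <- variants[order(allele_number(variants$allele)),
                       c("rsid", "cdna_change", "ref", "alt", "allele")]
  rownames(variants) <- NULL
  out <- list(
    variants = variants,
    alleles = c("*4", variants$allele),
    reference_allele = "*4"
  )
  class(out) <- "nat2_definitions"
  out
}

# Built-in NAT2 definition set: the three common reduced-function signature
# SNVs. *14 (rs1801279) is intentionally absent from the default set; it can
# be loaded from a user table but has no kinetic data, so scoring rejects it.
nat2_signature_variants <- function() {
  data.frame(
    rsid        = c("rs1801280", "rs1799930", "rs1799931"),
    cdna_change = c("c.341T>C", "c.590G>A", "c.857G>A"),
    ref         = c("T", "G", "G"),
    alt         = c("C", "A", "A"),
    allele      = c("*5", "*6", "*7"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.nat2_definitions <- function(x, ...) {
  cat("NAT2 star-allele definition set\n")
  cat("  reference allele:", x$reference_allele, "\n")
  cat("  signature variants:\n")
  print(x$variants)
  invisible(x)
}

# "*5" -> 5; used for canonical ordering of diplotype labels (*4/*6, never
# *6/*4) so that *14 sorts numerically, not lexicographically.
allele_number <- function(allele) {
  as.numeric(sub("^\\*", "", allele))
}

#' Canonical diplotype label
#'
#' Joins two star-allele names into the canonical unordered label with
#' alleles sorted by number, e.g. `canonical_diplotype("*6", "*4")` is
#' `"*4/*6"`.
#'
#' @param allele_a,allele_b Star-allele names.
#' @return Character vector of canonical `"*a/*b"` labels.
#' @export
canonical_diplotype <- function(allele_a, allele_b) {
  swap <- allele_number(allele_a) > allele_number(allele_b)
  a <- ifelse(swap, allele_b, allele_a)
  b <- ifelse(swap, allele_a, allele_b)
  paste(a, b, sep = "/")
}

# Split "*4/*6" into its two alleles.
split_diplotype <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed diplotype label: ", label[bad][1])
  parts
}

# The ten canonical diplotypes over a set of alleles (choose 2 with
# replacement), in canonical order.
all_diplotypes <- function(alleles) {
  alleles <- alleles[order(allele_number(alleles))]
  n <- length(alleles)
  labs <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      labs <- c(labs, paste(alleles[i], alleles[j], sep = "/"))
    }
  }
  labs
}
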