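# Michaelis-Menten parameter estimation per allele x drug, intrinsic
# clearance, and Tukey multiple comparisons between alleles.

#' The eight substrate drugs
#'
#' Drug codes used throughout: aminoglutethimide (AGT), diaminodiphenyl
#' sulfone (DDP), hydralazine (HLZ), isoniazid (INH), phenelzine (PZ),
#' procaineamide (PA), sulfamethazine (SMZ) and sulfapyrizine (SP).
#'
#' @return Character vector of the eight drug codes.
#' @export
nat2_drugs <- function() {
  c("AGT", "DDP", "HLZ", "INH", "PZ", "PA", "SMZ", "SP")
}

#' Fit Michaelis-Menten parameters to one velocity curve
#'
#' Two estimators are available. `"lineweaver_burk"` (the default) is the
#' double-reciprocal method: ordinary least squares of 1/v on 1/\[S\] over
#' points with \[S\] > 0 and v > 0, with Km = slope/intercept and
#' Vmax = 1/intercept. `"nls"` fits v = Vmax \[S\]/(Km + \[S\]) by nonlinear
#' least squares initialized from the Lineweaver-Burk estimate;
#' statistically preferable on noisy data because the reciprocal transform
#' inflates the weight of low-velocity points.
#'
#' Rows with \[S\] = 0 are blanks: they never enter the regression, and a
#' blank velocity exceeding `signal_floor` triggers a warning. Velocities
#' at or below `signal_floor` are dropped with a warning (a configurable
#' stand-in for an assay's limit of detection).
#'
#' @param substrate_conc Substrate concentrations in uM.
#' @param velocity Reaction velocities (relative peak area/min/mg protein).
#' @param method `"lineweaver_burk"` or `"nls"`.
#' @param signal_floor Velocities <= this value are excluded.
#' @return List with `Km` (uM), `Vmax`, `method`, `n_points`.
#' @examples
#' s <- c(1, 3, 10, 30, 100, 300, 1000)
#' v <- 50 * s / (100 + s)
#' fit_michaelis_menten(s, v)   # recovers Km = 100, Vmax = 50
#' @export
fit_michaelis_menten <- function(substrate_conc, velocity,
                                 method = c("lineweaver_burk", "nls"),
                                 signal_floor = 0) {
  method <- match.arg(method)
  stopifnot(length(substrate_conc) == length(velocity))
  if (any(substrate_conc < 0)) stop("negative substrate concentration")
  blank <- substrate_conc == 0
  if (any(blank & velocity > max(signal_floor, 1e-8))) {
    warning("non-zero velocity in [S]=0 blank(s); blanks are not fitted")
  }
  low <- !blank & velocity <= signal_floor
  if (any(low)) {
    warning(sum(low), " observation(s) at or below the signal floor dropped")
  }
  use <- !blank & !low & velocity > 0
  s <- substrate_conc[use]
  v <- velocity[use]
  if (length(unique(s)) < 3) {
    stop("need at least 3 distinct positive concentrations with positive velocities")
  }
  lb_fit <- function() {
    lb <- stats::lm(I(1 / v) ~ I(1 / s))
    intercept <- stats::coef(lb)[[1]]
    slope <- stats::coef(lb)[[2]]
    if (intercept <= 0) stop("non-convergent: non-positive Lineweaver-Burk intercept")
    km <- slope / intercept
    if (km <= 0) stop("non-convergent: non-positive Km estimate")
    c(Km = km, Vmax = 1 / intercept)
  }
  if (method == "lineweaver_burk") {
    est <- lb_fit()
  } else {
    # the reciprocal transform makes the LB intercept unstable under
    # multiplicative noise; fall back to a half-saturation heuristic start
    start <- tryCatch(as.list(lb_fit()), error = function(e) {
      list(Km = stats::approx(v, s, xout = max(v) / 2, ties = mean)$y %||%
             stats::median(s),
           Vmax = 1.1 * max(v))
    })
    if (!is.finite(start$Km) || start$Km <= 0) start$Km <- stats::median(s)
    fit <- stats::nls(v ~ Vmax * s / (Km + s), start = start,
                      algorithm = "port",
                      lower = c(Km = 1e-9, Vmax = 1e-9),
                      control = stats::nls.control(warnOnly = TRUE))
    est <- stats::coef(fit)
    if (est[["Km"]] <= 0 || est[["Vmax"]] <= 0) stop("non-convergent nonlinear fit")
  }
  list(Km = est[["Km"]], Vmax = est[["Vmax"]], method = method,
       n_points = length(s))
}

#' Fit kinetics for every drug x allele in a reaction table
#'
#' Fits each replicate's velocity curve separately, then summarizes Km,
#' Vmax and CLint as mean +/- standard error across replicates. CLint is
#' the mean of the per-replicate Vmax/Km ratios, not the ratio of the mean
#' Vmax to the mean Km.
#'
#' @param reactions Data frame with columns `drug`, `allele`, `replicate`,
#'   `conc_um`, `velocity`.
#' @param method Fitting method, see [fit_michaelis_menten()].
#' @param signal_floor Passed to [fit_michaelis_menten()].
#' @return Data frame of class `nat2_kinetics` with one row per
#'   drug x allele: `km`, `km_se`, `vmax`, `vmax_se`, `clint`, `clint_se`,
#'   `n_replicates`, plus a `replicates` attribute holding the
#'   per-replicate estimates.
#' @export
fit_kinetics <- function(reactions, method = c("lineweaver_burk", "nls"),
                         signal_floor = 0) {
  method <- match.arg(method)
  required <- c("drug", "allele", "replicate", "conc_um", "velocity")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols)) {
    stop("reaction table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(reactions$drug), nat2_drugs())
  if (length(unknown)) {
    stop("unknown drug code(s): ", paste(unknown, collapse = ", "))
  }
  groups <- split(reactions,
                  list(reactions$drug, reactions$allele, reactions$replicate),
                  drop = TRUE)
  reps <- do.call(rbind, lapply(groups, function(g) {
    fit <- fit_michaelis_menten(g$conc_um, g$velocity, method = method,
                                signal_floor = signal_floor)
    data.frame(drug = g$drug[1], allele = g$allele[1],
               replicate = g$replicate[1],
               km = fit$Km, vmax = fit$Vmax, clint = fit$Vmax / fit$Km,
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- do.call(rbind, lapply(split(reps, list(reps$drug, reps$allele), drop = TRUE),
    function(g) {
      data.frame(drug = g$drug[1], allele = g$allele[1],
                 n_replicates = nrow(g),
                 km = mean(g$km), km_se = se(g$km),
                 vmax = mean(g$vmax), vmax_se = se(g$vmax),
                 clint = mean(g$clint), clint_se = se(g$clint),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(match(out$drug, nat2_drugs()), allele_number(out$allele)), ]
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  attr(out, "method") <- method
  class(out) <- c("nat2_kinetics", "data.frame")
  out
}

#' Summarize intrinsic clearance across replicates
#'
#' CLint = Vmax/Km per replicate, then mean +/- SE (sample SD / sqrt(n))
#' across replicates.
#'
#' @param km,vmax Per-replicate Km and Vmax estimates (equal length).
#' @return List with `clint` (per-replicate ratios), `mean`, `se`, `n`.
#' @examples
#' compute_clint(76.24, 45.18)$mean   # 0.593 at 3 decimals
#' @export
compute_clint <- function(km, vmax) {
  stopifnot(length(km) == length(vmax))
  if (length(km) == 0) stop("zero replicates")
  if (any(km <= 0)) stop("Km must be positive")
  ratio <- vmax / km
  list(clint = ratio,
       mean = mean(ratio),
       se = if (length(ratio) > 1) stats::sd(ratio) / sqrt(length(ratio)) else NA_real_,
       n = length(ratio))
}

#' Clearance of an allele relative to the reference
#'
#' @param allele_clint Intrinsic clearance of the allele of interest.
#' @param reference_clint Intrinsic clearance of the reference allele (*4).
#' @return Percent of the reference clearance (100 x ratio).
#' @examples
#' relative_clearance(1.449, 11.706)   # isoniazid *5: 12.4%
#' @export
relative_clearance <- function(allele_clint, reference_clint) {
  if (any(reference_clint <= 0)) stop("reference CLint must be positive")
  100 * allele_clint / reference_clint
}

#' Tukey HSD comparison of alleles
#'
#' One-way ANOVA across alleles followed by Tukey's honestly-significant-
#' difference test over all pairs. Significance letters follow the
#' convention of marking, for each allele, a significant difference
#' (adjusted p < 0.05) versus *4 as "a", versus *5 as "b" and versus *6 as
#' "c". Groups with zero residual variance are handled by exact comparison
#' (p = 1 for identical means, p = 0 otherwise) with a warning.
#'
#' @param groups Named list mapping allele name to a numeric vector of
#'   per-replicate values (each of length >= 2; >= 2 groups).
#' @param alpha Significance level for the letters.
#' @return List with `p_values` (data frame: pair, diff, p_adj) and
#'   `letters` (named character vector per allele).
#' @export
compare_alleles_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2) {
    stop("need a named list of at least 2 allele groups")
  }
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 replicates")
  df <- data.frame(
    allele = factor(rep(names(groups), lengths(groups)), levels = names(groups)),
    value = unlist(groups, use.names = FALSE)
  )
  fit <- stats::aov(value ~ allele, data = df)
  resid_ss <- sum(stats::residuals(fit)^2)
  total_ss <- sum((df$value - mean(df$value))^2)
  if (resid_ss <= 1e-12 * max(total_ss, 1)) {
    warning("zero within-group variance; p-values from exact mean comparison")
    means <- vapply(groups, mean, numeric(1))
    pairs <- utils::combn(names(groups), 2)
    p <- ifelse(means[pairs[1, ]] == means[pairs[2, ]], 1, 0)
    pv <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = means[pairs[2, ]] - means[pairs[1, ]],
                     p_adj = as.numeric(p), stringsAsFactors = FALSE)
  } else {
    tk <- stats::TukeyHSD(fit)$allele
    pv <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  }
  rownames(pv) <- NULL
  # each row is marked only against the reference alleles preceding it in
  # the allele order: "a" vs *4, "b" vs *5, "c" vs *6
  letters_for <- c("*4" = "a", "*5" = "b", "*6" = "c")
  grp_order <- names(groups)
  letts <- vapply(grp_order, function(al) {
    marks <- vapply(names(letters_for), function(ref) {
      if (al == ref || !ref %in% grp_order) return("")
      if (match(ref, grp_order) > match(al, grp_order)) return("")
      hit <- pv$pair %in% c(paste(al, ref, sep = "-"), paste(ref, al, sep = "-"))
      if (any(hit) && any(pv$p_adj[hit] < alpha, na.rm = TRUE)) letters_for[[ref]] else ""
    }, character(1))
    paste(marks, collapse = "")
  }, character(1))
  list(p_values = pv, letters = letts)
}
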