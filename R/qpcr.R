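#' Fit qPCR amplification efficiency from a dilution series
#'
#' Mean Ct values are regressed on log10 of input amount; the amplification
#' efficiency is `E = 10^(-1/m)` where `m` is the least-squares slope in
#' cycles per decade. Perfect doubling chemistry gives m = -1/log10(2)
#' (about -3.32) and E = 2. Zero-concentration points are excluded before
#' fitting. A non-negative slope indicates an implausible assay and triggers
#' a warning, not an error, so screening runs can proceed.
#'
#' @param concentrations Input amounts (e.g. ng); must include >= 3 distinct
#'   positive values.
#' @param ct_values Mean cycle-threshold per concentration.
#' @return An object of class `standard_curve`: a list with `slope`,
#'   `efficiency`, `intercept` and `r_squared`.
#' @export
fit_efficiency <- function(concentrations, ct_values) {
  if (length(concentrations) != length(ct_values)) {
    stop("concentrations and ct_values must have equal length")
  }
  keep <- is.finite(concentrations) & concentrations > 0 &
    is.finite(ct_values)
  conc <- concentrations[keep]
  ct <- ct_values[keep]
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct positive concentrations")
  }
  fit <- stats::lm(ct ~ log10(conc))
  m <- unname(stats::coef(fit)[2])
  if (m >= 0) warning("non-negative slope (", signif(m, 3),
                      "): implausible assay")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  out <- list(slope = m, efficiency = 10^(-1 / m),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f cycles/decade, E = %.4f (R2 %.4f)\n",
              x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Efficiency-corrected expression fold change (Pfaffl)
#'
#' `FC = E_target^dCt_target / E_ref^dCt_ref` with `dCt = Ct_control -
#' Ct_case` for both the target and the reference assay. The sign convention
#' is anchored by: fold change > 1 exactly when the target amplifies earlier
#' (lower Ct) in the case sample, relative to the reference gene. Replicate
#' Cts should be averaged before calling.
#'
#' @param ct_target_ctrl,ct_target_case Target-assay Cts in control and case.
#' @param ct_ref_ctrl,ct_ref_case Reference-assay Cts in control and case.
#' @param e_target,e_ref Amplification efficiencies (> 1).
#' @return The linear fold change.
#' @export
expression_fc <- function(ct_target_ctrl, ct_target_case,
                          ct_ref_ctrl, ct_ref_case, e_target, e_ref) {
  check_efficiency(e_target, e_ref)
  d_tar <- ct_target_ctrl - ct_target_case
  d_ref <- ct_ref_ctrl - ct_ref_case
  e_target^d_tar / e_ref^d_ref
}

#' ChIP enrichment fold change (Pfaffl variant)
#'
#' The input-normalised enrichment of a target region over a control region:
#' `dCt = Ct_input - Ct_ChIP` for each region, and
#' `FC = E_target^dCt_target / E_ref^dCt_ref`. Enrichment > 1 exactly when
#' the target region amplifies earlier in the ChIP material (relative to its
#' input) than the control region does. With both efficiencies equal to 2
#' this reduces to the familiar `2^(dCt_target - dCt_ref)` (delta-delta-Ct).
#'
#' @param ct_input_tar,ct_chip_tar Target-region Cts in input and ChIP.
#' @param ct_input_ref,ct_chip_ref Control-region Cts in input and ChIP.
#' @param e_tar,e_ref Amplification efficiencies (> 1).
#' @return The enrichment fold change.
#' @export
chip_enrichment_fc <- function(ct_input_tar, ct_chip_tar,
                               ct_input_ref, ct_chip_ref, e_tar, e_ref) {
  check_efficiency(e_tar, e_ref)
  d_tar <- ct_input_tar - ct_chip_tar
  d_ref <- ct_input_ref - ct_chip_ref
  e_tar^d_tar / e_ref^d_ref
}

check_efficiency <- function(...) {
  e <- c(...)
  if (any(!is.finite(e)) || any(e <= 1)) {
    stop("amplification efficiencies must be > 1")
  }
  invisible(TRUE)
}

#' ChIP enrichment per region from a Ct table
#'
#' Averages replicate Cts per (region, condition), then computes the Pfaffl
#' variant enrichment of each region relative to the named reference region.
#' Zero or non-finite Cts are treated as missing (undetermined wells), never
#' as Ct = 0.
#'
#' @param ct_table data.frame with columns `region`, `condition` ("input" or
#'   "chip"), `ct` and `efficiency`.
#' @param reference Name of the control region.
#' @return A data.frame with columns `region`, `dct` and `fold_change`,
#'   excluding the reference region itself.
#' @export
chip_enrichment_table <- function(ct_table, reference) {
  need <- c("region", "condition", "ct", "efficiency")
  stopifnot(all(need %in% names(ct_table)))
  if (!reference %in% ct_table$region) {
    stop("reference region not in table: ", reference)
  }
  ct_table$ct[!is.finite(ct_table$ct) | ct_table$ct <= 0] <- NA_real_
  agg <- stats::aggregate(ct ~ region + condition, data = ct_table,
                          FUN = mean, na.action = stats::na.omit)
  eff <- tapply(ct_table$efficiency, ct_table$region, function(x) x[1])
  wide <- stats::reshape(agg, idvar = "region", timevar = "condition",
                         direction = "wide")
  dct <- wide$ct.input - wide$ct.chip
  names(dct) <- wide$region
  regions <- setdiff(names(dct), reference)
  fc <- vapply(regions, function(r) {
    chip_enrichment_fc(0, -dct[[r]], 0, -dct[[reference]],
                       eff[[r]], eff[[reference]])
  }, numeric(1))
  data.frame(region = regions, dct = as.numeric(dct[regions]),
             fold_change = as.numeric(fc), row.names = NULL,
             stringsAsFactors = FALSE)
}
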