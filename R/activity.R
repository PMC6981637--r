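#' Load the packaged cholinesterase activity table
#'
#' IC50 values (micromolar) for the compounds whose potencies were published
#' numerically: 5n against both enzymes, 6aa against BChE, and the
#' galantamine reference against BChE. An IC50 back-calculated from a
#' published selectivity index rather than measured directly is flagged in
#' the `derived` column; all other compounds are absent rather than imputed.
#'
#' @param path Optional path to an activity TSV (`compound`, `target`,
#'   `ic50_uM`, `sem_uM`, `derived`); defaults to the packaged table.
#' @return data.frame, one row per (compound, target) measurement.
#' @export
activity_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "activity.tsv", package = "thqche",
                        mustWork = TRUE)
  act <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(act$ic50_uM <= 0, na.rm = TRUE))
    stop("IC50 values must be positive", call. = FALSE)
  act
}

#' Selectivity index
#'
#' SI = IC50(BChE) / IC50(AChE). Values above 1 mean the compound is
#' AChE-selective (it takes more of it to inhibit BChE); values below 1 mean
#' BChE-selective.
#'
#' @param ic50_bche,ic50_ache Positive IC50 values in the same units.
#' @return Unitless ratio (unrounded; display at two decimals).
#' @examples
#' selectivity_index(22.00, 4.24)  # 5.19
#' @export
selectivity_index <- function(ic50_bche, ic50_ache) {
  if (any(ic50_bche <= 0) || any(ic50_ache <= 0))
    stop("IC50 values must be positive", call. = FALSE)
  ic50_bche / ic50_ache
}

#' Gas constant in kcal/(mol K)
#' @keywords internal
R_KCAL <- 1.987e-3

#' Convert an IC50 to an apparent binding free energy
#'
#' Uses the approximation Ki ~ IC50, giving dG = RT ln(IC50) with IC50 in
#' molar units and R = 1.987e-3 kcal/(mol K). More negative means more
#' potent; a 10-fold potency gain lowers dG by RT ln 10 (about 1.36 kcal/mol
#' at 298.15 K). This experimental scale is what consensus pose selection
#' correlates predicted energies against; only relative ordering matters
#' there, so the Ki ~ IC50 approximation is inconsequential.
#'
#' @param ic50 IC50 in molar concentration (e.g. `4.24e-6` for 4.24 uM).
#' @param temperature Temperature in K (default 298.15).
#' @return List with `dg` (kcal/mol) and `temperature` (K).
#' @examples
#' ic50_to_dg(4.24e-6)$dg  # about -7.33
#' @export
ic50_to_dg <- function(ic50, temperature = 298.15) {
  if (any(ic50 <= 0)) stop("ic50 must be positive", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  list(dg = R_KCAL * temperature * log(ic50), temperature = temperature)
}

#' Rule-of-five screen
#'
#' Flags the classical oral-drug-likeness violations on supplied descriptor
#' values (descriptors are inputs, not computed): molecular weight > 500,
#' logP > 5, hydrogen-bond donors > 5, hydrogen-bond acceptors > 10. All
#' comparisons are strict, so boundary values do not violate.
#'
#' @param mw Molecular weight, g/mol.
#' @param logp Octanol/water partition coefficient.
#' @param hb_donors,hb_acceptors Hydrogen-bond donor/acceptor counts
#'   (non-negative; fractional counts as produced by descriptor averaging
#'   are accepted).
#' @return Character vector of violation labels (empty when compliant),
#'   among `"MW>500"`, `"logP>5"`, `"HBD>5"`, `"HBA>10"`.
#' @examples
#' rule_of_five(502.396, 4.0, 0, 8)  # "MW>500"
#' @export
rule_of_five <- function(mw, logp, hb_donors, hb_acceptors) {
  vals <- c(mw, logp, hb_donors, hb_acceptors)
  if (any(!is.finite(vals))) stop("descriptors must be finite", call. = FALSE)
  if (hb_donors < 0 || hb_acceptors < 0)
    stop("hydrogen-bond counts must be non-negative", call. = FALSE)
  out <- character(0)
  if (mw > 500) out <- c(out, "MW>500")
  if (logp > 5) out <- c(out, "logP>5")
  if (hb_donors > 5) out <- c(out, "HBD>5")
  if (hb_acceptors > 10) out <- c(out, "HBA>10")
  out
}

#' Experimental free energies for a set of compounds
#'
#' Convenience join: converts the activity table's IC50 values for one
#' target into dG (kcal/mol) keyed by compound id.
#'
#' @param target `"AChE"` or `"BChE"`.
#' @param activity Activity data.frame as from [activity_table()].
#' @param temperature K.
#' @return Named numeric vector of dG values.
#' @export
dg_experimental <- function(target = c("AChE", "BChE"),
                            activity = activity_table(),
                            temperature = 298.15) {
  target <- match.arg(target)
  sub <- activity[activity$target == target & !is.na(activity$ic50_uM), ]
  stats::setNames(ic50_to_dg(sub$ic50_uM * 1e-6, temperature)$dg, sub$compound)
}
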