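#' Atomic mass tables
#'
#' Element mass tables backing all formula arithmetic. `average` holds the
#' IUPAC 2021 conventional standard atomic weights (g/mol); `monoisotopic`
#' holds the exact mass of the principal (most abundant) isotope in Da, with
#' carbon fixed at exactly 12 by definition. Only the elements occurring in
#' the supported compound chemistry (and their common ESI adduct cations) are
#' tabulated: C, H, N, O, F, Cl, Br, Na, K, S.
#'
#' @return Named list with numeric vectors `average` and `monoisotopic`,
#'   both keyed by element symbol, plus `electron` (electron mass in Da,
#'   tabulated for reference; adduct m/z arithmetic neglects it).
#' @examples
#' mass_tables()$monoisotopic[["C"]]  # exactly 12
#' @export
mass_tables <- function() {
  list(
    average = c(
      C = 12.011, H = 1.008, N = 14.007, O = 15.999,
      F = 18.998403163, Cl = 35.45, Br = 79.904,
      Na = 22.98976928, K = 39.0983, S = 32.06
    ),
    monoisotopic = c(
      C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
      F = 18.99840316273, Cl = 34.968852682, Br = 78.9183376,
      Na = 22.9897692809, K = 38.9637064864, S = 31.97207100
    ),
    electron = 0.000548579909
  )
}

#' Element symbols accepted in molecular formulas
#' @return Character vector of allowed element symbols.
#' @keywords internal
allowed_elements <- function() names(mass_tables()$average)
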