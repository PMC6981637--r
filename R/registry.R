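#' Load the THQ hybrid compound registry
#'
#' Returns the packaged registry of the 44 THQ-isoxazoline (series 5,
#' 16 compounds, two stereocenters each) and THQ-isoxazole (series 6,
#' 28 compounds, one stereocenter each) hybrids, transcribed from the
#' series' published experimental characterization data. Columns: compound
#' `id`, `series` (5 or 6), `r1_c6` (substituent at THQ C-6), `r5_c8`
#' (H, or Cl for the four 8'-chloro compounds 6f/6j/6o/6s), `aryl`
#' (C-3 aryl pattern), `formula` (Hill string), `n_stereocenters`,
#' `yield_pct`, `state`, and `esi_mh_mz` (the reported nominal `[M+H]+`
#' m/z where one was published, else NA).
#'
#' @param path Optional path to a registry TSV with the same columns;
#'   defaults to the packaged table.
#' @return A data.frame, one row per compound.
#' @examples
#' nrow(thq_registry())  # 44
#' @export
thq_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_registry.tsv", package = "thqche",
                        mustWork = TRUE)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(esi_mh_mz = "integer"))
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  req <- c("id", "series", "r1_c6", "r5_c8", "aryl", "formula",
           "n_stereocenters", "yield_pct", "state", "esi_mh_mz")
  miss <- setdiff(req, names(reg))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(reg$id)) stop("duplicate compound ids in registry", call. = FALSE)
  if (sum(reg$series == 5) != 16L || sum(reg$series == 6) != 28L)
    stop("registry must hold exactly 16 series-5 and 28 series-6 records", call. = FALSE)
  if (!all(reg$n_stereocenters[reg$series == 5] == 2L) ||
      !all(reg$n_stereocenters[reg$series == 6] == 1L))
    stop("series 5 records carry 2 stereocenters, series 6 records 1", call. = FALSE)
  cl8 <- sort(reg$id[reg$r5_c8 == "Cl"])
  if (!identical(cl8, sort(c("6f", "6j", "6o", "6s"))))
    stop("C-8 chloro substitution is restricted to 6f, 6j, 6o, 6s", call. = FALSE)
  invisible(lapply(reg$formula, parse_formula))  # every formula must parse
  invisible(reg)
}

#' Known discrepancies in the transcribed registry source
#'
#' Published characterization values that are internally inconsistent
#' (e.g. an `[2M+Na]+` m/z that does not equal 2M+23) are recorded here
#' rather than silently corrected or skipped. Tests consult this table to
#' whitelist the affected records.
#'
#' @return data.frame with columns `compound`, `quantity`, `reported`,
#'   `computed`, `note`.
#' @export
known_discrepancies <- function() {
  utils::read.delim(
    system.file("extdata", "known_discrepancies.tsv", package = "thqche",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Count stereoisomers per compound and in total
#'
#' Each record contributes `2^n_stereocenters` stereoisomers (no meso forms
#' exist in this chemotype: the two series-5 centers are independent). For
#' the full 44-compound registry the total is 120 -- the number of discrete
#' ligand structures enumerated for docking when scaffold chirality is
#' unknown.
#'
#' @param records Registry data.frame (default: the packaged registry) with
#'   columns `id` and `n_stereocenters` (each 1 or 2).
#' @return List with `per_record` (data.frame of `id`, `n_stereoisomers`)
#'   and `total`.
#' @examples
#' count_stereoisomers()$total  # 120
#' @export
count_stereoisomers <- function(records = thq_registry()) {
  n <- records$n_stereocenters
  if (!all(n %in% c(1L, 2L)))
    stop("n_stereocenters must be 1 or 2", call. = FALSE)
  per <- data.frame(id = records$id, n_stereoisomers = 2L ^ n)
  list(per_record = per, total = sum(per$n_stereoisomers))
}
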