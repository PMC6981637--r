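#' Parse a molecular formula string
#'
#' Parses a concatenation of element symbols with optional integer counts
#' (e.g. `"C23H25N3O2"`, `"H2O"`) into a `molecular_formula` object: a named
#' integer vector of per-element counts. An omitted count means 1. Only the
#' elements listed by [allowed_elements()] are accepted, and all counts must
#' be strictly positive.
#'
#' @param text Formula string.
#' @return A `molecular_formula`: named integer vector of counts, stored in
#'   Hill order (C, H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C23H25N3O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  rx <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  toks <- regmatches(text, gregexpr(rx, text, perl = TRUE))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("unparseable formula text: '", text, "'", call. = FALSE)
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Z][a-z]?", "", toks)
  bad <- setdiff(sym, allowed_elements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cnt <- ifelse(nzchar(num), suppressWarnings(as.integer(num)), 1L)
  if (anyNA(cnt) || any(cnt <= 0L))
    stop("element counts must be positive integers (got '", text, "')", call. = FALSE)
  counts <- tapply(cnt, sym, sum)
  new_formula(stats::setNames(as.integer(counts), names(counts)))
}

# constructor: validates and imposes Hill order
new_formula <- function(counts) {
  stopifnot(is.integer(counts), !is.null(names(counts)))
  bad <- setdiff(names(counts), allowed_elements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(counts <= 0L)) stop("all element counts must be >= 1", call. = FALSE)
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "molecular_formula")
}

hill_order <- function(sym) {
  rest <- sort(setdiff(sym, c("C", "H")))
  match(c(intersect(c("C", "H"), sym), rest), sym)
}

#' @export
format.molecular_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Combine two formulas by element-wise addition
#'
#' @param f1,f2 `molecular_formula` objects.
#' @return Their multiset union as a `molecular_formula`.
#' @export
formula_add <- function(f1, f2) {
  all_el <- union(names(f1), names(f2))
  counts <- stats::setNames(integer(length(all_el)), all_el)
  counts[names(f1)] <- counts[names(f1)] + unclass(f1)
  counts[names(f2)] <- counts[names(f2)] + unclass(f2)
  new_formula(counts)
}

#' Subtract a sub-formula
#'
#' @param f A `molecular_formula`.
#' @param x Sub-formula to remove; every element count of `x` must be covered
#'   by `f`, and the difference must be non-empty.
#' @return `f` minus `x` as a `molecular_formula`.
#' @export
formula_subtract <- function(f, x) {
  if (!is_subformula(x, f))
    stop("'", format(x), "' is not a sub-formula of '", format(f), "'", call. = FALSE)
  counts <- stats::setNames(as.integer(unclass(f)), names(f))
  counts[names(x)] <- counts[names(x)] - unclass(x)
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("subtraction leaves an empty formula", call. = FALSE)
  new_formula(counts)
}

is_subformula <- function(x, f) {
  all(names(x) %in% names(f)) && all(unclass(x) <= unclass(f)[names(x)])
}

as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) f else parse_formula(f)
}

#' Average (standard atomic weight) molecular mass
#'
#' Sum of per-element count times the conventional standard atomic weight.
#' Values agree with published "average MW" figures to about 0.01 g/mol;
#' third-decimal differences can arise from atomic-weight table revisions.
#'
#' @param f A `molecular_formula` or formula string.
#' @return Mass in g/mol.
#' @examples
#' average_mass("C23H25N3O2")  # 375.47
#' @export
average_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * mass_tables()$average[names(f)])
}

#' Monoisotopic molecular mass
#'
#' Sum of per-element count times the exact mass of the principal isotope.
#' Matches high-resolution "Anal. Calcd." values at 4-decimal display
#' precision.
#'
#' @inheritParams average_mass
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C26H28BrN3O5")  # 541.1212
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * mass_tables()$monoisotopic[names(f)])
}

#' Elemental mass percentages
#'
#' Per-element percentage of the average molecular mass, as reported by
#' combustion elemental analysis ("Anal. Calcd.").
#'
#' @inheritParams average_mass
#' @return Named numeric vector of percentages (unrounded; display at two
#'   decimals). Sums to 100 within rounding.
#' @examples
#' round(elemental_percentages("C23H25N3O2"), 2)  # C 73.57, H 6.71, N 11.19
#' @export
elemental_percentages <- function(f) {
  f <- as_formula(f)
  w <- unclass(f) * mass_tables()$average[names(f)]
  stats::setNames(100 * w / sum(w), names(f))
}

#' Electrospray adduct m/z
#'
#' Exact and nominal m/z for the common positive-mode ESI adducts of a
#' neutral molecule M: `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[2M+Na]+`, and the
#' in-source fragment `[M-X+H]+` for a neutral-loss sub-formula X. The
#' electron mass (0.00055 Da) is neglected, which is below 4-decimal display
#' precision. Nominal m/z is the exact value rounded to the nearest integer.
#'
#' @param f Neutral molecule as `molecular_formula` or string.
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"`, `"[2M+Na]+"`,
#'   `"[M-X+H]+"`.
#' @param fragment For `"[M-X+H]+"` only: the lost sub-formula X
#'   (`molecular_formula` or string).
#' @return List with `adduct`, `exact` (Da) and `nominal` (integer).
#' @examples
#' adduct_mz("C23H25N3O2", "[M+H]+")$nominal  # 376
#' @export
adduct_mz <- function(f, adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[2M+Na]+", "[M-X+H]+"),
                      fragment = NULL) {
  f <- as_formula(f)
  adduct <- match.arg(adduct)
  mono <- mass_tables()$monoisotopic
  m <- monoisotopic_mass(f)
  exact <- switch(adduct,
    "[M+H]+"   = m + mono[["H"]],
    "[M+Na]+"  = m + mono[["Na"]],
    "[M+K]+"   = m + mono[["K"]],
    "[2M+Na]+" = 2 * m + mono[["Na"]],
    "[M-X+H]+" = {
      if (is.null(fragment))
        stop("adduct [M-X+H]+ requires a 'fragment' formula", call. = FALSE)
      monoisotopic_mass(formula_subtract(f, as_formula(fragment))) + mono[["H"]]
    }
  )
  list(adduct = adduct, exact = unname(exact), nominal = as.integer(round(exact)))
}
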