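## Monoisotopic mass arithmetic: element table, formula parser, ESI adducts.
## Offsets follow the usual unit-charge conventions; the 13C-12C spacing is
## 1.003355 Da and one feature charge is assumed throughout (TOF peak tables
## here are singly charged after deconvolution).

#' @rdname adduct_mz
#' @format NULL
#' @export
ELEMENT_MASSES <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.96885271, F = 18.99840320
)

PROTON_MASS   <- 1.007276
NA_ADDUCT     <- 22.989218   # +Na -e
K_ADDUCT      <- 38.963158   # +K  -e
NA_MINUS_2H   <- 20.974666   # +Na -2H (negative mode)
K_MINUS_2H    <- 36.948606   # +K  -2H (negative mode)
C13_SPACING   <- 1.003355

#' Monoisotopic mass of a molecular formula
#'
#' @param formula character like "C8H10N4O2" (element symbols with optional
#'   counts; no parentheses/charges).
#' @return neutral monoisotopic mass in Da.
#' @export
#' @examples
#' formula_mass("C8H10N4O2")  # caffeine, 194.080376
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(parts) || paste(parts, collapse = "") != f)
      .fail("cannot parse molecular formula '%s'", f)
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      nc <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(nc)) as.integer(nc) else 1L
      if (!el %in% names(ELEMENT_MASSES))
        .fail("unknown element '%s' in formula '%s'", el, f)
      total <- total + ELEMENT_MASSES[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Adduct ion m/z values for a neutral mass
#'
#' Positive mode generates \[M+H\]+, \[M+Na\]+ and \[M+K\]+; negative mode
#' \[M-H\]-, \[M+Na-2H\]- and \[M+K-2H\]- (bare Na/K adducts carry no charge
#' in negative mode, so the charge-consistent minus-2H forms are used).
#' Optionally the first 13C isotopologue of each ion (+1.003355) is added,
#' as needed for drug-ion screening.
#'
#' @param neutral_mass neutral monoisotopic mass (Da), positive.
#' @param mode `"positive"` or `"negative"`.
#' @param isotopologues if `TRUE`, append the first 13C isotopologue of each
#'   adduct.
#' @return named numeric vector of ion m/z values.
#' @export
#' @examples
#' adduct_mz(194.080376, "positive")  # caffeine [M+H]+ = 195.087652
adduct_mz <- function(neutral_mass, mode = c("positive", "negative"),
                      isotopologues = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(neutral_mass) || neutral_mass <= 0)
    .fail("neutral_mass must be positive")
  ions <- if (mode == "positive") {
    c("[M+H]+"  = neutral_mass + PROTON_MASS,
      "[M+Na]+" = neutral_mass + NA_ADDUCT,
      "[M+K]+"  = neutral_mass + K_ADDUCT)
  } else {
    c("[M-H]-"     = neutral_mass - PROTON_MASS,
      "[M+Na-2H]-" = neutral_mass + NA_MINUS_2H,
      "[M+K-2H]-"  = neutral_mass + K_MINUS_2H)
  }
  if (isotopologues) {
    iso <- ions + C13_SPACING
    names(iso) <- paste0(names(ions), " 13C")
    ions <- c(ions, iso)
  }
  ions
}
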