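## Cerebral oximetry derivations.  SaO2 is the arterial (or preductal
## pulse-oximetry) saturation, ScO2/rcSO2 the NIRS regional cerebral tissue
## saturation.  Cerebral oxygen extraction CEO2 = SaO2 - ScO2 (ScO2 being
## close to venous saturation) and FTOE = CEO2 / SaO2.  Both saturations
## must be on the same scale (fraction or percent); FTOE is dimensionless
## either way.

.is_fraction <- function(x) all(x <= 1)
.is_percent <- function(x) any(x > 1)

#' Cerebral oxygen extraction
#'
#' `CEO2 = SaO2 - ScO2`.  Inputs must share a scale (both fractions in
#' (0, 1] or both percentages); a mix raises an error.  Negative CEO2
#' (tissue saturation above arterial) is physiologically noisy but kept, and
#' flagged via attribute `negative`.
#'
#' @param sao2 arterial / preductal oxygen saturation.
#' @param sco2 regional cerebral tissue oxygen saturation (rcSO2).
#' @return CEO2 on the input scale.
#' @export
#' @examples
#' compute_ceo2(85.6, 50.0)  # 35.6
compute_ceo2 <- function(sao2, sco2) {
  if (!length(sao2) || length(sao2) != length(sco2))
    .fail("sao2 and sco2 must have equal positive length")
  if (any(sao2 <= 0)) .fail("sao2 must be > 0")
  one_scale <- (.is_fraction(sao2) && .is_fraction(sco2)) ||
    (.is_percent(sao2) && .is_percent(sco2))
  if (!one_scale)
    .fail("sao2 and sco2 are on different scales (fraction vs percent)")
  ceo2 <- sao2 - sco2
  if (any(ceo2 < 0)) attr(ceo2, "negative") <- which(ceo2 < 0)
  ceo2
}

#' Fractional tissue oxygen extraction
#'
#' `FTOE = CEO2 / SaO2`, dimensionless and invariant under joint rescaling
#' of the saturations (percent vs fraction).
#'
#' @param ceo2 cerebral oxygen extraction (same scale as `sao2`).
#' @param sao2 arterial saturation, strictly positive.
#' @return FTOE.
#' @export
#' @examples
#' compute_ftoe(35.6, 85.6)  # 0.4158878...
compute_ftoe <- function(ceo2, sao2) {
  if (any(sao2 == 0)) .fail("sao2 must be nonzero")
  c(ceo2) / c(sao2)
}

#' Derive CEO2 and FTOE columns for a clinical sheet
#'
#' @param clinical data.frame with columns `patient_id`, `timepoint`,
#'   `sao2`, `sco2` (consistent scale).
#' @return the sheet with `ceo2`, `ftoe` and a `ceo2_negative` flag appended.
#' @export
derive_oximetry <- function(clinical) {
  need <- c("patient_id", "timepoint", "sao2", "sco2")
  if (!all(need %in% names(clinical)))
    .fail("clinical sheet needs columns %s", paste(need, collapse = ", "))
  ceo2 <- compute_ceo2(clinical$sao2, clinical$sco2)
  clinical$ceo2 <- c(ceo2)
  clinical$ftoe <- compute_ftoe(c(ceo2), clinical$sao2)
  clinical$ceo2_negative <- clinical$ceo2 < 0
  clinical
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks are used for ties.  For n <= 8 the two-sided p-value is
#' computed by exhaustive enumeration of all n! permutations of one margin
#' (probability of |rho| at least as extreme as observed); for larger n the
#' usual t approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairwise complete
#'   observations are used).
#' @return list with `rho`, `p`, `n`, and `flag` (`"constant"` when a margin
#'   has no variance, in which case rho and p are NA).
#' @export
spearman_assoc <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n)
    .fail("spearman_assoc() needs equal-length vectors with n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant"))
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- .all_permutations(n)
    ## rho for every permutation of the y ranks, same tie pattern
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    rho_null <- (matrix(ry_c[perms], nrow = nrow(perms)) %*% rx_c) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n, flag = NA_character_)
}

## all permutations of 1..n as a (n! x n) matrix, lexicographic
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * nrow(sub) + 1L):(k * nrow(sub))
    rest <- seq_len(n)[-k]
    out[rows, 1L] <- k
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}
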