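# Free / bioavailable testosterone from the two-binding-site equilibrium.
#
# Total testosterone partitions between the free pool, an albumin-bound pool
# (association lumped into the constant 0.5217 per g/L of albumin) and an
# SHBG-bound pool (1:1 binding, association constant 1 per nM in these
# units).  Mass balance:
#
#   T = (1 + 0.5217 A) FT + S * FT / (1 + FT)
#
# whose positive root is the closed form implemented in free_testosterone().

ALBUMIN_BINDING <- 0.5217  # per g/L albumin, unit-specific; do not rescale

#' Free testosterone from total testosterone, SHBG and albumin
#'
#' Computes free testosterone (FT, nM) as the positive root of the
#' two-binding-site equilibrium between testosterone, albumin and sex
#' hormone binding globulin (SHBG):
#' \deqn{FT = \frac{T - 0.5217A - S - 1 + \sqrt{(0.5217A + 1 + S - T)^2
#'   + 4T(0.5217A + 1)}}{2(0.5217A + 1)}}
#' Units are enforced: total testosterone and SHBG in nmol/L, albumin in
#' g/L.  The binding constant 0.5217 is specific to these units.
#'
#' @param total_t Total testosterone, nM (vector).
#' @param shbg SHBG, nM (vector, recycled).
#' @param albumin Albumin, g/L (vector, recycled).
#' @return Free testosterone in nM, clipped to `[0, total_t]`.
#' @examples
#' free_testosterone(11.96, 39.93, 45.53)  # ~0.21 nM
#' @export
free_testosterone <- function(total_t, shbg, albumin) {
  n <- max(length(total_t), length(shbg), length(albumin))
  total_t <- rep_len(total_t, n)
  shbg <- rep_len(shbg, n)
  albumin <- rep_len(albumin, n)
  bad <- !is.na(total_t) & !is.na(shbg) & !is.na(albumin) &
    (total_t < 0 | shbg < 0 | albumin < 0)
  if (any(bad)) {
    stop("free_testosterone: inputs must be non-negative (nM, nM, g/L)")
  }
  a <- ALBUMIN_BINDING * albumin
  disc <- (a + 1 + shbg - total_t)^2 + 4 * total_t * (a + 1)
  stopifnot(all(disc >= 0, na.rm = TRUE))
  ft <- (total_t - a - shbg - 1 + sqrt(disc)) / (2 * (a + 1))
  # guard rounding at extreme inputs; tolerance 1e-12
  ft <- pmin(pmax(ft, 0), total_t + 1e-12)
  pmin(ft, total_t)
}

#' Bioavailable testosterone from free testosterone and albumin
#'
#' Bioavailable testosterone (BAT) is the free plus albumin-bound pool:
#' \eqn{BAT = FT (1 + 0.5217 A)}.
#'
#' @param free_t Free testosterone, nM.
#' @param albumin Albumin, g/L.
#' @return Bioavailable testosterone, nM.
#' @export
bioavailable_testosterone <- function(free_t, albumin) {
  n <- max(length(free_t), length(albumin))
  free_t <- rep_len(free_t, n)
  albumin <- rep_len(albumin, n)
  bad <- !is.na(free_t) & !is.na(albumin) & (free_t < 0 | albumin < 0)
  if (any(bad)) stop("bioavailable_testosterone: inputs must be non-negative")
  free_t * (1 + ALBUMIN_BINDING * albumin)
}

#' Apply an assay detection floor
#'
#' Values below the minimum detectable limit are recoded to the limit
#' itself, mirroring how immunoassay results at the detection boundary are
#' usually reported.  The default of 0.35 nM is the detection limit of the
#' one-step competitive testosterone assay this package models.
#'
#' @param values Numeric vector of assay values (nM); NAs pass through.
#' @param floor Detection limit, must be > 0. Default 0.35 nM.
#' @return The floored vector, with attribute `n_floored` giving the number
#'   of replaced values.
#' @export
apply_detection_floor <- function(values, floor = 0.35) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  repl <- !is.na(values) & values < floor
  values[repl] <- floor
  structure(values, n_floored = sum(repl))
}

#' Derive free and bioavailable testosterone columns on a phenotype table
#'
#' Applies the detection floor to total testosterone, then adds `free_t`
#' and `bioavailable_t` columns derived from `total_t`, `shbg` and
#' `albumin`.  The floor is applied to the assay value before derivation.
#'
#' @param phenotypes Data frame with columns `total_t`, `shbg`, `albumin`.
#' @param floor Detection floor for total testosterone (nM).
#' @return The data frame with `total_t` floored and `free_t`,
#'   `bioavailable_t` columns added.
#' @export
derive_hormones <- function(phenotypes, floor = 0.35) {
  stopifnot(all(c("total_t", "shbg", "albumin") %in% names(phenotypes)))
  tt <- apply_detection_floor(phenotypes$total_t, floor)
  phenotypes$total_t <- as.numeric(tt)
  phenotypes$free_t <- free_testosterone(
    phenotypes$total_t, phenotypes$shbg, phenotypes$albumin
  )
  phenotypes$bioavailable_t <- bioavailable_testosterone(
    phenotypes$free_t, phenotypes$albumin
  )
  attr(phenotypes, "n_floored") <- attr(tt, "n_floored")
  phenotypes
}

# Inverse map used by the simulator: given BAT, SHBG and albumin, the total
# testosterone consistent with the equilibrium is
#   T = BAT + S * FT / (1 + FT),  FT = BAT / (1 + 0.5217 A).
total_from_bioavailable <- function(bat, shbg, albumin) {
  ft <- bat / (1 + ALBUMIN_BINDING * albumin)
  bat + shbg * ft / (1 + ft)
}
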