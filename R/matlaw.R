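#' Density-based HU to Young's modulus law
#'
#' The femur material chain used for subject-specific mapping: ash density
#' from attenuation, `rho_ash = -0.009 + 0.0007 * HU` (g/cm^3); apparent
#' density `rho_app = rho_ash / 0.6`; and the femoral power law
#' `E = 6950 * rho_app^1.49` (MPa). Negative ash densities (air, marrow)
#' clamp to zero before the power, and the returned modulus never drops
#' below `E_floor`, which keeps the assembled stiffness matrix positive
#' definite.
#'
#' @param ash_intercept,ash_slope HU to ash-density affine coefficients,
#'   g/cm^3 and g/cm^3 per HU.
#' @param ash_to_app_divisor ash-to-apparent density divisor.
#' @param E_coeff,E_exponent power-law coefficient (MPa) and exponent.
#' @param E_floor minimum returned modulus, MPa.
#' @return an object of class `density_modulus_law`.
#' @examples
#' hu_to_modulus(1500, density_modulus_law())  # ~15.8 GPa cortical bone
#' @export
density_modulus_law <- function(ash_intercept = -0.009, ash_slope = 0.0007,
                                ash_to_app_divisor = 0.6,
                                E_coeff = 6950, E_exponent = 1.49,
                                E_floor = 0.01) {
  if (ash_to_app_divisor <= 0) stopf("ash_to_app_divisor must be > 0")
  if (E_coeff <= 0) stopf("E_coeff must be > 0")
  if (E_floor < 0) stopf("E_floor must be >= 0")
  structure(list(
    ash_intercept = ash_intercept, ash_slope = ash_slope,
    ash_to_app_divisor = ash_to_app_divisor,
    E_coeff = E_coeff, E_exponent = E_exponent, E_floor = E_floor
  ), class = c("density_modulus_law", "hu_law"))
}

#' ScanIP-default HU to Young's modulus law
#'
#' The affine default of the commercial volume-averaging route: mineral
#' density `rho = 1.31e-10 + 1.067e-12 * HU` followed by
#' `E = -331 + 4.56e12 * rho` (MPa). Only the composition of the two
#' affine maps is observable, so the density constants are kept exactly as
#' printed. Values below `E_floor` clamp to it.
#'
#' @param rho_intercept,rho_slope HU to mineral-density coefficients.
#' @param E_intercept,E_slope density to modulus coefficients (MPa).
#' @param E_floor minimum returned modulus, MPa.
#' @param n_bins default bin count for piecewise (binned) assignment.
#' @return an object of class `scanip_law`.
#' @examples
#' hu_to_modulus(0, scanip_law())  # ~266 MPa
#' @export
scanip_law <- function(rho_intercept = 1.31e-10, rho_slope = 1.067e-12,
                       E_intercept = -331, E_slope = 4.56e12,
                       E_floor = 0.01, n_bins = 8L) {
  if (n_bins < 1) stopf("n_bins must be >= 1")
  if (E_floor < 0) stopf("E_floor must be >= 0")
  structure(list(
    rho_intercept = rho_intercept, rho_slope = rho_slope,
    E_intercept = E_intercept, E_slope = E_slope,
    E_floor = E_floor, n_bins = as.integer(n_bins)
  ), class = c("scanip_law", "hu_law"))
}

#' Evaluate an HU to modulus law
#'
#' @param hu numeric vector of attenuation values, HU.
#' @param law a [density_modulus_law()] or [scanip_law()].
#' @return Young's modulus, MPa (same length as `hu`); monotone
#'   non-decreasing in HU.
#' @export
hu_to_modulus <- function(hu, law) UseMethod("hu_to_modulus", law)

#' @export
hu_to_modulus.density_modulus_law <- function(hu, law) {
  if (any(!is.finite(hu))) stopf("HU values must be finite")
  rho_ash <- pmax(0, law$ash_intercept + law$ash_slope * hu)
  rho_app <- rho_ash / law$ash_to_app_divisor
  pmax(law$E_floor, law$E_coeff * rho_app^law$E_exponent)
}

#' @export
hu_to_modulus.scanip_law <- function(hu, law) {
  if (any(!is.finite(hu))) stopf("HU values must be finite")
  rho <- law$rho_intercept + law$rho_slope * hu
  pmax(law$E_floor, law$E_intercept + law$E_slope * rho)
}

#' Equal-width modulus bins and piecewise assignment
#'
#' `build_bins` splits `[E_min, E_max]` into `n_bins` equal-width bins;
#' the representative modulus of each bin is its midpoint. `apply_bins`
#' replaces each modulus by the representative of its containing bin;
#' values on a shared edge go to the higher bin and `E = E_max` goes to
#' the last bin.
#'
#' @param E_min,E_max modulus range, MPa (`E_min < E_max`).
#' @param n_bins number of bins (>= 1).
#' @return `build_bins`: an object of class `bin_set` with `edges`
#'   (length `n_bins + 1`) and `representative` (length `n_bins`).
#' @export
build_bins <- function(E_min, E_max, n_bins = 8L) {
  if (!(E_min < E_max)) stopf("E_min must be < E_max")
  if (n_bins < 1) stopf("n_bins must be >= 1")
  edges <- seq(E_min, E_max, length.out = n_bins + 1)
  structure(list(
    edges = edges,
    representative = (edges[-1] + edges[-length(edges)]) / 2
  ), class = "bin_set")
}

#' @rdname build_bins
#' @param E moduli to quantize, MPa.
#' @param bins a `bin_set`.
#' @return `apply_bins`: quantized moduli, MPa.
#' @export
apply_bins <- function(E, bins) {
  stopifnot(inherits(bins, "bin_set"))
  edges <- bins$edges
  if (any(E < edges[1]) || any(E > edges[length(edges)]))
    stopf("modulus outside the bin range [%g, %g]", edges[1], edges[length(edges)])
  # half-open [lo, hi) bins: a value at a shared edge goes to the higher bin;
  # E = E_max folds back into the last bin
  i <- pmin(findInterval(E, edges), length(bins$representative))
  bins$representative[i]
}

#' Volume-fraction histogram of element moduli
#'
#' The distribution report of the mapping-verification protocol: the
#' fraction of total mesh volume carried by elements whose modulus falls
#' in each bin.
#'
#' @param volumes per-element volumes, mm^3 (positive).
#' @param moduli per-element Young's moduli, MPa.
#' @param edges monotone bin edges, MPa, spanning all `moduli`.
#' @return an object of class `modulus_histogram`: list with `edges`,
#'   `volume_fraction` (sums to 1) and `counts`.
#' @export
modulus_volume_fractions <- function(volumes, moduli, edges) {
  if (length(volumes) != length(moduli)) stopf("one modulus per element required")
  if (any(volumes <= 0)) stopf("element volumes must be positive")
  if (is.unsorted(edges, strictly = TRUE)) stopf("edges must be strictly increasing")
  low <- moduli < edges[1]; high <- moduli > edges[length(edges)]
  if (any(low) || any(high))
    stopf("%d element moduli fall outside [%g, %g]",
          sum(low) + sum(high), edges[1], edges[length(edges)])
  i <- pmin(findInterval(moduli, edges), length(edges) - 1L)
  vf <- vapply(seq_len(length(edges) - 1L),
               function(b) sum(volumes[i == b]), numeric(1))
  structure(list(
    edges = edges,
    volume_fraction = vf / sum(volumes),
    counts = tabulate(i, nbins = length(edges) - 1L)
  ), class = "modulus_histogram")
}

#' Write a modulus histogram as CSV
#' @param h a `modulus_histogram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_modulus_histogram <- function(h, path) {
  stopifnot(inherits(h, "modulus_histogram"))
  df <- data.frame(
    bin_lo_MPa = h$edges[-length(h$edges)],
    bin_hi_MPa = h$edges[-1],
    volume_fraction = h$volume_fraction,
    n_elements = h$counts
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
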