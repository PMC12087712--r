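#' Synthetic phantom-femur specification
#'
#' Parameters of the synthetic long-bone CT volume that stands in for a
#' clinical scan: a cortical tube with a distal metaphyseal flare,
#' trabecular bone filling the metaphysis, a low-attenuation medullary
#' canal in the diaphysis, air background, and optional hydroxyapatite
#' calibration rods of nominal densities 0, 75 and 150 mg/cm^3.
#'
#' The bone axis is z; z = 0 is the distal (condylar) end. The outer
#' radius blends smoothly from `flare_radius` at z = 0 down to
#' `outer_radius` over `flare_length`; the endosteal surface keeps a
#' constant cortical thickness `outer_radius - inner_radius`. Interior
#' bone distal of `flare_length` is trabecular, proximal of it marrow.
#'
#' @param length bone length, mm.
#' @param outer_radius,inner_radius diaphysis periosteal / endosteal
#'   radius, mm (`inner_radius < outer_radius`).
#' @param flare_radius,flare_length distal metaphysis flare radius and
#'   axial extent, mm.
#' @param cortical_hu,cortical_sd cortical attenuation mean / sd, HU.
#' @param trabecular_hu,trabecular_sd trabecular mean / sd, HU.
#' @param trabecular_smoothness correlation length of the smooth
#'   trabecular noise field, mm.
#' @param proximal_fill_length axial extent of the trabecular-filled
#'   proximal metaphysis, mm (the canal is closed at both ends, as in a
#'   real long bone).
#' @param marrow_hu,marrow_sd medullary canal mean / sd, HU.
#' @param soft_tissue_hu,soft_tissue_sd,soft_tissue_thickness muscle/fat
#'   envelope around the periosteal surface: mean / sd (HU) and radial
#'   thickness (mm). A real limb scan never shows air at the bone
#'   surface; surface mesh nodes must sample tissue-like attenuation.
#' @param background_hu air background, HU.
#' @param include_calibration_rods generate the three density rods
#'   alongside the bone.
#' @param spacing voxel pitch, mm (scalar or length 3).
#' @param dims voxel counts per axis, or `NULL` to fit the geometry with
#'   a margin.
#' @param margin empty margin around the geometry when `dims` is `NULL`, mm.
#' @param seed integer RNG seed; the generated volume is a pure function
#'   of the spec including the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(length = 180, outer_radius = 12, inner_radius = 7,
                         flare_radius = 20, flare_length = 45,
                         cortical_hu = 1500, cortical_sd = 50,
                         trabecular_hu = 300, trabecular_sd = 80,
                         trabecular_smoothness = 4,
                         proximal_fill_length = 20,
                         marrow_hu = -50, marrow_sd = 25,
                         soft_tissue_hu = 40, soft_tissue_sd = 15,
                         soft_tissue_thickness = 6,
                         background_hu = -1000,
                         include_calibration_rods = FALSE,
                         spacing = 1, dims = NULL, margin = 4, seed = 1L) {
  if (inner_radius >= outer_radius) stopf("inner_radius must be < outer_radius")
  if (flare_radius < outer_radius) stopf("flare_radius must be >= outer_radius")
  if (any(c(cortical_sd, trabecular_sd, marrow_sd) < 0)) stopf("all sd values must be >= 0")
  if (length <= 0 || flare_length < 0) stopf("lengths must be positive")
  spacing <- if (base::length(spacing) == 1) rep(spacing, 3) else check_len3(spacing, "spacing")
  if (any(spacing <= 0)) stopf("spacing must be positive")
  structure(list(
    length = length, outer_radius = outer_radius, inner_radius = inner_radius,
    flare_radius = flare_radius, flare_length = flare_length,
    cortical_hu = cortical_hu, cortical_sd = cortical_sd,
    trabecular_hu = trabecular_hu, trabecular_sd = trabecular_sd,
    trabecular_smoothness = trabecular_smoothness,
    proximal_fill_length = proximal_fill_length,
    marrow_hu = marrow_hu, marrow_sd = marrow_sd,
    soft_tissue_hu = soft_tissue_hu, soft_tissue_sd = soft_tissue_sd,
    soft_tissue_thickness = soft_tissue_thickness,
    background_hu = background_hu,
    include_calibration_rods = isTRUE(include_calibration_rods),
    spacing = spacing, dims = if (!is.null(dims)) as.integer(dims) else NULL,
    margin = margin, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Periosteal and endosteal radius profile of the phantom
#'
#' @param spec a [phantom_spec()].
#' @param z axial coordinates, mm.
#' @return list with `outer` and `inner` radii at `z` (0 outside the bone).
#' @export
phantom_radii <- function(spec, z) {
  outer <- ifelse(z < spec$flare_length & spec$flare_length > 0,
    spec$outer_radius + (spec$flare_radius - spec$outer_radius) *
      0.5 * (1 + cos(pi * pmax(0, z) / spec$flare_length)),
    spec$outer_radius)
  outer[z < 0 | z > spec$length] <- 0
  thick <- spec$outer_radius - spec$inner_radius
  inner <- pmax(0, outer - thick)
  inner[z < 0 | z > spec$length] <- 0
  list(outer = outer, inner = inner)
}

phantom_rod_layout <- function(spec) {
  # three rods in the "table pad" region anterior of the bone (y < 0)
  y0 <- -(spec$flare_radius + 12)
  list(x = c(-24, 0, 24), y = y0, radius = 6,
       density = c(0, 75, 150),      # nominal mg/cm^3
       hu = c(0, 75, 150))           # water-equivalent base, ~1 HU per mg/cm^3
}

#' Generate a phantom femur CT volume
#'
#' Produces a deterministic CT-like volume from a [phantom_spec()]:
#' cortical voxels are drawn i.i.d. from N(cortical_hu, cortical_sd^2),
#' trabecular voxels carry a spatially smooth Gaussian field with
#' correlation length `trabecular_smoothness`, the medullary canal is
#' low-HU noise, and everything outside the geometry is air background.
#'
#' @param spec a [phantom_spec()].
#' @return a [ct_volume()] (int-valued HU).
#' @examples
#' vol <- generate_phantom_femur(phantom_spec(length = 40, spacing = 2, seed = 1))
#' range(vol$hu)
#' @export
generate_phantom_femur <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  rod <- if (spec$include_calibration_rods) phantom_rod_layout(spec) else NULL
  # world extent to cover
  rmax <- spec$flare_radius + spec$soft_tissue_thickness
  xr <- c(-rmax, rmax)
  yr <- c(-rmax, rmax)
  if (!is.null(rod)) {
    xr <- range(xr, rod$x - rod$radius, rod$x + rod$radius)
    yr <- range(yr, rod$y - rod$radius, rod$y + rod$radius)
  }
  zr <- c(0, spec$length)
  if (is.null(spec$dims)) {
    lo <- c(xr[1], yr[1], zr[1]) - spec$margin
    hi <- c(xr[2], yr[2], zr[2]) + spec$margin
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / sp)) + 1L)
    origin <- lo
  } else {
    dims <- spec$dims
    origin <- c(-(dims[1] - 1) * sp[1] / 2, -(dims[2] - 1) * sp[2] / 2, -spec$margin)
    ext_hi <- origin + (dims - 1) * sp
    if (ext_hi[3] < spec$length || origin[1] > -spec$flare_radius ||
        ext_hi[1] < spec$flare_radius || origin[2] > -spec$flare_radius ||
        ext_hi[2] < spec$flare_radius)
      stopf("bone geometry does not fit in the requested dims")
  }
  x <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  z <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]

  prof <- phantom_radii(spec, z)
  r2 <- outer(x^2, y^2, "+")                       # nx x ny squared radius
  hu <- array(spec$background_hu, dims)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  # smooth trabecular field sampled on a coarse lattice, trilinear interpolated
  trab_field <- smooth_noise_field(x, y, z, spec$trabecular_smoothness)

  nslice <- dims[1] * dims[2]
  cort_noise <- if (spec$cortical_sd > 0) rnorm(prod(dims), 0, spec$cortical_sd) else numeric(prod(dims))
  marr_noise <- if (spec$marrow_sd > 0) rnorm(prod(dims), 0, spec$marrow_sd) else numeric(prod(dims))
  soft_noise <- if (spec$soft_tissue_sd > 0) rnorm(prod(dims), 0, spec$soft_tissue_sd) else numeric(prod(dims))
  for (k in seq_len(dims[3])) {
    ro <- prof$outer[k]; ri <- prof$inner[k]
    if (ro <= 0) next
    idx0 <- (k - 1L) * nslice
    if (spec$soft_tissue_thickness > 0) {
      soft <- which(r2 > ro^2 & r2 <= (ro + spec$soft_tissue_thickness)^2)
      if (length(soft))
        hu[idx0 + soft] <- spec$soft_tissue_hu + soft_noise[idx0 + soft]
    }
    inside <- which(r2 <= ro^2)
    if (!length(inside)) next
    cortical <- inside[r2[inside] > ri^2]
    interior <- inside[r2[inside] <= ri^2]
    hu[idx0 + cortical] <- spec$cortical_hu + cort_noise[idx0 + cortical]
    if (length(interior)) {
      if (z[k] <= spec$flare_length ||
          z[k] >= spec$length - spec$proximal_fill_length) {
        hu[idx0 + interior] <- spec$trabecular_hu +
          spec$trabecular_sd * trab_field[idx0 + interior]
      } else {
        hu[idx0 + interior] <- spec$marrow_hu + marr_noise[idx0 + interior]
      }
    }
  }

  if (!is.null(rod)) {
    zmask <- z >= 0 & z <= spec$length
    for (i in seq_along(rod$x)) {
      d2 <- outer((x - rod$x[i])^2, (y - rod$y[i])^2, "+")
      in_rod <- which(d2 <= rod$radius^2)
      if (!length(in_rod)) next
      for (k in which(zmask)) hu[(k - 1L) * nslice + in_rod] <- rod$hu[i]
    }
  }

  hu <- round(hu)
  hu <- pmax(pmin(hu, 32767), -32768)
  storage.mode(hu) <- "integer"
  dim(hu) <- dims
  ct_volume(hu, origin = origin, spacing = sp)
}

# standard-normal field with approximate correlation length `len` (mm),
# built by trilinear interpolation of i.i.d. values on a coarse lattice
smooth_noise_field <- function(x, y, z, len) {
  if (len <= 0) {
    return(array(rnorm(length(x) * length(y) * length(z)),
                 c(length(x), length(y), length(z))))
  }
  gx <- coarse_axis(x, len); gy <- coarse_axis(y, len); gz <- coarse_axis(z, len)
  coarse <- array(rnorm(length(gx) * length(gy) * length(gz)),
                  c(length(gx), length(gy), length(gz)))
  trilinear_interp(coarse, gx, gy, gz, x, y, z)
}

coarse_axis <- function(v, len) {
  n <- max(2L, as.integer(ceiling((max(v) - min(v)) / len)) + 1L)
  seq(min(v), max(v), length.out = n)
}

trilinear_interp <- function(f, gx, gy, gz, x, y, z) {
  loc <- function(g, v) {
    i <- findInterval(v, g, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(g) - 1L)
    t <- (v - g[i]) / (g[i + 1L] - g[i])
    list(i = i, t = pmin(pmax(t, 0), 1))
  }
  lx <- loc(gx, x); ly <- loc(gy, y); lz <- loc(gz, z)
  nx <- length(x); ny <- length(y); nz <- length(z)
  out <- array(0, c(nx, ny, nz))
  dgx <- dim(f)[1]; dgxy <- dim(f)[1] * dim(f)[2]
  ix <- lx$i; tx <- lx$t
  for (k in seq_len(nz)) {
    kz <- lz$i[k]; tz <- lz$t[k]
    for (j in seq_len(ny)) {
      jy <- ly$i[j]; ty <- ly$t[j]
      base000 <- ix + (jy - 1L) * dgx + (kz - 1L) * dgxy
      c00 <- f[base000] * (1 - tx) + f[base000 + 1L] * tx
      c10 <- f[base000 + dgx] * (1 - tx) + f[base000 + dgx + 1L] * tx
      c01 <- f[base000 + dgxy] * (1 - tx) + f[base000 + dgxy + 1L] * tx
      c11 <- f[base000 + dgx + dgxy] * (1 - tx) + f[base000 + dgx + dgxy + 1L] * tx
      out[, j, k] <- (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                     (c01 * (1 - ty) + c11 * ty) * tz
    }
  }
  out
}

#' Analytic bone-tissue volume of the phantom
#'
#' Integrates the cross-section area of the cortical shell (and optionally
#' the full periosteal envelope) along the bone axis, independently of any
#' voxelisation.
#'
#' @param spec a [phantom_spec()].
#' @param what `"cortical"` (shell) or `"envelope"` (everything inside the
#'   periosteal surface).
#' @param n 1-D integration resolution.
#' @return volume, mm^3.
#' @export
phantom_analytic_volume <- function(spec, what = c("cortical", "envelope"), n = 20000) {
  what <- match.arg(what)
  z <- seq(0, spec$length, length.out = n)
  prof <- phantom_radii(spec, z)
  area <- if (what == "cortical") pi * (prof$outer^2 - prof$inner^2) else pi * prof$outer^2
  # trapezoid rule
  h <- z[2] - z[1]
  sum((area[-1] + area[-n]) / 2) * h
}
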