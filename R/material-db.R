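#' Voxel material database
#'
#' The decoupled material carrier of the workflow: the spatial limits of
#' the scan space, the voxel spacing, and the full HU voxel set. Built
#' once from a CT volume, it survives any later manipulation of the bone
#' geometry (fracture gap, screw holes) because material lookup is by
#' world position, not by mesh topology.
#'
#' Bounds follow the voxel-extent convention: each axis spans
#' `[origin - spacing/2, origin + spacing*(dims-1) + spacing/2]`.
#'
#' @param vol a [ct_volume()].
#' @return an object of class `material_db` with fields `bounds` (2 x 3
#'   matrix, min/max rows), `spacing`, `dims`, `origin` and `hu`.
#' @examples
#' db <- build_material_database(ct_volume(array(0L, c(10, 10, 10))))
#' db$bounds
#' @export
build_material_database <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  bounds <- rbind(
    lo = vol$origin - vol$spacing / 2,
    hi = vol$origin + vol$spacing * (vol$dims - 1) + vol$spacing / 2
  )
  colnames(bounds) <- c("x", "y", "z")
  structure(list(
    bounds = bounds, spacing = vol$spacing, dims = vol$dims,
    origin = vol$origin, hu = vol$hu
  ), class = "material_db")
}

#' @export
print.material_db <- function(x, ...) {
  cat(sprintf(
    "<material_db> %d voxels (%d x %d x %d), spacing %s mm\n  bounds x [%g, %g] y [%g, %g] z [%g, %g] mm\n",
    prod(x$dims), x$dims[1], x$dims[2], x$dims[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    x$bounds[1, 1], x$bounds[2, 1], x$bounds[1, 2], x$bounds[2, 2],
    x$bounds[1, 3], x$bounds[2, 3]
  ))
  invisible(x)
}

#' Read / write the material database container
#'
#' Serialized as a one-line JSON text header (bounds, spacing, dims, dtype,
#' byte order) followed by the little-endian raw HU block; int16 payloads
#' round-trip bit-exactly.
#'
#' @param db a `material_db` (see [build_material_database()]).
#' @param path file path (conventionally `.ctdb`).
#' @return `read_material_database` returns a `material_db`;
#'   `write_material_database` returns `path` invisibly.
#' @export
write_material_database <- function(db, path) {
  stopifnot(inherits(db, "material_db"))
  vol <- ct_volume(db$hu, origin = db$origin, spacing = db$spacing)
  write_rawvol(vol, path, extra = list(bounds = unname(db$bounds)))
  invisible(path)
}

#' @rdname write_material_database
#' @export
read_material_database <- function(path) {
  p <- read_rawvol_parts(path)
  db <- build_material_database(ct_volume(
    p$hu, origin = as.numeric(p$hdr$origin), spacing = as.numeric(p$hdr$spacing)
  ))
  if (!is.null(p$hdr$bounds)) {
    stored <- matrix(as.numeric(unlist(p$hdr$bounds)), nrow = 2)
    if (max(abs(stored - unname(db$bounds))) > 1e-9)
      stopf("stored bounds in %s disagree with origin/spacing/dims", path)
  }
  db
}

#' Nearest-voxel lookup in a material database
#'
#' For each query point, the voxel whose centre is nearest in Euclidean
#' distance. On a regular grid this reduces to per-axis rounding of the
#' fractional index; a point exactly halfway between two voxel centres is
#' assigned to the lower index (hence the lowest linear voxel index of the
#' tied set). Points outside the database bounds are clamped to the
#' nearest in-bounds voxel.
#'
#' @param db a `material_db`.
#' @param points n x 3 matrix of world coordinates, mm.
#' @return list with `index` (n x 3 integer, 1-based), `linear` (1-based
#'   linear voxel index) and `hu` (attenuation at those voxels).
#' @export
nearest_voxel <- function(db, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stopf("'points' must be an n x 3 matrix")
  idx <- matrix(0L, nrow(points), 3)
  for (a in 1:3) {
    t <- (points[, a] - db$origin[a]) / db$spacing[a]
    i <- ceiling(t - 0.5)              # round half down -> lowest linear index on ties
    idx[, a] <- pmin(pmax(as.integer(i), 0L), db$dims[a] - 1L) + 1L
  }
  lin <- idx[, 1] + (idx[, 2] - 1L) * db$dims[1] +
    (idx[, 3] - 1L) * db$dims[1] * db$dims[2]
  list(index = idx, linear = lin, hu = as.numeric(db$hu[lin]))
}
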