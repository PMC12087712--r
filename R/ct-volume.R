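#' CT-like voxel volume
#'
#' A regular scalar voxel grid in Hounsfield units (HU) with world-space
#' placement. World coordinates are millimetres; `origin` is the centre of
#' voxel (1,1,1) (0-based index (0,0,0)); storage is an R array with the x
#' index fastest.
#'
#' @param hu 3-D numeric/integer array of attenuation values, HU.
#' @param origin world position of the first voxel centre, mm (length 3).
#' @param spacing voxel pitch per axis, mm (length 3, strictly positive).
#' @return An object of class `ct_volume` with fields `hu`, `origin`,
#'   `spacing` and `dims`.
#' @examples
#' vol <- ct_volume(array(0L, c(4, 4, 4)), origin = c(0, 0, 0), spacing = c(1, 1, 1))
#' vol$dims
#' @export
ct_volume <- function(hu, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stopf("'hu' must be a 3-D array")
  origin <- check_len3(origin, "origin")
  spacing <- check_len3(spacing, "spacing")
  if (any(spacing <= 0)) stopf("voxel spacing must be strictly positive")
  if (any(!is.finite(hu))) stopf("all HU values must be finite")
  structure(
    list(hu = hu, origin = origin, spacing = spacing, dims = dim(hu)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm, HU [%g, %g]\n",
    x$dims[1], x$dims[2], x$dims[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(signif(x$origin, 4), collapse = ", "),
    min(x$hu), max(x$hu)
  ))
  invisible(x)
}

#' World coordinates of voxel centres along one axis
#' @param vol a [ct_volume()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates, mm.
#' @export
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(vol$dims[axis]) - 1) * vol$spacing[axis]
}

format_from_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.mha$", path)) "metaimage"
  else if (grepl("\\.ctdb$", path)) "raw"
  else stopf("cannot infer volume format from extension of '%s'", path)
}

#' Read / write CT volumes
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, via RNifti), MetaImage
#' (`.mha`, uncompressed local-data), and the package's raw database
#' container (`.ctdb`: one-line JSON header followed by a little-endian
#' int16 block). Write-then-read round-trips reproduce origin, spacing and
#' dims exactly and the HU payload bit-exactly for integer data.
#'
#' @param path file path.
#' @param format one of `"nifti"`, `"metaimage"`, `"raw"`; inferred from
#'   the extension when `NULL`.
#' @return `read_ct_volume` returns a [ct_volume()]; `write_ct_volume`
#'   returns `path` invisibly.
#' @export
read_ct_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% format_from_path(path)
  switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_mha_volume(path),
    raw = read_rawvol(path),
    stopf("unknown volume format '%s'", format)
  )
}

#' @rdname read_ct_volume
#' @param vol a [ct_volume()].
#' @export
write_ct_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- format %||% format_from_path(path)
  switch(format,
    nifti = write_nifti_volume(vol, path),
    metaimage = write_mha_volume(vol, path),
    raw = write_rawvol(vol, path),
    stopf("unknown volume format '%s'", format)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  # we write axis-aligned RAS sforms; diagonal carries spacing, column 4 origin
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  hu <- as.array(img)
  attributes(hu) <- list(dim = dim(img))
  ct_volume(hu, origin = as.numeric(aff[1:3, 4]), spacing = abs(diag(aff)[1:3]))
}

write_nifti_volume <- function(vol, path) {
  storage <- if (all(vol$hu == round(vol$hu)) &&
                 max(abs(vol$hu)) <= 32767) "int16" else "double"
  img <- RNifti::asNifti(vol$hu, datatype = storage)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = storage)
}

# --- MetaImage (.mha), local uncompressed payload ---------------------------

write_mha_volume <- function(vol, path) {
  int_ok <- all(vol$hu == round(vol$hu)) && max(abs(vol$hu)) <= 32767
  etype <- if (int_ok) "MET_SHORT" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(vol$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %s", paste(format(vol$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %d %d %d", vol$dims[1], vol$dims[2], vol$dims[3]),
    sprintf("ElementType = %s", etype),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (int_ok)
    writeBin(as.integer(vol$hu), con, size = 2L, endian = "little")
  else
    writeBin(as.numeric(vol$hu), con, size = 8L, endian = "little")
  invisible(path)
}

read_mha_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- read_text_line(con)
    if (is.null(line)) stopf("corrupt MetaImage header in %s (no ElementDataFile)", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("corrupt MetaImage header line: '%s'", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["ElementDataFile"]], "LOCAL"))
    stopf("only local-payload MetaImage files are supported")
  if (identical(fields[["CompressedData"]], "True"))
    stopf("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]])
  n <- prod(dims)
  etype <- fields[["ElementType"]]
  hu <- switch(etype,
    MET_SHORT = readBin(con, integer(), n = n, size = 2L, signed = TRUE, endian = "little"),
    MET_DOUBLE = readBin(con, numeric(), n = n, size = 8L, endian = "little"),
    stopf("unsupported MetaImage ElementType '%s'", etype)
  )
  if (length(hu) != n)
    stopf("MetaImage payload holds %d voxels but header declares %d", length(hu), n)
  ct_volume(array(hu, dims), origin = origin, spacing = spacing)
}

read_text_line <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) return(if (length(chars)) rawToChar(chars) else NULL)
    if (b == as.raw(10L)) return(rawToChar(chars))
    chars <- c(chars, b)
  }
}

# --- raw container (.ctdb): JSON header line + little-endian block ----------

write_rawvol <- function(vol, path, extra = list()) {
  int_ok <- all(vol$hu == round(vol$hu)) && max(abs(vol$hu)) <= 32767
  hdr <- c(list(
    magic = "osteofe-ctdb", version = 1L,
    dims = as.integer(vol$dims), spacing = vol$spacing, origin = vol$origin,
    dtype = if (int_ok) "int16" else "float64", byte_order = "little"
  ), extra)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  if (int_ok)
    writeBin(as.integer(vol$hu), con, size = 2L, endian = "little")
  else
    writeBin(as.numeric(vol$hu), con, size = 8L, endian = "little")
  invisible(path)
}

read_rawvol_parts <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_line <- read_text_line(con)
  hdr <- tryCatch(jsonlite::fromJSON(hdr_line),
                  error = function(e) stopf("corrupt header in %s: %s", path, conditionMessage(e)))
  if (!identical(hdr$magic, "osteofe-ctdb")) stopf("%s is not an osteofe volume container", path)
  dims <- as.integer(hdr$dims)
  n <- prod(dims)
  hu <- switch(hdr$dtype,
    int16 = readBin(con, integer(), n = n + 1L, size = 2L, signed = TRUE, endian = "little"),
    float64 = readBin(con, numeric(), n = n + 1L, size = 8L, endian = "little"),
    stopf("unsupported dtype '%s' in %s", hdr$dtype, path)
  )
  if (length(hu) != n)
    stopf("payload of %s holds %d voxels but header declares %d", path, length(hu), n)
  list(hdr = hdr, hu = array(hu, dims))
}

read_rawvol <- function(path) {
  p <- read_rawvol_parts(path)
  ct_volume(p$hu, origin = as.numeric(p$hdr$origin), spacing = as.numeric(p$hdr$spacing))
}
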