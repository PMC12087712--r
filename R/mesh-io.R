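#' Export a mesh (with optional fields) to VTU, MSH or Abaqus INP
#'
#' VTU is written as ASCII XML UnstructuredGrid with the region tag (and,
#' when given, per-element modulus, von Mises stress and nodal
#' displacement) attached as cell/point data. MSH is Gmsh legacy 2.2
#' ASCII with the region code as the physical tag. INP export writes
#' C3D4 elements with one element set + solid section per distinct
#' modulus value (import of INP is not supported).
#'
#' @param mesh a [tet_mesh()].
#' @param path output path; extension picks the format when `format` is
#'   `NULL` (`.vtu`, `.msh`, `.inp`).
#' @param field optional [material_field()] (element moduli exported).
#' @param solution optional `fe_solution` (displacements, von Mises).
#' @param format `"vtu"`, `"msh"` or `"inp"`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, field = NULL, solution = NULL, format = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- format %||% mesh_format_from_path(path)
  switch(format,
    vtu = write_vtu(mesh, path, field, solution),
    msh = write_msh(mesh, path),
    inp = write_inp(mesh, path, field),
    stopf("unsupported mesh format '%s'", format)
  )
  invisible(path)
}

#' @rdname export_mesh
#' @export
import_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% mesh_format_from_path(path)
  switch(format,
    vtu = read_vtu(path),
    msh = read_msh(path),
    inp = stopf("Abaqus INP import is not supported (export only)"),
    stopf("unsupported mesh format '%s'", format)
  )
}

mesh_format_from_path <- function(path) {
  if (grepl("\\.vtu$", path)) "vtu"
  else if (grepl("\\.msh$", path)) "msh"
  else if (grepl("\\.inp$", path)) "inp"
  else stopf("cannot infer mesh format from extension of '%s'", path)
}

num_line <- function(x, digits = 17) paste(format(x, digits = digits), collapse = " ")

write_vtu <- function(mesh, path, field = NULL, solution = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num_line), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 4L, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, m), collapse = " "), con)   # VTK_TETRA
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(REGION_CODES[mesh$region], collapse = " "), con)
  w('        </DataArray>')
  if (!is.null(field)) {
    w('        <DataArray type="Float64" Name="youngs_modulus_MPa" format="ascii">')
    writeLines(num_line(field$E_elem), con)
    w('        </DataArray>')
  }
  if (!is.null(solution)) {
    w('        <DataArray type="Float64" Name="von_mises_MPa" format="ascii">')
    writeLines(num_line(von_mises(solution$stress)), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('      <PointData>')
  if (!is.null(solution)) {
    w('        <DataArray type="Float64" NumberOfComponents="3" Name="displacement_mm" format="ascii">')
    writeLines(apply(solution$u, 1, num_line), con)
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}

# reads the ASCII VTU layout written by write_vtu
read_vtu <- function(path) {
  txt <- readLines(path)
  grab <- function(name_regex) {
    i0 <- grep(name_regex, txt)
    if (!length(i0)) return(NULL)
    i1 <- grep("</DataArray>", txt)
    i1 <- i1[i1 > i0[1]][1]
    as.numeric(scan(text = paste(txt[(i0[1] + 1):(i1 - 1)], collapse = " "),
                    what = numeric(), quiet = TRUE))
  }
  piece <- grep("<Piece ", txt, value = TRUE)[1]
  if (is.na(piece)) stopf("not a VTU piece file: %s", path)
  pts <- grab('NumberOfComponents="3" format="ascii"')
  conn <- grab('Name="connectivity"')
  types <- grab('Name="types"')
  if (!all(types == 10)) stopf("VTU contains non-tetrahedral cells")
  region_code <- grab('Name="region"')
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  elems <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  region <- REGION_LEVELS[as.integer(region_code)]
  tet_mesh(nodes, elems, region)
}

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   apply(mesh$nodes, 1, num_line)), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  # element type 4 = 4-node tetrahedron; two tags: physical + geometric entity
  code <- REGION_CODES[mesh$region]
  writeLines(paste(seq_len(nrow(mesh$elems)), 4L, 2L, code, code,
                   mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3], mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
}

read_msh <- function(path) {
  txt <- readLines(path)
  need <- function(tag) {
    i <- match(tag, txt)
    if (is.na(i)) stopf("missing %s section in %s", tag, path)
    i
  }
  i_n <- need("$Nodes")
  nn <- as.integer(txt[i_n + 1])
  node_rows <- do.call(rbind, strsplit(trimws(txt[(i_n + 2):(i_n + 1 + nn)]), "\\s+"))
  nodes <- matrix(as.numeric(node_rows[, 2:4]), ncol = 3)
  ord <- order(as.integer(node_rows[, 1]))
  nodes <- nodes[ord, , drop = FALSE]
  i_e <- need("$Elements")
  ne <- as.integer(txt[i_e + 1])
  el_rows <- strsplit(trimws(txt[(i_e + 2):(i_e + 1 + ne)]), "\\s+")
  parse_el <- function(r) {
    r <- as.integer(r)
    if (r[2] != 4L) return(NULL)              # keep tetrahedra only
    ntags <- r[3]
    c(r[4], r[(4 + ntags):(7 + ntags)])       # physical tag + 4 nodes
  }
  rows <- Filter(Negate(is.null), lapply(el_rows, parse_el))
  if (!length(rows)) stopf("no tetrahedral elements in %s", path)
  em <- do.call(rbind, rows)
  tet_mesh(nodes, em[, 2:5, drop = FALSE], REGION_LEVELS[em[, 1]])
}

write_inp <- function(mesh, path, field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("osteofe assembly export")
  w("*NODE")
  writeLines(paste0(seq_len(nrow(mesh$nodes)), ", ",
                    apply(mesh$nodes, 1, function(r)
                      paste(format(r, digits = 17), collapse = ", "))), con)
  w("*ELEMENT, TYPE=C3D4")
  writeLines(paste0(seq_len(nrow(mesh$elems)), ", ",
                    apply(mesh$elems, 1, paste, collapse = ", ")), con)
  E <- if (!is.null(field)) field$E_elem else rep(1, nrow(mesh$elems))
  nu <- if (!is.null(field)) field$nu_elem else rep(0.3, nrow(mesh$elems))
  groups <- split(seq_along(E), format(E, digits = 12))
  k <- 0L
  for (g in groups) {
    k <- k + 1L
    name <- sprintf("MAT%04d", k)
    w("*ELSET, ELSET=%s", name)
    writeLines(vapply(split(g, ceiling(seq_along(g) / 10)),
                      paste, character(1), collapse = ", "), con)
    w("*SOLID SECTION, ELSET=%s, MATERIAL=%s", name, name)
    w("*MATERIAL, NAME=%s", name)
    w("*ELASTIC")
    w("%s, %s", format(E[g[1]], digits = 12), format(nu[g[1]], digits = 6))
  }
}

#' Export a solved model to VTU
#'
#' Convenience wrapper attaching displacement and von Mises fields.
#' @param mesh a [tet_mesh()]; `field` a [material_field()]; `solution`
#'   an `fe_solution`; `path` the output `.vtu` path.
#' @inheritParams export_mesh
#' @return `path`, invisibly.
#' @export
export_solution <- function(mesh, field, solution, path) {
  export_mesh(mesh, path, field = field, solution = solution, format = "vtu")
}
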