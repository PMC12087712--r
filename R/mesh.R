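#' Tetrahedral mesh with region tags
#'
#' @param nodes n x 3 numeric matrix of world coordinates, mm.
#' @param elems m x 4 integer matrix of node indices (1-based), positively
#'   oriented (volume > 0).
#' @param region character vector (length m) with values among
#'   `bone, callus, plate, screw, pad`.
#' @param node_sets named list of integer node-index vectors.
#' @param h lattice edge length used to build the mesh, mm (or `NA`).
#' @param callus_modulus prescribed callus Young's modulus, MPa (or `NA`).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elems, region, node_sets = list(), h = NA_real_,
                     callus_modulus = NA_real_) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elems <- as.matrix(elems); storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3) stopf("'nodes' must be n x 3")
  if (ncol(elems) != 4) stopf("'elems' must be m x 4")
  if (length(region) != nrow(elems)) stopf("one region tag per element required")
  if (!all(region %in% REGION_LEVELS))
    stopf("unknown region tags: %s",
          paste(setdiff(unique(region), REGION_LEVELS), collapse = ", "))
  if (min(elems) < 1 || max(elems) > nrow(nodes)) stopf("element node index out of range")
  m <- structure(list(
    nodes = nodes, elems = elems, region = as.character(region),
    node_sets = node_sets, h = h, callus_modulus = callus_modulus
  ), class = "tet_mesh")
  v <- element_volumes(m)
  if (any(v <= 0)) stopf("%d elements are degenerate or inverted", sum(v <= 0))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  tags <- table(factor(x$region, REGION_LEVELS))
  cat(sprintf("<tet_mesh> %d nodes, %d linear tetrahedra\n",
              nrow(x$nodes), nrow(x$elems)))
  cat("  regions:", paste(sprintf("%s=%d", names(tags), tags), collapse = " "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = " "), "\n")
  invisible(x)
}

#' Signed element volumes
#' @param mesh a [tet_mesh()].
#' @return numeric vector of element volumes, mm^3.
#' @export
element_volumes <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  a <- n[e[, 2], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  b <- n[e[, 3], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  d <- n[e[, 4], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Element centroids
#' @param mesh a [tet_mesh()].
#' @return m x 3 matrix, mm.
#' @export
element_centroids <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  (n[e[, 1], , drop = FALSE] + n[e[, 2], , drop = FALSE] +
   n[e[, 3], , drop = FALSE] + n[e[, 4], , drop = FALSE]) / 4
}

#' Minimum dihedral angle over the mesh
#'
#' @param mesh a [tet_mesh()].
#' @return smallest dihedral angle across all elements, degrees.
#' @export
min_dihedral_angle <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  # face normals of the four faces opposite each vertex
  p <- lapply(1:4, function(a) n[e[, a], , drop = FALSE])
  cross <- function(u, v) cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  normalize <- function(u) u / sqrt(rowSums(u^2))
  # outward normal of face opposite vertex a
  faces <- list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  nrm <- lapply(faces, function(f)
    normalize(cross(p[[f[2]]] - p[[f[1]]], p[[f[3]]] - p[[f[1]]])))
  worst <- Inf
  for (a in 1:3) for (b in (a + 1):4) {
    cosang <- rowSums(nrm[[a]] * nrm[[b]])
    # dihedral angle between faces = pi - angle between outward normals
    ang <- 180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    worst <- min(worst, ang)
  }
  worst
}

# ---------------------------------------------------------------------------
# structured lattice mesher: cubic cells, Kuhn 6-tet split (conformal across
# cells since every face carries the same diagonal), region by cell centroid
# ---------------------------------------------------------------------------

KUHN_TETS <- rbind(
  c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 3, 8, 4),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 8, 7)
)

#' Mesh a region function on a structured lattice
#'
#' Fills the axis-aligned box `[lower, upper]` with cubic cells of edge
#' `h`, classifies each cell by the region label of its centroid
#' (`NA` = void, not meshed), and splits every retained cell into six
#' positively oriented tetrahedra sharing lattice nodes, so touching
#' regions are conformally tied.
#'
#' @param region_fn function taking an n x 3 coordinate matrix and
#'   returning a character vector of region labels (or `NA`).
#' @param lower,upper box corners, mm.
#' @param h target cell edge length, mm.
#' @return a [tet_mesh()].
#' @export
lattice_tet_mesh <- function(region_fn, lower, upper, h) {
  lower <- check_len3(lower, "lower"); upper <- check_len3(upper, "upper")
  if (any(upper <= lower)) stopf("upper must exceed lower on all axes")
  if (h <= 0) stopf("h must be positive")
  nc <- pmax(1L, as.integer(round((upper - lower) / h)))
  hs <- (upper - lower) / nc                      # actual (near-h) cell size
  ci <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  cj <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  ck <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  cx <- lower[1] + (ci - 0.5) * hs[1]
  cy <- lower[2] + (cj - 0.5) * hs[2]
  cz <- lower[3] + (ck - 0.5) * hs[3]
  lab <- region_fn(cbind(cx, cy, cz))
  keep <- which(!is.na(lab))
  if (!length(keep)) stopf("region function selected no cells")
  lab <- lab[keep]; ci <- ci[keep]; cj <- cj[keep]; ck <- ck[keep]

  nvx <- nc[1] + 1L; nvxy <- nvx * (nc[2] + 1L)
  corner <- function(dx, dy, dz)
    (ci - 1L + dx) + (cj - 1L + dy) * nvx + (ck - 1L + dz) * nvxy + 1L
  cid <- cbind(
    corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L), corner(1L, 1L, 0L),
    corner(0L, 0L, 1L), corner(1L, 0L, 1L), corner(0L, 1L, 1L), corner(1L, 1L, 1L)
  )
  elems <- do.call(rbind, lapply(seq_len(nrow(KUHN_TETS)), function(t)
    cid[, KUHN_TETS[t, ], drop = FALSE]))
  region <- rep(lab, times = nrow(KUHN_TETS))

  used <- sort(unique(as.vector(elems)))
  remap <- integer(nvxy * (nc[3] + 1L))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4)
  g0 <- used - 1L
  gi <- g0 %% nvx
  gj <- (g0 %/% nvx) %% (nc[2] + 1L)
  gk <- g0 %/% nvxy
  nodes <- cbind(lower[1] + gi * hs[1], lower[2] + gj * hs[2], lower[3] + gk * hs[3])
  tet_mesh(nodes, elems, region, h = max(hs))
}

#' Locking-plate osteosynthesis assembly specification
#'
#' Geometry of the phantom + implant construct: the bone comes from a
#' [phantom_spec()]; a flat plate of `n_holes` holes stands off the
#' lateral (+x) bone surface; screws fill a subset of the holes, crossing
#' the standoff gap and anchoring toward the far cortex; the transverse
#' fracture is a slab normal to the bone axis; the condyles rest on two
#' flexible support pads (medial x < 0, lateral x > 0) with fixed bases.
#'
#' @param phantom a [phantom_spec()] (bone geometry).
#' @param plate_length,plate_width,plate_thickness plate box, mm.
#' @param plate_z0 distal end of the plate along the bone axis, mm.
#' @param standoff bone-plate distance at the widest covered section, mm.
#' @param hole_z axial hole positions (length `n_holes`), mm.
#' @param hole_radius,screw_radius hole / screw radius, mm (equal by
#'   default: zero-interference holes).
#' @param filled_holes indices into `hole_z` that carry screws.
#' @param screw_tip_clearance distance from the screw tip to the far
#'   periosteal surface, mm.
#' @param fracture_z fracture plane position along the bone axis, mm.
#' @param gap_width fracture gap width, mm.
#' @param pad_height support pad height, mm; `pad_gap` the medial-lateral
#'   split between the two pads, mm.
#' @param pad_modulus,steel_modulus,poisson pad / implant-steel Young's
#'   moduli (MPa) and the common Poisson ratio.
#' @param h target element edge length, mm.
#' @return an object of class `assembly_spec`.
#' @export
assembly_spec <- function(phantom = phantom_spec(),
                          plate_length = 112, plate_width = 14,
                          plate_thickness = 4, plate_z0 = 6,
                          standoff = 2,
                          hole_z = c(12, 22, 32, 42, 60, 74, 88),
                          hole_radius = 2.5, screw_radius = 2.5,
                          filled_holes = c(1, 2, 3, 5, 6, 7),
                          screw_tip_clearance = 2,
                          fracture_z = 48, gap_width = 4,
                          pad_height = 8, pad_gap = 4,
                          pad_modulus = 25, steel_modulus = 193000,
                          poisson = 0.3, h = 2) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (standoff <= 0) stopf("standoff must be > 0")
  if (gap_width <= 0) stopf("gap_width must be > 0")
  if (!all(filled_holes %in% seq_along(hole_z)))
    stopf("filled_holes must be a subset of the hole indices")
  if (any(diff(sort(hole_z)) < 2 * hole_radius))
    stopf("plate holes overlap")
  if (max(hole_z) > plate_z0 + plate_length || min(hole_z) < plate_z0)
    stopf("holes fall outside the plate")
  structure(list(
    phantom = phantom, plate_length = plate_length, plate_width = plate_width,
    plate_thickness = plate_thickness, plate_z0 = plate_z0, standoff = standoff,
    hole_z = hole_z, hole_radius = hole_radius, screw_radius = screw_radius,
    filled_holes = as.integer(filled_holes),
    screw_tip_clearance = screw_tip_clearance,
    fracture_z = fracture_z, gap_width = gap_width,
    pad_height = pad_height, pad_gap = pad_gap,
    pad_modulus = pad_modulus, steel_modulus = steel_modulus,
    poisson = poisson, h = h
  ), class = "assembly_spec")
}

plate_plane_x <- function(spec) {
  zr <- c(spec$plate_z0, spec$plate_z0 + spec$plate_length)
  z <- seq(zr[1], zr[2], length.out = 400)
  max(phantom_radii(spec$phantom, z)$outer) + spec$standoff
}

#' Build the osteosynthesis assembly mesh
#'
#' Meshes bone, plate, screws and support pads conformally on a shared
#' lattice (the tied-interface contract: coincident parts share nodes).
#' Screws displace bone material where they cross it (zero-interference
#' screw holes); unfilled plate holes are left void. The fracture gap is
#' *not* introduced here — apply it afterwards with
#' [apply_fracture_gap()], which is the point of the decoupled workflow.
#'
#' Named node sets created: `load_surface` (proximal end face),
#' `pad_base` (all pad bottom nodes), `pad_base_medial` / `pad_base_lateral`.
#'
#' @param spec an [assembly_spec()].
#' @param include_plate set `FALSE` for an intact (bone-only) model.
#' @param conform_surface snap protruding periosteal lattice nodes onto
#'   the analytic bone surface so the mesh conforms to the geometry.
#' @return a [tet_mesh()].
#' @export
build_assembly_mesh <- function(spec, include_plate = TRUE,
                                conform_surface = TRUE) {
  stopifnot(inherits(spec, "assembly_spec"))
  ph <- spec$phantom
  px <- if (include_plate) plate_plane_x(spec) else 0
  if (include_plate) {
    tipx <- -(phantom_radii(ph, spec$hole_z)$outer - spec$screw_tip_clearance)
    if (any(tipx > px)) stopf("screw geometry infeasible (tip beyond plate)")
  }
  lower <- c(-ph$flare_radius, -ph$flare_radius, -spec$pad_height)
  upper <- c(max(ph$flare_radius, if (include_plate) px + spec$plate_thickness else 0),
             ph$flare_radius, ph$length)
  region_fn <- function(p) {
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    r <- sqrt(x^2 + y^2)
    prof <- phantom_radii(ph, z)
    lab <- rep(NA_character_, nrow(p))
    lab[prof$outer > 0 & r <= prof$outer] <- "bone"
    # support pads under the condylar end, split medial/lateral
    pad <- z < 0 & z >= -spec$pad_height & r <= ph$flare_radius &
      abs(x) >= spec$pad_gap / 2
    lab[pad] <- "pad"
    if (include_plate) {
      in_plate <- x >= px & x <= px + spec$plate_thickness &
        abs(y) <= spec$plate_width / 2 &
        z >= spec$plate_z0 & z <= spec$plate_z0 + spec$plate_length
      lab[in_plate] <- "plate"
      for (i in seq_along(spec$hole_z)) {
        d2 <- y^2 + (z - spec$hole_z[i])^2
        if (i %in% spec$filled_holes) {
          tipx_i <- -(phantom_radii(ph, spec$hole_z[i])$outer -
                        spec$screw_tip_clearance)
          # screw displaces bone/plate material and bridges the standoff void
          scr <- d2 <= spec$screw_radius^2 & x >= tipx_i &
            x <= px + spec$plate_thickness
          lab[scr] <- "screw"
        } else {
          hole <- d2 <= spec$hole_radius^2 & in_plate
          lab[hole] <- NA_character_
        }
      }
    }
    lab
  }
  mesh <- lattice_tet_mesh(region_fn, lower, upper, spec$h)
  if (conform_surface) mesh <- snap_bone_surface(mesh, ph)
  mesh$node_sets <- assembly_node_sets(mesh, spec)
  mesh
}

# Pull bone-only lattice nodes that protrude beyond the periosteal surface
# radially back onto it, so the mesh conforms to the bone geometry the way a
# surface-fitted mesh would (surface nodes then sample bone attenuation, not
# surrounding tissue). Movement is damped if it would invert an element.
snap_bone_surface <- function(mesh, ph) {
  is_bone <- mesh$region %in% c("bone", "callus")
  bone_nodes <- unique(as.vector(mesh$elems[is_bone, , drop = FALSE]))
  other_nodes <- unique(as.vector(mesh$elems[!is_bone, , drop = FALSE]))
  own <- setdiff(bone_nodes, other_nodes)
  r <- sqrt(mesh$nodes[own, 1]^2 + mesh$nodes[own, 2]^2)
  rout <- phantom_radii(ph, mesh$nodes[own, 3])$outer
  move <- which(rout > 0 & r > rout)
  if (!length(move)) return(mesh)
  ids <- own[move]
  orig <- mesh$nodes[ids, 1:2, drop = FALSE]
  target <- orig * (rout[move] / r[move])
  scale <- rep(1, length(ids))
  for (it in 1:8) {
    mesh$nodes[ids, 1:2] <- orig + scale * (target - orig)
    v <- element_volumes(mesh)
    if (all(v > 0)) break
    bad_nodes <- unique(as.vector(mesh$elems[v <= 0, , drop = FALSE]))
    hit <- ids %in% bad_nodes
    scale[hit] <- if (it < 7) scale[hit] / 2 else 0
  }
  mesh
}

assembly_node_sets <- function(mesh, spec) {
  nz <- mesh$nodes[, 3]
  zmax <- max(nz)
  tol <- 1e-6 * max(abs(zmax), 1)
  load_surface <- which(abs(nz - zmax) < tol)
  pad_elems <- which(mesh$region == "pad")
  pad_nodes <- unique(as.vector(mesh$elems[pad_elems, ]))
  zmin <- min(mesh$nodes[, 3])
  pad_base <- pad_nodes[abs(mesh$nodes[pad_nodes, 3] - zmin) < tol]
  list(
    load_surface = load_surface,
    pad_base = pad_base,
    pad_base_medial = pad_base[mesh$nodes[pad_base, 1] < 0],
    pad_base_lateral = pad_base[mesh$nodes[pad_base, 1] > 0]
  )
}

#' Transverse fracture specification
#' @param position point on the fracture mid-plane, mm (length 3).
#' @param normal fracture plane normal (defaults to the bone axis).
#' @param gap_width gap width, mm (>= 0; 0 re-tags nothing).
#' @return an object of class `fracture_spec`.
#' @export
fracture_spec <- function(position, normal = c(0, 0, 1), gap_width = 4) {
  position <- check_len3(position, "position")
  normal <- check_len3(normal, "normal")
  if (sum(normal^2) == 0) stopf("normal must be nonzero")
  if (gap_width < 0) stopf("gap_width must be >= 0")
  structure(list(position = position, normal = normal / sqrt(sum(normal^2)),
                 gap_width = gap_width), class = "fracture_spec")
}

#' Apply a fracture gap to a meshed bone
#'
#' Re-tags bone elements whose centroid lies inside the fracture slab as
#' `callus` and records the healing-stage modulus on the mesh. The slab is
#' `|(c - position) . normal| <= gap_width / 2`. Tags are independent of
#' the stage: only the recorded callus modulus differs between stages.
#'
#' @param mesh a [tet_mesh()].
#' @param fracture a [fracture_spec()].
#' @param stage_modulus callus Young's modulus, MPa (healing stages:
#'   1 granulation tissue, 10 fibrocartilage, 100 woven bone).
#' @return the modified [tet_mesh()].
#' @export
apply_fracture_gap <- function(mesh, fracture, stage_modulus = 1) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(fracture, "fracture_spec"))
  if (stage_modulus <= 0) stopf("stage_modulus must be > 0")
  mesh$callus_modulus <- stage_modulus
  if (fracture$gap_width == 0) return(mesh)
  cen <- element_centroids(mesh)
  d <- (cen[, 1] - fracture$position[1]) * fracture$normal[1] +
       (cen[, 2] - fracture$position[2]) * fracture$normal[2] +
       (cen[, 3] - fracture$position[3]) * fracture$normal[3]
  inside <- abs(d) <= fracture$gap_width / 2
  hit <- inside & mesh$region == "bone"
  if (!any(inside & mesh$region %in% c("bone", "callus")))
    stopf("fracture slab does not intersect the bone")
  mesh$region[hit] <- "callus"
  mesh
}
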