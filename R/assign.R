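#' Per-element / per-node material field
#'
#' @param E_elem per-element Young's modulus, MPa.
#' @param nu_elem per-element Poisson ratio.
#' @param E_node per-node modulus for bone nodes (NA elsewhere), MPa.
#' @param method `"nodewise"`, `"volume_averaged"` or `"prescribed"`.
#' @return an object of class `material_field`.
#' @export
material_field <- function(E_elem, nu_elem, E_node = NULL, method = "prescribed") {
  if (any(E_elem <= 0)) stopf("all element moduli must be positive")
  if (any(nu_elem <= 0 | nu_elem >= 0.5)) stopf("Poisson ratios must lie in (0, 0.5)")
  structure(list(E_elem = E_elem, nu_elem = nu_elem, E_node = E_node,
                 method = method), class = "material_field")
}

#' @export
print.material_field <- function(x, ...) {
  cat(sprintf("<material_field> (%s) %d elements, E [%g, %g] MPa\n",
              x$method, length(x$E_elem), min(x$E_elem), max(x$E_elem)))
  invisible(x)
}

region_modulus_defaults <- function(mesh, steel = 193000, pad = 25) {
  callus <- mesh$callus_modulus
  if ("callus" %in% mesh$region && is.na(callus))
    stopf("mesh has callus elements but no recorded callus modulus")
  c(plate = steel, screw = steel, pad = pad, callus = callus)
}

#' Node-wise material mapping
#'
#' The decoupled subject-specific route: each bone node takes the HU of
#' the voxel nearest to it (Euclidean distance to voxel centres,
#' out-of-bounds nodes clamped to the nearest in-bounds voxel), the law
#' converts that HU to a nodal Young's modulus, and each bone element
#' receives the plain average of its four nodal moduli (even nodal
#' weighting). Non-bone regions keep their prescribed moduli.
#'
#' @param mesh a [tet_mesh()].
#' @param db a `material_db` (see [build_material_database()]).
#' @param law an HU law ([density_modulus_law()] / [scanip_law()]).
#' @param nu Poisson ratio applied to every region.
#' @param steel_modulus,pad_modulus prescribed moduli for implant and pad
#'   regions, MPa.
#' @return a [material_field()] with per-node bone moduli filled in.
#' @export
assign_nodewise <- function(mesh, db, law, nu = 0.3,
                            steel_modulus = 193000, pad_modulus = 25) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(db, "material_db"))
  presets <- region_modulus_defaults(mesh, steel_modulus, pad_modulus)
  is_bone <- mesh$region == "bone"
  bone_nodes <- sort(unique(as.vector(mesh$elems[is_bone, , drop = FALSE])))
  E_node <- rep(NA_real_, nrow(mesh$nodes))
  if (length(bone_nodes)) {
    nv <- nearest_voxel(db, mesh$nodes[bone_nodes, , drop = FALSE])
    E_node[bone_nodes] <- hu_to_modulus(nv$hu, law)
  }
  E_elem <- numeric(nrow(mesh$elems))
  if (any(is_bone)) {
    be <- mesh$elems[is_bone, , drop = FALSE]
    E_elem[is_bone] <- (E_node[be[, 1]] + E_node[be[, 2]] +
                        E_node[be[, 3]] + E_node[be[, 4]]) / 4
  }
  for (rg in names(presets))
    E_elem[mesh$region == rg] <- presets[[rg]]
  material_field(E_elem, rep(nu, nrow(mesh$elems)), E_node, "nodewise")
}

# equal-volume barycentric sample points: two levels of red refinement give
# 64 sub-tetrahedra of equal volume; their centroids serve as quadrature
# points with equal weights
tet_subcell_barycentric <- function(levels = 2L) {
  verts <- diag(4)
  cells <- list(verts)
  refine <- function(v) {
    # v: 4 x 4 barycentric vertices of one sub-tet
    m <- list()
    mid <- function(a, b) (v[a, ] + v[b, ]) / 2
    e <- list(`12` = mid(1, 2), `13` = mid(1, 3), `14` = mid(1, 4),
              `23` = mid(2, 3), `24` = mid(2, 4), `34` = mid(3, 4))
    corner <- list(
      rbind(v[1, ], e$`12`, e$`13`, e$`14`),
      rbind(e$`12`, v[2, ], e$`23`, e$`24`),
      rbind(e$`13`, e$`23`, v[3, ], e$`34`),
      rbind(e$`14`, e$`24`, e$`34`, v[4, ])
    )
    # octahedron split along the 13-24 diagonal into four equal tets
    octa <- list(
      rbind(e$`12`, e$`13`, e$`14`, e$`24`),
      rbind(e$`12`, e$`13`, e$`23`, e$`24`),
      rbind(e$`13`, e$`14`, e$`24`, e$`34`),
      rbind(e$`13`, e$`23`, e$`24`, e$`34`)
    )
    c(corner, octa)
  }
  for (l in seq_len(levels)) cells <- do.call(c, lapply(cells, refine))
  t(vapply(cells, colMeans, numeric(4)))     # n_cells x 4 barycentric centroids
}

#' Volume-averaged material mapping
#'
#' The conventional orphan-mesh route: each bone element receives the
#' volume-averaged attenuation over its extent (fixed equal-volume
#' sub-sampling, 512 points per element by default), converted by the law
#' to a single element modulus, optionally quantized to bin midpoints
#' (the piecewise 8-bin commercial behaviour).
#'
#' @inheritParams assign_nodewise
#' @param bins optional `bin_set` (see [build_bins()]); when given,
#'   element moduli are replaced by their bin representative.
#' @param levels sub-sampling refinement levels (`8^levels` points; the
#'   512-point default keeps the quadrature error of discontinuous voxel
#'   fields within 1 percent of the attenuation span at voxel-scale elements).
#' @return a [material_field()].
#' @export
assign_volume_averaged <- function(mesh, db, law, bins = NULL, nu = 0.3,
                                   steel_modulus = 193000, pad_modulus = 25,
                                   levels = 3L) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(db, "material_db"))
  presets <- region_modulus_defaults(mesh, steel_modulus, pad_modulus)
  is_bone <- mesh$region == "bone"
  E_elem <- numeric(nrow(mesh$elems))
  if (any(is_bone)) {
    hu_mean <- element_mean_hu(mesh, db, which(is_bone), levels)
    E <- hu_to_modulus(hu_mean, law)
    if (!is.null(bins)) E <- apply_bins(E, bins)
    E_elem[is_bone] <- E
  }
  for (rg in names(presets))
    E_elem[mesh$region == rg] <- presets[[rg]]
  material_field(E_elem, rep(nu, nrow(mesh$elems)), NULL, "volume_averaged")
}

#' Volume-averaged attenuation per element
#'
#' @param mesh a [tet_mesh()].
#' @param db a `material_db`.
#' @param which_elems element indices to sample (default: all).
#' @param levels sub-sampling refinement levels.
#' @return mean HU per requested element.
#' @export
element_mean_hu <- function(mesh, db, which_elems = seq_len(nrow(mesh$elems)),
                            levels = 3L) {
  bc <- tet_subcell_barycentric(levels)          # q x 4
  q <- nrow(bc)
  e <- mesh$elems[which_elems, , drop = FALSE]
  acc <- numeric(length(which_elems))
  for (k in seq_len(q)) {
    pts <- bc[k, 1] * mesh$nodes[e[, 1], , drop = FALSE] +
           bc[k, 2] * mesh$nodes[e[, 2], , drop = FALSE] +
           bc[k, 3] * mesh$nodes[e[, 3], , drop = FALSE] +
           bc[k, 4] * mesh$nodes[e[, 4], , drop = FALSE]
    acc <- acc + nearest_voxel(db, pts)$hu
  }
  acc / q
}
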