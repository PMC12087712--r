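test_that("lattice mesher fills a box exactly with positively oriented tetrahedra", {
  m <- lattice_tet_mesh(function(p) rep("bone", nrow(p)), c(0, 0, 0), c(3, 2, 2), 1)
  expect_equal(nrow(m$elems), 3 * 2 * 2 * 6)
  v <- element_volumes(m)
  expect_true(all(v > 0))
  expect_equal(sum(v), 12, tolerance = 1e-12)
  # the Kuhn split of a cubic cell has 45-degree worst dihedral angles
  expect_gt(min_dihedral_angle(m), 44.9)
})

test_that("assembly mesh ties all parts through shared lattice nodes", {
  fx <- tiny_fixture()
  mesh <- fx$mesh
  expect_setequal(unique(mesh$region), c("bone", "plate", "screw", "pad"))
  # every screw element face on a region boundary has a coincident
  # neighbour face (shared nodes): collect faces once per region side
  face_key <- function(e) {
    faces <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)], e[, c(1, 3, 4)], e[, c(2, 3, 4)])
    faces <- t(apply(faces, 1, sort))
    paste(faces[, 1], faces[, 2], faces[, 3])
  }
  scr_e <- mesh$elems[mesh$region == "screw", , drop = FALSE]
  scr <- face_key(scr_e)
  bone_faces <- face_key(mesh$elems[mesh$region == "bone", , drop = FALSE])
  # faces of the screw region that are not internal to it
  boundary <- scr[!(scr %in% scr[duplicated(scr)])]
  # every screw boundary face buried in the bone envelope must have a
  # coincident bone face (shared nodes = the tied-interface contract)
  ph <- fx$spec$phantom
  keys_nodes <- do.call(rbind, strsplit(boundary, " "))
  storage.mode(keys_nodes) <- "integer"
  inside_bone <- sapply(seq_len(nrow(keys_nodes)), function(i) {
    p <- mesh$nodes[keys_nodes[i, ], , drop = FALSE]
    rr <- sqrt(p[, 1]^2 + p[, 2]^2)
    all(rr < phantom_radii(ph, p[, 3])$outer - 1e-6)
  })
  expect_true(any(inside_bone))
  expect_true(all(boundary[inside_bone] %in% bone_faces))
})

test_that("a screwless unfractured spec yields two disjoint tagged bodies", {
  fx <- tiny_fixture()
  spec <- fx$spec
  spec$filled_holes <- integer(0)
  m <- build_assembly_mesh(spec)
  expect_setequal(unique(m$region), c("bone", "plate", "pad"))
  bone_nodes <- unique(as.vector(m$elems[m$region == "bone", ]))
  plate_nodes <- unique(as.vector(m$elems[m$region == "plate", ]))
  expect_length(intersect(bone_nodes, plate_nodes), 0)
})

test_that("element quality of the conforming assembly stays above threshold", {
  fx <- tiny_fixture()
  # surface snapping squashes boundary cells; all elements stay valid
  expect_true(all(element_volumes(fx$mesh) > 0))
  expect_gt(min_dihedral_angle(fx$mesh), 1)
})

test_that("fracture gap re-tags the slab and only the slab", {
  fx <- tiny_fixture()
  frac <- fracture_spec(c(0, 0, fx$spec$fracture_z), gap_width = 4)
  m <- apply_fracture_gap(fx$mesh, frac, 10)
  expect_equal(m$callus_modulus, 10)
  cen <- element_centroids(m)
  d <- abs(cen[, 3] - fx$spec$fracture_z)
  expect_true(all(d[m$region == "callus"] <= 2 + 1e-9))
  expect_false(any(m$region == "bone" & d <= 2 - 1e-9 &
                     fx$mesh$region == "bone"))
  # zero-width slab re-tags nothing
  m0 <- apply_fracture_gap(fx$mesh, fracture_spec(c(0, 0, 24), gap_width = 0), 1)
  expect_false(any(m0$region == "callus"))
  # stages share tags, differ only in the recorded modulus
  mC1 <- apply_fracture_gap(fx$mesh, frac, 1)
  mC3 <- apply_fracture_gap(fx$mesh, frac, 100)
  expect_identical(mC1$region, mC3$region)
  expect_identical(mC1$elems, mC3$elems)
  # a slab that misses the bone errors
  expect_error(apply_fracture_gap(fx$mesh,
    fracture_spec(c(0, 0, 500), gap_width = 4), 1), "intersect")
})

test_that("callus volume matches the analytic slab-tube intersection", {
  # straight tube so the slab volume has a closed form
  ph <- phantom_spec(length = 60, outer_radius = 8, inner_radius = 5,
                     flare_radius = 8, flare_length = 0,
                     proximal_fill_length = 10, spacing = 1, seed = 2)
  spec <- assembly_spec(phantom = ph, plate_length = 40, plate_width = 8,
                        plate_thickness = 4, plate_z0 = 4,
                        hole_z = c(9, 15, 33, 39), filled_holes = 1:4,
                        fracture_z = 24, gap_width = 4, pad_height = 6, h = 1)
  m <- build_assembly_mesh(spec, include_plate = FALSE)
  m <- apply_fracture_gap(m, fracture_spec(c(0, 0, 24), gap_width = 4), 1)
  callus_vol <- sum(element_volumes(m)[m$region == "callus"])
  analytic <- pi * 8^2 * 4                     # full cross-section times width
  expect_lt(abs(callus_vol - analytic) / analytic, 0.05)
})

test_that("geometrically infeasible assemblies are rejected", {
  fx <- tiny_fixture()
  expect_error(assembly_spec(phantom = fx$spec$phantom,
                             hole_z = c(10, 12), hole_radius = 2.5,
                             plate_z0 = 4, plate_length = 40,
                             filled_holes = 1), "overlap")
  expect_error(assembly_spec(phantom = fx$spec$phantom, plate_z0 = 4,
                             plate_length = 10, hole_z = c(30),
                             filled_holes = 1), "outside the plate")
  expect_error(assembly_spec(phantom = fx$spec$phantom, standoff = 0), "standoff")
})

test_that("mesh export and import round-trip connectivity and tags", {
  fx <- tiny_fixture()
  m <- apply_fracture_gap(fx$mesh,
                          fracture_spec(c(0, 0, fx$spec$fracture_z), gap_width = 4), 10)
  for (ext in c(".vtu", ".msh")) {
    path <- tempfile(fileext = ext)
    export_mesh(m, path)
    back <- import_mesh(path)
    expect_equal(unname(back$nodes), unname(m$nodes), tolerance = 1e-12, label = ext)
    expect_identical(unname(back$elems), unname(m$elems), label = ext)
    expect_identical(back$region, m$region, label = ext)
  }
  expect_error(import_mesh(tempfile(fileext = ".inp")), "not")
})

test_that("Gmsh export is parseable by an independent minimal reader", {
  m <- lattice_tet_mesh(function(p) rep("plate", nrow(p)), c(0, 0, 0), c(2, 2, 1), 1)
  path <- tempfile(fileext = ".msh")
  export_mesh(m, path)
  txt <- readLines(path)              # independent parse, not the package reader
  expect_equal(txt[2], "2.2 0 8")
  n_decl <- as.integer(txt[which(txt == "$Nodes") + 1])
  expect_equal(n_decl, nrow(m$nodes))
  node_block <- txt[(which(txt == "$Nodes") + 2):(which(txt == "$EndNodes") - 1)]
  expect_length(node_block, nrow(m$nodes))
  e_decl <- as.integer(txt[which(txt == "$Elements") + 1])
  expect_equal(e_decl, nrow(m$elems))
})

test_that("Abaqus export writes one material section per distinct modulus", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  elems <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  m <- tet_mesh(nodes, elems, c("bone", "bone"))
  f <- material_field(c(1000, 2000), c(0.3, 0.3))
  path <- tempfile(fileext = ".inp")
  export_mesh(m, path, field = f)
  txt <- readLines(path)
  expect_equal(sum(grepl("^\\*SOLID SECTION", txt)), 2)
  expect_equal(sum(grepl("^\\*ELEMENT", txt)), 1)
  expect_equal(sum(grepl("^2, 2, 3, 4, 5$", txt)), 1)
})
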