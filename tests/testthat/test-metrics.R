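# Builds a fractured tiny assembly plus a fake solution holding an imposed
# displacement field, so IFM can be checked against exact rigid kinematics.
fractured_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_fixture()
      frac <- fracture_spec(c(0, 0, fx$spec$fracture_z), gap_width = fx$spec$gap_width)
      cache <<- list(fx = fx, frac = frac,
                     mesh = apply_fracture_gap(fx$mesh, frac, 1))
    }
    cache
  }
})

fake_solution <- function(mesh, u) {
  field <- material_field(rep(1000, nrow(mesh$elems)), rep(0.3, nrow(mesh$elems)))
  rec <- recover_strain_stress(mesh, field, u)
  structure(list(u = u, strain = rec$strain, stress = rec$stress,
                 reactions = matrix(0, nrow(mesh$nodes), 3),
                 f_ext = matrix(0, nrow(mesh$nodes), 3)),
            class = "fe_solution")
}

test_that("IFM reproduces imposed rigid fragment motions exactly", {
  ft <- fractured_tiny()
  mesh <- ft$mesh
  distal <- mesh$nodes[, 3] < ft$fx$spec$fracture_z - 2

  # axial translation of the distal fragment
  u <- matrix(0, nrow(mesh$nodes), 3)
  u[distal, 3] <- 0.37
  ifm <- compute_ifm(mesh, fake_solution(mesh, u), ft$frac)
  expect_equal(ifm$axial_near, 0.37, tolerance = 1e-12)
  expect_equal(ifm$axial_far, 0.37, tolerance = 1e-12)
  expect_equal(ifm$shear_far, 0, tolerance = 1e-12)

  # in-plane translation: pure shear at both cortices
  u2 <- matrix(0, nrow(mesh$nodes), 3)
  u2[distal, 1] <- -0.21; u2[distal, 2] <- 0.12
  ifm2 <- compute_ifm(mesh, fake_solution(mesh, u2), ft$frac)
  expect_equal(ifm2$axial_near, 0, tolerance = 1e-12)
  expect_equal(ifm2$shear_far, sqrt(0.21^2 + 0.12^2), tolerance = 1e-12)

  # small rotation about a cortex-tangent axis through the gap centre:
  # marker kinematics follow u = theta x (p - c)
  theta <- c(1e-3, 0, 0)
  ctr <- c(0, 0, ft$fx$spec$fracture_z)
  rel <- sweep(mesh$nodes, 2, ctr)
  u3 <- matrix(0, nrow(mesh$nodes), 3)
  spin <- cbind(theta[2] * rel[, 3] - theta[3] * rel[, 2],
                theta[3] * rel[, 1] - theta[1] * rel[, 3],
                theta[1] * rel[, 2] - theta[2] * rel[, 1])
  u3[distal, ] <- spin[distal, ]
  ifm3 <- compute_ifm(mesh, fake_solution(mesh, u3), ft$frac)
  mk <- ifm3$markers
  expected_axial <- function(pair) {
    d <- spin[pair["distal"], ] - c(0, 0, 0)
    d[3]
  }
  expect_equal(ifm3$axial_near, expected_axial(mk$near), tolerance = 1e-12)
  expect_equal(ifm3$axial_far, expected_axial(mk$far), tolerance = 1e-12)
  d_far <- spin[mk$far["distal"], ]
  expect_equal(ifm3$shear_far, sqrt(sum(d_far[1:2]^2)), tolerance = 1e-12)
})

test_that("IFM marker pairs straddle the gap at opposite cortices", {
  ft <- fractured_tiny()
  mk <- compute_ifm(ft$mesh, fake_solution(ft$mesh,
                    matrix(0, nrow(ft$mesh$nodes), 3)), ft$frac)$markers
  zc <- ft$fx$spec$fracture_z
  for (side in c("near", "far")) {
    expect_gt(ft$mesh$nodes[mk[[side]]["proximal"], 3], zc)
    expect_lt(ft$mesh$nodes[mk[[side]]["distal"], 3], zc)
  }
  # near cortex on the plate (+x) side, far on the opposite side
  expect_gt(ft$mesh$nodes[mk$near["proximal"], 1], 0)
  expect_lt(ft$mesh$nodes[mk$far["proximal"], 1], 0)
})

test_that("EqSV equals the brute-force flag-and-sum over elements", {
  ft <- fractured_tiny()
  mesh <- ft$mesh
  m <- nrow(mesh$elems)
  # uniform sub-threshold strain: both volumes empty
  strain <- matrix(0, m, 6)
  strain[, 1] <- 0.004; strain[, 3] <- -0.006
  sol <- fake_solution(mesh, matrix(0, nrow(mesh$nodes), 3))
  sol$strain <- strain
  eq <- compute_eqsv(mesh, sol, region = "bone")
  expect_equal(eq$tensile_volume, 0)
  expect_equal(eq$compressive_volume, 0)

  # one flagged element contributes exactly its own volume
  k <- which(mesh$region == "bone")[10]
  strain2 <- matrix(0, m, 6)
  strain2[k, 1] <- 0.006
  sol$strain <- strain2
  eq2 <- compute_eqsv(mesh, sol, region = "bone")
  expect_equal(eq2$tensile_volume, element_volumes(mesh)[k], tolerance = 1e-12)

  # random strain fields match an independent accumulation loop
  set.seed(43)
  strain3 <- matrix(rnorm(m * 6, sd = 0.004), m, 6)
  sol$strain <- strain3
  eq3 <- compute_eqsv(mesh, sol, region = "screws", screw_radius_mm = 5)
  sel <- which(mesh$region == "bone" & osteofe:::near_screws(mesh, 5))
  vols <- element_volumes(mesh)
  tens <- comp <- 0
  for (e in sel) {
    pr <- sort(eigen(matrix(c(strain3[e, 1], strain3[e, 4], strain3[e, 6],
                              strain3[e, 4], strain3[e, 2], strain3[e, 5],
                              strain3[e, 6], strain3[e, 5], strain3[e, 3]), 3, 3),
                     symmetric = TRUE)$values, decreasing = TRUE)
    if (pr[1] > 0.005) tens <- tens + vols[e]
    if (pr[3] < -0.007) comp <- comp + vols[e]
  }
  expect_equal(eq3$tensile_volume, tens, tolerance = 1e-9)
  expect_equal(eq3$compressive_volume, comp, tolerance = 1e-9)
  expect_lte(eq3$tensile_volume, eq3$region_volume)

  # strains scale with load: volumes are monotone in load magnitude
  sol$strain <- strain3 * 2
  eq4 <- compute_eqsv(mesh, sol, region = "screws")
  expect_gte(eq4$tensile_volume, eq3$tensile_volume)
  expect_gte(eq4$compressive_volume, eq3$compressive_volume)
})

test_that("averaged plate peak equals the O(n^2) oracle and never exceeds the raw peak", {
  ft <- fractured_tiny()
  mesh <- ft$mesh
  m <- nrow(mesh$elems)
  pe <- which(mesh$region == "plate")
  sol <- fake_solution(mesh, matrix(0, nrow(mesh$nodes), 3))

  # constant field: averaged peak equals the constant
  sol$stress <- matrix(0, m, 6); sol$stress[, 1] <- 42
  pps <- peak_plate_stress(mesh, sol, diameter = 3)
  expect_equal(pps$peak_MPa, 42, tolerance = 1e-12)
  expect_equal(pps$raw_peak_MPa, 42, tolerance = 1e-12)

  # single spike narrower than the disc: averaging strictly reduces it
  sol$stress <- matrix(0, m, 6)
  sol$stress[pe, 1] <- 10
  sol$stress[pe[17], 1] <- 500
  pps2 <- peak_plate_stress(mesh, sol, diameter = 3)
  expect_lt(pps2$peak_MPa, pps2$raw_peak_MPa)

  # random field vs brute-force neighborhood averaging
  set.seed(47)
  sol$stress <- matrix(rnorm(m * 6, sd = 20), m, 6)
  pps3 <- peak_plate_stress(mesh, sol, diameter = 4)
  vm <- von_mises(sol$stress[pe, , drop = FALSE])
  cen <- element_centroids(mesh)[pe, , drop = FALSE]
  vol <- element_volumes(mesh)[pe]
  oracle <- max(oracle_disc_average(cen, vm, vol, 2))
  expect_equal(pps3$peak_MPa, oracle, tolerance = 1e-12)
  expect_lte(pps3$peak_MPa, max(vm) + 1e-12)
})

test_that("repeated healing stages give identical per-stage results", {
  fx <- tiny_fixture()
  law <- density_modulus_law()
  sw <- run_healing_sweep(fx$mesh, fx$db, law, fx$spec,
                          stages = c(C1 = 1, C1b = 1))
  expect_equal(sw$summary$ifm_axial_far_mm[1], sw$summary$ifm_axial_far_mm[2],
               tolerance = 1e-12)
  expect_equal(sw$summary$peak_plate_stress_MPa[1],
               sw$summary$peak_plate_stress_MPa[2], tolerance = 1e-12)
  expect_equal(sw$summary$eqsv_tensile_mm3[1], sw$summary$eqsv_tensile_mm3[2],
               tolerance = 1e-12)
})

test_that("mapping comparison collapses to zero deltas when the methods coincide", {
  fx <- tiny_fixture()
  # uniform attenuation: node-wise and volume-averaged laws coincide exactly
  vol <- ct_volume(array(800L, c(30, 30, 50)), origin = c(-15, -15, -5),
                   spacing = c(1.5, 1.5, 1.5))
  db <- build_material_database(vol)
  im <- osteofe:::strip_pads(build_assembly_mesh(fx$spec, include_plate = FALSE))
  cmp <- compare_mapping_methods(im, db, density_modulus_law(), binned = FALSE)
  expect_equal(unname(cmp$deflection[1]), unname(cmp$deflection[2]),
               tolerance = 1e-8)
  expect_equal(cmp$deflection_ratio, 1, tolerance = 1e-8)
  expect_equal(cmp$histogram_l1, 0, tolerance = 1e-12)
  expect_equal(unname(cmp$section_peaks[1, ]), unname(cmp$section_peaks[2, ]),
               tolerance = 1e-8)
})
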