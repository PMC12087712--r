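test_that("patch test: imposed linear displacement reproduces uniform strain", {
  mesh <- jittered_cube(n = 4, h = 1, jitter = 0.2, seed = 5)
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 3e-4, 8e-4), 3, 3)     # symmetric displacement gradient
  bnd <- cube_boundary_nodes(mesh)
  bcs <- boundary_conditions(
    fixed = list(skin = list(nodes = bnd, dofs = 1:3,
                             value = mesh$nodes[bnd, ] %*% t(A))))
  sol <- assemble_and_solve(mesh, uniform_field(mesh), bcs)
  expected <- c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[2, 3], A[1, 3])
  rel <- max(abs(sweep(sol$strain, 2, expected))) / max(abs(expected))
  expect_lt(rel, 1e-10)
  # displacement field itself is linear everywhere
  expect_lt(max(abs(sol$u - mesh$nodes %*% t(A))), 1e-12)
})

test_that("single-tetrahedron solve equals the dense 12x12 stiffness oracle", {
  mesh <- single_tet()
  field <- material_field(1200, 0.27)
  force <- c(3, -2, 5)
  bcs <- boundary_conditions(
    fixed = list(base = list(nodes = 1:3, dofs = 1:3)),
    loads = list(apex = list(nodes = 4L, force = force)))
  sol <- assemble_and_solve(mesh, field, bcs)
  # dense oracle: assemble the 12x12 from scratch with numerical gradients
  K <- matrix(0, 12, 12)
  V <- element_volumes(mesh)
  E <- 1200; nu <- 0.27
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  # B matrix by finite differences of the linear shape functions
  shape <- function(x) {
    M <- cbind(1, mesh$nodes)
    as.numeric(solve(t(M), c(1, x)))
  }
  h <- 1e-6
  G <- matrix(0, 4, 3)
  for (a in 1:4) for (j in 1:3) {
    xp <- xm <- colMeans(mesh$nodes)
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    G[a, j] <- (shape(xp)[a] - shape(xm)[a]) / (2 * h)
  }
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- G[a, 1]; B[2, c0 + 2] <- G[a, 2]; B[3, c0 + 3] <- G[a, 3]
    B[4, c0 + 1] <- G[a, 2]; B[4, c0 + 2] <- G[a, 1]
    B[5, c0 + 2] <- G[a, 3]; B[5, c0 + 3] <- G[a, 2]
    B[6, c0 + 1] <- G[a, 3]; B[6, c0 + 3] <- G[a, 1]
  }
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  K <- V * t(B) %*% D %*% B
  u4 <- solve(K[10:12, 10:12], force)
  expect_equal(sol$u[4, ], u4, tolerance = 1e-6)
})

test_that("strain recovery: rigid motion gives zero strain, linear stretch is exact", {
  mesh <- jittered_cube(n = 3, h = 1, jitter = 0.15, seed = 7)
  field <- uniform_field(mesh)
  # rigid translation + small rotation
  theta <- 1e-6
  R <- matrix(c(0, -theta, 0, theta, 0, 0, 0, 0, 0), 3, 3)
  u_rigid <- matrix(rep(c(0.3, -0.2, 0.5), each = nrow(mesh$nodes)), ncol = 3) +
    mesh$nodes %*% t(R)
  rec <- recover_strain_stress(mesh, field, u_rigid)
  expect_lt(max(abs(rec$strain)), 1e-12)
  # uniaxial stretch u_x = alpha x
  alpha <- 2e-3
  u_ax <- cbind(alpha * mesh$nodes[, 1], 0, 0)
  rec2 <- recover_strain_stress(mesh, field, u_ax)
  expect_equal(unname(rec2$strain[, 1]), rep(alpha, nrow(mesh$elems)),
               tolerance = 1e-12)
  expect_lt(max(abs(rec2$strain[, 2:6])), 1e-15)
})

test_that("recovered stress is energy-consistent with the stiffness matrix", {
  mesh <- single_tet()
  field <- material_field(800, 0.3)
  set.seed(13)
  u <- matrix(rnorm(12, sd = 1e-3), ncol = 3)
  rec <- recover_strain_stress(mesh, field, u)
  V <- element_volumes(mesh)
  # strain energy from recovered tensors (shear components counted twice)
  W_rec <- 0.5 * V * sum(rec$stress[1, 1:3] * rec$strain[1, 1:3] +
                         2 * rec$stress[1, 4:6] * rec$strain[1, 4:6])
  K <- as.matrix(osteofe:::assemble_stiffness(mesh, field))
  uv <- as.numeric(t(u))
  W_K <- 0.5 * sum(uv * (K %*% uv))
  expect_equal(W_rec, W_K, tolerance = 1e-10)
  # finite-difference gradient of the recovery-based energy equals K u
  energy <- function(uvec) {
    um <- matrix(uvec, ncol = 3, byrow = TRUE)
    r <- recover_strain_stress(mesh, field, um)
    0.5 * V * sum(r$stress[1, 1:3] * r$strain[1, 1:3] +
                  2 * r$stress[1, 4:6] * r$strain[1, 4:6])
  }
  g_fd <- numeric(12)
  h <- 1e-7
  for (i in 1:12) {
    up <- um <- uv; up[i] <- up[i] + h; um[i] <- um[i] - h
    g_fd[i] <- (energy(up) - energy(um)) / (2 * h)
  }
  expect_equal(g_fd, as.numeric(K %*% uv), tolerance = 1e-5)
})

test_that("von Mises and principal values follow the tensor invariants", {
  # hydrostatic stress is deviatoric-free
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  # uniaxial stress
  s <- matrix(0, 3, 3); s[1, 1] <- -7.5
  expect_equal(von_mises(s), 7.5)
  expect_error(von_mises(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)), "symmetric")
  # random symmetric tensors against the independent eigen-solver
  set.seed(17)
  for (k in 1:50) {
    a <- matrix(rnorm(9), 3, 3); a <- (a + t(a)) / 2
    pr <- principal_strains(a)
    expect_equal(as.numeric(pr), sort(eigen(a, symmetric = TRUE)$values,
                                      decreasing = TRUE), tolerance = 1e-10)
  }
  # vectorized path agrees with the one-tensor path
  comp <- cbind(rnorm(20), rnorm(20), rnorm(20), rnorm(20), rnorm(20), rnorm(20))
  pr_all <- principal_strains(comp)
  for (k in 1:20) {
    a <- matrix(c(comp[k, 1], comp[k, 4], comp[k, 6],
                  comp[k, 4], comp[k, 2], comp[k, 5],
                  comp[k, 6], comp[k, 5], comp[k, 3]), 3, 3)
    expect_equal(unname(pr_all[k, ]),
                 sort(eigen(a, symmetric = TRUE)$values, decreasing = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("global equilibrium closes and the solution is linear in load and stiffness", {
  mesh <- jittered_cube(n = 3, h = 2, jitter = 0.1, seed = 19)
  field <- uniform_field(mesh, E = 3000)
  base <- which(abs(mesh$nodes[, 3]) < 1e-9)
  top <- which(abs(mesh$nodes[, 3] - 6) < 1e-9)
  bcs <- boundary_conditions(
    fixed = list(base = list(nodes = base, dofs = 1:3)),
    loads = list(top = list(nodes = top, force = c(40, -25, -100))))
  sol <- assemble_and_solve(mesh, field, bcs)
  rp <- reaction_partition(sol, list(base = base))
  expect_lt(rp$equilibrium_residual, 1e-6)
  expect_equal(rp$per_set$base, -c(40, -25, -100), tolerance = 1e-8)

  # doubling all moduli halves all displacements
  sol2 <- assemble_and_solve(mesh, uniform_field(mesh, E = 6000), bcs)
  expect_equal(sol2$u, sol$u / 2, tolerance = 1e-9)

  # doubling the load doubles the response
  bcs2 <- boundary_conditions(bcs$fixed,
    loads = list(top = list(nodes = top, force = 2 * c(40, -25, -100))))
  sol3 <- assemble_and_solve(mesh, field, bcs2)
  expect_equal(sol3$u, 2 * sol$u, tolerance = 1e-9)
})

test_that("solution is invariant under node renumbering", {
  mesh <- jittered_cube(n = 2, h = 1, jitter = 0.1, seed = 23)
  field <- uniform_field(mesh)
  base <- which(abs(mesh$nodes[, 3]) < 1e-9)
  top <- which(abs(mesh$nodes[, 3] - 2) < 1e-9)
  bcs <- boundary_conditions(
    fixed = list(base = list(nodes = base, dofs = 1:3)),
    loads = list(top = list(nodes = top, force = c(5, 3, -20))))
  sol <- assemble_and_solve(mesh, field, bcs)
  set.seed(29)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- tet_mesh(mesh$nodes[perm, ], matrix(inv[mesh$elems], ncol = 4),
                 mesh$region)
  bcs2 <- boundary_conditions(
    fixed = list(base = list(nodes = inv[base], dofs = 1:3)),
    loads = list(top = list(nodes = inv[top], force = c(5, 3, -20))))
  sol2 <- assemble_and_solve(m2, field, bcs2)
  expect_equal(sol2$u[inv, ], sol$u, tolerance = 1e-9)
})

test_that("raising any element's modulus never increases the external work", {
  mesh <- jittered_cube(n = 2, h = 1, jitter = 0.15, seed = 31)
  base <- which(abs(mesh$nodes[, 3]) < 1e-9)
  top <- which(abs(mesh$nodes[, 3] - 2) < 1e-9)
  bcs <- boundary_conditions(
    fixed = list(base = list(nodes = base, dofs = 1:3)),
    loads = list(top = list(nodes = top, force = c(10, 5, -50))))
  E0 <- rep(2000, nrow(mesh$elems))
  work <- function(E) {
    f <- material_field(E, rep(0.3, nrow(mesh$elems)))
    s <- assemble_and_solve(mesh, f, bcs)
    sum(s$f_ext * s$u)
  }
  w0 <- work(E0)
  set.seed(37)
  for (e in sample(nrow(mesh$elems), 4)) {
    E1 <- E0; E1[e] <- E0[e] * 5
    expect_lte(work(E1), w0 + 1e-9 * abs(w0))
  }
})

test_that("under-constrained systems and overlapping reaction sets are rejected", {
  mesh <- single_tet()
  field <- material_field(1000, 0.3)
  expect_error(assemble_and_solve(mesh, field,
    boundary_conditions(fixed = list(one = list(nodes = 1L, dofs = 1L)),
                        loads = list(t = list(nodes = 4L, force = c(0, 0, 1))))),
    "singular")
  bcs <- boundary_conditions(fixed = list(base = list(nodes = 1:3, dofs = 1:3)),
                             loads = list(t = list(nodes = 4L, force = c(0, 0, 1))))
  sol <- assemble_and_solve(mesh, field, bcs)
  expect_error(reaction_partition(sol, list(a = 1:2, b = 2:3)), "overlap")
})
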