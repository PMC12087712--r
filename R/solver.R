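#' Boundary conditions for the linear-static solve
#'
#' @param fixed named list of constraints; each entry is a list with
#'   `nodes` (integer indices), `dofs` (subset of 1:3 — x, y, z), and
#'   optionally `value` (prescribed displacement, mm; default 0).
#' @param loads named list of loads; each entry is a list with `nodes`
#'   and `force` (total force vector, N, shared equally over the nodes).
#' @return an object of class `boundary_conditions`.
#' @examples
#' bcs <- boundary_conditions(
#'   fixed = list(base = list(nodes = 1:4, dofs = 1:3)),
#'   loads = list(tip = list(nodes = 9L, force = c(0, 0, -100)))
#' )
#' @export
boundary_conditions <- function(fixed = list(), loads = list()) {
  for (f in fixed) {
    if (!all(f$dofs %in% 1:3)) stopf("constraint dofs must be within 1:3")
    if (!length(f$nodes)) stopf("empty constraint node set")
  }
  for (l in loads) {
    if (length(l$force) != 3) stopf("load force must be length 3")
    if (!length(l$nodes)) stopf("empty load node set")
  }
  structure(list(fixed = fixed, loads = loads), class = "boundary_conditions")
}

lame_parameters <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# shape-function gradients and volumes for all elements
# returns list(vol, grad = list over a=1..4 of m x 3 gradient matrices)
tet_gradients <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  a1 <- n[e[, 2], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  a2 <- n[e[, 3], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  a3 <- n[e[, 4], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  det <- a1[, 1] * (a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2]) -
         a1[, 2] * (a2[, 1] * a3[, 3] - a2[, 3] * a3[, 1]) +
         a1[, 3] * (a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1])
  if (any(det <= 0)) stopf("non-positive element volume in stiffness assembly")
  # rows of inv(J) where J has rows a1, a2, a3: grad N_{1+a} = row a of inv(J)
  inv <- list(
    cbind(a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2],
          a1[, 3] * a3[, 2] - a1[, 2] * a3[, 3],
          a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2]) / det,
    cbind(a2[, 3] * a3[, 1] - a2[, 1] * a3[, 3],
          a1[, 1] * a3[, 3] - a1[, 3] * a3[, 1],
          a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3]) / det,
    cbind(a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1],
          a1[, 2] * a3[, 1] - a1[, 1] * a3[, 2],
          a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1]) / det
  )
  # inv above is stored column-wise: inv[[k]] is column k of inv(J)?  build rows:
  g2 <- cbind(inv[[1]][, 1], inv[[2]][, 1], inv[[3]][, 1])
  g3 <- cbind(inv[[1]][, 2], inv[[2]][, 2], inv[[3]][, 2])
  g4 <- cbind(inv[[1]][, 3], inv[[2]][, 3], inv[[3]][, 3])
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6, grad = list(g1, g2, g3, g4))
}

#' Assemble and solve the heterogeneous linear-elastic system
#'
#' Small-strain isotropic elasticity on linear (constant-strain)
#' tetrahedra: assembles the sparse symmetric stiffness matrix `K`,
#' eliminates prescribed dofs, and solves `K u = f` by sparse Cholesky
#' factorization. Strain and stress recovery and the reaction forces are
#' returned alongside the displacements.
#'
#' @param mesh a [tet_mesh()].
#' @param field a [material_field()].
#' @param bcs a [boundary_conditions()].
#' @return an object of class `fe_solution`: `u` (n x 3 displacements,
#'   mm), `strain` and `stress` (m x 6, components xx, yy, zz, xy, yz,
#'   zx; stress in MPa), `reactions` (n x 3, N, nonzero only at
#'   constrained dofs), `f_ext` (n x 3 applied loads, N).
#' @export
assemble_and_solve <- function(mesh, field, bcs) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(field, "material_field"),
            inherits(bcs, "boundary_conditions"))
  nn <- nrow(mesh$nodes); ndof <- 3L * nn
  K <- assemble_stiffness(mesh, field)

  f <- numeric(ndof)
  for (l in bcs$loads) {
    share <- 1 / length(l$nodes)
    for (j in 1:3)
      f[3 * (l$nodes - 1L) + j] <- f[3 * (l$nodes - 1L) + j] + l$force[j] * share
  }

  fixed_dof <- integer(0); fixed_val <- numeric(0)
  for (fx in bcs$fixed) {
    # dof ids as [node, dof] matrix flattened column-wise
    dofs <- as.vector(outer(3 * (fx$nodes - 1L), fx$dofs, `+`))
    val <- fx$value %||% 0
    vals <- if (is.matrix(val)) {
      # (n_nodes x n_dofs) prescribed displacement matrix
      if (!all(dim(val) == c(length(fx$nodes), length(fx$dofs))))
        stopf("prescribed value matrix must be n_nodes x n_dofs")
      as.vector(val)
    } else rep(val, length.out = length(dofs))
    fixed_dof <- c(fixed_dof, dofs); fixed_val <- c(fixed_val, vals)
  }
  keep <- !duplicated(fixed_dof)
  fixed_dof <- fixed_dof[keep]; fixed_val <- fixed_val[keep]
  if (!length(fixed_dof)) stopf("no constraints: system has rigid-body modes")
  free <- setdiff(seq_len(ndof), fixed_dof)

  u <- numeric(ndof)
  u[fixed_dof] <- fixed_val
  rhs <- f[free]
  if (any(fixed_val != 0))
    rhs <- rhs - as.numeric(K[free, fixed_dof, drop = FALSE] %*% fixed_val)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  # CHOLMOD warns before erroring on indefinite systems; the error is the signal
  sol <- tryCatch(
    suppressWarnings(
      Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs, system = "A")),
    error = function(e) stopf("stiffness system is singular (under-constrained?): %s",
                              conditionMessage(e)))
  u[free] <- as.numeric(sol)

  resid <- as.numeric(K %*% u) - f
  reactions <- matrix(0, nn, 3)
  reactions[cbind((fixed_dof - 1L) %/% 3L + 1L, (fixed_dof - 1L) %% 3L + 1L)] <-
    resid[fixed_dof]

  um <- matrix(u, ncol = 3, byrow = TRUE)
  rec <- recover_strain_stress(mesh, field, um)
  structure(list(
    u = um, strain = rec$strain, stress = rec$stress,
    reactions = reactions, f_ext = matrix(f, ncol = 3, byrow = TRUE),
    fixed_dof = fixed_dof
  ), class = "fe_solution")
}

assemble_stiffness <- function(mesh, field) {
  g <- tet_gradients(mesh)
  lam <- lame_parameters(field$E_elem, field$nu_elem)
  V <- g$vol
  m <- nrow(mesh$elems)
  blocks <- 144L
  ii <- integer(blocks * m); jj <- integer(blocks * m); xx <- numeric(blocks * m)
  pos <- 0L
  for (a in 1:4) {
    ga <- g$grad[[a]]
    ra <- 3L * (mesh$elems[, a] - 1L)
    for (b in 1:4) {
      gb <- g$grad[[b]]
      rb <- 3L * (mesh$elems[, b] - 1L)
      dot <- rowSums(ga * gb)
      for (i in 1:3) for (j in 1:3) {
        v <- V * (lam$lambda * ga[, i] * gb[, j] + lam$mu * ga[, j] * gb[, i])
        if (i == j) v <- v + V * lam$mu * dot
        idx <- pos + seq_len(m)
        ii[idx] <- ra + i; jj[idx] <- rb + j; xx[idx] <- v
        pos <- pos + m
      }
    }
  }
  ndof <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

#' Recover element strain and stress from nodal displacements
#'
#' Constant-strain recovery: the infinitesimal strain tensor from the
#' linear shape-function gradients, then Hooke's law
#' `sigma = lambda tr(eps) I + 2 mu eps` per element.
#'
#' @param mesh a [tet_mesh()].
#' @param field a [material_field()].
#' @param u n x 3 nodal displacement matrix, mm.
#' @return list with `strain` and `stress`, both m x 6 matrices with
#'   columns `xx, yy, zz, xy, yz, zx` (tensor shear components).
#' @export
recover_strain_stress <- function(mesh, field, u) {
  g <- tet_gradients(mesh)
  m <- nrow(mesh$elems)
  H <- matrix(0, m, 9)   # displacement gradient du_i/dx_j, columns i*3+j
  for (a in 1:4) {
    ua <- u[mesh$elems[, a], , drop = FALSE]
    ga <- g$grad[[a]]
    for (i in 1:3) for (j in 1:3)
      H[, (i - 1) * 3 + j] <- H[, (i - 1) * 3 + j] + ua[, i] * ga[, j]
  }
  eps <- cbind(
    xx = H[, 1], yy = H[, 5], zz = H[, 9],
    xy = (H[, 2] + H[, 4]) / 2,
    yz = (H[, 6] + H[, 8]) / 2,
    zx = (H[, 3] + H[, 7]) / 2
  )
  lam <- lame_parameters(field$E_elem, field$nu_elem)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  stress <- cbind(
    xx = lam$lambda * tr + 2 * lam$mu * eps[, 1],
    yy = lam$lambda * tr + 2 * lam$mu * eps[, 2],
    zz = lam$lambda * tr + 2 * lam$mu * eps[, 3],
    xy = 2 * lam$mu * eps[, 4],
    yz = 2 * lam$mu * eps[, 5],
    zx = 2 * lam$mu * eps[, 6]
  )
  list(strain = eps, stress = stress)
}

#' Von Mises equivalent stress
#'
#' @param stress m x 6 matrix (columns xx, yy, zz, xy, yz, zx) or a
#'   symmetric 3 x 3 stress tensor, MPa.
#' @return non-negative scalar(s), MPa.
#' @export
von_mises <- function(stress) {
  s <- as_tensor6(stress)
  sqrt(pmax(0,
    0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
    3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)
  ))
}

#' Principal values of symmetric tensors
#'
#' Closed-form (trigonometric) eigenvalues of each symmetric 3 x 3
#' tensor, sorted descending.
#'
#' @param strain m x 6 matrix (columns xx, yy, zz, xy, yz, zx) or a
#'   symmetric 3 x 3 tensor.
#' @return m x 3 matrix; column 1 the maximum (most tensile) principal
#'   value, column 3 the minimum (most compressive).
#' @export
principal_strains <- function(strain) {
  s <- as_tensor6(strain)
  a11 <- s[, 1]; a22 <- s[, 2]; a33 <- s[, 3]
  a12 <- s[, 4]; a23 <- s[, 5]; a13 <- s[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(p2 / 6)
  out <- matrix(rep(q, 3), ncol = 3)
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b23 <- a23[nz] / p[nz]; b13 <- a13[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    out[nz, ] <- cbind(e1, e2, e3)
  }
  colnames(out) <- c("e1", "e2", "e3")
  out
}

as_tensor6 <- function(x) {
  if (is.matrix(x) && nrow(x) == 3 && ncol(x) == 3) {
    if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x))))
      stopf("tensor input must be symmetric")
    return(matrix(c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[2, 3], x[1, 3]),
                  nrow = 1))
  }
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != 6) stopf("expected an m x 6 component matrix or a 3 x 3 tensor")
  x
}

#' Partition reaction forces over node sets
#'
#' Sums the reaction force vector over each named node set and checks
#' global equilibrium (reactions balance applied loads).
#'
#' @param solution an `fe_solution` (see [assemble_and_solve()]).
#' @param node_sets named list of node-index vectors; sets must not
#'   overlap.
#' @return list with `per_set` (named list of 3-vectors, N), `total`
#'   reaction vector, and `equilibrium_residual` (|sum reactions + sum
#'   loads| / |loads|).
#' @export
reaction_partition <- function(solution, node_sets) {
  all_nodes <- unlist(node_sets)
  if (anyDuplicated(all_nodes)) stopf("node sets overlap")
  per_set <- lapply(node_sets, function(ns) colSums(solution$reactions[ns, , drop = FALSE]))
  total <- colSums(solution$reactions)
  load <- colSums(solution$f_ext)
  denom <- max(sqrt(sum(load^2)), 1e-300)
  list(per_set = per_set, total = total,
       equilibrium_residual = sqrt(sum((total + load)^2)) / denom)
}
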