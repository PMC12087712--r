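# Shared fixtures and independent oracles used across the suite.

# exhaustive nearest-voxel scan: O(V) distance loop, ties -> lowest linear index
oracle_nearest_voxel <- function(vol, pt) {
  cx <- voxel_centers(vol, 1); cy <- voxel_centers(vol, 2); cz <- voxel_centers(vol, 3)
  d2 <- outer(outer((cx - pt[1])^2, (cy - pt[2])^2, "+"), (cz - pt[3])^2, "+")
  which(d2 == min(d2))[1]
}

# Monte-Carlo volume average of the nearest-voxel HU field over one tetrahedron
oracle_mc_mean_hu <- function(db, verts, n = 2e5) {
  # uniform barycentric sampling via sorted uniform triples (vectorized sort)
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  mn <- pmin(u1, u2, u3); mx <- pmax(u1, u2, u3)
  md <- u1 + u2 + u3 - mn - mx
  w <- cbind(mn, md - mn, mx - md, 1 - mx)
  pts <- w %*% verts
  mean(nearest_voxel(db, pts)$hu)
}

# reorder four vertices so the tetrahedron is positively oriented
orient_tet <- function(verts) {
  v <- det(rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
                 verts[4, ] - verts[1, ]))
  if (v < 0) verts[c(1, 2, 4, 3), ] else verts
}

# small irregular one-tet mesh
single_tet <- function() {
  nodes <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0.1, 0.9, 0), c(0.25, 0.3, 1.05))
  tet_mesh(nodes, matrix(1:4, 1), "bone")
}

# a small lattice cube mesh with optional interior jitter (stays valid)
jittered_cube <- function(n = 4, h = 1, jitter = 0.2, seed = 5) {
  mesh <- lattice_tet_mesh(function(p) rep("bone", nrow(p)),
                           c(0, 0, 0), c(n, n, n) * h, h)
  set.seed(seed)
  interior <- which(apply(mesh$nodes, 1, function(r)
    all(r > h / 2) && all(r < n * h - h / 2)))
  mesh$nodes[interior, ] <- mesh$nodes[interior, ] +
    matrix(runif(length(interior) * 3, -jitter, jitter) * h, ncol = 3)
  mesh
}

cube_boundary_nodes <- function(mesh) {
  lim <- range(mesh$nodes)
  which(apply(mesh$nodes, 1, function(r)
    any(abs(r - lim[1]) < 1e-9) || any(abs(r - lim[2]) < 1e-9)))
}

uniform_field <- function(mesh, E = 5000, nu = 0.3) {
  material_field(rep(E, nrow(mesh$elems)), rep(nu, nrow(mesh$elems)))
}

# O(n^2) neighborhood averaging oracle for the plate-stress disc average
oracle_disc_average <- function(cen, val, vol, radius) {
  out <- numeric(length(val))
  for (q in seq_along(val)) {
    d2 <- rowSums((cen - matrix(cen[q, ], nrow(cen), 3, byrow = TRUE))^2)
    nb <- d2 <= radius^2
    out[q] <- sum(val[nb] * vol[nb]) / sum(vol[nb])
  }
  out
}

# the tiny plated-phantom assembly is expensive enough to share across files
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixtures("tiny_assembly", seed = 3)
    cache
  }
})
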