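# Shared fixture builders and independent brute-force oracles.

# Regular planar grid in z = const, CCW seen from +z.
grid_mesh <- function(x0, x1, y0, y1, nx, ny, z = 0) {
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  V <- cbind(as.matrix(expand.grid(x = xs, y = ys)), z)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  Fm <- matrix(0L, 0, 3)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    Fm <- rbind(Fm,
                c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  }
  trimesh(V, Fm)
}

# Open cylindrical tube sector (no caps), outward normals.
tube_mesh <- function(th0, th1, nth, r = 10, L = 40, nz = 16) {
  th <- seq(th0, th1, length.out = nth + 1)
  zs <- seq(0, L, length.out = nz + 1)
  V <- NULL
  for (z in zs) V <- rbind(V, cbind(r * cos(th), r * sin(th), z))
  id <- function(j, i) (j - 1L) * (nth + 1L) + i
  Fm <- matrix(0L, 0, 3)
  for (j in seq_len(nz)) for (i in seq_len(nth)) {
    Fm <- rbind(Fm,
                c(id(j, i), id(j, i + 1L), id(j + 1L, i + 1L)),
                c(id(j, i), id(j + 1L, i + 1L), id(j + 1L, i)))
  }
  trimesh(V, Fm)
}

# Regular icosahedron centered at the origin.
icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  Fm <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
              c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
              c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
              c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
              c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  trimesh(V, Fm)
}

# Independent point-triangle closest point: plane projection with an
# inside test, else the best of the three edge segments. Different
# derivation from the region-based production code.
oracle_point_triangle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nl <- sqrt(sum(n^2))
  cand <- list()
  if (nl > 0) {
    n <- n / nl
    proj <- p - sum((p - a) * n) * n
    # inside test via same-side sign of edge cross products
    s1 <- sum(pracma_cross(b - a, proj - a) * n)
    s2 <- sum(pracma_cross(c - b, proj - b) * n)
    s3 <- sum(pracma_cross(a - c, proj - c) * n)
    if (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12)
      cand[[length(cand) + 1L]] <- proj
  }
  seg <- function(u, v) {
    uv <- v - u
    t <- sum((p - u) * uv) / sum(uv^2)
    u + min(1, max(0, t)) * uv
  }
  cand <- c(cand, list(seg(a, b), seg(b, c), seg(c, a)))
  d <- vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1))
  list(point = cand[[which.min(d)]], dist = min(d))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Exhaustive nearest-surface-point search: scans faces in index order with
# strict improvement so exact ties resolve to the lowest face index. Also
# reports the set of faces within `tie_tol` of the minimum: two
# independent floating-point routes can legitimately disagree inside that
# set (geometrically equidistant faces), but never outside it.
oracle_closest <- function(p, mesh, tie_tol = 1e-12) {
  dists <- vapply(seq_len(nrow(mesh$faces)), function(f) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    oracle_point_triangle(p, tri[1, ], tri[2, ], tri[3, ])$dist
  }, numeric(1))
  f <- which.min(dists) # which.min returns the first (lowest) index
  tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
  list(dist = dists[f], face = f,
       point = oracle_point_triangle(p, tri[1, ], tri[2, ], tri[3, ])$point,
       tie_set = which(dists <= dists[f] + tie_tol))
}

# Edge census oracle: per-vertex boundary flag by counting incident faces
# of each undirected edge by brute force.
oracle_boundary_flags <- function(mesh) {
  n <- nrow(mesh$vertices)
  flag <- logical(n)
  Fm <- mesh$faces
  keys <- character(0)
  for (f in seq_len(nrow(Fm))) {
    tri <- Fm[f, ]
    keys <- c(keys, paste(pmin(tri, tri[c(2, 3, 1)]),
                          pmax(tri, tri[c(2, 3, 1)])))
  }
  tab <- table(keys)
  single <- names(tab)[tab == 1L]
  for (s in single) {
    ij <- as.integer(strsplit(s, " ")[[1]])
    flag[ij] <- TRUE
  }
  flag
}

count_boundary_edges <- function(mesh) {
  ec <- bonereduce:::edge_census(mesh)
  sum(ec$count == 1L)
}

count_nonmanifold_edges <- function(mesh) {
  ec <- bonereduce:::edge_census(mesh)
  sum(ec$count > 2L)
}

# RMS vertex error of a recovered fragment pose against its reference.
pose_rms <- function(fit, displaced_mesh, reference_mesh) {
  rec <- predict(fit, displaced_mesh)
  sqrt(mean(rowSums((rec$vertices - reference_mesh$vertices)^2)))
}

# Standard noise-free single-cut alignment problem used across tests.
make_alignment_problem <- function(seed, sigma = 0, max_rot_deg = 5,
                                   max_trans_mm = 2, resolution = 28) {
  case <- make_fracture_case(phantom_params = list(resolution = resolution),
                             max_rot_deg = max_rot_deg,
                             max_trans_mm = max_trans_mm,
                             sigma = sigma, seed = seed)
  list(case = case,
       src = fracture_patch_mesh(case$fragments[[2]]),
       tgt = fracture_patch_mesh(case$fragments[[1]]))
}
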