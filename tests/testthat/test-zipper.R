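phantom_halves <- function(resolution = 24, zc = 40, band = 6) {
  ph <- make_phantom(resolution = resolution)
  fc <- (ph$vertices[ph$faces[, 1], 3] + ph$vertices[ph$faces[, 2], 3] +
           ph$vertices[ph$faces[, 3], 3]) / 3
  list(phantom = ph,
       N = bonereduce:::compact_mesh(
         bonereduce:::submesh_faces(ph, which(fc < zc + band))),
       M = bonereduce:::compact_mesh(
         bonereduce:::submesh_faces(ph, which(fc > zc - band))))
}

test_that("redundancy removal leaves disjoint meshes untouched", {
  A <- grid_mesh(0, 5, 0, 5, 5, 5, z = 0)
  B <- grid_mesh(0, 5, 0, 5, 5, 5, z = 10)
  rr <- remove_redundant(A, B, d = 1)
  expect_length(rr$removed_N, 0)
  expect_length(rr$removed_M, 0)
  expect_error(remove_redundant(A, B, d = 0), "d must be > 0")
})

test_that("identical overlapping copies thin one copy to the rim", {
  A <- grid_mesh(0, 6, 0, 6, 6, 6)
  B <- grid_mesh(0, 6, 0, 6, 6, 6)
  rr <- remove_redundant(A, B, d = 0.5) # A thinned first
  expect_gt(length(rr$removed_N), 0)
  expect_length(rr$removed_M, 0) # second copy untouched: union still covers
  # every removed face had all 3 vertices on non-boundary positions of B
  bflag <- oracle_boundary_flags(B)
  for (f in rr$removed_N) {
    tri <- A$faces[f, ]
    # A and B share the same grid: vertex v of A coincides with v of B
    expect_true(all(!bflag[tri]))
  }
})

test_that("redundancy removal equals per-triangle brute force on strips", {
  A <- grid_mesh(0, 8, 0, 3, 8, 3, z = 0)
  B <- grid_mesh(5, 13, 0, 3, 8, 3, z = 0.1)
  d <- 0.6
  # brute-force simulation of the alternating rule
  aliveA <- rep(TRUE, nrow(A$faces))
  aliveB <- rep(TRUE, nrow(B$faces))
  pass <- function(X, aliveX, Y, aliveY) {
    if (!any(aliveY)) return(integer(0))
    Ysub <- bonereduce:::submesh_faces(Y, which(aliveY))
    bflag <- oracle_boundary_flags(Ysub)
    bedges <- detect_boundary(Ysub)$edges
    out <- integer(0)
    for (f in which(aliveX)) {
      ok <- TRUE
      for (v in X$faces[f, ]) {
        o <- oracle_closest(X$vertices[v, ], Ysub)
        if (o$dist > d) { ok <- FALSE; break }
        # boundary contact: nearest point within 1e-9 of a boundary edge
        onb <- FALSE
        for (k in seq_len(nrow(bedges))) {
          a <- Ysub$vertices[bedges[k, 1], ]
          b <- Ysub$vertices[bedges[k, 2], ]
          ab <- b - a
          t <- min(1, max(0, sum((o$point - a) * ab) / sum(ab^2)))
          if (sqrt(sum((o$point - (a + t * ab))^2)) <= 1e-9) {
            onb <- TRUE
            break
          }
        }
        if (onb) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, f)
    }
    out
  }
  repeat {
    r1 <- pass(B, aliveB, A, aliveA) # N = B thinned first
    aliveB[r1] <- FALSE
    r2 <- pass(A, aliveA, B, aliveB)
    aliveA[r2] <- FALSE
    if (!length(r1) && !length(r2)) break
  }
  rr <- remove_redundant(B, A, d)
  expect_setequal(rr$removed_N, which(!aliveB))
  expect_setequal(rr$removed_M, which(!aliveA))
})

test_that("wall extension sweeps the boundary along the surface normal", {
  g <- grid_mesh(0, 6, 0, 6, 6, 6)
  w <- extend_wall(g, height = 2)
  expect_length(w$walls, 1)
  # planar mesh in z = 0: every wall triangle is perpendicular to the plane
  for (wl in w$walls) {
    fn <- face_normals(trimesh(wl$vertices, wl$faces,
                               validate = FALSE))$normals
    expect_true(all(abs(fn[, 3]) < 1e-6))
    expect_identical(nrow(wl$faces), 2L * length(wl$loop))
    # each wall quad contains its parent boundary edge midpoint
    for (k in seq_len(nrow(wl$faces))) {
      pe <- wl$parent_edge[k, ]
      mid <- (g$vertices[pe[1], ] + g$vertices[pe[2], ]) / 2
      tri <- wl$vertices[wl$faces[k, ], , drop = FALSE]
      o <- oracle_point_triangle(mid, tri[1, ], tri[2, ], tri[3, ])
      if (k %% 2 == 1) expect_lt(o$dist, 1e-9) # first tri of the quad
    }
  }
  expect_error(extend_wall(icosahedron_mesh(), 1), "nothing to extend")
})

test_that("a square hole in a plane gets one wall loop", {
  g <- grid_mesh(0, 6, 0, 6, 6, 6)
  # punch out the central 2x2 cells
  cen <- (g$vertices[g$faces[, 1], , drop = FALSE] +
            g$vertices[g$faces[, 2], , drop = FALSE] +
            g$vertices[g$faces[, 3], , drop = FALSE]) / 3
  keep <- !(cen[, 1] > 2 & cen[, 1] < 4 & cen[, 2] > 2 & cen[, 2] < 4)
  holed <- bonereduce:::compact_mesh(
    bonereduce:::submesh_faces(g, which(keep)))
  w <- extend_wall(holed, 1)
  expect_length(w$walls, 2) # outer rim + hole
  lens <- vapply(w$walls, function(wl) length(wl$loop), integer(1))
  hole <- w$walls[[which.min(lens)]]
  expect_identical(nrow(hole$faces), 2L * length(hole$loop))
})

test_that("coplanar overlapping rectangles merge to exactly the union", {
  N <- grid_mesh(0, 10, 0, 6, 10, 6)
  M <- grid_mesh(4, 14, 1, 5, 10, 4)
  res <- zipper(M, N, d = 1.2)
  union_area <- 10 * 6 + 4 * 4 # N plus the part of M beyond x = 10
  expect_equal(mesh_area(res$mesh), union_area, tolerance = 1e-6)
  expect_identical(count_nonmanifold_edges(res$mesh), 0L)
  expect_gt(nrow(res$seam), 0)
  # seam points lie on both input surfaces (here: the shared plane)
  expect_true(all(abs(res$seam[, 3]) < 1e-9))
})

test_that("identical boundary curves weld without new triangles", {
  A <- grid_mesh(0, 4, 0, 4, 4, 4)
  B <- grid_mesh(4, 8, 0, 4, 4, 4) # shares the x = 4 boundary row exactly
  rr <- remove_redundant(B, A, d = 0.5)
  cm <- clip_and_merge(rr$M, rr$N, NULL, d = 0.5)
  expect_identical(cm$counts$created, 0L)
  expect_identical(nrow(cm$mesh$faces), nrow(A$faces) + nrow(B$faces))
  expect_gt(cm$welded, 0)
  expect_identical(count_boundary_edges(cm$mesh), 24L) # outer rim only
})

test_that("staggered strips merge without boundary inside the overlap", {
  A <- grid_mesh(0, 10, 0, 4, 10, 4, z = 0)
  B <- grid_mesh(8, 18, 0, 4, 10, 4, z = 0.2)
  res <- zipper(A, B, d = 1.1)
  expect_gt(nrow(res$seam), 0)
  m <- res$mesh
  expect_identical(count_nonmanifold_edges(m), 0L)
  ec <- bonereduce:::edge_census(m)
  bv <- unique(as.vector(ec$edges[ec$count == 1, , drop = FALSE]))
  pb <- m$vertices[bv, , drop = FALSE]
  inside <- pb[, 1] > 8.2 & pb[, 1] < 9.8 & pb[, 2] > 0.2 & pb[, 2] < 3.8
  expect_identical(sum(inside), 0L)
})

test_that("clipping errors when the surfaces never meet", {
  A <- grid_mesh(0, 5, 0, 5, 5, 5, z = 0)
  B <- grid_mesh(0, 5, 0, 5, 5, 5, z = 10)
  expect_error(zipper(A, B, d = 1), "do not meet")
})

test_that("small-triangle removal enforces the edge threshold", {
  g <- grid_mesh(0, 4, 0, 4, 4, 4)
  expect_identical(remove_small_triangles(g, 0)$faces, g$faces)
  # create a needle vertex a hair from vertex 1
  V <- rbind(g$vertices, g$vertices[1, ] + c(1e-4, 0, 0))
  Fm <- rbind(g$faces[-1, ], c(1, 26, 2), c(26, 7, 2))
  needle <- trimesh(V, Fm, validate = FALSE)
  out <- remove_small_triangles(needle, 1e-3)
  expect_lt(nrow(out$vertices), nrow(V))
  expect_identical(count_nonmanifold_edges(out), 0L)
  e <- bonereduce:::edge_census(out)$edges
  elen <- sqrt(rowSums((out$vertices[e[, 1], , drop = FALSE] -
                        out$vertices[e[, 2], , drop = FALSE])^2))
  expect_true(all(elen >= 1e-3))
})

test_that("a fully redundant patch is absorbed into the closed mesh", {
  ph <- make_phantom(resolution = 16)
  fc <- ph$vertices[ph$faces[, 1], 3]
  patch <- bonereduce:::compact_mesh(
    bonereduce:::submesh_faces(ph, which(fc > 20 & fc < 35)))
  res <- zipper(ph, patch, d = 0.5) # N = patch is thinned first
  expect_identical(nrow(res$mesh$faces), nrow(ph$faces))
  expect_identical(count_boundary_edges(res$mesh), 0L)
})

test_that("two overlapping halves of a closed phantom zipper watertight", {
  h <- phantom_halves()
  res <- zipper(h$M, h$N, d = 1.5)
  m <- res$mesh
  expect_identical(count_boundary_edges(m), 0L)
  expect_identical(count_nonmanifold_edges(m), 0L)
  expect_identical(euler_characteristic(m), 2L)
  expect_lt(abs(mesh_area(m) - mesh_area(h$phantom)) / mesh_area(h$phantom),
            0.02)
  # no surviving edge shorter than the cleanup threshold
  e <- bonereduce:::edge_census(m)$edges
  elen <- sqrt(rowSums((m$vertices[e[, 1], , drop = FALSE] -
                        m$vertices[e[, 2], , drop = FALSE])^2))
  expect_true(all(elen >= 0.15))
})

test_that("half-tubes merge into an open cylinder across both seams", {
  H1 <- tube_mesh(0, pi + 0.4, 20)
  H2 <- tube_mesh(pi, 2 * pi + 0.4, 20)
  res <- zipper(H1, H2, d = 2)
  m <- res$mesh
  expect_identical(count_nonmanifold_edges(m), 0L)
  expect_identical(euler_characteristic(m), 0L) # tube topology
  # boundary only at the two end rings, none along the lengthwise seams
  ec <- bonereduce:::edge_census(m)
  bv <- unique(as.vector(ec$edges[ec$count == 1, , drop = FALSE]))
  z <- m$vertices[bv, 3]
  expect_true(all(z < 1e-6 | z > 40 - 1e-6))
  expect_lt(abs(mesh_area(m) - 2 * pi * 10 * 40) / (2 * pi * 10 * 40),
            0.02)
})

test_that("consensus averaging pulls the survivor toward the removed
           geometry", {
  h <- phantom_halves(resolution = 16)
  # perturb the copy that will lose its overlap so averaging has an effect
  Nn <- add_noise(h$N, 0.15, seed = 4)
  plain <- zipper(h$M, Nn, d = 2)
  cons <- zipper(h$M, Nn, d = 2, consensus = TRUE)
  expect_identical(nrow(plain$mesh$faces), nrow(cons$mesh$faces))
  moved <- rowSums(abs(plain$mesh$vertices - cons$mesh$vertices)) > 0
  expect_gt(sum(moved), 0)
  expect_lt(max(sqrt(rowSums((plain$mesh$vertices -
                                cons$mesh$vertices)^2))), 2)
})

test_that("redundancy removal reaches a fixed point in few rounds", {
  h <- phantom_halves(resolution = 16)
  rr <- remove_redundant(h$N, h$M, d = 1.5)
  expect_lt(rr$rounds, 20)
  # running it again changes nothing
  rr2 <- remove_redundant(rr$N, rr$M, d = 1.5)
  expect_length(rr2$removed_N, 0)
  expect_length(rr2$removed_M, 0)
})
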