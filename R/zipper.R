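#' Alternating redundant-triangle removal
#'
#' Before two aligned meshes are joined, triangles that the opposite mesh
#' already covers are dropped: a triangle is redundant when the
#' distance-limited queries of its three vertices against the other mesh
#' all succeed and hit only non-boundary points. Removal alternates (first
#' from `N`, then from `M`) and repeats until both meshes remain unchanged.
#' Faces are removed but vertex data is retained (available for optional
#' consensus averaging later).
#'
#' @param N,M aligned [trimesh()] objects (`N` is thinned first).
#' @param d query tolerance distance (mm, > 0).
#' @return list with `N`, `M` (reduced meshes, original vertex arrays
#'   intact), `removed_N`, `removed_M` (face-index vectors removed from the
#'   originals) and `rounds`.
#' @export
remove_redundant <- function(N, M, d) {
  if (d <= 0) stop("distance tolerance d must be > 0")
  aliveN <- rep(TRUE, nrow(N$faces))
  aliveM <- rep(TRUE, nrow(M$faces))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    r1 <- redundant_faces(N, aliveN, M, aliveM, d)
    aliveN[r1] <- FALSE
    r2 <- redundant_faces(M, aliveM, N, aliveN, d)
    aliveM[r2] <- FALSE
    if (!length(r1) && !length(r2)) break
  }
  list(N = submesh_faces(N, which(aliveN)),
       M = submesh_faces(M, which(aliveM)),
       removed_N = which(!aliveN), removed_M = which(!aliveM),
       rounds = rounds)
}

# Indices (into A's full face list) of alive A faces redundant against the
# alive part of B.
redundant_faces <- function(A, aliveA, B, aliveB, d) {
  if (!any(aliveA) || !any(aliveB)) return(integer(0))
  Bsub <- submesh_faces(B, which(aliveB))
  bnd <- detect_boundary(Bsub)
  Fa <- A$faces[aliveA, , drop = FALSE]
  vids <- sort(unique(as.vector(Fa)))
  q <- closest_points_cpp(A$vertices[vids, , drop = FALSE],
                          Bsub$vertices, Bsub$faces, d)
  ann <- annotate_surface_points(q, Bsub, bnd)
  ok <- logical(nrow(A$vertices))
  ok[vids] <- ann$found & !ann$on_boundary
  red <- ok[Fa[, 1]] & ok[Fa[, 2]] & ok[Fa[, 3]]
  which(aliveA)[red]
}

#' Boundary wall extension
#'
#' Extends every boundary loop of `N` by a strip of triangles approximately
#' perpendicular to the surface: each boundary vertex is swept by
#' half the wall height along its vertex normal in both directions, and
#' each boundary edge spans a two-triangle quad between the swept curves.
#' In three dimensions the edges of two meshes rarely intersect exactly;
#' the opposite mesh's boundary edges are intersected with these walls
#' instead.
#'
#' @param N a [trimesh()] with at least one boundary loop.
#' @param height total wall height (mm).
#' @return object of class `wall_extension`: per-loop list with `loop`
#'   (parent vertex ids), `vertices`, `faces` (into the wall's own
#'   vertices), `parent_edge` (k x 2 parent vertex ids per wall face) and
#'   the `height`.
#' @export
extend_wall <- function(N, height) {
  if (height <= 0) stop("wall height must be > 0")
  b <- detect_boundary(N)
  if (!length(b$loops))
    stop("nothing to extend: mesh has no boundary")
  # isolated vertices (retained by redundancy removal) are irrelevant here
  vn <- suppressWarnings(compute_vertex_normals(N))
  walls <- lapply(b$loops, function(loop) {
    L <- length(loop)
    P <- N$vertices[loop, , drop = FALSE]
    nrm <- vn[loop, , drop = FALSE]
    W <- rbind(P - height / 2 * nrm, P + height / 2 * nrm)
    i <- seq_len(L)
    j <- c(i[-1L], i[1L])
    faces <- rbind(cbind(i, j, L + j), cbind(i, L + j, L + i))
    parent <- rbind(cbind(loop[i], loop[j]), cbind(loop[i], loop[j]))
    list(loop = loop, vertices = W, faces = faces, parent_edge = parent)
  })
  structure(list(walls = walls, height = height), class = "wall_extension")
}

#' @export
print.wall_extension <- function(x, ...) {
  cat(sprintf("<wall_extension> %d loop(s), height %g mm, %d wall triangles\n",
              length(x$walls), x$height,
              sum(vapply(x$walls, function(w) nrow(w$faces), integer(1)))))
  invisible(x)
}

# Segment-triangle intersection: returns the intersection point of segment
# (p, q) with triangle (a, b, c) or NULL. Tolerant inclusive boundaries.
segment_triangle_intersection <- function(p, q, a, b, c, eps = 1e-6) {
  dir <- q - p
  e1 <- b - a
  e2 <- c - a
  h <- cross3(dir, e2)
  det <- sum(e1 * h)
  # scale-normalized parallel/degenerate rejection: a segment sliding in
  # the triangle's plane has no well-defined crossing
  scale <- sqrt(sum(dir^2) * sum(e1^2) * sum(e2^2))
  if (abs(det) < eps * max(scale, .Machine$double.xmin)) return(NULL)
  s <- p - a
  u <- sum(s * h) / det
  if (u < -1e-9 || u > 1 + 1e-9) return(NULL)
  qv <- cross3(s, e1)
  v <- sum(dir * qv) / det
  if (v < -1e-9 || u + v > 1 + 1e-9) return(NULL)
  t <- sum(e2 * qv) / det
  if (t < -1e-9 || t > 1 + 1e-9) return(NULL)
  p + t * dir
}

# Nearest point on segment (a, b) to p, with its parameter.
project_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 > 0) min(1, max(0, sum((p - a) * ab) / len2)) else 0
  list(point = a + t * ab, t = t)
}

# Per-boundary-edge outward in-plane direction (edge direction crossed with
# the incident face normal) for the directed boundary edges of a mesh.
boundary_outward <- function(mesh, bnd = NULL) {
  if (is.null(bnd)) bnd <- detect_boundary(mesh)
  be <- bnd$edges
  if (!nrow(be))
    return(list(edges = be, outward = matrix(numeric(0), 0, 3)))
  fn <- face_normals(mesh)$normals
  # map each directed boundary edge to its single incident face
  f <- mesh$faces
  de <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  fid <- rep(seq_len(nrow(f)), 3L)
  dekey <- paste(de[, 1], de[, 2])
  face_of <- fid[match(paste(be[, 1], be[, 2]), dekey)]
  e <- mesh$vertices[be[, 2], , drop = FALSE] -
    mesh$vertices[be[, 1], , drop = FALSE]
  n <- fn[face_of, , drop = FALSE]
  out <- cbind(e[, 2] * n[, 3] - e[, 3] * n[, 2],
               e[, 3] * n[, 1] - e[, 1] * n[, 3],
               e[, 1] * n[, 2] - e[, 2] * n[, 1])
  len <- sqrt(rowSums(out^2))
  nz <- len > 0
  out[nz, ] <- out[nz, , drop = FALSE] / len[nz]
  list(edges = be, outward = out)
}

# Which points of P lie over the "common area" of `mesh` (within d): the
# query hits a non-boundary point, or it hits the boundary without being
# on the far (outward) side. Points lying exactly ON the boundary curve
# are exempt: they are weld/seam points, not redundant area.
covered_points <- function(P, mesh, d, bnd = NULL, on_tol = 1e-9) {
  if (nrow(mesh$faces) == 0L) return(rep(FALSE, nrow(P)))
  if (is.null(bnd)) bnd <- detect_boundary(mesh)
  q <- closest_points_cpp(P, mesh$vertices, mesh$faces, d)
  ann <- annotate_surface_points(q, mesh, bnd)
  cov <- ann$found & !ann$on_boundary
  touch <- which(ann$found & ann$on_boundary)
  if (length(touch)) {
    bo <- boundary_outward(mesh, bnd)
    Va <- mesh$vertices[bo$edges[, 1], , drop = FALSE]
    Vb <- mesh$vertices[bo$edges[, 2], , drop = FALSE]
    for (i in touch) {
      p <- P[i, ]
      qpt <- ann$point[i, ]
      if (ann$dist[i] <= on_tol) { # on the boundary curve itself
        cov[i] <- FALSE
        next
      }
      # outward in-plane direction at the contact point
      best <- Inf
      outward <- c(0, 0, 0)
      for (k in seq_len(nrow(bo$edges))) {
        pr <- project_to_segment(qpt, Va[k, ], Vb[k, ])
        dd <- sqrt(sum((qpt - pr$point)^2))
        if (dd < best - 1e-12) {
          best <- dd
          outward <- bo$outward[k, ]
        } else if (dd < best + 1e-12) {
          outward <- outward + bo$outward[k, ]
        }
      }
      side <- sum((p - qpt) * outward)
      cov[i] <- side <= 1e-9
    }
  }
  # points essentially on the surface may still sit on the rim curve
  # (within alignment tolerance): those are weld points, not common area
  near <- which(cov & ann$dist <= on_tol)
  if (length(near) && nrow(bnd$edges)) {
    Va <- mesh$vertices[bnd$edges[, 1], , drop = FALSE]
    Vb <- mesh$vertices[bnd$edges[, 2], , drop = FALSE]
    for (i in near) {
      p <- P[i, ]
      for (k in seq_len(nrow(bnd$edges))) {
        pr <- project_to_segment(p, Va[k, ], Vb[k, ])
        if (sum((p - pr$point)^2) <= on_tol^2) {
          cov[i] <- FALSE
          break
        }
      }
    }
  }
  cov
}

# Weld vertices closer than `tol`: spatial cell hashing with
# neighbor-cell search and true distance checks, so near-duplicates that
# straddle a cell border still merge. Returns the merged vertex array,
# the remapped faces (degenerate ones dropped) and the old-to-new map.
weld_vertices <- function(V, Fm, tol = 1e-9, carry = NULL) {
  n <- nrow(V)
  cell <- floor(V / tol)
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  map <- integer(n)
  reps <- integer(0)
  tol2 <- tol^2
  for (i in seq_len(n)) {
    found <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        for (dz in -1:1) {
          key <- paste(cell[i, 1] + dx, cell[i, 2] + dy, cell[i, 3] + dz)
          cand <- buckets[[key]]
          for (r in cand) {
            if (sum((V[i, ] - V[r, ])^2) <= tol2) {
              found <- r
              break
            }
          }
          if (found) break
        }
        if (found) break
      }
      if (found) break
    }
    if (found) {
      map[i] <- map[found]
    } else {
      reps <- c(reps, i)
      map[i] <- length(reps)
      key <- paste(cell[i, 1], cell[i, 2], cell[i, 3])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  Vw <- V[reps, , drop = FALSE]
  Fw <- matrix(map[Fm], ncol = 3L)
  degen <- Fw[, 1] == Fw[, 2] | Fw[, 2] == Fw[, 3] | Fw[, 1] == Fw[, 3]
  Fw <- Fw[!degen, , drop = FALSE]
  out <- list(V = Vw, Fm = Fw, map = map)
  if (!is.null(carry))
    out$carry <- lapply(carry, function(x) x[reps])
  out
}

# Cyclic runs of TRUE in a logical vector; returns list of index vectors,
# each possibly wrapping; attribute "closed" when everything is TRUE.
cyclic_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) {
    out <- list(seq_len(n))
    attr(out[[1L]], "closed") <- TRUE
    return(out)
  }
  if (!any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  # merge wrap-around
  if (flag[1L] && flag[n] && length(runs) > 1L) {
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

# Greedy triangle strip between vertex sequence `aseq` and `bseq`
# (indices into V). Returns a face matrix (orientation fixed later).
greedy_strip <- function(V, aseq, bseq, closed = FALSE) {
  if (closed) {
    aseq <- c(aseq, aseq[1L])
    bseq <- c(bseq, bseq[1L])
  }
  i <- 1L
  j <- 1L
  faces <- list()
  while (i < length(aseq) || j < length(bseq)) {
    advance_a <- if (i < length(aseq) && j < length(bseq)) {
      da <- sum((V[aseq[i + 1L], ] - V[bseq[j], ])^2)
      db <- sum((V[aseq[i], ] - V[bseq[j + 1L], ])^2)
      da <= db
    } else i < length(aseq)
    if (advance_a) {
      faces[[length(faces) + 1L]] <- c(aseq[i], aseq[i + 1L], bseq[j])
      i <- i + 1L
    } else {
      faces[[length(faces) + 1L]] <- c(aseq[i], bseq[j + 1L], bseq[j])
      j <- j + 1L
    }
  }
  fm <- do.call(rbind, faces)
  fm[fm[, 1] != fm[, 2] & fm[, 2] != fm[, 3] & fm[, 1] != fm[, 3], ,
     drop = FALSE]
}

# Flip new faces whose shared edges traverse an existing directed edge in
# the same direction (consistent outward orientation), propagating among
# the new faces themselves.
orient_new_faces <- function(Ffixed, Fnew) {
  if (is.null(Fnew) || nrow(Fnew) == 0L) return(Fnew)
  dir_edges <- function(Fm)
    paste(rbind(Fm[, c(1, 2), drop = FALSE], Fm[, c(2, 3), drop = FALSE],
                Fm[, c(3, 1), drop = FALSE])[, 1],
          rbind(Fm[, c(1, 2), drop = FALSE], Fm[, c(2, 3), drop = FALSE],
                Fm[, c(3, 1), drop = FALSE])[, 2])
  fixed <- dir_edges(Ffixed)
  oriented <- logical(nrow(Fnew))
  for (pass in 1:10) {
    changed <- FALSE
    for (k in which(!oriented)) {
      tri <- Fnew[k, ]
      fwd <- paste(tri[c(1, 2, 3)], tri[c(2, 3, 1)])
      rev_ <- paste(tri[c(2, 3, 1)], tri[c(1, 2, 3)])
      if (any(fwd %in% fixed)) {
        Fnew[k, ] <- tri[c(1, 3, 2)]
        oriented[k] <- TRUE
        changed <- TRUE
      } else if (any(rev_ %in% fixed)) {
        oriented[k] <- TRUE
        changed <- TRUE
      }
      if (oriented[k])
        fixed <- c(fixed, paste(Fnew[k, c(1, 2, 3)], Fnew[k, c(2, 3, 1)]))
    }
    if (!changed || all(oriented)) break
  }
  Fnew
}

# Stitch facing boundary gaps of a welded mesh: for every pair of boundary
# loops, contiguous runs of vertices within d of the other loop are bridged
# with a greedy triangle strip. Returns new faces (or NULL).
bridge_boundary_gaps <- function(V, Fm, d) {
  mesh <- trimesh(V, Fm, validate = FALSE)
  b <- detect_boundary(mesh)
  loops <- b$loops
  if (length(loops) < 2L) return(NULL)
  newF <- list()
  for (i in seq_along(loops)) {
    for (j in seq_along(loops)) {
      if (i >= j) next
      A <- loops[[i]]
      B <- loops[[j]]
      if (length(A) < 2L || length(B) < 2L) next
      LB <- V[B, , drop = FALSE]
      dA <- points_to_polyline_dist(V[A, , drop = FALSE], LB,
                                    closed = TRUE)
      runs <- cyclic_runs(dA <= d)
      for (run in runs) {
        aseq <- A[run]
        closed <- isTRUE(attr(run, "closed"))
        Pa <- V[aseq, , drop = FALSE]
        nearest_b <- vapply(seq_along(aseq), function(k) {
          which.min(colSums((t(LB) - Pa[k, ])^2))
        }, integer(1))
        if (closed) {
          # direction along B that tracks the A run
          stepfwd <- (nearest_b[2L] - nearest_b[1L]) %% length(B)
          dirn <- if (stepfwd <= length(B) / 2) 1L else -1L
          ord <- ((nearest_b[1L] - 1L + dirn * (seq_len(length(B)) - 1L)) %%
                    length(B)) + 1L
          bseq <- B[ord]
          newF[[length(newF) + 1L]] <-
            greedy_strip(V, aseq, bseq, closed = TRUE)
        } else {
          j0 <- nearest_b[1L]
          j1 <- nearest_b[length(nearest_b)]
          path <- function(dirn) {
            if (j0 == j1) return(j0)
            ord <- j0
            cur <- j0
            while (cur != j1) {
              cur <- ((cur - 1L + dirn) %% length(B)) + 1L
              ord <- c(ord, cur)
            }
            ord
          }
          p1 <- path(1L)
          p2 <- path(-1L)
          score <- function(pth)
            mean(points_to_polyline_dist(V[B[pth], , drop = FALSE], Pa))
          bseq <- B[if (score(p1) <= score(p2)) p1 else p2]
          if (length(bseq) < 1L) next
          newF[[length(newF) + 1L]] <- greedy_strip(V, aseq, bseq)
        }
      }
    }
  }
  if (!length(newF)) return(NULL)
  do.call(rbind, newF)
}

# Intersect the boundary edges of A with the wall triangles extended from
# B's boundary; every intersection is moved to the nearest position on the
# wall's parent boundary edge of B and ordered along B's boundary loops.
# Returns the ordered seam points plus, per point, the carrying B boundary
# edge and its parameter (for seam-vertex insertion).
seam_from_walls <- function(A, Ab, B, walls) {
  empty <- list(points = matrix(numeric(0), 0, 3),
                edge = matrix(integer(0), 0, 2), t = numeric(0))
  if (is.null(walls) || nrow(Ab$edges) == 0L) return(empty)
  pts <- list()
  edges <- list()
  ts <- numeric(0)
  pos <- numeric(0)
  for (w in walls$walls) {
    looplen <- c(0, cumsum(sqrt(rowSums(
      (B$vertices[c(w$loop[-1L], w$loop[1L]), , drop = FALSE] -
         B$vertices[w$loop, , drop = FALSE])^2))))
    for (me in seq_len(nrow(Ab$edges))) {
      p <- A$vertices[Ab$edges[me, 1], ]
      q <- A$vertices[Ab$edges[me, 2], ]
      for (wf in seq_len(nrow(w$faces))) {
        tri <- w$vertices[w$faces[wf, ], , drop = FALSE]
        ip <- segment_triangle_intersection(p, q, tri[1, ], tri[2, ],
                                            tri[3, ])
        if (is.null(ip)) next
        pe <- w$parent_edge[wf, ]
        pr <- project_to_segment(ip, B$vertices[pe[1], ],
                                 B$vertices[pe[2], ])
        k <- match(pe[1], w$loop)
        elen <- sqrt(sum((B$vertices[pe[2], ] - B$vertices[pe[1], ])^2))
        pts[[length(pts) + 1L]] <- pr$point
        edges[[length(edges) + 1L]] <- pe
        ts <- c(ts, pr$t)
        pos <- c(pos, looplen[k] + pr$t * elen)
      }
    }
  }
  if (!length(pts)) return(empty)
  P <- do.call(rbind, pts)
  E <- do.call(rbind, edges)
  ord <- order(pos)
  P <- P[ord, , drop = FALSE]
  E <- E[ord, , drop = FALSE]
  ts <- ts[ord]
  # drop duplicate (tangential-touch) seam points
  keep <- rep(TRUE, nrow(P))
  if (nrow(P) > 1L)
    keep[-1L] <- sqrt(rowSums(diff(P)^2)) >= 1e-9
  list(points = P[keep, , drop = FALSE], edge = E[keep, , drop = FALSE],
       t = ts[keep])
}

# Insert seam points lying in the interior of boundary edges as new mesh
# vertices (splitting the single incident face into a fan). Endpoint hits
# are left alone (the vertex already exists). Returns the refined mesh and
# the inserted vertex ids.
insert_boundary_points <- function(mesh, seam, tol = 1e-9) {
  V <- mesh$vertices
  Fm <- mesh$faces
  inserted <- integer(0)
  if (!nrow(seam$points)) return(list(mesh = mesh, inserted = inserted))
  # skip points that coincide with an edge endpoint (within tol in mm, or
  # within 0.1% of the edge length): those nodes already exist, and
  # near-parallel crossings project onto them with amplified noise
  elen <- sqrt(rowSums((V[seam$edge[, 2], , drop = FALSE] -
                          V[seam$edge[, 1], , drop = FALSE])^2))
  lo <- pmax(tol, 1e-3 * elen)
  interior <- which(seam$t * elen > lo & (1 - seam$t) * elen > lo)
  if (!length(interior)) return(list(mesh = mesh, inserted = inserted))
  key <- paste(seam$edge[interior, 1], seam$edge[interior, 2])
  groups <- split(interior, key)
  dekey <- paste(rbind(Fm[, c(1, 2), drop = FALSE],
                       Fm[, c(2, 3), drop = FALSE],
                       Fm[, c(3, 1), drop = FALSE])[, 1],
                 rbind(Fm[, c(1, 2), drop = FALSE],
                       Fm[, c(2, 3), drop = FALSE],
                       Fm[, c(3, 1), drop = FALSE])[, 2])
  fid <- rep(seq_len(nrow(Fm)), 3L)
  drop_faces <- integer(0)
  add_faces <- list()
  for (g in groups) {
    a <- seam$edge[g[1L], 1]
    b <- seam$edge[g[1L], 2]
    # the single face carrying directed boundary edge (a, b)
    hit <- match(paste(a, b), dekey)
    if (is.na(hit)) next
    f <- fid[hit]
    tri <- Fm[f, ]
    while (!(tri[1] == a && tri[2] == b)) tri <- tri[c(2, 3, 1)]
    c_ <- tri[3]
    ord <- g[order(seam$t[g])]
    ids <- integer(length(ord))
    for (m in seq_along(ord)) {
      V <- rbind(V, seam$points[ord[m], ])
      ids[m] <- nrow(V)
    }
    chain <- c(a, ids, b)
    for (m in seq_len(length(chain) - 1L))
      add_faces[[length(add_faces) + 1L]] <-
        c(chain[m], chain[m + 1L], c_)
    drop_faces <- c(drop_faces, f)
    inserted <- c(inserted, ids)
  }
  if (length(drop_faces)) {
    Fm <- rbind(Fm[-drop_faces, , drop = FALSE], do.call(rbind, add_faces))
  }
  list(mesh = trimesh(V, Fm, validate = FALSE), inserted = inserted)
}

# Accept candidate faces only while every edge keeps at most two incident
# faces (bridging/filling must never break manifoldness).
admit_manifold_faces <- function(Fm, cand) {
  if (is.null(cand) || !nrow(cand)) return(cand)
  key <- c(edge_key(Fm[, 1], Fm[, 2]), edge_key(Fm[, 2], Fm[, 3]),
           edge_key(Fm[, 3], Fm[, 1]))
  cnt <- new.env(parent = emptyenv())
  for (k in key) assign(k, (if (is.null(cnt[[k]])) 0L else cnt[[k]]) + 1L,
                        envir = cnt)
  ok <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ek <- c(edge_key(cand[i, 1], cand[i, 2]),
            edge_key(cand[i, 2], cand[i, 3]),
            edge_key(cand[i, 3], cand[i, 1]))
    cur <- vapply(ek, function(k)
      if (is.null(cnt[[k]])) 0L else cnt[[k]], integer(1))
    if (all(cur <= 1L)) {
      ok[i] <- TRUE
      for (k in ek) assign(k, (if (is.null(cnt[[k]])) 0L
                               else cnt[[k]]) + 1L, envir = cnt)
    }
  }
  cand[ok, , drop = FALSE]
}

# Fan-fill residual small holes (perimeter below max_perimeter) left by
# staircase gaps that bridging cannot close; adds one centroid vertex per
# hole. Genuine openings (large loops) are never touched.
fill_small_holes <- function(V, Fm, max_perimeter) {
  mesh <- trimesh(V, Fm, validate = FALSE)
  b <- detect_boundary(mesh)
  newV <- list()
  newF <- list()
  for (loop in b$loops) {
    if (length(loop) < 3L || length(loop) > 16L) next
    P <- V[loop, , drop = FALSE]
    per <- sum(sqrt(rowSums((rbind(P[-1L, , drop = FALSE],
                                   P[1L, , drop = FALSE]) - P)^2)))
    if (per > max_perimeter) next
    ctr <- colMeans(P)
    newV[[length(newV) + 1L]] <- ctr
    apex <- nrow(V) + length(newV)
    nxt <- c(loop[-1L], loop[1L])
    newF[[length(newF) + 1L]] <- cbind(apex, nxt, loop)
  }
  if (!length(newV))
    return(list(V = V, faces = matrix(integer(0), 0, 3),
                new_vertices = integer(0)))
  list(V = rbind(V, do.call(rbind, newV)),
       faces = do.call(rbind, newF),
       new_vertices = nrow(V) + seq_along(newV))
}

#' Clip and merge two redundancy-thinned meshes
#'
#' Joins `M` and `N` (already thinned by [remove_redundant()]) into one
#' connected mesh. The seam is located by intersecting the boundary edges
#' of `M` with the wall extension of `N` and moving every intersection to
#' the nearest position on the corresponding `N` boundary edge; `M`
#' triangles left over the interior of `N` are discarded; coincident
#' vertices are welded and any remaining facing boundary gaps are
#' triangulated up to the seam.
#'
#' @param M,N [trimesh()] objects after redundancy removal.
#' @param walls a [extend_wall()] result for `N` (may be `NULL` when `N`
#'   has no boundary or no faces).
#' @param d matching tolerance (mm).
#' @return object of class `merge_result`: `mesh`, `seam` (ordered seam
#'   points, possibly 0-row), `counts` (triangles cut from `M`, created by
#'   bridging) and `welded` vertex count.
#' @export
clip_and_merge <- function(M, N, walls, d) {
  countsM_cut <- 0L
  created <- 0L
  if (nrow(N$faces) == 0L) {
    out <- compact_mesh(M)
    return(structure(list(mesh = out,
                          seam = matrix(numeric(0), 0, 3),
                          counts = list(cut = 0L, created = 0L),
                          welded = 0L),
                     class = "merge_result"))
  }
  if (nrow(M$faces) == 0L) {
    out <- compact_mesh(N)
    return(structure(list(mesh = out,
                          seam = matrix(numeric(0), 0, 3),
                          counts = list(cut = 0L, created = 0L),
                          welded = 0L),
                     class = "merge_result"))
  }
  Mb <- detect_boundary(M)
  Nb <- detect_boundary(N)
  # seam: M boundary edges against N's walls, projected onto N's boundary;
  # when the boundaries run parallel without crossing, try the symmetric
  # direction (N boundary edges against a wall built on M)
  sw <- seam_from_walls(M, Mb, N, walls)
  seam_on_N <- TRUE
  if (nrow(sw$points) == 0L && nrow(Mb$edges) > 0L && !is.null(walls)) {
    mwalls <- tryCatch(extend_wall(M, walls$height),
                       error = function(e) NULL)
    if (!is.null(mwalls)) {
      sw2 <- seam_from_walls(N, Nb, M, mwalls)
      if (nrow(sw2$points)) {
        sw <- sw2
        seam_on_N <- FALSE
      }
    }
  }
  seam <- sw$points
  # discard M triangles over the interior of N: a triangle is common-area
  # when any vertex -- or its centroid (all-rim-vertex slivers) -- lies
  # over N's interior
  on_tol <- max(1e-9, 1e-6 * d)
  cov <- covered_points(M$vertices, N, d, Nb, on_tol)
  Fm_M <- M$faces
  cut <- cov[Fm_M[, 1]] | cov[Fm_M[, 2]] | cov[Fm_M[, 3]]
  if (any(!cut)) {
    idx <- which(!cut)
    cen <- (M$vertices[Fm_M[idx, 1], , drop = FALSE] +
              M$vertices[Fm_M[idx, 2], , drop = FALSE] +
              M$vertices[Fm_M[idx, 3], , drop = FALSE]) / 3
    cut[idx] <- covered_points(cen, N, d, Nb, on_tol)
  }
  countsM_cut <- sum(cut)
  Mcl <- trimesh(M$vertices, Fm_M[!cut, , drop = FALSE], validate = FALSE)
  # insert seam points as new nodes on the carrying boundary
  N2 <- N
  new_N <- integer(0)
  new_M <- integer(0)
  if (nrow(seam)) {
    if (seam_on_N) {
      ins <- insert_boundary_points(N, sw, tol = max(1e-9, 1e-6 * d))
      N2 <- ins$mesh
      new_N <- ins$inserted
    } else {
      ins <- insert_boundary_points(Mcl, sw, tol = max(1e-9, 1e-6 * d))
      Mcl <- ins$mesh
      new_M <- ins$inserted
    }
  }
  # concatenate and weld coincident vertices across the two sides; the
  # weld tolerance scales with d so that surfaces aligned to estimator
  # precision (rather than bitwise-identical) still share seam vertices
  weld_tol <- max(1e-9, 1e-6 * d)
  V <- rbind(N2$vertices, Mcl$vertices)
  Fall <- rbind(N2$faces, Mcl$faces + nrow(N2$vertices))
  from_N <- c(rep(TRUE, nrow(N2$vertices)), rep(FALSE, nrow(Mcl$vertices)))
  is_new <- logical(nrow(V))
  is_new[c(new_N, nrow(N2$vertices) + new_M)] <- TRUE
  w <- weld_vertices(V, Fall, tol = weld_tol)
  cross_weld <- sum(vapply(split(from_N, w$map), function(g)
    any(g) && !all(g), logical(1)))
  welded <- nrow(V) - nrow(w$V)
  is_new_w <- as.logical(tapply(is_new, w$map, any))
  # bridge remaining facing gaps up to the seam (iterated: closing one gap
  # can expose the next), then fan-fill any small residual holes
  for (pass in 1:3) {
    newF <- bridge_boundary_gaps(w$V, w$Fm, d)
    newF <- admit_manifold_faces(w$Fm, newF)
    if (is.null(newF) || !nrow(newF)) break
    newF <- orient_new_faces(w$Fm, newF)
    created <- created + nrow(newF)
    w$Fm <- rbind(w$Fm, newF)
  }
  fill <- fill_small_holes(w$V, w$Fm, max_perimeter = 12 * d)
  if (length(fill$new_vertices)) {
    w$V <- fill$V
    is_new_w <- c(is_new_w, rep(TRUE, length(fill$new_vertices)))
    newF <- admit_manifold_faces(w$Fm, fill$faces)
    newF <- orient_new_faces(w$Fm, newF)
    created <- created + nrow(newF)
    w$Fm <- rbind(w$Fm, newF)
  }
  if (nrow(seam) == 0L && cross_weld == 0L && created == 0L)
    stop("surfaces do not meet within d: no seam intersections found")
  if (nrow(seam) == 0L && cross_weld > 0L && nrow(Nb$edges)) {
    # contact line: the part of N's boundary welded to the clipped M side,
    # in loop order
    nb_keys <- apply(round(N$vertices / weld_tol), 1, paste,
                     collapse = ",")
    Mkb <- detect_boundary(Mcl)
    mb_pts <- Mcl$vertices[unique(as.vector(Mkb$edges)), , drop = FALSE]
    if (nrow(mb_pts)) {
      key_m <- apply(round(mb_pts / weld_tol), 1, paste, collapse = ",")
      shared <- unlist(lapply(Nb$loops, function(l)
        l[nb_keys[l] %in% key_m]))
      seam <- N$vertices[shared, , drop = FALSE]
    }
  }
  merged <- compact_mesh(trimesh(w$V, w$Fm, validate = FALSE))
  kept <- attr(merged, "kept_vertices")
  new_vertices <- which(is_new_w[kept])
  structure(list(mesh = merged, seam = seam,
                 new_vertices = new_vertices,
                 counts = list(cut = as.integer(countsM_cut),
                               created = as.integer(created)),
                 welded = as.integer(welded)),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("<merge_result> %d vertices, %d faces; seam of %d point(s)\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces), nrow(x$seam)))
  cts <- x$counts
  cat(sprintf("  counts: %s\n",
              paste(sprintf("%s=%s", names(cts), unlist(cts)),
                    collapse = ", ")))
  invisible(x)
}

#' Remove small triangles after matching
#'
#' Any vertex whose shortest incident edge falls below `min_edge` is
#' deleted together with its incident triangles; the hole is closed by
#' collapsing the vertex into its nearest neighbor (which retriangulates
#' the hole as that neighbor's fan). Vertices introduced during matching
#' are processed first when `prefer_new` is set. Repeats until no vertex
#' violates the threshold.
#'
#' @param mesh a [trimesh()].
#' @param min_edge edge-length threshold (mm, >= 0; 0 leaves the mesh
#'   unchanged).
#' @param prefer_new process matching-introduced vertices first.
#' @param new_vertices integer ids of matching-introduced vertices.
#' @return the cleaned, compacted [trimesh()].
#' @export
remove_small_triangles <- function(mesh, min_edge, prefer_new = TRUE,
                                   new_vertices = integer(0)) {
  if (min_edge < 0) stop("min_edge must be >= 0")
  if (min_edge == 0 || nrow(mesh$faces) == 0L) return(mesh)
  V <- mesh$vertices
  Fm <- mesh$faces
  is_new <- logical(nrow(V))
  is_new[new_vertices] <- TRUE
  blocked <- logical(nrow(V))
  repeat {
    m <- trimesh(V, Fm, validate = FALSE)
    ec <- edge_census(m)
    e <- ec$edges
    if (!nrow(e)) break
    elen <- sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                          V[e[, 2], , drop = FALSE])^2))
    minlen <- rep(Inf, nrow(V))
    for (k in seq_len(nrow(e))) {
      if (elen[k] < minlen[e[k, 1]]) minlen[e[k, 1]] <- elen[k]
      if (elen[k] < minlen[e[k, 2]]) minlen[e[k, 2]] <- elen[k]
    }
    viol <- which(minlen < min_edge & !blocked)
    if (!length(viol)) break
    ord <- viol[order(!(prefer_new & is_new[viol]), minlen[viol])]
    v <- ord[1L]
    adj <- vertex_adjacency(m)
    vf <- vertex_faces(m)
    nbrs <- adj[[v]]
    nbrs <- nbrs[order(sqrt(rowSums((V[nbrs, , drop = FALSE] -
                                     matrix(V[v, ], length(nbrs), 3,
                                            byrow = TRUE))^2)))]
    collapsed <- FALSE
    for (u in nbrs) {
      shared <- intersect(vf[[v]], vf[[u]])
      common <- intersect(adj[[v]], adj[[u]])
      opp <- setdiff(unique(as.vector(Fm[shared, , drop = FALSE])),
                     c(u, v))
      if (length(common) != length(opp) || !setequal(common, opp)) next
      Fnew <- Fm
      Fnew[Fnew == v] <- u
      degen <- Fnew[, 1] == Fnew[, 2] | Fnew[, 2] == Fnew[, 3] |
        Fnew[, 1] == Fnew[, 3]
      Fm <- Fnew[!degen, , drop = FALSE]
      collapsed <- TRUE
      break
    }
    if (!collapsed) blocked[v] <- TRUE # no legal collapse for this vertex
  }
  compact_mesh(trimesh(V, Fm, validate = FALSE))
}

#' Zipper two aligned meshes into one consensus surface
#'
#' The full three-stage integration: redundant-triangle removal
#' ([remove_redundant()]), boundary-wall clipping and merging
#' ([extend_wall()] + [clip_and_merge()]), and small-triangle cleanup
#' ([remove_small_triangles()]), with a consolidated report.
#'
#' @param M,N aligned [trimesh()] objects (`N` is typically the fragment,
#'   thinned first).
#' @param d matching tolerance (mm).
#' @param wall_height wall extension height (mm, default `4 * d`).
#' @param min_edge small-triangle threshold (mm, default `d / 10`).
#' @param consensus average the surviving surface with the retained
#'   (removed-but-kept) redundant-zone geometry: each merged vertex within
#'   `d` of the removed triangles moves halfway to its nearest point on
#'   them. Off by default; the exact averaging rule for unpaired points is
#'   a tool choice.
#' @return a `merge_result` whose `counts` cover all stages.
#' @export
zipper <- function(M, N, d, wall_height = 4 * d, min_edge = d / 10,
                   consensus = FALSE) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("zipper stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  rr <- stage("remove_redundant", remove_redundant(N, M, d))
  walls <- NULL
  if (nrow(rr$N$faces) > 0L &&
      length(detect_boundary(rr$N)$loops) > 0L)
    walls <- stage("extend_wall", extend_wall(rr$N, wall_height))
  cm <- stage("clip_and_merge", clip_and_merge(rr$M, rr$N, walls, d))
  nv_before <- nrow(cm$mesh$vertices)
  cleaned <- stage("remove_small_triangles",
                   remove_small_triangles(cm$mesh, min_edge,
                                          prefer_new = TRUE,
                                          new_vertices = cm$new_vertices))
  if (consensus && (length(rr$removed_N) || length(rr$removed_M))) {
    removed <- merge_mesh_soup(list(
      submesh_faces(N, rr$removed_N), submesh_faces(M, rr$removed_M)))
    removed <- compact_mesh(removed)
    if (nrow(removed$faces)) {
      q <- closest_points_cpp(cleaned$vertices, removed$vertices,
                              removed$faces, d)
      hit <- which(q$found)
      cleaned$vertices[hit, ] <- (cleaned$vertices[hit, , drop = FALSE] +
                                    q$point[hit, , drop = FALSE]) / 2
    }
  }
  cm$counts <- list(redundant_N = length(rr$removed_N),
                    redundant_M = length(rr$removed_M),
                    cut = cm$counts$cut,
                    created = cm$counts$created,
                    small_removed = nv_before - nrow(cleaned$vertices))
  cm$mesh <- cleaned
  cm
}
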