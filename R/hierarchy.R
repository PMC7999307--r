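#' Mesh decimation by shortest-edge collapse
#'
#' Iteratively collapses the shortest edges (midpoint placement, boundary
#' vertices pinned) until the mesh reaches `target_nv` vertices. Collapses
#' that would break manifold-or-boundary connectivity (link condition) or
#' flip face normals are skipped. Used to build the coarse levels of the
#' matching hierarchy; shape fidelity only needs to be good enough to warm
#' start coarse alignment.
#'
#' @param mesh a [trimesh()].
#' @param target_nv desired number of vertices (>= 4).
#' @return a decimated [trimesh()] (intensities are dropped).
#' @export
decimate_mesh <- function(mesh, target_nv) {
  if (target_nv < 4L)
    stop("decimation collapsing below 4 vertices")
  cur <- trimesh(mesh$vertices, mesh$faces, validate = FALSE)
  nv <- nrow(cur$vertices)
  while (nv > target_nv) {
    res <- decimate_sweep(cur, nv - target_nv)
    if (res$removed == 0L) break # no legal collapse left
    cur <- res$mesh
    nv <- nrow(cur$vertices)
  }
  cur
}

# One greedy sweep of edge collapses (each vertex takes part in at most one
# collapse per sweep); returns the compacted mesh and collapse count.
decimate_sweep <- function(mesh, max_remove) {
  V <- mesh$vertices
  Fm <- mesh$faces
  nv <- nrow(V)
  ec <- edge_census(mesh)
  e <- ec$edges
  elen <- sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                        V[e[, 2], , drop = FALSE])^2))
  ord <- order(elen)
  bvert <- logical(nv)
  bedge_key <- ec$key[ec$count == 1L]
  if (length(bedge_key)) {
    bm <- do.call(rbind, strsplit(bedge_key, " "))
    bvert[as.integer(bm)] <- TRUE
  }
  adj <- vertex_adjacency(mesh)
  vf <- vertex_faces(mesh)
  fn <- face_normals(mesh)$normals
  ekey <- ec$key
  names(elen) <- ekey

  dirty <- logical(nv)
  map <- seq_len(nv)
  removed <- 0L
  dead_face <- logical(nrow(Fm))
  for (i in ord) {
    if (removed >= max_remove) break
    u <- e[i, 1]; v <- e[i, 2]
    if (dirty[u] || dirty[v]) next
    is_bedge <- edge_key(u, v) %in% bedge_key
    if (bvert[u] && bvert[v] && !is_bedge) next # would pinch the boundary
    # collapse v into u; prefer keeping a boundary vertex fixed
    if (bvert[v] && !bvert[u]) { tmp <- u; u <- v; v <- tmp }
    shared <- intersect(vf[[u]], vf[[v]])
    # link condition: common neighbors must be exactly the opposite
    # vertices of the faces sharing edge (u, v)
    common <- intersect(adj[[u]], adj[[v]])
    opp <- setdiff(unique(as.vector(Fm[shared, , drop = FALSE])), c(u, v))
    if (length(common) != length(opp) || !setequal(common, opp)) next
    newpos <- if (bvert[u]) V[u, ] else (V[u, ] + V[v, ]) / 2
    # normal-flip / degeneracy guard on surviving incident faces
    surv <- setdiff(union(vf[[u]], vf[[v]]), shared)
    ok <- TRUE
    for (fi in surv) {
      tri <- Fm[fi, ]
      tri[tri == v] <- u
      P <- V[tri, , drop = FALSE]
      P[tri == u, ] <- matrix(newpos, sum(tri == u), 3, byrow = TRUE)
      nrm <- cross3(P[2, ] - P[1, ], P[3, ] - P[1, ])
      l <- sqrt(sum(nrm^2))
      if (l < 1e-12 || sum(nrm / l * fn[fi, ]) <= 0) { ok <- FALSE; break }
    }
    if (!ok) next
    map[v] <- u
    V[u, ] <- newpos
    dead_face[shared] <- TRUE
    dirty[c(u, v, adj[[u]], adj[[v]])] <- TRUE
    removed <- removed + 1L
  }
  if (removed == 0L)
    return(list(mesh = mesh, removed = 0L))
  Fnew <- matrix(map[Fm], ncol = 3L)
  degen <- Fnew[, 1] == Fnew[, 2] | Fnew[, 2] == Fnew[, 3] |
    Fnew[, 1] == Fnew[, 3]
  Fnew <- Fnew[!dead_face & !degen, , drop = FALSE]
  out <- compact_mesh(trimesh(V, Fnew, validate = FALSE))
  list(mesh = out, removed = removed)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coarse-to-fine mesh hierarchy
#'
#' Builds `levels` meshes from coarsest to finest by repeated decimation
#' (each coarser level targets one quarter of the vertices of the next finer
#' one) together with the per-level matching threshold `d`: the threshold
#' halves at each advance in the hierarchy, reaching `d_finest` at the
#' finest level.
#'
#' @param mesh a [trimesh()]; becomes the finest level.
#' @param levels number of levels (>= 1).
#' @param d_finest matching threshold at the finest level (mm).
#' @return object of class `mesh_hierarchy`: list with `meshes` (coarsest
#'   first) and `d` (per-level thresholds, exactly geometric with ratio 2
#'   down the list).
#' @export
build_hierarchy <- function(mesh, levels, d_finest) {
  stopifnot(levels >= 1L, d_finest > 0)
  nv <- nrow(mesh$vertices)
  if (nv <= 4L * levels)
    stop("mesh too small for the requested number of levels")
  targets <- round(nv / 4^(rev(seq_len(levels)) - 1L)) # coarsest..finest
  if (any(targets < 4L))
    stop("decimation collapsing below 4 vertices")
  meshes <- vector("list", levels)
  meshes[[levels]] <- mesh
  if (levels > 1L) {
    for (k in rev(seq_len(levels - 1L)))
      meshes[[k]] <- decimate_mesh(meshes[[k + 1L]], targets[k])
  }
  counts <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  if (levels > 1L && any(diff(counts) <= 0L))
    stop("hierarchy vertex counts are not strictly increasing")
  structure(list(meshes = meshes,
                 d = d_finest * 2^(rev(seq_len(levels)) - 1L)),
            class = "mesh_hierarchy")
}

#' @export
print.mesh_hierarchy <- function(x, ...) {
  counts <- vapply(x$meshes, function(m) nrow(m$vertices), integer(1))
  cat(sprintf("<mesh_hierarchy> %d level(s)\n", length(x$meshes)))
  for (k in seq_along(counts))
    cat(sprintf("  level %d: %d vertices, d = %g mm\n", k, counts[k],
                x$d[k]))
  invisible(x)
}
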