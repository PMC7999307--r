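#' Triangle mesh
#'
#' The universal geometry carrier of the package: vertex positions in
#' millimetres plus triangular faces with counter-clockwise winding (outward
#' normals), optionally carrying a per-vertex scalar CT intensity in
#' Hounsfield units (HU).
#'
#' Validation enforces the structural invariants every downstream operation
#' relies on: all face indices in range, three distinct indices per face
#' (no degenerate faces), and every edge shared by at most two faces
#' (manifold-or-boundary connectivity).
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm).
#' @param faces integer matrix, one row per triangle, three 1-based vertex
#'   indices in counter-clockwise order seen from outside.
#' @param intensity optional numeric vector of per-vertex Hounsfield
#'   intensities, one value per vertex.
#' @param validate logical; skip invariant checks when the caller guarantees
#'   them (internal fast path).
#'
#' @return An object of class `trimesh`: a list with elements `vertices`,
#'   `faces` and (possibly `NULL`) `intensity`.
#' @export
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' m
trimesh <- function(vertices, faces, intensity = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns (x, y, z)")
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L)
    stop("`faces` must have 3 columns")
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != nrow(vertices))
      stop("`intensity` must have one value per vertex")
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      intensity = intensity),
                 class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

#' @rdname trimesh
#' @param x a `trimesh`.
#' @export
validate_trimesh <- function(x) {
  v <- x$vertices
  f <- x$faces
  if (anyNA(v)) stop("vertices contain NA")
  if (nrow(f) > 0L) {
    if (anyNA(f) || min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range")
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen))
      stop(sprintf("degenerate face(s) with repeated vertex indices: %s",
                   paste(utils::head(which(degen), 5L), collapse = ", ")))
    ec <- edge_census(x)
    if (any(ec$count > 2L)) {
      bad <- which(ec$count > 2L)[1L]
      stop(sprintf("non-manifold edge (%d, %d) shared by %d faces",
                   ec$edges[bad, 1], ec$edges[bad, 2], ec$count[bad]))
    }
  }
  invisible(x)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$intensity)) ", per-vertex intensity [HU]" else ""))
  if (nrow(x$vertices) > 0) {
    rng <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3],
                rng[2, 3]))
  }
  be <- tryCatch(sum(edge_census(x)$count == 1L), error = function(e) NA)
  cat(sprintf("  boundary edges: %s\n", be))
  invisible(x)
}

# Undirected edge census: unique edges (as min,max index pairs) with the
# number of incident faces. The backbone of boundary detection and
# manifoldness checks.
edge_census <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L)
    return(list(edges = matrix(integer(0), 0, 2), count = integer(0),
                key = integer(0)))
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  a <- pmin(e[, 1], e[, 2])
  b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  tab <- table(key)
  first <- !duplicated(key)
  ord <- match(names(tab), key[first])
  edges <- cbind(a[first], b[first])[ord, , drop = FALSE]
  list(edges = edges, count = as.integer(tab), key = names(tab))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Per-face unit normals and areas
#'
#' @param mesh a [trimesh()].
#' @return list with `normals` (m x 3, unit length, outward for CCW winding)
#'   and `areas` (mm^2). Zero-area faces get a zero normal.
#' @export
face_normals <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  areas <- len / 2
  nz <- len > 0
  n[nz, ] <- n[nz, , drop = FALSE] / len[nz]
  list(normals = n, areas = areas)
}

#' Per-vertex unit normals
#'
#' The normal at a vertex is the normalized (unweighted) average of the unit
#' normals of its incident faces. Isolated vertices receive a zero normal
#' with a warning.
#'
#' @param mesh a [trimesh()].
#' @return numeric n x 3 matrix of unit vectors (rows of zeros for isolated
#'   vertices).
#' @export
compute_vertex_normals <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  fn <- face_normals(mesh)$normals
  idx <- as.vector(mesh$faces)
  contrib <- fn[rep(seq_len(nrow(fn)), 3L), , drop = FALSE]
  n <- nrow(mesh$vertices)
  acc <- rowsum(contrib, group = idx)
  out <- matrix(0, n, 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  iso <- !(seq_len(n) %in% idx)
  if (any(iso))
    warning(sprintf("%d isolated vertex/vertices assigned zero normal",
                    sum(iso)))
  nz <- len > 0
  out[nz, ] <- out[nz, , drop = FALSE] / len[nz]
  out
}

#' Boundary detection
#'
#' A vertex is a boundary vertex iff it lies on an edge with exactly one
#' incident face. Boundary loops are returned as closed ordered vertex
#' cycles, oriented as the boundary edges appear in their (single) incident
#' face.
#'
#' @param mesh a [trimesh()].
#' @return list with `vertex` (logical per-vertex flags), `edges` (k x 2
#'   matrix of boundary edges) and `loops` (list of integer vertex cycles;
#'   the first vertex is not repeated at the end).
#' @export
detect_boundary <- function(mesh) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  if (nrow(f) == 0L)
    return(list(vertex = logical(n), edges = matrix(integer(0), 0, 2),
                loops = list()))
  # directed edges as they appear in faces; boundary edges are those whose
  # undirected edge has a single incident face
  de <- rbind(f[, c(1, 2), drop = FALSE],
              f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  key <- edge_key(de[, 1], de[, 2])
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1L]
    stop(sprintf("non-manifold edge (%s) with %d incident faces",
                 gsub(" ", ", ", bad), max(cnt)))
  }
  is_b <- cnt[key] == 1L
  bedges <- de[is_b, , drop = FALSE]
  flag <- logical(n)
  flag[unique(as.vector(bedges))] <- TRUE
  # walk directed boundary edges into cycles
  loops <- list()
  if (nrow(bedges) > 0L) {
    nxt <- split(bedges[, 2], bedges[, 1])
    used <- logical(nrow(bedges))
    ekey <- paste(bedges[, 1], bedges[, 2])
    eidx <- seq_len(nrow(bedges))
    names(eidx) <- ekey
    remaining <- rep(TRUE, nrow(bedges))
    while (any(remaining)) {
      s <- which(remaining)[1L]
      start <- bedges[s, 1]
      cur <- start
      loop <- integer(0)
      repeat {
        loop <- c(loop, cur)
        cands <- nxt[[as.character(cur)]]
        # pick the first unused outgoing boundary edge
        found <- FALSE
        for (cand in cands) {
          id <- eidx[[paste(cur, cand)]]
          if (remaining[id]) {
            remaining[id] <- FALSE
            cur <- cand
            found <- TRUE
            break
          }
        }
        if (!found) break
        if (cur == start) break
      }
      loops[[length(loops) + 1L]] <- loop
    }
  }
  list(vertex = flag, edges = bedges, loops = loops)
}

#' Total surface area
#' @param mesh a [trimesh()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_normals(mesh)$areas)

#' Euler characteristic V - E + F
#' @param mesh a [trimesh()].
#' @return integer; counts only vertices referenced by faces.
#' @export
euler_characteristic <- function(mesh) {
  nv <- length(unique(as.vector(mesh$faces)))
  ne <- nrow(edge_census(mesh)$edges)
  nf <- nrow(mesh$faces)
  as.integer(nv - ne + nf)
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented closed surfaces.
#' @param mesh a [trimesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Drop vertices not referenced by any face, remapping face indices (and any
# per-vertex attributes passed in `carry`, a list of vectors/matrices).
compact_mesh <- function(mesh, carry = list()) {
  keep <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  out <- trimesh(mesh$vertices[keep, , drop = FALSE],
                 matrix(map[mesh$faces], ncol = 3L),
                 intensity = if (!is.null(mesh$intensity))
                   mesh$intensity[keep] else NULL,
                 validate = FALSE)
  attr(out, "kept_vertices") <- keep
  if (length(carry)) {
    attr(out, "carry") <- lapply(carry, function(x) {
      if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]
    })
  }
  out
}

# Submesh consisting of the given faces (keeping all vertices; use
# compact_mesh to renumber).
submesh_faces <- function(mesh, face_idx) {
  trimesh(mesh$vertices, mesh$faces[face_idx, , drop = FALSE],
          intensity = mesh$intensity, validate = FALSE)
}

# Vertex adjacency list (neighbors along edges).
vertex_adjacency <- function(mesh) {
  ec <- edge_census(mesh)
  e <- ec$edges
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  if (nrow(e)) {
    both <- rbind(e, e[, 2:1, drop = FALSE])
    adj_split <- split(both[, 2], both[, 1])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  adj
}

# Faces incident to each vertex.
vertex_faces <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  vf <- vector("list", n)
  if (nrow(f)) {
    s <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
    vf[as.integer(names(s))] <- s
  }
  vf
}
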