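#' @useDynLib bonereduce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tolerance for classifying barycentric coordinates as exact zeros/ones.
.bary_eps <- 1e-12

#' Distance-limited nearest-point query
#'
#' Finds the globally nearest point on the continuous surface of `mesh`
#' (which may fall on a vertex, in the interior of an edge, or in the
#' interior of a face) to the query point `p`, provided its distance does
#' not exceed the threshold `d`; otherwise reports nothing. Equidistant
#' candidates resolve to the lowest face index, so results are
#' deterministic and equal exhaustive search.
#'
#' @param p numeric length-3 point (mm), or an n x 3 matrix of query points.
#' @param mesh a [trimesh()] with at least one face.
#' @param d positive distance threshold (mm); matches farther than `d` are
#'   discarded.
#' @param boundary optional precomputed [detect_boundary()] result for
#'   `mesh`; computed on the fly when `NULL`.
#'
#' @return For a single point: a `surface_point` (see Details) or `NULL` if
#'   no surface point lies within `d`. For a matrix: a list with elements
#'   `found`, `face`, `dist`, `point`, `bary`, `kind`, `on_boundary`.
#'
#' @details A `surface_point` is a list with fields `location` (3-vector),
#'   `kind` (`"vertex"`, `"edge"` or `"face"`), `face` (1-based face index),
#'   `bary` (barycentric coordinates in that face, summing to 1, all >= 0),
#'   `dist` (distance to the query) and `on_boundary` (whether the point
#'   touches a boundary vertex or lies on a boundary edge).
#' @export
closest_point_query <- function(p, mesh, d, boundary = NULL) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  if (d <= 0) stop("distance threshold d must be > 0")
  single <- is.null(dim(p))
  P <- if (single) matrix(as.numeric(p), 1L, 3L) else {
    stopifnot(ncol(p) == 3L)
    p
  }
  res <- closest_points_cpp(P, mesh$vertices, mesh$faces, d)
  ann <- annotate_surface_points(res, mesh, boundary)
  if (!single) return(ann)
  if (!ann$found[1L]) return(NULL)
  structure(list(location = ann$point[1L, ], kind = ann$kind[1L],
                 face = ann$face[1L], bary = ann$bary[1L, ],
                 dist = ann$dist[1L], on_boundary = ann$on_boundary[1L]),
            class = "surface_point")
}

# Classify raw query output rows into vertex/edge/face kinds and flag
# contacts with the target boundary.
annotate_surface_points <- function(res, mesh, boundary = NULL) {
  if (is.null(boundary)) boundary <- detect_boundary(mesh)
  n <- length(res$found)
  kind <- rep(NA_character_, n)
  onb <- rep(NA, n)
  bkey <- if (nrow(boundary$edges))
    edge_key(boundary$edges[, 1], boundary$edges[, 2]) else character(0)
  for (i in seq_len(n)) {
    if (!res$found[i]) next
    b <- res$bary[i, ]
    fidx <- mesh$faces[res$face[i], ]
    one <- b >= 1 - .bary_eps
    zero <- b <= .bary_eps
    if (any(one)) {
      kind[i] <- "vertex"
      onb[i] <- boundary$vertex[fidx[which(one)[1L]]]
    } else if (any(zero)) {
      kind[i] <- "edge"
      pair <- fidx[!zero]
      onb[i] <- edge_key(pair[1L], pair[2L]) %in% bkey
    } else {
      kind[i] <- "face"
      onb[i] <- FALSE
    }
  }
  res$kind <- kind
  res$on_boundary <- onb
  res
}

#' @export
print.surface_point <- function(x, ...) {
  cat(sprintf(
    "<surface_point> %s on face %d at (%.4f, %.4f, %.4f), dist %.4g mm%s\n",
    x$kind, x$face, x$location[1], x$location[2], x$location[3], x$dist,
    if (x$on_boundary) " [boundary]" else ""))
  invisible(x)
}

# Distance from points (n x 3) to a polyline (k x 3, closed if `closed`),
# returning per-point minimum distance. Used for seam/bridge bookkeeping.
points_to_polyline_dist <- function(P, L, closed = FALSE) {
  if (is.null(dim(P))) P <- matrix(P, 1L, 3L)
  segs <- cbind(seq_len(nrow(L) - 1L), seq_len(nrow(L) - 1L) + 1L)
  if (closed && nrow(L) > 2L) segs <- rbind(segs, c(nrow(L), 1L))
  best <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(segs))) {
    a <- L[segs[s, 1], ]
    b <- L[segs[s, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(P, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, as.vector(ap %*% ab) / len2)) else 0
    q <- outer(t, ab) + matrix(a, nrow(P), 3, byrow = TRUE)
    d <- sqrt(rowSums((P - q)^2))
    best <- pmin(best, d)
  }
  best
}
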