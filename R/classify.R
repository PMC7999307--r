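#' Classify mesh vertices as intact or fracture surface
#'
#' Labels every vertex of an intensity-carrying mesh as `intact` (dense
#' cortical shell, high Hounsfield intensity) or `fracture`
#' (cancellous-exposed cut surface, low intensity). A vertex is intact iff
#' the mean intensity over the surface vertices within
#' `neighborhood_radius` of it (geodesic distance approximated by shortest
#' path along mesh edges) reaches `cortical_low`; with radius 0 this
#' degenerates to per-vertex thresholding. The neighborhood mean emulates
#' the robustness of volumetric mask refinement while staying purely
#' surface-based.
#'
#' @param mesh a [trimesh()] carrying per-vertex `intensity` (HU).
#' @param cortical_low lower bound of the cortical intensity range (HU);
#'   default 700.
#' @param neighborhood_radius averaging radius (mm, >= 0).
#' @return object of class `surface_labeling`: list with `class` (factor,
#'   levels `intact`/`fracture`), and empty `patches` until
#'   [extract_patches()] is run.
#' @export
classify_vertices <- function(mesh, cortical_low = 700,
                              neighborhood_radius = 0) {
  if (is.null(mesh$intensity))
    stop("mesh carries no per-vertex intensities")
  if (neighborhood_radius < 0) stop("neighborhood_radius must be >= 0")
  hu <- mesh$intensity
  n <- nrow(mesh$vertices)
  if (neighborhood_radius == 0) {
    meanhu <- hu
  } else {
    adj <- vertex_adjacency(mesh)
    V <- mesh$vertices
    meanhu <- vapply(seq_len(n), function(i) {
      mean(hu[graph_ball(i, adj, V, neighborhood_radius)])
    }, numeric(1))
  }
  cls <- factor(ifelse(meanhu >= cortical_low, "intact", "fracture"),
                levels = c("intact", "fracture"))
  if (length(unique(cls)) == 1L)
    warning(sprintf(
      "all vertices labeled '%s'; the %g HU threshold may be inappropriate",
      as.character(cls[1L]), cortical_low))
  structure(list(class = cls, patches = NULL,
                 params = list(cortical_low = cortical_low,
                               neighborhood_radius = neighborhood_radius)),
            class = "surface_labeling")
}

# Dijkstra ball: vertices within `radius` edge-path distance of vertex i.
graph_ball <- function(i, adj, V, radius) {
  dist <- c(structure(0, names = i))
  frontier <- i
  repeat {
    newd <- numeric(0)
    for (u in frontier) {
      du <- dist[[as.character(u)]]
      for (w in adj[[u]]) {
        dw <- du + sqrt(sum((V[u, ] - V[w, ])^2))
        if (dw <= radius) {
          key <- as.character(w)
          if (!(key %in% names(dist)) || dw < dist[[key]] - 1e-12) {
            dist[key] <- dw
            newd <- c(newd, w)
          }
        }
      }
    }
    if (!length(newd)) break
    frontier <- unique(newd)
  }
  as.integer(names(dist))
}

#' @export
print.surface_labeling <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<surface_labeling> %d intact, %d fracture vertices\n",
              tab[["intact"]], tab[["fracture"]]))
  if (!is.null(x$patches))
    cat(sprintf("  %d fracture patch(es), %d vertices discarded in %d small component(s)\n",
                length(x$patches$members), x$patches$discarded_vertices,
                x$patches$discarded_components))
  invisible(x)
}

#' Connected fracture patches
#'
#' Groups fracture-labeled vertices into edge-connected components, the
#' pairing units of fragment-to-base matching. Component area is the summed
#' area of faces whose three vertices all belong to the component;
#' components below `min_area` are discarded (and counted). Patches are
#' numbered by decreasing area (ties by smallest member vertex index).
#'
#' @param mesh a [trimesh()].
#' @param labeling a [classify_vertices()] result (or any
#'   `surface_labeling`).
#' @param min_area minimum patch area (mm^2).
#' @return the `surface_labeling` with `patches` filled in: `members` (list
#'   of integer vertex sets), `area` (mm^2), `centroid` (k x 3), `vertex`
#'   (per-vertex patch id, `NA` if none), discard counters.
#' @export
extract_patches <- function(mesh, labeling, min_area = 0) {
  stopifnot(inherits(labeling, "surface_labeling"))
  frac <- labeling$class == "fracture"
  n <- nrow(mesh$vertices)
  comp <- rep(NA_integer_, n)
  if (any(frac)) {
    ec <- edge_census(mesh)
    e <- ec$edges
    e <- e[frac[e[, 1]] & frac[e[, 2]], , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (nrow(e))
      for (k in seq_len(nrow(e)))
        parent[find(e[k, 1])] <- find(e[k, 2])
    comp[frac] <- vapply(which(frac), find, integer(1))
  }
  ids <- unique(stats::na.omit(comp))
  fa <- face_normals(mesh)$areas
  fcomp <- matrix(comp[mesh$faces], ncol = 3L)
  allsame <- !is.na(fcomp[, 1]) & !is.na(fcomp[, 2]) &
    !is.na(fcomp[, 3]) & fcomp[, 1] == fcomp[, 2] &
    fcomp[, 1] == fcomp[, 3]
  members <- lapply(ids, function(id) which(comp == id))
  areas <- vapply(ids, function(id)
    sum(fa[allsame & fcomp[, 1] == id]), numeric(1))
  keep <- areas >= min_area & areas > 0
  discarded_components <- sum(!keep)
  discarded_vertices <- sum(lengths(members[!keep]))
  members <- members[keep]
  areas <- areas[keep]
  ord <- order(-areas, vapply(members, min, integer(1)))
  members <- members[ord]
  areas <- areas[ord]
  vert <- rep(NA_integer_, n)
  for (k in seq_along(members)) vert[members[[k]]] <- k
  centroid <- if (length(members))
    t(vapply(members, function(m)
      colMeans(mesh$vertices[m, , drop = FALSE]), numeric(3)))
  else matrix(numeric(0), 0, 3)
  labeling$patches <- list(members = members, area = areas,
                           centroid = centroid, vertex = vert,
                           discarded_components = discarded_components,
                           discarded_vertices = discarded_vertices)
  labeling
}

#' Intact outer shell of a labeled fragment
#'
#' The open submesh of everything that is not wholly fracture surface:
#' the fragment's original outer (cortical) surface. This is the natural
#' input to [zipper()] when rebuilding the consensus bone surface from
#' reduced fragments -- the fracture caps of seated fragments face each
#' other inside the bone and would otherwise survive as internal
#' membranes.
#'
#' @param mesh a [trimesh()].
#' @param labeling a [classify_vertices()] labeling of `mesh`.
#' @return an open [trimesh()].
#' @export
intact_shell <- function(mesh, labeling) {
  frac <- labeling$class == "fracture"
  Fm <- mesh$faces
  keep <- !(frac[Fm[, 1]] & frac[Fm[, 2]] & frac[Fm[, 3]])
  compact_mesh(submesh_faces(mesh, which(keep)))
}

#' Heuristic patch pairing proposals
#'
#' Ranks candidate (fragment patch, base patch) pairs by relative area
#' difference for the operator to confirm; the operator's own pairing file
#' always takes precedence. Ties resolve by (fragment patch id, base patch
#' id) order, so the ranking is deterministic.
#'
#' @param frag_patches,base_patches `patches` elements of
#'   [extract_patches()] results (or whole `surface_labeling`s).
#' @param fragment id used in the output (default `1`).
#' @return data.frame with columns `fragment`, `frag_patch`, `base_patch`,
#'   `score` (relative area difference) and `provenance` (`"heuristic"`).
#' @export
propose_pairs <- function(frag_patches, base_patches, fragment = 1L) {
  fp <- if (inherits(frag_patches, "surface_labeling"))
    frag_patches$patches else frag_patches
  bp <- if (inherits(base_patches, "surface_labeling"))
    base_patches$patches else base_patches
  if (!length(fp$members) || !length(bp$members))
    stop("need at least one patch on each side")
  grid <- expand.grid(frag_patch = seq_along(fp$members),
                      base_patch = seq_along(bp$members))
  a <- fp$area[grid$frag_patch]
  b <- bp$area[grid$base_patch]
  grid$score <- abs(a - b) / pmax(a, b)
  grid <- grid[order(grid$score, grid$frag_patch, grid$base_patch), ]
  rownames(grid) <- NULL
  data.frame(fragment = fragment, grid[, c("frag_patch", "base_patch")],
             score = grid$score, provenance = "heuristic",
             stringsAsFactors = FALSE)
}
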