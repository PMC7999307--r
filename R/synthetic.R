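#' Procedural bone phantom
#'
#' Builds a closed, manifold, genus-0 surface emulating a long-bone segment:
#' a capped cylindrical shaft whose upper portion flares smoothly outward
#' (metaphysis-like widening). Fully deterministic for given parameters; the
#' `seed` is only recorded so downstream case manifests can reproduce a
#' whole pipeline from one number.
#'
#' @param shaft_radius shaft radius (mm).
#' @param length bone segment length (mm).
#' @param flare ratio of the flared end radius to the shaft radius (>= 1).
#' @param resolution number of circumferential segments (>= 8); axial
#'   spacing is matched to the circumferential spacing.
#' @param seed optional integer, recorded as an attribute.
#' @return a closed [trimesh()].
#' @export
make_phantom <- function(shaft_radius = 10, length = 80, flare = 1.6,
                         resolution = 32, seed = NULL) {
  if (shaft_radius <= 0 || length <= 0 || flare < 1)
    stop("phantom dimensions must be positive and flare >= 1")
  if (resolution < 8)
    stop("resolution too low for a manifold phantom (need >= 8)")
  nc <- as.integer(resolution)
  ds <- 2 * pi * shaft_radius / nc
  nz <- max(4L, as.integer(round(length / ds)))
  zs <- seq(0, length, length.out = nz + 1L)
  # smooth flare over the top 30% of the shaft
  tt <- pmin(1, pmax(0, (zs - 0.7 * length) / (0.3 * length)))
  s <- tt^2 * (3 - 2 * tt)
  radii <- shaft_radius * (1 + (flare - 1) * s)
  th <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  V <- do.call(rbind, lapply(seq_along(zs), function(j)
    cbind(radii[j] * cos(th), radii[j] * sin(th), zs[j])))
  vid <- function(j, i) (j - 1L) * nc + ((i - 1L) %% nc) + 1L
  F_ <- vector("list", nz)
  for (j in seq_len(nz)) {
    i <- seq_len(nc)
    a <- vid(j, i); b <- vid(j, i + 1L)
    c_ <- vid(j + 1L, i + 1L); d <- vid(j + 1L, i)
    F_[[j]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  base_c <- nrow(V) + 1L
  top_c <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, 0), c(0, 0, length))
  i <- seq_len(nc)
  caps <- rbind(cbind(base_c, vid(1L, i + 1L), vid(1L, i)),
                cbind(top_c, vid(nz + 1L, i), vid(nz + 1L, i + 1L)))
  m <- trimesh(V, rbind(do.call(rbind, F_), caps))
  attr(m, "seed") <- seed
  m
}

# Signed implicit function of a cut description.
cut_function <- function(cut) {
  if (identical(cut$type, "sphere")) {
    center <- cut$center
    radius <- cut$radius
    function(P) sqrt(rowSums(sweep(P, 2, center)^2)) - radius
  } else {
    nrm <- cut$normal / sqrt(sum(cut$normal^2))
    pt <- cut$point
    function(P) as.vector(sweep(P, 2, pt) %*% nrm)
  }
}

#' Describe a planar or spherical cut
#' @param point,normal plane through `point` with normal `normal`.
#' @return a cut description for [fracture()].
#' @export
plane_cut <- function(point, normal)
  list(type = "plane", point = as.numeric(point),
       normal = as.numeric(normal))

#' @rdname plane_cut
#' @param center,radius sphere parameters (mm).
#' @export
sphere_cut <- function(center, radius)
  list(type = "sphere", center = as.numeric(center), radius = radius)

# Subdivide mesh faces along the zero level set of f; returns mesh whose
# faces no longer cross the level set, plus per-vertex signed values and a
# flag for vertices created on the cut.
split_by_levelset <- function(V, Fm, created, f, tol = 1e-9) {
  s <- f(V)
  s[abs(s) < tol] <- 0
  cache <- new.env(parent = emptyenv())
  newF <- vector("list", nrow(Fm))
  for (k in seq_len(nrow(Fm))) {
    tri <- Fm[k, ]
    sv <- s[tri]
    if (!(any(sv > 0) && any(sv < 0))) {
      newF[[k]] <- matrix(tri, 1L, 3L)
      next
    }
    # intersection vertex on a crossing edge, cached by undirected edge;
    # the linear-interpolation estimate is refined by bisection so the
    # vertex lies on the (possibly curved) level set to machine precision
    ipt <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(cache[[key]])) return(cache[[key]])
      lo <- 0
      hi <- 1
      flo <- s[a]
      pt <- function(t) V[a, ] + t * (V[b, ] - V[a, ])
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        fm <- f(matrix(pt(mid), 1, 3))
        if (fm == 0) { lo <- mid; hi <- mid; break }
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      p <- pt((lo + hi) / 2)
      V <<- rbind(V, p)
      s <<- c(s, 0)
      created <<- c(created, TRUE)
      cache[[key]] <- nrow(V)
      nrow(V)
    }
    nzero <- sum(sv == 0)
    if (nzero == 1L) { # one vertex on the cut, two on opposite sides
      o <- tri[sv == 0]
      pq <- tri[sv != 0]
      m <- ipt(pq[1], pq[2])
      # preserve winding: rotate so tri = (o, p, q)
      rot <- tri
      while (s[rot[1]] != 0) rot <- rot[c(2, 3, 1)]
      newF[[k]] <- rbind(c(rot[1], rot[2], m), c(rot[1], m, rot[3]))
    } else { # one vertex isolated on its side of the cut
      iso_side <- if (sum(sv > 0) == 1L) 1 else -1
      rot <- tri
      while (sign(s[rot[1]]) != iso_side) rot <- rot[c(2, 3, 1)]
      m1 <- ipt(rot[1], rot[2])
      m2 <- ipt(rot[1], rot[3])
      newF[[k]] <- rbind(c(rot[1], m1, m2),
                         c(m1, rot[2], rot[3]),
                         c(m1, rot[3], m2))
    }
  }
  list(V = V, Fm = do.call(rbind, newF), s = s, created = created)
}

#' Simulated fracture of a closed phantom
#'
#' Splits a closed mesh by one or more cuts (planes or spheres), caps every
#' cut cross-section with a triangulated fan, and labels the cap vertices as
#' ground-truth fracture surface. Fragment count equals the number of
#' spatial cells the cuts induce that intersect the solid; fragments are
#' returned largest (by volume) first, the largest acting as the base bone.
#'
#' @param mesh a closed [trimesh()].
#' @param cuts list of cut descriptions from [plane_cut()]/[sphere_cut()].
#' @param seed optional integer recorded in the result.
#' @param roughness amplitude (mm) of the deterministic roughness applied
#'   to the interior of each fracture surface; 0 gives smooth caps.
#' @param cap_rounds cap subdivision rounds (interior resolution of the
#'   fracture surfaces).
#' @return object of class `fracture_set`: list with `fragments` (each a
#'   list with `mesh`, `fracture_mask` (logical per vertex), `cut_id`
#'   (integer per vertex, `NA` off the cut surfaces), `volume`), plus
#'   `cuts` and `seed`. Fragment 1 is the base.
#' @export
fracture <- function(mesh, cuts, seed = NULL, roughness = 0.4,
                     cap_rounds = 2L) {
  if (!length(cuts)) stop("need at least one cut")
  V <- mesh$vertices
  Fm <- mesh$faces
  created <- rep(FALSE, nrow(V))
  scale <- max(apply(V, 2, function(x) diff(range(x))))
  keep <- logical(length(cuts))
  for (ci in seq_along(cuts)) {
    f <- cut_function(cuts[[ci]])
    sv <- f(V)
    if (all(sv >= -1e-9 * scale) || all(sv <= 1e-9 * scale)) {
      warning(sprintf("cut %d does not intersect the solid; skipped", ci))
      next
    }
    keep[ci] <- TRUE
    res <- split_by_levelset(V, Fm, created, f, tol = 1e-9 * scale)
    V <- res$V; Fm <- res$Fm; created <- res$created
  }
  cuts <- cuts[keep]
  if (!length(cuts)) stop("no cut intersects the solid")
  # signs per cut for every (possibly new) vertex
  S <- vapply(cuts, function(cut) {
    s <- cut_function(cut)(V)
    s[abs(s) < 1e-9 * scale] <- 0
    sign(s)
  }, numeric(nrow(V)))
  S <- matrix(S, nrow = nrow(V))
  # cell id per face: per cut, the nonzero sign of its vertices
  fc <- vapply(seq_along(cuts), function(ci) {
    sv <- matrix(S[Fm, ci], ncol = 3L)
    out <- sign(rowSums(sv))
    out[out == 0] <- 1 # faces lying exactly on a cut: arbitrary stable side
    out
  }, numeric(nrow(Fm)))
  fc <- matrix(fc, nrow = nrow(Fm))
  cell <- apply(fc, 1, paste, collapse = "/")
  fragments <- list()
  for (cl in unique(cell)) {
    fidx <- which(cell == cl)
    comp <- face_components(Fm[fidx, , drop = FALSE])
    for (cmp in comp)
      fragments[[length(fragments) + 1L]] <- fidx[cmp]
  }
  out <- lapply(fragments, function(fidx) {
    open <- compact_mesh(submesh_faces(trimesh(V, Fm, validate = FALSE),
                                       fidx),
                         carry = list(created = created))
    kept <- attr(open, "kept_vertices")
    capped <- cap_holes(open, cuts = cuts, roughness = roughness,
                        rounds = cap_rounds)
    nv <- nrow(capped$mesh$vertices)
    mask <- logical(nv)
    mask[capped$cap_vertices] <- TRUE
    cut_id <- rep(NA_integer_, nv)
    # attribute cap vertices to the nearest cut level set
    if (any(mask)) {
      P <- capped$mesh$vertices[mask, , drop = FALSE]
      dmat <- vapply(cuts, function(cut) abs(cut_function(cut)(P)),
                     numeric(nrow(P)))
      dmat <- matrix(dmat, nrow = nrow(P))
      cut_id[mask] <- max.col(-dmat, ties.method = "first")
    }
    list(mesh = capped$mesh, fracture_mask = mask, cut_id = cut_id,
         volume = abs(mesh_volume(capped$mesh)))
  })
  out <- out[order(vapply(out, `[[`, numeric(1), "volume"),
                   decreasing = TRUE)]
  structure(list(fragments = out, cuts = cuts, seed = seed),
            class = "fracture_set")
}

#' @export
print.fracture_set <- function(x, ...) {
  cat(sprintf("<fracture_set> %d fragment(s) from %d cut(s)\n",
              length(x$fragments), length(x$cuts)))
  for (i in seq_along(x$fragments)) {
    fr <- x$fragments[[i]]
    cat(sprintf("  fragment %d%s: %d vertices, volume %.1f mm^3, %d fracture vertices\n",
                i, if (i == 1) " (base)" else "", nrow(fr$mesh$vertices),
                fr$volume, sum(fr$fracture_mask)))
  }
  invisible(x)
}

# Connected components of a face set via shared edges; returns list of
# integer index vectors into the rows of Fm.
face_components <- function(Fm) {
  nf <- nrow(Fm)
  if (nf == 0L) return(list())
  key <- c(edge_key(Fm[, 1], Fm[, 2]), edge_key(Fm[, 2], Fm[, 3]),
           edge_key(Fm[, 3], Fm[, 1]))
  fid <- rep(seq_len(nf), 3L)
  groups <- split(fid, key)
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (g in groups) {
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) parent[find(j)] <- r
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  unname(split(seq_len(nf), roots))
}

# Cap every boundary loop of a fragment: fan from the loop centroid,
# refined by subdivision with new vertices projected onto the cut surface
# and roughened by a deterministic positional bump field. A smooth fan is
# a cone -- close to a surface of revolution, whose sliding symmetry makes
# fragment pose unobservable; real fracture surfaces are rough and
# irregular, which is what makes fracture reduction well-posed. Both
# fragments build the identical cap from the shared rim, so caps stay
# exactly complementary (fragment volumes still sum to the phantom's).
cap_holes <- function(mesh, cuts = NULL, roughness = 0, rounds = 2L) {
  b <- detect_boundary(mesh)
  V <- mesh$vertices
  Fm <- mesh$faces
  capv <- integer(0)
  for (loop in b$loops) {
    if (length(loop) < 3L) next
    # each loop's cap is built independently, from its own rim only, so
    # the two fragments sharing a rim construct the identical cap
    centroid <- colMeans(V[loop, , drop = FALSE])
    V <- rbind(V, centroid)
    apex <- nrow(V)
    nxt <- c(loop[-1L], loop[1L])
    # fill traverses each boundary edge opposite to its surface direction
    capF <- cbind(apex, nxt, loop)
    cutfun <- NULL
    if (!is.null(cuts) && length(cuts)) {
      probe <- V[loop, , drop = FALSE]
      dev <- vapply(cuts, function(cut)
        mean(abs(cut_function(cut)(probe))), numeric(1))
      cutfun <- cut_function(cuts[[which.min(dev)]])
    }
    is_rim <- logical(nrow(V))
    is_rim[loop] <- TRUE
    for (r in seq_len(rounds)) {
      res <- split_cap_faces(V, capF, is_rim)
      V <- res$V
      capF <- res$faces
      is_rim <- c(is_rim, rep(FALSE, nrow(V) - length(is_rim)))
    }
    interior <- setdiff(unique(as.vector(capF)), which(is_rim))
    if (!is.null(cutfun) && length(interior)) {
      # project interior cap vertices onto the cut surface (fixed-point
      # steps along the numerical gradient)
      P <- V[interior, , drop = FALSE]
      for (it in 1:4) {
        fv <- cutfun(P)
        g <- numeric_gradient(cutfun, P)
        gl2 <- rowSums(g^2)
        gl2[gl2 == 0] <- 1
        P <- P - (fv / gl2) * g
      }
      if (roughness > 0) {
        # deterministic bump field along the cut-surface normal, tapered
        # to zero at the rim so the outer wall is untouched
        g <- numeric_gradient(cutfun, P)
        gl <- sqrt(rowSums(g^2))
        gl[gl == 0] <- 1
        n <- g / gl
        bump <- (sin(0.9 * P[, 1] + 1.3 * P[, 2]) +
                   cos(1.2 * P[, 2] - 0.8 * P[, 3]) +
                   sin(1.1 * P[, 3] + 0.5 * P[, 1])) / 3
        rim_d <- points_to_polyline_dist(P, V[loop, , drop = FALSE],
                                         closed = TRUE)
        taper <- pmin(1, rim_d / 2)
        P <- P + roughness * bump * taper * n
      }
      V[interior, ] <- P
    }
    Fm <- rbind(Fm, capF)
    capv <- c(capv, as.vector(capF))
  }
  list(mesh = trimesh(V, Fm, validate = FALSE),
       cap_vertices = unique(capv))
}

# One round of cap subdivision: split every cap-face edge except rim-rim
# edges (those are shared with the outer wall and must stay intact).
split_cap_faces <- function(V, Fm, is_rim) {
  cache <- new.env(parent = emptyenv())
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (!is.null(cache[[key]])) return(cache[[key]])
    V <<- rbind(V, (V[a, ] + V[b, ]) / 2)
    cache[[key]] <- nrow(V)
    nrow(V)
  }
  out <- vector("list", nrow(Fm))
  for (k in seq_len(nrow(Fm))) {
    tri <- Fm[k, ]
    splits <- !(is_rim[tri] & is_rim[tri[c(2, 3, 1)]]) # edges 12, 23, 31
    ns <- sum(splits)
    if (ns == 0L) {
      out[[k]] <- matrix(tri, 1, 3)
    } else if (ns == 3L) {
      m12 <- midpoint(tri[1], tri[2])
      m23 <- midpoint(tri[2], tri[3])
      m31 <- midpoint(tri[3], tri[1])
      out[[k]] <- rbind(c(tri[1], m12, m31), c(m12, tri[2], m23),
                        c(m31, m23, tri[3]), c(m12, m23, m31))
    } else {
      # rotate so unsplit edges come last
      while (!splits[1]) {
        tri <- tri[c(2, 3, 1)]
        splits <- splits[c(2, 3, 1)]
      }
      if (ns == 1L) {
        m <- midpoint(tri[1], tri[2])
        out[[k]] <- rbind(c(tri[1], m, tri[3]), c(m, tri[2], tri[3]))
      } else {
        # two split edges; rotate so the unsplit edge is (3, 1)
        while (splits[3]) {
          tri <- tri[c(2, 3, 1)]
          splits <- splits[c(2, 3, 1)]
        }
        m12 <- midpoint(tri[1], tri[2])
        m23 <- midpoint(tri[2], tri[3])
        # quad (tri1, m12, m23, tri3): pick its diagonal by coordinate
        # order so both fragments (which see this face with opposite
        # winding) triangulate the shared cap identically
        if (coord_less(V[tri[1], ], V[tri[3], ])) {
          out[[k]] <- rbind(c(tri[1], m12, m23), c(m12, tri[2], m23),
                            c(tri[1], m23, tri[3]))
        } else {
          out[[k]] <- rbind(c(tri[1], m12, tri[3]), c(m12, tri[2], m23),
                            c(m12, m23, tri[3]))
        }
      }
    }
  }
  list(V = V, faces = do.call(rbind, out))
}

# Strict lexicographic comparison of two coordinate triples.
coord_less <- function(a, b) {
  for (k in 1:3) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

numeric_gradient <- function(f, P, h = 1e-5) {
  cbind(f(P + matrix(c(h, 0, 0), nrow(P), 3, byrow = TRUE)) -
          f(P - matrix(c(h, 0, 0), nrow(P), 3, byrow = TRUE)),
        f(P + matrix(c(0, h, 0), nrow(P), 3, byrow = TRUE)) -
          f(P - matrix(c(0, h, 0), nrow(P), 3, byrow = TRUE)),
        f(P + matrix(c(0, 0, h), nrow(P), 3, byrow = TRUE)) -
          f(P - matrix(c(0, 0, h), nrow(P), 3, byrow = TRUE))) / (2 * h)
}

#' Fracture-surface submesh of a fragment
#'
#' Extracts the open submesh spanned by the faces whose three vertices all
#' carry the ground-truth fracture mask (optionally restricted to one cut).
#' This is the open "network" that fracture-surface matching operates on;
#' aligning whole closed fragments instead creates false pairs across the
#' cut rim that destabilize the fit.
#'
#' @param fragment one element of a `fracture_set`'s `fragments` list.
#' @param cut optional cut id restriction.
#' @return an open [trimesh()].
#' @export
fracture_patch_mesh <- function(fragment, cut = NULL) {
  mask <- fragment$fracture_mask
  if (!is.null(cut)) mask <- mask & !is.na(fragment$cut_id) &
      fragment$cut_id == cut
  Fm <- fragment$mesh$faces
  keep <- mask[Fm[, 1]] & mask[Fm[, 2]] & mask[Fm[, 3]]
  if (!any(keep)) stop("no face lies fully on the requested fracture surface")
  compact_mesh(submesh_faces(fragment$mesh, which(keep)))
}

#' Displace fragments with recorded ground truth
#'
#' Applies a random rigid displacement (rotation about the fragment
#' centroid plus translation) to every fragment except the base (fragment
#' 1), recording the exact transforms so alignment can be scored against
#' ground truth.
#'
#' @param fs a `fracture_set` from [fracture()].
#' @param max_rot_deg maximum rotation angle (degrees).
#' @param max_trans_mm maximum translation norm (mm).
#' @param seed integer seed.
#' @return the `fracture_set` with displaced fragment meshes and a
#'   `transforms` element (list of [rigid_transform()], identity for the
#'   base).
#' @export
displace <- function(fs, max_rot_deg, max_trans_mm, seed) {
  stopifnot(inherits(fs, "fracture_set"))
  with_seed(seed, {
    tfs <- vector("list", length(fs$fragments))
    tfs[[1L]] <- rigid_transform()
    for (i in seq_along(fs$fragments)[-1L]) {
      R <- if (max_rot_deg > 0)
        random_rotation(max_rot_deg * pi / 180) else diag(3)
      tdir <- stats::rnorm(3)
      tdir <- tdir / sqrt(sum(tdir^2))
      tlen <- if (max_trans_mm > 0) stats::runif(1, 0, max_trans_mm) else 0
      ctr <- colMeans(fs$fragments[[i]]$mesh$vertices)
      tf <- rigid_transform(R, ctr - as.vector(R %*% ctr) + tlen * tdir)
      fs$fragments[[i]]$mesh <- apply_transform(tf, fs$fragments[[i]]$mesh)
      tfs[[i]] <- tf
    }
    fs$transforms <- tfs
    fs$displace_seed <- seed
    fs
  })
}

#' Surface noise along vertex normals
#'
#' Perturbs vertex positions by independent normal displacements of
#' standard deviation `sigma` along the vertex normals, emulating
#' segmentation surface-location uncertainty. Faces are unchanged.
#'
#' @param mesh a [trimesh()].
#' @param sigma standard deviation (mm).
#' @param seed integer seed.
#' @param vertices optional integer subset of vertices to perturb (e.g. cap
#'   vertices only, for fracture-surface roughness).
#' @return the perturbed mesh.
#' @export
add_noise <- function(mesh, sigma, seed, vertices = NULL) {
  if (sigma == 0) return(mesh)
  with_seed(seed, {
    n <- compute_vertex_normals(mesh)
    idx <- if (is.null(vertices)) seq_len(nrow(mesh$vertices)) else vertices
    disp <- stats::rnorm(length(idx), 0, sigma)
    mesh$vertices[idx, ] <- mesh$vertices[idx, , drop = FALSE] +
      disp * n[idx, , drop = FALSE]
    mesh
  })
}

#' Synthetic Hounsfield intensities
#'
#' Assigns per-vertex CT intensities consistent with the cortical /
#' cancellous contrast exploited by the surface classifier: intact-surface
#' vertices draw uniformly from the cortical range (default 700-2500 HU)
#' while ground-truth fracture (cut-face) vertices draw from a normal
#' distribution around the exposed-cancellous level (default mean 350 HU,
#' sd 100, clipped at 0).
#'
#' @param fs a `fracture_set`.
#' @param cortical_range length-2 range of intact-surface intensities (HU).
#' @param cancellous_mean,cancellous_sd fracture-surface intensity
#'   distribution (HU).
#' @param seed integer seed.
#' @return the `fracture_set` with `intensity` set on every fragment mesh.
#' @export
synth_intensities <- function(fs, cortical_range = c(700, 2500),
                              cancellous_mean = 350, cancellous_sd = 100,
                              seed = 1L) {
  stopifnot(inherits(fs, "fracture_set"))
  with_seed(seed, {
    fs$fragments <- lapply(fs$fragments, function(fr) {
      n <- nrow(fr$mesh$vertices)
      hu <- stats::runif(n, cortical_range[1], cortical_range[2])
      k <- sum(fr$fracture_mask)
      if (k)
        hu[fr$fracture_mask] <-
          pmax(0, stats::rnorm(k, cancellous_mean, cancellous_sd))
      fr$mesh$intensity <- hu
      fr
    })
    fs
  })
}

#' Complete synthetic fracture case
#'
#' One-call fixture: phantom, fracture, synthetic intensities, recorded
#' random displacement, optional surface noise. All randomness flows from
#' the single `seed`.
#'
#' The default cut is a single spherical (curved) fracture surface with
#' its center offset from the bone axis. Curvature matters: a perfectly
#' flat fracture surface leaves the in-plane motion of the fragment
#' unobservable (the sliding/degenerate failure mode the alignment
#' diagnostics flag), so a flat default would make pose recovery
#' ill-posed by construction rather than testing the estimator.
#'
#' @param cuts list of cuts (default: one offset spherical cut through the
#'   metaphyseal region).
#' @param phantom_params list of [make_phantom()] arguments.
#' @param max_rot_deg,max_trans_mm displacement magnitudes.
#' @param sigma surface noise standard deviation (mm).
#' @param seed integer seed.
#' @return object of class `fracture_case`: the displaced, intensity-carrying
#'   `fracture_set` plus `phantom` and the pristine (undisplaced) fragments
#'   in `reference`.
#' @export
make_fracture_case <- function(cuts = NULL, phantom_params = list(),
                               max_rot_deg = 5, max_trans_mm = 2,
                               sigma = 0, seed = 1L) {
  phantom <- do.call(make_phantom, c(phantom_params, list(seed = seed)))
  if (is.null(cuts)) {
    r <- max(sqrt(rowSums(phantom$vertices[, 1:2]^2)))
    L <- max(phantom$vertices[, 3])
    cuts <- list(sphere_cut(c(0.4 * r, 0.2 * r, 0.69 * L), 1.05 * r))
  }
  fs <- fracture(phantom, cuts, seed = seed)
  fs <- synth_intensities(fs, seed = seed + 1L)
  reference <- fs$fragments
  fs <- displace(fs, max_rot_deg, max_trans_mm, seed = seed + 2L)
  if (sigma > 0)
    fs$fragments <- lapply(seq_along(fs$fragments), function(i) {
      fr <- fs$fragments[[i]]
      fr$mesh <- add_noise(fr$mesh, sigma, seed = seed + 10L + i)
      fr
    })
  structure(c(fs, list(phantom = phantom, reference = reference,
                       sigma = sigma, case_seed = seed)),
            class = c("fracture_case", "fracture_set"))
}
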