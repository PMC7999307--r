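#' Find distance-limited correspondences
#'
#' Pairs every source point with the nearest point on the continuous target
#' surface, provided it lies within the capture range `d` (pairs "too far
#' apart" are never created). Each correspondence carries the interpolated
#' target unit normal (barycentric blend of vertex normals) and a flag
#' marking targets that touch the target boundary.
#'
#' @param source_points n x 3 matrix of source points (mm).
#' @param target a [trimesh()].
#' @param d capture range (mm, > 0).
#' @param precomp optional list with precomputed `boundary`
#'   ([detect_boundary()]) and `vnormals` ([compute_vertex_normals()]) of
#'   the target.
#' @return object of class `correspondences`: list of parallel fields
#'   `src`, `tgt` (matrices), `dist`, `face`, `bary`, `normal`,
#'   `on_boundary`, `weight` (initialized to 1).
#' @export
find_correspondences <- function(source_points, target, d, precomp = NULL) {
  if (inherits(source_points, "trimesh"))
    source_points <- source_points$vertices
  if (is.null(precomp))
    precomp <- list(boundary = detect_boundary(target),
                    vnormals = compute_vertex_normals(target))
  res <- closest_points_cpp(source_points, target$vertices, target$faces, d)
  res <- annotate_surface_points(res, target, precomp$boundary)
  keep <- which(res$found)
  if (!length(keep))
    stop("surfaces not within capture range: no correspondence within d")
  vn <- precomp$vnormals
  fidx <- target$faces[res$face[keep], , drop = FALSE]
  bary <- res$bary[keep, , drop = FALSE]
  nrm <- bary[, 1] * vn[fidx[, 1], , drop = FALSE] +
    bary[, 2] * vn[fidx[, 2], , drop = FALSE] +
    bary[, 3] * vn[fidx[, 3], , drop = FALSE]
  len <- sqrt(rowSums(nrm^2))
  nz <- len > 0
  nrm[nz, ] <- nrm[nz, , drop = FALSE] / len[nz]
  structure(list(src = source_points[keep, , drop = FALSE],
                 tgt = res$point[keep, , drop = FALSE],
                 dist = res$dist[keep],
                 face = res$face[keep],
                 bary = bary,
                 normal = nrm,
                 on_boundary = res$on_boundary[keep],
                 weight = rep(1, length(keep)),
                 source_index = keep),
            class = "correspondences")
}

#' @export
print.correspondences <- function(x, ...) {
  cat(sprintf(
    "<correspondences> %d pairs, mean distance %.4g mm, %d on boundary\n",
    length(x$dist), mean(x$dist), sum(x$on_boundary)))
  invisible(x)
}

#' @export
length.correspondences <- function(x) length(x$dist)

subset_corrs <- function(corrs, keep) {
  out <- lapply(corrs, function(fld) {
    if (is.matrix(fld)) fld[keep, , drop = FALSE] else fld[keep]
  })
  class(out) <- "correspondences"
  out
}

#' Remove boundary-touching pairs
#'
#' Drops every correspondence whose target point lies on a boundary vertex
#' or in the interior of a boundary edge: matches against the delimitation
#' of the base network drag the solution sideways and are excluded from the
#' fit. Order is preserved.
#'
#' @param corrs a [find_correspondences()] result.
#' @return the filtered `correspondences`.
#' @export
filter_boundary_pairs <- function(corrs) {
  out <- subset_corrs(corrs, !corrs$on_boundary)
  if (!length(out$dist))
    stop("all correspondences touch the target boundary; nothing to fit")
  out
}

#' Trust weight of a target surface point
#'
#' Confidence of a matched target point: the scalar product of the surface
#' normal with a viewing direction, clamped to `[0, 1]` (a legacy range-scan
#' heuristic; for CT-derived surfaces the binary operator mode of
#' [apply_trust_weights()] is the default). Zero normals yield weight 0
#' with a warning.
#'
#' @param normal unit normal (length-3 vector or n x 3 matrix).
#' @param view_direction unit viewing direction.
#' @return weight(s) in `[0, 1]`.
#' @export
trust_weight <- function(normal, view_direction) {
  if (is.null(dim(normal))) normal <- matrix(normal, 1L, 3L)
  view_direction <- view_direction / sqrt(sum(view_direction^2))
  len <- sqrt(rowSums(normal^2))
  if (any(len == 0))
    warning("zero normal(s): assigning weight 0")
  w <- pmax(0, as.vector(normal %*% view_direction))
  w[len == 0] <- 0
  w
}

#' Set correspondence weights
#'
#' `"binary"` mode implements operator certainty: weight 1 everywhere
#' except indices listed in `exclude` (weight 0). `"scalar"` mode uses
#' [trust_weight()] against `view_direction` (defaulting to the mean source
#' displacement-to-target direction is meaningless for CT, so the caller
#' supplies it; [icp()] defaults it to the mean source patch normal).
#'
#' @param corrs a `correspondences` object.
#' @param mode `"binary"` or `"scalar"`.
#' @param view_direction unit vector for `"scalar"` mode.
#' @param exclude integer indices (into the correspondence list) zeroed in
#'   `"binary"` mode.
#' @return the `correspondences` with `weight` set.
#' @export
apply_trust_weights <- function(corrs, mode = c("binary", "scalar"),
                                view_direction = NULL, exclude = NULL) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    w <- rep(1, length(corrs$dist))
    if (length(exclude)) w[exclude] <- 0
  } else {
    if (is.null(view_direction))
      stop("scalar trust weighting needs a view_direction")
    w <- trust_weight(corrs$normal, view_direction)
  }
  corrs$weight <- w
  corrs
}

degeneracy_error <- function(msg) {
  stop(structure(class = c("bonereduce_degeneracy", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Weighted point-to-point rigid solve
#'
#' Global minimizer of the weighted sum of squared pair distances
#' `sum_i w_i |M_i - (R N_i + t)|^2` by the closed-form weighted
#' cross-covariance / orthogonal decomposition with determinant correction
#' (rotation about the weighted source centroid, then centroid-matching
#' translation).
#'
#' @param corrs a `correspondences` object with weights.
#' @return a [rigid_transform()] with attributes `residual` (the objective
#'   at the solution, mm^2) and `singular_values`.
#' @export
solve_point_to_point <- function(corrs) {
  w <- corrs$weight
  if (sum(w) <= 0) degeneracy_error("total correspondence weight is zero")
  if (sum(w > 0) < 3L)
    degeneracy_error("need at least 3 positively weighted correspondences")
  X <- corrs$src
  Y <- corrs$tgt
  Nc <- colSums(X * w) / sum(w)
  Mc <- colSums(Y * w) / sum(w)
  Xc <- sweep(X, 2, Nc)
  Yc <- sweep(Y, 2, Mc)
  H <- crossprod(Xc * w, Yc)
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], .Machine$double.eps))
    degeneracy_error(
      "rank-deficient cross-covariance (collinear correspondences)")
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tf <- rigid_transform(R, Mc - as.vector(R %*% Nc))
  resid <- sum(w * rowSums((Y - apply_transform(tf, X))^2))
  attr(tf, "residual") <- resid
  attr(tf, "singular_values") <- sv$d
  tf
}

# Build the 6x6 linearized point-to-plane normal system about the weighted
# source centroid. Returns the system and centroid.
p2plane_system <- function(corrs) {
  w <- corrs$weight
  ctr <- colSums(corrs$src * w) / sum(w)
  X <- sweep(corrs$src, 2, ctr)
  n <- corrs$normal
  # residual model: n . (x + omega x x + t - (M - ctr))
  A <- cbind(X[, 2] * n[, 3] - X[, 3] * n[, 2],
             X[, 3] * n[, 1] - X[, 1] * n[, 3],
             X[, 1] * n[, 2] - X[, 2] * n[, 1],
             n)
  b <- rowSums((corrs$tgt - corrs$src) * n)
  ATA <- crossprod(A * w, A)
  ATb <- as.vector(crossprod(A * w, b))
  list(ATA = ATA, ATb = ATb, centroid = ctr)
}

#' Point-to-plane degeneracy diagnostics
#'
#' Eigen-spectrum of the 6 x 6 point-to-plane normal system. Surfaces that
#' leave a rigid motion unconstrained (perfectly flat patches, surfaces of
#' revolution) show a near-zero eigenvalue; the verdict flags a condition
#' ratio (smallest/largest eigenvalue) below `cond_tol` and names the
#' unconstrained direction.
#'
#' @param corrs a `correspondences` object with normals and weights.
#' @param cond_tol condition-ratio threshold (default 1e-6).
#' @return list with `eigenvalues`, `condition_ratio`, `verdict` (`"ok"` or
#'   `"degenerate"`) and `direction` (description of the weakest mode).
#' @export
diagnose_degeneracy <- function(corrs, cond_tol = 1e-6) {
  sys <- p2plane_system(corrs)
  ev <- eigen(sys$ATA, symmetric = TRUE)
  vals <- ev$values
  ratio <- max(0, vals[6]) / max(vals[1], .Machine$double.eps)
  vec <- ev$vectors[, 6]
  rot <- sqrt(sum(vec[1:3]^2))
  direction <- if (rot >= sqrt(sum(vec[4:6]^2))) {
    ax <- vec[1:3] / max(rot, .Machine$double.eps)
    sprintf("rotation about axis (%.2f, %.2f, %.2f)", ax[1], ax[2], ax[3])
  } else {
    tv <- vec[4:6] / sqrt(sum(vec[4:6]^2))
    sprintf("translation along (%.2f, %.2f, %.2f)", tv[1], tv[2], tv[3])
  }
  list(eigenvalues = vals, condition_ratio = ratio,
       verdict = if (ratio < cond_tol) "degenerate" else "ok",
       direction = direction)
}

#' Weighted point-to-plane rigid solve
#'
#' Minimizes the weighted squared residuals projected on the target
#' normals, `sum_i w_i [(R N_i + t - M_i) . n_i]^2`, by small-angle
#' linearization: the 6 x 6 normal equations are solved for a rotation
#' vector and translation about the weighted source centroid, and the
#' rotation is re-exponentiated (Rodrigues) to an exact rotation matrix.
#' Raises a degeneracy error when the system leaves a rigid motion
#' unconstrained (see [diagnose_degeneracy()]).
#'
#' @param corrs a `correspondences` object (needs >= 6 pairs with normals).
#' @param cond_tol condition-ratio threshold for the degeneracy verdict.
#' @return a [rigid_transform()] with attributes `eigenvalues` (of the
#'   normal system) and `residual` (plane-projected objective at the
#'   solution).
#' @export
solve_point_to_plane <- function(corrs, cond_tol = 1e-6) {
  if (length(corrs$dist) < 6L)
    degeneracy_error("need at least 6 correspondences for point-to-plane")
  if (sum(corrs$weight) <= 0)
    degeneracy_error("total correspondence weight is zero")
  diag_ <- diagnose_degeneracy(corrs, cond_tol)
  if (diag_$verdict == "degenerate")
    degeneracy_error(sprintf(
      "degenerate point-to-plane system (condition ratio %.2e): unconstrained %s",
      diag_$condition_ratio, diag_$direction))
  sys <- p2plane_system(corrs)
  x <- solve(sys$ATA, sys$ATb)
  omega <- x[1:3]
  ang <- sqrt(sum(omega^2))
  R <- if (ang > 0) axis_angle_rotation(omega / ang, ang) else diag(3)
  ctr <- sys$centroid
  tf <- rigid_transform(R, ctr - as.vector(R %*% ctr) + x[4:6])
  moved <- apply_transform(tf, corrs$src)
  resid <- sum(corrs$weight *
                 rowSums((moved - corrs$tgt) * corrs$normal)^2)
  attr(tf, "residual") <- resid
  attr(tf, "eigenvalues") <- diag_$eigenvalues
  tf
}

#' Constrained iterative closest point alignment
#'
#' Fits the rigid transform seating a fragment (source) onto the base bone
#' (target) by iterating: distance-limited nearest-surface matching,
#' boundary-pair exclusion, trust weighting, and a weighted rigid solve
#' (point-to-point or point-to-plane). The target never moves. Iteration
#' stops when the relative change of the weighted squared-distance residual
#' falls below `rel_tol` or after `max_iter` iterations.
#'
#' @param source a [trimesh()] or an n x 3 point matrix (the fragment or
#'   one of its fracture patches).
#' @param target a [trimesh()] (the base bone).
#' @param d capture range in mm; defaults to 10 x the median target edge
#'   length.
#' @param variant `"p2plane"` (default, allows tangential sliding) or
#'   `"p2p"`.
#' @param max_iter maximum iterations (default 100).
#' @param rel_tol relative residual-change convergence tolerance (default
#'   1e-6).
#' @param weighting `"binary"` (operator certainty, default: all 1) or
#'   `"scalar"` (normal-dot-view trust).
#' @param view_direction viewing direction for `"scalar"` weighting;
#'   defaults to the mean source normal when the source is a mesh.
#' @param exclude correspondence indices zeroed in `"binary"` mode.
#' @param init initial [rigid_transform()] guess.
#' @param source_points optional explicit n x 3 matrix of source sample
#'   points overriding the source vertices (e.g. a fracture patch subset).
#'
#' @return an object of class `icp_fit`; see [coef.icp_fit()],
#'   [summary.icp_fit()], [plot.icp_fit()], [predict.icp_fit()].
#' @seealso [hierarchical_icp()] for the coarse-to-fine variant.
#' @export
icp <- function(source, target, d = NULL,
                variant = c("p2plane", "p2p"),
                max_iter = 100L, rel_tol = 1e-6,
                weighting = c("binary", "scalar"),
                view_direction = NULL, exclude = NULL,
                init = rigid_transform(), source_points = NULL) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  if (is.null(d)) d <- 10 * median_edge_length(target)
  src_pts <- if (!is.null(source_points)) source_points
  else if (inherits(source, "trimesh")) source$vertices
  else as.matrix(source)
  if (weighting == "scalar" && is.null(view_direction)) {
    if (!inherits(source, "trimesh"))
      stop("scalar weighting on raw points needs an explicit view_direction")
    vn <- compute_vertex_normals(source)
    view_direction <- colMeans(vn)
  }
  precomp <- list(boundary = detect_boundary(target),
                  vnormals = compute_vertex_normals(target))
  tf <- init
  eps_trace <- numeric(0)
  ncorr_trace <- integer(0)
  converged <- FALSE
  corrs <- NULL
  for (it in seq_len(max_iter)) {
    step <- tryCatch({
      cur <- apply_transform(tf, src_pts)
      corrs <- find_correspondences(cur, target, d, precomp)
      corrs <- filter_boundary_pairs(corrs)
      corrs <- apply_trust_weights(corrs, mode = weighting,
                                   view_direction = view_direction,
                                   exclude = exclude)
      if (variant == "p2p") solve_point_to_point(corrs)
      else solve_point_to_plane(corrs)
    }, error = function(e) {
      stop(sprintf("ICP iteration %d: %s", it, conditionMessage(e)),
           call. = FALSE)
    })
    tf <- compose_transforms(step, tf)
    moved <- apply_transform(step, corrs$src)
    eps <- sum(corrs$weight * rowSums((corrs$tgt - moved)^2))
    eps_trace <- c(eps_trace, eps)
    ncorr_trace <- c(ncorr_trace, length(corrs$dist))
    if (eps <= 1e-14 * length(corrs$dist) ||
        (it > 1L && abs(eps_trace[it - 1L] - eps) <=
           rel_tol * max(eps_trace[it - 1L], .Machine$double.eps))) {
      converged <- TRUE
      break
    }
  }
  diagnostics <- diagnose_degeneracy(corrs)
  structure(list(transform = tf, residuals = eps_trace,
                 iterations = length(eps_trace), converged = converged,
                 diagnostics = diagnostics, n_corr = ncorr_trace,
                 final_dist = corrs$dist, variant = variant, d = d,
                 levels = NULL),
            class = "icp_fit")
}

# Median edge length (mm) -- the scale-free basis of the default capture
# range.
median_edge_length <- function(mesh) {
  e <- edge_census(mesh)$edges
  stats::median(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                              mesh$vertices[e[, 2], , drop = FALSE])^2)))
}

#' Hierarchical (coarse-to-fine) ICP
#'
#' Runs [icp()] over a coarse-to-fine hierarchy: alignment starts with a
#' decimated source and a wide capture range, and each finer level
#' warm-starts from the previous transform while the matching threshold
#' `d` halves, ending at `d_finest` with the full-resolution source. This
#' widens the basin of convergence for large initial displacements. The
#' target is matched at full resolution throughout: decimating an open
#' target patch would turn most of it into boundary, and the
#' boundary-exclusion constraint would then starve the solver.
#'
#' @param source,target [trimesh()] objects.
#' @param levels number of hierarchy levels (1 reduces to plain [icp()]).
#' @param d_finest matching threshold at the finest level (mm).
#' @param ... further arguments passed to [icp()].
#' @return an `icp_fit` whose `levels` element records per-level vertex
#'   counts, thresholds and iterations.
#' @export
hierarchical_icp <- function(source, target, levels = 3L, d_finest = NULL,
                             ...) {
  stopifnot(levels >= 1L)
  if (is.null(d_finest)) d_finest <- 2 * median_edge_length(target)
  if (levels == 1L)
    return(icp(source, target, d = d_finest, ...))
  nv <- nrow(source$vertices)
  d_levels <- d_finest * 2^(rev(seq_len(levels)) - 1L) # coarsest first
  # quarter the source per level, but never below a floor that would
  # starve the solver after boundary-pair exclusion
  floor_nv <- 64L
  targets <- pmax(floor_nv, round(nv / 4^(rev(seq_len(levels)) - 1L)))
  targets <- pmin(targets, nv)
  meshes <- vector("list", levels)
  meshes[[levels]] <- source
  if (levels > 1L)
    for (k in rev(seq_len(levels - 1L)))
      meshes[[k]] <- if (targets[k] >= nrow(meshes[[k + 1L]]$vertices))
        meshes[[k + 1L]] else decimate_mesh(meshes[[k + 1L]], targets[k])
  tf <- rigid_transform()
  level_info <- list()
  fit <- NULL
  for (k in seq_len(levels)) {
    fit <- tryCatch(
      icp(meshes[[k]], target, d = d_levels[k], init = tf, ...),
      error = function(e)
        stop(sprintf("hierarchy level %d (d = %g mm): %s", k, d_levels[k],
                     conditionMessage(e)), call. = FALSE))
    tf <- fit$transform
    level_info[[k]] <- list(level = k, d = d_levels[k],
                            source_vertices = nrow(meshes[[k]]$vertices),
                            target_vertices = nrow(target$vertices),
                            iterations = fit$iterations,
                            residual = utils::tail(fit$residuals, 1L))
  }
  fit$levels <- level_info
  fit
}

#' @export
print.icp_fit <- function(x, ...) {
  ang <- rotation_angle(x$transform$rotation) * 180 / pi
  cat(sprintf("<icp_fit> %s, %d iteration(s)%s, %s\n",
              x$variant, x$iterations,
              if (!is.null(x$levels))
                sprintf(" over %d level(s)", length(x$levels)) else "",
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  rotation %.4f deg, translation %.4f mm, final residual %.4g mm^2\n",
              ang, sqrt(sum(x$transform$translation^2)),
              utils::tail(x$residuals, 1L)))
  cat(sprintf("  degeneracy: %s (condition ratio %.2e)\n",
              x$diagnostics$verdict, x$diagnostics$condition_ratio))
  invisible(x)
}

#' Methods for `icp_fit` objects
#'
#' `coef()` returns the fitted transform as a 4 x 4 homogeneous matrix;
#' `predict()` applies it to new points or meshes; `residuals()` returns
#' the final per-correspondence distances (mm); `summary()` condenses the
#' fit; `plot()` draws the residual trace per iteration.
#'
#' @param object,x an `icp_fit`.
#' @param newdata points or [trimesh()] for `predict`.
#' @param ... unused.
#' @name icp_fit-methods
NULL

#' @rdname icp_fit-methods
#' @export
coef.icp_fit <- function(object, ...) as.matrix(object$transform)

#' @rdname icp_fit-methods
#' @export
predict.icp_fit <- function(object, newdata, ...)
  apply_transform(object$transform, newdata)

#' @rdname icp_fit-methods
#' @export
residuals.icp_fit <- function(object, ...) object$final_dist

#' @rdname icp_fit-methods
#' @export
summary.icp_fit <- function(object, ...) {
  out <- list(variant = object$variant,
              iterations = object$iterations,
              converged = object$converged,
              rotation_deg = rotation_angle(object$transform$rotation) *
                180 / pi,
              translation_mm = sqrt(sum(object$transform$translation^2)),
              final_residual = utils::tail(object$residuals, 1L),
              mean_distance = mean(object$final_dist),
              n_correspondences = utils::tail(object$n_corr, 1L),
              degeneracy = object$diagnostics$verdict,
              condition_ratio = object$diagnostics$condition_ratio,
              levels = object$levels)
  class(out) <- "summary.icp_fit"
  out
}

#' @export
print.summary.icp_fit <- function(x, ...) {
  cat(sprintf("ICP alignment (%s)\n", x$variant))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  pose: rotation %.4f deg, translation %.4f mm\n",
              x$rotation_deg, x$translation_mm))
  cat(sprintf("  residual: %.4g mm^2 over %d pairs (mean distance %.4g mm)\n",
              x$final_residual, x$n_correspondences, x$mean_distance))
  cat(sprintf("  degeneracy verdict: %s (condition ratio %.2e)\n",
              x$degeneracy, x$condition_ratio))
  if (!is.null(x$levels))
    for (li in x$levels)
      cat(sprintf("  level %d: d = %g mm, %d + %d vertices, %d iteration(s)\n",
                  li$level, li$d, li$source_vertices, li$target_vertices,
                  li$iterations))
  invisible(x)
}

#' @rdname icp_fit-methods
#' @export
plot.icp_fit <- function(x, ...) {
  graphics::plot(seq_along(x$residuals), x$residuals, type = "b",
                 log = if (all(x$residuals > 0)) "y" else "",
                 xlab = "iteration", ylab = "weighted residual [mm²]",
                 main = sprintf("ICP residual trace (%s)", x$variant), ...)
  invisible(x)
}

# Concatenate meshes into one (no welding); used to align against the
# union of already-placed geometry.
merge_mesh_soup <- function(meshes) {
  offs <- 0L
  Vs <- list()
  Fs <- list()
  for (m in meshes) {
    Vs[[length(Vs) + 1L]] <- m$vertices
    Fs[[length(Fs) + 1L]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  trimesh(do.call(rbind, Vs), do.call(rbind, Fs), validate = FALSE)
}

#' Multi-fragment assembly
#'
#' Aligns several fragments to a base bone over an operator-confirmed
#' pairing graph: fragments are processed breadth-first from the base, each
#' aligned (by [hierarchical_icp()] or [icp()]) against the already-placed
#' geometry. When patch labelings are supplied, matching is
#' patch-to-patch: the fragment's paired fracture-patch vertices are
#' aligned to the union of the corresponding placed fracture-patch
#' submeshes (aligning whole closed fragments instead creates false pairs
#' across the cut rims). Pairs that close a cycle are not re-solved; they
#' are reported as residual checks.
#'
#' @param fragments named list of [trimesh()] fragments.
#' @param base the base-bone [trimesh()].
#' @param pairs data.frame with columns `fragment`, `frag_patch`, `target`
#'   (a fragment name or `"base"`), `target_patch`. Patch columns may be
#'   `NA` when no labeling is supplied.
#' @param labelings optional named list of [extract_patches()] labelings,
#'   keyed by fragment name plus `"base"`.
#' @param levels,d_finest hierarchy controls (see [hierarchical_icp()]);
#'   `levels = 1` uses plain [icp()].
#' @param ... further arguments passed to [icp()].
#' @return list with `transforms` (named list of [rigid_transform()]),
#'   `fits` (named list of `icp_fit`), `order` (alignment order) and
#'   `pair_residuals` (data.frame: per-pair mean patch distance after
#'   placement, with `solved` marking tree edges vs. cycle checks).
#' @export
assemble_fragments <- function(fragments, base, pairs, labelings = NULL,
                               levels = 1L, d_finest = NULL, ...) {
  stopifnot(is.list(fragments), length(names(fragments)) == length(fragments))
  if (is.null(pairs$target)) pairs$target <- "base"
  nodes <- c("base", names(fragments))
  bad <- setdiff(unique(c(pairs$fragment, pairs$target)), nodes)
  if (length(bad))
    stop(sprintf("pairs reference unknown fragment(s): %s",
                 paste(bad, collapse = ", ")))
  # breadth-first order from the base over the pairing graph
  placed <- "base"
  order_ <- character(0)
  tree_edges <- integer(0)
  repeat {
    frontier <- which(!(pairs$fragment %in% placed) &
                        (pairs$target %in% placed))
    rev_frontier <- which((pairs$fragment %in% placed) &
                            !(pairs$target %in% placed))
    if (!length(frontier) && !length(rev_frontier)) break
    nxt <- unique(c(pairs$fragment[frontier], pairs$target[rev_frontier]))
    for (fr in nxt) {
      order_ <- c(order_, fr)
      placed <- c(placed, fr)
    }
    tree_edges <- union(tree_edges, c(frontier, rev_frontier))
  }
  unreachable <- setdiff(names(fragments), placed)
  if (length(unreachable))
    stop(sprintf("fragment(s) not connected to the base: %s",
                 paste(unreachable, collapse = ", ")))
  placed_meshes <- list(base = base)
  all_meshes <- c(list(base = base), fragments)
  # patch submesh of a node (NULL when no labeling/patch available)
  node_patch <- function(node, patch_id, mesh = NULL) {
    if (is.null(labelings) || !(node %in% names(labelings)) ||
        is.na(patch_id)) return(NULL)
    m <- if (is.null(mesh)) all_meshes[[node]] else mesh
    patch_submesh(m, labelings[[node]], patch_id)
  }
  transforms <- list()
  fits <- list()
  for (fr in order_) {
    mesh <- fragments[[fr]]
    rows <- which((pairs$fragment == fr &
                     pairs$target %in% names(placed_meshes)) |
                    (pairs$target == fr &
                       pairs$fragment %in% names(placed_meshes)))
    # source sample points: vertices of the fragment patches involved
    src_pts <- NULL
    if (!is.null(labelings) && fr %in% names(labelings)) {
      pids <- unique(c(pairs$frag_patch[rows][pairs$fragment[rows] == fr],
                       pairs$target_patch[rows][pairs$target[rows] == fr]))
      pids <- pids[!is.na(pids)]
      if (length(pids)) {
        vs <- unique(unlist(labelings[[fr]]$patches$members[pids]))
        src_pts <- mesh$vertices[vs, , drop = FALSE]
      }
    }
    # target: union of the placed patch submeshes this fragment pairs to
    # (whole placed meshes when no labeling is available)
    tgt_parts <- list()
    for (k in rows) {
      other <- if (pairs$fragment[k] == fr) pairs$target[k]
      else pairs$fragment[k]
      opatch <- if (pairs$fragment[k] == fr) pairs$target_patch[k]
      else pairs$frag_patch[k]
      sub <- node_patch(other, opatch, placed_meshes[[other]])
      tgt_parts[[length(tgt_parts) + 1L]] <-
        if (is.null(sub)) placed_meshes[[other]] else sub
    }
    target <- merge_mesh_soup(tgt_parts)
    src <- if (is.null(src_pts)) mesh else src_pts
    fit <- if (levels > 1L && is.null(src_pts))
      hierarchical_icp(mesh, target, levels = levels, d_finest = d_finest,
                       ...)
    else icp(src, target, d = d_finest, ...)
    transforms[[fr]] <- fit$transform
    fits[[fr]] <- fit
    placed_meshes[[fr]] <- apply_transform(fit$transform, mesh)
  }
  # per-pair residuals on the final placement (patch-to-patch when known)
  resid <- data.frame(fragment = pairs$fragment, target = pairs$target,
                      mean_distance = NA_real_,
                      solved = seq_len(nrow(pairs)) %in% tree_edges)
  for (k in seq_len(nrow(pairs))) {
    a <- node_patch(pairs$fragment[k], pairs$frag_patch[k],
                    placed_meshes[[pairs$fragment[k]]])
    if (is.null(a)) a <- placed_meshes[[pairs$fragment[k]]]
    b <- node_patch(pairs$target[k], pairs$target_patch[k],
                    placed_meshes[[pairs$target[k]]])
    if (is.null(b)) b <- placed_meshes[[pairs$target[k]]]
    dd <- max(1, 10 * median_edge_length(b))
    q <- closest_points_cpp(a$vertices, b$vertices, b$faces, dd)
    resid$mean_distance[k] <- mean(q$dist[q$found])
  }
  list(transforms = transforms, fits = fits, order = order_,
       pair_residuals = resid)
}
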