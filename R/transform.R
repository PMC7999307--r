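#' Rigid transform (rotation + translation)
#'
#' The 6-degree-of-freedom solution of each alignment step: a proper
#' rotation matrix `R` and a translation `t` in mm, mapping a point `p` to
#' `R p + t`.
#'
#' @param rotation 3 x 3 proper rotation matrix (`R'R = I`, `det R = +1`,
#'   both within 1e-9).
#' @param translation numeric length-3 translation (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthogonal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 within 1e-9 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation %.3f mm\n",
              ang * 180 / pi, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @param ... unused.
#' @return `as.matrix()`: the 4 x 4 homogeneous matrix.
#' @export
as.matrix.rigid_transform <- function(x, ...) {
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.vector(rt %*% tf$translation))
}

#' Apply a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @param x an n x 3 point matrix, a length-3 point, or a [trimesh()]
#'   (intensities ride along unchanged).
#' @return the transformed object, same shape as the input.
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "trimesh")) {
    out <- x
    out$vertices <- apply_transform(tf, x$vertices)
    return(out)
  }
  single <- is.null(dim(x))
  P <- if (single) matrix(as.numeric(x), 1L, 3L) else as.matrix(x)
  out <- P %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (single) as.vector(out) else out
}

# Rotation angle (radians) of a rotation matrix.
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# Rodrigues rotation about `axis` (unit) by `angle` radians.
axis_angle_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniformly random rotation axis + bounded angle (uses the current RNG).
random_rotation <- function(max_angle_rad) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  axis_angle_rotation(ax, stats::runif(1, 0, max_angle_rad))
}

# Evaluate .Random.seed-safe seeded code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
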