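make_corrs <- function(src, tgt, normal = NULL, w = NULL) {
  n <- nrow(src)
  structure(list(src = src, tgt = tgt,
                 dist = sqrt(rowSums((src - tgt)^2)),
                 normal = if (is.null(normal))
                   matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
                 else normal,
                 on_boundary = rep(FALSE, n),
                 weight = if (is.null(w)) rep(1, n) else w),
            class = "correspondences")
}

test_that("correspondence search respects identity, range and boundaries", {
  ico <- icosahedron_mesh()
  corrs <- find_correspondences(ico$vertices, ico, d = 1)
  expect_equal(corrs$dist, rep(0, 12))
  expect_false(any(corrs$on_boundary))
  expect_identical(filter_boundary_pairs(corrs)$dist, corrs$dist)

  g <- grid_mesh(0, 10, 0, 10, 5, 5)
  pts <- sweep(g$vertices, 2, c(0, 0, 2), "+")
  expect_error(find_correspondences(pts, g, d = 1), "capture range")

  # nearest points on a finite plane's rim are boundary-flagged and
  # excluding them can empty the set
  hover <- cbind(12, seq(1, 9, by = 2), 0.5)
  corrs <- find_correspondences(hover, g, d = 5)
  expect_true(all(corrs$on_boundary))
  expect_error(filter_boundary_pairs(corrs), "boundary")

  # mixed case agrees with a per-point boundary census
  mixed <- rbind(cbind(seq(2, 8, by = 2), 5, 1), cbind(12, c(3, 7), 1))
  corrs <- find_correspondences(mixed, g, d = 5)
  surv <- filter_boundary_pairs(corrs)
  bnd <- detect_boundary(g)
  oracle_keep <- vapply(seq_len(nrow(mixed)), function(i) {
    o <- oracle_closest(mixed[i, ], g)
    # boundary iff nearest point sits within 1e-9 of a boundary edge
    be <- bnd$edges
    mind <- min(vapply(seq_len(nrow(be)), function(k) {
      a <- g$vertices[be[k, 1], ]
      b <- g$vertices[be[k, 2], ]
      ab <- b - a
      t <- min(1, max(0, sum((o$point - a) * ab) / sum(ab^2)))
      sqrt(sum((o$point - (a + t * ab))^2))
    }, numeric(1)))
    mind > 1e-9
  }, logical(1))
  expect_equal(length(surv$dist), sum(oracle_keep))
})

test_that("trust weights follow the clamped scalar product", {
  expect_equal(trust_weight(c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(trust_weight(c(1, 0, 0), c(0, 0, 1)), 0)
  ang60 <- c(sin(pi / 3), 0, cos(pi / 3))
  expect_equal(trust_weight(ang60, c(0, 0, 1)), 0.5, tolerance = 1e-12)
  expect_warning(w <- trust_weight(c(0, 0, 0), c(0, 0, 1)), "zero normal")
  expect_equal(w, 0)
  # binary mode: excluded pairs get weight zero
  corrs <- make_corrs(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  corrs <- apply_trust_weights(corrs, "binary", exclude = c(2, 4))
  expect_equal(corrs$weight, c(1, 0, 1, 0, 1))
})

test_that("point-to-point solve is exact on noiseless correspondences", {
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  R <- bonereduce:::axis_angle_rotation(c(1, 2, 3), 0.35)
  tt <- c(0.5, -1, 2)
  Y <- X %*% t(R) + matrix(tt, 10, 3, byrow = TRUE)
  tf <- solve_point_to_point(make_corrs(X, Y))
  expect_lt(attr(tf, "residual"), 1e-12)
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$translation, tt, tolerance = 1e-9)

  # identity in, identity out
  tf0 <- solve_point_to_point(make_corrs(X, X))
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-12)
  expect_lt(attr(tf0, "residual"), 1e-20)

  # a zero-weight pair has provably zero influence
  Xz <- rbind(X, c(100, -50, 80))
  Yz <- rbind(Y, c(-30, 60, 10))
  tfz <- solve_point_to_point(make_corrs(Xz, Yz, w = c(rep(1, 10), 0)))
  expect_equal(tfz$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(tfz$translation, tf$translation, tolerance = 1e-12)

  # collinear correspondences are a detected degeneracy
  L <- cbind(1:10, 0, 0)
  expect_error(solve_point_to_point(make_corrs(L, L + 1)), "collinear",
               class = "bonereduce_degeneracy")
})

test_that("weighted solve attains the global minimum found by search", {
  # independent oracle: direct nonlinear minimization of the weighted
  # objective over axis-angle + translation from several starts
  objective <- function(par, X, Y, w) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang > 0)
      bonereduce:::axis_angle_rotation(par[1:3] / ang, ang) else diag(3)
    sum(w * rowSums((Y - X %*% t(R) -
                       matrix(par[4:6], nrow(X), 3, byrow = TRUE))^2))
  }
  set.seed(31)
  for (k in 1:4) {
    X <- matrix(rnorm(15), 5, 3)
    Y <- matrix(rnorm(15), 5, 3)
    w <- runif(5, 0.2, 1)
    tf <- solve_point_to_point(make_corrs(X, Y, w = w))
    best <- Inf
    for (s in 1:8) {
      par0 <- c(rnorm(3, 0, 0.8), rnorm(3, 0, 1))
      o <- optim(par0, objective, X = X, Y = Y, w = w, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_lte(attr(tf, "residual"), best + 1e-6)
  }
})

test_that("point-to-plane solve recovers small transforms and flags flats", {
  # zero residuals in, identity out
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  n <- matrix(rnorm(60), 20, 3)
  n <- n / sqrt(rowSums(n^2))
  tf <- solve_point_to_plane(make_corrs(X, X, normal = n))
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-9)

  # small known transform of a curved (ellipsoidal, fully constraining)
  # patch: near-exact after one solve
  th <- runif(30, 0.2, pi / 2)
  ph_ <- runif(30, 0.2, pi / 2)
  ax <- c(10, 7, 4)
  P <- cbind(ax[1] * sin(th) * cos(ph_), ax[2] * sin(th) * sin(ph_),
             ax[3] * cos(th))
  nrm <- cbind(P[, 1] / ax[1]^2, P[, 2] / ax[2]^2, P[, 3] / ax[3]^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  R <- bonereduce:::axis_angle_rotation(c(0, 1, 1), 2 * pi / 180)
  tt <- c(0.3, -0.2, 0.4)
  Q <- P %*% t(R) + matrix(tt, 30, 3, byrow = TRUE)
  nq <- nrm %*% t(R)
  one <- solve_point_to_plane(make_corrs(P, Q, normal = nq))
  expect_lt(max(abs(one$rotation - R)), 1e-3)
  # iterate the linearized solve to exactness
  tf_acc <- rigid_transform()
  cur <- P
  for (it in 1:12) {
    step <- solve_point_to_plane(make_corrs(cur, Q, normal = nq))
    tf_acc <- compose_transforms(step, tf_acc)
    cur <- apply_transform(tf_acc, P)
  }
  expect_lt(max(abs(tf_acc$rotation - R)), 1e-9)
  expect_lt(max(abs(tf_acc$translation - tt)), 1e-8)

  # flat patch with in-plane displacement: unconstrained translation
  G <- as.matrix(expand.grid(x = 0:4, y = 0:4))
  G <- cbind(G, 0)
  nz <- matrix(rep(c(0, 0, 1), 25), 25, 3, byrow = TRUE)
  shifted <- G + matrix(c(1, 0.5, 0), 25, 3, byrow = TRUE)
  expect_error(solve_point_to_plane(make_corrs(G, shifted, normal = nz)),
               "degenerate", class = "bonereduce_degeneracy")
})

test_that("degeneracy verdict fires on flats and revolutions, not patches", {
  G <- cbind(as.matrix(expand.grid(x = 0:5, y = 0:5)), 0)
  nz <- matrix(rep(c(0, 0, 1), 36), 36, 3, byrow = TRUE)
  flat <- diagnose_degeneracy(make_corrs(G, G, normal = nz))
  expect_identical(flat$verdict, "degenerate")

  th <- seq(0, 2 * pi, length.out = 41)[-41]
  cyl <- NULL
  ncyl <- NULL
  for (z in seq(0, 10, length.out = 6)) {
    cyl <- rbind(cyl, cbind(8 * cos(th), 8 * sin(th), z))
    ncyl <- rbind(ncyl, cbind(cos(th), sin(th), 0))
  }
  # both rotation about the axis and translation along it are free modes
  rev_ <- diagnose_degeneracy(make_corrs(cyl, cyl, normal = ncyl))
  expect_identical(rev_$verdict, "degenerate")

  case <- make_fracture_case(phantom_params = list(resolution = 24),
                             seed = 13)
  src <- fracture_patch_mesh(case$fragments[[2]])
  tgt <- fracture_patch_mesh(case$fragments[[1]])
  corrs <- find_correspondences(src$vertices, tgt, d = 10)
  patch <- diagnose_degeneracy(corrs)
  expect_identical(patch$verdict, "ok")
})

test_that("ICP converges immediately on aligned surfaces", {
  case <- make_fracture_case(phantom_params = list(resolution = 24),
                             max_rot_deg = 0, max_trans_mm = 0, seed = 2)
  src <- fracture_patch_mesh(case$fragments[[2]])
  tgt <- fracture_patch_mesh(case$fragments[[1]])
  fit <- icp(src, tgt, d = 2)
  expect_true(fit$converged)
  expect_identical(fit$iterations, 1L)
  expect_lt(tail(fit$residuals, 1), 1e-10)
})

test_that("ICP recovers a displaced fragment pose from its fracture patch", {
  prob <- make_alignment_problem(seed = 4)
  fit <- icp(prob$src, prob$tgt, d = 4, variant = "p2plane")
  rms <- pose_rms(fit, prob$case$fragments[[2]]$mesh,
                  prob$case$reference[[2]]$mesh)
  expect_lt(rms, 0.01)
  expect_true(fit$converged)
  # residual never increases from first to last iteration
  expect_lte(tail(fit$residuals, 1), fit$residuals[1])
  # methods on the fit object
  expect_equal(dim(coef(fit)), c(4, 4))
  expect_length(residuals(fit), tail(fit$n_corr, 1))
  s <- summary(fit)
  expect_s3_class(s, "summary.icp_fit")
  expect_identical(s$degeneracy, "ok")
})

test_that("noisy alignment error scales with the noise level", {
  errs <- vapply(1:8, function(seed) {
    prob <- make_alignment_problem(seed = seed, sigma = 0.1)
    fit <- icp(prob$src, prob$tgt, d = 4, variant = "p2plane")
    # translation error against ground truth
    truth <- invert_transform(prob$case$transforms[[2]])
    delta <- compose_transforms(invert_transform(truth), fit$transform)
    sqrt(sum(delta$translation^2))
  }, numeric(1))
  n <- 150 # typical patch point count
  expect_lt(median(errs), 3 * 0.1 / sqrt(n) * 10) # order-of-magnitude bound
  expect_lt(median(errs), 0.3)
})

test_that("tangential sliding favors point-to-plane over point-to-point", {
  wavy <- function(x0, x1, nx, y0, y1, ny, amp = 0.4) {
    xs <- seq(x0, x1, length.out = nx + 1)
    ys <- seq(y0, y1, length.out = ny + 1)
    V <- as.matrix(expand.grid(x = xs, y = ys))
    V <- cbind(V, amp * sin(V[, 1] * 0.8) * cos(V[, 2] * 0.6))
    id <- function(i, j) (j - 1) * (nx + 1) + i
    Fm <- matrix(0L, 0, 3)
    for (j in seq_len(ny)) for (i in seq_len(nx))
      Fm <- rbind(Fm, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                  c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    trimesh(V, Fm)
  }
  tgt <- wavy(0, 20, 40, 0, 10, 20)
  src <- apply_transform(rigid_transform(diag(3), c(1.2, 0.4, 0.3)),
                         wavy(4, 16, 24, 2, 8, 12))
  r5 <- vapply(c("p2p", "p2plane"), function(v)
    tail(icp(src, tgt, d = 3, variant = v, max_iter = 5,
             rel_tol = 0)$residuals, 1), numeric(1))
  expect_lt(r5[["p2plane"]], r5[["p2p"]])
})

test_that("hierarchical ICP reduces to plain ICP at one level", {
  prob <- make_alignment_problem(seed = 6)
  f1 <- hierarchical_icp(prob$src, prob$tgt, levels = 1, d_finest = 2)
  f2 <- icp(prob$src, prob$tgt, d = 2)
  expect_equal(as.matrix(f1$transform), as.matrix(f2$transform),
               tolerance = 1e-12)
})

test_that("hierarchy levels log exact threshold halvings", {
  prob <- make_alignment_problem(seed = 6)
  fit <- hierarchical_icp(prob$src, prob$tgt, levels = 3, d_finest = 1)
  ds <- vapply(fit$levels, `[[`, numeric(1), "d")
  expect_equal(ds, c(4, 2, 1))
})

test_that("coarse-to-fine succeeds on displacements that defeat one level", {
  case <- make_fracture_case(phantom_params = list(resolution = 40),
                             max_rot_deg = 15, max_trans_mm = 8, seed = 6)
  src <- fracture_patch_mesh(case$fragments[[2]])
  tgt <- fracture_patch_mesh(case$fragments[[1]])
  frag <- case$fragments[[2]]$mesh
  ref <- case$reference[[2]]$mesh
  single <- icp(src, tgt, d = 1.5, variant = "p2plane")
  hier <- hierarchical_icp(src, tgt, levels = 3, d_finest = 1.5,
                           variant = "p2plane")
  expect_gt(pose_rms(single, frag, ref), 0.5) # stuck far from the truth
  expect_lt(pose_rms(hier, frag, ref), 0.05)
})

test_that("multi-fragment assembly recovers a chain through the base", {
  ph <- make_phantom(resolution = 28)
  fs <- fracture(ph, list(sphere_cut(c(6, 3, 55), 17)))
  fs <- synth_intensities(fs, seed = 3)
  expect_length(fs$fragments, 3)
  ref <- lapply(fs$fragments, function(fr) fr$mesh)
  fs <- displace(fs, 8, 4, seed = 11)
  labs <- lapply(fs$fragments, function(fr)
    extract_patches(fr$mesh, classify_vertices(fr$mesh), min_area = 10))
  cz <- labs[[2]]$patches$centroid[, 3]
  pairs <- data.frame(fragment = c("B", "C"),
                      frag_patch = c(which.min(cz), 1L),
                      target = c("base", "B"),
                      target_patch = c(1L, which.max(cz)))
  res <- assemble_fragments(list(B = fs$fragments[[2]]$mesh,
                                 C = fs$fragments[[3]]$mesh),
                            fs$fragments[[1]]$mesh, pairs,
                            labelings = list(base = labs[[1]],
                                             B = labs[[2]], C = labs[[3]]),
                            d_finest = 3, variant = "p2plane")
  expect_identical(res$order, c("B", "C"))
  for (nm in c("B", "C")) {
    i <- if (nm == "B") 2L else 3L
    rec <- apply_transform(res$transforms[[nm]], fs$fragments[[i]]$mesh)
    expect_lt(sqrt(mean(rowSums((rec$vertices - ref[[i]]$vertices)^2))),
              0.05)
  }
  expect_true(all(res$pair_residuals$solved))
  expect_true(all(res$pair_residuals$mean_distance < 0.1))
})

test_that("assembly rejects fragments unreachable from the base", {
  ph <- make_phantom(resolution = 24)
  pairs <- data.frame(fragment = "A", frag_patch = NA, target = "base",
                      target_patch = NA)
  expect_error(
    assemble_fragments(list(A = ph, Z = ph), ph, pairs),
    "not connected.*Z")
})

test_that("cyclic pairs are reported as checks, not re-solved", {
  case <- make_fracture_case(phantom_params = list(resolution = 24),
                             max_rot_deg = 3, max_trans_mm = 1, seed = 8)
  lab2 <- extract_patches(case$fragments[[2]]$mesh,
                          classify_vertices(case$fragments[[2]]$mesh),
                          min_area = 10)
  lab1 <- extract_patches(case$fragments[[1]]$mesh,
                          classify_vertices(case$fragments[[1]]$mesh),
                          min_area = 10)
  # two fragments both pair to the base; a third pair between them closes
  # a cycle and must only be residual-checked
  frag <- case$fragments[[2]]$mesh
  pairs <- data.frame(fragment = c("A", "B", "A"),
                      frag_patch = c(1L, 1L, 1L),
                      target = c("base", "base", "B"),
                      target_patch = c(1L, 1L, 1L))
  res <- assemble_fragments(list(A = frag, B = frag),
                            case$fragments[[1]]$mesh, pairs,
                            labelings = list(base = lab1, A = lab2,
                                             B = lab2),
                            d_finest = 3)
  expect_identical(res$pair_residuals$solved, c(TRUE, TRUE, FALSE))
  # the cycle pair still gets a residual check (both copies seat onto the
  # same surface, so their patches end up close)
  expect_lt(res$pair_residuals$mean_distance[3], 0.5)
})
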