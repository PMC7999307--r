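test_that("the phantom is a closed genus-0 surface, deterministic in its
           parameters", {
  ph <- make_phantom(resolution = 20)
  expect_identical(count_boundary_edges(ph), 0L)
  expect_identical(euler_characteristic(ph), 2L)
  expect_silent(validate_trimesh(ph))
  ph2 <- make_phantom(resolution = 20)
  expect_identical(ph$vertices, ph2$vertices)
  expect_identical(ph$faces, ph2$faces)
  expect_error(make_phantom(resolution = 4), "resolution too low")
  expect_error(make_phantom(shaft_radius = -1), "positive")
})

test_that("phantom area converges under refinement", {
  a1 <- mesh_area(make_phantom(resolution = 32))
  a2 <- mesh_area(make_phantom(resolution = 64))
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("plane cuts split the phantom into closed complementary pieces", {
  ph <- make_phantom(resolution = 20)
  fs <- fracture(ph, list(plane_cut(c(0, 0, 40), c(0.1, 0, 1))),
                 roughness = 0)
  expect_length(fs$fragments, 2)
  for (fr in fs$fragments) {
    expect_identical(count_boundary_edges(fr$mesh), 0L)
    expect_identical(euler_characteristic(fr$mesh), 2L)
  }
  vols <- vapply(fs$fragments, `[[`, numeric(1), "volume")
  expect_lt(abs(sum(vols) - mesh_volume(ph)) / mesh_volume(ph), 0.005)

  fs3 <- fracture(ph, list(plane_cut(c(0, 0, 30), c(0, 0, 1)),
                           plane_cut(c(0, 0, 50), c(0, 0, 1))))
  expect_length(fs3$fragments, 3)
  n_cuts <- vapply(fs3$fragments, function(fr)
    length(unique(stats::na.omit(fr$cut_id))), integer(1))
  expect_identical(sort(n_cuts), c(1L, 1L, 2L))
  vols3 <- vapply(fs3$fragments, `[[`, numeric(1), "volume")
  expect_lt(abs(sum(vols3) - mesh_volume(ph)) / mesh_volume(ph), 0.005)
})

test_that("rough spherical cuts stay volume-complementary", {
  ph <- make_phantom(resolution = 24)
  fs <- fracture(ph, list(sphere_cut(c(6, 3, 55), 17)), roughness = 0.4)
  vols <- vapply(fs$fragments, `[[`, numeric(1), "volume")
  expect_lt(abs(sum(vols) - mesh_volume(ph)) / mesh_volume(ph), 0.005)
  for (fr in fs$fragments)
    expect_identical(count_boundary_edges(fr$mesh), 0L)
})

test_that("cuts that miss the solid are skipped with a warning", {
  ph <- make_phantom(resolution = 16)
  expect_warning(fs <- fracture(ph, list(
    plane_cut(c(0, 0, 40), c(0, 0, 1)),
    plane_cut(c(0, 0, 500), c(0, 0, 1)))), "does not intersect")
  expect_length(fs$cuts, 1)
  expect_warning(
    expect_error(fracture(ph, list(plane_cut(c(0, 0, 500), c(0, 0, 1)))),
                 "no cut intersects"))
})

test_that("displacement records exact invertible ground truth", {
  ph <- make_phantom(resolution = 16)
  fs <- fracture(ph, list(plane_cut(c(0, 0, 40), c(0, 0, 1))))
  f0 <- displace(fs, 0, 0, seed = 1)
  expect_equal(as.matrix(f0$transforms[[2]]), diag(4), tolerance = 1e-15)

  fd <- displace(fs, 10, 5, seed = 2)
  tf <- fd$transforms[[2]]
  rt <- compose_transforms(invert_transform(tf), tf)
  expect_equal(as.matrix(rt), diag(4), tolerance = 1e-12)
  # the recorded transform maps the pristine fragment onto the displaced one
  expect_equal(apply_transform(tf, fs$fragments[[2]]$mesh$vertices),
               fd$fragments[[2]]$mesh$vertices, tolerance = 1e-12)
  fd2 <- displace(fs, 10, 5, seed = 2)
  expect_identical(fd$fragments[[2]]$mesh$vertices,
                   fd2$fragments[[2]]$mesh$vertices)
})

test_that("surface noise has the half-normal displacement magnitude", {
  ph <- make_phantom(resolution = 64, length = 160) # ~10k vertices
  expect_identical(add_noise(ph, 0, seed = 1)$vertices, ph$vertices)
  noisy <- add_noise(ph, 0.1, seed = 3)
  disp <- sqrt(rowSums((noisy$vertices - ph$vertices)^2))
  expect_equal(mean(disp), 0.1 * sqrt(2 / pi), tolerance = 0.03)
  noisy2 <- add_noise(ph, 0.1, seed = 3)
  expect_identical(noisy$vertices, noisy2$vertices)
})

test_that("synthetic intensities separate cortical from cancellous", {
  ph <- make_phantom(resolution = 20)
  fs <- fracture(ph, list(sphere_cut(c(6, 3, 55), 17)))
  fs <- synth_intensities(fs, seed = 4)
  for (fr in fs$fragments) {
    hu <- fr$mesh$intensity
    expect_true(all(hu[!fr$fracture_mask] >= 700))
    expect_true(all(hu[!fr$fracture_mask] <= 2500))
    k <- sum(fr$fracture_mask)
    expect_lt(abs(mean(hu[fr$fracture_mask]) - 350), 3 * 100 / sqrt(k) + 1)
  }
  fs2 <- synth_intensities(fs, seed = 4)
  expect_identical(fs$fragments[[1]]$mesh$intensity,
                   fs2$fragments[[1]]$mesh$intensity)
})

test_that("full loop: classify, pair, align recovers the displacement and
           degrades gracefully with noise", {
  rms_at <- function(sigma, seeds) {
    vapply(seeds, function(seed) {
      case <- make_fracture_case(
        phantom_params = list(resolution = 24),
        max_rot_deg = 5, max_trans_mm = 2, sigma = sigma, seed = seed)
      lab2 <- extract_patches(case$fragments[[2]]$mesh,
                              classify_vertices(case$fragments[[2]]$mesh),
                              min_area = 10)
      lab1 <- extract_patches(case$fragments[[1]]$mesh,
                              classify_vertices(case$fragments[[1]]$mesh),
                              min_area = 10)
      src <- patch_submesh(case$fragments[[2]]$mesh, lab2, 1)
      tgt <- patch_submesh(case$fragments[[1]]$mesh, lab1, 1)
      fit <- hierarchical_icp(src, tgt, levels = 2, d_finest = 2,
                              variant = "p2plane")
      pose_rms(fit, case$fragments[[2]]$mesh,
               case$reference[[2]]$mesh)
    }, numeric(1))
  }
  seeds <- 1:6
  med <- vapply(c(0, 0.05, 0.1, 0.2), function(s) median(rms_at(s, seeds)),
                numeric(1))
  expect_lt(med[1], 0.05)
  expect_true(all(diff(med) > -0.02)) # monotone up to small jitter
})

test_that("zippering a seated fragment back onto the base restores the
           phantom surface", {
  ph <- make_phantom(resolution = 24)
  fs <- fracture(ph, list(sphere_cut(c(6, 3, 55), 17)))
  # open outer shells: drop the fracture caps, keep the original surface
  shell <- function(fr) {
    keep <- !(fr$fracture_mask[fr$mesh$faces[, 1]] &
                fr$fracture_mask[fr$mesh$faces[, 2]] &
                fr$fracture_mask[fr$mesh$faces[, 3]])
    bonereduce:::compact_mesh(
      bonereduce:::submesh_faces(fr$mesh, which(keep)))
  }
  merged <- zipper(shell(fs$fragments[[1]]), shell(fs$fragments[[2]]),
                   d = 1)
  merged <- zipper(merged$mesh, shell(fs$fragments[[3]]), d = 1)
  m <- merged$mesh
  expect_identical(count_boundary_edges(m), 0L)
  expect_lt(abs(mesh_area(m) - mesh_area(ph)) / mesh_area(ph), 0.02)
})
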