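test_that("homogeneous paths reproduce the Beer-Lambert closed form", {
  # absorbance k*L, attenuation 10^(-k*L), for k in {0, 0.02, 0.1} and
  # L in {10, 100} mm (L = 0 is the trivially empty field)
  for (kv in c(0.02, 0.1)) {
    for (L in c(10, 100)) {
      f <- slab_field(kv, if (kv == 0.1) 2L else 1L, L, n = 220)
      r <- cast_ray(f, c(1, 0, 0))
      expect_equal(if (kv == 0.1) r$absorbance_vas else r$absorbance_tra,
                   kv * L, tolerance = 1e-9)
      expect_equal(if (kv == 0.1) r$avas else r$atra, 10^(-kv * L),
                   tolerance = 1e-9)
    }
  }
  # k = 0 (and L = 0): no absorbance at all
  f0 <- slab_field(0, 1L, 50)
  r0 <- cast_ray(f0, c(1, 0, 0))
  expect_equal(r0$absorbance_tra, 0)
  expect_equal(r0$atra, 1)
})

test_that("per-class absorbances accumulate separately", {
  # 50 mm of soft tissue (k = 0.02) then 10 mm of vessel (k = 0.1):
  # Atra = 10^-1 and Avas = 10^-1
  n <- 160
  f <- slab_field(0.02, 1L, 50, n = n)
  tgt <- f$target
  wx <- (seq_len(n) - 1) * f$spacing[1]
  ves <- wx > tgt[1] + 50 & wx <= tgt[1] + 60
  f$cls[ves, , ] <- 2L
  f$k[ves, , ] <- 0.1
  r <- cast_ray(f, c(1, 0, 0))
  expect_equal(r$absorbance_tra, 1, tolerance = 1e-9)
  expect_equal(r$absorbance_vas, 1, tolerance = 1e-9)
  expect_equal(r$atra, 0.1, tolerance = 1e-9)
  expect_equal(r$avas, 0.1, tolerance = 1e-9)
})

test_that("an opaque voxel stops the march and zeroes the indicator", {
  n <- 160
  f <- slab_field(0.02, 1L, 60, n = n)
  wx <- (seq_len(n) - 1) * f$spacing[1]
  f$opaque[wx > f$target[1] + 30 & wx <= f$target[1] + 32, , ] <- TRUE
  r <- cast_ray(f, c(1, 0, 0))
  expect_equal(r$iobs, 0L)
  # attenuation reported up to the stop: ~30 mm of k = 0.02
  expect_equal(r$absorbance_tra, 0.02 * 30, tolerance = 1e-6)
})

test_that("Beer-Lambert attenuation is multiplicative over segments", {
  # attenuation of a concatenated path equals the product of segment
  # attenuations: random per-ray segmentations, float-exact
  set.seed(31)
  for (i in 1:200) {
    ks <- stats::runif(5, 0, 0.1)
    ls <- stats::runif(5, 0, 40)
    a_total <- 10^(-sum(ks * ls))
    a_prod <- prod(10^(-ks * ls))
    expect_equal(a_total, a_prod, tolerance = 1e-9)
  }
  # and the marcher's own accumulation obeys it: splitting a slab in two
  f <- slab_field(0.02, 1L, 80, n = 200)
  r <- cast_ray(f, c(1, 0, 0))
  f1 <- slab_field(0.02, 1L, 30, n = 200)
  f2 <- slab_field(0.02, 1L, 50, n = 200)
  r1 <- cast_ray(f1, c(1, 0, 0))
  r2 <- cast_ray(f2, c(1, 0, 0))
  expect_equal(r$atra, r1$atra * r2$atra, tolerance = 1e-12)
})

test_that("exact traversal matches the dense line-integral oracle", {
  field <- random_absorption_field(seed = 7)
  dirs <- random_directions(200, seed = 8)
  orc <- oracle_line_integral(field, dirs, field$needle_mm,
                              h = 0.1 * field$spacing[1])
  res <- .cast_rays_cpp(field$k, field$cls, field$opaque, field$skin,
                        dim(field$k), field$spacing, field$origin,
                        field$target, dirs, field$needle_mm,
                        field$parent_box$lo, field$parent_box$hi,
                        TRUE, TRUE, TRUE)
  expect_equal(res$a_tra, orc[, 1], tolerance = 0.01)
  expect_equal(res$a_vas, orc[, 2], tolerance = 0.01)
})

test_that("skin normals agree with analytic geometry", {
  # flat skin plane z = c with the body below: outward normal is +z
  n <- 40
  arr <- array(0L, rep(n, 3))
  arr[, , 1:20] <- 1L
  vol <- label_volume(arr, spacing = c(1, 1, 1))
  roi <- structure(vol, class = c("roi_volume", "label_volume"))
  pt <- c(20, 20, 19.5)
  nm <- estimate_skin_normal(roi, pt)
  expect_equal(drop(nm), c(0, 0, 1), tolerance = 1e-6)

  # spherical body: normals parallel to the radial direction within 5 deg
  vol <- ball_volume(n = 60, spacing = 2, body_r = 50)
  roi <- structure(vol, class = c("roi_volume", "label_volume"))
  ctr <- attr(vol, "target")
  set.seed(12)
  dirs <- random_directions(200, seed = 12)
  pts <- sweep(dirs * 49, 2, ctr, "+")
  nm <- estimate_skin_normal(roi, pts, fallback_dir = dirs)
  ang <- acos(pmin(1, rowSums(nm * dirs))) * 180 / pi
  expect_lt(max(ang), 5)

  # an isolated point with zero gradient falls back to the ray direction
  empty <- label_volume(array(0L, c(20, 20, 20)))
  roi0 <- structure(empty, class = c("roi_volume", "label_volume"))
  expect_message(
    nm0 <- estimate_skin_normal(roi0, c(10, 10, 10),
                                fallback_dir = c(0, 1, 0)),
    "fallback")
  expect_equal(drop(nm0), c(0, 1, 0))
})

test_that("Lambertian factor follows the cosine law with clamping", {
  expect_equal(lambertian(cos(0)), 1)
  expect_equal(lambertian(cos(60 * pi / 180)), 0.5)
  expect_equal(lambertian(cos(90 * pi / 180)), 0, tolerance = 1e-12)
  expect_equal(lambertian(cos(120 * pi / 180)), 0)  # inward: clamped
})

test_that("composed intensity obeys its algebraic identities", {
  # a blocked path is zero regardless of the attenuation terms
  expect_equal(compose_intensity(0.9, 0.8, 0.7, iobs = 0), 0)
  # zero exponents reduce the intensity to the obstacle indicator
  expect_equal(compose_intensity(0.3, 0, 0.1, iobs = 1,
                                 weights = c(0, 0, 0)), 1)
  expect_equal(compose_intensity(0.5, 1, 1, iobs = 1,
                                 weights = c(2, 0, 0)), 0.25)
  # monotone: decreasing any term or raising its exponent (terms < 1)
  # never increases the intensity
  set.seed(44)
  a <- matrix(stats::runif(3 * 500), ncol = 3)
  w <- matrix(stats::runif(3 * 500, 0, 4), ncol = 3)
  for (j in 1:3) {
    a2 <- a
    a2[, j] <- a2[, j] * stats::runif(500)
    i1 <- compose_intensity(a[, 1], a[, 2], a[, 3], 1, weights = c(1, 1, 1))
    base <- mapply(function(x, y, z, wa, wb, wc)
      compose_intensity(x, y, z, 1, c(wa, wb, wc)),
      a[, 1], a[, 2], a[, 3], w[, 1], w[, 2], w[, 3])
    wup <- w
    wup[, j] <- wup[, j] + stats::runif(500, 0, 2)
    up <- mapply(function(x, y, z, wa, wb, wc)
      compose_intensity(x, y, z, 1, c(wa, wb, wc)),
      a[, 1], a[, 2], a[, 3], wup[, 1], wup[, 2], wup[, 3])
    i2 <- compose_intensity(a2[, 1], a2[, 2], a2[, 3], 1, c(1, 1, 1))
    expect_true(all(i2 <= i1 + 1e-12))
    expect_true(all(up <= base + 1e-12))
  }
})

test_that("obstacle dilation enforces the clearance margin", {
  # a single opaque voxel dilated by 2 mm at 1 mm spacing becomes a
  # radius-2 Euclidean ball
  d <- c(21, 21, 21)
  roi <- structure(list(labels = array(0L, d)), class = "dummy")
  f <- structure(list(k = array(0, d), cls = array(0L, d),
                      opaque = array(FALSE, d), skin = array(FALSE, d),
                      spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      target = c(10, 10, 10), needle_mm = 10,
                      parent_box = list(lo = rep(-1e9, 3),
                                        hi = rep(1e9, 3)),
                      margin_applied = 0), class = "absorption_field")
  f$opaque[11, 11, 11] <- TRUE
  f$obstacle_distance <- array(.edt3d_cpp(f$opaque, d, f$spacing), d)
  fd <- dilate_obstacles(f, 2)
  got <- which(fd$opaque, arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(got, 2, c(11, 11, 11))^2))
  expect_true(all(r <= 2 + 1e-9))
  expect_equal(nrow(got), sum(f$obstacle_distance <= 2))
  # margin 0 leaves the mask unchanged
  expect_identical(dilate_obstacles(f, 0)$opaque, f$opaque)
})

test_that("rays surviving dilation keep the margin from original obstacles", {
  vol <- generate_phantom(phantom_spec(size = 48, spacing = 2, seed = 6))
  cfg <- phantom_tissue_config()
  roi <- crop_roi(vol, needle_query(attr(vol, "target"), 90))
  field <- build_absorption_field(roi, cfg)
  field <- dilate_obstacles(field, 2)
  shell <- compute_shell_map(roi, field, resolution_deg = 4)
  feas <- which(shell$iobs == 1L & !is.na(shell$depth))
  expect_gt(length(feas), 0)
  set.seed(77)
  pick <- sample(feas, min(1000, length(feas)))
  d <- dim(field$k)
  for (ij in pick) {
    i <- (ij - 1) %% length(shell$phi) + 1
    j <- (ij - 1) %/% length(shell$phi) + 1
    dirv <- drop(dir_from_angles(shell$phi[i], shell$lambda[j]))
    ts <- seq(0, shell$depth[i, j], by = 0.5 * field$spacing[1])
    pts <- sweep(outer(ts, dirv), 2, field$target, "+")
    idx <- round(sweep(sweep(pts, 2, field$origin, "-"), 2,
                       field$spacing, "/")) + 1
    lin <- idx[, 1] + d[1] * ((idx[, 2] - 1) + d[2] * (idx[, 3] - 1))
    expect_true(all(field$obstacle_distance[lin] > 2 - 1e-9))
  }
})

test_that("optimization toggles change no marcher output", {
  vol <- generate_phantom(phantom_spec(size = 48, spacing = 2, seed = 6))
  cfg <- phantom_tissue_config()
  roi <- crop_roi(vol, needle_query(attr(vol, "target"), 90))
  field <- build_absorption_field(roi, cfg)
  dirs <- random_directions(300, seed = 13)
  args <- list(field$k, field$cls, field$opaque, field$skin, dim(field$k),
               field$spacing, field$origin, field$target, dirs,
               field$needle_mm, field$parent_box$lo, field$parent_box$hi)
  on_on <- do.call(.cast_rays_cpp, c(args, TRUE, TRUE, TRUE))
  off_off <- do.call(.cast_rays_cpp, c(args, FALSE, FALSE, TRUE))
  for (nm in names(on_on))
    expect_equal(on_on[[nm]], off_off[[nm]], tolerance = 1e-12,
                 info = nm)
})

test_that("shell map exposes one bright patch per clear corridor", {
  # a body ball with an opaque shell pierced by a single conical window:
  # exactly one connected bright patch appears on the shell
  vol <- ball_volume(n = 60, spacing = 2, body_r = 50,
                     opaque_shell = c(25, 32))
  ctr <- attr(vol, "target")
  # open a window: clear opaque voxels within 25 deg of +x
  idx <- which(vol$labels == 6L, arr.ind = TRUE)
  w <- sweep(sweep(idx, 2, c(1, 1, 1), "-"), 2, vol$spacing, "*")
  v <- sweep(w, 2, ctr, "-")
  cosang <- v[, 1] / sqrt(rowSums(v^2))
  open_idx <- idx[cosang > cos(25 * pi / 180), , drop = FALSE]
  labs <- vol$labels
  labs[open_idx] <- 1L
  vol <- label_volume(labs, vol$spacing, vol$origin)
  cfg <- ball_config()
  roi <- crop_roi(vol, needle_query(ctr, 80))
  field <- build_absorption_field(roi, cfg)
  shell <- compute_shell_map(roi, field, resolution_deg = 3)
  bright <- shell$intensity > 0
  expect_gt(sum(bright), 0)
  comps <- .label8_cpp(bright)
  # wrap-around at the +-180 meridian would split a patch; the window is
  # at longitude +90 so a single component is expected
  expect_equal(max(comps), 1L)
  # and all bright directions are within the window cone (plus slack)
  grid <- expand.grid(phi = shell$phi, lambda = shell$lambda)
  dirs <- dir_from_angles(grid$phi, grid$lambda)
  ang <- acos(pmin(1, pmax(-1, dirs[, 1]))) * 180 / pi
  expect_true(all(ang[as.vector(bright)] < 25 + 6))

  # a fully opaque shell blacks out the whole sphere
  vol2 <- ball_volume(n = 60, spacing = 2, body_r = 50,
                      opaque_shell = c(25, 32))
  roi2 <- crop_roi(vol2, needle_query(attr(vol2, "target"), 80))
  field2 <- build_absorption_field(roi2, ball_config())
  shell2 <- compute_shell_map(roi2, field2, resolution_deg = 5)
  expect_true(all(shell2$intensity == 0))
})

test_that("bright-patch solid angle is stable under resolution doubling", {
  vol <- generate_phantom(phantom_spec(size = 48, spacing = 2, seed = 10))
  cfg <- phantom_tissue_config()
  roi <- crop_roi(vol, needle_query(attr(vol, "target"), 90))
  field <- build_absorption_field(roi, cfg)
  field <- dilate_obstacles(field, 2)
  frac <- sapply(c(4, 2), function(res) {
    shell <- compute_shell_map(roi, field, resolution_deg = res)
    # solid-angle weighted bright fraction (weight cos(phi) per row)
    wgt <- matrix(cos(shell$phi * pi / 180), length(shell$phi),
                  length(shell$lambda))
    sum(wgt[shell$intensity > 0]) / sum(wgt)
  })
  expect_gt(frac[2], 0)
  expect_lt(abs(frac[1] - frac[2]), 0.02)
})
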