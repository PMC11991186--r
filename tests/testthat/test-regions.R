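# helper: wrap a raw RGB raster as a projection_image (all pixels valid)
raw_projection <- function(img) {
  structure(list(img = img, valid = matrix(TRUE, dim(img)[1], dim(img)[2]),
                 resolution = 1, target = c(0, 0, 0), needle_mm = 100),
            class = "projection_image")
}

blob_image <- function(H = 80, W = 80, blobs) {
  img <- array(0, c(H, W, 3))
  for (b in blobs) {
    rows <- b$r[1]:b$r[2]; cols <- b$c[1]:b$c[2]
    img[rows, cols, 1] <- b$rgb[1]
    img[rows, cols, 2] <- b$rgb[2]
    img[rows, cols, 3] <- b$rgb[3]
  }
  raw_projection(img)
}

test_that("region segmentation applies thresholds and the size filter", {
  # an all-black image yields no regions
  expect_length(segment_safe_regions(raw_projection(array(0, c(40, 40, 3)))),
                0)
  # two blobs of 300 and 30 pixels; min_area 100 keeps only the large one
  img <- blob_image(blobs = list(
    list(r = c(10, 29), c = c(10, 24), rgb = c(0.2, 0.6, 0.9)),  # 300 px
    list(r = c(50, 54), c = c(50, 55), rgb = c(0.2, 0.6, 0.9)))) # 30 px
  regs <- segment_safe_regions(img, min_area = 100)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$area, 300)
  # with min_area 1 both survive, disjoint, and their union is the mask
  regs2 <- segment_safe_regions(img, min_area = 1)
  expect_length(regs2, 2)
  all_px <- do.call(rbind, lapply(regs2, `[[`, "pixels"))
  expect_equal(nrow(all_px), 330)
  expect_equal(nrow(unique(all_px)), 330)
  # every returned pixel has positive blue (feasible direction)
  B <- img$img[, , 3]
  expect_true(all(B[all_px] > 0))
  # the green threshold can exclude a dim blob
  img2 <- blob_image(blobs = list(
    list(r = c(10, 29), c = c(10, 24), rgb = c(0.2, 0.01, 0.9)),
    list(r = c(50, 54), c = c(50, 55), rgb = c(0.2, 0.6, 0.9))))
  regs3 <- segment_safe_regions(img2, min_area = 1)
  expect_length(regs3, 1)
  expect_equal(regs3[[1]]$area, 30)
})

test_that("components use 8-connectivity and stable enumeration", {
  img <- array(0, c(20, 20, 3))
  img[5, 5, ] <- 0.5
  img[6, 6, ] <- 0.5   # diagonal neighbour: same component
  img[10, 10, ] <- 0.5 # separate
  pr <- raw_projection(img)
  regs <- segment_safe_regions(pr, min_area = 1)
  expect_length(regs, 2)
  expect_equal(regs[[1]]$area, 2)
  # deterministic across calls
  regs_b <- segment_safe_regions(pr, min_area = 1)
  expect_identical(lapply(regs, `[[`, "pixels"),
                   lapply(regs_b, `[[`, "pixels"))
})

test_that("features of a filled square match analytic values", {
  img <- blob_image(blobs = list(
    list(r = c(11, 20), c = c(31, 40), rgb = c(0.25, 0.5, 0.75))))
  regs <- segment_safe_regions(img, min_area = 1)
  f <- extract_features(regs[[1]], img)
  expect_equal(unname(f["area"]), 100)
  expect_equal(unname(f["extent"]), 1)
  expect_equal(unname(f["eccentricity"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["solidity"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["bbox_height"]), 10)
  expect_equal(unname(f["bbox_width"]), 10)
  expect_equal(unname(f["perimeter"]), 40)
  expect_equal(unname(f["centroid_row"]), 15.5)
  # uniform intensity: mean = min = max, std = 0, sum = area * value
  expect_equal(unname(f["g_mean"]), 0.5)
  expect_equal(unname(f["g_min"]), 0.5)
  expect_equal(unname(f["g_max"]), 0.5)
  expect_equal(unname(f["g_std"]), 0)
  expect_equal(unname(f["g_sum"]), 50)
  expect_length(f, 50)
  expect_identical(names(f), region_feature_names())
})

test_that("Hu moments are invariant under rotation, shapes under translation", {
  # an L-shaped region and its 90-degree rotation
  img <- array(0, c(60, 60, 3))
  img[10:30, 10:14, ] <- 0.5
  img[26:30, 10:24, ] <- 0.5
  pr <- raw_projection(img)
  r1 <- segment_safe_regions(pr, min_area = 1)[[1]]
  f1 <- extract_features(r1, pr)

  rot <- array(0, c(60, 60, 3))
  for (a in 1:3) rot[, , a] <- t(img[60:1, , a])
  pr2 <- raw_projection(rot)
  r2 <- segment_safe_regions(pr2, min_area = 1)[[1]]
  f2 <- extract_features(r2, pr2)
  hu <- paste0("hu", 1:7)
  expect_equal(f1[hu], f2[hu], tolerance = 1e-6)

  # translation invariance of shape features
  sh <- array(0, c(60, 60, 3))
  sh[25:45, 30:34, ] <- 0.5
  sh[41:45, 30:44, ] <- 0.5
  pr3 <- raw_projection(sh)
  f3 <- extract_features(segment_safe_regions(pr3, min_area = 1)[[1]], pr3)
  shape <- c("area", "perimeter", "major_axis_length", "minor_axis_length",
             "eccentricity", "extent", "solidity", "convex_area",
             "equivalent_diameter", "compactness", "aspect_ratio",
             paste0("eta", c("20", "11", "02", "30", "21", "12", "03")),
             hu)
  expect_equal(f1[shape], f3[shape], tolerance = 1e-9)
})

test_that("area is scale-covariant under pixel upscaling", {
  img <- array(0, c(30, 30, 3))
  img[8:17, 12:17, ] <- 0.4
  pr <- raw_projection(img)
  f1 <- extract_features(segment_safe_regions(pr, min_area = 1)[[1]], pr)
  big <- array(0, c(90, 90, 3))
  for (a in 1:3) big[, , a] <- img[rep(1:30, each = 3), rep(1:30, each = 3), a]
  prb <- raw_projection(big)
  f2 <- extract_features(segment_safe_regions(prb, min_area = 1)[[1]], prb)
  expect_equal(unname(f2["area"]), 9 * unname(f1["area"]))
  expect_equal(unname(f2["equivalent_diameter"]),
               3 * unname(f1["equivalent_diameter"]), tolerance = 1e-9)
})

test_that("erosion returns the centre of symmetric regions", {
  sq <- as.matrix(expand.grid(11:15, 21:25))  # 5x5 square
  expect_equal(erode_to_point(sq), c(13, 23))
  expect_equal(erode_to_point(matrix(c(7, 9), ncol = 2)), c(7, 9))
})

test_that("erosion always lands inside the region, deterministically", {
  set.seed(99)
  for (i in 1:100) {
    px <- random_connected_region(sample(3:120, 1))
    p1 <- erode_to_point(px)
    p2 <- erode_to_point(px)
    expect_identical(p1, p2)
    expect_true(any(px[, 1] == p1[1] & px[, 2] == p1[2]))
  }
})
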