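#' Segment candidate safe regions from the projection
#'
#' Thresholds the RGB raster into the feasible-entry mask — a pixel passes
#' iff its blue channel is positive (feasible direction) and every channel
#' meets its threshold — then labels 8-connected components and drops
#' components smaller than the area threshold. Vessels are penalised
#' through intensity rather than excluded, so the red threshold defaults
#' to 0.
#'
#' @param img a `projection_image`.
#' @param thresholds named numeric `c(r=, g=, b=)` channel thresholds in
#'   `[0, 1]`.
#' @param min_area minimum component area in pixels; default corresponds
#'   to 25 square degrees at the image resolution.
#' @return list of `candidate_region` objects (possibly empty): each has
#'   `pixels` (n x 2 row/col), `area`, `centroid`, per-channel means,
#'   `img_dim` and `id`.
#' @export
segment_safe_regions <- function(img,
                                 thresholds = c(r = 0, g = 0.05, b = 0),
                                 min_area = NULL) {
  stopifnot(inherits(img, "projection_image"))
  if (is.null(min_area))
    min_area <- max(1L, round(25 / img$resolution^2))
  R <- img$img[, , 1]; G <- img$img[, , 2]; B <- img$img[, , 3]
  mask <- img$valid & B > 0 & R >= thresholds[["r"]] &
    G >= thresholds[["g"]] & B >= thresholds[["b"]]
  lab <- .label8_cpp(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  regions <- list()
  for (id in seq_len(nlab)) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    lin <- px[, 1] + nrow(mask) * (px[, 2] - 1)
    regions[[length(regions) + 1L]] <- structure(list(
      pixels = unname(px), area = nrow(px),
      centroid = c(mean(px[, 1]), mean(px[, 2])),
      r_mean = mean(R[lin]), g_mean = mean(G[lin]), b_mean = mean(B[lin]),
      img_dim = dim(mask), id = length(regions) + 1L),
      class = "candidate_region")
  }
  regions
}

#' Canonical region feature names
#'
#' The fixed, ordered 50-entry feature vector computed per candidate
#' region (versioned; classifiers refuse mismatched versions): 18 shape
#' descriptors, 7 normalised central moments, 7 Hu moment invariants, 15
#' per-channel intensity statistics, 2 green-weighted centroid
#' coordinates and the centroid's distance to the image centre.
#'
#' @return character vector of length 50.
#' @export
region_feature_names <- function() {
  c("area", "perimeter", "centroid_row", "centroid_col",
    "bbox_min_row", "bbox_min_col", "bbox_height", "bbox_width",
    "major_axis_length", "minor_axis_length", "eccentricity",
    "orientation", "extent", "solidity", "convex_area",
    "equivalent_diameter", "compactness", "aspect_ratio",
    "eta20", "eta11", "eta02", "eta30", "eta21", "eta12", "eta03",
    paste0("hu", 1:7),
    paste0(rep(c("r", "g", "b"), each = 5), "_",
           rep(c("mean", "min", "max", "std", "sum"), 3)),
    "wg_centroid_row", "wg_centroid_col", "dist_to_center")
}

region_feature_version <- "illumipath-features-1"

#' Extract the 50-feature vector of a region
#'
#' Shape features from the pixel set (second-moment ellipse axes,
#' eccentricity and orientation; convex hull solidity; boundary-edge
#' perimeter), normalised central moments and Hu invariants, and intensity
#' statistics per RGB channel. Order and names are fixed by
#' [region_feature_names()].
#'
#' @param region a `candidate_region`.
#' @param img the `projection_image` it came from.
#' @return named numeric vector of length 50.
#' @export
extract_features <- function(region, img) {
  px <- region$pixels
  n <- nrow(px)
  if (n == 0L) stop("empty region")
  r <- px[, 1]; c <- px[, 2]
  cr <- mean(r); cc <- mean(c)

  # central moments (pixel-centre coordinates)
  dr <- r - cr; dc <- c - cc
  mu <- function(p, q) sum(dc^p * dr^q)   # x = col, y = row
  m20 <- mu(2, 0); m02 <- mu(0, 2); m11 <- mu(1, 1)
  m30 <- mu(3, 0); m03 <- mu(0, 3); m21 <- mu(2, 1); m12 <- mu(1, 2)
  eta <- function(m, p, q) m / n^(1 + (p + q) / 2)
  e20 <- eta(m20, 2, 0); e02 <- eta(m02, 0, 2); e11 <- eta(m11, 1, 1)
  e30 <- eta(m30, 3, 0); e03 <- eta(m03, 0, 3)
  e21 <- eta(m21, 2, 1); e12 <- eta(m12, 1, 2)
  hu <- c(
    e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    (e30 - 3 * e12)^2 + (3 * e21 - e03)^2,
    (e30 + e12)^2 + (e21 + e03)^2,
    (e30 - 3 * e12) * (e30 + e12) *
      ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
      (3 * e21 - e03) * (e21 + e03) *
      (3 * (e30 + e12)^2 - (e21 + e03)^2),
    (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
      4 * e11 * (e30 + e12) * (e21 + e03),
    (3 * e21 - e03) * (e30 + e12) *
      ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
      (e30 - 3 * e12) * (e21 + e03) *
      (3 * (e30 + e12)^2 - (e21 + e03)^2))

  # equivalent-ellipse axes from the covariance eigenvalues
  cov <- matrix(c(m20, m11, m11, m02) / n, 2)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  orient <- 0.5 * atan2(2 * m11, m20 - m02)

  # perimeter: count of pixel edges adjacent to non-region pixels
  key <- paste(r, c)
  inset <- function(rr, cc2) paste(rr, cc2) %in% key
  perim <- sum(!inset(r - 1, c)) + sum(!inset(r + 1, c)) +
    sum(!inset(r, c - 1)) + sum(!inset(r, c + 1))

  # convex hull over the 4 pixel corners (so a filled square has
  # convex_area equal to its area)
  corners <- rbind(cbind(c - 0.5, r - 0.5), cbind(c + 0.5, r - 0.5),
                   cbind(c - 0.5, r + 0.5), cbind(c + 0.5, r + 0.5))
  hull_area <- n
  if (n > 1) {
    hidx <- grDevices::chull(corners)
    hp <- corners[hidx, , drop = FALSE]
    m <- nrow(hp)
    nxt <- c(2:m, 1)
    hull_area <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  } else hull_area <- 1

  bb <- c(min(r), min(c), max(r) - min(r) + 1, max(c) - min(c) + 1)
  lin <- r + region$img_dim[1] * (c - 1)
  stat5 <- function(ch) {
    v <- img$img[, , ch][lin]
    c(mean(v), min(v), max(v), stats::sd(c(v, if (n == 1) v)), sum(v))
  }
  s <- c(stat5(1), stat5(2), stat5(3))
  s[is.na(s)] <- 0

  gw <- img$img[, , 2][lin]
  if (sum(gw) > 0) {
    wgr <- sum(r * gw) / sum(gw)
    wgc <- sum(c * gw) / sum(gw)
  } else {
    wgr <- cr; wgc <- cc
  }
  ctr <- region$img_dim / 2 + 0.5

  out <- c(n, perim, cr, cc, bb[1], bb[2], bb[3], bb[4],
           major, minor, ecc, orient,
           n / (bb[3] * bb[4]), min(1, n / hull_area), hull_area,
           2 * sqrt(n / pi), if (perim > 0) 4 * pi * n / perim^2 else 0,
           if (minor > 0) major / minor else 1,
           e20, e11, e02, e30, e21, e12, e03, hu, s, wgr, wgc,
           sqrt((cr - ctr[1])^2 + (cc - ctr[2])^2))
  stats::setNames(out, region_feature_names())
}

#' Feature matrix for a list of regions
#'
#' @param regions list of `candidate_region`.
#' @param img the `projection_image` they came from.
#' @return numeric matrix, one row per region, 50 named columns.
#' @export
features_matrix <- function(regions, img) {
  m <- t(vapply(regions, extract_features, numeric(50), img = img))
  colnames(m) <- region_feature_names()
  m
}

#' Erode a region to a single entry pixel
#'
#' Repeated 3 x 3 binary erosion; when a further erosion would empty the
#' set, the surviving pixel closest to the centroid of the last non-empty
#' set is returned (ties: smallest row, then column). The result is always
#' a member of the original region and is deterministic.
#'
#' @param region a `candidate_region` (or an n x 2 pixel matrix).
#' @return integer `c(row, col)`.
#' @export
erode_to_point <- function(region) {
  px <- if (inherits(region, "candidate_region")) region$pixels else region
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  if (nrow(px) == 0L) stop("empty region")
  # crop to a padded local window
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  nr <- max(px[, 1]) - r0 + 2L; nc <- max(px[, 2]) - c0 + 2L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1] - r0, px[, 2] - c0)] <- TRUE
  erode1 <- function(m) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(FALSE, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs - dr, cs - dc] <- m[rs, cs]
      out <- out & sh
    }
    out
  }
  while (TRUE) {
    nxt <- erode1(m)
    if (!any(nxt)) break
    m <- nxt
  }
  surv <- which(m, arr.ind = TRUE)
  ctr <- colMeans(surv)
  d2 <- (surv[, 1] - ctr[1])^2 + (surv[, 2] - ctr[2])^2
  best <- surv[order(d2, surv[, 1], surv[, 2])[1], ]
  unname(c(best[1] + r0, best[2] + c0))
}
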