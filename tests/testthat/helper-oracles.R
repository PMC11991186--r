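# Independent oracles and fixture builders. Everything here is written
# against the documented conventions only (voxel-centre grids, world mm),
# never by calling the implementation paths under test.

# dense midpoint-rule line integral of a piecewise-constant field along a
# ray from `target`, one value per absorption class; `h` is the sampling
# step in mm
oracle_line_integral <- function(field, dirs, R, h) {
  d <- dim(field$k)
  ts <- seq(h / 2, R, by = h)
  out <- matrix(0, nrow(dirs), 2)
  for (r in seq_len(nrow(dirs))) {
    pts <- sweep(outer(ts, dirs[r, ]), 2, field$target, "+")
    idx <- round(sweep(sweep(pts, 2, field$origin, "-"), 2,
                       field$spacing, "/")) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    lin <- idx[ok, 1] + d[1] * ((idx[ok, 2] - 1) + d[2] * (idx[ok, 3] - 1))
    out[r, 1] <- sum(field$k[lin] * h * (field$cls[lin] == 1L))
    out[r, 2] <- sum(field$k[lin] * h * (field$cls[lin] == 2L))
  }
  out
}

# hand-assembled absorption field over a seeded random two-class blob
# grid (soft tissue k = 0.02 background with vessel-class k = 0.1 blobs),
# no skin and no opacity: a pure Beer-Lambert integration fixture
random_absorption_field <- function(seed, n = 48, spacing = 2,
                                    vessel_frac = 0.35) {
  set.seed(seed)
  d <- rep(n, 3)
  coarse_n <- max(4L, n %/% 8L)
  coarse <- array(stats::runif(coarse_n^3), rep(coarse_n, 3))
  rep_idx <- rep(seq_len(coarse_n), each = ceiling(n / coarse_n))[1:n]
  up <- coarse[rep_idx, rep_idx, rep_idx]
  cls <- array(ifelse(up > 1 - vessel_frac, 2L, 1L), d)
  k <- array(ifelse(cls == 2L, 0.1, 0.02), d)
  ctr <- (n - 1) * spacing / 2
  structure(list(k = k, cls = cls, opaque = array(FALSE, d),
                 skin = array(FALSE, d),
                 obstacle_distance = array(Inf, d),
                 spacing = rep(spacing, 3), origin = c(0, 0, 0),
                 target = rep(ctr, 3), needle_mm = 0.4 * n * spacing,
                 parent_box = list(lo = rep(-1e9, 3), hi = rep(1e9, 3)),
                 margin_applied = 0),
            class = "absorption_field")
}

# a thick slab of labelled tissue perpendicular to +x, target at its
# near face: homogeneous closed-form absorbance fixture
slab_field <- function(k_label, cls_label, slab_mm, n = 120, spacing = 1) {
  d <- rep(n, 3)
  cls <- array(0L, d)
  k <- array(0, d)
  tgt <- rep((n - 1) * spacing / 2, 3)
  wx <- (seq_len(n) - 1) * spacing
  inslab <- wx > tgt[1] & wx <= tgt[1] + slab_mm
  cls[inslab, , ] <- cls_label
  k[inslab, , ] <- k_label
  structure(list(k = k, cls = cls, opaque = array(FALSE, d),
                 skin = array(FALSE, d), obstacle_distance = array(Inf, d),
                 spacing = rep(spacing, 3), origin = c(0, 0, 0),
                 target = tgt, needle_mm = (n / 2 - 1) * spacing,
                 parent_box = list(lo = rep(-1e9, 3), hi = rep(1e9, 3)),
                 margin_applied = 0), class = "absorption_field")
}

# uniform random unit directions
random_directions <- function(n, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n * 3), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# simple spherical "body" label volume: body ball + one-voxel skin shell
# around it, target at the centre; optionally an opaque shell of given
# radii. All labels follow the phantom vocabulary.
ball_volume <- function(n = 48, spacing = 2, body_r = NULL,
                        opaque_shell = NULL, skin_label = 2L,
                        body_label = 1L, opaque_label = 6L) {
  d <- rep(n, 3)
  ctr <- rep((n - 1) * spacing / 2, 3)
  if (is.null(body_r)) body_r <- 0.4 * n * spacing / 2 * 2
  w <- (seq_len(n) - 1) * spacing
  r2 <- outer(outer((w - ctr[1])^2, (w - ctr[2])^2, "+"), (w - ctr[3])^2,
              "+")
  rr <- sqrt(r2)
  arr <- array(0L, d)
  arr[rr <= body_r] <- body_label
  # skin: outermost body voxels (within one voxel of the boundary)
  arr[rr <= body_r & rr > body_r - spacing] <- skin_label
  if (!is.null(opaque_shell))
    arr[rr >= opaque_shell[1] & rr <= opaque_shell[2]] <- opaque_label
  vol <- label_volume(arr, spacing = rep(spacing, 3), origin = c(0, 0, 0))
  attr(vol, "target") <- ctr
  vol
}

ball_config <- function() {
  tissue_config(list(
    "0" = list(role = "transparent"),
    "1" = list(role = "soft"),
    "2" = list(role = "soft"),
    "6" = list(role = "opaque")),
    skin_label = 2L)
}

# brute-force voxel walk along a segment: nearest-voxel labels every
# `step` mm from `from` to `to`
walk_labels <- function(vol, from, to, step = NULL) {
  if (is.null(step)) step <- 0.25 * min(vol$spacing)
  len <- sqrt(sum((to - from)^2))
  ts <- seq(0, len, by = step)
  dirv <- (to - from) / len
  pts <- sweep(outer(ts, dirv), 2, from, "+")
  d <- dim(vol$labels)
  idx <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing,
                     "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  lin <- idx[ok, 1] + d[1] * ((idx[ok, 2] - 1) + d[2] * (idx[ok, 3] - 1))
  list(labels = vol$labels[lin], lin = lin, n_out = sum(!ok))
}

# brute-force minimum distance (mm) from a set of traversed voxels
# (linear indices) to any voxel in `mask`, via voxel-centre coordinates
brute_min_distance <- function(vol, lin, mask) {
  obst <- which(mask)
  if (!length(obst)) return(Inf)
  d <- dim(vol$labels)
  to_xyz <- function(l) {
    l0 <- l - 1
    i <- l0 %% d[1]
    j <- (l0 %/% d[1]) %% d[2]
    k <- l0 %/% (d[1] * d[2])
    cbind(i, j, k)
  }
  a <- sweep(to_xyz(lin), 2, vol$spacing[1], "*")
  b <- sweep(to_xyz(obst), 2, vol$spacing[1], "*")
  mind <- Inf
  for (r in seq_len(nrow(a))) {
    dd <- sqrt((b[, 1] - a[r, 1])^2 + (b[, 2] - a[r, 2])^2 +
                 (b[, 3] - a[r, 3])^2)
    mind <- min(mind, min(dd))
  }
  mind
}

# random 8-connected region grown from a seed pixel
random_connected_region <- function(n_pixels, nrow_img = 60, ncol_img = 60) {
  px <- matrix(c(sample(10:(nrow_img - 10), 1),
                 sample(10:(ncol_img - 10), 1)), ncol = 2)
  seen <- new.env()
  assign(paste(px[1, ], collapse = ","), TRUE, envir = seen)
  while (nrow(px) < n_pixels) {
    base <- px[sample(nrow(px), 1), ]
    cand <- base + c(sample(-1:1, 1), sample(-1:1, 1))
    cand <- pmin(pmax(cand, 2), c(nrow_img, ncol_img) - 1)
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      px <- rbind(px, cand)
    }
  }
  unname(px)
}

# brute-force evaluation of the candidate-entry conditions for each
# direction: the segment from the needle tail P = T + R*d to T must cross
# the skin, the crossing must lie inside the parent-image world box, and
# the ray must not re-enter labelled tissue after leaving the skin.
# Exact: enumerates every voxel-face crossing parameter along the ray and
# reads the label of each traversed interval at its midpoint. Voxels whose
# centre lies outside the R-sphere are background (the candidate region is
# the sphere; the ROI crop documents exactly this discretisation).
brute_force_entry_screen <- function(vol, target, R, skin_label, dirs) {
  d <- dim(vol$labels)
  sp <- vol$spacing
  org <- vol$origin
  box <- list(lo = org - 0.5 * sp, hi = org + (d - 0.5) * sp)
  apply(dirs, 1, function(dirv) {
    ts <- c(0, R)
    for (a in 1:3) {
      if (abs(dirv[a]) < 1e-12) next
      planes <- org[a] + (seq(-1, d[a]) + 0.5 - 1) * sp[a]
      tt <- (planes - target[a]) / dirv[a]
      ts <- c(ts, tt[tt > 1e-9 & tt < R - 1e-9])
    }
    ts <- sort(unique(ts))
    mids <- (ts[-length(ts)] + ts[-1]) / 2
    pts <- sweep(outer(mids, dirv), 2, target, "+")
    idx <- round(sweep(sweep(pts, 2, org, "-"), 2, sp, "/")) + 1
    inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    labs <- rep(0L, length(mids))
    lin <- idx[inb, 1] + d[1] * ((idx[inb, 2] - 1) + d[2] * (idx[inb, 3] - 1))
    labs[inb] <- vol$labels[lin]
    centres <- sweep(sweep(idx - 1, 2, sp, "*"), 2, org, "+")
    labs[sqrt(rowSums(sweep(centres, 2, target)^2)) > R] <- 0L
    sk <- labs == skin_label
    if (!any(sk)) return(FALSE)
    first <- which(sk)[1]
    pcross <- target + ts[first] * dirv  # entry into the first skin voxel
    if (any(pcross < box$lo - 1e-9) || any(pcross > box$hi + 1e-9))
      return(FALSE)
    run_end <- first
    while (run_end < length(mids) && sk[run_end + 1]) run_end <- run_end + 1
    if (run_end < length(mids) &&
        any(labs[(run_end + 1):length(mids)] != 0L)) return(FALSE)
    TRUE
  })
}
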