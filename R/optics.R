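#' Build the absorption field for a cropped ROI
#'
#' Converts labels to per-voxel optical properties using the tissue
#' configuration: an absorption coefficient k (per mm), an absorption class
#' (soft tissue vs vessel, accumulated separately), an opacity mask, and
#' the skin mask. The exact Euclidean distance (mm) to the nearest
#' *un-dilated* obstacle voxel is precomputed so the safety margin of any
#' surviving path can be audited after dilation.
#'
#' @param roi a `roi_volume` from [crop_roi()].
#' @param cfg a [tissue_config()] covering every label in the ROI.
#' @return an object of class `absorption_field`.
#' @export
build_absorption_field <- function(roi, cfg) {
  stopifnot(inherits(roi, "roi_volume"), inherits(cfg, "tissue_config"))
  check_config_covers(cfg, roi)
  labs <- sort(unique(as.vector(roi$labels)))
  maxl <- max(labs)
  lut_k <- numeric(maxl + 1L)
  lut_cls <- integer(maxl + 1L)
  lut_op <- logical(maxl + 1L)
  for (lb in labs) {
    r <- cfg$roles[[as.character(lb)]]
    lut_op[lb + 1L] <- r$role == "opaque"
    lut_k[lb + 1L] <- if (r$role %in% c("soft", "vessel")) r$k else 0
    lut_cls[lb + 1L] <- switch(r$role, soft = 1L, vessel = 2L, 0L)
  }
  d <- dim(roi$labels)
  idx <- roi$labels + 1L
  k <- array(lut_k[idx], d)
  cls <- array(lut_cls[idx], d)
  opaque <- array(lut_op[idx], d)
  skin <- roi$labels == cfg$skin_label

  dist <- array(.edt3d_cpp(opaque, d, roi$spacing), d)

  structure(list(k = k, cls = cls, opaque = opaque, skin = skin,
                 obstacle_distance = dist,
                 spacing = roi$spacing, origin = roi$origin,
                 target = roi$target, needle_mm = roi$needle_mm,
                 parent_box = roi$parent_box,
                 margin_applied = 0),
            class = "absorption_field")
}

#' Dilate obstacles by a safety margin
#'
#' Grows the opaque mask by a Euclidean ball of radius `margin_mm`
#' (thresholding the exact distance transform of the original obstacles),
#' turning the minimum-clearance requirement into a hard constraint: any
#' ray surviving the dilated mask keeps at least `margin_mm` of clearance
#' from every original obstacle voxel. `obstacle_distance` stays relative
#' to the original (un-dilated) obstacles so the guarantee is checkable.
#'
#' @param field an [build_absorption_field()] result.
#' @param margin_mm dilation radius in mm (>= 0).
#' @return the field with the dilated opaque mask.
#' @export
dilate_obstacles <- function(field, margin_mm = 2) {
  stopifnot(inherits(field, "absorption_field"))
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (margin_mm > 0) {
    field$opaque <- field$obstacle_distance <= margin_mm
    dim(field$opaque) <- dim(field$k)
  }
  field$margin_applied <- margin_mm
  field
}

#' Cast a single ray from the target
#'
#' Marches outward from the target along `dir` to radius R, accumulating
#' Beer-Lambert absorbance A = sum k_i * l_i separately for the soft-tissue
#' and vessel classes and reporting the attenuations 10^(-A). By default
#' the traversal is exact (per-voxel chord lengths); a positive `step`
#' requests fixed-step midpoint sampling with nearest-voxel lookup
#' instead. The first opaque voxel stops the ray (obstacle indicator 0);
#' all outputs are reported up to the stopping point.
#'
#' @param field an `absorption_field`.
#' @param dir unit direction (world).
#' @param roi optionally, the `roi_volume`, to estimate the skin normal and
#'   the Lambertian factor at the skin crossing.
#' @param step `NULL` for exact traversal, or a positive step (mm).
#' @return a list: `iobs`, `atra`, `avas` (attenuations), `absorbance_tra`,
#'   `absorbance_vas`, `skin_point` (world mm or `NULL`), `depth_mm`,
#'   `cos_theta`, `feasible`, `reason`.
#' @export
cast_ray <- function(field, dir, roi = NULL, step = NULL) {
  stopifnot(inherits(field, "absorption_field"))
  dir <- as.numeric(dir)
  dir <- dir / sqrt(sum(dir^2))
  if (is.null(step)) {
    res <- .cast_rays_cpp(field$k, field$cls, field$opaque, field$skin,
                          dim(field$k), field$spacing, field$origin,
                          field$target, matrix(dir, 1), field$needle_mm,
                          field$parent_box$lo, field$parent_box$hi,
                          TRUE, TRUE, TRUE)
    a_tra <- res$a_tra[1]; a_vas <- res$a_vas[1]
    iobs <- res$iobs[1]; t_skin <- res$t_skin[1]
    skin_ok <- res$skin_ok[1] == 1L; reason <- res$reason[1]
  } else {
    res <- cast_ray_fixed_step(field, dir, step)
    a_tra <- res$a_tra; a_vas <- res$a_vas
    iobs <- res$iobs; t_skin <- res$t_skin
    skin_ok <- res$skin_ok; reason <- res$reason
  }
  skin_point <- if (!is.na(t_skin)) field$target + t_skin * dir else NULL
  cos_theta <- NA_real_
  if (!is.null(skin_point) && !is.null(roi)) {
    n <- estimate_skin_normal(roi, skin_point, fallback_dir = dir)
    cos_theta <- max(0, sum(dir * n))
  }
  list(iobs = iobs, atra = 10^(-a_tra), avas = 10^(-a_vas),
       absorbance_tra = a_tra, absorbance_vas = a_vas,
       skin_point = skin_point,
       depth_mm = if (is.na(t_skin)) NA_real_ else t_skin,
       cos_theta = cos_theta,
       feasible = iobs == 1L && skin_ok,
       reason = ray_reason_labels[reason + 1L])
}

ray_reason_labels <- c("ok", "no_skin_reach", "outside_image",
                       "multi_crossing", "blocked")

# fixed-step midpoint sampling with nearest-voxel lookup (reference
# sampling mode; the exact traversal is the default). Same state-machine
# semantics as the exact marcher, quantised to the sampling step.
cast_ray_fixed_step <- function(field, dir, step) {
  stopifnot(step > 0)
  d <- dim(field$k)
  box <- field$parent_box
  ts <- seq(step / 2, field$needle_mm, by = step)
  state <- 0L
  blocked <- FALSE
  multi <- FALSE
  t_skin <- NA_real_
  a <- c(0, 0)
  for (m in seq_along(ts)) {
    p <- field$target + ts[m] * dir
    idx <- round((p - field$origin) / field$spacing) + 1
    sk <- FALSE; op <- FALSE; kk <- 0; cl <- 0L
    if (all(idx >= 1 & idx <= d)) {
      lin <- idx[1] + d[1] * ((idx[2] - 1) + d[2] * (idx[3] - 1))
      sk <- field$skin[lin]; op <- field$opaque[lin]
      kk <- field$k[lin]; cl <- field$cls[lin]
    }
    if (state == 2L) {
      if (sk || op || kk > 0) { multi <- TRUE; break }
    } else {
      if (state == 0L && sk) {
        state <- 1L
        t_skin <- ts[m] - step / 2
      } else if (state == 1L && !sk) {
        state <- 2L
      }
      if (state < 2L) {
        if (op) { blocked <- TRUE; break }
        if (kk > 0 && cl %in% 1:2) a[cl] <- a[cl] + kk * step
      } else if (op || kk > 0) {
        multi <- TRUE; break
      }
    }
  }
  t_img <- Inf
  for (axis in 1:3) {
    if (dir[axis] > 1e-9)
      t_img <- min(t_img, (box$hi[axis] - field$target[axis]) / dir[axis])
    else if (dir[axis] < -1e-9)
      t_img <- min(t_img, (box$lo[axis] - field$target[axis]) / dir[axis])
  }
  has_skin <- !is.na(t_skin)
  skin_ok <- has_skin && t_skin <= t_img + 1e-9 && !multi && !blocked
  list(iobs = if (blocked) 0L else 1L, a_tra = a[1], a_vas = a[2],
       t_skin = t_skin, skin_ok = skin_ok,
       reason = if (blocked) 4L else if (multi) 3L else
         if (!has_skin) 1L else if (t_skin > t_img + 1e-9) 2L else 0L)
}

#' Estimate the outward skin normal at a point
#'
#' The outward normal of the Gaussian-smoothed binary body mask,
#' evaluated with a derivative-of-Gaussian kernel centred exactly on the
#' query point and normalised to unit length. The default sigma of 2
#' voxels keeps the estimate within a few degrees of the true surface
#' normal even on the axis-aligned facets a discretised smooth surface
#' develops (a 1-voxel kernel is too narrow to bridge them). Points with
#' a degenerate (zero) gradient fall back to the supplied ray direction.
#'
#' @param roi a `roi_volume` (the body mask is `labels != 0`).
#' @param pts one point (length 3) or an n x 3 matrix, world mm.
#' @param fallback_dir direction(s) used where the gradient vanishes.
#' @param sigma_vox Gaussian sigma in voxels.
#' @return a unit vector (or n x 3 matrix of unit vectors).
#' @export
estimate_skin_normal <- function(roi, pts, fallback_dir = NULL,
                                 sigma_vox = 2) {
  stopifnot(inherits(roi, "label_volume"))
  single <- is.null(dim(pts))
  pts <- rbind_pts(pts)
  body <- roi$labels != 0L
  raw <- .skin_normals_cpp(body, dim(roi$labels), roi$spacing, roi$origin,
                           pts, sigma_vox)
  nrm <- sqrt(rowSums(raw^2))
  degen <- nrm < 1e-12
  out <- raw / pmax(nrm, 1e-12)
  if (any(degen)) {
    if (is.null(fallback_dir))
      stop("zero gradient at skin point and no fallback direction given")
    fb <- rbind_pts(fallback_dir)
    if (nrow(fb) == 1L) fb <- fb[rep(1L, nrow(pts)), , drop = FALSE]
    out[degen, ] <- fb[degen, , drop = FALSE]
    message(sum(degen), " skin point(s) had a degenerate normal; ",
            "ray direction used as fallback")
  }
  if (single) out[1, ] else out
}

#' Lambertian attenuation term
#'
#' Diffuse-reflection factor of the insertion-angle soft constraint:
#' `Aref = max(0, cos(theta))`, where theta is the angle between the
#' outward ray direction and the outward surface normal. A ray along the
#' normal (perpendicular insertion) gives 1; grazing or inward-facing
#' geometry gives 0.
#'
#' @param cos_theta dot product of the unit ray direction and unit outward
#'   normal (vectorised).
#' @return attenuation value(s) in `[0, 1]`.
#' @export
lambertian <- function(cos_theta) pmax(0, pmin(1, cos_theta))

#' Composed illumination intensity
#'
#' The final per-direction score `I = Iobs * Atra^alpha * Aref^beta *
#' Avas^gamma`: a binary obstacle indicator times the three normalized
#' attenuation terms, each raised to an adjustable clinician-preference
#' exponent. `0^0` is defined as 1, so a zero exponent disables its term
#' entirely.
#'
#' @param atra,aref,avas attenuation terms in `[0, 1]` (vectorised).
#' @param iobs binary obstacle indicator (1 = path not blocked).
#' @param weights numeric `c(alpha, beta, gamma)`, all >= 0.
#' @return intensity value(s) in `[0, 1]`.
#' @export
compose_intensity <- function(atra, aref, avas, iobs = 1,
                              weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  pw <- function(x, p) if (p == 0) rep(1, length(x)) else x^p
  iobs * pw(atra, weights[1]) * pw(aref, weights[2]) * pw(avas, weights[3])
}

# latitude-longitude direction grid over the sphere; resolution must
# divide 180 evenly
shell_grid <- function(resolution_deg) {
  if (abs(180 / resolution_deg - round(180 / resolution_deg)) > 1e-9)
    stop("resolution_deg must divide 180 evenly")
  phi <- seq(90, -90, by = -resolution_deg)
  lambda <- seq(-180, 180 - resolution_deg, by = resolution_deg)
  grid <- expand.grid(phi = phi, lambda = lambda)
  dirs <- dir_from_angles(grid$phi, grid$lambda)
  list(phi = phi, lambda = lambda, nphi = length(phi),
       nlam = length(lambda), dirs = dirs)
}

#' Compute the spherical illumination map
#'
#' Casts one ray per node of a latitude-longitude grid from the target to
#' radius R, recording the obstacle indicator, per-class attenuations, the
#' skin entry point and depth, the Lambertian insertion-angle factor, and
#' the composed intensity. Directions failing the skin-reach screen (no
#' skin crossing within R inside the visible image, or multi-crossing)
#' have their obstacle indicator forced to 0.
#'
#' @param roi a `roi_volume`.
#' @param field the matching `absorption_field` (typically after
#'   [dilate_obstacles()]).
#' @param q a [needle_query()] (must match the ROI's target and R).
#' @param resolution_deg angular resolution (degrees; divides 180).
#' @param weights exponents `c(alpha, beta, gamma)` of the composed model.
#' @param apply_skin_screen force the obstacle indicator to 0 where the
#'   skin screen fails (default `TRUE`).
#' @return an object of class `shell_map`.
#' @export
compute_shell_map <- function(roi, field, q = NULL, resolution_deg = 1,
                              weights = c(alpha = 1, beta = 1, gamma = 1),
                              apply_skin_screen = TRUE) {
  stopifnot(inherits(roi, "roi_volume"), inherits(field, "absorption_field"))
  grid <- shell_grid(resolution_deg)
  res <- .cast_rays_cpp(field$k, field$cls, field$opaque, field$skin,
                        dim(field$k), field$spacing, field$origin,
                        field$target, grid$dirs, field$needle_mm,
                        field$parent_box$lo, field$parent_box$hi,
                        TRUE, TRUE, TRUE)
  nphi <- grid$nphi; nlam <- grid$nlam
  iobs_ray <- matrix(res$iobs, nphi, nlam)
  skin_ok <- matrix(res$skin_ok == 1L, nphi, nlam)
  iobs <- if (apply_skin_screen) iobs_ray * skin_ok else iobs_ray
  t_skin <- matrix(res$t_skin, nphi, nlam)
  atra <- matrix(10^(-res$a_tra), nphi, nlam)
  avas <- matrix(10^(-res$a_vas), nphi, nlam)

  # skin entry points and Lambertian factor for feasible directions
  aref <- matrix(0, nphi, nlam)
  skin_pts <- array(NA_real_, c(nphi, nlam, 3))
  feas <- which(iobs == 1L & !is.na(t_skin))
  if (length(feas)) {
    dmat <- grid$dirs[feas, , drop = FALSE]
    pts <- dmat * t_skin[feas]
    pts <- sweep(pts, 2, field$target, "+")
    nrm <- estimate_skin_normal(roi, pts, fallback_dir = dmat)
    aref[feas] <- lambertian(rowSums(dmat * nrm))
    for (a in 1:3) {
      tmp <- skin_pts[, , a]
      tmp[feas] <- pts[, a]
      skin_pts[, , a] <- tmp
    }
  }

  weights <- as.numeric(weights)
  intensity <- matrix(compose_intensity(as.vector(atra), as.vector(aref),
                                        as.vector(avas), as.vector(iobs),
                                        weights), nphi, nlam)
  structure(list(resolution = resolution_deg, phi = grid$phi,
                 lambda = grid$lambda,
                 iobs = iobs, iobs_ray = iobs_ray, skin_ok = skin_ok,
                 reason = matrix(res$reason, nphi, nlam),
                 atra = atra, avas = avas, aref = aref,
                 depth = t_skin, skin_points = skin_pts,
                 intensity = intensity, weights = weights,
                 target = field$target, needle_mm = field$needle_mm),
            class = "shell_map")
}

#' @export
print.shell_map <- function(x, ...) {
  cat("shell_map:", length(x$phi), "x", length(x$lambda), "directions at",
      x$resolution, "deg\n")
  cat("  feasible directions:", sum(x$iobs == 1L), "of", length(x$iobs),
      sprintf("(%.1f%%)\n", 100 * mean(x$iobs == 1L)))
  cat("  needle length:", x$needle_mm, "mm; target:",
      paste(round(x$target, 1), collapse = ", "), "\n")
  invisible(x)
}
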