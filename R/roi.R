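#' Needle query
#'
#' The puncture target T (world mm) and the rigid needle length R (mm).
#' All candidate entry points lie on the sphere of radius R centred on T;
#' any feasible trajectory is the straight segment from a skin entry point
#' to T with depth at most R.
#'
#' @param target numeric length-3, world mm.
#' @param needle_mm needle length R in mm (> 0).
#' @return an object of class `needle_query`.
#' @export
needle_query <- function(target, needle_mm = 153) {
  target <- as.numeric(target)
  stopifnot(length(target) == 3L)
  if (needle_mm <= 0) stop("needle length must be > 0")
  structure(list(target = target, needle_mm = needle_mm),
            class = "needle_query")
}

#' Crop the needle-length ROI around the target
#'
#' Extracts a centred cube whose side is `2*ceiling(R/spacing) + 1` voxels
#' so the target sits at the exact centre voxel; regions where the sphere's
#' bounding box leaves the parent image are zero-padded, and voxels outside
#' the R-sphere are zeroed and flagged invalid. World coordinates are
#' preserved (the ROI keeps its own origin), and the parent image's world
#' bounds are retained for the visible-region condition of the
#' candidate-entry screen.
#'
#' @param vol an isotropic [label_volume()].
#' @param q a [needle_query()]; the target must lie inside the volume.
#' @return a `roi_volume` (a [label_volume()] with extra fields).
#' @export
crop_roi <- function(vol, q) {
  stopifnot(inherits(vol, "label_volume"), inherits(q, "needle_query"))
  sp <- vol$spacing
  if (max(sp) - min(sp) > 1e-9)
    stop("volume must be isotropic; run resample_isotropic() first")
  s <- sp[1]
  d <- dim(vol$labels)
  ci <- round((q$target - vol$origin) / sp) + 1
  if (any(ci < 1) || any(ci > d)) stop("target lies outside the volume")

  h <- as.integer(ceiling(q$needle_mm / s))
  side <- 2L * h + 1L
  out <- array(0L, dim = c(side, side, side))

  src_lo <- pmax(1L, as.integer(ci) - h)
  src_hi <- pmin(d, as.integer(ci) + h)
  dst_lo <- src_lo - (as.integer(ci) - h) + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    vol$labels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
               src_lo[3]:src_hi[3]]

  origin_roi <- vol$origin + (ci - 1L - h) * sp

  # validity: voxel centre inside the R-sphere about T and inside parent
  wx <- origin_roi[1] + (seq_len(side) - 1) * s
  wy <- origin_roi[2] + (seq_len(side) - 1) * s
  wz <- origin_roi[3] + (seq_len(side) - 1) * s
  insphere <- outer(outer((wx - q$target[1])^2, (wy - q$target[2])^2, "+"),
                    (wz - q$target[3])^2, "+") <= q$needle_mm^2
  box <- volume_world_box(vol)
  inimg <- outer(outer(wx >= box$lo[1] & wx <= box$hi[1],
                       wy >= box$lo[2] & wy <= box$hi[2], "&"),
                 wz >= box$lo[3] & wz <= box$hi[3], "&")
  valid <- insphere & inimg
  out[!valid] <- 0L

  roi <- label_volume(out, spacing = rep(s, 3), origin = origin_roi)
  roi$target <- q$target
  roi$needle_mm <- q$needle_mm
  roi$center_index <- rep(h + 1L, 3L)
  roi$parent_offset <- as.integer(ci) - h - 1L  # parent index = roi index + offset
  roi$parent_box <- box
  roi$valid <- valid
  class(roi) <- c("roi_volume", "label_volume")
  roi
}

#' Screen out directions with no reachable skin
#'
#' For every direction on the spherical shell, the ray from the target is
#' walked outward to radius R; directions whose ray never crosses the skin,
#' whose skin crossing lies outside the parent image (not in the visible
#' scanned region), or whose ray re-enters labelled tissue after leaving
#' the skin (multi-crossing, e.g. through an arm fold) are marked
#' infeasible, so the downstream obstacle indicator is forced to 0 there.
#' Equivalent to evaluating the candidate-region conditions (needle tail
#' within R, outside the skin, segment crossing the skin, within the
#' visible region) per direction.
#'
#' If the ROI contains no skin voxels at all (the needle cannot reach the
#' skin anywhere), every direction is removed.
#'
#' @param roi a `roi_volume` from [crop_roi()].
#' @param skin_label integer id of the skin label.
#' @param resolution_deg angular grid resolution (must divide 180).
#' @return `roi` with a `skin_screen` field (`ok`, `t_skin`, `reason`
#'   matrices over the latitude-longitude grid, plus `resolution`).
#' @export
remove_no_skin_directions <- function(roi, skin_label,
                                      resolution_deg = 1) {
  stopifnot(inherits(roi, "roi_volume"))
  skin <- roi$labels == as.integer(skin_label)
  grid <- shell_grid(resolution_deg)
  if (!any(skin)) {
    # no skin within needle reach: every direction is removed (the
    # planner reports no feasible path); a volume with no skin label at
    # all is rejected earlier, by plan_path
    roi$skin_screen <- list(
      resolution = resolution_deg, phi = grid$phi, lambda = grid$lambda,
      ok = matrix(FALSE, grid$nphi, grid$nlam),
      t_skin = matrix(NA_real_, grid$nphi, grid$nlam),
      reason = matrix(1L, grid$nphi, grid$nlam))
    return(roi)
  }
  # matter (anything labelled, except skin itself) must be visible to the
  # marcher so post-skin re-entry is detected; cls = 0 so nothing is
  # accumulated
  matter <- array(as.double(roi$labels != 0L & !skin), dim(roi$labels))
  res <- .cast_rays_cpp(matter, array(0L, dim(roi$labels)),
                        array(FALSE, dim(roi$labels)), skin,
                        dim(roi$labels), roi$spacing, roi$origin,
                        roi$target, grid$dirs, roi$needle_mm,
                        roi$parent_box$lo, roi$parent_box$hi,
                        TRUE, TRUE, FALSE)
  roi$skin_screen <- list(
    resolution = resolution_deg,
    phi = grid$phi, lambda = grid$lambda,
    ok = matrix(res$skin_ok == 1L, grid$nphi, grid$nlam),
    t_skin = matrix(res$t_skin, grid$nphi, grid$nlam),
    reason = matrix(res$reason, grid$nphi, grid$nlam))
  roi
}
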