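#' Direction vectors from spherical angles
#'
#' The shell is parameterised by latitude `phi` (degrees, +90 at the
#' superior pole) and longitude `lambda` (degrees, 0 at the anterior
#' direction). With the patient frame x = left, y = posterior, z =
#' superior, the anterior (ventral) direction is `(0, -1, 0)`:
#' `d = (cos(phi) sin(lambda), -cos(phi) cos(lambda), sin(phi))`.
#'
#' @param phi,lambda angles in degrees (vectorised).
#' @return n x 3 matrix of unit vectors.
#' @export
dir_from_angles <- function(phi, lambda) {
  p <- phi * pi / 180
  l <- lambda * pi / 180
  cbind(cos(p) * sin(l), -cos(p) * cos(l), sin(p))
}

#' @rdname dir_from_angles
#' @param dir unit vector(s), n x 3 or length 3.
#' @return for `angles_from_dir`, a matrix with columns `phi`, `lambda`
#'   (degrees).
#' @export
angles_from_dir <- function(dir) {
  dir <- rbind_pts(dir)
  phi <- asin(pmin(1, pmax(-1, dir[, 3]))) * 180 / pi
  lambda <- atan2(dir[, 1], -dir[, 2]) * 180 / pi
  cbind(phi = phi, lambda = lambda)
}

#' Sinusoidal equal-area projection of the shell map
#'
#' Maps the sphere to a raster with `x = lambda * cos(phi)`, `y = phi`
#' (one pixel per `resolution` degrees), an equal-area projection: pixel
#' counts of any region are proportional to its solid angle. The anterior
#' direction sits at the image centre; pixels outside the sinusoidal lens
#' outline are invalid and zero. Channels follow the planning convention:
#' R = vessel attenuation, G = tissue attenuation, B = obstacle indicator
#' premultiplied with the Lambertian angle factor, so B > 0 marks feasible
#' directions.
#'
#' @param shell a [compute_shell_map()] result.
#' @return an object of class `projection_image` with the H x W x 3 raster
#'   in `[0, 1]`, the validity mask and the pixel/direction mapping
#'   parameters.
#' @export
project_sinusoidal <- function(shell) {
  stopifnot(inherits(shell, "shell_map"))
  res <- shell$resolution
  H <- length(shell$phi)            # rows: +90 .. -90
  W <- length(shell$lambda)         # 360 / res columns (even)
  c0 <- W / 2 + 1                   # anterior (lambda = 0) column
  phi_row <- shell$phi              # row r -> phi
  x_col <- (seq_len(W) - c0) * res  # col c -> x = lambda * cos(phi)

  cosphi <- cos(phi_row * pi / 180)
  valid <- abs(outer(rep(1, H), x_col)) <=
    outer(cosphi * 180, rep(1, W)) + 1e-9
  lam <- outer(1 / pmax(cosphi, 1e-12), x_col)  # lambda per pixel
  lam[!valid] <- NA

  # nearest shell node: rows match exactly; wrap longitude
  jj <- (round((lam + 180) / res) %% W) + 1L
  ii <- matrix(rep(seq_len(H), W), H, W)
  node <- cbind(as.vector(ii), as.vector(jj))
  ok <- !is.na(node[, 2])

  ch <- function(m) {
    out <- matrix(0, H, W)
    out[ok] <- m[node[ok, , drop = FALSE]]
    out[is.na(out)] <- 0
    out
  }
  img <- array(0, c(H, W, 3))
  img[, , 1] <- ch(shell$avas)
  img[, , 2] <- ch(shell$atra)
  img[, , 3] <- ch(shell$iobs * shell$aref)
  for (a in 1:3) {
    tmp <- img[, , a]
    tmp[!valid] <- 0
    img[, , a] <- tmp
  }
  structure(list(img = img, valid = valid, resolution = res,
                 target = shell$target, needle_mm = shell$needle_mm),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat("projection_image:", nrow(x$valid), "x", ncol(x$valid),
      "pixels at", x$resolution, "deg;", sum(x$valid), "valid\n")
  invisible(x)
}

#' Map a pixel back to a shell direction
#'
#' Exact inverse of the sinusoidal mapping: `phi` from the row,
#' `lambda = x / cos(phi)` from the column. Round-tripping any valid pixel
#' through [project_direction()] recovers it exactly.
#'
#' @param img a `projection_image`.
#' @param pixel integer `c(row, col)`.
#' @return unit direction vector (length 3).
#' @export
unproject_pixel <- function(img, pixel) {
  r <- pixel[1]; c <- pixel[2]
  H <- nrow(img$valid); W <- ncol(img$valid)
  if (r < 1 || r > H || c < 1 || c > W || !img$valid[r, c])
    stop("pixel (", r, ", ", c, ") is outside the sinusoidal lens")
  res <- img$resolution
  phi <- 90 - (r - 1) * res
  x <- (c - (W / 2 + 1)) * res
  cp <- cos(phi * pi / 180)
  lambda <- if (cp < 1e-12) 0 else x / cp
  drop(dir_from_angles(phi, lambda))
}

#' Project a direction to its pixel
#'
#' @param img a `projection_image`.
#' @param dir unit direction (world).
#' @return integer `c(row, col)`.
#' @export
project_direction <- function(img, dir) {
  ang <- angles_from_dir(dir)
  res <- img$resolution
  H <- nrow(img$valid); W <- ncol(img$valid)
  r <- round((90 - ang[1, "phi"]) / res) + 1
  x <- ang[1, "lambda"] * cos(ang[1, "phi"] * pi / 180)
  c <- (round(x / res + W / 2) %% W) + 1  # wraps lambda = +180 to -180
  unname(c(max(1, min(H, r)), c))
}

#' Entry point on the skin for a projection pixel
#'
#' Looks up the stored skin crossing of the pixel's shell direction and
#' returns the 3-D entry point (world mm), completing the reverse mapping
#' from the 2-D recommendation image to a straight needle trajectory.
#'
#' @param img a `projection_image`.
#' @param shell the matching `shell_map`.
#' @param pixel integer `c(row, col)`; must be feasible (obstacle
#'   indicator 1 with a recorded skin crossing).
#' @return list with `entry` (world mm), `direction` (unit, target to
#'   entry), `depth_mm`.
#' @export
pixel_to_entry_point <- function(img, shell, pixel) {
  dirv <- unproject_pixel(img, pixel)
  ang <- angles_from_dir(dirv)
  res <- shell$resolution
  i <- round((90 - ang[1, "phi"]) / res) + 1
  j <- (round((ang[1, "lambda"] + 180) / res) %% length(shell$lambda)) + 1
  if (shell$iobs[i, j] != 1L || is.na(shell$depth[i, j]))
    stop("infeasible direction: no skin entry recorded for this pixel")
  node_dir <- drop(dir_from_angles(shell$phi[i], shell$lambda[j]))
  depth <- shell$depth[i, j]
  list(entry = shell$target + depth * node_dir,
       direction = node_dir, depth_mm = depth)
}

#' Plot a projection image
#'
#' Renders the RGB raster (R = vessel, G = tissue, B = feasibility x
#' angle); optionally overlays the recommended entry pixel.
#'
#' @param x a `projection_image`.
#' @param entry_pixel optional `c(row, col)` to mark.
#' @param ... ignored.
#' @export
plot.projection_image <- function(x, entry_pixel = NULL, ...) {
  img <- x$img
  img[] <- pmin(1, pmax(0, img))
  rast <- grDevices::as.raster(img)
  graphics::plot(c(0, ncol(x$valid)), c(0, nrow(x$valid)), type = "n",
                 asp = 1, xlab = "x (deg)", ylab = "latitude row",
                 main = "sinusoidal projection")
  graphics::rasterImage(rast, 0, 0, ncol(x$valid), nrow(x$valid))
  if (!is.null(entry_pixel))
    graphics::points(entry_pixel[2] - 0.5,
                     nrow(x$valid) - entry_pixel[1] + 0.5,
                     col = "white", pch = 3, cex = 2, lwd = 2)
  invisible(x)
}

#' Export a projection image as 8-bit PNG
#'
#' For visual inspection only; planning math stays in float.
#'
#' @param img a `projection_image`.
#' @param path output path.
#' @export
write_projection_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  arr <- img$img
  arr[] <- pmin(1, pmax(0, arr))  # clamp in place, keeping dimensions
  png::writePNG(arr, path)
  invisible(path)
}
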