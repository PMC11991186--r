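#' Labelled anatomy volume
#'
#' A `label_volume` is the package's container for a 3-D multi-label
#' segmentation: an integer array of label ids together with the voxel
#' spacing (mm per axis) and the world position (mm) of the centre of voxel
#' `(1,1,1)`. Conventions used throughout the package: voxel-centre,
#' axis-aligned grids, world coordinates in mm; 1-based array indices in R
#' map to world via `world = origin + (index - 1) * spacing`. Label 0 is
#' background/air.
#'
#' @param labels 3-D integer array of non-negative label ids.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the centre of
#'   the first voxel.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (is.double(labels)) {
    if (any(labels != round(labels), na.rm = TRUE))
      stop("non-integer labels: volume looks like a probability map, not a label mask")
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("label_volume:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = ", "), "\n")
  cat("  origin  (mm):", paste(format(x$origin), collapse = ", "), "\n")
  tb <- table(x$labels)
  cat("  labels:", paste(names(tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Convert between world (mm) and voxel-index coordinates
#'
#' @param vol a [label_volume()].
#' @param pts matrix (n x 3) of points; world mm for `world_to_index`,
#'   1-based (possibly fractional) voxel indices for `index_to_world`.
#' @return n x 3 matrix in the other coordinate system.
#' @export
world_to_index <- function(vol, pts) {
  pts <- rbind_pts(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, pts) {
  pts <- rbind_pts(pts)
  sweep(sweep(pts - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  stopifnot(ncol(pts) == 3L)
  pts
}

# world bounds (outer voxel faces) of a volume, used for the
# visible-region condition of the candidate-region screen
volume_world_box <- function(vol) {
  d <- dim(vol$labels)
  list(lo = vol$origin - 0.5 * vol$spacing,
       hi = vol$origin + (d - 0.5) * vol$spacing)
}

#' Read a label volume from NIfTI or NRRD
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; NRRD (`.nrrd`) through
#' a minimal built-in reader (raw or gzip encoding, attached header).
#' Voxel values must be exactly integral; fractional values signal a
#' probability map and are rejected. The grid must be axis-aligned with
#' positive spacing; spacing and origin are taken from the header.
#'
#' @param path file path.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    return(read_nrrd_volume(path))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
  attributes(arr) <- list(dim = dim(arr))  # drop NIfTI header attributes
  xf <- RNifti::xform(img)
  offd <- xf[1:3, 1:3]
  diag(offd) <- 0
  if (any(abs(offd) > 1e-6))
    stop("oblique orientation not supported; expected an axis-aligned volume")
  dg <- diag(xf[1:3, 1:3])
  if (any(dg <= 0))
    stop("negative-direction orientation not supported; expected +x/+y/+z axes")
  label_volume(arr, spacing = dg, origin = xf[1:3, 4])
}

#' Write a label volume to NIfTI or NRRD
#'
#' @param vol a [label_volume()].
#' @param path output path; `.nii`/`.nii.gz` for NIfTI, `.nrrd` for NRRD.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    return(write_nrrd_volume(vol, path))
  }
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal NRRD support (attached header, raw/gzip, little endian) ----

nrrd_types <- c("signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
                "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
                "uint8_t" = "uint8",
                "short" = "int16", "int16" = "int16", "int16_t" = "int16",
                "ushort" = "uint16", "uint16" = "uint16", "uint16_t" = "uint16",
                "int" = "int32", "int32" = "int32", "int32_t" = "int32",
                "float" = "float", "double" = "double")

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header")
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[trimws(tolower(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  type <- nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("expected a 3-D NRRD volume")
  enc <- tolower(fields[["encoding"]])
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(sizes)
  bytes <- c(int8 = 1, uint8 = 1, int16 = 2, uint16 = 2, int32 = 4,
             float = 4, double = 8)[[type]]
  raw_data <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip" || enc == "gz") {
    raw_data <- memDecompress(raw_data, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  what <- if (type %in% c("float", "double")) "double" else "integer"
  vals <- readBin(raw_data, what, n = n, size = bytes,
                  signed = !(type %in% c("uint8", "uint16")),
                  endian = endian)
  if (is.double(vals) && any(vals != round(vals)))
    stop("non-integer labels: volume looks like a probability map, not a label mask")
  arr <- array(as.integer(vals), dim = sizes)

  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    offd <- m
    diag(offd) <- 0
    if (any(abs(offd) > 1e-6)) stop("oblique NRRD orientation not supported")
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  }
  label_volume(arr, spacing = spacing, origin = origin)
}

write_nrrd_volume <- function(vol, path) {
  d <- dim(vol$labels)
  hdr <- c("NRRD0004",
           "type: int32",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           paste0("space directions: (", vol$spacing[1], ",0,0) (0,",
                  vol$spacing[2], ",0) (0,0,", vol$spacing[3], ")"),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: gzip",
           paste0("space origin: (", paste(vol$origin, collapse = ","), ")"),
           "")
  payload <- memCompress(writeBin(as.integer(vol$labels), raw(),
                                  size = 4L, endian = "little"),
                         type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a label volume to isotropic resolution
#'
#' The smallest input spacing is taken as the target resolution and all axes
#' are resampled to it with nearest-neighbour interpolation (the only
#' label-safe choice). An already-isotropic volume is returned unchanged.
#' The world extent is preserved to within one output voxel per face.
#'
#' @param vol a [label_volume()].
#' @return an isotropic [label_volume()].
#' @export
resample_isotropic <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  s <- vol$spacing
  if (max(s) - min(s) < 1e-9) return(vol)
  t <- min(s)
  d <- dim(vol$labels)
  nd <- pmax(1L, as.integer(round(d * s / t)))
  idx <- lapply(1:3, function(a) {
    src <- round(((seq_len(nd[a]) - 1) * t) / s[a]) + 1
    pmin(pmax(src, 1L), d[a])
  })
  label_volume(vol$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               spacing = rep(t, 3), origin = vol$origin)
}

# ---- tissue configuration -------------------------------------------------

tissue_roles <- c("opaque", "soft", "vessel", "transparent", "target")

#' Tissue optical configuration
#'
#' Maps every label id in a volume to an optical role and, for absorbing
#' roles, a per-mm absorption coefficient k. Roles: `opaque` (high-risk
#' structures that block rays outright: bones, heart, non-target lobes,
#' airways), `soft` (passable tissue, default k = 0.02/mm), `vessel`
#' (partially traversable vasculature, default k = 0.1/mm), `transparent`
#' and `target` (k = 0). Also carries the obstacle safety margin (mm), the
#' preference exponents alpha/beta/gamma of the composed-intensity model,
#' and the id of the skin label (needed by the skin-reach screen and the
#' insertion-angle model).
#'
#' @param roles named list: names are label ids (as characters), each value
#'   a list with `$role` and optionally `$k`.
#' @param skin_label integer label id of the skin shell.
#' @param obstacle_margin_mm dilation margin for opaque structures (mm).
#' @param weights numeric length-3 `c(alpha, beta, gamma)`, exponents of
#'   the tissue, reflection and vessel attenuation terms (all >= 0).
#' @return an object of class `tissue_config`.
#' @export
tissue_config <- function(roles, skin_label, obstacle_margin_mm = 2,
                          weights = c(alpha = 1, beta = 1, gamma = 1)) {
  default_k <- c(opaque = 0, soft = 0.02, vessel = 0.1, transparent = 0,
                 target = 0)
  roles <- lapply(roles, function(r) {
    if (is.character(r)) r <- list(role = r)
    if (!r$role %in% tissue_roles)
      stop("unknown tissue role: ", r$role)
    if (is.null(r$k)) r$k <- unname(default_k[[r$role]])
    if (r$role %in% c("transparent", "target")) r$k <- 0
    if (r$k < 0) stop("absorption coefficient k must be >= 0")
    r
  })
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 3L)
  if (any(weights < 0)) stop("weights alpha, beta, gamma must be >= 0")
  if (obstacle_margin_mm < 0) stop("obstacle_margin_mm must be >= 0")
  structure(list(roles = roles, skin_label = as.integer(skin_label),
                 obstacle_margin_mm = obstacle_margin_mm,
                 weights = stats::setNames(weights,
                                           c("alpha", "beta", "gamma"))),
            class = "tissue_config")
}

#' @export
print.tissue_config <- function(x, ...) {
  cat("tissue_config:", length(x$roles), "labels; skin label",
      x$skin_label, "\n")
  for (lb in names(x$roles))
    cat(sprintf("  %3s: %-12s k = %g\n", lb, x$roles[[lb]]$role,
                x$roles[[lb]]$k))
  cat("  obstacle margin:", x$obstacle_margin_mm, "mm;  weights:",
      paste(sprintf("%s=%g", names(x$weights), x$weights), collapse = " "),
      "\n")
  invisible(x)
}

#' Read a tissue configuration file
#'
#' YAML (or JSON, by extension) document with a `labels` map keyed by label
#' id, each entry holding a `role` and optional `k`, plus optional
#' `skin_label`, `obstacle_margin_mm` and `weights` entries. Every label
#' present in `vol` must be covered; an unmapped label is an error.
#'
#' @param path configuration file path.
#' @param vol a [label_volume()] the config must cover.
#' @return a [tissue_config()].
#' @export
read_tissue_config <- function(path, vol) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$labels)) stop("config must contain a `labels` map")
  w <- doc$weights %||% list(alpha = 1, beta = 1, gamma = 1)
  cfg <- tissue_config(doc$labels,
                       skin_label = doc$skin_label %||%
                         stop("config must give `skin_label`"),
                       obstacle_margin_mm = doc$obstacle_margin_mm %||% 2,
                       weights = c(w$alpha %||% 1, w$beta %||% 1,
                                   w$gamma %||% 1))
  check_config_covers(cfg, vol)
  cfg
}

check_config_covers <- function(cfg, vol) {
  present <- sort(unique(as.vector(vol$labels)))
  missing <- setdiff(as.character(present), names(cfg$roles))
  if (length(missing))
    stop("labels present in volume but absent from config: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a tissue configuration to YAML
#'
#' @param cfg a [tissue_config()].
#' @param path output path.
#' @export
write_tissue_config <- function(cfg, path) {
  doc <- list(labels = cfg$roles, skin_label = cfg$skin_label,
              obstacle_margin_mm = cfg$obstacle_margin_mm,
              weights = as.list(cfg$weights))
  yaml::write_yaml(doc, path)
  invisible(path)
}
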