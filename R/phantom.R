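#' Synthetic thorax phantom specification
#'
#' Parameters of the seeded, parametric thorax-like label volume used to
#' exercise the planning pipeline without patient data: a body ellipsoid
#' wrapped by a one-voxel skin shell, two lungs split into lobe
#' compartments, branching vessel trees with graded radii, rib-like opaque
#' arcs with an anterior (ventral) gap, an opaque heart blob, an opaque
#' airway tube, and a spherical nodule inside the target lobe.
#'
#' @param size integer length-3 grid size in voxels (each >= 48).
#' @param spacing voxel size in mm (isotropic scalar or length-3).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param n_ribs number of rib arcs.
#' @param rib_radius rib tube radius (mm).
#' @param n_lobes total lobe compartments across both lungs (2 to 5).
#' @param vessel_levels branching depth of each lung's vessel tree (1-3).
#' @param vessel_radii per-level vessel radii (mm), coarsest first.
#' @param nodule_radius nodule radius (mm).
#' @param labels named integer vector of label ids.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64, 64, 64), spacing = 2, seed = 1,
                         n_ribs = 4, rib_radius = 2.5, n_lobes = 4,
                         vessel_levels = 3,
                         vessel_radii = c(3.5, 2.2, 1.2),
                         nodule_radius = 6,
                         labels = c(background = 0L, body = 1L, skin = 2L,
                                    lobe_target = 3L, lobe_other = 4L,
                                    vessel = 5L, bone = 6L, heart = 7L,
                                    airway = 8L, nodule = 9L)) {
  size <- rep_len(as.integer(size), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(size < 48L)) stop("phantom grid must be at least 48 voxels per axis")
  if (n_lobes < 2 || n_lobes > 5) stop("n_lobes must be between 2 and 5")
  structure(list(size = size, spacing = spacing, seed = as.integer(seed),
                 n_ribs = as.integer(n_ribs), rib_radius = rib_radius,
                 n_lobes = as.integer(n_lobes),
                 vessel_levels = as.integer(vessel_levels),
                 vessel_radii = vessel_radii,
                 nodule_radius = nodule_radius, labels = labels),
            class = "phantom_spec")
}

#' Default tissue configuration for the phantom label vocabulary
#'
#' Opaque: non-target lobes, bone, heart, airway. Soft (k = 0.02/mm): body,
#' skin, target lobe. Vessel (k = 0.1/mm): vessels. Transparent:
#' background. Target: nodule.
#'
#' @param spec a [phantom_spec()] (for the label ids).
#' @param ... passed to [tissue_config()] (e.g. `obstacle_margin_mm`,
#'   `weights`).
#' @return a [tissue_config()].
#' @export
phantom_tissue_config <- function(spec = phantom_spec(), ...) {
  lb <- spec$labels
  roles <- stats::setNames(list(
    list(role = "transparent"),            # background
    list(role = "soft"),                   # body
    list(role = "soft"),                   # skin
    list(role = "soft"),                   # target lobe
    list(role = "opaque"),                 # other lobes
    list(role = "vessel"),                 # vessels
    list(role = "opaque"),                 # bone
    list(role = "opaque"),                 # heart
    list(role = "opaque"),                 # airway
    list(role = "target")                  # nodule
  ), as.character(lb[c("background", "body", "skin", "lobe_target",
                       "lobe_other", "vessel", "bone", "heart", "airway",
                       "nodule")]))
  tissue_config(roles, skin_label = lb[["skin"]], ...)
}

# stamp a ball of radius r (mm) centred at world point p into arr,
# overwriting with `value`; arr dims d, spacing sp, origin org
stamp_ball <- function(arr, p, r, value, sp, org) {
  d <- dim(arr)
  lo <- pmax(1L, as.integer(floor((p - r - org) / sp) + 1))
  hi <- pmin(d, as.integer(ceiling((p + r - org) / sp) + 1))
  if (any(lo > hi)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  wx <- org[1] + (ix - 1) * sp[1]
  wy <- org[2] + (iy - 1) * sp[2]
  wz <- org[3] + (iz - 1) * sp[3]
  dx2 <- (wx - p[1])^2
  dy2 <- (wy - p[2])^2
  dz2 <- (wz - p[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  sub <- arr[ix, iy, iz, drop = FALSE]
  sub[m] <- value
  arr[ix, iy, iz] <- sub
  arr
}

# stamp a capsule (tube) from p to q, radius r, by stamping balls every
# half voxel along the segment
stamp_capsule <- function(arr, p, q, r, value, sp, org) {
  len <- sqrt(sum((q - p)^2))
  n <- max(2L, ceiling(len / (0.5 * min(sp))) + 1L)
  for (t in seq(0, 1, length.out = n))
    arr <- stamp_ball(arr, p + t * (q - p), r, value, sp, org)
  arr
}

#' Generate a synthetic thorax phantom
#'
#' Deterministic given the seed. The generated volume satisfies the
#' phantom invariants (one-voxel skin shell exactly on the body/background
#' boundary, disjoint structures, nodule strictly inside the target lobe)
#' and is verified by a brute-force ray sweep to contain at least one
#' obstacle-free corridor from the nodule to the skin; if the sampled
#' geometry has none, the internal geometry is perturbed deterministically
#' and regeneration is retried.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] with attributes `target` (nodule centroid,
#'   world mm) and `phantom_spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (attempt in 0:7) {
    set.seed(spec$seed + 7919L * attempt)
    vol <- build_phantom_once(spec)
    if (!is.null(vol) && phantom_has_corridor(vol, spec)) {
      attr(vol, "phantom_attempt") <- attempt
      return(vol)
    }
  }
  stop("phantom spec infeasible: no obstacle-free corridor after 8 attempts")
}

build_phantom_once <- function(spec) {
  d <- spec$size
  sp <- spec$spacing
  org <- c(0, 0, 0)
  lb <- spec$labels
  ext <- (d - 1) * sp
  ctr <- org + ext / 2

  wx <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  wy <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  wz <- org[3] + (seq_len(d[3]) - 1) * sp[3]

  # body ellipsoid (anterior = -y)
  semi <- c(0.42, 0.36, 0.46) * ext
  bx <- (wx - ctr[1]) / semi[1]
  by <- (wy - ctr[2]) / semi[2]
  bz <- (wz - ctr[3]) / semi[3]
  body <- outer(outer(bx^2, by^2, "+"), bz^2, "+") <= 1
  arr <- array(lb[["background"]], dim = d)
  arr[body] <- lb[["body"]]

  # lungs: two ellipsoids; lobes: z-plane compartments
  lung_semi <- c(0.38 * semi[1], 0.56 * semi[2], 0.62 * semi[3])
  lcx <- 0.47 * semi[1]
  lung_ctr <- list(right = ctr + c(-lcx, 0, 2),
                   left  = ctr + c(lcx, 0, 2))
  lung_mask <- list()
  for (side in names(lung_ctr)) {
    lc <- lung_ctr[[side]]
    lx <- (wx - lc[1]) / lung_semi[1]
    ly <- (wy - lc[2]) / lung_semi[2]
    lz <- (wz - lc[3]) / lung_semi[3]
    lung_mask[[side]] <- outer(outer(lx^2, ly^2, "+"), lz^2, "+") <= 1
  }
  # compartments: split right lung into ceil(n/2), left into floor(n/2)
  n_right <- ceiling(spec$n_lobes / 2)
  n_left <- spec$n_lobes - n_right
  zcut_jitter <- stats::runif(1, -4, 4)
  Z <- outer(outer(rep(1, d[1]), rep(1, d[2])), wz)
  compartment <- function(mask, nsplit, lc) {
    if (nsplit <= 1) return(list(mask))
    zr <- range(wz[apply(mask, 3, any)])
    cuts <- seq(zr[1], zr[2], length.out = nsplit + 1)[2:nsplit] + zcut_jitter
    out <- list()
    lowcut <- -Inf
    for (cc in c(cuts, Inf)) {
      out[[length(out) + 1]] <- mask & Z > lowcut & Z <= cc
      lowcut <- cc
    }
    out
  }
  comps <- c(compartment(lung_mask$right, n_right, lung_ctr$right),
             if (n_left > 0) compartment(lung_mask$left, n_left,
                                         lung_ctr$left))
  # target lobe: lower-right compartment (anterior corridors are open there)
  target_comp <- 1L
  for (i in seq_along(comps))
    arr[comps[[i]]] <- if (i == target_comp) lb[["lobe_target"]] else
      lb[["lobe_other"]]

  # vessel trees, one per lung, rooted at the medial hilum
  for (side in names(lung_ctr)) {
    lc <- lung_ctr[[side]]
    medial <- if (side == "right") c(lung_semi[1] * 0.8, 0, 0) else
      c(-lung_semi[1] * 0.8, 0, 0)
    root <- lc + medial
    dir0 <- -medial / sqrt(sum(medial^2))
    nodes <- list(list(p = root, dir = dir0, level = 1L))
    while (length(nodes)) {
      nd <- nodes[[1]]
      nodes <- nodes[-1]
      r <- spec$vessel_radii[min(nd$level, length(spec$vessel_radii))]
      len <- c(18, 12, 8)[min(nd$level, 3)]
      q <- nd$p + nd$dir * len
      arr <- stamp_capsule(arr, nd$p, q, r, lb[["vessel"]], sp, org)
      if (nd$level < spec$vessel_levels) {
        for (b in 1:2) {
          pert <- stats::rnorm(3, 0, 0.6)
          ndir <- nd$dir + pert
          ndir <- ndir / sqrt(sum(ndir^2))
          nodes[[length(nodes) + 1]] <-
            list(p = q, dir = ndir, level = nd$level + 1L)
        }
      }
    }
  }

  # heart: opaque ellipsoid, medial and slightly anterior
  hc <- ctr + c(stats::runif(1, -3, 3), -0.18 * semi[2], -0.05 * semi[3])
  hsemi <- c(0.17, 0.22, 0.26) * semi
  hx <- (wx - hc[1]) / hsemi[1]
  hy <- (wy - hc[2]) / hsemi[2]
  hz <- (wz - hc[3]) / hsemi[3]
  heart <- outer(outer(hx^2, hy^2, "+"), hz^2, "+") <= 1
  arr[heart] <- lb[["heart"]]

  # airway: opaque vertical tube from above the lungs down to the carina
  top <- ctr + c(0, 0.05 * semi[2], 0.85 * semi[3])
  carina <- ctr + c(0, 0.05 * semi[2], 0.15 * semi[3])
  arr <- stamp_capsule(arr, top, carina, 3, lb[["airway"]], sp, org)

  # ribs: opaque arcs in axial planes with an anterior gap
  if (spec$n_ribs > 0) {
    zlevels <- seq(-0.55, 0.55, length.out = spec$n_ribs) * semi[3] + ctr[3]
    for (zj in zlevels) {
      f <- sqrt(max(0, 1 - ((zj - ctr[3]) / semi[3])^2))
      th <- seq(-50, 230, by = 2) * pi / 180  # 80 deg ventral gap
      pts <- cbind(ctr[1] + 0.86 * semi[1] * f * cos(th),
                   ctr[2] + 0.86 * semi[2] * f * sin(th),
                   zj)
      for (i in seq_len(nrow(pts)))
        arr <- stamp_ball(arr, pts[i, ], spec$rib_radius, lb[["bone"]],
                          sp, org)
    }
  }

  # nodule: sphere strictly inside the target lobe
  tl_world <- which(arr == lb[["lobe_target"]], arr.ind = TRUE)
  if (!nrow(tl_world)) return(NULL)
  for (try in 1:25) {
    lc <- lung_ctr$right
    cand <- lc + c(stats::runif(1, -0.25, 0.25) * lung_semi[1],
                   stats::runif(1, -0.45, -0.05) * lung_semi[2],
                   stats::runif(1, -0.55, -0.15) * lung_semi[3])
    # all voxels of the would-be nodule must currently be target lobe
    probe <- stamp_ball(array(0L, d), cand, spec$nodule_radius + min(sp),
                        1L, sp, org)
    inside <- arr[probe == 1L]
    if (length(inside) &&
        all(inside %in% c(lb[["lobe_target"]], lb[["vessel"]]))) {
      arr <- stamp_ball(arr, cand, spec$nodule_radius, lb[["nodule"]],
                        sp, org)
      nodule_ctr <- cand
      break
    }
    if (try == 25) return(NULL)
  }

  # skin: exactly the body-component voxels face-adjacent to background
  nonbg <- arr != lb[["background"]]
  interior <- shift_all_neighbors(nonbg)
  skin <- nonbg & !interior
  arr[skin] <- lb[["skin"]]

  vol <- label_volume(arr, spacing = sp, origin = org)
  # report the nodule centroid (world mm) as the puncture target
  nv <- which(vol$labels == lb[["nodule"]], arr.ind = TRUE)
  tgt <- colMeans(index_to_world(vol, nv))
  attr(vol, "target") <- tgt
  attr(vol, "phantom_spec") <- spec
  vol
}

# TRUE where all six face neighbours are TRUE (treating outside as FALSE)
shift_all_neighbors <- function(m) {
  d <- dim(m)
  out <- m
  pad <- function(a, axis, dir) {
    r <- array(FALSE, dim(a))
    if (axis == 1) {
      if (dir > 0) r[1:(d[1] - 1), , ] <- a[2:d[1], , ]
      else r[2:d[1], , ] <- a[1:(d[1] - 1), , ]
    } else if (axis == 2) {
      if (dir > 0) r[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
      else r[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
    } else {
      if (dir > 0) r[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
      else r[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
    }
    r
  }
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out & pad(m, axis, dir)
  out
}

# brute-force coarse ray sweep: does at least one obstacle-free corridor
# from the nodule to the skin exist (respecting the safety margin)?
phantom_has_corridor <- function(vol, spec,
                                 margin_mm = 2, angular_step = 12) {
  lb <- spec$labels
  tgt <- attr(vol, "target")
  permitted <- c(lb[["body"]], lb[["skin"]], lb[["lobe_target"]],
                 lb[["vessel"]], lb[["nodule"]])
  obstacle <- vol$labels %in% c(lb[["lobe_other"]], lb[["bone"]],
                                lb[["heart"]], lb[["airway"]])
  dim(obstacle) <- dim(vol$labels)
  dist <- array(.edt3d_cpp(obstacle, dim(obstacle), vol$spacing),
                dim(obstacle))
  step <- 0.5 * min(vol$spacing)
  for (phi in seq(-80, 80, by = angular_step)) {
    for (lam in seq(-180, 180 - angular_step, by = angular_step)) {
      dirv <- dir_from_angles(phi, lam)
      tmax <- sqrt(sum(((dim(vol$labels) - 1) * vol$spacing)^2))
      ts <- seq(step, tmax, by = step)
      pts <- cbind(tgt[1] + ts * dirv[1], tgt[2] + ts * dirv[2],
                   tgt[3] + ts * dirv[3])
      idx <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing,
                         "/")) + 1
      ok <- idx[, 1] >= 1 & idx[, 1] <= dim(vol$labels)[1] &
        idx[, 2] >= 1 & idx[, 2] <= dim(vol$labels)[2] &
        idx[, 3] >= 1 & idx[, 3] <= dim(vol$labels)[3]
      if (!any(ok)) next
      idx <- idx[ok, , drop = FALSE]
      lin <- idx[, 1] + dim(vol$labels)[1] *
        ((idx[, 2] - 1) + dim(vol$labels)[2] * (idx[, 3] - 1))
      labs <- vol$labels[lin]
      hit <- which(labs == lb[["skin"]])
      if (!length(hit)) next
      seg <- seq_len(hit[1])
      if (all(labs[seg] %in% permitted) &&
          all(dist[lin[seg]] >= margin_mm))
        return(TRUE)
    }
  }
  FALSE
}

#' Rule-based "surgeon" annotation of candidate regions
#'
#' A fixed, documented stand-in for expert annotation on the synthetic
#' corpus: exactly one region is labelled positive, the maximiser of
#' area x mean green-channel intensity (large, low-absorbance regions),
#' with ties broken by the smaller distance of the region centroid to the
#' image centre. An optional label-flip noise rate supports robustness
#' experiments.
#'
#' @param regions list of candidate regions from [segment_safe_regions()].
#' @param flip_rate probability of flipping each label (default 0).
#' @param seed seed for the optional noise.
#' @return logical vector, one element per region.
#' @export
annotate_regions_rulebased <- function(regions, flip_rate = 0, seed = NULL) {
  if (!length(regions)) stop("empty region list")
  score <- vapply(regions, function(r) r$area * r$g_mean, numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1) {
    ctr <- regions[[best[1]]]$img_dim / 2 + 0.5
    d2 <- vapply(best, function(i)
      sum((regions[[i]]$centroid - ctr)^2), numeric(1))
    best <- best[order(d2, vapply(best, function(i)
      regions[[i]]$centroid[1], numeric(1)),
      vapply(best, function(i) regions[[i]]$centroid[2], numeric(1)))][1]
  } else {
    best <- best[1]
  }
  labels <- seq_along(regions) == best
  if (flip_rate > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                       envir = globalenv())
      })
      set.seed(seed)
    }
    flip <- stats::runif(length(labels)) < flip_rate
    labels <- xor(labels, flip)
  }
  labels
}
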