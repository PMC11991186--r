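#' Region dataset for recommendation training
#'
#' Feature matrix, binary labels (expert-selected or rule-annotated) and a
#' group id per source image: all regions from one image always share a
#' group, so grouped splits are leakage-free.
#'
#' @param features numeric matrix, one row per region (50 named columns).
#' @param labels logical/binary vector.
#' @param group group (image) id per region.
#' @return object of class `region_dataset`.
#' @export
region_dataset <- function(features, labels, group) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(group))
  structure(list(features = features, labels = as.logical(labels),
                 group = group, split = NULL,
                 feature_version = region_feature_version),
            class = "region_dataset")
}

#' @export
print.region_dataset <- function(x, ...) {
  cat("region_dataset:", nrow(x$features), "regions from",
      length(unique(x$group)), "images;", sum(x$labels), "positive\n")
  if (!is.null(x$split))
    cat("  split:", paste(names(table(x$split)), table(x$split),
                          sep = "=", collapse = " "), "(by group)\n")
  invisible(x)
}

#' Assign a grouped train/validation/test split
#'
#' Whole images (groups) are shuffled deterministically and assigned
#' 7:1:2 by default, so no group spans two subsets.
#'
#' @param ds a [region_dataset()].
#' @param ratio numeric length-3 proportions for train/val/test.
#' @param seed integer seed for the group shuffle.
#' @return the dataset with a `split` factor.
#' @export
split_grouped <- function(ds, ratio = c(7, 1, 2) / 10, seed = 1) {
  stopifnot(inherits(ds, "region_dataset"))
  groups <- unique(ds$group)
  ord <- with_seed(seed, sample(length(groups)))
  groups <- groups[ord]
  n <- length(groups)
  n_tr <- round(ratio[1] / sum(ratio) * n)
  n_va <- round(ratio[2] / sum(ratio) * n)
  assign <- stats::setNames(rep("test", n), groups)
  assign[seq_len(n_tr)] <- "train"
  if (n_va > 0) assign[n_tr + seq_len(n_va)] <- "val"
  ds$split <- factor(unname(assign[as.character(ds$group)]),
                     levels = c("train", "val", "test"))
  stopifnot(!anyNA(ds$split))
  ds
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Balance the training split by synthetic minority oversampling
#'
#' SMOTE-style interpolation: each synthetic minority sample lies on the
#' segment between a random minority sample and one of its k nearest
#' minority neighbours, bringing the minority class to parity with the
#' majority. Applied to the training rows only; validation and test rows
#' are untouched. Deterministic given the seed.
#'
#' @param ds a [region_dataset()] (if it carries a split, only the train
#'   rows are balanced).
#' @param seed integer seed.
#' @param k number of nearest neighbours for interpolation.
#' @return a balanced [region_dataset()] (synthetic rows appended, group
#'   id `"synthetic"`, split `"train"`).
#' @export
balance_training_set <- function(ds, seed = 1, k = 5) {
  stopifnot(inherits(ds, "region_dataset"))
  tr <- if (is.null(ds$split)) seq_along(ds$labels) else
    which(ds$split == "train")
  y <- ds$labels[tr]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == n_neg) return(ds)
  minority <- if (n_pos < n_neg) TRUE else FALSE
  n_min <- min(n_pos, n_neg)
  if (n_min < 2)
    stop("fewer than 2 minority samples in the training split; ",
         "SMOTE needs neighbours - use the rule-based fallback instead")
  need <- abs(n_pos - n_neg)
  X <- ds$features[tr, , drop = FALSE][y == minority, , drop = FALSE]
  # scale features for the neighbour search
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  kk <- min(k, n_min - 1)
  nn <- t(apply(D, 1, function(row) order(row)[seq_len(kk)]))
  syn <- with_seed(seed, {
    i <- sample.int(n_min, need, replace = TRUE)
    j <- nn[cbind(i, sample.int(kk, need, replace = TRUE))]
    u <- stats::runif(need)
    X[i, , drop = FALSE] + u * (X[j, , drop = FALSE] - X[i, , drop = FALSE])
  })
  out <- region_dataset(rbind(ds$features, syn),
                        c(ds$labels, rep(minority, need)),
                        c(as.character(ds$group),
                          rep("synthetic", need)))
  if (!is.null(ds$split))
    out$split <- factor(c(as.character(ds$split), rep("train", need)),
                        levels = levels(ds$split))
  out
}

#' Train the entry-region classifier
#'
#' Mimics expert region preference: the default engine is a 100-tree
#' random forest with maximum depth 10 and balanced class weights;
#' gradient boosting (xgboost) is available behind the same interface.
#' Training uses the (typically SMOTE-balanced) training split; held-out
#' performance (AUC-ROC, precision, recall, F1, specificity, confusion
#' matrix, with one positive prediction per image: the highest-probability
#' region) is reported on the test groups.
#'
#' @param ds a split (and usually balanced) [region_dataset()].
#' @param engine `"ranger"` (random forest) or `"xgboost"`.
#' @param seed integer seed.
#' @param num_trees,max_depth forest/boosting size parameters.
#' @return object of class `region_classifier`.
#' @export
train_region_classifier <- function(ds, engine = c("ranger", "xgboost"),
                                    seed = 1, num_trees = 100,
                                    max_depth = 10) {
  stopifnot(inherits(ds, "region_dataset"))
  engine <- match.arg(engine)
  if (is.null(ds$split)) ds <- split_grouped(ds, seed = seed)
  tr <- which(ds$split == "train")
  if (length(unique(ds$labels[tr])) < 2)
    stop("degenerate single-class training data")
  Xtr <- ds$features[tr, , drop = FALSE]
  ytr <- factor(ds$labels[tr], levels = c(FALSE, TRUE))

  if (engine == "ranger") {
    # balanced class weights: inverse class frequency, factor-level order
    fit <- ranger::ranger(
      x = Xtr, y = ytr, num.trees = num_trees, max.depth = max_depth,
      probability = TRUE, class.weights = as.numeric(1 / table(ytr)),
      seed = seed, num.threads = 1)
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("the xgboost package is required for engine = 'xgboost'")
    spw <- sum(ytr == "FALSE") / max(1, sum(ytr == "TRUE"))
    fit <- xgboost::xgboost(
      data = Xtr, label = as.numeric(ytr == "TRUE"),
      nrounds = num_trees, max_depth = min(max_depth, 6),
      objective = "binary:logistic", scale_pos_weight = spw,
      verbose = 0, nthread = 1)
  }
  obj <- structure(list(engine = engine, fit = fit,
                        feature_names = colnames(ds$features),
                        feature_version = ds$feature_version,
                        seed = seed, metrics = NULL),
                   class = "region_classifier")
  te <- which(ds$split == "test" & ds$group != "synthetic")
  if (length(te) && length(unique(ds$labels[te])) == 2) {
    p <- predict(obj, ds$features[te, , drop = FALSE])
    obj$metrics <- classification_metrics(ds$labels[te], p, ds$group[te])
  }
  obj
}

# held-out metrics under the deployment inference rule: within each image
# the highest-probability region is called positive, all others negative
classification_metrics <- function(y, p, group) {
  pred <- logical(length(y))
  for (g in unique(group)) {
    i <- which(group == g)
    pred[i[which.max(p[i])]] <- TRUE
  }
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  list(auc = auc,
       precision = tp / max(1, tp + fp),
       recall = tp / max(1, tp + fn),
       f1 = 2 * tp / max(1, 2 * tp + fp + fn),
       specificity = tn / max(1, tn + fp),
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(truth = c("pos", "neg"),
                                          pred = c("pos", "neg"))))
}

#' @export
predict.region_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "region_dataset")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature name/version mismatch: classifier was trained on ",
         object$feature_version)
  if (object$engine == "ranger") {
    pr <- predict(object$fit, data = as.data.frame(newdata),
                  num.threads = 1)$predictions
    unname(pr[, "TRUE"])
  } else {
    as.numeric(predict(object$fit, newdata))
  }
}

#' @export
print.region_classifier <- function(x, ...) {
  cat("region_classifier (", x$engine, ")\n", sep = "")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  held-out: AUC %.3f | precision %.3f | recall %.3f | F1 %.3f | specificity %.3f\n",
                m$auc, m$precision, m$recall, m$f1, m$specificity))
  }
  invisible(x)
}

#' Select the recommended entry region
#'
#' Argmax of predicted probability; ties broken by larger area, then by
#' the centroid nearest the image centre. With `model = NULL` a
#' heuristic (area x mean tissue-attenuation intensity) is used instead.
#'
#' @param model a `region_classifier`, or `NULL` for the heuristic.
#' @param regions list of candidate regions carrying `features`.
#' @return list: `index`, `region`, `probabilities`.
#' @export
select_region <- function(model, regions) {
  if (!length(regions)) stop("no feasible path: empty region list")
  if (is.null(model)) {
    p <- vapply(regions, function(r) r$area * r$g_mean, numeric(1))
    p <- if (max(p) > 0) p / max(p) else p
  } else {
    feats <- t(vapply(regions, function(r) r$features, numeric(50)))
    colnames(feats) <- region_feature_names()
    p <- predict(model, feats)
  }
  area <- vapply(regions, function(r) r$area, numeric(1))
  ctr <- regions[[1]]$img_dim / 2 + 0.5
  d2 <- vapply(regions, function(r) sum((r$centroid - ctr)^2), numeric(1))
  ord <- order(-p, -area, d2)
  list(index = ord[1], region = regions[[ord[1]]], probabilities = p)
}

# run the pipeline from an isotropic volume + query to candidate regions
illumination_pipeline <- function(vol, q, cfg, resolution_deg = 1,
                                  thresholds = c(r = 0, g = 0.05, b = 0),
                                  min_area = NULL) {
  roi <- crop_roi(vol, q)
  roi <- remove_no_skin_directions(roi, cfg$skin_label, resolution_deg)
  field <- build_absorption_field(roi, cfg)
  field <- dilate_obstacles(field, cfg$obstacle_margin_mm)
  shell <- compute_shell_map(roi, field, q, resolution_deg,
                             weights = cfg$weights)
  img <- project_sinusoidal(shell)
  regions <- segment_safe_regions(img, thresholds, min_area)
  if (length(regions)) {
    feats <- features_matrix(regions, img)
    for (i in seq_along(regions)) regions[[i]]$features <- feats[i, ]
  }
  list(roi = roi, field = field, shell = shell, img = img,
       regions = regions)
}

#' Plan a straight biopsy trajectory
#'
#' Runs the full pipeline: isotropic resampling, needle-length ROI
#' extraction, skin-reach screening, absorption-field construction with
#' obstacle dilation, spherical illumination, sinusoidal RGB projection,
#' safe-region segmentation, feature extraction, region recommendation
#' (classifier, heuristic, or manual choice), erosion of the chosen region
#' to a single entry pixel, and reverse mapping to the 3-D skin entry
#' point. Clinical path metrics are attached: depth (mm), the angle
#' between the needle and the skin surface (degrees; 90 is perpendicular
#' insertion), and the minimum distance (mm) to any un-dilated obstacle,
#' sampled every half voxel along the path against the exact distance
#' transform.
#'
#' @param vol a [label_volume()].
#' @param target world-mm target point (or `NULL` to use the volume's
#'   `target` attribute, e.g. for phantoms).
#' @param cfg a [tissue_config()].
#' @param needle_mm needle length R (mm).
#' @param model optional `region_classifier`; `NULL` uses the heuristic.
#' @param resolution_deg shell/projection resolution (degrees).
#' @param thresholds,min_area region segmentation parameters.
#' @param manual_region optional integer: bypass the recommender and use
#'   this region index (manual selection mode).
#' @return an object of class `needle_plan`. If no feasible path exists
#'   the object has `feasible = FALSE` and a structured `reason`
#'   (`"no_skin_reach"`, `"full_occlusion"` or `"no_region"`).
#' @export
plan_path <- function(vol, target = NULL, cfg, needle_mm = 153,
                      model = NULL, resolution_deg = 1,
                      thresholds = c(r = 0, g = 0.05, b = 0),
                      min_area = NULL, manual_region = NULL) {
  stopifnot(inherits(vol, "label_volume"), inherits(cfg, "tissue_config"))
  if (is.null(target)) target <- attr(vol, "target")
  if (is.null(target)) stop("no target given and volume has no target attribute")
  if (!any(vol$labels == cfg$skin_label))
    stop("no skin voxels in the volume: degenerate mask (skin label ",
         cfg$skin_label, ")")
  vol <- resample_isotropic(vol)
  q <- needle_query(target, needle_mm)
  pipe <- illumination_pipeline(vol, q, cfg, resolution_deg, thresholds,
                                min_area)
  shell <- pipe$shell

  fail <- function(reason) {
    structure(list(feasible = FALSE, reason = reason, target = target,
                   needle_mm = needle_mm, shell = shell,
                   projection = pipe$img, regions = pipe$regions),
              class = "needle_plan")
  }
  # skin reach is judged by the screen (which ignores opacity), so a
  # target encased in bone reports occlusion, not missing skin
  if (!any(pipe$roi$skin_screen$ok)) return(fail("no_skin_reach"))
  if (!any(shell$iobs == 1L)) return(fail("full_occlusion"))
  if (!length(pipe$regions)) return(fail("no_region"))

  sel <- if (!is.null(manual_region)) {
    if (manual_region < 1 || manual_region > length(pipe$regions))
      stop("manual_region out of range")
    list(index = manual_region, region = pipe$regions[[manual_region]],
         probabilities = rep(NA_real_, length(pipe$regions)))
  } else {
    select_region(model, pipe$regions)
  }

  pixel <- erode_to_point(sel$region)
  ep <- pixel_to_entry_point(pipe$img, shell, pixel)

  # angle between needle and skin plane = 90 deg - angle to the normal
  ang <- angles_from_dir(ep$direction)
  i <- round((90 - ang[1, "phi"]) / shell$resolution) + 1
  j <- (round((ang[1, "lambda"] + 180) / shell$resolution) %%
          length(shell$lambda)) + 1
  cos_theta <- shell$aref[i, j]
  skin_angle <- asin(pmin(1, pmax(0, cos_theta))) * 180 / pi

  # minimum clearance from un-dilated obstacles along the path
  step <- 0.5 * pipe$field$spacing[1]
  ts <- seq(0, ep$depth_mm, by = step)
  pts <- sweep(outer(ts, ep$direction), 2, shell$target, "+")
  idx <- round(sweep(sweep(pts, 2, pipe$field$origin, "-"), 2,
                     pipe$field$spacing, "/")) + 1
  d <- dim(pipe$field$k)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  lin <- idx[ok, 1] + d[1] * ((idx[ok, 2] - 1) + d[2] * (idx[ok, 3] - 1))
  min_dist <- suppressWarnings(min(pipe$field$obstacle_distance[lin]))

  structure(list(feasible = TRUE, reason = "ok",
                 entry = ep$entry, target = shell$target,
                 direction = ep$direction,
                 depth_mm = ep$depth_mm,
                 skin_angle_deg = skin_angle,
                 min_obstacle_mm = min_dist,
                 entry_pixel = pixel, region_index = sel$index,
                 probabilities = sel$probabilities,
                 shell = shell, projection = pipe$img,
                 regions = pipe$regions, field = pipe$field,
                 resolution = resolution_deg, needle_mm = needle_mm),
            class = "needle_plan")
}

#' @export
print.needle_plan <- function(x, ...) {
  if (!x$feasible) {
    cat("needle_plan: NO FEASIBLE PATH (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("needle_plan: feasible trajectory\n")
  cat(sprintf("  entry (mm):  %s\n",
              paste(sprintf("%.1f", x$entry), collapse = ", ")))
  cat(sprintf("  target (mm): %s\n",
              paste(sprintf("%.1f", x$target), collapse = ", ")))
  cat(sprintf("  depth: %.1f mm | skin angle: %.1f deg | obstacle clearance: %.1f mm\n",
              x$depth_mm, x$skin_angle_deg, x$min_obstacle_mm))
  cat(sprintf("  region %d of %d candidates\n", x$region_index,
              length(x$regions)))
  invisible(x)
}

#' @export
summary.needle_plan <- function(object, ...) {
  print(object)
  if (object$feasible) {
    cat("  probabilities:",
        paste(sprintf("%.3f", object$probabilities), collapse = " "), "\n")
    cat("  feasible shell fraction:",
        sprintf("%.1f%%", 100 * mean(object$shell$iobs == 1L)), "\n")
  }
  invisible(object)
}

#' @export
plot.needle_plan <- function(x, ...) {
  plot(x$projection,
       entry_pixel = if (x$feasible) x$entry_pixel else NULL, ...)
  invisible(x)
}

#' Build a labelled synthetic region corpus
#'
#' Generates `n_images` seeded phantoms, runs the illumination pipeline on
#' each, extracts candidate-region features, and labels them with the
#' rule-based annotator. The corpus emulates the study design of an
#' expert-annotated projection-image dataset, with the image id as the
#' leakage group.
#'
#' @param n_images number of phantoms.
#' @param seed corpus seed; phantom i uses `seed + 101 * i`.
#' @param resolution_deg shell/projection resolution (degrees).
#' @param needle_mm needle length (mm).
#' @param cfg tissue configuration (defaults to the phantom vocabulary).
#' @param flip_rate annotation label-flip noise (default 0).
#' @param spec_template a [phantom_spec()] supplying the geometry
#'   parameters (its seed is overridden per image).
#' @return a [region_dataset()].
#' @export
build_region_corpus <- function(n_images, seed = 1, resolution_deg = 2,
                                needle_mm = 153,
                                cfg = phantom_tissue_config(),
                                flip_rate = 0,
                                spec_template = phantom_spec()) {
  feats <- list(); labs <- list(); grp <- list()
  for (i in seq_len(n_images)) {
    sp <- spec_template
    sp$seed <- as.integer(seed + 101L * i)
    vol <- generate_phantom(sp)
    q <- needle_query(attr(vol, "target"), needle_mm)
    pipe <- illumination_pipeline(vol, q, cfg, resolution_deg)
    if (!length(pipe$regions)) next
    y <- annotate_regions_rulebased(pipe$regions, flip_rate = flip_rate,
                                    seed = sp$seed)
    f <- t(vapply(pipe$regions, function(r) r$features, numeric(50)))
    colnames(f) <- region_feature_names()
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- y
    grp[[length(grp) + 1L]] <- rep(i, length(y))
  }
  region_dataset(do.call(rbind, feats), unlist(labs), unlist(grp))
}
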