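# a small synthetic dataset with a linearly separable signal
toy_dataset <- function(n_images = 30, sep = TRUE, seed = 1) {
  set.seed(seed)
  rows <- list(); labs <- c(); grp <- c()
  nf <- 50
  for (g in seq_len(n_images)) {
    k <- sample(3:6, 1)
    X <- matrix(stats::rnorm(k * nf), k, nf)
    y <- rep(FALSE, k)
    y[sample(k, 1)] <- TRUE
    if (sep) X[y, 1] <- X[y, 1] + 8  # separable on feature 1
    rows[[g]] <- X; labs <- c(labs, y); grp <- c(grp, rep(g, k))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- region_feature_names()
  region_dataset(X, labs, grp)
}

test_that("grouped splits never leak an image across subsets", {
  ds <- split_grouped(toy_dataset(40), seed = 3)
  tab <- table(ds$group, ds$split)
  expect_true(all(rowSums(tab > 0) == 1))
  # 7:1:2 by image count
  n_by_split <- colSums(table(ds$group, ds$split) > 0)
  expect_equal(unname(n_by_split), c(28, 4, 8))
  # deterministic given the seed
  ds2 <- split_grouped(toy_dataset(40), seed = 3)
  expect_identical(ds$split, ds2$split)
})

test_that("SMOTE balances to parity with convex synthetic points", {
  set.seed(2)
  X <- matrix(stats::rnorm(110 * 50), 110, 50)
  colnames(X) <- region_feature_names()
  y <- c(rep(TRUE, 10), rep(FALSE, 100))
  ds <- region_dataset(X, y, seq_len(110))
  bal <- balance_training_set(ds, seed = 7)
  expect_equal(sum(bal$labels), sum(!bal$labels))   # 100 / 100
  syn <- bal$features[bal$group == "synthetic", , drop = FALSE]
  expect_equal(nrow(syn), 90)
  # every synthetic row is a convex combination of two minority rows
  minority <- X[y, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    found <- FALSE
    for (a in seq_len(nrow(minority))) {
      da <- s - minority[a, ]
      for (b in seq_len(nrow(minority))) {
        if (a == b) next
        dab <- minority[b, ] - minority[a, ]
        u <- sum(da * dab) / sum(dab * dab)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(da - u * dab)) < 1e-8) { found <- TRUE; break }
      }
      if (found) break
    }
    expect_true(found, info = paste("synthetic row", i))
  }
  # balanced input is returned unchanged
  ds_bal <- region_dataset(X[1:20, ], rep(c(TRUE, FALSE), 10), 1:20)
  expect_identical(balance_training_set(ds_bal, seed = 1), ds_bal)
  # fewer than two minority samples is an error
  ds_one <- region_dataset(X[1:11, ], c(TRUE, rep(FALSE, 10)), 1:11)
  expect_error(balance_training_set(ds_one, seed = 1), "minority")
})

test_that("a separable signal is learned perfectly, and only with signal", {
  ds <- split_grouped(toy_dataset(40, sep = TRUE), seed = 5)
  bal <- balance_training_set(ds, seed = 5)
  m <- train_region_classifier(bal, seed = 5)
  expect_gte(m$metrics$auc, 0.99)
  # training on permuted labels drops held-out AUC to chance
  ds0 <- ds
  set.seed(8)
  tr <- which(ds0$split == "train")
  ds0$labels[tr] <- sample(ds0$labels[tr])
  m0 <- train_region_classifier(balance_training_set(ds0, seed = 8),
                                seed = 8)
  expect_lt(abs(m0$metrics$auc - 0.5), 0.25)
})

test_that("prediction refuses mismatched feature versions", {
  ds <- split_grouped(toy_dataset(20), seed = 1)
  m <- train_region_classifier(balance_training_set(ds, seed = 1), seed = 1)
  bad <- ds$features
  colnames(bad)[1] <- "not_a_feature"
  expect_error(predict(m, bad), "mismatch")
})

test_that("region selection takes the argmax with documented tie-breaks", {
  mk <- function(area, centroid, feats) {
    structure(list(area = area, centroid = centroid, g_mean = 0.5,
                   img_dim = c(91, 180), features = feats),
              class = "candidate_region")
  }
  # probabilities {0.9, 0.2}: first region wins
  ds <- split_grouped(toy_dataset(20), seed = 2)
  m <- train_region_classifier(balance_training_set(ds, seed = 2), seed = 2)
  f_hi <- stats::setNames(rep(0, 50), region_feature_names())
  f_hi["area"] <- 1; f_hi[1] <- 10   # strong positive signal (feature 1)
  f_lo <- stats::setNames(rep(0, 50), region_feature_names())
  sel <- select_region(m, list(mk(10, c(5, 5), f_hi),
                               mk(10, c(5, 5), f_lo)))
  expect_equal(sel$index, 1)
  expect_length(sel$probabilities, 2)
  # single region: selected regardless of probability
  expect_equal(select_region(m, list(mk(10, c(5, 5), f_lo)))$index, 1)
  # exact tie (heuristic mode): larger area wins, then centre proximity
  sel2 <- select_region(NULL, list(mk(10, c(5, 5), f_lo),
                                   mk(50, c(80, 80), f_lo)))
  expect_equal(sel2$index, 2)
  ctr <- c(91, 180) / 2 + 0.5
  sel3 <- select_region(NULL, list(mk(50, ctr + 40, f_lo),
                                   mk(50, ctr + 2, f_lo)))
  expect_equal(sel3$index, 2)
  expect_error(select_region(m, list()), "no feasible")
})

test_that("plan_path returns structured infeasibility reasons", {
  cfg <- phantom_tissue_config()
  # target fully encased in bone: full occlusion
  vol <- ball_volume(n = 48, spacing = 2, body_r = 40,
                     opaque_shell = c(20, 26))
  plan <- plan_path(vol, attr(vol, "target"), ball_config(),
                    needle_mm = 60, resolution_deg = 5)
  expect_false(plan$feasible)
  expect_equal(plan$reason, "full_occlusion")
  print(plan)  # smoke: printing an infeasible plan works

  # needle shorter than the distance to any skin: no skin reach
  vol2 <- ball_volume(n = 60, spacing = 2, body_r = 55)
  plan2 <- plan_path(vol2, attr(vol2, "target"), ball_config(),
                     needle_mm = 30, resolution_deg = 5)
  expect_false(plan2$feasible)
  expect_equal(plan2$reason, "no_skin_reach")
})

test_that("plan metrics are self-consistent and manual mode works", {
  vol <- generate_phantom(phantom_spec(seed = 14))
  cfg <- phantom_tissue_config()
  plan <- plan_path(vol, cfg = cfg, resolution_deg = 2)
  expect_true(plan$feasible)
  # depth equals the entry-target distance
  expect_equal(plan$depth_mm, sqrt(sum((plan$entry - plan$target)^2)),
               tolerance = 1e-6)
  expect_lte(plan$depth_mm, 153)
  expect_gte(plan$min_obstacle_mm, cfg$obstacle_margin_mm)
  expect_true(plan$skin_angle_deg >= 0 && plan$skin_angle_deg <= 90)
  # manual region choice bypasses the recommender
  plan_m <- plan_path(vol, cfg = cfg, resolution_deg = 2,
                      manual_region = length(plan$regions))
  expect_true(plan_m$feasible)
  expect_equal(plan_m$region_index, length(plan$regions))
  expect_error(plan_path(vol, cfg = cfg, resolution_deg = 2,
                         manual_region = 99), "out of range")
})

test_that("a perpendicular flat-skin geometry reports a ~90 degree angle", {
  # body slab with flat skin on top, target right below the skin centre
  n <- 64
  arr <- array(0L, rep(n, 3))
  arr[8:(n - 7), 8:(n - 7), 8:40] <- 1L
  arr[8:(n - 7), 8:(n - 7), 40] <- 2L  # flat skin plane
  # make side/bottom faces skin too so only the top plane is relevant via
  # proximity (target sits just below the top)
  vol <- label_volume(arr, spacing = c(2, 2, 2))
  # target 30 mm under the top skin plane (world z = 78); needle 32 mm
  # leaves only a ~20 degree feasible cap about the vertical
  tgt <- c(63, 63, 48)
  plan <- plan_path(vol, tgt, ball_config(), needle_mm = 32,
                    resolution_deg = 2)
  expect_true(plan$feasible)
  # the recommended path exits through the flat top: angle near 90 deg
  expect_gt(plan$skin_angle_deg, 80)
  expect_equal(drop(plan$direction %*% c(0, 0, 1)), 1, tolerance = 0.1)
})
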