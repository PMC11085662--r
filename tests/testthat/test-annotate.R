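# brute-force oracle: try every split between distinct sorted depth values,
# score by between-group variance, return the nearer group's median (or the
# overall median if the groups are closer than 5% of the map range)
oracle_depth <- function(depth_map, bbox) {
  vals <- as.numeric(depth_map[(bbox[2] + 1):bbox[4], (bbox[1] + 1):bbox[3]])
  u <- sort(unique(vals))
  if (length(u) == 1) return(u)
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(vals)
  score <- vapply(mids, function(t) {
    g1 <- vals[vals <= t]; g2 <- vals[vals > t]
    (length(g1) / n) * (length(g2) / n) * (mean(g1) - mean(g2))^2
  }, numeric(1))
  t <- mids[which.max(score)]
  g1 <- vals[vals <= t]; g2 <- vals[vals > t]
  if (abs(median(g2) - median(g1)) < 0.05 * (max(depth_map) - min(depth_map)))
    return(median(vals))
  median(g1)
}

test_that("bbox area and center handle real, degenerate and full boxes", {
  expect_equal(bbox_area(c(10, 10, 20, 30)), 200)
  expect_equal(bbox_area(c(0, 0, 0, 0)), 0)
  expect_equal(bbox_area(c(0, 0, 256, 256)), 65536)
  expect_error(bbox_area(c(20, 10, 10, 30)), "inverted")
  expect_equal(unname(bbox_center(c(10, 10, 20, 30))), c(15, 20))
  expect_equal(unname(bbox_center(c(5, 5, 5, 5))), c(5, 5))
  expect_equal(unname(bbox_center(c(0, 0, 256, 256))), c(128, 128))
})

test_that("object depth is the nearer-group median, not the box mean", {
  dm <- matrix(8, 40, 40)
  expect_equal(estimate_object_depth(matrix(3, 10, 10), c(0, 0, 10, 10)), 3)

  dm1 <- dm; dm1[11:30, 11:20] <- 2          # half object, half background
  expect_equal(estimate_object_depth(dm1, c(10, 10, 30, 30)), 2)
  expect_equal(oracle_depth(dm1, c(10, 10, 30, 30)), 2)

  dm2 <- dm; dm2[11:20, 11:14] <- 2          # object covers only 10%
  bb <- c(10, 10, 30, 30)
  expect_equal(estimate_object_depth(dm2, bb), 2)
  expect_equal(estimate_object_depth(dm2, bb), oracle_depth(dm2, bb))
  expect_gt(mean(dm2[11:30, 11:30]), 7)       # the naive mean would be wrong
})

test_that("depth estimator matches the brute-force split on noisy maps", {
  set.seed(21)
  for (k in 1:20) {
    dm <- matrix(8 + rnorm(900, sd = 0.1), 30, 30)
    w <- sample(5:20, 1)
    d0 <- runif(1, 1, 5)
    dm[5 + seq_len(w), 5 + seq_len(w)] <- d0 + rnorm(w * w, sd = 0.05)
    bb <- c(3, 3, min(30, 7 + w), min(30, 7 + w))
    expect_equal(estimate_object_depth(dm, bb), oracle_depth(dm, bb),
                 tolerance = 1e-12)
  }
})

test_that("depth estimate is within 2% of truth on clean synthetic scenes", {
  set.seed(31)
  tried <- 0
  for (k in 1:30) {
    s <- generate_scene(scene_spec(n_objects = 1, noise_sd = 0))
    r <- s$objects[1, ]
    cover <- sum(s$depth_map[(r$y1 + 1):r$y2, (r$x1 + 1):r$x2] == r$depth) /
      r$area_px
    if (cover < 0.6) next
    tried <- tried + 1
    est <- estimate_object_depth(s$depth_map, c(r$x1, r$y1, r$x2, r$y2))
    expect_lt(abs(est - r$depth) / r$depth, 0.02)
  }
  expect_gt(tried, 10)
})

test_that("actual size applies the inverse-square depth transfer", {
  expect_equal(actual_size(100, 2, 1), 400)
  expect_equal(actual_size(100, 1, 1), 100)
  expect_error(actual_size(100, -1, 1), "depth")
  # same physical object rendered at d and 2d has equal actual size (+-5%);
  # the object must be large enough that +-1 px edge rounding stays small
  spec <- tiny_spec(image_side = 256L)
  a <- render_objects(spec, obj_row(depth = 1.2, phys_size = 120,
                                    xc = 128, yc = 128))$objects
  b <- render_objects(spec, obj_row(depth = 2.4, phys_size = 120,
                                    xc = 128, yc = 128))$objects
  sa <- actual_size(a$area_px, a$depth, 1)
  sb <- actual_size(b$area_px, b$depth, 1)
  expect_lt(abs(sa - sb) / sa, 0.05)
})

test_that("labeling rule: size and depth criteria, padding, degenerate input", {
  params <- labeling_params(d_ref = 1, alpha = 0.5, beta = 0.75)
  one <- data.frame(area_px = 100, depth = 2, actual_size = 400)
  expect_equal(label_primariness(one, params, d_max = 8),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # equal actual sizes; only the nearer one passes the depth criterion
  two <- data.frame(area_px = c(100, 25), depth = c(2, 7),
                    actual_size = c(400, 400))
  expect_equal(label_primariness(two, params, d_max = 8)[1:2],
               c(TRUE, FALSE))
  pads <- data.frame(area_px = numeric(0), depth = numeric(0),
                     actual_size = numeric(0))
  expect_equal(label_primariness(pads, params, d_max = 8), rep(FALSE, 5))
})

test_that("labels are invariant to re-rendering at another depth", {
  # same physical scene, second object moved deeper but within beta * d_max
  params <- labeling_params()
  a <- data.frame(area_px = c(400, 300), depth = c(2, 2),
                  actual_size = c(1600, 1200))
  b <- data.frame(area_px = c(400, 75), depth = c(2, 4),
                  actual_size = c(1600, 1200))
  expect_equal(label_primariness(a, params, d_max = 8),
               label_primariness(b, params, d_max = 8))
})

test_that("enlarging an object's actual size never flips it off", {
  set.seed(77)
  params <- labeling_params()
  for (k in 1:50) {
    n <- sample(1:5, 1)
    rec <- data.frame(area_px = runif(n, 10, 500), depth = runif(n, 1, 7))
    rec$actual_size <- actual_size(rec$area_px, rec$depth, 1)
    before <- label_primariness(rec, params, d_max = 8)
    i <- sample(n, 1)
    rec$actual_size[i] <- rec$actual_size[i] * runif(1, 1, 3)
    after <- label_primariness(rec, params, d_max = 8)
    expect_true(after[i] >= before[i])
  }
})

test_that("annotate_records reproduces generator ground truth on clean scenes", {
  set.seed(55)
  ok <- 0; tot <- 0
  for (k in 1:15) {
    spec <- scene_spec(n_objects = sample(1:4, 1), noise_sd = 0)
    s <- generate_scene(spec)
    if (nrow(s$objects) == 0) next
    raw <- s$objects[, c("class_id", "x1", "y1", "x2", "y2", "score")]
    ann <- annotate_records(raw, s$depth_map,
                            labeling_params(d_ref = spec$depth_range[1]))
    tot <- tot + nrow(ann)
    ok <- ok + sum(ann$primary ==
                     s$truth_labels[seq_len(nrow(ann))])
  }
  expect_gt(ok / tot, 0.9)   # estimated depths occasionally flip borderline objects
})
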