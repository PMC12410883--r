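test_that("identical masks score perfect overlap", {
  m <- disk_mask(60, 60, 30, 30, 15)
  pm <- pixel_metrics(m, m, 17.28)
  expect_equal(pm$iou, 1)
  expect_equal(pm$dice, 1)
  expect_equal(pm$hausdorff95_um, 0)
  empty <- matrix(FALSE, 60, 60)
  pm0 <- pixel_metrics(empty, empty, 17.28)
  expect_equal(pm0$iou, 1); expect_equal(pm0$hausdorff95_um, 0)
  pm1 <- pixel_metrics(m, empty, 17.28)
  expect_equal(pm1$iou, 0); expect_true(is.infinite(pm1$hausdorff95_um))
})

test_that("half-overlapping squares give the counted IoU and Dice", {
  a <- matrix(FALSE, 40, 40); a[11:20, 11:20] <- TRUE
  b <- matrix(FALSE, 40, 40); b[11:20, 16:25] <- TRUE
  pm <- pixel_metrics(a, b, 17.28)
  expect_equal(pm$iou, 1 / 3)
  expect_equal(pm$dice, 0.5)
})

test_that("the Dice-IoU identity holds on random masks", {
  set.seed(61)
  for (i in 1:15) {
    a <- matrix(runif(900) < 0.4, 30, 30)
    b <- matrix(runif(900) < 0.4, 30, 30)
    pm <- pixel_metrics(a, b, 17.28)
    expect_equal(pm$dice, 2 * pm$iou / (1 + pm$iou), tolerance = 1e-9)
    pm_swap <- pixel_metrics(b, a, 17.28)
    expect_equal(pm_swap$iou, pm$iou)
    expect_equal(pm_swap$hausdorff95_um, pm$hausdorff95_um)
  }
})

test_that("HD95 matches a brute-force boundary-distance oracle", {
  a <- disk_mask(50, 50, 20, 25, 10)
  b <- disk_mask(50, 50, 26, 25, 10)
  pm <- pixel_metrics(a, b, 1000)  # 1 um pixels for readability
  boundary <- function(m) {
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(m * 1),
                                            EBImage::makeBrush(3, "box"))) > 0.5
    which(m & !er, arr.ind = TRUE)
  }
  ba <- boundary(a); bb <- boundary(b)
  d_ab <- apply(ba, 1, function(p) min(sqrt((bb[, 1] - p[1])^2 +
                                            (bb[, 2] - p[2])^2)))
  d_ba <- apply(bb, 1, function(p) min(sqrt((ba[, 1] - p[1])^2 +
                                            (ba[, 2] - p[2])^2)))
  expect_equal(pm$hausdorff95_um, quantile(c(d_ab, d_ba), 0.95,
                                           names = FALSE), tolerance = 1e-9)
})

make_pair_maps <- function(boxes_gt, boxes_pred, nx = 80, ny = 80) {
  gt <- matrix(0L, nx, ny); pred <- matrix(0L, nx, ny)
  for (i in seq_along(boxes_gt)) {
    b <- boxes_gt[[i]]; gt[b[1]:b[2], b[3]:b[4]] <- i
  }
  for (i in seq_along(boxes_pred)) {
    b <- boxes_pred[[i]]; pred[b[1]:b[2], b[3]:b[4]] <- i
  }
  list(gt = instance_maps(gt, matrix(0L, nx, ny), 17.28),
       pred = instance_maps(pred, matrix(0L, nx, ny), 17.28))
}

test_that("a perfect prediction matches every fiber with no FP/FN", {
  cfg <- phantom_config(fiber_count = 5, canvas = c(400, 400), seed = 62)
  ph <- generate_phantom(cfg)
  mt <- match_instances(ph$instances, ph$instances)
  expect_equal(nrow(mt$pairs), 5)
  expect_equal(mt$pairs$overlap_gt, rep(1, 5))
  expect_length(mt$false_positives, 0)
  expect_length(mt$false_negatives, 0)
})

test_that("a missing prediction is exactly one false negative", {
  mm <- make_pair_maps(
    boxes_gt = list(c(5, 14, 5, 14), c(30, 39, 30, 39)),
    boxes_pred = list(c(5, 14, 5, 14)))
  mt <- match_instances(mm$pred, mm$gt)
  expect_equal(nrow(mt$pairs), 1)
  expect_length(mt$false_positives, 0)
  expect_equal(mt$false_negatives, 2L)
})

test_that("overlap at or below 40 percent yields an FP/FN pair, above matches", {
  # 10x10 squares overlapping in a 10x4 strip: fraction 0.40, not a match
  mm40 <- make_pair_maps(boxes_gt = list(c(11, 20, 11, 20)),
                         boxes_pred = list(c(11, 20, 17, 26)))
  mt40 <- match_instances(mm40$pred, mm40$gt, threshold = 0.40)
  expect_equal(nrow(mt40$pairs), 0)
  expect_equal(mt40$false_positives, 1L)
  expect_equal(mt40$false_negatives, 1L)
  # 10x5 overlap: fraction 0.50 on both sides, a match
  mm50 <- make_pair_maps(boxes_gt = list(c(11, 20, 11, 20)),
                         boxes_pred = list(c(11, 20, 16, 25)))
  mt50 <- match_instances(mm50$pred, mm50$gt, threshold = 0.40)
  expect_equal(nrow(mt50$pairs), 1)
})

test_that("an engulfing blob fails the two-sided overlap rule but passes gt-sided", {
  mm <- make_pair_maps(boxes_gt = list(c(11, 20, 11, 20)),
                       boxes_pred = list(c(1, 60, 1, 60)))
  mt <- match_instances(mm$pred, mm$gt)
  expect_equal(nrow(mt$pairs), 0)
  mt_gt <- match_instances(mm$pred, mm$gt, denominator = "gt")
  expect_equal(nrow(mt_gt$pairs), 1)
})

test_that("matching is stable under relabeling and translation", {
  cfg <- phantom_config(fiber_count = 6, canvas = c(400, 400), seed = 63)
  ph <- generate_phantom(cfg)
  a <- ph$instances$axon; m <- ph$instances$myelin
  perm <- c(4L, 6L, 1L, 3L, 2L, 5L)
  relab <- function(x) { y <- x; y[x > 0] <- perm[x[x > 0]]; y }
  pred <- instance_maps(relab(a), relab(m), 17.28)
  mt <- match_instances(pred, ph$instances)
  expect_equal(nrow(mt$pairs), 6)
  expect_equal(mt$pairs$pred_id[order(mt$pairs$gt_id)], perm)
  expect_length(mt$false_positives, 0)
})

test_that("paired agreement reports exact arithmetic on constructed deltas", {
  gt <- rbind(make_record(1, axon = 0.5), make_record(2, axon = 0.7))
  pred <- rbind(make_record(1, axon = 0.4), make_record(2, axon = 0.8))
  pairs <- data.frame(gt_id = 1:2, pred_id = 1:2)
  agr <- paired_agreement(pred, gt, pairs, "axon_minor_um")
  expect_equal(agr$mean_difference, 0)
  expect_equal(agr$mae, 0.1)
  expect_equal(unname(agr$loa["upper"]), 1.96 * sd(c(0.1, -0.1)))
  ident <- paired_agreement(gt, gt, pairs, "axon_minor_um")
  expect_equal(ident$mean_difference, 0)
  expect_equal(unname(ident$loa), c(0, 0))
  expect_equal(ident$mae, 0)
  expect_error(paired_agreement(pred, gt, pairs[0, ], "axon_minor_um"),
               "empty match set")
  expect_error(paired_agreement(pred, gt, pairs, "nope"), "not found")
})

test_that("limits of agreement cover ~95 percent of normal deltas", {
  set.seed(64)
  n <- 10000
  gt <- make_record(1)[rep(1, n), ]
  gt$fiber_id <- 1:n
  pred <- gt
  pred$axon_minor_um <- gt$axon_minor_um - rnorm(n, mean = 0.02, sd = 0.05)
  pairs <- data.frame(gt_id = 1:n, pred_id = 1:n)
  agr <- paired_agreement(pred, gt, pairs, "axon_minor_um")
  coverage <- mean(agr$deltas >= agr$loa["lower"] &
                   agr$deltas <= agr$loa["upper"])
  expect_gt(coverage, 0.94)
  expect_equal(coverage, 0.95, tolerance = 0.01)
  expect_lt(abs(agr$mean_difference - 0.02), 0.003)
})
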