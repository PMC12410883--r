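test_that("contrast enhancement preserves range and degenerate inputs", {
  const <- matrix(0.4, 64, 64)
  expect_identical(preprocess_contrast(const), const)
  set.seed(31)
  img <- matrix(runif(128 * 128, 0.2, 0.6), 128, 128)
  out <- preprocess_contrast(img)
  expect_gte(min(out), min(img) - 1e-12)
  expect_lte(max(out), max(img) + 1e-12)
  # two-level step image: both levels remain separable
  step <- matrix(0.2, 64, 64); step[33:64, ] <- 0.8
  outs <- preprocess_contrast(step)
  expect_gt(min(outs[33:64, ]), max(outs[1:32, ]))
  expect_error(preprocess_contrast(array(0, c(4, 4, 2))), "2-D")
})

test_that("thresholding follows the per-pixel argmax rule", {
  sc <- array(0, c(8, 8, 3))
  sc[, , 1] <- 1
  sc[4, 4, ] <- c(0.2, 0.5, 0.3)  # axon under argmax
  sc[5, 5, ] <- c(0.2, 0.3, 0.5)
  m <- threshold_semantic(semantic_map(sc, 17.28), morph_radius = 0,
                          min_object_area = 1)
  expect_true(m$axon[4, 4]); expect_false(m$myelin[4, 4])
  expect_true(m$myelin[5, 5])
  expect_equal(sum(m$axon), 1)
})

test_that("a one-hot phantom map thresholds back to its ground-truth masks", {
  cfg <- phantom_config(fiber_count = 8, canvas = c(512, 512), seed = 32)
  ph <- generate_phantom(cfg)
  m <- threshold_semantic(ph$semantic, morph_radius = 0, min_object_area = 1)
  expect_identical(m$axon, ph$instances$axon > 0)
  expect_identical(m$myelin, ph$instances$myelin > 0)
  # default binary clean-up is near-identity on smooth ellipses
  md <- threshold_semantic(ph$semantic)
  iou <- sum(md$myelin & ph$instances$myelin > 0) /
    sum(md$myelin | ph$instances$myelin > 0)
  expect_gt(iou, 0.99)
})

test_that("specks below the minimum object area are removed", {
  sc <- array(0, c(64, 64, 3)); sc[, , 1] <- 1
  sc[10:25, 10:25, 3] <- 1; sc[10:25, 10:25, 1] <- 0   # real object
  sc[40, 40:41, 3] <- 1; sc[40, 40:41, 1] <- 0          # 2-px speck
  m <- threshold_semantic(semantic_map(sc, 17.28), morph_radius = 0,
                          min_object_area = 10)
  lab <- EBImage::bwlabel(EBImage::Image(m$myelin * 1))
  expect_equal(max(lab), 1)
  expect_false(m$myelin[40, 40])
})

test_that("an isolated annulus with core yields exactly one instance", {
  axon <- disk_mask(120, 120, 60, 60, 10)
  myelin <- annulus_mask(120, 120, 60, 60, 10, 20)
  inst <- separate_instances(axon, myelin, pixel_size_nm = 17.28)
  expect_equal(instance_ids(inst), 1L)
  expect_true(all(inst$axon[axon] == 1L))
  expect_true(all(inst$myelin[myelin] == 1L))
})

test_that("tangent equal disks split along the tangent perpendicular", {
  none <- matrix(FALSE, 120, 120)
  d1 <- disk_mask(120, 120, 40, 60, 20)
  d2 <- disk_mask(120, 120, 80, 60, 20)
  inst <- separate_instances(none, d1 | d2, pixel_size_nm = 17.28)
  expect_length(instance_ids(inst), 2)
  L <- inst$myelin
  w1 <- which(L == 1L, arr.ind = TRUE); w2 <- which(L == 2L, arr.ind = TRUE)
  split_x <- c(max(pmin(max(w1[, 1]), max(w2[, 1]))),
               min(pmax(min(w1[, 1]), min(w2[, 1]))))
  expect_true(all(abs(split_x - 60) <= 2))
})

test_that("the watershed partition conserves pixels", {
  cfg <- phantom_config(fiber_count = 12, canvas = c(512, 512), seed = 33,
                        degradation = degradation_params(kissing_fraction = 0.5))
  ph <- generate_phantom(cfg)
  m <- threshold_semantic(ph$semantic)
  inst <- separate_instances(m$axon, m$myelin, pixel_size_nm = 17.28)
  un <- m$axon | m$myelin
  expect_equal(sum(inst$axon > 0) + sum(inst$myelin > 0), sum(un))
  per_id <- tabulate(c(inst$axon[inst$axon > 0], inst$myelin[inst$myelin > 0]))
  expect_equal(sum(per_id), sum(un))
})

test_that("instance counts match fiber counts on undegraded phantoms", {
  cfg <- phantom_config(fiber_count = 20, canvas = c(700, 700), seed = 34)
  ph <- generate_phantom(cfg)
  m <- threshold_semantic(ph$semantic)
  inst <- separate_instances(m$axon, m$myelin, pixel_size_nm = 17.28)
  expect_length(instance_ids(inst), 20)
})

test_that("segmentation is invariant to translation and 90-degree rotation", {
  cfg <- phantom_config(fiber_count = 6, canvas = c(360, 360), seed = 35)
  ph <- generate_phantom(cfg)
  m <- threshold_semantic(ph$semantic)
  inst <- separate_instances(m$axon, m$myelin, pixel_size_nm = 17.28)
  sizes <- function(x) sort(tabulate(c(x$axon[x$axon > 0],
                                       x$myelin[x$myelin > 0])))
  shift <- function(mm, dx, dy) {  # translate into a larger canvas
    out <- matrix(FALSE, nrow(mm) + dx, ncol(mm) + dy)
    out[(1 + dx):(nrow(mm) + dx), (1 + dy):(ncol(mm) + dy)] <- mm
    out
  }
  inst_t <- separate_instances(shift(m$axon, 7, 5), shift(m$myelin, 7, 5),
                               pixel_size_nm = 17.28)
  expect_equal(sizes(inst_t), sizes(inst))
  rot <- function(mm) t(mm)[ncol(mm):1, ]  # 90-degree rotation
  inst_r <- separate_instances(rot(m$axon), rot(m$myelin),
                               pixel_size_nm = 17.28)
  expect_equal(sizes(inst_r), sizes(inst))
})

test_that("empty masks give empty instance maps without error", {
  none <- matrix(FALSE, 50, 50)
  inst <- separate_instances(none, none, pixel_size_nm = 17.28)
  expect_length(instance_ids(inst), 0)
})

test_that("the plausibility filter rejects with machine-readable reasons", {
  recs <- rbind(make_record(1, g = 1.2), make_record(2), make_record(3, g = 0.4))
  out <- filter_instances(recs, filter_rule())
  expect_equal(nrow(out$kept), 2)
  expect_equal(out$rejected$fiber_id, 1L)
  expect_equal(out$rejected$reason, "g_ratio_out_of_range")

  empty <- filter_instances(make_record(1)[0, ], filter_rule())
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)

  recs10 <- do.call(rbind, lapply(1:10, function(i)
    make_record(i, axon = ifelse(i <= 3, 20, 0.6), outer = 22)))
  out10 <- filter_instances(recs10, filter_rule(max_outer_diameter = 30))
  expect_equal(nrow(out10$kept), 7)
  expect_true(all(out10$rejected$reason == "axon_too_large"))

  flagged <- rbind(make_record(1, qc = "no_myelin"),
                   make_record(2, qc = "border_touch"))
  outf <- filter_instances(flagged, filter_rule())
  expect_setequal(outf$rejected$reason, c("no_myelin", "border_touch"))
  outk <- filter_instances(flagged, filter_rule(border_policy = "keep"))
  expect_equal(outk$rejected$reason, "no_myelin")
})

test_that("loosening filter bounds never decreases the kept count", {
  set.seed(36)
  recs <- do.call(rbind, lapply(1:40, function(i)
    make_record(i, axon = runif(1, 0.05, 3), outer = runif(1, 0.1, 4),
                g = runif(1, 0.2, 1.3))))
  strict <- filter_instances(recs, filter_rule(min_axon_diameter = 0.5,
                                               max_axon_diameter = 2,
                                               g_ratio_range = c(0.3, 0.8)))
  loose <- filter_instances(recs, filter_rule())
  expect_gte(nrow(loose$kept), nrow(strict$kept))
})
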