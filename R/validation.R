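#' Per-pixel overlap metrics between two masks
#'
#' Intersection-over-union, Dice coefficient, and the 95th-percentile
#' symmetric Hausdorff distance between a predicted and a ground-truth
#' binary mask. HD95 is computed over Euclidean distances from every
#' boundary pixel of one mask to the nearest boundary pixel of the
#' other, pooled over both directions, and reported in µm. Convention
#' for degenerate inputs: two empty masks agree perfectly (IoU = 1,
#' Dice = 1, HD95 = 0); one empty mask gives IoU = 0, Dice = 0,
#' HD95 = Inf.
#'
#' @param pred_mask,gt_mask logical matrices of identical dimension.
#' @param pixel_size_nm pixel edge length, nm.
#' @return list with `iou`, `dice`, `hausdorff95_um`.
#' @export
pixel_metrics <- function(pred_mask, gt_mask, pixel_size_nm = 17.28) {
  stopifnot(identical(dim(pred_mask), dim(gt_mask)))
  a <- sum(pred_mask); b <- sum(gt_mask)
  inter <- sum(pred_mask & gt_mask)
  if (a == 0 && b == 0)
    return(list(iou = 1, dice = 1, hausdorff95_um = 0))
  if (a == 0 || b == 0)
    return(list(iou = 0, dice = 0, hausdorff95_um = Inf))
  uni <- a + b - inter
  iou <- inter / uni
  dice <- 2 * inter / (a + b)
  bp <- mask_boundary(pred_mask)
  bg <- mask_boundary(gt_mask)
  d_to_g <- boundary_distances(bp, bg)
  d_to_p <- boundary_distances(bg, bp)
  hd95 <- stats::quantile(c(d_to_g, d_to_p), 0.95, names = FALSE)
  list(iou = iou, dice = dice,
       hausdorff95_um = hd95 * pixel_size_nm / 1000)
}

# distances (px) from TRUE pixels of `from` to the nearest TRUE pixel of `to`
boundary_distances <- function(from, to) {
  dist_to <- ebi_data(EBImage::distmap(as_ebi(!to)))
  dist_to[from]
}

#' Match predicted to ground-truth fiber instances
#'
#' Greedy one-to-one matching of predicted against ground-truth fiber
#' instances by overlap. For each candidate pair the intersection area
#' is divided by the ground-truth area and by the prediction area; by
#' default both fractions must exceed `threshold` (0.40) — the
#' two-sided rule prevents one oversized predicted blob matching every
#' ground-truth fiber. Candidates are taken in order of decreasing
#' overlap (the smaller of the two fractions); each id joins at most one
#' pair. Unmatched predictions are false positives, unmatched
#' ground-truth fibers false negatives.
#'
#' @param pred,gt [instance_maps()] of identical dimension. A fiber's
#'   footprint is the union of its axon and myelin pixels.
#' @param threshold overlap-fraction threshold (default 0.40).
#' @param denominator `"both"` (default) requires both fractions above
#'   threshold; `"gt"` or `"pred"` use one side only.
#' @return list of class `match_result`: `pairs` (data.frame `gt_id`,
#'   `pred_id`, `overlap_gt`, `overlap_pred`), `false_positives` (pred
#'   ids), `false_negatives` (gt ids).
#' @export
match_instances <- function(pred, gt, threshold = 0.40,
                            denominator = c("both", "gt", "pred")) {
  denominator <- match.arg(denominator)
  stopifnot(identical(dim(pred$axon), dim(gt$axon)))
  pl <- pmax(pred$axon, pred$myelin)
  gl <- pmax(gt$axon, gt$myelin)
  pred_ids <- sort(unique(pl[pl > 0]))
  gt_ids <- sort(unique(gl[gl > 0]))
  both <- pl > 0 & gl > 0
  if (any(both)) {
    tab <- table(gt = gl[both], pred = pl[both])
    inter <- as.data.frame(tab, stringsAsFactors = FALSE)
    inter <- inter[inter$Freq > 0, ]
    inter$gt <- as.integer(inter$gt)
    inter$pred <- as.integer(inter$pred)
  } else {
    inter <- data.frame(gt = integer(), pred = integer(), Freq = integer())
  }
  gt_area <- tabulate(gl[gl > 0])
  pred_area <- tabulate(pl[pl > 0])
  if (nrow(inter)) {
    inter$frac_gt <- inter$Freq / gt_area[inter$gt]
    inter$frac_pred <- inter$Freq / pred_area[inter$pred]
    ok <- switch(denominator,
                 both = inter$frac_gt > threshold & inter$frac_pred > threshold,
                 gt = inter$frac_gt > threshold,
                 pred = inter$frac_pred > threshold)
    cand <- inter[ok, , drop = FALSE]
    cand <- cand[order(-pmin(cand$frac_gt, cand$frac_pred)), , drop = FALSE]
  } else {
    cand <- inter
  }
  used_gt <- integer(0); used_pred <- integer(0)
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$gt[i] %in% used_gt || cand$pred[i] %in% used_pred) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      gt_id = cand$gt[i], pred_id = cand$pred[i],
      overlap_gt = cand$frac_gt[i], overlap_pred = cand$frac_pred[i])
    used_gt <- c(used_gt, cand$gt[i])
    used_pred <- c(used_pred, cand$pred[i])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gt_id = integer(), pred_id = integer(),
               overlap_gt = numeric(), overlap_pred = numeric())
  structure(list(pairs = pairs,
                 false_positives = setdiff(pred_ids, pairs$pred_id),
                 false_negatives = setdiff(gt_ids, pairs$gt_id)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result: ", nrow(x$pairs), " matched pairs, ",
      length(x$false_positives), " FP, ",
      length(x$false_negatives), " FN\n", sep = "")
  invisible(x)
}

#' Paired agreement between two measurement techniques
#'
#' Bland–Altman-style agreement for one measure over matched fiber
#' pairs. Deltas are defined as validation (ground truth) minus
#' prediction; the report carries the mean difference (bias), its sd,
#' the limits of agreement `mean ± 1.96 sd`, the mean absolute error,
#' and deltas stratified by ground-truth axon diameter so size-dependent
#' bias is visible. Computed on the raw measurement scale.
#'
#' @param pred_records,gt_records fiber-record data.frames.
#' @param pairs data.frame with `gt_id` and `pred_id` columns (from
#'   [match_instances()]).
#' @param measure column name to compare (e.g. `"axon_minor_um"`,
#'   `"g_ratio"`).
#' @param size_breaks breaks (µm) for stratifying by ground-truth axon
#'   minor-axis diameter.
#' @return list of class `agreement_report`: `measure`, `n`, `deltas`,
#'   `mean_difference`, `sd_difference`, `loa` (lower/upper),
#'   `mae`, `by_size` (data.frame of per-stratum n, bias, MAE),
#'   `means` (pairwise means, for plotting).
#' @export
paired_agreement <- function(pred_records, gt_records, pairs, measure,
                             size_breaks = c(0, 0.4, 0.8, 1.2, Inf)) {
  if (nrow(pairs) == 0L) stop("empty match set: no pairs to compare")
  if (!measure %in% names(pred_records) || !measure %in% names(gt_records))
    stop(sprintf("column '%s' not found in the fiber records", measure))
  gi <- match(pairs$gt_id, gt_records$fiber_id)
  pi_ <- match(pairs$pred_id, pred_records$fiber_id)
  ok <- !is.na(gi) & !is.na(pi_)
  gv <- gt_records[[measure]][gi[ok]]
  pv <- pred_records[[measure]][pi_[ok]]
  fin <- is.finite(gv) & is.finite(pv)
  gv <- gv[fin]; pv <- pv[fin]
  if (!length(gv)) stop("no finite paired values for this measure")
  deltas <- gv - pv
  md <- mean(deltas)
  sdd <- stats::sd(deltas)
  if (!is.finite(sdd)) sdd <- 0
  gt_size <- gt_records$axon_minor_um[gi[ok]][fin]
  strata <- cut(gt_size, breaks = size_breaks, include.lowest = TRUE)
  by_size <- do.call(rbind, lapply(levels(strata), function(lv) {
    sel <- which(strata == lv)
    data.frame(stratum = lv, n = length(sel),
               bias = if (length(sel)) mean(deltas[sel]) else NA_real_,
               mae = if (length(sel)) mean(abs(deltas[sel])) else NA_real_)
  }))
  structure(list(measure = measure, n = length(deltas), deltas = deltas,
                 mean_difference = md, sd_difference = sdd,
                 loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
                 mae = mean(abs(deltas)),
                 by_size = by_size, means = (gv + pv) / 2),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "agreement [%s]: n = %d, bias = %.4g, LoA = [%.4g, %.4g], MAE = %.4g\n",
    x$measure, x$n, x$mean_difference, x$loa["lower"], x$loa["upper"], x$mae))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) {
  graphics::plot(x$means, x$deltas, pch = 16,
                 col = grDevices::adjustcolor("black", 0.3),
                 xlab = paste("mean of methods:", x$measure),
                 ylab = "validation - prediction",
                 main = paste("Bland-Altman:", x$measure))
  graphics::abline(h = c(x$mean_difference, x$loa), lty = c(1, 2, 2),
                   col = c("blue", "red", "red"))
  invisible(x)
}
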