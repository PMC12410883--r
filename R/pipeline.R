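#' End-to-end run configuration
#'
#' Bundles every parameter of the phantom → segment → measure → fit →
#' velocity → validate pipeline, with an explicit seed for each
#' stochastic stage. Round-trips losslessly through JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param phantom list of [phantom_config()] arguments (without `seed`).
#' @param segmentation list with `morph_radius`, `min_object_area`,
#'   `peak_min_distance`.
#' @param filter list of [filter_rule()] arguments.
#' @param gev list with `column` (measurement column to fit), `chains`,
#'   `warmup`, `draws`, `min_n` (smallest sample worth fitting) and
#'   optional `priors` ([gev_priors()] arguments).
#' @param velocity list with `scaling_s`, `alpha`, `g_mode`.
#' @param seeds list with integer `phantom` and `mcmc` seeds.
#' @param out_dir optional output directory; when set, every stage
#'   artifact is written there.
#' @return a list of class `run_config`.
#' @export
run_config <- function(phantom = list(),
                       segmentation = list(morph_radius = 1,
                                           min_object_area = 10,
                                           peak_min_distance = 10),
                       filter = list(),
                       gev = list(column = "axon_minor_um", chains = 4,
                                  warmup = 1000, draws = 1000, min_n = 50),
                       velocity = list(scaling_s = 7.5, alpha = 0.68,
                                       g_mode = "per_fiber"),
                       seeds = list(phantom = 1L, mcmc = 2L),
                       out_dir = NULL) {
  seg_def <- list(morph_radius = 1, min_object_area = 10, peak_min_distance = 10)
  gev_def <- list(column = "axon_minor_um", chains = 4, warmup = 1000,
                  draws = 1000, min_n = 50)
  vel_def <- list(scaling_s = 7.5, alpha = 0.68, g_mode = "per_fiber")
  structure(list(
    phantom = phantom,
    segmentation = utils::modifyList(seg_def, segmentation),
    filter = filter,
    gev = utils::modifyList(gev_def, gev),
    velocity = utils::modifyList(vel_def, velocity),
    seeds = list(phantom = as.integer(seeds$phantom %||% 1L),
                 mcmc = as.integer(seeds$mcmc %||% 2L)),
    out_dir = out_dir
  ), class = "run_config")
}

raw_config_args <- function(raw) {
  if (!is.null(raw$phantom)) {
    for (f in c("axon_diameter_law", "g_ratio_law", "cut_angle_law"))
      if (!is.null(raw$phantom[[f]])) raw$phantom[[f]] <- unlist(raw$phantom[[f]])
    if (!is.null(raw$phantom$canvas)) raw$phantom$canvas <- unlist(raw$phantom$canvas)
    if (!is.null(raw$phantom$degradation))
      raw$phantom$degradation <-
        do.call(degradation_params, as.list(raw$phantom$degradation))
  }
  for (f in c("segmentation", "filter", "gev", "velocity", "seeds"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.list(raw[[f]])
  if (!is.null(raw$filter$g_ratio_range))
    raw$filter$g_ratio_range <- unlist(raw$filter$g_ratio_range)
  raw[!vapply(raw, is.null, TRUE)]
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a phantom, segments its semantic map into
#' fiber instances, measures and filters them, fits the GEV
#' diameter-distribution model, estimates per-fiber conduction
#' velocities, and — because the phantom's ground truth is available —
#' runs the complete segmentation-validation protocol. All randomness is
#' governed by the seeds in the configuration, so identical
#' configurations produce identical reports.
#'
#' @param config a [run_config()].
#' @param phantom optionally, a pre-built `phantom` object (its truth is
#'   used for validation); by default one is generated from the config.
#' @return a list of class `run_report`: `status`, `counts` (fibers
#'   generated / segmented / kept / rejected, FP, FN), `population`
#'   (medians of axon and outer minor axes, mean and median g-ratio),
#'   `gev` (posterior means, 99% HPD bounds, R-hat, ESS), `velocity`
#'   (median m/s), `validation` (per-class IoU/Dice/HD95, match counts,
#'   per-measure agreement), plus `records`, `fit`, `phantom` carried as
#'   attributes for further analysis (the phantom's score rasters are
#'   dropped after segmentation to bound memory on large canvases; its
#'   instance maps, truth table and specs are retained).
#' @export
run_pipeline <- function(config, phantom = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pc <- do.call(phantom_config,
                c(config$phantom, list(seed = config$seeds$phantom)))
  ph <- phantom %||% generate_phantom(pc)

  report <- list(status = "ok",
                 parameters = list(pixel_size_nm = pc$pixel_size_nm,
                                   seeds = config$seeds))

  if (nrow(ph$specs) == 0L) {
    report$status <- "no fibers"
    report$counts <- list(generated = 0L, segmented = 0L, kept = 0L,
                          rejected = 0L, false_positives = 0L,
                          false_negatives = 0L)
    return(structure(report, class = "run_report"))
  }

  if (!is.null(out_dir))
    write_semantic_map(ph$semantic, file.path(out_dir, "semantic.tif"))
  masks <- threshold_semantic(ph$semantic,
                              morph_radius = config$segmentation$morph_radius,
                              min_object_area = config$segmentation$min_object_area)
  # the score rasters are no longer needed; keep the run's peak memory flat
  ph$semantic <- NULL
  ph$semantic_clean <- NULL
  gc(FALSE)
  inst <- separate_instances(masks$axon, masks$myelin,
                             peak_min_distance = config$segmentation$peak_min_distance,
                             pixel_size_nm = pc$pixel_size_nm)
  gc(FALSE)
  records <- measure_instances(inst)
  rule <- do.call(filter_rule, config$filter)
  fl <- filter_instances(records, rule)
  kept <- fiber_velocities(fl$kept,
                           velocity_model(config$velocity$scaling_s,
                                          config$velocity$alpha),
                           g_mode = config$velocity$g_mode)

  fit <- NULL
  col <- config$gev$column
  vals <- kept[[col]]
  vals <- vals[is.finite(vals)]
  if (length(vals) >= config$gev$min_n) {
    priors <- do.call(gev_priors, as.list(config$gev$priors %||% list()))
    fit <- fit_gev(vals, priors = priors, chains = config$gev$chains,
                   warmup = config$gev$warmup, draws = config$gev$draws,
                   seed = config$seeds$mcmc)
  }

  truth_records <- measure_instances(ph$instances)
  mt <- match_instances(inst, ph$instances)
  gc(FALSE)
  pm_axon <- pixel_metrics(masks$axon, ph$instances$axon > 0, pc$pixel_size_nm)
  pm_my <- pixel_metrics(masks$myelin, ph$instances$myelin > 0, pc$pixel_size_nm)
  agreement <- list()
  if (nrow(mt$pairs) > 0) {
    for (m in c("axon_minor_um", "outer_minor_um", "g_ratio")) {
      agr <- tryCatch(paired_agreement(records, truth_records, mt$pairs, m),
                      error = function(e) NULL)
      if (!is.null(agr))
        agreement[[m]] <- list(n = agr$n, bias = agr$mean_difference,
                               loa = unname(agr$loa), mae = agr$mae)
    }
  }

  report$counts <- list(generated = nrow(ph$specs),
                        segmented = length(instance_ids(inst)),
                        kept = nrow(kept), rejected = nrow(fl$rejected),
                        false_positives = length(mt$false_positives),
                        false_negatives = length(mt$false_negatives))
  report$population <- list(
    axon_minor_median_um = stats::median(kept$axon_minor_um, na.rm = TRUE),
    outer_minor_median_um = stats::median(kept$outer_minor_um, na.rm = TRUE),
    g_ratio_mean = mean(kept$g_ratio, na.rm = TRUE),
    g_ratio_median = stats::median(kept$g_ratio, na.rm = TRUE))
  if (!is.null(fit)) {
    report$gev <- list(column = col,
                       mean = as.list(coef(fit)),
                       hpd99 = list(mu = unname(fit$hpd99[1, ]),
                                    sigma = unname(fit$hpd99[2, ]),
                                    xi = unname(fit$hpd99[3, ])),
                       rhat = fit$diagnostics$rhat,
                       ess = fit$diagnostics$ess)
  } else {
    report$gev <- list(column = col, status = "skipped: too few fibers")
  }
  report$velocity <- list(median_mps = stats::median(kept$v_mps, na.rm = TRUE),
                          g_mode = config$velocity$g_mode)
  report$validation <- list(
    pixel = list(axon = pm_axon, myelin = pm_my),
    matched = nrow(mt$pairs),
    agreement = agreement)

  if (!is.null(out_dir)) {
    write_instance_maps(inst, file.path(out_dir, "instances_pred"))
    write_instance_maps(ph$instances, file.path(out_dir, "instances_truth"))
    write_fiber_table(ph$truth, file.path(out_dir, "truth.csv"))
    write_fiber_table(records, file.path(out_dir, "measurements.csv"))
    if (nrow(fl$rejected))
      write_fiber_table(fl$rejected[, c("fiber_id", "reason")],
                        file.path(out_dir, "rejections.csv"))
    if (!is.null(fit)) {
      pooled <- apply(fit$draws, 3, c)
      post <- data.frame(
        chain = rep(seq_len(fit$chains), each = fit$n_draws),
        draw = rep(seq_len(fit$n_draws), fit$chains),
        mu = pooled[, 1], sigma = pooled[, 2], xi = pooled[, 3])
      write_fiber_table(post, file.path(out_dir, "posterior.csv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(report, records = kept, fit = fit, phantom = ph,
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$status, "\n")
  if (!is.null(x$counts))
    cat(sprintf("  fibers: %d generated, %d segmented, %d kept (%d rejected), %d FP, %d FN\n",
                x$counts$generated, x$counts$segmented, x$counts$kept,
                x$counts$rejected, x$counts$false_positives,
                x$counts$false_negatives))
  if (!is.null(x$population))
    cat(sprintf("  medians: axon %.3f um, outer %.3f um; mean g = %.3f\n",
                x$population$axon_minor_median_um,
                x$population$outer_minor_median_um,
                x$population$g_ratio_mean))
  if (!is.null(x$gev$mean))
    cat(sprintf("  GEV[%s]: mu %.3f, sigma %.3f, xi %.3f\n", x$gev$column,
                x$gev$mean$mu, x$gev$mean$sigma, x$gev$mean$xi))
  if (!is.null(x$velocity))
    cat(sprintf("  median velocity: %.2f m/s\n", x$velocity$median_mps))
  invisible(x)
}
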