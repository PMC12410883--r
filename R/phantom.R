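#' Phantom population configuration
#'
#' Describes a synthetic population of obliquely cut myelinated fibers:
#' an axon-diameter law (GEV, matching the family used for real
#' diameter populations), a g-ratio law (normal truncated to (0, 1),
#' centered at 0.54, the mean reported for both short- and long-range
#' human white matter), a cut-angle law (uniform in degrees from the
#' section normal), canvas geometry, and degradation parameters.
#'
#' The default pixel size of 17.28 nm corresponds to 4.32-nm
#' transmission-EM acquisition downsampled fourfold per axis, the working
#' resolution of the segmentation this generator emulates. Cut angles
#' default to uniform on [0°, 60°]: beyond ~60° the rasterized myelin
#' annulus becomes unreliably thin at this resolution.
#'
#' @param fiber_count number of fibers to generate.
#' @param canvas integer c(width, height) in pixels.
#' @param pixel_size_nm pixel edge length, nm.
#' @param axon_diameter_law named numeric `c(mu=, sigma=, xi=)` of the
#'   GEV axon-diameter distribution, µm.
#' @param g_ratio_law named numeric `c(mean=, sd=)` of the truncated
#'   normal g-ratio law; `sd = 0` gives a degenerate (point-mass) law.
#' @param cut_angle_law named numeric `c(min=, max=)` in degrees,
#'   within [0, 90).
#' @param degradation a [degradation_params()] object.
#' @param seed integer seed driving all phantom randomness.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(fiber_count = 200,
                           canvas = c(2048L, 2048L),
                           pixel_size_nm = 17.28,
                           axon_diameter_law = c(mu = 0.5, sigma = 0.15, xi = 0.1),
                           g_ratio_law = c(mean = 0.54, sd = 0.06),
                           cut_angle_law = c(min = 0, max = 60),
                           degradation = degradation_params(),
                           seed = 1L) {
  stopifnot(fiber_count >= 0, length(canvas) == 2, all(canvas >= 8),
            pixel_size_nm > 0,
            axon_diameter_law[["sigma"]] > 0,
            g_ratio_law[["mean"]] > 0, g_ratio_law[["mean"]] < 1,
            g_ratio_law[["sd"]] >= 0,
            cut_angle_law[["min"]] >= 0, cut_angle_law[["max"]] < 90,
            cut_angle_law[["min"]] <= cut_angle_law[["max"]])
  structure(list(fiber_count = as.integer(fiber_count),
                 canvas = as.integer(canvas),
                 pixel_size_nm = pixel_size_nm,
                 axon_diameter_law = axon_diameter_law,
                 g_ratio_law = g_ratio_law,
                 cut_angle_law = cut_angle_law,
                 degradation = degradation,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Degradation parameters for phantom semantic maps
#'
#' Controls the artifact model applied to the ideal one-hot semantic map:
#' angular myelin-sheath gaps (emulating partly broken-down myelin),
#' tangentially placed "kissing" fiber pairs, boundary jitter, and
#' Gaussian blurring of the class scores.
#'
#' @param myelin_gap_probability fraction of fibers whose myelin loses an
#'   angular sector, in [0, 1].
#' @param gap_arc sector size in degrees, in [0, 180].
#' @param kissing_fraction fraction of fibers placed tangent to a
#'   partner, in [0, 1] (consumed at placement time).
#' @param boundary_noise_amplitude jitter radius in pixels (integer).
#' @param semantic_blur Gaussian sigma in pixels applied to the class
#'   scores (0 disables).
#' @return a list of class `degradation_params`.
#' @export
degradation_params <- function(myelin_gap_probability = 0, gap_arc = 90,
                               kissing_fraction = 0,
                               boundary_noise_amplitude = 0,
                               semantic_blur = 0) {
  stopifnot(myelin_gap_probability >= 0, myelin_gap_probability <= 1,
            gap_arc >= 0, gap_arc <= 180,
            kissing_fraction >= 0, kissing_fraction <= 1,
            boundary_noise_amplitude >= 0, semantic_blur >= 0)
  structure(list(myelin_gap_probability = myelin_gap_probability,
                 gap_arc = gap_arc,
                 kissing_fraction = kissing_fraction,
                 boundary_noise_amplitude = boundary_noise_amplitude,
                 semantic_blur = semantic_blur),
            class = "degradation_params")
}

# outer minor/major semi-axes in px for a spec row
spec_semiaxes_px <- function(specs, pixel_size_nm) {
  px_um <- pixel_size_nm / 1000
  r_out <- specs$axon_radius_um + specs$myelin_thickness_um
  list(
    b_axon = specs$axon_radius_um / px_um,
    a_axon = specs$axon_radius_um / cospi(specs$cut_angle_deg / 180) / px_um,
    b_out = r_out / px_um,
    a_out = r_out / cospi(specs$cut_angle_deg / 180) / px_um
  )
}

#' Sample a fiber population
#'
#' Draws per-fiber geometry from the configured laws — axon diameters
#' from the GEV law (non-positive draws are rejected and redrawn), true
#' g-ratios from the truncated normal law, cut angles and in-plane
#' orientations uniformly — and places fibers on the canvas. Myelin
#' thickness follows from diameter and g-ratio:
#' `t = r * (1/g - 1)`, so that `g = d / (d + 2 t)` exactly. Non-kissing
#' fibers are placed with non-overlapping outer-ellipse bounding circles;
#' kissing pairs are placed tangent along the minor-axis direction with a
#' 1-px overlap so their sheaths share a boundary.
#'
#' @param config a [phantom_config()].
#' @param place if FALSE, skip canvas placement (centers are NA); useful
#'   for population-statistics work at sizes exceeding any canvas.
#' @return a data.frame of fiber specs: `fiber_id`, `axon_radius_um`,
#'   `myelin_thickness_um`, `cut_angle_deg`, `center_x_um`,
#'   `center_y_um`, `orientation_deg`, `kissing_partner`, `g_ratio_true`.
#' @export
sample_population <- function(config, place = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n <- config$fiber_count
  if (n == 0L) {
    return(data.frame(fiber_id = integer(), axon_radius_um = numeric(),
                      myelin_thickness_um = numeric(),
                      cut_angle_deg = numeric(), center_x_um = numeric(),
                      center_y_um = numeric(), orientation_deg = numeric(),
                      kissing_partner = integer(), g_ratio_true = numeric()))
  }
  law <- config$axon_diameter_law
  d <- rgev(n, law[["mu"]], law[["sigma"]], law[["xi"]])
  bad <- which(d <= 0)
  while (length(bad)) {
    d[bad] <- rgev(length(bad), law[["mu"]], law[["sigma"]], law[["xi"]])
    bad <- bad[d[bad] <= 0]
  }
  g <- rtrunc_norm(n, config$g_ratio_law[["mean"]], config$g_ratio_law[["sd"]],
                   lower = 1e-3, upper = 1 - 1e-3)
  r <- d / 2
  t <- r * (1 / g - 1)
  ang <- runif(n, config$cut_angle_law[["min"]], config$cut_angle_law[["max"]])
  orient <- runif(n, -90, 90)

  specs <- data.frame(
    fiber_id = seq_len(n), axon_radius_um = r, myelin_thickness_um = t,
    cut_angle_deg = ang, center_x_um = NA_real_, center_y_um = NA_real_,
    orientation_deg = orient, kissing_partner = NA_integer_,
    g_ratio_true = g
  )

  n_pairs <- floor(config$degradation$kissing_fraction * n / 2)
  if (n_pairs > 0) {
    idx <- seq_len(2L * n_pairs)
    specs$kissing_partner[idx] <- ifelse(idx %% 2 == 1L, idx + 1L, idx - 1L)
  }

  if (place) specs <- place_fibers(specs, config)
  specs
}

place_fibers <- function(specs, config) {
  px_um <- config$pixel_size_nm / 1000
  ax <- spec_semiaxes_px(specs, config$pixel_size_nm)
  rad_px <- ax$a_out + 2  # bounding circle with 2-px margin
  W <- config$canvas[1]; H <- config$canvas[2]
  n <- nrow(specs)
  cx <- numeric(n); cy <- numeric(n)
  placed <- logical(n)

  try_place <- function(i, fixed = NULL) {
    lo_x <- min(rad_px[i], W / 2); hi_x <- max(W - rad_px[i], W / 2)
    lo_y <- min(rad_px[i], H / 2); hi_y <- max(H - rad_px[i], H / 2)
    for (att in seq_len(1000L)) {
      if (is.null(fixed)) {
        px <- runif(1, lo_x, hi_x); py <- runif(1, lo_y, hi_y)
      } else {
        px <- fixed[1]; py <- fixed[2]
      }
      others <- which(placed)
      others <- setdiff(others, specs$kissing_partner[i])
      ok <- TRUE
      if (length(others)) {
        dd <- sqrt((cx[others] - px)^2 + (cy[others] - py)^2)
        ok <- all(dd > rad_px[others] + rad_px[i])
      }
      if (ok) return(c(px, py))
      if (!is.null(fixed)) return(NULL)
    }
    NULL
  }

  # large fibers are hardest to place; handle them first
  for (i in order(rad_px, decreasing = TRUE)) {
    if (placed[i]) next
    partner <- specs$kissing_partner[i]
    if (!is.na(partner) && !placed[partner]) {
      # place the pair together: partner tangent along i's minor axis
      v <- c(-sinpi(specs$orientation_deg[i] / 180),
             cospi(specs$orientation_deg[i] / 180))
      gap_px <- ax$b_out[i] + ax$b_out[partner] - 1  # 1-px shared overlap
      done <- FALSE
      for (att in seq_len(1000L)) {
        p1 <- try_place(i)
        if (is.null(p1)) break
        cx[i] <- p1[1]; cy[i] <- p1[2]; placed[i] <- TRUE
        p2 <- try_place(partner, fixed = p1 + v * gap_px)
        if (!is.null(p2) &&
            p2[1] > rad_px[partner] && p2[1] < W - rad_px[partner] &&
            p2[2] > rad_px[partner] && p2[2] < H - rad_px[partner]) {
          cx[partner] <- p2[1]; cy[partner] <- p2[2]
          placed[partner] <- TRUE
          done <- TRUE
          break
        }
        placed[i] <- FALSE
      }
      if (!done) stop(placement_error(sum(placed), n))
    } else {
      p <- try_place(i)
      if (is.null(p)) stop(placement_error(sum(placed), n))
      cx[i] <- p[1]; cy[i] <- p[2]; placed[i] <- TRUE
    }
  }
  specs$center_x_um <- cx * px_um
  specs$center_y_um <- cy * px_um
  # kissing pairs share the partner's orientation so tangency is exact
  pk <- which(!is.na(specs$kissing_partner))
  specs$orientation_deg[pk] <-
    specs$orientation_deg[pmin(pk, specs$kissing_partner[pk])]
  specs
}

placement_error <- function(achieved, wanted) {
  structure(class = c("fibermorph_placement_error", "error", "condition"),
            list(message = sprintf(
              "canvas too small: placed %d of %d fibers without overlap",
              achieved, wanted), call = NULL))
}

#' Rasterize a fiber population
#'
#' Renders each fiber as two concentric ellipses — the axon ellipse
#' inside a myelin annulus — whose minor semi-axes equal the true radii
#' and whose major semi-axes are scaled by `1/cos(cut_angle)`: the
#' geometry of a tubular structure intersected by an oblique section
#' plane, whose minor axis always equals the true tube diameter.
#'
#' @param specs a fiber-spec data.frame from [sample_population()].
#' @param canvas integer c(width, height) in pixels.
#' @param pixel_size_nm pixel edge length, nm.
#' @return list with `semantic` (one-hot [semantic_map()]), `instances`
#'   ([instance_maps()]), and `truth` (data.frame with true ellipse axes
#'   in µm, true g-ratio, and a `clipped_flag` for fibers extending
#'   beyond the canvas).
#' @export
rasterize_population <- function(specs, canvas, pixel_size_nm) {
  W <- canvas[1]; H <- canvas[2]
  px_um <- pixel_size_nm / 1000
  axon_lab <- matrix(0L, W, H)
  my_lab <- matrix(0L, W, H)
  clipped <- logical(nrow(specs))
  ax <- spec_semiaxes_px(specs, pixel_size_nm)

  for (i in seq_len(nrow(specs))) {
    cxp <- specs$center_x_um[i] / px_um
    cyp <- specs$center_y_um[i] / px_um
    if (!is.finite(cxp) || !is.finite(cyp))
      stop("specs must be placed (non-NA centers) before rasterization")
    ext <- ax$a_out[i] + 1
    x0 <- floor(cxp - ext); x1 <- ceiling(cxp + ext)
    y0 <- floor(cyp - ext); y1 <- ceiling(cyp + ext)
    clipped[i] <- x0 < 0 || y0 < 0 || x1 > W || y1 > H
    xs <- max(1L, x0):min(W, x1)
    ys <- max(1L, y0):min(H, y1)
    if (!length(xs) || !length(ys)) next
    gx <- matrix(xs - 0.5 - cxp, length(xs), length(ys))
    gy <- matrix(rep(ys - 0.5 - cyp, each = length(xs)), length(xs), length(ys))
    co <- cospi(specs$orientation_deg[i] / 180)
    si <- sinpi(specs$orientation_deg[i] / 180)
    pu <- gx * co + gy * si   # along major axis
    pv <- -gx * si + gy * co  # along minor axis
    in_axon <- (pu / ax$a_axon[i])^2 + (pv / ax$b_axon[i])^2 <= 1
    in_out <- (pu / ax$a_out[i])^2 + (pv / ax$b_out[i])^2 <= 1
    sub_a <- axon_lab[xs, ys]
    sub_m <- my_lab[xs, ys]
    new_ax <- in_axon & sub_a == 0L & sub_m == 0L
    new_my <- in_out & !in_axon & sub_a == 0L & sub_m == 0L
    sub_a[new_ax] <- specs$fiber_id[i]
    sub_m[new_my] <- specs$fiber_id[i]
    axon_lab[xs, ys] <- sub_a
    my_lab[xs, ys] <- sub_m
  }

  scores <- array(0, dim = c(W, H, 3))
  scores[, , 2] <- (axon_lab > 0) * 1
  scores[, , 3] <- (my_lab > 0) * 1
  scores[, , 1] <- 1 - scores[, , 2] - scores[, , 3]

  truth <- data.frame(
    fiber_id = specs$fiber_id,
    axon_radius_um = specs$axon_radius_um,
    myelin_thickness_um = specs$myelin_thickness_um,
    cut_angle_deg = specs$cut_angle_deg,
    g_ratio_true = specs$g_ratio_true,
    axon_minor_true_um = 2 * specs$axon_radius_um,
    axon_major_true_um = 2 * specs$axon_radius_um /
      cospi(specs$cut_angle_deg / 180),
    outer_minor_true_um = 2 * (specs$axon_radius_um + specs$myelin_thickness_um),
    outer_major_true_um = 2 * (specs$axon_radius_um + specs$myelin_thickness_um) /
      cospi(specs$cut_angle_deg / 180),
    clipped_flag = clipped
  )

  list(semantic = semantic_map(scores, pixel_size_nm),
       instances = instance_maps(axon_lab, my_lab, pixel_size_nm),
       truth = truth)
}

#' Degrade a phantom semantic map
#'
#' Applies the artifact model to an ideal semantic map: removes an
#' angular myelin sector for a configured fraction of fibers (emulating
#' partly broken-down sheaths), jitters class boundaries, and blurs the
#' class scores. The output is always a valid semantic map (scores in
#' [0, 1], channels summing to 1 per pixel). Sector removal uses the
#' parametric (normalized-ellipse) angle, so a `gap_arc` of 90° removes
#' one quarter of the annulus area regardless of cut angle.
#'
#' @param map a [semantic_map()].
#' @param params a [degradation_params()].
#' @param seed integer seed.
#' @param instances the ground-truth [instance_maps()] (required when
#'   `myelin_gap_probability > 0`).
#' @param specs the fiber-spec data.frame (required with `instances`).
#' @return a degraded [semantic_map()].
#' @export
degrade_semantic <- function(map, params, seed = 1L, instances = NULL,
                             specs = NULL) {
  stopifnot(inherits(map, "semantic_map"), inherits(params, "degradation_params"))
  set.seed(seed)
  scores <- map$scores
  W <- dim(scores)[1]; H <- dim(scores)[2]
  px_um <- map$pixel_size_nm / 1000

  if (params$myelin_gap_probability > 0 && params$gap_arc > 0) {
    if (is.null(instances) || is.null(specs))
      stop("instances and specs are required to carve myelin gaps")
    ax <- spec_semiaxes_px(specs, map$pixel_size_nm)
    hit <- runif(nrow(specs)) < params$myelin_gap_probability
    start <- runif(nrow(specs), 0, 360)
    w <- which(instances$myelin > 0)
    if (length(w)) {
      ids <- instances$myelin[w]
      by_id <- split(w, ids)
      for (k in which(hit)) {
        pix <- by_id[[as.character(specs$fiber_id[k])]]
        if (is.null(pix)) next
        xi <- (pix - 1L) %% W + 1L
        yi <- (pix - 1L) %/% W + 1L
        cxp <- specs$center_x_um[k] / px_um
        cyp <- specs$center_y_um[k] / px_um
        co <- cospi(specs$orientation_deg[k] / 180)
        si <- sinpi(specs$orientation_deg[k] / 180)
        dx <- xi - 0.5 - cxp; dy <- yi - 0.5 - cyp
        pu <- (dx * co + dy * si) / ax$a_out[k]
        pv <- (-dx * si + dy * co) / ax$b_out[k]
        theta <- (atan2(pv, pu) * 180 / pi) %% 360
        rel <- (theta - start[k]) %% 360
        gone <- pix[rel < params$gap_arc]
        if (length(gone)) {
          scores[, , 1][gone] <- 1
          scores[, , 2][gone] <- 0
          scores[, , 3][gone] <- 0
        }
      }
    }
  }

  A <- round(params$boundary_noise_amplitude)
  if (A >= 1) {
    cls <- max.col(matrix(scores, W * H, 3), ties.method = "first")
    cls_m <- matrix(cls, W, H)
    edge <- matrix(FALSE, W, H)
    edge[-W, ] <- edge[-W, ] | cls_m[-W, ] != cls_m[-1, ]
    edge[-1, ] <- edge[-1, ] | cls_m[-W, ] != cls_m[-1, ]
    edge[, -H] <- edge[, -H] | cls_m[, -H] != cls_m[, -1]
    edge[, -1] <- edge[, -1] | cls_m[, -H] != cls_m[, -1]
    zone <- ebi_data(EBImage::dilate(as_ebi(edge),
                                     EBImage::makeBrush(2L * A + 1L, "disc"))) > 0.5
    w <- which(zone & matrix(runif(W * H) < 0.5, W, H))
    if (length(w)) {
      xi <- (w - 1L) %% W + 1L
      yi <- (w - 1L) %/% W + 1L
      sx <- pmin(pmax(xi + sample(-A:A, length(w), TRUE), 1L), W)
      sy <- pmin(pmax(yi + sample(-A:A, length(w), TRUE), 1L), H)
      src <- (sy - 1L) * W + sx
      for (c in 1:3) scores[, , c][w] <- scores[, , c][src]
    }
  }

  if (params$semantic_blur > 0) {
    for (c in 1:3) {
      scores[, , c] <- ebi_data(EBImage::gblur(EBImage::Image(scores[, , c]),
                                               sigma = params$semantic_blur))
    }
    scores[scores < 0] <- 0
    tot <- scores[, , 1] + scores[, , 2] + scores[, , 3]
    tot[tot <= 0] <- 1
    for (c in 1:3) scores[, , c] <- scores[, , c] / tot
  }

  semantic_map(scores, map$pixel_size_nm)
}

#' Generate a complete phantom
#'
#' Convenience wrapper: [sample_population()], [rasterize_population()],
#' then [degrade_semantic()]. Re-running with the same configuration
#' (including its seed) reproduces identical rasters and tables.
#'
#' @param config a [phantom_config()].
#' @return list of class `phantom`: `semantic` (degraded map),
#'   `semantic_clean` (pre-degradation one-hot map), `instances`
#'   (ground-truth labels), `truth`, `specs`, `config`.
#' @export
generate_phantom <- function(config) {
  specs <- sample_population(config)
  ras <- rasterize_population(specs, config$canvas, config$pixel_size_nm)
  degraded <- degrade_semantic(ras$semantic, config$degradation,
                               seed = config$seed + 1L,
                               instances = ras$instances, specs = specs)
  structure(list(semantic = degraded, semantic_clean = ras$semantic,
                 instances = ras$instances, truth = ras$truth,
                 specs = specs, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom: ", nrow(x$specs), " fibers on ", x$config$canvas[1], " x ",
      x$config$canvas[2], " px @ ", x$config$pixel_size_nm, " nm/px\n",
      sep = "")
  invisible(x)
}
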