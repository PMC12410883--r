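#' Local contrast enhancement (CLAHE)
#'
#' Contrast-limited adaptive histogram equalization of a single-channel
#' raster, the standard preprocessing applied to raw electron
#' micrographs before semantic prediction. The output is rescaled to the
#' input's value range. Constant images are returned unchanged. The
#' stage is bypassed entirely for phantom inputs, which are already class
#' scores.
#'
#' @param img numeric matrix (single-channel image).
#' @param clip_limit contrast clip limit (default 2).
#' @param tile_grid number of contextual tiles per axis (default 8).
#' @return numeric matrix of the same dimension.
#' @export
preprocess_contrast <- function(img, clip_limit = 2, tile_grid = 8) {
  if (length(dim(img)) != 2L)
    stop("preprocess_contrast expects a single-channel 2-D raster")
  lo <- min(img); hi <- max(img)
  if (hi - lo <= 0) return(img)
  x01 <- (img - lo) / (hi - lo)
  out <- ebi_data(EBImage::clahe(EBImage::Image(x01), nx = tile_grid,
                                 ny = tile_grid, limit = clip_limit))
  out <- pmin(pmax(out, 0), 1)
  out * (hi - lo) + lo
}

#' Threshold a semantic map into binary class masks
#'
#' Assigns each pixel to its highest-scoring class (per-pixel argmax; on
#' exact ties the earlier channel in background/axon/myelin order wins),
#' then cleans the binary masks: morphological opening on the axon mask,
#' closing plus hole-filling on the myelin mask (holes enclosed by a
#' sheath that are not axon become myelin), and removal of connected
#' components below `min_object_area`. Axon pixels always take
#' precedence, so the two masks are disjoint.
#'
#' @param map a [semantic_map()].
#' @param morph_radius structuring-element radius in px for the binary
#'   clean-up (0 disables morphology and hole-filling).
#' @param min_object_area smallest connected-component area kept, px.
#' @return list with logical matrices `axon` and `myelin`.
#' @export
threshold_semantic <- function(map, morph_radius = 1, min_object_area = 10) {
  stopifnot(inherits(map, "semantic_map"))
  # per-pixel argmax with first-channel tie preference (bg > axon > myelin),
  # done on channel slices to avoid materializing an (n x 3) copy
  s1 <- map$scores[, , 1]; s2 <- map$scores[, , 2]; s3 <- map$scores[, , 3]
  axon <- s2 > s1 & s2 >= s3
  myelin <- s3 > s1 & s3 > s2
  rm(s1, s2, s3)
  if (morph_radius > 0) {
    brush <- EBImage::makeBrush(2L * morph_radius + 1L, "disc")
    if (any(axon))
      axon <- ebi_data(EBImage::opening(as_ebi(axon), brush)) > 0.5
    if (any(myelin)) {
      myelin <- ebi_data(EBImage::closing(as_ebi(myelin), brush)) > 0.5
      myelin <- fill_holes(myelin) & !axon
    }
  }
  axon <- remove_small_objects(axon, min_object_area)
  myelin <- remove_small_objects(myelin, min_object_area)
  list(axon = axon, myelin = myelin)
}

# peak position (max-distance pixel) and height per basin label
basin_peaks <- function(lab, dist) {
  w <- which(lab > 0)
  ids <- lab[w]
  ord <- w[order(ids, dist[w])]  # within each id, peak pixel comes last
  last <- ord[cumsum(tabulate(ids)[sort(unique(ids))])]
  xi <- (last - 1L) %% nrow(lab) + 1L
  yi <- (last - 1L) %/% nrow(lab) + 1L
  data.frame(id = sort(unique(ids)), x = xi, y = yi, h = dist[last])
}

# pairs of distinct adjacent labels (4-connectivity)
adjacent_labels <- function(lab) {
  p <- rbind(cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
             cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1])))
  p <- p[p[, 1] > 0 & p[, 2] > 0 & p[, 1] != p[, 2], , drop = FALSE]
  unique(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}

#' Separate fiber instances by distance-transform watershed
#'
#' Joins the axon and myelin masks, computes the Euclidean distance
#' transform of the union, and partitions the union by a watershed of
#' the inverted distance surface seeded at every distance-transform peak
#' (plateau peaks merged) — placing basin boundaries along the waists
#' where touching ("kissing") sheaths meet. Adjacent basins whose peaks
#' lie closer than `peak_min_distance` are merged (the higher peak's id
#' survives), suppressing spurious double seeds inside one fiber. Each
#' basin is then split back into its axon and myelin compartments using
#' the binary masks, and ids are renumbered densely from 1.
#'
#' @param axon_mask,myelin_mask logical matrices of identical dimension.
#' @param peak_min_distance minimum peak separation in px (default 10).
#' @param tolerance minimum height of an object in the distance map for
#'   it to be seeded separately (watershed merge tolerance, px).
#' @param pixel_size_nm pixel edge length, nm (stamped on the output).
#' @return an [instance_maps()]; empty masks give empty maps.
#' @export
separate_instances <- function(axon_mask, myelin_mask, peak_min_distance = 10,
                               tolerance = 1, pixel_size_nm = 17.28) {
  stopifnot(identical(dim(axon_mask), dim(myelin_mask)),
            peak_min_distance >= 1)
  un <- axon_mask | myelin_mask
  empty <- matrix(0L, nrow(un), ncol(un))
  if (!any(un))
    return(instance_maps(empty, empty, pixel_size_nm))
  dist <- ebi_data(EBImage::distmap(as_ebi(un)))
  lab <- ebi_data(EBImage::watershed(EBImage::Image(dist),
                                     tolerance = tolerance))
  lab <- matrix(as.integer(round(lab)), nrow(un), ncol(un))
  # merge adjacent basins whose peaks are closer than peak_min_distance
  repeat {
    pk <- basin_peaks(lab, dist)
    adj <- adjacent_labels(lab)
    if (!nrow(adj)) break
    i <- match(adj[, 1], pk$id); j <- match(adj[, 2], pk$id)
    d2 <- (pk$x[i] - pk$x[j])^2 + (pk$y[i] - pk$y[j])^2
    close <- order(d2)[d2[order(d2)] < peak_min_distance^2]
    if (!length(close)) break
    # batch non-chaining merges this round, then relabel once
    touched <- integer(0)
    remap <- seq_len(max(pk$id))
    for (k in close) {
      a <- adj[k, 1]; b <- adj[k, 2]
      if (a %in% touched || b %in% touched) next
      keep_id <- if (pk$h[i[k]] >= pk$h[j[k]]) a else b
      drop_id <- if (keep_id == a) b else a
      remap[drop_id] <- keep_id
      touched <- c(touched, a, b)
    }
    if (all(remap == seq_along(remap))) break
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  old <- sort(unique(lab[lab > 0]))
  relab <- integer(max(old))
  relab[old] <- seq_along(old)
  lab[lab > 0] <- relab[lab[lab > 0]]
  instance_maps(lab * axon_mask, lab * myelin_mask, pixel_size_nm)
}

#' Plausibility filter rule for measured fibers
#'
#' Bounds on measured fiber records used to discard unrealistic fibers —
#' the post-measurement filter of the segmentation pipeline (g-ratio
#' above 1, implausibly small or large diameters, fibers touching the
#' image border, sheathless axons). Defaults are deliberately wide for
#' mammalian white matter and are fully overridable.
#'
#' @param min_axon_diameter,max_axon_diameter axon minor-axis bounds, µm.
#' @param min_outer_diameter,max_outer_diameter outer minor-axis bounds, µm.
#' @param g_ratio_range permissible (open, closed] g-ratio interval.
#' @param border_policy `"drop"` (default) rejects fibers touching the
#'   image edge (their ellipses are truncated); `"keep"` retains them.
#' @return a list of class `filter_rule`.
#' @export
filter_rule <- function(min_axon_diameter = 0.1, max_axon_diameter = 15,
                        min_outer_diameter = 0.2, max_outer_diameter = 20,
                        g_ratio_range = c(0, 1),
                        border_policy = c("drop", "keep")) {
  border_policy <- match.arg(border_policy)
  stopifnot(min_axon_diameter < max_axon_diameter,
            min_outer_diameter < max_outer_diameter,
            g_ratio_range[1] < g_ratio_range[2])
  structure(list(min_axon_diameter = min_axon_diameter,
                 max_axon_diameter = max_axon_diameter,
                 min_outer_diameter = min_outer_diameter,
                 max_outer_diameter = max_outer_diameter,
                 g_ratio_range = g_ratio_range,
                 border_policy = border_policy),
            class = "filter_rule")
}

#' Filter measured fiber records
#'
#' Partitions fiber records into kept and rejected sets under a
#' [filter_rule()]. Every rejection carries a machine-readable reason
#' code (`axon_too_small`, `axon_too_large`, `outer_too_small`,
#' `outer_too_large`, `g_ratio_out_of_range`, `border_touch`,
#' `no_myelin`, `no_axon`, `degenerate_region`); the first violated
#' bound is reported. Kept and rejected rows partition the input.
#'
#' @param records a fiber-record data.frame from [measure_instances()].
#' @param rule a [filter_rule()].
#' @return list with data.frames `kept` and `rejected` (the latter with
#'   a `reason` column).
#' @export
filter_instances <- function(records, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  if (nrow(records) == 0L) {
    return(list(kept = records,
                rejected = cbind(records, reason = character(0))))
  }
  flags <- strsplit(ifelse(is.na(records$qc_flags), "", records$qc_flags), ";")
  reason <- character(nrow(records))
  has_flag <- function(f) vapply(flags, function(x) f %in% x, TRUE)
  take <- function(cond, code) reason == "" & !is.na(cond) & cond
  sel <- take(has_flag("no_axon"), "no_axon"); reason[sel] <- "no_axon"
  sel <- take(has_flag("no_myelin"), "no_myelin"); reason[sel] <- "no_myelin"
  sel <- take(has_flag("degenerate_region"), "x"); reason[sel] <- "degenerate_region"
  if (rule$border_policy == "drop") {
    sel <- take(has_flag("border_touch"), "x"); reason[sel] <- "border_touch"
  }
  sel <- take(records$axon_minor_um < rule$min_axon_diameter, "x")
  reason[sel] <- "axon_too_small"
  sel <- take(records$axon_minor_um > rule$max_axon_diameter, "x")
  reason[sel] <- "axon_too_large"
  sel <- take(records$outer_minor_um < rule$min_outer_diameter, "x")
  reason[sel] <- "outer_too_small"
  sel <- take(records$outer_minor_um > rule$max_outer_diameter, "x")
  reason[sel] <- "outer_too_large"
  sel <- take(records$g_ratio <= rule$g_ratio_range[1] |
                records$g_ratio > rule$g_ratio_range[2], "x")
  reason[sel] <- "g_ratio_out_of_range"

  kept <- records[reason == "", , drop = FALSE]
  rejected <- records[reason != "", , drop = FALSE]
  rejected$reason <- reason[reason != ""]
  rownames(kept) <- NULL; rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
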