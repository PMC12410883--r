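#' Semantic probability map
#'
#' Container for a 3-channel per-pixel class-score raster (background,
#' axon, myelin) with its physical pixel size. Scores are in [0, 1] and
#' sum to 1 per pixel.
#'
#' @param scores numeric array `nx x ny x 3`, channel order
#'   background/axon/myelin.
#' @param pixel_size_nm physical pixel edge length in nanometers.
#' @return an object of class `semantic_map`.
#' @export
semantic_map <- function(scores, pixel_size_nm) {
  stopifnot(length(dim(scores)) == 3, dim(scores)[3] == 3,
            is.numeric(pixel_size_nm), pixel_size_nm > 0)
  sums <- scores[, , 1] + scores[, , 2] + scores[, , 3]
  if (any(abs(sums - 1) > 1e-6))
    stop("semantic_map channel scores must sum to 1 per pixel")
  structure(list(scores = scores, pixel_size_nm = pixel_size_nm),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  d <- dim(x$scores)
  cat("semantic_map: ", d[1], " x ", d[2], " px, pixel size ",
      x$pixel_size_nm, " nm\n", sep = "")
  invisible(x)
}

#' Paired axon/myelin instance label rasters
#'
#' Two integer label rasters sharing fiber ids: one labels each fiber's
#' axon pixels, the other its myelin pixels; 0 is background.
#'
#' @param axon,myelin integer matrices of identical dimension.
#' @param pixel_size_nm physical pixel edge length in nanometers.
#' @return an object of class `instance_maps`.
#' @export
instance_maps <- function(axon, myelin, pixel_size_nm) {
  stopifnot(identical(dim(axon), dim(myelin)), pixel_size_nm > 0)
  storage.mode(axon) <- "integer"
  storage.mode(myelin) <- "integer"
  structure(list(axon = axon, myelin = myelin,
                 pixel_size_nm = pixel_size_nm),
            class = "instance_maps")
}

#' @export
print.instance_maps <- function(x, ...) {
  ids <- instance_ids(x)
  cat("instance_maps: ", nrow(x$axon), " x ", ncol(x$axon), " px, ",
      length(ids), " fiber ids, pixel size ", x$pixel_size_nm, " nm\n",
      sep = "")
  invisible(x)
}

#' @rdname instance_maps
#' @export
instance_ids <- function(axon, myelin = NULL) {
  if (inherits(axon, "instance_maps")) {
    myelin <- axon$myelin; axon <- axon$axon
  }
  sort(unique(c(axon[axon > 0], myelin[myelin > 0])))
}
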