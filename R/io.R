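# Raster, table and config I/O.
#
# On disk, rasters follow standard image orientation (first TIFF
# dimension = row = y); in memory the package indexes [x, y], so arrays
# are transposed on the way in and out. Lengths in tables are µm; pixel
# sizes in configs and sidecars are nm.

#' Read and write semantic maps
#'
#' Semantic maps are stored as 3-channel 32-bit float TIFFs (channel
#' order background/axon/myelin, scores in [0, 1]) with a JSON sidecar
#' (`<file>.json`) recording the pixel size in nm and the channel order.
#'
#' @param map a [semantic_map()].
#' @param path TIFF file path.
#' @param pixel_size_nm fallback pixel size when no sidecar exists.
#' @return `read_semantic_map` returns a [semantic_map()];
#'   `write_semantic_map` returns `path` invisibly.
#' @export
write_semantic_map <- function(map, path) {
  stopifnot(inherits(map, "semantic_map"))
  tiff::writeTIFF(aperm(map$scores, c(2, 1, 3)), path, bits.per.sample = 32)
  jsonlite::write_json(
    list(pixel_size_nm = map$pixel_size_nm,
         channels = c("background", "axon", "myelin")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_semantic_map
#' @export
read_semantic_map <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] != 3L)
    stop("malformed semantic map '", path, "': expected 3 channels, found ",
         if (length(dim(arr)) == 3L) dim(arr)[3] else 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size_nm <- meta$pixel_size_nm
  }
  if (is.null(pixel_size_nm))
    stop("pixel size unknown: no sidecar at '", sidecar,
         "' and no pixel_size_nm given")
  semantic_map(aperm(arr, c(2, 1, 3)), pixel_size_nm)
}

#' Read and write instance label maps
#'
#' Label rasters are stored as single-channel 16-bit unsigned TIFFs
#' (0 = background). Label ids above 65535 cannot be represented in
#' 16 bits; writing such a raster is an error advising 32-bit mode
#' (`bits = 32`, stored as float).
#'
#' @param labels integer label matrix, or an [instance_maps()] for the
#'   pair helpers.
#' @param path file path; the pair helpers write `axon_labels.tif` and
#'   `myelin_labels.tif` under a directory.
#' @param bits 16 (default) or 32.
#' @return read functions return integer matrices / [instance_maps()];
#'   write functions return the path invisibly.
#' @export
write_label_map <- function(labels, path, bits = 16) {
  mx <- max(labels)
  if (bits == 16 && mx > 65535L)
    stop("label image holds ", mx, " labels, exceeding the 16-bit limit ",
         "(65535); write with bits = 32 instead")
  if (bits == 16) {
    tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(t(labels) / 2^31, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, bits = 16) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- tiff::readTIFF(path, as.is = (bits == 16))
  if (length(dim(r)) != 2L)
    stop("malformed label map '", path, "': expected a single channel")
  m <- if (bits == 16) t(r) else round(t(r) * 2^31)
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_label_map
#' @export
write_instance_maps <- function(labels, path, bits = 16) {
  stopifnot(inherits(labels, "instance_maps"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_label_map(labels$axon, file.path(path, "axon_labels.tif"), bits)
  write_label_map(labels$myelin, file.path(path, "myelin_labels.tif"), bits)
  jsonlite::write_json(list(pixel_size_nm = labels$pixel_size_nm),
                       file.path(path, "instance_maps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_instance_maps <- function(path, bits = 16, pixel_size_nm = NULL) {
  meta_path <- file.path(path, "instance_maps.json")
  if (file.exists(meta_path))
    pixel_size_nm <- jsonlite::read_json(meta_path)$pixel_size_nm
  if (is.null(pixel_size_nm)) stop("pixel size unknown for '", path, "'")
  instance_maps(read_label_map(file.path(path, "axon_labels.tif"), bits),
                read_label_map(file.path(path, "myelin_labels.tif"), bits),
                pixel_size_nm)
}

#' Read and write fiber measurement tables
#'
#' Plain CSV, one row per fiber, lengths in µm. `read_fiber_table` can
#' assert that required columns are present, giving an explicit
#' column-not-found error for downstream stages (e.g. the GEV fit
#' requesting a missing measurement column).
#'
#' @param records a data.frame.
#' @param path CSV file path.
#' @param required character vector of required column names.
#' @return `read_fiber_table` returns a data.frame.
#' @export
write_fiber_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiber_table
#' @export
read_fiber_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("qc_flags" %in% names(tab)) {  # all-empty column reads back as NA
    tab$qc_flags <- as.character(tab$qc_flags)
    tab$qc_flags[is.na(tab$qc_flags)] <- ""
  }
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("column(s) not found in '", path, "': ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Read and write run configurations
#'
#' A [run_config()] round-trips losslessly through JSON.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw_config_args(raw))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # keep names: named vectors become JSON objects
  } else x
}
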