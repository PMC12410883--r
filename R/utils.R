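# Internal helpers shared across modules.
#
# Image convention: a 2-D raster is a plain matrix indexed [x, y] (first
# dimension horizontal), matching EBImage's Image layout so matrices can be
# handed to EBImage verbatim. Pixel centers sit at (i - 0.5, j - 0.5) in
# pixel units.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats runif qnorm pnorm
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  if (pu - pl <= 0) stop("truncation interval has zero mass")
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

as_ebi <- function(m) EBImage::Image(m * 1)

ebi_data <- function(img) {
  d <- EBImage::imageData(img)
  dim(d) <- dim(d)[1:2]
  d
}

# pixel-center coordinate grids for an nx x ny raster
pixel_grid <- function(nx, ny) {
  list(
    x = matrix(seq_len(nx) - 0.5, nx, ny),
    y = matrix(rep(seq_len(ny) - 0.5, each = nx), nx, ny)
  )
}

# bounding box (with pad) of TRUE pixels, clipped to the raster
mask_bbox <- function(mask, pad = 1L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  list(
    x = c(max(1L, min(w[, 1]) - pad), min(nrow(mask), max(w[, 1]) + pad)),
    y = c(max(1L, min(w[, 2]) - pad), min(ncol(mask), max(w[, 2]) + pad))
  )
}

crop_mask <- function(mask, bb) mask[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], drop = FALSE]

# remove connected components below a pixel-area threshold
remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- ebi_data(EBImage::bwlabel(as_ebi(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  if (!any(mask)) return(mask)
  ebi_data(EBImage::fillHull(as_ebi(mask))) > 0.5
}

# 8-connected boundary pixels of a binary mask
mask_boundary <- function(mask) {
  if (!any(mask)) return(mask)
  er <- ebi_data(EBImage::erode(as_ebi(mask), EBImage::makeBrush(3, "box"))) > 0.5
  mask & !er
}

# Zhang-Suen thinning; returns the 1-px skeleton of a binary mask.
zs_thin <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  m <- matrix(FALSE, nx + 2L, ny + 2L)
  m[2:(nx + 1L), 2:(ny + 1L)] <- mask
  shift <- function(a, dx, dy) {
    out <- matrix(FALSE, nrow(a), ncol(a))
    xs <- seq_len(nrow(a)) - dx; ys <- seq_len(ncol(a)) - dy
    ok_x <- xs >= 1 & xs <= nrow(a); ok_y <- ys >= 1 & ys <= ncol(a)
    out[ok_x, ok_y] <- a[xs[ok_x], ys[ok_y]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north; y+1 is "north" here (the
      # labelling is arbitrary, the algorithm is symmetric)
      p2 <- shift(m, 0, 1);  p3 <- shift(m, 1, 1);  p4 <- shift(m, 1, 0)
      p5 <- shift(m, 1, -1); p6 <- shift(m, 0, -1); p7 <- shift(m, -1, -1)
      p8 <- shift(m, -1, 0); p9 <- shift(m, -1, 1)
      bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ap <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nx + 1L), 2:(ny + 1L), drop = FALSE]
}

stop_domain <- function(msg) {
  stop(structure(class = c("fibermorph_domain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
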