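# Geometric fixtures built in code, used across test files.

disk_mask <- function(nx, ny, cx, cy, r) {
  g <- pixel_centers(nx, ny)
  matrix(sqrt((g$x - cx)^2 + (g$y - cy)^2) <= r, nx, ny)
}

ellipse_mask <- function(nx, ny, cx, cy, a, b, angle_deg = 0) {
  g <- pixel_centers(nx, ny)
  co <- cospi(angle_deg / 180); si <- sinpi(angle_deg / 180)
  dx <- g$x - cx; dy <- g$y - cy
  pu <- dx * co + dy * si; pv <- -dx * si + dy * co
  matrix((pu / a)^2 + (pv / b)^2 <= 1, nx, ny)
}

annulus_mask <- function(nx, ny, cx, cy, r_in, r_out) {
  disk_mask(nx, ny, cx, cy, r_out) & !disk_mask(nx, ny, cx, cy, r_in)
}

pixel_centers <- function(nx, ny) {
  list(x = as.vector(matrix(seq_len(nx) - 0.5, nx, ny)),
       y = as.vector(matrix(rep(seq_len(ny) - 0.5, each = nx), nx, ny)))
}

# one hand-placed fiber rasterized through the phantom machinery
single_fiber_raster <- function(axon_radius_um = 0.4, myelin_thickness_um = 0.2,
                                cut_angle_deg = 0, orientation_deg = 30,
                                canvas = c(300L, 300L), pixel_size_nm = 17.28) {
  px_um <- pixel_size_nm / 1000
  specs <- data.frame(
    fiber_id = 1L, axon_radius_um = axon_radius_um,
    myelin_thickness_um = myelin_thickness_um,
    cut_angle_deg = cut_angle_deg,
    center_x_um = canvas[1] / 2 * px_um, center_y_um = canvas[2] / 2 * px_um,
    orientation_deg = orientation_deg, kissing_partner = NA_integer_,
    g_ratio_true = axon_radius_um / (axon_radius_um + myelin_thickness_um))
  rasterize_population(specs, canvas, pixel_size_nm)
}

# one-sided Kolmogorov-Smirnov statistic of a sample against an analytic cdf
ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf(x)
  max(abs(fx - seq_len(n) / n), abs(fx - (seq_len(n) - 1) / n))
}

# minimal fiber-record rows for filter tests
make_record <- function(fiber_id = 1L, axon = 0.6, outer = 1.1, g = 0.55,
                        qc = "") {
  data.frame(fiber_id = fiber_id, axon_minor_um = axon,
             axon_major_um = axon * 1.2, outer_minor_um = outer,
             outer_major_um = outer * 1.2, eccentricity_axon = 0.5,
             eccentricity_outer = 0.5, orientation_deg = 0, g_ratio = g,
             axon_area_um2 = 0.3, outer_area_um2 = 1,
             d_eq_axon_um = axon * 1.1, myelin_thickness_skel_um = 0.25,
             qc_flags = qc)
}
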