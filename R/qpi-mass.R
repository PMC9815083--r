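#' Settings for the quantitative-phase dry-mass pipeline
#'
#' @param refraction_increment_cell specific refraction increment for
#'   cellular dry matter, mL/g. The literature-standard 0.18 mL/g is the
#'   default; it is a property of the dry matter, not of the instrument.
#' @param refraction_increment_bead increment used for polystyrene bead
#'   controls, mL/g (default 0.244, so a bead of refractive index 1.59 in
#'   medium of 1.333 has density (1.59 - 1.333)/0.244 ~ 1.053 pg/um^3).
#' @param background_percentile percentile (0-50) of pixel values used as
#'   the scalar background estimate.
#' @param segmentation_threshold OPD threshold for object detection, um.
#' @param min_area_px connected components smaller than this are discarded.
#' @return list of class \code{"qpi_settings"}.
#' @export
qpi_settings <- function(refraction_increment_cell = 0.18,
                         refraction_increment_bead = 0.244,
                         background_percentile = 5,
                         segmentation_threshold = 0.005,
                         min_area_px = 10L) {
  stopifnot_scalar_pos(refraction_increment_cell, "refraction_increment_cell")
  stopifnot_scalar_pos(refraction_increment_bead, "refraction_increment_bead")
  if (background_percentile < 0 || background_percentile > 50)
    stop("'background_percentile' must be in [0, 50]")
  stopifnot_scalar_pos(segmentation_threshold, "segmentation_threshold")
  structure(list(refraction_increment_cell = refraction_increment_cell,
                 refraction_increment_bead = refraction_increment_bead,
                 background_percentile = background_percentile,
                 segmentation_threshold = segmentation_threshold,
                 min_area_px = as.integer(min_area_px)),
            class = "qpi_settings")
}

as_phase_image <- function(img, pixel_size = NULL) {
  if (inherits(img, "phase_image")) return(img)
  if (is.matrix(img)) {
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
    return(structure(list(opd = img, pixel_size = pixel_size),
                     class = "phase_image"))
  }
  stop("not a phase image")
}

#' Subtract a scalar background from a phase image
#'
#' Estimates the background as a low percentile of all pixel values and
#' subtracts it, so that off-object pixels average approximately zero. A
#' scalar estimate is adequate for the flat synthetic backgrounds produced
#' by [render_phase_image()]; spatially varying (polynomial) background
#' models are out of scope.
#'
#' @param img a \code{"phase_image"}.
#' @param background_percentile percentile in [0, 50] (default 5).
#' @return The background-corrected \code{"phase_image"}.
#' @export
subtract_background <- function(img, background_percentile = 5) {
  img <- as_phase_image(img)
  if (background_percentile < 0 || background_percentile > 50)
    stop("'background_percentile' must be in [0, 50]")
  bg <- stats::quantile(img$opd, background_percentile / 100, names = FALSE)
  img$opd <- img$opd - bg
  img
}

#' Threshold-segment objects in a phase image
#'
#' Labels connected components (8-connectivity) of pixels whose OPD exceeds
#' \code{threshold}; components smaller than \code{min_area_px} pixels are
#' discarded and the remaining labels renumbered 1..K. An image with nothing
#' above threshold yields an all-zero label matrix, not an error.
#'
#' @param img a \code{"phase_image"}.
#' @param threshold OPD threshold, um (> 0).
#' @param min_area_px minimum component size in pixels.
#' @return Integer label matrix of the same shape as the image.
#' @export
segment_objects <- function(img, threshold = 0.005, min_area_px = 10L) {
  img <- as_phase_image(img)
  stopifnot_scalar_pos(threshold, "threshold")
  bin <- img$opd > threshold
  if (!any(bin)) return(matrix(0L, nrow(img$opd), ncol(img$opd)))
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(img$opd), ncol(img$opd))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(matrix(0L, nrow(img$opd), ncol(img$opd)))
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Integrate dry mass over a mask
#'
#' Dry mass from quantitative phase imaging: the optical path difference
#' integrated over the object area, divided by the specific refraction
#' increment,
#' \deqn{m = \frac{\Delta x^2}{\alpha} \sum_{mask} OPD,}
#' with \eqn{\Delta x} the pixel size (um), OPD in um, \eqn{\alpha} in mL/g
#' (= um^3/pg), giving mass in pg.
#'
#' @param img a \code{"phase_image"}.
#' @param mask logical matrix of the image shape, or an integer label matrix
#'   together with \code{label}; \code{NULL} integrates the whole image.
#' @param refraction_increment alpha, mL/g.
#' @param label which label of an integer mask to integrate.
#' @return Dry mass, pg. An empty mask returns 0 with a warning.
#' @examples
#' opd <- matrix(0.1, 10, 10)
#' img <- structure(list(opd = opd, pixel_size = 0.045), class = "phase_image")
#' integrate_dry_mass(img, refraction_increment = 0.18)  # 0.1125 pg
#' @export
integrate_dry_mass <- function(img, mask = NULL, refraction_increment = 0.18,
                               label = 1L) {
  img <- as_phase_image(img)
  stopifnot_scalar_pos(refraction_increment, "refraction_increment")
  if (is.null(mask)) {
    sel <- rep(TRUE, length(img$opd))
  } else {
    if (!all(dim(mask) == dim(img$opd)))
      stop("mask dimensions do not match the image")
    sel <- if (is.logical(mask)) mask else mask == label
  }
  if (!any(sel)) {
    warning("empty mask: returning mass 0")
    return(0)
  }
  img$pixel_size^2 / refraction_increment * sum(img$opd[sel])
}

#' Spherocylinder volume
#'
#' Volume of the standard rod-cell model: a cylinder of length
#' \code{length - width} capped by two hemispheres of diameter \code{width},
#' \deqn{V = \pi (w/2)^2 (l - w) + \tfrac{4}{3}\pi (w/2)^3.}
#' \code{length == width} degenerates to a sphere.
#'
#' @param length,width cell dimensions, um; \code{length >= width > 0}.
#' @return Volume, um^3.
#' @examples
#' spherocylinder_volume(1, 1)   # pi/6, a sphere
#' spherocylinder_volume(3, 1)   # 2.0944
#' @export
spherocylinder_volume <- function(length, width) {
  if (any(width <= 0) || any(length < width))
    stop("spherocylinder requires length >= width > 0")
  r <- width / 2
  pi * r^2 * (length - width) + 4 / 3 * pi * r^3
}

#' Dry-mass density
#'
#' @param m_cell dry mass, pg.
#' @param v_cell volume, um^3 (> 0).
#' @return Density \code{m_cell / v_cell}, pg/um^3.
#' @export
dry_mass_density <- function(m_cell, v_cell) {
  if (any(v_cell <= 0)) stop("'v_cell' must be positive")
  m_cell / v_cell
}

#' Measure single cells in a phase image
#'
#' The full dry-mass pipeline: background correction, threshold
#' segmentation, per-object mass integration and method-of-moments
#' spherocylinder morphometrics, giving mass, volume and dry-mass density
#' per cell.
#'
#' Two design points matter for accuracy at the ~20-pixel scale of a
#' bacterium. First, each object's mass is integrated over its detection
#' mask dilated by \code{dilate_px} pixels, recovering the faint rim where
#' the projected thickness falls below the segmentation threshold; the
#' residual background is estimated as the mean of all off-object pixels
#' and removed first, so the dilation ring contributes zero-mean noise
#' only. Second, length and width are not taken from mask extents (which
#' carry whole-pixel aliasing) but from the OPD-weighted second moments:
#' for a spherocylinder the perpendicular and axial variances of the
#' projected-thickness distribution have closed forms in the radius and
#' cylinder half-length, and inverting the two moment equations yields
#' sub-pixel estimates that are threshold-free and robust to noise. The
#' uniform pixel-integration variance \code{pixel_size^2 / 12} is
#' subtracted from each moment before inversion.
#'
#' @param img a \code{"phase_image"}.
#' @param settings a [qpi_settings()].
#' @param t_min acquisition time stamp propagated to the output, min.
#' @param refraction_increment overrides the cell increment if given, mL/g.
#' @param dilate_px mask dilation radius for mass integration and moment
#'   computation, px.
#' @return Data frame with columns \code{cell_id}, \code{t_min},
#'   \code{mass_pg}, \code{volume_um3}, \code{density_pg_um3},
#'   \code{length_um}, \code{width_um}, \code{area_um2}.
#' @export
measure_cells <- function(img, settings = qpi_settings(), t_min = 0,
                          refraction_increment = NULL, dilate_px = 5L) {
  img <- as_phase_image(img)
  alpha <- if (is.null(refraction_increment))
    settings$refraction_increment_cell else refraction_increment
  px <- img$pixel_size
  # rough scalar background, then refine with the off-object mean
  work <- img$opd - stats::median(img$opd)
  wimg <- structure(list(opd = work, pixel_size = px), class = "phase_image")
  lab <- segment_objects(wimg, settings$segmentation_threshold,
                         settings$min_area_px)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(cell_id = integer(), t_min = numeric(),
                      mass_pg = numeric(), volume_um3 = numeric(),
                      density_pg_um3 = numeric(), length_um = numeric(),
                      width_um = numeric(), area_um2 = numeric()))
  dil_all <- dilate_mask(lab > 0L, dilate_px)
  if (any(!dil_all)) work <- work - mean(work[!dil_all])
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sel <- lab == i
    msel <- dilate_mask(sel, dilate_px)
    geo <- opd_moments_geometry(work, msel, px)
    m <- px^2 / alpha * sum(work[msel])
    v <- spherocylinder_volume(max(geo[["length"]], geo[["width"]]),
                               geo[["width"]])
    out[[i]] <- data.frame(cell_id = i, t_min = t_min, mass_pg = m,
                           volume_um3 = v, density_pg_um3 = m / v,
                           length_um = geo[["length"]],
                           width_um = geo[["width"]],
                           area_um2 = sum(sel) * px^2)
  }
  do.call(rbind, out)
}

# spherocylinder geometry from OPD-weighted second moments.
# With weight proportional to projected thickness, the closed forms are
#   Var_perp = r^2 (Vc/4 + Vs/5) / (Vc + Vs)
#   Var_ax   = [ (2/3) pi r^2 a^3
#                + 2 pi ((2/3) a^2 r^3 + (1/2) a r^4 + (2/15) r^5) ]
#              / (Vc + Vs)
# with Vc = 2 pi r^2 a (cylinder of half-length a) and Vs = (4/3) pi r^3
# (the two hemispherical caps); a = 0 degenerates to a sphere, where both
# variances equal r^2/5.
capsule_var_perp <- function(r, a) {
  vc <- 2 * pi * r^2 * a; vs <- 4 / 3 * pi * r^3
  r^2 * (vc / 4 + vs / 5) / (vc + vs)
}
capsule_var_ax <- function(r, a) {
  vc <- 2 * pi * r^2 * a; vs <- 4 / 3 * pi * r^3
  cyl <- (2 / 3) * pi * r^2 * a^3
  caps <- 2 * pi * ((2 / 3) * a^2 * r^3 + 0.5 * a * r^4 + (2 / 15) * r^5)
  (cyl + caps) / (vc + vs)
}

solve_capsule_moments <- function(v_pe, v_ax) {
  if (v_ax < v_pe) v_ax <- v_pe               # numerically spherical
  r <- 2 * sqrt(v_pe)
  a <- 0
  for (it in 1:60) {
    a <- if (capsule_var_ax(r, 0) >= v_ax) 0 else
      stats::uniroot(function(aa) capsule_var_ax(r, aa) - v_ax,
                     c(0, 50 * r + 10 * sqrt(v_ax)), tol = 1e-12)$root
    r_new <- stats::uniroot(function(rr) capsule_var_perp(rr, a) - v_pe,
                            c(1e-9, 10 * sqrt(v_pe) + 1e-6),
                            tol = 1e-12)$root
    done <- abs(r_new - r) < 1e-12
    r <- r_new
    if (done) break
  }
  c(width = 2 * r, length = 2 * a + 2 * r)
}

opd_moments_geometry <- function(work, mask, px) {
  idx <- which(mask, arr.ind = TRUE)
  v <- work[mask]
  if (length(v) < 4L || sum(v) <= 0) return(c(length = px, width = px))
  xy <- cbind(idx[, 2], idx[, 1]) * px
  ctr <- colSums(xy * v) / sum(v)
  xyc <- sweep(xy, 2, ctr)
  cv <- t(xyc) %*% (xyc * v) / sum(v)
  ev <- eigen(cv, symmetric = TRUE)$values
  # remove the variance of uniform averaging over a pixel
  v_ax <- max(ev[1] - px^2 / 12, 1e-12)
  v_pe <- max(ev[2] - px^2 / 12, 1e-12)
  solve_capsule_moments(v_pe, v_ax)
}

# binary dilation with a square structuring element (radius r pixels)
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

#' Per-cell density statistics over a time course
#'
#' Summarizes dry-mass density of each tracked cell across time points and
#' flags cells whose density drifts more than expected, a check of the
#' density-homeostasis assumption (density stays constant during
#' exponential growth; only measurement noise should remain).
#'
#' @param records data frame with columns \code{cell_id}, \code{t_min},
#'   \code{density_pg_um3} (as written by [measure_cells()]).
#' @param cv_bound flag cells whose density CV exceeds this bound.
#' @return Data frame with per-cell \code{n}, \code{mean_density},
#'   \code{sd_density}, \code{cv}, and logical \code{flagged}.
#' @export
density_timecourse <- function(records, cv_bound = 0.1) {
  if (!all(c("cell_id", "t_min", "density_pg_um3") %in% names(records)))
    stop("records must have columns cell_id, t_min, density_pg_um3")
  sp <- split(records$density_pg_um3, records$cell_id)
  bad <- names(sp)[vapply(sp, length, 1L) < 2L]
  if (length(bad))
    stop("need >= 2 time points per cell (cell ", bad[1], " has fewer)")
  out <- data.frame(
    cell_id = names(sp),
    n = vapply(sp, length, 1L),
    mean_density = vapply(sp, mean, 1),
    sd_density = vapply(sp, stats::sd, 1))
  out$cv <- out$sd_density / out$mean_density
  out$flagged <- out$cv > cv_bound
  rownames(out) <- NULL
  out
}
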