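#' Configuration for the mother-machine track generator
#'
#' Bundles and validates the parameters of the synthetic division-event
#' generator. The defaults reproduce the study conditions of the microfluidic
#' perfusion ("mother machine") experiments the analysis pipeline was built
#' for: Monod kinetics with \code{mu_max} = 0.66 1/h and a mean whole-cell
#' glucose affinity of 486 ug/L with ~48\% cell-to-cell coefficient of
#' variation, ~40\% multiplicative observation noise on doubling times, eight
#' log-spaced glucose levels spanning 1e-5 to 10 g/L, three mother lineages
#' of 60 division events each per level, and a 5-min imaging interval.
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param ks_mean mean Monod (half-saturation) constant, g/L.
#' @param ks_cv coefficient of variation of the per-cell Monod constant
#'   (drawn from a normal truncated at zero).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise applied to each doubling time. The multiplier has unit median so
#'   geometric-mean statistics remain centred.
#' @param glucose_levels vector of steady glucose concentrations, g/L.
#' @param events_per_level division events generated per lineage and level.
#' @param n_lineages mother lineages tracked per glucose level.
#' @param frame_interval imaging interval, min; division timestamps are
#'   quantized to this grid to emulate frame-limited detection.
#' @param artifact_rate probability per division event of injecting a
#'   spurious "consecutive division" artifact (an extra division one frame
#'   after the previous one), which downstream analysis must down-weight.
#' @param seed integer seed making the generator reproducible.
#' @return A validated list of class \code{"generator_config"}.
#' @seealso [simulate_mother_machine_tracks()]
#' @export
generator_config <- function(mu_max = 0.66,
                             ks_mean = 4.86e-4,
                             ks_cv = 234 / 486,
                             noise_cv = 0.4,
                             glucose_levels = 10^seq(-5, 1, length.out = 8),
                             events_per_level = 60L,
                             n_lineages = 3L,
                             frame_interval = 5,
                             artifact_rate = 0.01,
                             seed = 1L) {
  stopifnot_scalar_pos(mu_max, "mu_max")
  stopifnot_scalar_pos(ks_mean, "ks_mean")
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (ks_cv < 0 || noise_cv < 0)
    stop("'ks_cv' and 'noise_cv' must be >= 0")
  if (length(glucose_levels) < 1L || any(!is.finite(glucose_levels)) ||
      any(glucose_levels <= 0))
    stop("glucose levels must be positive finite concentrations (g/L); got ",
         paste(format(glucose_levels), collapse = ", "))
  if (events_per_level < 1L) stop("'events_per_level' must be >= 1")
  if (n_lineages < 1L) stop("'n_lineages' must be >= 1")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("'artifact_rate' must be in [0, 1]")
  structure(list(mu_max = mu_max, ks_mean = ks_mean, ks_cv = ks_cv,
                 noise_cv = noise_cv, glucose_levels = as.numeric(glucose_levels),
                 events_per_level = as.integer(events_per_level),
                 n_lineages = as.integer(n_lineages),
                 frame_interval = frame_interval,
                 artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate mother-machine division-event tracks
#'
#' Generates lineage-resolved division timestamps for mother cells grown at
#' steady glucose concentrations. Each offspring cell draws its own Monod
#' constant from a normal distribution truncated at zero (mean
#' \code{ks_mean}, CV \code{ks_cv}); its doubling time is
#' \code{log(2) / mu} with \code{mu = mu_max * S / (ks_cell + S)}, multiplied
#' by unit-median lognormal noise with CV \code{noise_cv}. Cumulative
#' division timestamps are quantized to the imaging frame interval, and
#' spurious consecutive-division artifacts (an extra detected division one
#' frame later) are injected at rate \code{artifact_rate} so that the
#' outlier down-weighting rule of the kinetics module is exercised.
#'
#' @param cfg a [generator_config()].
#' @return A data frame with one row per division event and columns
#'   \code{lineage_id}, \code{cell_id}, \code{parent_id}, \code{generation},
#'   \code{division_time_min}, \code{glucose_g_per_L}, plus attribute
#'   \code{"config"} carrying the generator settings.
#' @examples
#' cfg <- generator_config(glucose_levels = c(0.01, 1), events_per_level = 20,
#'                         n_lineages = 1, seed = 7)
#' tracks <- simulate_mother_machine_tracks(cfg)
#' head(tracks)
#' @export
simulate_mother_machine_tracks <- function(cfg) {
  if (!inherits(cfg, "generator_config"))
    cfg <- do.call(generator_config, cfg)
  set.seed(cfg$seed)
  rows <- vector("list", length(cfg$glucose_levels) * cfg$n_lineages)
  k <- 0L
  for (li in seq_along(cfg$glucose_levels)) {
    S <- cfg$glucose_levels[li]
    for (lin in seq_len(cfg$n_lineages)) {
      n <- cfg$events_per_level
      ks_cell <- rtruncnorm_pos(n, cfg$ks_mean, cfg$ks_cv * cfg$ks_mean)
      mu_cell <- cfg$mu_max * S / (ks_cell + S)
      td_min <- log(2) / mu_cell * 60 * rlnorm_cv(n, cfg$noise_cv)
      t_div <- cumsum(td_min)
      # frame-limited detection: divisions are only seen on the imaging grid
      t_div <- round(t_div / cfg$frame_interval) * cfg$frame_interval
      # quantization may collapse two events onto one frame; push ties apart
      t_div <- fix_monotone_frames(t_div, cfg$frame_interval)
      # spurious double-detections: an extra "division" one frame after a
      # real one, as produced by segmentation glitches
      if (cfg$artifact_rate > 0) {
        spur <- which(stats::runif(n) < cfg$artifact_rate)
        if (length(spur)) {
          extra <- t_div[spur] + cfg$frame_interval
          t_div <- sort(c(t_div, extra))
        }
      }
      n_ev <- length(t_div)
      lineage <- sprintf("S%02d_L%02d", li, lin)
      k <- k + 1L
      rows[[k]] <- data.frame(
        lineage_id = lineage,
        cell_id = sprintf("%s_c%03d", lineage, seq_len(n_ev)),
        parent_id = c(sprintf("%s_c000", lineage),
                      sprintf("%s_c%03d", lineage, seq_len(n_ev - 1L))),
        generation = seq_len(n_ev),
        division_time_min = t_div,
        glucose_g_per_L = S,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}

# push ties apart by one frame so timestamps are strictly increasing
fix_monotone_frames <- function(t, frame) {
  for (i in seq_along(t)[-1]) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + frame
  t
}

#' Specify cells or beads for phase-image rendering
#'
#' Builds the object table consumed by [render_phase_image()]. Cells are
#' modelled as spherocylinders (a cylinder of length \code{length - width}
#' capped by hemispheres of diameter \code{width}); a bead is the degenerate
#' case \code{length == width}, i.e. a sphere.
#'
#' @param length,width object dimensions, um; \code{length >= width > 0}.
#' @param density dry-mass density, pg/um^3.
#' @param refraction_increment specific refraction increment alpha, mL/g
#'   (numerically equal to um^3/pg).
#' @param x,y centre position, um.
#' @param orientation major-axis angle, radians.
#' @return A data frame with one row per object.
#' @export
cell_spec <- function(length, width, density,
                      refraction_increment = 0.18,
                      x = 0, y = 0, orientation = 0) {
  d <- data.frame(length = length, width = width, density = density,
                  refraction_increment = refraction_increment,
                  x = x, y = y, orientation = orientation)
  bad <- d$width <= 0 | d$length < d$width
  if (any(bad))
    stop("cell_spec requires length >= width > 0 (violated for object(s) ",
         paste(which(bad), collapse = ", "), ")")
  if (any(d$density <= 0) || any(d$refraction_increment <= 0))
    stop("density and refraction_increment must be positive")
  d
}

#' Render a synthetic optical-path-difference (phase) image
#'
#' Projects 3-D spherocylinders (cells) or spheres (beads) onto the image
#' plane. The optical path difference at a pixel is the sum over objects of
#' \code{density * refraction_increment * thickness}, where \code{thickness}
#' is the chord length of the object along the optical axis at that pixel,
#' plus optional additive Gaussian background noise. OPD is in um; this is
#' the idealized projection model (no diffraction or halo artifacts).
#'
#' @param objects object table from [cell_spec()] (possibly empty).
#' @param pixel_size pixel edge length, um (default 0.045).
#' @param image_shape integer vector (rows, cols) in pixels.
#' @param noise_sd standard deviation of additive Gaussian background, um.
#' @param seed optional seed for the noise draw.
#' @return A \code{"phase_image"}: list with matrix \code{opd} (um) and
#'   \code{pixel_size} (um).
#' @examples
#' bead <- cell_spec(1, 1, density = 1.05, refraction_increment = 0.244,
#'                   x = 1.5, y = 1.5)
#' img <- render_phase_image(bead, image_shape = c(64, 64), noise_sd = 0)
#' sum(img$opd) * img$pixel_size^2   # ~ density * alpha * sphere volume
#' @export
render_phase_image <- function(objects, pixel_size = 0.045,
                               image_shape = c(128L, 128L),
                               noise_sd = 0, seed = NULL) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (nr < 1L || nc < 1L) stop("image_shape must be positive")
  opd <- matrix(0, nr, nc)
  # pixel centres; x runs along columns, y along rows (row-major, 0-based)
  xs <- (seq_len(nc) - 0.5) * pixel_size
  ys <- (seq_len(nr) - 0.5) * pixel_size
  if (!is.null(objects) && nrow(objects) > 0) {
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      half <- ob$length / 2
      if (ob$x - half < 0 || ob$x + half > nc * pixel_size ||
          ob$y - half < 0 || ob$y + half > nr * pixel_size)
        stop("object ", i, " extends beyond image bounds")
      r <- ob$width / 2
      a <- (ob$length - ob$width) / 2       # half-length of cylindrical part
      # restrict to the bounding box of the object for speed
      ci <- which(xs >= ob$x - half - pixel_size & xs <= ob$x + half + pixel_size)
      ri <- which(ys >= ob$y - half - pixel_size & ys <= ob$y + half + pixel_size)
      dx0 <- outer(rep(1, length(ri)), xs[ci] - ob$x)
      dy0 <- outer(ys[ri] - ob$y, rep(1, length(ci)))
      co <- cos(ob$orientation); si <- sin(ob$orientation)
      ax <- dx0 * co + dy0 * si             # along major axis
      pe <- -dx0 * si + dy0 * co            # perpendicular
      axc <- pmin(pmax(ax, -a), a)          # nearest axis-segment point
      d2 <- (ax - axc)^2 + pe^2
      th <- matrix(0, length(ri), length(ci))
      inside <- d2 < r^2
      th[inside] <- 2 * sqrt(r^2 - d2[inside])
      opd[ri, ci] <- opd[ri, ci] +
        ob$density * ob$refraction_increment * th
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    opd <- opd + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  structure(list(opd = opd, pixel_size = pixel_size), class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  cat("phase image:", nrow(x$opd), "x", ncol(x$opd), "px,",
      "pixel", x$pixel_size, "um, OPD range",
      format(min(x$opd), digits = 3), "to",
      format(max(x$opd), digits = 3), "um\n")
  invisible(x)
}

#' Simulate a picoliter batch chamber experiment
#'
#' Integrates Monod batch growth of a microcolony in a sealed chamber of
#' known volume: biomass grows at \code{mu(S)} with
#' \code{S = substrate_mass / reactor_volume} (pg/pL = g/L), substrate is
#' consumed at \code{mu * X / yield_true}, and the observable is the
#' projected colony area \code{biomass / (density * chamber_height)} sampled
#' every \code{dt} minutes, optionally with multiplicative lognormal
#' measurement noise. The series ends at substrate exhaustion (remaining
#' substrate below 1e-6 of the initial amount) or at \code{t_max}.
#'
#' @param s0_mass initial substrate mass in the chamber, pg.
#' @param reactor_volume total cultivation volume, pL (default 606, the
#'   chamber-plus-reservoir volume of the picoliter batch device).
#' @param chamber_height chamber height, um (default 1, monolayer growth).
#' @param yield_true substrate-to-biomass yield used by the generator, g/g.
#' @param monod list with \code{mu_max} (1/h) and \code{ks} (g/L).
#' @param x0_mass inoculum dry mass, pg.
#' @param density cell dry-mass density used to convert biomass to projected
#'   area, pg/um^3.
#' @param dt observation interval, min (default 20, the batch imaging rate).
#' @param t_max maximum simulated time, min.
#' @param post_exhaustion_frames stationary-phase frames recorded after
#'   substrate exhaustion, so downstream yield estimation sees the plateau.
#' @param area_noise_cv CV of multiplicative lognormal noise on the observed
#'   area (default 0.02, emulating segmentation error).
#' @param seed seed for the measurement noise.
#' @return Data frame with columns \code{time_min}, \code{area_um2},
#'   \code{substrate_pg}, plus attribute \code{"truth"} with the generating
#'   parameters.
#' @examples
#' ser <- simulate_picoliter_batch(s0_mass = 606, yield_true = 0.45,
#'                                 x0_mass = 6, area_noise_cv = 0)
#' tail(ser, 2)  # final biomass = area * height * density ~ 6 + 0.45*606
#' @export
simulate_picoliter_batch <- function(s0_mass,
                                     reactor_volume = 606,
                                     chamber_height = 1,
                                     yield_true = 0.44,
                                     monod = list(mu_max = 0.66, ks = 4.86e-4),
                                     x0_mass = 2,
                                     density = 0.2,
                                     dt = 20,
                                     t_max = 5760,
                                     post_exhaustion_frames = 10L,
                                     area_noise_cv = 0.02,
                                     seed = 1L) {
  stopifnot_scalar_pos(s0_mass, "s0_mass")
  stopifnot_scalar_pos(reactor_volume, "reactor_volume")
  stopifnot_scalar_pos(chamber_height, "chamber_height")
  stopifnot_scalar_pos(density, "density")
  stopifnot_scalar_pos(dt, "dt")
  if (!is.numeric(yield_true) || yield_true <= 0)
    stop("'yield_true' must be positive")
  if (x0_mass < 0) stop("'x0_mass' must be >= 0")
  mu_max <- monod$mu_max; ks <- monod$ks
  stopifnot_scalar_pos(mu_max, "monod$mu_max")
  stopifnot_scalar_pos(ks, "monod$ks")

  # substrate follows from biomass by mass balance, so the ODE reduces to a
  # scalar RK4 integration of X; carbon book-keeping is then exact
  x_cap <- x0_mass + yield_true * s0_mass
  mu_of_x <- function(x) {
    s <- max(s0_mass - (x - x0_mass) / yield_true, 0)
    mu_max * (s / reactor_volume) / (ks + s / reactor_volume)
  }
  h_min <- dt / ceiling(dt / 0.5)          # internal step <= 0.5 min
  h <- h_min / 60                          # h
  times <- seq(0, t_max, by = dt)
  x <- numeric(length(times)); x[1] <- x0_mass
  cur <- x0_mass
  n_sub <- round(dt / h_min)
  last <- length(times)
  for (i in seq_along(times)[-1]) {
    for (s in seq_len(n_sub)) {
      k1 <- mu_of_x(cur) * cur
      k2 <- mu_of_x(cur + h / 2 * k1) * (cur + h / 2 * k1)
      k3 <- mu_of_x(cur + h / 2 * k2) * (cur + h / 2 * k2)
      k4 <- mu_of_x(cur + h * k3) * (cur + h * k3)
      cur <- min(cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), x_cap)
    }
    x[i] <- cur
    if (s0_mass - (cur - x0_mass) / yield_true < 1e-6 * s0_mass) {
      last <- i; break
    }
  }
  times <- times[seq_len(last)]; x <- x[seq_len(last)]
  # stationary-phase plateau after exhaustion (flat biomass, spent medium)
  if (last < length(seq(0, t_max, by = dt)) && post_exhaustion_frames > 0L) {
    extra <- seq_len(post_exhaustion_frames)
    times <- c(times, times[last] + extra * dt)
    x <- c(x, rep(x[last], post_exhaustion_frames))
  }
  substrate <- pmax(s0_mass - (x - x0_mass) / yield_true, 0)
  area <- x / (density * chamber_height)
  if (area_noise_cv > 0) {
    set.seed(seed)
    area <- area * rlnorm_cv(length(area), area_noise_cv)
  }
  out <- data.frame(time_min = times, area_um2 = area, substrate_pg = substrate)
  attr(out, "truth") <- list(yield_true = yield_true, x0_mass = x0_mass,
                             s0_mass = s0_mass, density = density,
                             chamber_height = chamber_height,
                             reactor_volume = reactor_volume,
                             monod = list(mu_max = mu_max, ks = ks))
  out
}
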