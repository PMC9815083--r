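# flat key-value configuration and shared readers/writers

config_defaults <- function() {
  list(
    pixel_size_um         = 0.045,  # phase imaging, 160x magnification
    frame_interval_mm_min = 5,      # mother-machine imaging interval
    frame_interval_plb_min = 20,    # picoliter-batch imaging interval
    alpha_cell_ml_per_g   = 0.18,   # refraction increment, cellular dry matter
    alpha_bead_ml_per_g   = 0.244,  # refraction increment, polystyrene
    chamber_width_um      = 60,
    chamber_length_um     = 100,
    chamber_height_um     = 1,
    reactor_volume_pl     = 606,
    m_x_g_per_cmol        = 24.63,  # biomass CH1.8O0.5N0.2
    m_s_g_per_cmol        = 30.03,  # glucose CH2O
    mu_max_h              = 0.66,
    ks_mean_g_l           = 4.86e-4,
    ks_cv                 = 234 / 486,
    noise_cv              = 0.4,
    yield_xs_g_g          = 0.44,
    mu_ref_h              = 0.61,   # growth rate at the reference batch level
    density_pg_um3        = 0.2,
    s0_g_l                = 1,      # reference batch glucose level (0.1% w/v)
    seed                  = 1,
    output_dir            = "microphys-out")
}

# keys that must be strictly positive numbers
config_positive_keys <- function() {
  setdiff(names(config_defaults()), c("seed", "output_dir"))
}

#' Load a flat key-value run configuration
#'
#' Reads a plain-text configuration of \code{key = value} (or
#' \code{key: value}) lines; blank lines and \code{#} comments are ignored.
#' Missing keys take their defaults; unknown keys and non-positive physical
#' quantities are rejected with the offending key named. The returned
#' object records, per key, whether the value came from the file or from
#' the defaults.
#'
#' @param path path to the configuration file, or \code{NULL} for all
#'   defaults.
#' @return List of class \code{"run_config"} with attribute
#'   \code{"provenance"} (named character vector, \code{"user"} or
#'   \code{"default"}).
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  prov <- setNames(rep("default", length(cfg)), names(cfg))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
      if (length(kv) != 2L)
        stop("cannot parse config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg))
        stop("unknown config key: '", key, "'")
      if (key == "output_dir") {
        cfg[[key]] <- val
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num))
          stop("config key '", key, "' must be numeric; got '", val, "'")
        cfg[[key]] <- num
      }
      prov[key] <- "user"
    }
  }
  for (key in config_positive_keys())
    if (!is.finite(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config key '", key, "' must be positive; got ", cfg[[key]])
  structure(cfg, provenance = prov, class = "run_config")
}

#' Save a run configuration
#'
#' Writes the configuration back as \code{key = value} lines at full
#' precision, so that \code{load_config(save_config(cfg, f))} round-trips.
#'
#' @param cfg a \code{"run_config"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  vals <- vapply(names(config_defaults()), function(k) {
    v <- cfg[[k]]
    if (is.character(v)) v else format(v, digits = 17)
  }, "")
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("run configuration:\n")
  for (k in names(config_defaults()))
    cat(sprintf("  %-23s %-12s (%s)\n", k, format(x[[k]]), prov[[k]]))
  invisible(x)
}

#' Write and read a phase image as float TIFF with a metadata sidecar
#'
#' The OPD matrix is stored as a 32-bit float single-page TIFF. Because the
#' TIFF writer stores values in [0, 1], the OPD is affinely encoded and the
#' offset/scale recorded, together with the pixel size, in a plain-text
#' sidecar (\code{<image>.meta}); \code{read_phase_image} inverts the
#' encoding.
#'
#' @param img a \code{"phase_image"}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly (writer); a \code{"phase_image"} (reader).
#' @export
write_phase_image <- function(img, path) {
  img <- as_phase_image(img)
  lo <- min(img$opd); hi <- max(img$opd)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$opd - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  writeLines(c(paste("pixel_size_um =", format(img$pixel_size, digits = 17)),
               paste("opd_offset_um =", format(lo, digits = 17)),
               paste("opd_scale_um =", format(scale, digits = 17))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_phase_image
#' @param path path to a TIFF written by \code{write_phase_image}.
#' @export
read_phase_image <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- load_kv(meta_path)
  m <- tiff::readTIFF(path)
  opd <- m * meta$opd_scale_um + meta$opd_offset_um
  structure(list(opd = opd, pixel_size = meta$pixel_size_um),
            class = "phase_image")
}

load_kv <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) as.numeric(trimws(p[2])))
  setNames(vals, vapply(kv, function(p) trimws(p[1]), ""))
}

#' Run the microscale physiology pipeline end to end
#'
#' Chains the workflow stages on synthetic data: \code{generate} (tracks,
#' phase image, batch chamber series), \code{mass} (single-cell dry masses
#' and densities from the phase image), \code{kinetics} (growth points and
#' the Monod fit), \code{yield} (chamber-wise substrate-to-biomass yields),
#' \code{balance} (Cmol carbon closure) and \code{model} (ensemble batch
#' simulation with affinity heterogeneity). Stages must form a prefix of
#' this order; each stage reads its predecessors' outputs from the output
#' directory and a JSON run report records package version, seed,
#' parameters and per-stage row counts.
#'
#' @param config a \code{"run_config"} from [load_config()].
#' @param stages character vector, a prefix of
#'   \code{c("generate", "mass", "kinetics", "yield", "balance", "model")}.
#' @return The run report (list), invisibly; artifacts and
#'   \code{report.json} are written to \code{config$output_dir}.
#' @export
run_pipeline <- function(config = load_config(),
                         stages = c("generate", "mass", "kinetics",
                                    "yield", "balance", "model")) {
  order_ <- c("generate", "mass", "kinetics", "yield", "balance", "model")
  if (!all(stages %in% order_))
    stop("unknown stage(s): ", paste(setdiff(stages, order_), collapse = ", "))
  if (!identical(as.character(stages), order_[seq_along(stages)]))
    stop("stages must form a prefix of: ", paste(order_, collapse = " -> "))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(package = "microphys",
                 version = as.character(utils::packageVersion("microphys")),
                 seed = seed,
                 parameters = unclass(config)[config_positive_keys()],
                 stages = list())
  log_stage <- function(stage, ...) message("[", stage, "] ", ...)
  need_file <- function(stage, f) {
    p <- file.path(out, f)
    if (!file.exists(p))
      stop("stage '", stage, "' requires '", f,
           "' from an earlier stage; run the preceding stages first")
    p
  }

  for (stage in stages) {
    if (stage == "generate") {
      log_stage(stage, "simulating tracks, phase image and batch series")
      cfg <- generator_config(mu_max = config$mu_max_h,
                              ks_mean = config$ks_mean_g_l,
                              ks_cv = config$ks_cv,
                              noise_cv = config$noise_cv,
                              frame_interval = config$frame_interval_mm_min,
                              seed = derive_seed(seed, 1L))
      tracks <- simulate_mother_machine_tracks(cfg)
      write.csv(tracks, file.path(out, "tracks.csv"), row.names = FALSE)
      set.seed(derive_seed(seed, 2L))
      cells <- cell_spec(length = stats::runif(6, 2, 3.5),
                         width = stats::runif(6, 0.8, 1.0),
                         density = stats::runif(6, 0.13, 0.28),
                         refraction_increment = config$alpha_cell_ml_per_g,
                         x = rep(c(3, 8, 13), 2), y = rep(c(4, 10), each = 3),
                         orientation = stats::runif(6, 0, pi))
      img <- render_phase_image(cells, pixel_size = config$pixel_size_um,
                                image_shape = c(360L, 360L),
                                noise_sd = 0.001,
                                seed = derive_seed(seed, 3L))
      write_phase_image(img, file.path(out, "phase.tif"))
      geom <- reactor_geometry(config$chamber_width_um,
                               config$chamber_length_um,
                               config$chamber_height_um,
                               config$reactor_volume_pl)
      s0_conc <- c(0.5, 1, 2) * config$s0_g_l
      for (i in seq_along(s0_conc)) {
        ser <- simulate_picoliter_batch(
          s0_mass = initial_substrate_mass(s0_conc[i], geom),
          reactor_volume = geom$total_volume,
          chamber_height = geom$chamber_height,
          yield_true = config$yield_xs_g_g,
          monod = list(mu_max = config$mu_max_h, ks = config$ks_mean_g_l),
          x0_mass = 2, density = config$density_pg_um3,
          dt = config$frame_interval_plb_min,
          seed = derive_seed(seed, 10L + i))
        write.csv(ser, file.path(out, sprintf("chamber_%02d.csv", i)),
                  row.names = FALSE)
      }
      writeLines(format(s0_conc, digits = 17), file.path(out, "s0_g_l.txt"))
      report$stages$generate <- list(
        tracks_rows = nrow(tracks), chambers = length(s0_conc),
        image_px = prod(dim(img$opd)))
    } else if (stage == "mass") {
      img <- read_phase_image(need_file(stage, "phase.tif"))
      log_stage(stage, "measuring single-cell dry masses")
      rec <- measure_cells(img, qpi_settings(
        refraction_increment_cell = config$alpha_cell_ml_per_g))
      write.csv(rec, file.path(out, "cell_masses.csv"), row.names = FALSE)
      report$stages$mass <- list(cells = nrow(rec),
                                 mean_density = mean(rec$density_pg_um3))
    } else if (stage == "kinetics") {
      tracks <- read.csv(need_file(stage, "tracks.csv"),
                         stringsAsFactors = FALSE)
      log_stage(stage, "fitting Monod kinetics")
      pts <- growth_points(tracks,
                           frame_interval = config$frame_interval_mm_min)
      write.csv(pts, file.path(out, "growth_points.csv"), row.names = FALSE)
      fit <- fit_monod(pts, frame_interval = config$frame_interval_mm_min)
      co <- coef(fit)
      fit_report <- list(
        variants = lapply(rownames(co), function(v)
          list(variant = v, mu_max_h = co[v, "mu_max"],
               ks_g_l = co[v, "ks"], ks_ug_l = co[v, "ks"] * 1e6,
               r2 = fit$r2[[v]])),
        n_points = nrow(pts))
      jsonlite::write_json(fit_report, file.path(out, "monod_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$kinetics <- list(points = nrow(pts),
                                     mu_max_h = co["mean", "mu_max"],
                                     ks_ug_l = co["mean", "ks"] * 1e6)
    } else if (stage == "yield") {
      masses <- read.csv(need_file(stage, "cell_masses.csv"))
      log_stage(stage, "computing chamber-wise yields")
      density <- mean(masses$density_pg_um3)
      s0_conc <- as.numeric(readLines(need_file(stage, "s0_g_l.txt")))
      files <- file.path(out, sprintf("chamber_%02d.csv",
                                      seq_along(s0_conc)))
      for (f in files) if (!file.exists(f))
        stop("stage 'yield' requires '", basename(f), "' from 'generate'")
      series <- lapply(files, read.csv)
      geom <- reactor_geometry(config$chamber_width_um,
                               config$chamber_length_um,
                               config$chamber_height_um,
                               config$reactor_volume_pl)
      yl <- yield_from_series(series,
                              s0_mass = initial_substrate_mass(s0_conc, geom),
                              chamber_height = geom$chamber_height,
                              density = density,
                              m_x_cmol = config$m_x_g_per_cmol,
                              m_s_cmol = config$m_s_g_per_cmol)
      write.csv(yl, file.path(out, "yields.csv"), row.names = FALSE)
      report$stages$yield <- list(chambers = nrow(yl),
                                  mean_y_xs = mean(yl$y_xs[!yl$excluded]))
    } else if (stage == "balance") {
      yl <- read.csv(need_file(stage, "yields.csv"))
      log_stage(stage, "closing the Cmol carbon balance")
      y_xs <- mean(yl$y_xs[!yl$excluded])
      st <- carbon_balance_close(config$mu_ref_h, y_xs,
                                 config$m_x_g_per_cmol,
                                 config$m_s_g_per_cmol)
      jsonlite::write_json(unclass(st), file.path(out, "stoichiometry.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$balance <- list(y_xs = y_xs, y_ps = st$y_ps,
                                    q_s = st$q_s, r_p = st$r_p)
    } else if (stage == "model") {
      fit <- jsonlite::read_json(need_file(stage, "monod_fit.json"),
                                 simplifyVector = TRUE)
      st_in <- jsonlite::read_json(need_file(stage, "stoichiometry.json"),
                                   simplifyVector = TRUE)
      log_stage(stage, "simulating the phenotype ensemble")
      mean_var <- fit$variants[fit$variants$variant == "mean", ]
      tracks <- read.csv(need_file(stage, "tracks.csv"))
      ksd <- ks_distribution(tracks, mu_max = mean_var$mu_max_h,
                             frame_interval = config$frame_interval_mm_min)
      st <- carbon_balance_close(st_in$mu, st_in$y_xs, st_in$m_x_cmol,
                                 st_in$m_s_cmol)
      ens <- simulate_ensemble(ksd, n_members = 100L,
                               x0 = 1e-3, s0 = config$s0_g_l,
                               mu_max = mean_var$mu_max_h, stoich = st,
                               t_end = 24, dt = 0.005,
                               seed = derive_seed(seed, 20L))
      long <- do.call(rbind, lapply(seq_along(ens$members), function(i) {
        m <- ens$members[[i]]
        thin <- seq(1, nrow(m), by = 10L)
        data.frame(member_id = i, t_h = m$t_h[thin], x_g_l = m$x_g_l[thin],
                   s_g_l = m$s_g_l[thin], p_cmol_l = m$p_cmol_l[thin])
      }))
      write.csv(long, file.path(out, "ensemble.csv"), row.names = FALSE)
      env <- phenotype_space_summary(ens)
      write.csv(env, file.path(out, "envelopes.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(n_members = length(ens$members), ks_mean_g_l = ksd$mean,
             ks_sd_g_l = ksd$sd, mu_max_h = ens$mu_max,
             solver = "fixed-step classical 4th-order", dt_h = 0.005,
             t_end_h = 24, seed = derive_seed(seed, 20L)),
        file.path(out, "model_spec.json"), auto_unbox = TRUE, digits = NA)
      report$stages$model <- list(members = length(ens$members),
                                  envelope_rows = nrow(env))
    }
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
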