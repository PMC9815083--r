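#' Doubling times from a division track
#'
#' Differences of consecutive division timestamps of one lineage, with the
#' first interval excluded (the age of the initially observed cell is
#' unknown, so its first interval is not a doubling time). Intervals no
#' longer than one imaging frame are flagged with weight 0: two divisions
#' detected on consecutive frames indicate a segmentation artifact rather
#' than a real doubling, and such events are excluded from the geometric
#' mean but kept in the record.
#'
#' @param division_times_min strictly increasing division timestamps, min.
#' @param frame_interval imaging interval, min.
#' @return Data frame with columns \code{td_min} and \code{weight} (0 or 1);
#'   empty for fewer than two division events.
#' @examples
#' doubling_times(c(0, 60, 65, 125), frame_interval = 5)
#' @export
doubling_times <- function(division_times_min, frame_interval = 5) {
  t <- as.numeric(division_times_min)
  if (is.unsorted(t, strictly = TRUE))
    stop("division timestamps must be strictly increasing")
  if (length(t) < 2L)
    return(data.frame(td_min = numeric(), weight = numeric()))
  td <- diff(t)[-1]                      # first interval dropped
  if (length(td) == 0L)
    return(data.frame(td_min = numeric(), weight = numeric()))
  data.frame(td_min = td, weight = as.numeric(td > frame_interval))
}

#' Classify growth at one glucose level
#'
#' Applies the event-count rules used for mother-machine data: a level is
#' \code{"valid"} when a single lineage provides at least 50 division
#' events; \code{"pooled"} when no lineage reaches 50 events but the summed
#' lineages cover at least 4 generations; and \code{"no_growth"} when fewer
#' than 4 generations were observed in total.
#'
#' @param tracks division-event data frame for one glucose level, with
#'   columns \code{lineage_id} and \code{generation}.
#' @param min_events_valid events required for a single-lineage level.
#' @param min_generations generations below which a level is no growth.
#' @return One of \code{"valid"}, \code{"pooled"}, \code{"no_growth"}.
#' @export
classify_growth <- function(tracks, min_events_valid = 50L,
                            min_generations = 4L) {
  if (is.null(tracks) || nrow(tracks) == 0L) return("no_growth")
  per_lineage <- table(tracks$lineage_id)
  gen <- tapply(tracks$generation, tracks$lineage_id, max)
  total_generations <- sum(gen)
  if (any(per_lineage >= min_events_valid)) return("valid")
  if (total_generations >= min_generations) return("pooled")
  "no_growth"
}

#' Geometric-mean growth rate with outlier down-weighting
#'
#' The per-level doubling time is the geometric mean of the admissible
#' (weight 1) doubling times, which is robust to multiplicative outliers;
#' the specific growth rate is \code{log(2)} divided by it. Growth
#' heterogeneity is reported as the weighted standard deviation of the
#' per-event rates \code{log(2)/td} using the 0/1 weights and a
#' \code{sum(w) - 1} denominator.
#'
#' @param td data frame from [doubling_times()] (columns \code{td_min},
#'   \code{weight}), or a numeric vector of doubling times in minutes.
#' @param weight optional weights when \code{td} is a vector.
#' @return List with \code{mu_gm} and \code{mu_sd} (1/h), \code{td_gm_min},
#'   and \code{n_events} (admissible events).
#' @examples
#' geometric_mean_mu(c(120, 480))   # GM 4 h, mu ~ 0.173 1/h
#' @export
geometric_mean_mu <- function(td, weight = NULL) {
  if (is.data.frame(td)) {
    weight <- td$weight
    td <- td$td_min
  }
  if (is.null(weight)) weight <- rep(1, length(td))
  if (any(td <= 0)) stop("doubling times must be positive")
  adm <- weight > 0
  if (!any(adm)) stop("no admissible events (all weights are zero)")
  td_h <- td / 60
  td_gm <- exp(mean(log(td_h[adm])))
  mu_i <- log(2) / td_h
  list(mu_gm = log(2) / td_gm,
       mu_sd = weighted_sd(mu_i, as.numeric(adm)),
       td_gm_min = td_gm * 60,
       n_events = sum(adm))
}

#' Monod growth rate
#'
#' \deqn{\mu(S) = \mu_{max} \frac{S}{K_S + S}}
#'
#' @param S substrate concentration(s), g/L (>= 0).
#' @param mu_max maximum specific growth rate, 1/h.
#' @param ks Monod (half-saturation) constant, g/L.
#' @return Specific growth rate(s), 1/h.
#' @export
monod_mu <- function(S, mu_max, ks) {
  if (any(S < 0)) stop("'S' must be >= 0")
  stopifnot_scalar_pos(mu_max, "mu_max")
  stopifnot_scalar_pos(ks, "ks")
  mu_max * S / (ks + S)
}

#' Per-level growth points from division tracks
#'
#' Groups a division-event table by glucose level, classifies each level
#' ([classify_growth()]), pools admissible doubling times across the
#' level's lineages, and computes geometric-mean growth rates and weighted
#' heterogeneity ([geometric_mean_mu()]). Levels classified as no growth
#' get \code{mu_gm = 0}.
#'
#' @param tracks division-event data frame with columns \code{lineage_id},
#'   \code{generation}, \code{division_time_min}, \code{glucose_g_per_L}
#'   (the schema written by [simulate_mother_machine_tracks()]).
#' @param frame_interval imaging interval used for outlier flagging, min.
#' @return Data frame with one row per glucose level: \code{glucose_g_per_L},
#'   \code{mu_gm}, \code{mu_sd}, \code{n_events}, \code{status}.
#' @export
growth_points <- function(tracks, frame_interval = 5) {
  need <- c("lineage_id", "generation", "division_time_min", "glucose_g_per_L")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns ", paste(need, collapse = ", "))
  levels_ <- sort(unique(tracks$glucose_g_per_L))
  out <- vector("list", length(levels_))
  for (i in seq_along(levels_)) {
    tr <- tracks[tracks$glucose_g_per_L == levels_[i], ]
    status <- classify_growth(tr)
    if (status == "no_growth") {
      out[[i]] <- data.frame(glucose_g_per_L = levels_[i], mu_gm = 0,
                             mu_sd = NA_real_, n_events = 0L,
                             status = status)
      next
    }
    tds <- do.call(rbind, lapply(split(tr$division_time_min, tr$lineage_id),
                                 doubling_times,
                                 frame_interval = frame_interval))
    gm <- geometric_mean_mu(tds)
    out[[i]] <- data.frame(glucose_g_per_L = levels_[i], mu_gm = gm$mu_gm,
                           mu_sd = gm$mu_sd, n_events = gm$n_events,
                           status = status)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the Monod model to per-level growth points
#'
#' Nonlinear least-squares fit of the Monod equation viewed as a sigmoid on
#' the log-concentration axis, \code{mu = mu_max * 10^x / (ks + 10^x)} with
#' \code{x = log10(S)} — the reproducible counterpart of reading the
#' half-maximum point off a sigmoidal regression of the logarithmic plot.
#' Three variants are fitted: the mean curve through \code{mu_gm}, and upper
#' and lower boundary curves through \code{mu_gm + mu_sd} and
#' \code{max(mu_gm - mu_sd, 0)}, delimiting the heterogeneity band. Note
#' the boundary naming: the upper boundary (faster growth) has the smaller
#' Monod constant.
#'
#' @param points data frame from [growth_points()] (columns
#'   \code{glucose_g_per_L}, \code{mu_gm}, \code{mu_sd}, optionally
#'   \code{status}); levels with status \code{"no_growth"} are excluded
#'   from the fit.
#' @param frame_interval imaging interval, min; stored for downstream use.
#' @return An object of class \code{"monod_fit"}: list with
#'   \code{coefficients} (matrix of \code{mu_max}, \code{ks} for variants
#'   mean/upper_boundary/lower_boundary), \code{r2} per variant,
#'   \code{points}, and the mean-variant \code{nls} fit. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{plot}, \code{simulate}.
#' @examples
#' S <- 10^seq(-5, 1, length.out = 8)
#' pts <- data.frame(glucose_g_per_L = S, mu_gm = monod_mu(S, 0.66, 4.86e-4),
#'                   mu_sd = 0.1)
#' fit <- fit_monod(pts)
#' coef(fit)
#' @export
fit_monod <- function(points, frame_interval = 5) {
  need <- c("glucose_g_per_L", "mu_gm")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "))
  if (!is.null(points$status))
    points <- points[points$status != "no_growth", , drop = FALSE]
  if (nrow(points) < 4L)
    stop("need at least 4 growth points spanning the affinity range")
  if (all(points$mu_gm <= 0))
    stop("all growth rates are zero; no sigmoid to fit")
  if (is.null(points$mu_sd)) points$mu_sd <- 0
  fit_one <- function(mu) {
    S <- points$glucose_g_per_L
    start <- c(mu_max = max(mu), ks = ks_start_guess(S, mu))
    lm_fit <- minpack.lm::nls.lm(
      par = start,
      fn = function(p) mu - p[["mu_max"]] * S / (p[["ks"]] + S),
      lower = c(mu_max = 1e-9, ks = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    if (!lm_fit$info %in% 1:4)
      stop("Monod fit did not converge: ", lm_fit$message,
           " (points: ", length(S), ", mu range ",
           paste(format(range(mu), digits = 3), collapse = " - "), ")",
           call. = FALSE)
    co <- lm_fit$par
    ss_res <- sum(lm_fit$fvec^2)
    ss_tot <- sum((mu - mean(mu))^2)
    if (min(S) > 100 * co[["ks"]])
      warning("ks poorly identified: all points saturate the fitted Monod curve")
    list(coef = co, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         nls = lm_fit)
  }
  mean_fit <- fit_one(points$mu_gm)
  sdv <- ifelse(is.na(points$mu_sd), 0, points$mu_sd)
  upper_fit <- fit_one(points$mu_gm + sdv)
  lower_fit <- fit_one(pmax(points$mu_gm - sdv, 0))
  coefs <- rbind(mean = mean_fit$coef,
                 upper_boundary = upper_fit$coef,
                 lower_boundary = lower_fit$coef)
  structure(list(coefficients = coefs,
                 r2 = c(mean = mean_fit$r2, upper_boundary = upper_fit$r2,
                        lower_boundary = lower_fit$r2),
                 points = points,
                 fit = mean_fit$nls,
                 frame_interval = frame_interval),
            class = "monod_fit")
}

# half-maximum abscissa on the log axis as a starting value for ks
ks_start_guess <- function(S, mu) {
  mu_top <- max(mu)
  i <- order(S)
  S <- S[i]; mu <- mu[i]
  below <- which(mu < mu_top / 2)
  if (length(below) == 0L || max(below) == length(S)) return(stats::median(S))
  j <- max(below)
  # log-linear interpolation between the points straddling mu_top/2
  x1 <- log10(S[j]); x2 <- log10(S[j + 1])
  y1 <- mu[j]; y2 <- mu[j + 1]
  10^(x1 + (mu_top / 2 - y1) / (y2 - y1) * (x2 - x1))
}

#' @export
coef.monod_fit <- function(object, ...) object$coefficients

#' @export
print.monod_fit <- function(x, digits = 4, ...) {
  cat("Monod growth-kinetics fit (sigmoid on log10 S)\n")
  co <- x$coefficients
  for (v in rownames(co))
    cat(sprintf("  %-15s mu_max = %s 1/h, ks = %s ug/L (R2 = %s)\n", v,
                format(co[v, "mu_max"], digits = digits),
                format(co[v, "ks"] * 1e6, digits = digits),
                format(x$r2[[v]], digits = 3)))
  cat("  fitted on", nrow(x$points), "growth points\n")
  invisible(x)
}

#' @export
summary.monod_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients, r2 = object$r2,
                 points = object$points,
                 nls_summary = summary(object$fit)), class = "summary.monod_fit")
}

#' @export
print.summary.monod_fit <- function(x, ...) {
  cat("Monod fit variants:\n")
  print(cbind(x$coefficients, r2 = x$r2))
  cat("\nGrowth points:\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Predict growth rates from a Monod fit
#'
#' @param object a \code{"monod_fit"}.
#' @param newdata data frame with column \code{glucose_g_per_L}, or a
#'   numeric vector of concentrations (g/L); defaults to the fitted points.
#' @param variant which fitted curve to evaluate.
#' @param ... unused.
#' @return Predicted specific growth rates, 1/h.
#' @export
predict.monod_fit <- function(object, newdata = NULL,
                              variant = c("mean", "upper_boundary",
                                          "lower_boundary"), ...) {
  variant <- match.arg(variant)
  S <- if (is.null(newdata)) object$points$glucose_g_per_L
       else if (is.data.frame(newdata)) newdata$glucose_g_per_L
       else as.numeric(newdata)
  co <- object$coefficients[variant, ]
  monod_mu(S, co[["mu_max"]], co[["ks"]])
}

#' @export
residuals.monod_fit <- function(object, ...) {
  object$points$mu_gm - predict(object)
}

#' Plot a Monod fit
#'
#' Growth points with heterogeneity bars on a logarithmic concentration
#' axis, with the mean fit and the upper/lower boundary curves.
#'
#' @param x a \code{"monod_fit"}.
#' @param ... passed to \code{plot}.
#' @export
plot.monod_fit <- function(x, ...) {
  p <- x$points
  S <- p$glucose_g_per_L
  grid <- 10^seq(log10(min(S)) - 0.5, log10(max(S)) + 0.5, length.out = 200)
  ylim <- range(0, p$mu_gm + ifelse(is.na(p$mu_sd), 0, p$mu_sd))
  plot(S, p$mu_gm, log = "x", xlab = "glucose (g/L)",
       ylab = expression(mu ~ (h^-1)), ylim = ylim, pch = 19, ...)
  sdv <- ifelse(is.na(p$mu_sd), 0, p$mu_sd)
  suppressWarnings(arrows_safe(S, p$mu_gm - sdv, S, p$mu_gm + sdv))
  lines(grid, predict(x, grid), lwd = 2)
  lines(grid, predict(x, grid, variant = "upper_boundary"), col = 2, lty = 2)
  lines(grid, predict(x, grid, variant = "lower_boundary"), col = 4, lty = 2)
  legend("topleft", bty = "n", lwd = c(2, 1, 1), lty = c(1, 2, 2),
         col = c(1, 2, 4), legend = c("mean fit", "upper boundary",
                                      "lower boundary"))
  invisible(x)
}

arrows_safe <- function(x0, y0, x1, y1) {
  ok <- is.finite(y0) & is.finite(y1) & (y1 - y0) > 0
  if (any(ok))
    graphics::arrows(x0[ok], y0[ok], x1[ok], y1[ok], angle = 90, code = 3,
                     length = 0.03)
}

#' Simulate division tracks from a fitted Monod model
#'
#' Draws new synthetic mother-machine datasets whose kinetics follow the
#' fitted mean Monod curve, closing the generator/estimator loop.
#'
#' @param object a \code{"monod_fit"}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... passed to [generator_config()] (e.g. \code{glucose_levels},
#'   \code{noise_cv}).
#' @return A list of \code{nsim} division-event data frames.
#' @export
simulate.monod_fit <- function(object, nsim = 1, seed = 1L, ...) {
  co <- object$coefficients["mean", ]
  lapply(seq_len(nsim), function(i) {
    cfg <- generator_config(mu_max = co[["mu_max"]], ks_mean = co[["ks"]],
                            seed = derive_seed(seed, i), ...)
    simulate_mother_machine_tracks(cfg)
  })
}

#' Empirical distribution of single-cell Monod constants
#'
#' Inverts the Monod equation per cell: a cell growing at rate
#' \code{mu_cell} under concentration \code{S} has
#' \code{ks = S * (mu_max / mu_cell - 1)}. Cells whose observed rate
#' reaches or exceeds \code{mu_max} carry no affinity information and are
#' skipped (counted in \code{n_skipped}). Returns the empirical values, a
#' normal fit (mean/SD), and a histogram, the form in which substrate
#' affinity heterogeneity feeds the ensemble batch model.
#'
#' @param tracks division-event data frame (one or more glucose levels);
#'   per-cell rates are taken from admissible doubling times.
#' @param mu_max maximum specific growth rate used for the inversion, 1/h.
#' @param frame_interval imaging interval, min.
#' @param breaks histogram bin specification (passed to \code{hist}).
#' @return Object of class \code{"ks_distribution"}: list with \code{mean},
#'   \code{sd} (g/L), \code{values}, \code{n_skipped}, \code{histogram}.
#' @export
ks_distribution <- function(tracks, mu_max, frame_interval = 5,
                            breaks = "Sturges") {
  stopifnot_scalar_pos(mu_max, "mu_max")
  vals <- numeric(0)
  n_skip <- 0L
  for (lin in split(tracks, tracks$lineage_id)) {
    tds <- doubling_times(lin$division_time_min, frame_interval)
    adm <- tds$td_min[tds$weight > 0]
    S <- lin$glucose_g_per_L[1]
    mu_cell <- log(2) / (adm / 60)
    ok <- mu_cell < mu_max
    n_skip <- n_skip + sum(!ok)
    vals <- c(vals, S * (mu_max / mu_cell[ok] - 1))
  }
  if (length(vals) < 2L)
    stop("fewer than 2 usable cells for the affinity distribution")
  h <- hist(vals, breaks = breaks, plot = FALSE)
  structure(list(mean = mean(vals), sd = stats::sd(vals), values = vals,
                 n_skipped = n_skip, histogram = h),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf(
    "single-cell Monod constant distribution: %d cells, %s +/- %s ug/L (%d skipped)\n",
    length(x$values), format(x$mean * 1e6, digits = 4),
    format(x$sd * 1e6, digits = 4), x$n_skipped))
  invisible(x)
}

#' @export
plot.ks_distribution <- function(x, ...) {
  plot(x$histogram, main = "single-cell substrate affinity",
       xlab = expression(K[S] ~ (g ~ L^-1)), ...)
  abline(v = x$mean, lwd = 2)
  invisible(x)
}
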