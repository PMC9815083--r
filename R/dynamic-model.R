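#' Simulate a Monod batch trajectory
#'
#' Integrates the batch reactor material balance
#' \deqn{\frac{dX}{dt} = \mu(S) X, \quad
#'       \frac{dS}{dt} = -\frac{\mu(S)}{Y_{X,S}} X, \quad
#'       \frac{dP}{dt} = r_P(S) X,}
#' with Monod kinetics \eqn{\mu(S) = \mu_{max} S / (K_S + S)} and the
#' by-product rate from the Cmol balance closure,
#' \eqn{r_P = \mu\,(1/(Y_{X,S} M_S) - 1/M_X)}. Because \eqn{dS} and
#' \eqn{dP} are proportional to \eqn{dX}, the system is integrated as a
#' scalar fixed-step classical 4th-order (Runge-Kutta) equation in X with S
#' and P recovered from the balance, which makes total carbon
#' \eqn{X/M_X + S/M_S + P} conserved to machine precision along the whole
#' trajectory. Substrate is floored at zero on exhaustion, after which
#' \eqn{\mu = 0} and all states are constant.
#'
#' @param x0,s0,p0 initial biomass (g/L), substrate (g/L), product (Cmol/L).
#' @param monod list with \code{mu_max} (1/h) and \code{ks} (g/L).
#' @param stoich a \code{"stoichiometry_set"} from [carbon_balance_close()],
#'   or a list with \code{y_xs}, \code{m_x_cmol}, \code{m_s_cmol}.
#' @param t_end simulation horizon, h.
#' @param dt integration and output step, h (default 0.001).
#' @param max_rel_step error if the relative biomass change in one step
#'   exceeds this bound (advises a smaller \code{dt}).
#' @return Object of class \code{"batch_trajectory"}: data frame with
#'   columns \code{t_h}, \code{x_g_l}, \code{s_g_l}, \code{p_cmol_l} and
#'   attributes \code{"monod"} and \code{"stoich"}.
#' @examples
#' st <- carbon_balance_close(mu = 0.61, y_xs = 0.44)
#' tr <- simulate_batch(x0 = 1e-3, s0 = 1, monod = list(mu_max = 0.66,
#'                      ks = 4.86e-4), stoich = st, t_end = 24)
#' tail(tr, 1)   # X_end ~ x0 + 0.44 * 1
#' @export
simulate_batch <- function(x0, s0, p0 = 0,
                           monod = list(mu_max = 0.66, ks = 4.86e-4),
                           stoich = carbon_balance_close(0.61, 0.44),
                           t_end = 24, dt = 0.001,
                           max_rel_step = 0.1) {
  if (x0 < 0 || s0 < 0 || p0 < 0) stop("initial states must be >= 0")
  stopifnot_scalar_pos(t_end, "t_end")
  stopifnot_scalar_pos(dt, "dt")
  mu_max <- monod$mu_max; ks <- monod$ks
  stopifnot_scalar_pos(mu_max, "monod$mu_max")
  stopifnot_scalar_pos(ks, "monod$ks")
  y_xs <- stoich$y_xs
  m_x <- stoich$m_x_cmol; m_s <- stoich$m_s_cmol
  y_px <- 1 / (y_xs * m_s) - 1 / m_x        # Cmol product per g biomass
  if (y_px < 0)
    stop("balance violated: more carbon in biomass than in substrate")

  x_cap <- x0 + y_xs * s0                    # biomass at substrate exhaustion
  s_of_x <- function(x) pmax(s0 - (x - x0) / y_xs, 0)
  f <- function(x) mu_max * s_of_x(x) / (ks + s_of_x(x)) * x
  times <- seq(0, t_end, by = dt)
  x <- numeric(length(times)); x[1] <- x0
  cur <- x0
  for (i in seq_along(times)[-1]) {
    k1 <- f(cur)
    k2 <- f(cur + dt / 2 * k1)
    k3 <- f(cur + dt / 2 * k2)
    k4 <- f(cur + dt * k3)
    nxt <- min(cur + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), x_cap)
    if (cur > 0 && (nxt - cur) / cur > max_rel_step)
      stop("relative state change ", format((nxt - cur) / cur, digits = 3),
           " per step exceeds ", max_rel_step,
           ": use a smaller dt")
    cur <- nxt
    x[i] <- cur
  }
  out <- data.frame(t_h = times, x_g_l = x, s_g_l = s_of_x(x),
                    p_cmol_l = p0 + (x - x0) * y_px)
  attr(out, "monod") <- list(mu_max = mu_max, ks = ks)
  attr(out, "stoich") <- list(y_xs = y_xs, m_x_cmol = m_x, m_s_cmol = m_s,
                              y_px = y_px)
  class(out) <- c("batch_trajectory", "data.frame")
  out
}

#' Total carbon along a batch trajectory
#'
#' \code{X/M_X + S/M_S + P} per time point, Cmol/L; constant for a closed
#' balance.
#'
#' @param traj a \code{"batch_trajectory"}.
#' @return Numeric vector of total carbon, Cmol/L.
#' @export
total_carbon <- function(traj) {
  st <- attr(traj, "stoich")
  traj$x_g_l / st$m_x_cmol + traj$s_g_l / st$m_s_cmol + traj$p_cmol_l
}

#' @export
print.batch_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "batch trajectory: %d steps over %s h; X %s -> %s g/L, S %s -> %s g/L\n",
    n, format(x$t_h[n]), format(x$x_g_l[1], digits = 4),
    format(x$x_g_l[n], digits = 4), format(x$s_g_l[1], digits = 4),
    format(x$s_g_l[n], digits = 4)))
  invisible(x)
}

#' Plot a batch trajectory
#'
#' @param x a \code{"batch_trajectory"}.
#' @param ... passed to \code{plot}.
#' @export
plot.batch_trajectory <- function(x, ...) {
  old <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(old))
  plot(x$t_h, x$x_g_l, type = "l", lwd = 2, xlab = "time (h)",
       ylab = "X, S (g/L)", ...)
  lines(x$t_h, x$s_g_l, col = 2, lwd = 2)
  graphics::par(new = TRUE)
  plot(x$t_h, x$p_cmol_l, type = "l", col = 4, lty = 2, axes = FALSE,
       xlab = "", ylab = "")
  axis(4, col.axis = 4)
  graphics::mtext("P (Cmol/L)", side = 4, line = 2.5, col = 4)
  legend("right", bty = "n", col = c(1, 2, 4), lty = c(1, 1, 2),
         legend = c("biomass X", "substrate S", "product P"))
  invisible(x)
}

#' Simulate an ensemble of batch phenotypes
#'
#' Draws \code{n_members} substrate affinities from a normal distribution
#' truncated at zero (or resamples an empirical [ks_distribution()]) and
#' integrates one batch trajectory per member on a common time grid. All
#' members share \code{mu_max} and the stoichiometry; only the Monod
#' constant varies, reflecting that observed heterogeneity enters through
#' the affinity distribution.
#'
#' @param ks_mean,ks_sd mean and SD of the affinity distribution, g/L.
#'   Alternatively pass a \code{"ks_distribution"} as \code{ks_mean}, whose
#'   normal fit is used.
#' @param n_members ensemble size.
#' @param x0,s0,p0 shared initial state (g/L, g/L, Cmol/L).
#' @param mu_max shared maximum growth rate, 1/h.
#' @param stoich shared stoichiometry, see [simulate_batch()].
#' @param t_end,dt integration horizon and step, h.
#' @param seed integer seed for the affinity draws.
#' @return Object of class \code{"batch_ensemble"}: list with \code{members}
#'   (list of trajectories), \code{ks} (the draws), and the shared settings.
#' @export
simulate_ensemble <- function(ks_mean = 4.86e-4, ks_sd = 2.34e-4,
                              n_members = 100L,
                              x0 = 1e-3, s0 = 1, p0 = 0,
                              mu_max = 0.66,
                              stoich = carbon_balance_close(0.61, 0.44),
                              t_end = 24, dt = 0.001, seed = 1L) {
  if (inherits(ks_mean, "ks_distribution")) {
    ks_sd <- ks_mean$sd
    ks_mean <- ks_mean$mean
  }
  if (n_members < 1L) stop("'n_members' must be >= 1")
  set.seed(seed)
  ks <- rtruncnorm_pos(n_members, ks_mean, ks_sd)
  members <- lapply(ks, function(k)
    simulate_batch(x0, s0, p0, monod = list(mu_max = mu_max, ks = k),
                   stoich = stoich, t_end = t_end, dt = dt))
  structure(list(members = members, ks = ks, mu_max = mu_max,
                 stoich = stoich, seed = seed),
            class = "batch_ensemble")
}

#' @export
print.batch_ensemble <- function(x, ...) {
  cat(sprintf(
    "batch ensemble: %d members, ks %s +/- %s ug/L, shared mu_max %s 1/h\n",
    length(x$members), format(mean(x$ks) * 1e6, digits = 4),
    format(stats::sd(x$ks) * 1e6, digits = 3), format(x$mu_max)))
  invisible(x)
}

#' Time-resolved phenotype-space envelopes
#'
#' Quantile envelopes (min, 5\%, median, 95\%, max) of biomass, substrate
#' and product across ensemble members at every time point — the
#' physiological space spanned by the heterogeneous phenotypes.
#'
#' @param ensemble a \code{"batch_ensemble"}, or a list of
#'   \code{"batch_trajectory"} objects on a common time grid.
#' @return Data frame in long format: \code{variable} (x/s/p), \code{t_h},
#'   \code{min}, \code{q05}, \code{median}, \code{q95}, \code{max}.
#' @export
phenotype_space_summary <- function(ensemble) {
  members <- if (inherits(ensemble, "batch_ensemble")) ensemble$members
             else ensemble
  if (length(members) < 1L) stop("need at least one trajectory")
  t0 <- members[[1]]$t_h
  for (m in members)
    if (length(m$t_h) != length(t0) || any(m$t_h != t0))
      stop("trajectories are not on a common time grid")
  cols <- c(x = "x_g_l", s = "s_g_l", p = "p_cmol_l")
  out <- vector("list", length(cols))
  for (i in seq_along(cols)) {
    mat <- vapply(members, function(m) m[[cols[i]]], numeric(length(t0)))
    mat <- matrix(mat, nrow = length(t0))
    qs <- t(apply(mat, 1, stats::quantile,
                  probs = c(0, 0.05, 0.5, 0.95, 1), names = FALSE))
    out[[i]] <- data.frame(variable = names(cols)[i], t_h = t0,
                           min = qs[, 1], q05 = qs[, 2], median = qs[, 3],
                           q95 = qs[, 4], max = qs[, 5])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot phenotype-space envelopes
#'
#' @param ensemble a \code{"batch_ensemble"} or envelope table from
#'   [phenotype_space_summary()].
#' @param variable which state to show.
#' @param ... passed to \code{plot}.
#' @export
plot_phenotype_space <- function(ensemble, variable = c("x", "s", "p"), ...) {
  variable <- match.arg(variable)
  env <- if (is.data.frame(ensemble)) ensemble
         else phenotype_space_summary(ensemble)
  e <- env[env$variable == variable, ]
  ylab <- c(x = "biomass X (g/L)", s = "substrate S (g/L)",
            p = "product P (Cmol/L)")[variable]
  plot(e$t_h, e$median, type = "n", xlab = "time (h)", ylab = ylab,
       ylim = range(e$min, e$max), ...)
  graphics::polygon(c(e$t_h, rev(e$t_h)), c(e$q05, rev(e$q95)),
                    col = gray(0.85), border = NA)
  lines(e$t_h, e$min, lty = 3); lines(e$t_h, e$max, lty = 3)
  lines(e$t_h, e$median, lwd = 2)
  invisible(e)
}
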