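#' Picoliter reactor geometry
#'
#' Defaults describe the picoliter batch device: growth chambers of
#' 60 x 100 x 1 um (width, length, height) connected to a medium reservoir
#' for a total cultivation volume of 606 pL.
#'
#' @param chamber_width,chamber_length,chamber_height chamber dimensions, um.
#' @param total_volume total cultivation volume (chamber + reservoir), pL.
#' @return list of class \code{"reactor_geometry"}.
#' @export
reactor_geometry <- function(chamber_width = 60, chamber_length = 100,
                             chamber_height = 1, total_volume = 606) {
  for (nm in c("chamber_width", "chamber_length", "chamber_height",
               "total_volume"))
    stopifnot_scalar_pos(get(nm), nm)
  structure(list(chamber_width = chamber_width,
                 chamber_length = chamber_length,
                 chamber_height = chamber_height,
                 total_volume = total_volume), class = "reactor_geometry")
}

#' Initial substrate mass in a chamber
#'
#' \code{s0 = concentration * total_volume}; with concentration in g/L and
#' volume in pL this is numerically pg (1 g/L = 1 pg/pL).
#'
#' @param concentration substrate concentration, g/L (>= 0). Note
#'   1\% w/v = 10 g/L.
#' @param geometry a [reactor_geometry()].
#' @return Substrate mass, pg.
#' @examples
#' initial_substrate_mass(1)    # 606 pg in the default reactor
#' @export
initial_substrate_mass <- function(concentration, geometry = reactor_geometry()) {
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  concentration * geometry$total_volume
}

#' Total biomass from projected colony area
#'
#' Monolayer growth makes colony volume = projected area x chamber height;
#' multiplying by the dry-mass density from quantitative phase imaging
#' gives total dry biomass.
#'
#' @param projected_area total projected cell area, um^2.
#' @param chamber_height chamber height, um.
#' @param density dry-mass density, pg/um^3.
#' @return Biomass, pg.
#' @export
total_biomass <- function(projected_area, chamber_height = 1, density = 0.2) {
  if (any(projected_area < 0) || chamber_height < 0 || density < 0)
    stop("all arguments must be >= 0")
  projected_area * chamber_height * density
}

#' Substrate-to-biomass yield coefficient
#'
#' \deqn{Y_{X,S} = \frac{m_{total,end} - m_{total,0}}{S_0}}
#'
#' @param m_total_end final total biomass, pg.
#' @param m_total_0 initial total biomass, pg.
#' @param s0_mass initial substrate mass, pg (> 0).
#' @return Yield, g/g. A negative yield (biomass loss) is returned with a
#'   warning rather than an error, so flagged chambers stay visible.
#' @export
yield_xs <- function(m_total_end, m_total_0, s0_mass) {
  if (any(s0_mass <= 0)) stop("'s0_mass' must be positive")
  if (any(m_total_end < m_total_0))
    warning("final biomass below initial biomass: negative yield")
  (m_total_end - m_total_0) / s0_mass
}

#' Chamber-wise yields from batch series
#'
#' Computes one [yield_xs()] record per chamber series: initial biomass
#' from the first frame, final biomass as the mean of the last
#' \code{n_final} frames (the stationary plateau; averaging suppresses
#' frame-level segmentation noise). Chambers whose yield implies more
#' carbon in biomass than was supplied as substrate (carbon yield > 1) are
#' flagged \code{excluded}, as are chambers starting with fewer than
#' \code{min_initial_cells} cells — both mirror the screening applied to
#' the lowest-substrate chambers.
#'
#' @param series list of chamber data frames (\code{time_min},
#'   \code{area_um2}) or a single data frame.
#' @param s0_mass initial substrate mass per chamber, pg (recycled).
#' @param chamber_height chamber height, um.
#' @param density dry-mass density used for the area-to-mass conversion,
#'   pg/um^3.
#' @param n_final frames averaged for the final biomass.
#' @param min_initial_cells chambers with fewer initial cells (estimated
#'   from initial biomass / \code{cell_mass_pg}) are flagged.
#' @param cell_mass_pg nominal single-cell dry mass for the initial-cell
#'   estimate, pg.
#' @param m_x_cmol,m_s_cmol Cmol masses used for the carbon-yield screen.
#' @return Data frame with columns \code{chamber_id}, \code{s0_mass},
#'   \code{m_total_0}, \code{m_total_end}, \code{y_xs}, \code{excluded}.
#' @export
yield_from_series <- function(series, s0_mass, chamber_height = 1,
                              density = 0.2, n_final = 5L,
                              min_initial_cells = 1L, cell_mass_pg = 0.15,
                              m_x_cmol = 24.63, m_s_cmol = 30.03) {
  if (is.data.frame(series)) series <- list(series)
  s0_mass <- rep_len(s0_mass, length(series))
  out <- vector("list", length(series))
  for (i in seq_along(series)) {
    ser <- series[[i]]
    if (!all(c("time_min", "area_um2") %in% names(ser)))
      stop("chamber series must have columns time_min, area_um2")
    nf <- min(n_final, nrow(ser))
    m0 <- total_biomass(ser$area_um2[1], chamber_height, density)
    mend <- total_biomass(mean(tail(ser$area_um2, nf)), chamber_height,
                          density)
    y <- yield_xs(mend, m0, s0_mass[i])
    excl <- (m0 / cell_mass_pg) < min_initial_cells ||
      y > m_x_cmol / m_s_cmol
    out[[i]] <- data.frame(chamber_id = i, s0_mass = s0_mass[i],
                           m_total_0 = m0, m_total_end = mend, y_xs = y,
                           excluded = excl)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specific substrate uptake rate
#'
#' \deqn{q_S = \mu / Y_{X,S}}
#'
#' @param mu specific growth rate, 1/h.
#' @param y_xs substrate-to-biomass yield, g/g (> 0).
#' @return Uptake rate, g/(g h).
#' @export
specific_uptake_rate <- function(mu, y_xs) {
  if (any(y_xs <= 0)) stop("'y_xs' must be positive")
  mu / y_xs
}

#' Specific product formation rate from a product yield
#'
#' \deqn{r_P = \mu \, Y_{P,X}}
#'
#' @param mu specific growth rate, 1/h.
#' @param y_px product-per-biomass yield, Cmol/g (>= 0).
#' @return Product formation rate, Cmol/(g h).
#' @export
product_rate_from_yield <- function(mu, y_px) {
  if (any(y_px < 0)) stop("'y_px' must be >= 0")
  mu * y_px
}

#' Close the carbon material balance on a Cmol basis
#'
#' With the by-product pool P lumping everything that is neither substrate
#' nor biomass (CO2, organic acids), carbon conservation around the cell
#' fixes the product terms from the measured growth rate and yield:
#' \deqn{q_S^{Cmol} = \frac{\mu}{Y_{X,S} M_S}, \quad
#'       r_P = q_S^{Cmol} - \frac{\mu}{M_X}, \quad
#'       Y_{P,S} = \frac{r_P}{q_S^{Cmol}} = 1 - Y_{X,S}\frac{M_S}{M_X},}
#' where \eqn{M_X} and \eqn{M_S} are the Cmol masses of biomass and
#' substrate. The defaults use biomass CH1.8O0.5N0.2 (24.63 g/Cmol) and
#' glucose CH2O (30.03 g/Cmol); both are configurable and surfaced in the
#' returned object since the exact elemental composition is strain- and
#' condition-dependent.
#'
#' @param mu specific growth rate, 1/h.
#' @param y_xs substrate-to-biomass yield, g/g (> 0).
#' @param m_x_cmol biomass Cmol mass, g/Cmol.
#' @param m_s_cmol substrate Cmol mass, g/Cmol.
#' @return List of class \code{"stoichiometry_set"}: \code{mu}, \code{y_xs},
#'   \code{q_s} (g/(g h)), \code{q_s_cmol} (Cmol/(g h)), \code{r_p}
#'   (Cmol/(g h)), \code{y_px} (Cmol/g), \code{y_ps} (Cmol/Cmol),
#'   \code{m_x_cmol}, \code{m_s_cmol}.
#' @examples
#' carbon_balance_close(mu = 0.61, y_xs = 0.44)
#' @export
carbon_balance_close <- function(mu, y_xs, m_x_cmol = 24.63,
                                 m_s_cmol = 30.03) {
  if (any(mu < 0)) stop("'mu' must be >= 0")
  stopifnot_scalar_pos(y_xs, "y_xs")
  stopifnot_scalar_pos(m_x_cmol, "m_x_cmol")
  stopifnot_scalar_pos(m_s_cmol, "m_s_cmol")
  if (y_xs > m_x_cmol / m_s_cmol)
    stop("balance violated: more carbon in biomass than in substrate ",
         "(y_xs = ", y_xs, " > ", format(m_x_cmol / m_s_cmol, digits = 4),
         " g/g)")
  q_s_cmol <- mu / (y_xs * m_s_cmol)
  r_p <- q_s_cmol - mu / m_x_cmol
  y_ps <- if (mu > 0) r_p / q_s_cmol else 1 - y_xs * m_s_cmol / m_x_cmol
  structure(list(mu = mu, y_xs = y_xs,
                 q_s = specific_uptake_rate(mu, y_xs),
                 q_s_cmol = q_s_cmol, r_p = r_p,
                 y_px = if (mu > 0) r_p / mu else
                   1 / (y_xs * m_s_cmol) - 1 / m_x_cmol,
                 y_ps = y_ps,
                 m_x_cmol = m_x_cmol, m_s_cmol = m_s_cmol),
            class = "stoichiometry_set")
}

#' @export
print.stoichiometry_set <- function(x, digits = 4, ...) {
  cat("Cmol carbon balance closure\n")
  cat(sprintf("  mu      = %s 1/h,  Y_X,S = %s g/g\n",
              format(x$mu, digits = digits), format(x$y_xs, digits = digits)))
  cat(sprintf("  q_S     = %s g/(g h)  (%s Cmol/(g h))\n",
              format(x$q_s, digits = digits),
              format(x$q_s_cmol, digits = digits)))
  cat(sprintf("  r_P     = %s Cmol/(g h),  Y_P,X = %s Cmol/g\n",
              format(x$r_p, digits = digits),
              format(x$y_px, digits = digits)))
  cat(sprintf("  Y_P,S   = %s Cmol/Cmol  (biomass CH1.8O0.5N0.2: %s g/Cmol, glucose: %s g/Cmol)\n",
              format(x$y_ps, digits = digits),
              format(x$m_x_cmol, digits = digits),
              format(x$m_s_cmol, digits = digits)))
  invisible(x)
}
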