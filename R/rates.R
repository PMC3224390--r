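# Biomass-specific rates from concentration time series.
#
# The central estimator is the dynamic product mass balance
#   dCp/dt = qp * Cx - D * Cp
# solved for qp after smoothing the measured concentration curves, with
# companion balances for mu, qs and the gas transfer rates:
#   mu  = D + (dCx/dt)/Cx
#   qs  = (D (S_feed - S) - dS/dt) / Cx
#   qO2 = OUR/Cx,  qCO2 = CER/Cx
# Derivatives are always taken analytically from the fitted smooth, never
# from finite differences of raw data.

#' Fit a smooth curve with an evaluable derivative to one observable
#'
#' Default is a global least-squares polynomial on a centred and scaled
#' time axis; \code{method = "spline"} uses a piecewise-cubic smoothing
#' spline (\code{stats::smooth.spline}) instead, which tracks long
#' profiles with sharp features better in their low tail.
#'
#' @param table a \code{\link{timeseries_table}}.
#' @param observable column name to fit.
#' @param degree polynomial degree (ignored for \code{method = "spline"}).
#' @param window length-2 numeric, time window of the fit (h); default the
#'   full table range.
#' @param method \code{"poly"} or \code{"spline"}.
#' @return Object of class \code{smooth_fit} with closures \code{value(t)}
#'   and \code{deriv(t)} and a residual summary.
#' @export
fit_smooth <- function(table, observable, degree = 5, window = NULL,
                       method = c("poly", "spline")) {
  method <- match.arg(method)
  if (!observable %in% names(table))
    stop("fit_smooth: no column \"", observable, "\" in table")
  t <- table$time
  y <- table[[observable]]
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (method == "poly") {
    if (n < degree + 2)
      stop("fit_smooth: degree-", degree, " fit needs at least ",
           degree + 2, " points in the window, got ", n)
    ctr <- mean(t); scl <- stats::sd(t)
    if (scl == 0) scl <- 1
    z <- (t - ctr) / scl
    X <- outer(z, 0:degree, `^`)
    beta <- qr.coef(qr(X), y)
    dbeta <- beta[-1] * seq_len(degree)  # derivative coefficients (in z)
    value <- function(tt) drop(outer((tt - ctr) / scl, 0:degree, `^`) %*% beta)
    deriv <- function(tt)
      drop(outer((tt - ctr) / scl, 0:(degree - 1), `^`) %*% dbeta) / scl
  } else {
    if (n < 4) stop("fit_smooth: spline fit needs at least 4 points, got ", n)
    sf <- stats::smooth.spline(t, y, all.knots = TRUE)
    value <- function(tt) stats::predict(sf, tt)$y
    deriv <- function(tt) stats::predict(sf, tt, deriv = 1)$y
  }
  res <- y - value(t)
  structure(list(observable = observable, method = method, degree = degree,
                 window = range(t), n = n, value = value, deriv = deriv,
                 residuals = res, rmse = sqrt(mean(res^2))),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("smooth_fit: %s (%s%s), %d points on [%g, %g], RMSE %.4g\n",
              x$observable, x$method,
              if (x$method == "poly") paste0(" degree ", x$degree) else "",
              x$n, x$window[1], x$window[2], x$rmse))
  invisible(x)
}

#' q_p(t) from the dynamic product mass balance
#'
#' Evaluates \eqn{q_p(t) = (dC_p/dt + D C_p) / C_x} on the interior of the
#' overlap of the two fit windows (the outer 5\% on each side is dropped to
#' avoid polynomial edge artifacts). Biomass is converted from g DW/L to
#' Cmol/L with \code{gdw_per_cmol}, so q_p comes out in mmol PenG/Cmol
#' biomass/h.
#'
#' @param fit_p \code{\link{fit_smooth}} of the PenG column (mmol/L).
#' @param fit_x \code{\link{fit_smooth}} of the biomass column (g DW/L).
#' @param D dilution rate, 1/h.
#' @param gdw_per_cmol biomass conversion, g DW per Cmol.
#' @param n number of evaluation points.
#' @param edge_trim fraction of the window trimmed at each edge.
#' @return data.frame (class \code{rate_profile}) with columns \code{time}
#'   and \code{qp}.
#' @export
qp_profile <- function(fit_p, fit_x, D, gdw_per_cmol = 24.6, n = 241,
                       edge_trim = 0.05) {
  stopifnot(inherits(fit_p, "smooth_fit"), inherits(fit_x, "smooth_fit"))
  if (D <= 0) stop("qp_profile: D must be > 0")
  lo <- max(fit_p$window[1], fit_x$window[1])
  hi <- min(fit_p$window[2], fit_x$window[2])
  if (lo >= hi) stop("qp_profile: fit windows do not overlap")
  span <- hi - lo
  grid <- seq(lo + edge_trim * span, hi - edge_trim * span, length.out = n)
  cx <- fit_x$value(grid) / gdw_per_cmol
  if (any(cx <= 0))
    stop("qp_profile: fitted biomass non-positive at t = ",
         signif(grid[cx <= 0][1], 4))
  qp <- (fit_p$deriv(grid) + D * fit_p$value(grid)) / cx
  structure(data.frame(time = grid, qp = qp),
            class = c("rate_profile", "data.frame"))
}

#' Companion rates from mass balances
#'
#' Growth rate, substrate uptake and gas transfer rates on the same grid
#' and window conventions as \code{\link{qp_profile}}, plus the number of
#' generations (doublings, \eqn{t D/\ln 2}) since the start of the
#' chemostat phase.
#'
#' @inheritParams fit_smooth
#' @inheritParams qp_profile
#' @param D dilution rate; 0 for a batch-phase slice. Defaults to the
#'   table metadata.
#' @param feed_ethanol feed ethanol (Cmol/L), from metadata by default.
#' @return data.frame (class \code{rate_profile}) with columns \code{time},
#'   \code{mu}, \code{qs}, and where gas columns exist \code{qo2},
#'   \code{qco2}, plus \code{generations}.
#' @export
companion_rates <- function(table, D = NULL, feed_ethanol = NULL,
                            degree = 5, window = NULL,
                            method = c("poly", "spline"),
                            gdw_per_cmol = NULL, n = 241, edge_trim = 0.05) {
  method <- match.arg(method)
  md <- attr(table, "metadata")
  if (is.null(D)) D <- md$D
  if (is.null(D)) stop("companion_rates: D not given and absent from metadata")
  if (is.null(feed_ethanol)) feed_ethanol <- md$feed_ethanol
  if (is.null(gdw_per_cmol))
    gdw_per_cmol <- if (!is.null(md$gdw_per_cmol)) md$gdw_per_cmol else 24.6
  if (!"ethanol" %in% names(table))
    stop("companion_rates: missing ethanol column needed for q_s")
  fit_x <- fit_smooth(table, "biomass", degree, window, method)
  fit_s <- fit_smooth(table, "ethanol", degree, window, method)
  span <- diff(fit_x$window)
  grid <- seq(fit_x$window[1] + edge_trim * span,
              fit_x$window[2] - edge_trim * span, length.out = n)
  cx_g <- fit_x$value(grid)
  if (any(cx_g <= 0))
    stop("companion_rates: fitted biomass non-positive on the grid")
  cx <- cx_g / gdw_per_cmol
  mu <- D + fit_x$deriv(grid) / cx_g
  qs <- (D * (feed_ethanol - fit_s$value(grid)) - fit_s$deriv(grid)) / cx
  out <- data.frame(time = grid, mu = mu, qs = qs)
  for (gas in c(o2_uptake = "qo2", co2_evolution = "qco2")) {
    col <- names(which(c(o2_uptake = "qo2", co2_evolution = "qco2") == gas))
    if (col %in% names(table)) {
      vol <- stats::approx(table$time, table[[col]], xout = grid)$y
      out[[gas]] <- vol / cx
    }
  }
  t_switch <- if (!is.null(md$t_switch)) md$t_switch else 0
  out$generations <- generations(pmax(grid - t_switch, 0), max(D, 1e-12))
  structure(out, class = c("rate_profile", "data.frame"))
}

#' Full rate profile of the chemostat phase
#'
#' Convenience wrapper: restricts the table to the chemostat phase (using
#' the \code{t_switch} metadata), fits PenG, biomass and ethanol, and
#' returns q_p together with the companion rates on a common grid.
#'
#' @inheritParams companion_rates
#' @return data.frame (class \code{rate_profile}) with columns \code{time},
#'   \code{qp}, \code{mu}, \code{qs}, \code{qo2}, \code{qco2},
#'   \code{generations}.
#' @export
estimate_rates <- function(table, degree = 5, window = NULL,
                           method = c("poly", "spline"), n = 241,
                           edge_trim = 0.05) {
  method <- match.arg(method)
  md <- attr(table, "metadata")
  if (is.null(md$D)) stop("estimate_rates: metadata lacks D")
  if (is.null(window)) {
    t_switch <- if (!is.null(md$t_switch)) md$t_switch else 0
    window <- c(t_switch, max(table$time))
  }
  fit_p <- fit_smooth(table, "peng", degree, window, method)
  fit_x <- fit_smooth(table, "biomass", degree, window, method)
  gdw <- if (!is.null(md$gdw_per_cmol)) md$gdw_per_cmol else 24.6
  qp <- qp_profile(fit_p, fit_x, md$D, gdw, n = n, edge_trim = edge_trim)
  comp <- companion_rates(table, degree = degree, window = window,
                          method = method, n = n, edge_trim = edge_trim)
  stopifnot(all(abs(qp$time - comp$time) < 1e-8))
  out <- cbind(qp, comp[setdiff(names(comp), "time")])
  structure(out, class = c("rate_profile", "data.frame"))
}

#' Number of generations (doublings) after time t in a chemostat
#'
#' At steady state the specific growth rate equals the dilution rate, so
#' the culture doubles every \eqn{\ln 2 / D} hours and
#' \eqn{generations = t D / \ln 2}. 500 h at D = 0.03 1/h gives 21.6
#' doublings, i.e. about 22 generations. (An e-folding convention,
#' \eqn{t D}, would give 15; this package uses doublings throughout.)
#'
#' @param t time since the start of the chemostat phase, h.
#' @param D dilution rate, 1/h.
#' @return Number of doublings (unrounded).
#' @export
generations <- function(t, D) {
  if (any(t < 0)) stop("generations: t must be >= 0")
  if (any(D <= 0)) stop("generations: D must be > 0")
  t * D / log(2)
}

#' Peak production rate and fold-decline of a degeneration profile
#'
#' \code{qp_peak} locates the maximum of the estimated q_p(t);
#' \code{fold_decline} divides it by q_p at a reference time after feed
#' start (500 h by default). The decline metric uses the spline smoother
#' by default because a global low-order polynomial cannot resolve the
#' very low tail of a >10-fold decline.
#'
#' @param table a \code{\link{timeseries_table}} of a full cultivation.
#' @param degree polynomial degree for the peak estimate.
#' @param t_ref reference time, h after the start of the chemostat phase.
#' @param method smoothing method for the tail estimate.
#' @return \code{qp_peak}: list with \code{qp_max} and \code{t_max} (h after
#'   feed start). \code{fold_decline}: a single number, peak q_p divided by
#'   q_p at \code{t_ref}.
#' @export
qp_peak <- function(table, degree = 5, method = "poly") {
  prof <- estimate_rates(table, degree = degree, method = method)
  i <- which.max(prof$qp)
  t_switch <- attr(table, "metadata")$t_switch
  if (is.null(t_switch)) t_switch <- 0
  list(qp_max = prof$qp[i], t_max = prof$time[i] - t_switch)
}

#' @rdname qp_peak
#' @export
fold_decline <- function(table, t_ref = 500, method = "spline") {
  prof <- estimate_rates(table, method = method)
  t_switch <- attr(table, "metadata")$t_switch
  if (is.null(t_switch)) t_switch <- 0
  tt <- t_switch + t_ref
  if (tt > max(prof$time) || tt < min(prof$time))
    stop("fold_decline: reference time ", t_ref,
         " h lies outside the estimated window")
  qp_ref <- stats::approx(prof$time, prof$qp, xout = tt)$y
  if (qp_ref <= 0)
    stop("fold_decline: estimated q_p at the reference time is not positive")
  max(prof$qp) / qp_ref
}
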