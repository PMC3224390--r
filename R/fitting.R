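# Inference of the non-producing subpopulation fraction f0 from an
# observed degeneration profile q_p(t), by forward simulation of the
# competition model. The selection strength delta (growth-rate gap between
# the subpopulations) is fixed by the producer's production burden by
# default and only optionally freed, mirroring a fit where bioenergetics
# are taken as known and only the population composition is estimated.

.sim_qp_at <- function(times, config, producer, nonproducer,
                       dt = 2, rtol = 1e-6, atol = 1e-8) {
  sim <- simulate_culture(config, producer, nonproducer, dt = dt,
                          rtol = rtol, atol = atol)
  stats::approx(sim$times, sim$rates$qp, xout = times, rule = 2)$y
}

.qp_objective <- function(observed, config, producer, nonproducer,
                          weight_floor = 0.1) {
  qp_obs <- observed$qp
  floor_ <- weight_floor * max(abs(qp_obs))
  w <- 1 / pmax(abs(qp_obs), floor_)^2
  # Batch-phase growth is identical for producer and non-producer (no
  # production under catabolite repression), so the feed-start time does
  # not depend on f0: resolve it once and reuse it for every candidate,
  # which removes event-location noise from the objective surface.
  if (identical(config$t_switch, "auto")) {
    ref <- simulate_culture(config, producer, nonproducer, dt = 2,
                            rtol = 1e-6, atol = 1e-8)
    config$t_switch <- ref$t_switch
  }
  function(f0, delta_scale = 1) {
    cfg <- config
    cfg$f0 <- f0
    pr <- producer
    pr$Yps_burden <- producer$Yps_burden * delta_scale
    qp_sim <- tryCatch(
      .sim_qp_at(observed$time, cfg, pr, nonproducer),
      error = function(e) NULL)
    if (is.null(qp_sim)) return(NA_real_)
    sum(w * (qp_sim - qp_obs)^2)
  }
}

#' Fit the initial non-producer fraction to a degeneration profile
#'
#' Minimises the weighted sum of squared differences between the observed
#' biomass-specific production rate profile and the population q_p(t) of
#' the competition model, over the initial non-producer fraction f0 (and
#' optionally the selection strength, freed as a multiplier on the
#' producer's production burden). Weights are the inverse squared observed
#' magnitude (floored at 10\% of the profile maximum), i.e. approximately
#' relative error, so the low tail does not dominate. A coarse grid scan
#' (step 0.01 on \[0, 0.5\]) is followed by two-stage parabolic
#' refinement; the procedure is deterministic for given inputs.
#'
#' @param observed a \code{rate_profile} (or data.frame with \code{time},
#'   absolute h, and \code{qp}) spanning the rise and decline.
#' @param config \code{\link{chemostat_config}} of the experiment (its
#'   \code{f0} entry is ignored).
#' @param producer,nonproducer \code{\link{strain_params}}.
#' @param free character subset of \code{c("f0", "delta")}.
#' @param f0_grid coarse scan grid.
#' @return Object of class \code{fit_result}: \code{f0}, \code{delta}
#'   (realised selection coefficient at full enzyme level, 1/h),
#'   \code{delta_scale}, \code{objective}, \code{conf_int} (approximate
#'   95\% interval from the local profile curvature), \code{convergence},
#'   \code{identifiability_warning}, and the scan \code{profile}.
#' @export
fit_f0 <- function(observed, config, producer, nonproducer,
                   free = "f0", f0_grid = seq(0, 0.5, by = 0.01)) {
  if (!all(free %in% c("f0", "delta")))
    stop("fit_f0: free must be a subset of {f0, delta}")
  if (!all(c("time", "qp") %in% names(observed)))
    stop("fit_f0: observed needs columns time and qp")
  if (nrow(observed) < 5)
    stop("fit_f0: need at least 5 observed points spanning rise and decline")
  warn <- length(free) > 1 && nrow(observed) < 8
  if (identical(config$t_switch, "auto")) {
    ref <- simulate_culture(config, producer, nonproducer, dt = 2,
                            rtol = 1e-6, atol = 1e-8)
    config$t_switch <- ref$t_switch
  }
  obj <- .qp_objective(observed, config, producer, nonproducer)

  fit_delta <- "delta" %in% free
  inner <- function(f0) {
    if (!fit_delta) return(c(obj(f0), 1))
    op <- stats::optimize(function(ds) obj(f0, ds), c(0.25, 4), tol = 1e-3)
    c(op$objective, op$minimum)
  }
  scan <- t(vapply(f0_grid, inner, numeric(2)))
  profile <- data.frame(f0 = f0_grid, sse = scan[, 1],
                        delta_scale = scan[, 2])
  ok <- which(!is.na(profile$sse))
  if (!length(ok)) stop("fit_f0: simulation failed on the whole grid")
  i <- ok[which.min(profile$sse[ok])]
  ds_hat <- profile$delta_scale[i]

  # two-stage parabolic refinement. Interpolating a parabola through SSE
  # evaluations averages over the small numerical roughness of the
  # objective (adaptive integration, event location), which a line search
  # would chase into spurious micro-minima.
  vertex <- function(xs, ys) {
    X <- cbind(1, xs, xs^2)
    cf <- solve(X, ys)
    if (is.finite(cf[3]) && cf[3] > 0)
      min(max(-cf[2] / (2 * cf[3]), xs[1]), xs[3])
    else xs[which.min(ys)]
  }
  f0_hat <- f0_grid[i]
  if (i > 1 && i < length(f0_grid) &&
      all(is.finite(profile$sse[(i - 1):(i + 1)])))
    f0_hat <- vertex(f0_grid[(i - 1):(i + 1)], profile$sse[(i - 1):(i + 1)])
  h2 <- 0.0025
  xs <- sort(unique(pmin(pmax(c(f0_hat - h2, f0_hat, f0_hat + h2), 0), 1)))
  if (length(xs) == 3) {
    ys <- vapply(xs, function(x) obj(x, ds_hat), numeric(1))
    if (all(is.finite(ys))) f0_hat <- vertex(xs, ys)
  }
  obj_hat <- obj(f0_hat, ds_hat)
  if (!is.finite(obj_hat) || profile$sse[i] < obj_hat) {
    f0_hat <- f0_grid[i]
    obj_hat <- profile$sse[i]
  }
  delta <- producer$Yxs_max * producer$Yps_burden * ds_hat *
    producer$qp_cell_max
  # approximate 95% interval from a sandwich variance estimate: robust to
  # the mixed relative/floored weighting, using the sensitivity of the
  # simulated profile to f0 (one extra forward simulation)
  ci <- c(NA_real_, NA_real_)
  cfg <- config
  pr <- producer
  pr$Yps_burden <- producer$Yps_burden * ds_hat
  h <- 0.005
  sim_at <- function(f0) tryCatch({
    cfg$f0 <- f0
    .sim_qp_at(observed$time, cfg, pr, nonproducer)
  }, error = function(e) NULL)
  qp_hat <- sim_at(f0_hat)
  qp_up <- sim_at(min(f0_hat + h, 1))
  qp_dn <- sim_at(max(f0_hat - h, 0))
  if (!is.null(qp_hat) && !is.null(qp_up) && !is.null(qp_dn)) {
    # weights from the fitted profile, not the noisy observations, so the
    # sandwich terms are uncorrelated with the residuals
    floor_ <- 0.1 * max(abs(qp_hat))
    w <- 1 / pmax(abs(qp_hat), floor_)^2
    J <- (qp_up - qp_dn) / (min(f0_hat + h, 1) - max(f0_hat - h, 0))
    r <- qp_hat - observed$qp
    A <- sum(w * J^2)
    if (A > 0) {
      lev <- pmin(w * J^2 / A, 0.99)          # leverage of each point
      B <- sum(w^2 * J^2 * r^2 / (1 - lev)^2) # HC3 small-sample correction
      se <- sqrt(B) / A
      q <- stats::qt(0.975, max(nrow(observed) - length(free), 1))
      ci <- pmin(pmax(f0_hat + c(-1, 1) * q * se, 0), 1)
    }
  }
  structure(list(f0 = f0_hat, delta = delta, delta_scale = ds_hat,
                 objective = obj_hat, conf_int = ci, convergence = TRUE,
                 identifiability_warning = warn, profile = profile,
                 free = free),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("Degeneration profile fit: f0 = %.4f ",
                     "(delta = %.4f 1/h%s), objective %.4g\n"),
              x$f0, x$delta,
              if ("delta" %in% x$free)
                sprintf(", scale %.3f fitted", x$delta_scale) else ", fixed",
              x$objective))
  if (x$identifiability_warning)
    cat("  warning: too few informative points to separate f0 and delta\n")
  invisible(x)
}

#' Objective profile over an f0 grid
#'
#' Evaluates the fit objective by forward simulation at each grid value;
#' failed simulations are recorded as NA rather than aborting the scan.
#'
#' @inheritParams fit_f0
#' @param f0_grid grid of f0 values in \[0, 1\].
#' @return data.frame with columns \code{f0} and \code{sse}.
#' @export
objective_profile <- function(observed, config, producer, nonproducer,
                              f0_grid) {
  if (length(f0_grid) == 0) stop("objective_profile: empty f0 grid")
  if (any(f0_grid < 0 | f0_grid > 1))
    stop("objective_profile: grid must lie in [0, 1]")
  obj <- .qp_objective(observed, config, producer, nonproducer)
  data.frame(f0 = f0_grid,
             sse = vapply(f0_grid, function(f) obj(f), numeric(1)))
}
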