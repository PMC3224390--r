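# Two-subpopulation model of batch + ethanol-limited chemostat cultivation.
#
# State vector (concentrations in the broth):
#   x_p    producer biomass, Cmol/L
#   x_np   non-producer biomass, Cmol/L
#   s      ethanol, Cmol/L
#   p      penicillin-G, mmol/L
#   paa    phenylacetic acid, mmol/L
#   ohpaa  o-OH-phenylacetic acid, mmol/L
#   toc    dissolved biomass-like byproduct (lysis TOC), Cmol/L
#   e      relative pathway enzyme level, dimensionless in [0, 1]

# carbon content (Cmol per mmol) and degree of reduction (e- per Cmol)
# of the species the model tracks; PenG C16H18N2O4S, PAA C8H8O2,
# o-OH-PAA C8H8O3, biomass CH1.8O0.5N0.2
.C_PENG  <- 0.016
.C_PAA   <- 0.008
.C_OHPAA <- 0.008
.G_ETH   <- 6.0
.G_X     <- 4.2
.G_PAA   <- 4.5
.G_PENG  <- 4.625
.G_OHPAA <- 4.25

.state_names <- c("x_p", "x_np", "s", "p", "paa", "ohpaa", "toc", "e")

#' Construct a culture state vector
#'
#' @param x_p,x_np producer / non-producer biomass, Cmol/L.
#' @param s ethanol, Cmol/L.
#' @param p penicillin-G, mmol/L.
#' @param paa phenylacetic acid, mmol/L.
#' @param ohpaa o-OH-PAA, mmol/L.
#' @param toc dissolved lysis byproduct, Cmol carbon/L.
#' @param e relative pathway enzyme level in [0, 1].
#' @return Named numeric vector of class \code{culture_state}.
#' @export
culture_state <- function(x_p = 0, x_np = 0, s = 0, p = 0, paa = 0,
                          ohpaa = 0, toc = 0, e = 0) {
  st <- c(x_p = x_p, x_np = x_np, s = s, p = p, paa = paa,
          ohpaa = ohpaa, toc = toc, e = e)
  if (any(!is.finite(st))) stop("culture_state: non-finite component")
  if (any(st < 0))
    stop("culture_state: negative value for ",
         paste(names(st)[st < 0], collapse = ", "))
  if (st["e"] > 1) stop("culture_state: enzyme level e must be <= 1")
  class(st) <- c("culture_state", "numeric")
  st
}

# maximum substrate uptake capacity implied by mu_max, accounting for the
# lysis diversion: observed net mu_max = (1 - toc_fraction) * Yxs * (qs_max - ms)
.qs_max <- function(params, toc_fraction) {
  params$mu_max / (1 - toc_fraction) / params$Yxs_max + params$ms
}

# All per-strain and volumetric fluxes at one state. Internal workhorse
# shared by the ODE right-hand side, the rate annotations and the balances.
.model_fluxes <- function(state, config, producer, nonproducer) {
  st <- pmax(unlist(state)[.state_names], 0)  # integrator may probe < 0
  fl <- config$toc_fraction
  strains <- list(p = producer, np = nonproducer)
  xs <- c(p = st[["x_p"]], np = st[["x_np"]])
  qs <- mu <- qp <- side <- numeric(2)
  names(qs) <- names(mu) <- names(qp) <- names(side) <- c("p", "np")
  for (k in c("p", "np")) {
    pr <- strains[[k]]
    qs[k] <- .qs_max(pr, fl) * st[["s"]] / (pr$Ks + st[["s"]])
    qp[k] <- pr$qp_cell_max * st[["e"]]
    side[k] <- pr$paa_side_fraction / (1 - pr$paa_side_fraction) * qp[k]
    mu[k] <- pr$Yxs_max * (qs[k] - pr$ms - pr$Yps_burden * qp[k])
  }
  x <- sum(xs)
  # volumetric CO2 (Cmol/L/h) from the carbon balance of each strain:
  # uptake = gross biomass + carbon into PenG + CO2
  cer_cmol <- sum(xs * (qs - mu - .C_PENG / 2 * qp))
  # volumetric O2 uptake (mol/L/h) from the electron balance
  our_mol <- sum(xs * (.G_ETH * qs +
                       .G_PAA * .C_PAA * (qp + side) -
                       .G_X * mu -
                       .G_PENG * .C_PENG * qp -
                       .G_OHPAA * .C_OHPAA * side)) / 4
  list(qs = qs, mu_gross = mu, mu_net = mu * (1 - fl), qp = qp, side = side,
       x = x, cer = 1000 * cer_cmol, our = 1000 * our_mol,
       qp_pop = if (x > 0) sum(qp * xs) / x else 0,
       mu_pop = if (x > 0) sum(mu * (1 - fl) * xs) / x else 0,
       qs_pop = if (x > 0) sum(qs * xs) / x else 0,
       qo2 = if (x > 0) 1000 * our_mol / x else 0,
       qco2 = if (x > 0) 1000 * cer_cmol / x else 0)
}

# shared right-hand side; `chemostat` switches the dilution terms on
.rhs <- function(state, config, producer, nonproducer, chemostat) {
  fx <- .model_fluxes(state, config, producer, nonproducer)
  st <- pmax(unlist(state)[.state_names], 0)
  D <- if (chemostat) config$D else 0
  fl <- config$toc_fraction
  xs <- c(st[["x_p"]], st[["x_np"]])
  pr <- producer
  d <- c(
    x_p   = (fx$mu_gross[["p"]] * (1 - fl) - D) * st[["x_p"]],
    x_np  = (fx$mu_gross[["np"]] * (1 - fl) - D) * st[["x_np"]],
    s     = D * (config$feed_ethanol - st[["s"]]) - sum(fx$qs * xs),
    p     = sum(fx$qp * xs) - D * st[["p"]],
    paa   = D * (config$feed_paa - st[["paa"]]) -
            sum((fx$qp + fx$side) * xs),
    ohpaa = sum(fx$side * xs) - D * st[["ohpaa"]],
    toc   = fl * sum(fx$mu_gross * xs) - D * st[["toc"]],
    e     = pr$k_induction * (1 - st[["e"]]) *
            (st[["s"]] < pr$repression_threshold) - pr$k_decay * st[["e"]]
  )
  d
}

#' Time derivative of the culture state
#'
#' Evaluates the right-hand side of the cultivation model at one state:
#' Monod uptake, Herbert-Pirt growth with production burden, first-order
#' enzyme induction gated by catabolite repression, PAA consumption with a
#' fixed side-fraction to o-OH-PAA, and (during the chemostat phase)
#' dilution terms \eqn{-D (c - c_{feed})}.
#'
#' @param state a \code{\link{culture_state}} (or named non-negative vector).
#' @param config a \code{\link{chemostat_config}}.
#' @param producer,nonproducer \code{\link{strain_params}} of the two
#'   subpopulations.
#' @param t time, h. Only used to decide whether the feed is running
#'   (\code{t >= t_switch}); the kinetics are autonomous.
#' @return Named numeric vector of time derivatives of every state field.
#' @export
derivative <- function(state, config, producer, nonproducer, t = Inf) {
  st <- unlist(state)
  missing_f <- setdiff(.state_names, names(st))
  if (length(missing_f))
    stop("derivative: state lacks field(s) ",
         paste(missing_f, collapse = ", "))
  st <- st[.state_names]
  if (any(st < 0))
    stop("derivative: negative state component: ",
         paste(.state_names[st < 0], collapse = ", "))
  if (identical(config$t_switch, "auto"))
    stop("derivative: resolve t_switch first (numeric) or use simulate_culture")
  .rhs(st, config, producer, nonproducer, chemostat = t >= config$t_switch)
}

#' Simulate batch + chemostat cultivation of a mixed population
#'
#' Integrates the cultivation model over \code{[0, horizon]}. The culture
#' starts as a batch on the feed medium; when \code{t_switch = "auto"} the
#' feed is started just before ethanol depletion, detected by an integrator
#' root at a residual ethanol of 1e-4 Cmol/L. A stiff-capable adaptive
#' integrator (\code{deSolve::lsodar}) is used throughout.
#'
#' @inheritParams derivative
#' @param dt spacing of the returned dense output grid, h.
#' @param rtol,atol integrator tolerances.
#' @return Object of class \code{culture_sim}: list with \code{times},
#'   \code{states} (matrix, one row per time), \code{rates} (data.frame of
#'   population-level q_p, mu, q_s, q_O2, q_CO2 and the producer fraction),
#'   \code{t_switch}, and the inputs.
#' @export
simulate_culture <- function(config = chemostat_config(),
                             producer = strain_params(qp_cell_max = 1),
                             nonproducer = strain_params(qp_cell_max = 0),
                             dt = 0.5, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "chemostat_config"),
            inherits(producer, "strain_params"),
            inherits(nonproducer, "strain_params"))
  y0 <- c(x_p = (1 - config$f0) * config$batch_init_biomass,
          x_np = config$f0 * config$batch_init_biomass,
          s = config$batch_init_ethanol, p = 0, paa = config$feed_paa,
          ohpaa = 0, toc = 0, e = 0)
  auto <- identical(config$t_switch, "auto")

  f_batch <- function(t, y, parms)
    list(.rhs(y, config, producer, nonproducer, chemostat = FALSE))
  f_chem <- function(t, y, parms)
    list(.rhs(y, config, producer, nonproducer, chemostat = TRUE))

  if (auto) {
    root_s <- function(t, y, parms) y[["s"]] - 1e-4
    batch_times <- seq(0, config$horizon, by = dt)
    outA <- deSolve::lsodar(y0, batch_times, f_batch, parms = NULL,
                            rootfunc = root_s, rtol = rtol, atol = atol)
    t_switch <- attr(outA, "troot")
    if (is.null(t_switch) || length(t_switch) == 0)
      stop("simulate_culture: ethanol never depleted within the horizon; ",
           "last valid time ", max(outA[, "time"]))
    t_switch <- t_switch[1]
  } else {
    t_switch <- config$t_switch
    if (t_switch > 0) {
      batch_times <- sort(unique(c(seq(0, t_switch, by = dt), t_switch)))
      outA <- deSolve::lsodar(y0, batch_times, f_batch, parms = NULL,
                              rtol = rtol, atol = atol)
    } else {
      outA <- matrix(c(0, y0), nrow = 1,
                     dimnames = list(NULL, c("time", names(y0))))
    }
  }
  if (config$horizon <= t_switch)
    stop("simulate_culture: horizon (", config$horizon,
         ") does not exceed the batch phase (t_switch = ",
         round(t_switch, 2), " h)")

  yB <- unlist(outA[nrow(outA), .state_names])
  chem_times <- sort(unique(c(t_switch, seq(ceiling(t_switch / dt) * dt,
                                            config$horizon, by = dt),
                              config$horizon)))
  outB <- deSolve::lsodar(yB, chem_times, f_chem, parms = NULL,
                          rtol = rtol, atol = atol)
  if (max(outB[, "time"]) < config$horizon - 1e-8)
    stop("simulate_culture: integration failed at t = ",
         max(outB[, "time"]), " h")

  keepA <- outA[, "time"] < t_switch
  times <- c(outA[keepA, "time"], outB[, "time"])
  states <- rbind(outA[keepA, .state_names, drop = FALSE],
                  outB[, .state_names, drop = FALSE])
  states[states < 0 & states > -atol * 10] <- 0
  rownames(states) <- NULL

  rates <- t(vapply(seq_along(times), function(i) {
    fx <- .model_fluxes(states[i, ], config, producer, nonproducer)
    x <- fx$x
    c(qp = fx$qp_pop, mu = fx$mu_pop, qs = fx$qs_pop,
      qo2 = fx$qo2, qco2 = fx$qco2, our = fx$our, cer = fx$cer,
      producer_fraction = if (x > 0) states[i, "x_p"] / x else NA_real_)
  }, numeric(8)))
  rates <- data.frame(time = times, rates)

  cfg <- config
  cfg$t_switch <- t_switch
  structure(list(times = times, states = states, rates = rates,
                 t_switch = t_switch, config = cfg, producer = producer,
                 nonproducer = nonproducer),
            class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "Chemostat cultivation simulation\n",
    "  batch phase: 0 .. %.1f h, chemostat: %.1f .. %.1f h (D = %g 1/h)\n",
    "  final biomass %.3f Cmol/L (%.2f g DW/L), producer fraction %.3f\n",
    "  peak population q_p %.3f mmol/Cmol/h\n"),
    x$t_switch, x$t_switch, max(x$times), x$config$D,
    sum(x$states[nrow(x$states), c("x_p", "x_np")]),
    sum(x$states[nrow(x$states), c("x_p", "x_np")]) * x$config$gdw_per_cmol,
    x$rates$producer_fraction[nrow(x$rates)],
    max(x$rates$qp)))
  invisible(x)
}

#' Algebraic single-strain chemostat steady state
#'
#' Solves \eqn{\mu(s) = D} for the residual substrate concentration and the
#' substrate balance for biomass, for a single strain growing alone in the
#' chemostat. With production burden, the apparent yield is reduced
#' relative to \code{Yxs_max} by maintenance and the PenG cost.
#'
#' @inheritParams derivative
#' @param params \code{\link{strain_params}} of the (single) strain.
#' @return A \code{\link{culture_state}} with attributes
#'   \code{biomass_gdw_l} (g DW/L) and \code{residual_ethanol}.
#' @export
steady_state <- function(config = chemostat_config(),
                         params = strain_params(qp_cell_max = 0)) {
  stopifnot(inherits(config, "chemostat_config"),
            inherits(params, "strain_params"))
  fl <- config$toc_fraction
  D <- config$D
  if (D >= params$mu_max)
    stop("steady_state: washout (D = ", D, " >= mu_max = ", params$mu_max, ")")
  mu_gross <- D / (1 - fl)
  qsm <- .qs_max(params, fl)
  # enzyme level: repressed if residual ethanol ends up above the threshold,
  # otherwise the induction/decay balance
  e_ss <- if (params$k_induction + params$k_decay > 0)
    params$k_induction / (params$k_induction + params$k_decay) else 0
  qp <- params$qp_cell_max * e_ss
  qs <- mu_gross / params$Yxs_max + params$ms + params$Yps_burden * qp
  if (qs >= qsm)
    stop("steady_state: washout; required uptake ", signif(qs, 4),
         " exceeds capacity ", signif(qsm, 4), " Cmol/Cmol/h")
  s <- params$Ks * qs / (qsm - qs)
  if (s >= params$repression_threshold) {  # repressed: no production burden
    e_ss <- 0
    qp <- 0
    qs <- mu_gross / params$Yxs_max + params$ms
    s <- params$Ks * qs / (qsm - qs)
  }
  x <- D * (config$feed_ethanol - s) / qs
  side <- params$paa_side_fraction / (1 - params$paa_side_fraction) * qp
  st <- culture_state(
    x_p = if (params$qp_cell_max > 0) x else 0,
    x_np = if (params$qp_cell_max > 0) 0 else x,
    s = s, p = qp * x / D,
    paa = max(config$feed_paa - (qp + side) * x / D, 0),
    ohpaa = side * x / D, toc = fl * mu_gross * x / D, e = e_ss)
  attr(st, "biomass_gdw_l") <- x * config$gdw_per_cmol
  attr(st, "residual_ethanol") <- s
  st
}
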