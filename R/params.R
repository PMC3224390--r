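#' Strain parameters for the chemostat competition model
#'
#' Bundles the physiological constants of one subpopulation (producer or
#' non-producer). Substrate uptake follows Monod kinetics
#' \eqn{q_s = q_{s,max} s/(K_s + s)} and growth follows a Herbert-Pirt
#' partition of uptake over growth, maintenance and product formation:
#' \deqn{\mu = Y_{xs}^{max} (q_s - m_s - Y_{ps} q_p).}
#' Penicillin-G formation carries a substrate-equivalent burden
#' \code{Yps_burden} (carbon incorporated into the product plus the ATP cost
#' of synthesis and export, expressed as Cmol ethanol per mmol PenG), which
#' is what gives the non-producing variant its selective advantage under
#' carbon limitation.
#'
#' @param mu_max maximum (net) specific growth rate, 1/h.
#' @param Ks substrate (ethanol) affinity constant, Cmol/L.
#' @param Yxs_max maximum biomass yield, Cmol biomass / Cmol ethanol.
#' @param ms maintenance coefficient, Cmol ethanol / Cmol biomass / h.
#' @param qp_cell_max maximal per-cell PenG production rate at full enzyme
#'   level, mmol PenG / Cmol biomass / h. Zero for the non-producer.
#' @param Yps_burden substrate-equivalent cost of production, Cmol ethanol
#'   per mmol PenG. Physically at least the 0.008 Cmol/mmol carbon
#'   incorporated into the ethanol-derived half of the PenG molecule;
#'   smaller values (down to 0, which switches selection off) are accepted
#'   for what-if analyses.
#' @param k_induction first-order rate constant of pathway-enzyme synthesis
#'   after derepression, 1/h.
#' @param k_decay first-order enzyme decay rate constant, 1/h.
#' @param repression_threshold residual ethanol concentration above which
#'   enzyme synthesis is repressed (carbon catabolite repression), Cmol/L.
#' @param paa_side_fraction fraction of consumed phenylacetic acid diverted
#'   to the o-hydroxylated byproduct o-OH-PAA (dimensionless).
#'
#' @return An object of class \code{strain_params}.
#' @export
strain_params <- function(mu_max = 0.088, Ks = 1e-3, Yxs_max = 0.6,
                          ms = 0.0115, qp_cell_max = 0, Yps_burden = 0.025,
                          k_induction = 0.022, k_decay = 0,
                          repression_threshold = 0.01,
                          paa_side_fraction = 0.10) {
  p <- list(mu_max = mu_max, Ks = Ks, Yxs_max = Yxs_max, ms = ms,
            qp_cell_max = qp_cell_max, Yps_burden = Yps_burden,
            k_induction = k_induction, k_decay = k_decay,
            repression_threshold = repression_threshold,
            paa_side_fraction = paa_side_fraction)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("strain_params: all fields must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  neg <- vapply(p, function(x) x < 0, logical(1))
  if (any(neg))
    stop("strain_params: negative value for ",
         paste(names(p)[neg], collapse = ", "))
  if (p$paa_side_fraction >= 1)
    stop("strain_params: paa_side_fraction must be < 1")
  if (p$Yxs_max > 1)
    stop("strain_params: Yxs_max > 1 violates carbon conservation")
  structure(p, class = "strain_params")
}

#' Cultivation configuration (batch phase + chemostat phase)
#'
#' @param D dilution rate of the chemostat phase, 1/h.
#' @param feed_ethanol ethanol concentration in the feed, Cmol/L.
#' @param feed_paa phenylacetic acid concentration in the feed, mmol/L.
#' @param batch_init_ethanol initial ethanol at inoculation, Cmol/L.
#' @param batch_init_biomass initial biomass at inoculation, Cmol/L.
#' @param f0 initial non-producer biomass fraction (0..1).
#' @param t_switch time at which the feed is started, h, or \code{"auto"}
#'   to start the feed just before ethanol depletion (detected by an
#'   integrator root at s = 1e-4 Cmol/L).
#' @param horizon total simulated time, h.
#' @param gdw_per_cmol biomass conversion factor, g dry weight per Cmol
#'   (generic biomass CH1.8O0.5N0.2 is about 24.6 g DW/Cmol).
#' @param toc_fraction fraction of gross biomass synthesis lost to a
#'   dissolved biomass-like byproduct pool (cell lysis, measured as TOC).
#'
#' @return An object of class \code{chemostat_config}.
#' @export
chemostat_config <- function(D = 0.03, feed_ethanol = 0.25, feed_paa = 4,
                             batch_init_ethanol = 0.25,
                             batch_init_biomass = 0.005,
                             f0 = 0.15, t_switch = "auto", horizon = 650,
                             gdw_per_cmol = 24.6, toc_fraction = 0.02) {
  auto <- identical(t_switch, "auto")
  if (!auto && (!is.numeric(t_switch) || t_switch < 0))
    stop("chemostat_config: t_switch must be \"auto\" or a non-negative time")
  if (D <= 0) stop("chemostat_config: D must be > 0")
  if (f0 < 0 || f0 > 1) stop("chemostat_config: f0 must lie in [0, 1]")
  if (toc_fraction < 0 || toc_fraction >= 0.1)
    stop("chemostat_config: toc_fraction must lie in [0, 0.1)")
  if (!auto && horizon <= t_switch)
    stop("chemostat_config: horizon must exceed t_switch")
  structure(list(D = D, feed_ethanol = feed_ethanol, feed_paa = feed_paa,
                 batch_init_ethanol = batch_init_ethanol,
                 batch_init_biomass = batch_init_biomass, f0 = f0,
                 t_switch = t_switch, horizon = horizon,
                 gdw_per_cmol = gdw_per_cmol, toc_fraction = toc_fraction),
            class = "chemostat_config")
}

#' @export
print.strain_params <- function(x, ...) {
  cat("Strain parameters (Monod / Herbert-Pirt):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.chemostat_config <- function(x, ...) {
  cat("Chemostat configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
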