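# Redox sensor-reaction ratios, adenylate energy charge, and intracellular
# level <-> concentration conversions.
#
# The near-equilibrium reactions F6P <-> mannitol-6P and FBP <-> G3P couple
# their mass-action ratio to the cytosolic NADH/NAD couple, so the ratio of
# the two metabolite levels tracks NADH/NAD up to an (unknown) equilibrium
# constant. Relative to a reference time point the constant cancels:
#   (NADH/NAD)_t / (NADH/NAD)_t1 = (M6P/F6P)_t / (M6P/F6P)_t1
# and equivalently with (G3P/FBP).

#' Relative NADH/NAD ratio from a sensor metabolite pair
#'
#' @param series data.frame with columns \code{label} (time-point label),
#'   \code{num} (numerator metabolite level, e.g. mannitol-6P) and
#'   \code{den} (denominator level, e.g. F6P), in any consistent unit.
#' @param reference label of the reference time point (t1).
#' @return data.frame with \code{label} and \code{relative_ratio}; the
#'   reference row is exactly 1.
#' @export
relative_redox_ratio <- function(series, reference) {
  need <- c("label", "num", "den")
  if (length(setdiff(need, names(series))))
    stop("relative_redox_ratio: series needs columns ",
         paste(need, collapse = ", "))
  if (!reference %in% series$label)
    stop("relative_redox_ratio: reference label \"", reference,
         "\" not in series")
  if (any(series$num <= 0) || any(series$den <= 0))
    stop("relative_redox_ratio: metabolite levels must be > 0")
  r <- series$num / series$den
  r1 <- r[match(reference, series$label)]
  data.frame(label = series$label, relative_ratio = r / r1)
}

#' Adenylate energy charge
#'
#' Atkinson's index \eqn{(ATP + ADP/2) / (ATP + ADP + AMP)}, a number in
#' \[0, 1\] summarising the cellular energy status.
#'
#' @param atp,adp,amp nucleotide levels (any common unit, e.g.
#'   \eqn{\mu}mol/g DW); vectors are recycled element-wise.
#' @return Energy charge in \[0, 1\].
#' @export
energy_charge <- function(atp, adp, amp) {
  if (any(atp < 0 | adp < 0 | amp < 0))
    stop("energy_charge: nucleotide levels must be >= 0")
  tot <- atp + adp + amp
  if (any(tot == 0))
    stop("energy_charge: all-zero nucleotide panel")
  (atp + 0.5 * adp) / tot
}

#' Intracellular level to concentration
#'
#' Converts a biomass-specific metabolite level (\eqn{\mu}mol per g DW) to
#' an intracellular concentration using the whole-cell volume convention of
#' 2.5 mL per g DW (no compartment correction). 1 \eqn{\mu}mol/g DW maps to
#' 400 \eqn{\mu}M.
#'
#' @param level metabolite level, \eqn{\mu}mol/g DW.
#' @param cell_volume specific cell volume, mL/g DW.
#' @return Concentration in \eqn{\mu}M.
#' @export
to_concentration <- function(level, cell_volume = 2.5) {
  if (any(level < 0)) stop("to_concentration: level must be >= 0")
  if (any(cell_volume <= 0)) stop("to_concentration: volume must be > 0")
  level / cell_volume * 1000
}

#' Saturation of an enzyme by its substrate
#'
#' @param conc substrate concentration, \eqn{\mu}M.
#' @param km Michaelis constant, \eqn{\mu}M.
#' @return List with \code{fold_km} (conc/Km) and \code{saturation}
#'   (the Michaelis fraction conc/(Km + conc)).
#' @export
km_saturation <- function(conc, km) {
  if (any(km <= 0)) stop("km_saturation: km must be > 0")
  if (any(conc < 0)) stop("km_saturation: conc must be >= 0")
  list(fold_km = conc / km, saturation = conc / (km + conc))
}
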