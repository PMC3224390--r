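# Pseudo-steady-state metabolic flux analysis.
#
# The balanced-metabolite equations N v = 0 are solved exactly by
# parameterising the flux space with an orthonormal null-space basis K of
# N (rank decisions by SVD with relative tolerance 1e-10): v = K a. The
# measured fluxes then give a weighted least-squares problem in a, with
# inverse-variance weights. This keeps the steady-state constraint exact
# for every returned flux vector, makes over/under-determination explicit
# (redundant measurements show up as a weighted residual; missing ones as
# non-estimable flux directions), and never silently pseudo-inverts an
# underdetermined system.
#
# The bundled network is a reduced ethanol-grown P. chrysogenum model:
# ethanol -> acetaldehyde -> acetate -> acetyl-CoA, TCA cycle, glyoxylate
# shunt, gluconeogenesis, a lumped NADPH-producing pentose-phosphate
# oxidation, sulfate assimilation to cysteine, valine and alpha-aminoadipate
# biosynthesis, the ACV/IPN/PenG reactions with PAA activation, byproduct
# drains (o-OH-PAA, OPC, 6-APA, 8-HPA), a lumped biomass equation and
# ATP/NADH/NADPH pseudo-metabolites (P/O ratio 1.5 in the oxp reaction).
# Redox cofactors carry the pseudo-formula H2 and the adenylates an empty
# formula, so every reaction balances over C/H/O/N/S exactly while the
# cofactors stay exempt from carbon and degree-of-reduction accounting.

.parse_equation <- function(eq, rid) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop("load_network: reaction ", rid, ": malformed equation \"", eq, "\"")
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(NULL)
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1) list(coef = sign, id = parts[1])
      else {
        cf <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(cf))
          stop("load_network: reaction ", rid, ": bad coefficient in \"",
               tm, "\"")
        list(coef = sign * cf, id = paste(parts[-1], collapse = " "))
      }
    })
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], +1))
}

#' Load and validate a stoichiometric reaction network
#'
#' Reads the reaction table (columns \code{reaction_id, equation,
#' reversible, measured}) and metabolite table (columns \code{id, c, h, o,
#' n, s, balanced, exempt}), builds the stoichiometric matrix, and
#' validates that every reaction is elementally balanced over C/H/O/N/S
#' within 1e-9 and that no balanced metabolite is orphaned. Cofactor
#' pseudo-metabolites are marked \code{exempt} and carry pseudo-formulas
#' (H2 for redox carriers, empty for ATP) chosen so the elemental check
#' still closes.
#'
#' @param reactions_path,metabolites_path TSV files; defaults are the
#'   bundled reduced network.
#' @return Object of class \code{reaction_network}: stoichiometric matrix
#'   \code{S} (metabolites x reactions), metabolite and reaction tables,
#'   and the measured reaction ids.
#' @export
load_network <- function(
    reactions_path = system.file("extdata", "network", "reactions.tsv",
                                 package = "chemodegen"),
    metabolites_path = system.file("extdata", "network", "metabolites.tsv",
                                   package = "chemodegen")) {
  if (!file.exists(reactions_path))
    stop("load_network: no such file: ", reactions_path)
  rxns <- utils::read.delim(reactions_path, stringsAsFactors = FALSE,
                            colClasses = c(reaction_id = "character",
                                           equation = "character"))
  mets <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
  need <- c("reaction_id", "equation", "reversible", "measured")
  if (length(setdiff(need, names(rxns))))
    stop("load_network: reaction table lacks column(s) ",
         paste(setdiff(need, names(rxns)), collapse = ", "))
  needm <- c("id", "c", "h", "o", "n", "s", "balanced", "exempt")
  if (length(setdiff(needm, names(mets))))
    stop("load_network: metabolite table lacks column(s) ",
         paste(setdiff(needm, names(mets)), collapse = ", "))
  if (anyDuplicated(rxns$reaction_id))
    stop("load_network: duplicated reaction ids")
  if (anyDuplicated(mets$id)) stop("load_network: duplicated metabolite ids")

  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$reaction_id))
  for (j in seq_len(nrow(rxns))) {
    terms <- .parse_equation(rxns$equation[j], rxns$reaction_id[j])
    for (tm in terms) {
      if (!tm$id %in% mets$id)
        stop("load_network: reaction ", rxns$reaction_id[j],
             ": unknown metabolite \"", tm$id, "\"")
      S[tm$id, j] <- S[tm$id, j] + tm$coef
    }
  }

  # elemental validation (cofactor pseudo-formulas included, see header)
  E <- as.matrix(mets[, c("c", "h", "o", "n", "s")])
  rownames(E) <- mets$id
  imb <- t(E) %*% S
  for (j in seq_len(ncol(S))) {
    bad <- abs(imb[, j]) > 1e-9
    if (any(bad))
      stop("load_network: reaction ", colnames(S)[j],
           " is elementally unbalanced: ",
           paste(sprintf("%s %+.4g", rownames(imb)[bad], imb[bad, j]),
                 collapse = ", "))
  }
  orphan <- mets$id[mets$balanced == 1 & rowSums(S != 0) == 0]
  if (length(orphan))
    stop("load_network: orphan balanced metabolite(s): ",
         paste(orphan, collapse = ", "))

  structure(list(S = S, metabolites = mets, reactions = rxns,
                 balanced = mets$id[mets$balanced == 1],
                 measured = rxns$reaction_id[rxns$measured == 1]),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(paste0("Reaction network: %d reactions (%d designated ",
                     "measured), %d metabolites (%d balanced)\n"),
              ncol(x$S), length(x$measured), nrow(x$S), length(x$balanced)))
  invisible(x)
}

# orthonormal null-space basis with relative SVD tolerance
.null_basis <- function(A, rtol = 1e-10) {
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- c(sv$d, rep(0, ncol(A) - length(sv$d)))
  keep <- d <= max(d) * rtol
  out <- sv$v[, keep, drop = FALSE]
  rownames(out) <- colnames(A)
  out
}

#' Solve the pseudo-steady-state flux distribution
#'
#' @param net a \code{\link{reaction_network}}.
#' @param measured data.frame with columns \code{reaction_id},
#'   \code{value} and optionally \code{se} (standard error, > 0; default
#'   5\% of |value| with a small floor). Units must be consistent across
#'   all measurements (here mmol/Cmol biomass/h, with biomass drain in
#'   mCmol/Cmol/h).
#' @param rtol relative rank tolerance of the factorizations.
#' @param consistency_tol maximal acceptable reduced weighted residual
#'   (chi-square per redundant measurement) before the measurements are
#'   declared inconsistent.
#' @return Object of class \code{flux_estimate}: \code{fluxes} (named
#'   vector over all reactions), \code{solvability} (\code{"determined"},
#'   \code{"overdetermined"} or \code{"underdetermined"}),
#'   \code{non_estimable} (reaction ids without unique solution),
#'   \code{wrss} (weighted residual sum of squares of the redundant part),
#'   \code{redundancy}, \code{residual_inf} (max |N v|), and the fitted
#'   vs measured table.
#' @export
solve_fluxes <- function(net, measured, rtol = 1e-10,
                         consistency_tol = 25) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.numeric(measured) && !is.null(names(measured)))
    measured <- data.frame(reaction_id = names(measured),
                           value = as.numeric(measured))
  if (!all(c("reaction_id", "value") %in% names(measured)))
    stop("solve_fluxes: measured needs columns reaction_id and value")
  if (nrow(measured) < 1) stop("solve_fluxes: at least one measured flux")
  bad <- setdiff(measured$reaction_id, colnames(net$S))
  if (length(bad))
    stop("solve_fluxes: measured id(s) not in network: ",
         paste(bad, collapse = ", "))
  if (is.null(measured$se))
    measured$se <- pmax(0.05 * abs(measured$value), 1e-3)
  if (any(measured$se <= 0)) stop("solve_fluxes: standard errors must be > 0")

  N <- net$S[net$balanced, , drop = FALSE]
  K <- .null_basis(N, rtol)
  if (ncol(K) == 0) stop("solve_fluxes: network admits only the zero flux")
  Km <- K[measured$reaction_id, , drop = FALSE]
  w <- 1 / measured$se
  A <- Km * w
  b <- measured$value * w
  qa <- qr(A, LAPACK = TRUE)
  rank <- sum(abs(diag(qr.R(qa))) > max(abs(diag(qr.R(qa)))) * rtol)

  non_estimable <- character()
  if (rank < ncol(K)) {
    # directions in the flux null space unseen by the measurements
    Z <- .null_basis(A, rtol)
    free <- K %*% Z
    non_estimable <-
      colnames(net$S)[sqrt(rowSums(free^2)) > 1e-8]
    # minimum-norm component in the estimable subspace is still reported,
    # but the caller is told which fluxes are not unique
    a <- qr.coef(qa, b)
    a[is.na(a)] <- 0
    solvability <- "underdetermined"
  } else {
    a <- qr.coef(qa, b)
    solvability <- if (nrow(A) > rank) "overdetermined" else "determined"
  }
  v <- drop(K %*% a)
  names(v) <- colnames(net$S)
  fitted_m <- v[measured$reaction_id]
  res <- (fitted_m - measured$value) / measured$se
  redundancy <- max(nrow(A) - rank, 0)
  wrss <- sum(res^2)
  if (redundancy > 0 && length(non_estimable) == 0 &&
      wrss / redundancy > consistency_tol) {
    rep_tab <- data.frame(reaction_id = measured$reaction_id,
                          measured = measured$value, fitted = fitted_m,
                          weighted_residual = res)
    stop("solve_fluxes: measurements inconsistent with the network ",
         "(reduced chi-square ", signif(wrss / redundancy, 4), " > ",
         consistency_tol, "):\n",
         paste(utils::capture.output(print(rep_tab, digits = 4)),
               collapse = "\n"))
  }
  structure(list(fluxes = v, solvability = solvability,
                 non_estimable = non_estimable, wrss = wrss,
                 redundancy = redundancy,
                 residual_inf = max(abs(N %*% v)),
                 measured = data.frame(reaction_id = measured$reaction_id,
                                       measured = measured$value,
                                       se = measured$se, fitted = fitted_m,
                                       weighted_residual = res)),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(paste0("Flux estimate: %s system, %d redundant measurement",
                     "(s), WRSS %.3g, max |N v| %.2g\n"),
              x$solvability, x$redundancy, x$wrss, x$residual_inf))
  if (length(x$non_estimable))
    cat("  non-estimable fluxes:",
        paste(x$non_estimable, collapse = ", "), "\n")
  print(round(x$fluxes, 6))
  invisible(x)
}

#' Ratio of one reaction's flux between two culture states
#'
#' @param a,b \code{flux_estimate}s (e.g. production peak vs degenerated).
#' @param reaction_id reaction to compare.
#' @return Signed ratio \code{a/b}.
#' @export
flux_ratio <- function(a, b, reaction_id) {
  stopifnot(inherits(a, "flux_estimate"), inherits(b, "flux_estimate"))
  for (x in list(a, b))
    if (!reaction_id %in% names(x$fluxes))
      stop("flux_ratio: reaction \"", reaction_id, "\" not in estimate")
  den <- b$fluxes[[reaction_id]]
  if (den == 0)
    stop("flux_ratio: zero denominator flux for \"", reaction_id, "\"")
  a$fluxes[[reaction_id]] / den
}

# per-mol carbon content and degree of reduction of the measured species
.MFA_C <- c(t_eth = 2, t_paa = 8, t_x = 1, t_peng = 16, t_ohpaa = 8,
            t_opc = 6, t_6apa = 8, t_8hpa = 9)
.MFA_G <- c(t_eth = 12, t_paa = 36, t_x = 4.2, t_peng = 74, t_ohpaa = 34,
            t_opc = 24, t_6apa = 38, t_8hpa = 38)

#' Measured exchange-rate set for MFA from a simulation snapshot
#'
#' Extracts the population rates at one chemostat time, adds trace
#' byproduct secretion (OPC, 6-APA, 8-HPA, as fixed fractions of q_p:
#' their secretion is not part of the cultivation model but falls with
#' production in the measurements the network analysis uses), and derives
#' q_CO2 and q_O2 from exact carbon and electron closure of the measured
#' set, so the set is self-consistent. All values in mmol/Cmol biomass/h
#' (biomass drain in mCmol/Cmol/h).
#'
#' @param sim a \code{culture_sim}.
#' @param t_chemostat snapshot time, h after feed start.
#' @param se_rel relative standard error attached to each measurement.
#' @param byproduct_fractions named fractions of q_p secreted as opc,
#'   apa6, hpa8.
#' @return data.frame with columns \code{reaction_id}, \code{value},
#'   \code{se} and attribute \code{label}.
#' @export
mfa_scenario_rates <- function(sim, t_chemostat, se_rel = 0.05,
                               byproduct_fractions = c(opc = 0.08,
                                                       apa6 = 0.03,
                                                       hpa8 = 0.01)) {
  stopifnot(inherits(sim, "culture_sim"))
  tt <- sim$t_switch + t_chemostat
  if (tt > max(sim$times)) stop("mfa_scenario_rates: time beyond horizon")
  at <- function(y) stats::approx(sim$times, y, xout = tt)$y
  qp <- at(sim$rates$qp)
  side <- sim$producer$paa_side_fraction /
    (1 - sim$producer$paa_side_fraction) * qp
  v <- c(t_eth = 1000 * at(sim$rates$qs) / 2,
         t_x = 1000 * at(sim$rates$mu),
         t_peng = qp,
         t_ohpaa = side,
         t_opc = byproduct_fractions[["opc"]] * qp,
         t_6apa = byproduct_fractions[["apa6"]] * qp,
         t_8hpa = byproduct_fractions[["hpa8"]] * qp)
  v["t_paa"] <- v["t_peng"] + v["t_ohpaa"]
  cin <- sum(.MFA_C[c("t_eth", "t_paa")] * v[c("t_eth", "t_paa")])
  cout <- sum(.MFA_C[c("t_x", "t_peng", "t_ohpaa", "t_opc", "t_6apa",
                       "t_8hpa")] *
              v[c("t_x", "t_peng", "t_ohpaa", "t_opc", "t_6apa", "t_8hpa")])
  v["t_co2"] <- cin - cout
  ein <- sum(.MFA_G[c("t_eth", "t_paa")] * v[c("t_eth", "t_paa")])
  eout <- sum(.MFA_G[c("t_x", "t_peng", "t_ohpaa", "t_opc", "t_6apa",
                       "t_8hpa")] *
              v[c("t_x", "t_peng", "t_ohpaa", "t_opc", "t_6apa", "t_8hpa")])
  v["t_o2"] <- (ein - eout) / 4
  out <- data.frame(reaction_id = names(v), value = as.numeric(v),
                    se = pmax(se_rel * abs(v), 1e-4))
  attr(out, "label") <- sprintf("t%g", t_chemostat)
  out
}
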