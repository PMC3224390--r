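# Pipeline plumbing tying the stages together: generate -> rates ->
# balances -> fit-f0, with JSON summaries. These functions are the
# package's front door; each stage is also callable on its own.

# small rolling string hash so every artifact can carry a config stamp
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.pkg_version <- function()
  as.character(utils::packageVersion("chemodegen"))

#' Generate a measurement-like dataset from a preset
#'
#' @param preset preset name, see \code{\link{list_presets}}.
#' @param seed RNG seed for the measurement noise.
#' @param noise_sd single relative noise level overriding the preset's
#'   per-observable defaults, or \code{NULL} to keep them; 0 gives
#'   noise-free data.
#' @param output optional CSV path (interchange dialect).
#' @return The \code{\link{timeseries_table}}, invisibly if written.
#' @export
generate_dataset <- function(preset = "chemostat-1", seed = 1L,
                             noise_sd = NULL, output = NULL) {
  p <- load_preset(preset)
  noise <- p$noise
  noise$seed <- as.integer(seed)
  if (!is.null(noise_sd))
    noise$relative_sd[] <- noise_sd
  sim <- simulate_culture(p$config, p$producer, p$nonproducer)
  tab <- sample_timeseries(sim, noise)
  md <- attr(tab, "metadata")
  md$preset <- preset
  md$version <- .pkg_version()
  md$config_hash <- .config_hash(p)
  attr(tab, "metadata") <- md
  if (!is.null(output)) {
    write_timeseries(tab, output)
    return(invisible(tab))
  }
  tab
}

#' Run one pipeline stage
#'
#' Dispatches among \code{generate}, \code{rates}, \code{balances},
#' \code{fit-f0} and \code{report}. File-based stages read and write the
#' interchange CSV / JSON formats; every artifact records the seed, the
#' package version and a configuration hash, making outputs reproducible
#' from (inputs, config, seed, version).
#'
#' @param subcommand one of \code{"generate"}, \code{"rates"},
#'   \code{"balances"}, \code{"fit-f0"}, \code{"report"}.
#' @param input input CSV path (stages after generate) or \code{NULL} to
#'   generate in-memory from \code{preset}.
#' @param output optional output path.
#' @param preset,seed,noise_sd see \code{\link{generate_dataset}}.
#' @param ... passed to the underlying stage function.
#' @return The stage's artifact (table, profile, report or summary list).
#' @export
run_pipeline <- function(subcommand, input = NULL, output = NULL,
                         preset = "chemostat-1", seed = 1L, noise_sd = NULL,
                         ...) {
  subcommand <- match.arg(subcommand,
                          c("generate", "rates", "balances", "fit-f0",
                            "report"))
  get_table <- function()
    if (is.null(input)) generate_dataset(preset, seed, noise_sd)
    else read_timeseries(input)
  art <- switch(subcommand,
    "generate" = generate_dataset(preset, seed, noise_sd, output = output),
    "rates" = {
      prof <- estimate_rates(get_table(), ...)
      if (!is.null(output))
        utils::write.csv(prof, output, row.names = FALSE)
      prof
    },
    "balances" = {
      rep <- close_balances(get_table(), ...)
      if (!is.null(output))
        jsonlite::write_json(rep[c("carbon_recovery", "redox_recovery",
                                   "paa_recovery", "ohpaa_share_of_paa",
                                   "toc_share")],
                             output, auto_unbox = TRUE, digits = NA)
      rep
    },
    "fit-f0" = {
      p <- load_preset(preset)
      tab <- get_table()
      prof <- estimate_rates(tab)
      obs <- prof[seq(1, nrow(prof), length.out = 31), c("time", "qp")]
      fit <- fit_f0(obs, p$config, p$producer, p$nonproducer, ...)
      if (!is.null(output))
        jsonlite::write_json(fit[c("f0", "delta", "objective")], output,
                             auto_unbox = TRUE, digits = NA)
      fit
    },
    "report" = degeneration_report(preset, seed, noise_sd, output = output))
  invisible(art)
}

#' Full degeneration report for one scenario
#'
#' Chains generation, rate estimation, balance closure and f0 inference on
#' a preset and summarises the scenario in a single list: peak q_p and its
#' timing, fold-decline to 500 h, generations elapsed at the 10-fold
#' decline point, balance recoveries, and the inferred non-producer
#' fraction.
#'
#' @inheritParams generate_dataset
#' @param output optional JSON path.
#' @return Named list (JSON-ready summary).
#' @export
degeneration_report <- function(preset = "chemostat-1", seed = 1L,
                                noise_sd = NULL, output = NULL) {
  p <- load_preset(preset)
  tab <- generate_dataset(preset, seed, noise_sd)
  md <- attr(tab, "metadata")
  pk <- qp_peak(tab)
  prof_sp <- estimate_rates(tab, method = "spline")
  t_sw <- md$t_switch
  fold <- tryCatch(fold_decline(tab), error = function(e) NA_real_)
  i_pk <- which.max(prof_sp$qp)
  below <- which(prof_sp$qp < prof_sp$qp[i_pk] / 10 &
                 seq_along(prof_sp$qp) > i_pk)
  gen10 <- if (length(below))
    generations(prof_sp$time[below[1]] - t_sw, md$D) else NA_real_
  bal <- close_balances(tab)
  prof <- estimate_rates(tab)
  obs <- prof[seq(1, nrow(prof), length.out = 31), c("time", "qp")]
  fit <- fit_f0(obs, p$config, p$producer, p$nonproducer)
  out <- list(preset = preset, seed = as.integer(seed),
              version = .pkg_version(), config_hash = .config_hash(p),
              qp_peak = pk$qp_max, t_peak_h = pk$t_max,
              fold_decline_500h = fold,
              generations_to_10fold = gen10,
              carbon_recovery_pct = bal$carbon_recovery,
              redox_recovery_pct = bal$redox_recovery,
              paa_recovery_pct = bal$paa_recovery,
              ohpaa_share_of_paa_pct = bal$ohpaa_share_of_paa,
              f0_hat = fit$f0)
  if (!is.null(output))
    jsonlite::write_json(out, output, auto_unbox = TRUE, digits = NA)
  out
}
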