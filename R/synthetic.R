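# Measurement-like datasets from simulator trajectories, and the
# interchange CSV dialect (comma-separated, period decimal, `#`-prefixed
# metadata header lines).

# run code with a private, restored RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.observables <- c("biomass", "peng", "paa", "ethanol", "ohpaa", "toc",
                  "o2_uptake", "co2_evolution")
.mandatory_cols <- c("time", "biomass", "peng", "paa", "ethanol")

#' Measurement noise model
#'
#' Multiplicative Gaussian noise, truncated at zero, applied independently
#' per observable and sample point.
#'
#' @param relative_sd named numeric vector of relative standard deviations
#'   per observable (names among \code{biomass, peng, paa, ethanol, ohpaa,
#'   toc, o2_uptake, co2_evolution}); a single unnamed value applies to all.
#' @param seed integer RNG seed; identical seed and inputs give identical
#'   output.
#' @param sampling_interval sampling grid spacing, h.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(relative_sd = 0.03, seed = 1L,
                        sampling_interval = 12) {
  if (is.null(names(relative_sd)) && length(relative_sd) == 1)
    relative_sd <- stats::setNames(rep(relative_sd, length(.observables)),
                                   .observables)
  bad <- setdiff(names(relative_sd), .observables)
  if (length(bad))
    stop("noise_model: unknown observable(s) ", paste(bad, collapse = ", "))
  if (any(relative_sd < 0)) stop("noise_model: relative_sd must be >= 0")
  if (sampling_interval <= 0)
    stop("noise_model: sampling_interval must be > 0")
  structure(list(relative_sd = relative_sd, seed = as.integer(seed),
                 sampling_interval = sampling_interval),
            class = "noise_model")
}

#' Construct / validate a concentration time-series table
#'
#' @param df data.frame with columns \code{time} (h), \code{biomass}
#'   (g DW/L), \code{peng} (mmol/L), \code{paa} (mmol/L), \code{ethanol}
#'   (Cmol/L) and optionally \code{ohpaa} (mmol/L), \code{toc} (Cmol/L),
#'   \code{o2_uptake}, \code{co2_evolution} (mmol/L/h).
#' @param metadata named list; must contain \code{D} (> 0) and usually the
#'   feed composition, \code{gdw_per_cmol} and \code{t_switch}.
#' @return The validated data.frame with class \code{timeseries_table} and
#'   attribute \code{metadata}.
#' @export
timeseries_table <- function(df, metadata = list()) {
  miss <- setdiff(.mandatory_cols, names(df))
  if (length(miss))
    stop("timeseries_table: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("timeseries_table: empty table")
  if (any(diff(df$time) <= 0))
    stop("timeseries_table: time must be strictly increasing")
  vals <- df[setdiff(names(df), "time")]
  if (any(vapply(vals, function(v) any(v < 0), logical(1))))
    stop("timeseries_table: negative concentrations present")
  if (!is.null(metadata$D) && metadata$D <= 0)
    stop("timeseries_table: metadata D must be > 0")
  structure(df, metadata = metadata,
            class = c("timeseries_table", "data.frame"))
}

#' Sample a simulation into a measurement-like table
#'
#' Evaluates the trajectory on a regular sampling grid, converts biomass to
#' g DW/L, and applies the multiplicative noise model (values are truncated
#' at zero, a negligible bias at the default 3\% noise).
#'
#' @param sim a \code{culture_sim} from \code{\link{simulate_culture}}.
#' @param noise a \code{\link{noise_model}}; use \code{relative_sd = 0} for
#'   noise-free sampling.
#' @return A \code{\link{timeseries_table}}.
#' @export
sample_timeseries <- function(sim, noise = noise_model()) {
  stopifnot(inherits(sim, "culture_sim"), inherits(noise, "noise_model"))
  if (length(sim$times) < 2) stop("sample_timeseries: empty trajectory")
  tmax <- max(sim$times)
  if (noise$sampling_interval > tmax)
    stop("sample_timeseries: sampling interval exceeds the horizon")
  grid <- seq(0, tmax, by = noise$sampling_interval)
  ip <- function(y) stats::approx(sim$times, y, xout = grid)$y
  cfg <- sim$config
  df <- data.frame(
    time = grid,
    biomass = ip(sim$states[, "x_p"] + sim$states[, "x_np"]) *
      cfg$gdw_per_cmol,
    peng = ip(sim$states[, "p"]),
    paa = ip(sim$states[, "paa"]),
    ethanol = ip(sim$states[, "s"]),
    ohpaa = ip(sim$states[, "ohpaa"]),
    toc = ip(sim$states[, "toc"]),
    o2_uptake = ip(sim$rates$our),
    co2_evolution = ip(sim$rates$cer))
  df <- .with_seed(noise$seed, {
    for (obs in intersect(names(noise$relative_sd), names(df))) {
      sdr <- noise$relative_sd[[obs]]
      if (sdr > 0)
        df[[obs]] <- pmax(df[[obs]] *
                            (1 + stats::rnorm(nrow(df), 0, sdr)), 0)
    }
    df
  })
  timeseries_table(df, metadata = list(
    D = cfg$D, feed_ethanol = cfg$feed_ethanol, feed_paa = cfg$feed_paa,
    gdw_per_cmol = cfg$gdw_per_cmol, t_switch = sim$t_switch,
    toc_fraction = cfg$toc_fraction, seed = noise$seed,
    sampling_interval = noise$sampling_interval))
}

# metadata key <-> header-line naming
.meta_keys <- c(D = "D_h-1", feed_ethanol = "feed_ethanol_cmol_l",
                feed_paa = "feed_paa_mmol_l", gdw_per_cmol = "gdw_per_cmol",
                t_switch = "t_switch_h", toc_fraction = "toc_fraction",
                seed = "seed", sampling_interval = "sampling_interval_h")

#' Write / read the interchange CSV
#'
#' Comma-separated, period decimal point, with metadata in `#`-prefixed
#' header lines (e.g. \code{# D_h-1=0.03}). Numeric values are written with
#' 10 significant digits so a write/read round trip is lossless to that
#' precision. Files using locale-style decimal commas are rejected with a
#' parse error rather than silently misread.
#'
#' @param table a \code{\link{timeseries_table}}.
#' @param path file path.
#' @return \code{write_timeseries} returns \code{path} invisibly;
#'   \code{read_timeseries} returns a \code{\link{timeseries_table}}.
#' @export
write_timeseries <- function(table, path) {
  stopifnot(inherits(table, "timeseries_table"))
  md <- attr(table, "metadata")
  hdr <- vapply(names(md), function(k) {
    key <- if (k %in% names(.meta_keys)) .meta_keys[[k]] else k
    sprintf("# %s=%s", key, format(md[[k]], digits = 12))
  }, character(1))
  body <- vapply(seq_len(nrow(table)), function(i)
    paste(sprintf("%.10g", as.numeric(table[i, ])), collapse = ","),
    character(1))
  writeLines(c(hdr, paste(names(table), collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  md <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    canon <- names(.meta_keys)[match(key, .meta_keys)]
    if (is.na(canon)) canon <- key
    num <- suppressWarnings(as.numeric(val))
    md[[canon]] <- if (is.na(num)) val else num
  }
  body <- lines[!is_meta & nzchar(lines)]
  if (length(body) < 2) stop("read_timeseries: no data rows in ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header)))
    stop("read_timeseries: parse error at data row ",
         which(nf != length(header))[1],
         ": expected ", length(header), " comma-separated fields, found ",
         nf[nf != length(header)][1],
         " (locale-style decimal commas are not accepted)")
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (any(is.na(v)))
      stop("read_timeseries: parse error in column \"", header[j],
           "\": non-numeric value \"", df[[j]][is.na(v)][1], "\"")
    df[[j]] <- v
  }
  timeseries_table(df, metadata = md)
}

#' @export
print.timeseries_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Concentration time series: %d samples, t = %g .. %g h\n",
              nrow(x), min(x$time), max(x$time)))
  if (!is.null(md$D)) cat("  D =", md$D, "1/h\n")
  NextMethod()
}
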