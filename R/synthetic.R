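# Seeded synthetic titration generator.  Emulates the statistical
# structure of a TEMPOL titration: mono-exponentially decaying signals
# whose rate constants are linear in radical concentration, amplitudes a
# few percent of thermal signal for LLS-derived channels, and additive
# homoscedastic Gaussian noise.  Ground truth travels in a sidecar object
# (and sidecar JSON on disk), never inside the measurement table.

#' Specification of a synthetic titration
#'
#' @param rate0 ground-truth rate constant at zero radical concentration,
#'   s^-1.
#' @param relaxivity ground-truth relaxivity (slope) on the published
#'   per-mM scale, i.e. s^-1 per mmol/L (multiply by 1e3 for M^-1 s^-1);
#'   see [relaxivity_reference()].
#' @param concentrations_mM radical concentrations in mmol/L; the default
#'   is the titration ladder 0, 0.5, 1, 2, 3, 4, 6 mM.
#' @param n_delays delays per decay series (default 8).
#' @param delay_span delay range per series in units of the decay time
#'   `1/R`: log-spaced delays between `delay_span[1]/R` and
#'   `delay_span[2]/R`, so every series covers the same decay extent
#'   regardless of rate.
#' @param amplitude initial amplitude as a fraction of the thermal signal.
#'   Default by channel: 1.0 for longitudinal, 0.05 for the single-SLIC
#'   (`SQ`) LLS channel, 0.10 for poly-SLIC (`DQ`) conversion yields.
#' @param noise Gaussian noise standard deviation relative to the series'
#'   initial amplitude (default 0.01).
#' @param seed integer seed recorded with the dataset.
#' @param compound,group,channel,variant labels (see [decay_series()]).
#' @return Object of class `titration_spec`.
#' @export
titration_spec <- function(rate0, relaxivity,
                           concentrations_mM = c(0, 0.5, 1, 2, 3, 4, 6),
                           n_delays = 8L, delay_span = c(0.1, 3),
                           amplitude = NULL, noise = 0.01, seed = 1L,
                           compound = "", group = "",
                           channel = c("longitudinal", "LLS"),
                           variant = "") {
  channel <- match.arg(channel)
  if (any(concentrations_mM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (noise < 0) stop("'noise' must be >= 0", call. = FALSE)
  if (!is.finite(rate0) || rate0 <= 0) {
    stop("'rate0' must be a positive rate in s^-1", call. = FALSE)
  }
  if (is.null(amplitude)) {
    amplitude <- if (channel == "longitudinal") 1.0 else
      if (identical(variant, "DQ")) 0.10 else 0.05
  }
  structure(list(rate0 = rate0, relaxivity = relaxivity,
                 concentrations_mM = as.numeric(concentrations_mM),
                 n_delays = as.integer(n_delays),
                 delay_span = as.numeric(delay_span),
                 amplitude = amplitude, noise = noise,
                 seed = as.integer(seed),
                 compound = compound, group = group, channel = channel,
                 variant = variant),
            class = "titration_spec")
}

#' Generate a synthetic titration dataset
#'
#' For every concentration `c` (in mM, matching the per-mM relaxivity
#' scale) the decay series is `A * exp(-(R0 + r * c) * tau) + eps` with
#' `eps ~ N(0, (noise * A)^2)`, evaluated on the spec's log-spaced delay
#' grid.  Deterministic for a fixed seed.
#'
#' @param spec a [titration_spec()].
#' @return Object of class `titration`: list with `series` (list of
#'   [decay_series()]), `spec`, and `ground_truth` (the generating `rate0`
#'   and `relaxivity`, per-concentration rates, and the seed).
#' @export
generate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  set.seed(spec$seed)
  conc_M <- spec$concentrations_mM * 1e-3
  series <- vector("list", length(conc_M))
  rates <- numeric(length(conc_M))
  for (k in seq_along(conc_M)) {
    R <- spec$rate0 + spec$relaxivity * spec$concentrations_mM[k]
    rates[k] <- R
    delays <- exp(seq(log(spec$delay_span[1L] / R),
                      log(spec$delay_span[2L] / R),
                      length.out = spec$n_delays))
    amp <- spec$amplitude * exp(-R * delays)
    if (spec$noise > 0) {
      amp <- amp + stats::rnorm(length(amp),
                                sd = spec$noise * spec$amplitude)
    }
    series[[k]] <- decay_series(delays, amp, conc_M[k],
                                channel = spec$channel,
                                compound = spec$compound,
                                group = spec$group, variant = spec$variant)
  }
  structure(list(series = series, spec = spec,
                 ground_truth = list(rate0 = spec$rate0,
                                     relaxivity = spec$relaxivity,
                                     rates = rates, seed = spec$seed)),
            class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("Synthetic titration: %s %s [%s%s], %d concentrations",
                     " x %d delays, noise %g, seed %d\n"),
              s$compound, s$group, s$channel,
              if (nzchar(s$variant)) paste0("/", s$variant) else "",
              length(s$concentrations_mM), s$n_delays, s$noise, s$seed))
  invisible(x)
}

#' Fixture titrations for every published reference cell
#'
#' Builds one synthetic titration per (compound, group, channel, variant)
#' combination that has published values in [relaxivity_reference()]:
#' 10 longitudinal datasets, 6 SQ LLS datasets and 9 DQ LLS datasets.
#'
#' @param seed base seed; each dataset uses `seed + row index`.
#' @param noise relative noise level passed to every spec.
#' @return Named list of `titration` objects.
#' @export
titration_fixtures <- function(seed = 1L, noise = 0.01) {
  ref <- relaxivity_reference()
  out <- vector("list", nrow(ref))
  names(out) <- paste(ref$compound, ref$group, ref$channel,
                      ifelse(nzchar(ref$variant), ref$variant, "-"),
                      sep = ".")
  for (i in seq_len(nrow(ref))) {
    sp <- titration_spec(rate0 = ref$rate0[i],
                         relaxivity = ref$relaxivity[i],
                         noise = noise, seed = seed + i,
                         compound = ref$compound[i], group = ref$group[i],
                         channel = ref$channel[i], variant = ref$variant[i])
    out[[i]] <- generate_titration(sp)
  }
  out
}

#' Fit a whole titration: decays, then the relaxivity regression
#'
#' Fits every decay series mono-exponentially, then regresses the fitted
#' rate constants on concentration.
#'
#' @param titration a `titration` object (from [generate_titration()] or
#'   [read_titration_csv()]), or a bare list of [decay_series()].
#' @param weighted weight the relaxivity regression by the decay-rate
#'   standard errors?  Because the delay grids are anchored to `1/R`, every
#'   series in a titration has the same *relative* rate uncertainty; the
#'   pipeline therefore pools the per-series relative standard errors
#'   (`se_i = R_i * sqrt(mean((se/R)^2))`) before weighting, which removes
#'   the noise of individual variance estimates and keeps the regression
#'   standard errors calibrated.
#' @return Object of class `titration_fit`: list with `decays` (list of
#'   [fit_decay()] results), `rates` (data frame), and `relaxivity`
#'   (a [fit_relaxivity()] result).
#' @export
fit_titration <- function(titration, weighted = FALSE) {
  series <- if (inherits(titration, "titration")) titration$series else
    titration
  decays <- lapply(series, fit_decay)
  rates <- data.frame(
    conc_M = vapply(series, function(s) attr(s, "concentration_M"),
                    numeric(1L)),
    rate = vapply(decays, function(f) f$rate, numeric(1L)),
    rate_se = vapply(decays, function(f) f$rate_se, numeric(1L)))
  first <- series[[1L]]
  se_use <- rates$rate_se
  if (weighted && all(is.finite(rates$rate_se))) {
    rel <- sqrt(mean((rates$rate_se / rates$rate)^2))
    se_use <- rates$rate * rel
  }
  rf <- fit_relaxivity(rates$conc_M, rates$rate, conc_unit = "M",
                       rate_se = se_use, weighted = weighted,
                       channel = attr(first, "channel"),
                       compound = attr(first, "compound"),
                       group = attr(first, "group"),
                       variant = attr(first, "variant"))
  structure(list(decays = decays, rates = rates, relaxivity = rf),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit over %d series:\n", nrow(x$rates)))
  print(x$relaxivity)
  invisible(x)
}

#' Write titration measurements as CSV
#'
#' Measurement rows only (labels, concentration with explicit unit, delay,
#' amplitude); the generating ground truth, if present, goes to a JSON
#' sidecar via [write_ground_truth()] so that fitting code can never read
#' the answer from the measurement table.
#'
#' @param titration a `titration` or list of [decay_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(titration, path) {
  series <- if (inherits(titration, "titration")) titration$series else
    titration
  rows <- lapply(series, function(s) {
    data.frame(compound = attr(s, "compound"), group = attr(s, "group"),
               channel = attr(s, "channel"), variant = attr(s, "variant"),
               concentration = attr(s, "concentration_M"),
               concentration_unit = "M",
               delay_s = s$delay_s, amplitude = s$amplitude)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param titration a `titration` with ground truth.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(titration, path) {
  stopifnot(inherits(titration, "titration"))
  jsonlite::write_json(titration$ground_truth, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a titration measurement CSV
#'
#' Validates the measurement schema (including the explicit concentration
#' unit column) and reassembles per-concentration decay series.
#'
#' @param path CSV path written by [write_titration_csv()] or of the same
#'   shape.
#' @return A `titration` object (without spec or ground truth).
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "group", "channel", "variant", "concentration",
            "concentration_unit", "delay_s", "amplitude")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("titration CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(d$concentration_unit %in% c("M", "mM"))) {
    stop("concentration_unit must be 'M' or 'mM'", call. = FALSE)
  }
  d$conc_M <- d$concentration * ifelse(d$concentration_unit == "mM", 1e-3, 1)
  d$variant[is.na(d$variant)] <- ""
  key <- paste(d$compound, d$group, d$channel, d$variant, d$conc_M)
  series <- lapply(split(d, factor(key, levels = unique(key))), function(g) {
    o <- order(g$delay_s)
    decay_series(g$delay_s[o], g$amplitude[o], g$conc_M[1L],
                 channel = g$channel[1L], compound = g$compound[1L],
                 group = g$group[1L], variant = g$variant[1L])
  })
  names(series) <- NULL
  structure(list(series = series, spec = NULL, ground_truth = NULL),
            class = "titration")
}
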