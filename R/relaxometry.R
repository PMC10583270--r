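# Relaxometry: mono-exponential decay fits, relaxivity regressions, and
# relaxivity-ratio (kappa) summaries for paramagnetic titrations.

#' A single signal-decay series
#'
#' Amplitudes of an LLS-derived or longitudinal signal measured at
#' increasing relaxation delays, for one sample (one radical
#' concentration).
#'
#' @param delays_s relaxation delays in seconds, strictly increasing,
#'   at least 4 points.
#' @param amplitudes signal amplitudes (arbitrary units), same length.
#' @param concentration_M radical concentration in mol/L.
#' @param channel `"longitudinal"` or `"LLS"`.
#' @param compound,group free-text labels (compound and CH2-group).
#' @param variant optional excitation variant label (e.g. `"SQ"`, `"DQ"`).
#' @return Object of class `decay_series` (a data frame of `delay_s`,
#'   `amplitude` with metadata attributes).
#' @export
decay_series <- function(delays_s, amplitudes, concentration_M,
                         channel = c("longitudinal", "LLS"),
                         compound = "", group = "", variant = "") {
  channel <- match.arg(channel)
  delays_s <- as.numeric(delays_s); amplitudes <- as.numeric(amplitudes)
  if (length(delays_s) < 4L) {
    stop("a decay series needs at least 4 points", call. = FALSE)
  }
  if (length(amplitudes) != length(delays_s)) {
    stop("'delays_s' and 'amplitudes' lengths differ", call. = FALSE)
  }
  if (any(diff(delays_s) <= 0)) {
    stop("'delays_s' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(delays_s)) || any(!is.finite(amplitudes))) {
    stop("delays and amplitudes must be finite", call. = FALSE)
  }
  if (!is.finite(concentration_M) || concentration_M < 0) {
    stop("'concentration_M' must be a non-negative mol/L value",
         call. = FALSE)
  }
  structure(data.frame(delay_s = delays_s, amplitude = amplitudes),
            concentration_M = concentration_M, channel = channel,
            compound = compound, group = group, variant = variant,
            class = c("decay_series", "data.frame"))
}

#' Fit a mono-exponential decay
#'
#' Nonlinear least-squares fit of `A * exp(-R * t)` (optionally plus a
#' constant baseline) by Levenberg-Marquardt, started from the log-linear
#' regression of the positive amplitudes.  Returns the rate constant and
#' amplitude with their asymptotic standard errors.
#'
#' @param series a [decay_series()] (any data frame with `delay_s` and
#'   `amplitude` columns works).
#' @param baseline include a constant offset term?  Off by default: the
#'   modelled signals decay to zero.
#' @param model `"mono"` (default, the published analysis convention) or
#'   `"biexponential"`, a diagnostic option for delocalized LLS signals
#'   whose long-lived terms may decay at different rates; the reported
#'   `rate` is then the slower component.
#' @return Object of class `decay_fit`.
#' @export
fit_decay <- function(series, baseline = FALSE,
                      model = c("mono", "biexponential")) {
  model <- match.arg(model)
  d <- as.data.frame(series)[c("delay_s", "amplitude")]
  if (all(d$amplitude <= 0)) {
    stop("all amplitudes are non-positive; nothing to fit", call. = FALSE)
  }
  pos <- d$amplitude > 0
  ll <- stats::lm(log(amplitude) ~ delay_s, data = d[pos, , drop = FALSE])
  start <- list(A = exp(stats::coef(ll)[[1L]]), R = -stats::coef(ll)[[2L]])
  if (!is.finite(start$R) || start$R <= 0) start$R <- 1 / max(d$delay_s)
  if (model == "biexponential") {
    fml <- amplitude ~ A * exp(-R * delay_s) + A2 * exp(-R2 * delay_s)
    start <- list(A = 0.7 * start$A, R = start$R,
                  A2 = 0.3 * start$A, R2 = 3 * start$R)
  } else {
    fml <- amplitude ~ A * exp(-R * delay_s)
  }
  if (baseline) {
    fml <- stats::update(fml, . ~ . + C)
    start$C <- 0
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("decay fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) {
                   stats::setNames(rep(NA_real_, length(cf)), names(cf))
                 })
  slow <- "R"
  if (model == "biexponential" && cf[["R2"]] < cf[["R"]]) slow <- "R2"
  amp_of <- c(R = "A", R2 = "A2")[[slow]]
  structure(
    list(rate = cf[[slow]], amplitude = cf[[amp_of]],
         baseline = if (baseline) cf[["C"]] else 0,
         rate_se = se[[slow]], amplitude_se = se[[amp_of]],
         sigma = stats::sigma(fit), fit = fit, series = series,
         baseline_term = baseline, model = model),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential decay fit: R = %.5g (SE %.2g) s^-1, A = %.5g (SE %.2g)\n",
              x$rate, x$rate_se, x$amplitude, x$amplitude_se))
  if (x$baseline_term) cat(sprintf("  baseline C = %.4g\n", x$baseline))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) stats::coef(object$fit)

#' @export
summary.decay_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(delay_s = newdata)
  as.numeric(stats::predict(object$fit, newdata = newdata))
}

#' @export
residuals.decay_fit <- function(object, ...) stats::residuals(object$fit)

#' Fit a relaxivity (rate versus concentration regression)
#'
#' Linear model `R(c) = R(0) + r * c` fitted by ordinary least squares
#' (optionally weighted by the inverse squared rate standard errors).
#' The slope is the relaxivity in M^-1 s^-1 and the intercept the rate
#' constant at zero radical concentration.  Concentration units must be
#' declared; values are converted to mol/L before the regression so the
#' reported relaxivity is always in M^-1 s^-1.  Because published
#' compilations of TEMPOL proton relaxivities are printed on the per-mM
#' scale, the fit also carries `slope_per_mM = slope / 1e3` (s^-1 per
#' mmol/L) for direct comparison.
#'
#' @param concentration radical concentrations.
#' @param rate fitted relaxation rate constants, s^-1.
#' @param conc_unit `"M"` or `"mM"`; required, no default guessing beyond
#'   these two explicit choices.
#' @param rate_se optional standard errors of the rates.
#' @param weighted if `TRUE`, weight the regression by `1 / rate_se^2` and
#'   treat the supplied standard errors as known measurement variances:
#'   coefficient standard errors are then taken from `(X' W X)^-1`
#'   (fixed-effect meta-regression convention) instead of being rescaled
#'   by the residual variance, which keeps them calibrated when the
#'   per-point uncertainties vary systematically across the titration.
#' @param channel,compound,group,variant labels carried into the result.
#' @return Object of class `relaxivity_fit`.
#' @export
fit_relaxivity <- function(concentration, rate, conc_unit = c("M", "mM"),
                           rate_se = NULL, weighted = FALSE,
                           channel = "", compound = "", group = "",
                           variant = "") {
  conc_unit <- match.arg(conc_unit)
  conc_M <- as.numeric(concentration) * if (conc_unit == "mM") 1e-3 else 1
  rate <- as.numeric(rate)
  if (length(conc_M) != length(rate)) {
    stop("'concentration' and 'rate' lengths differ", call. = FALSE)
  }
  if (length(unique(conc_M)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  if (weighted) {
    if (is.null(rate_se)) stop("weighted fit needs 'rate_se'", call. = FALSE)
    w <- 1 / rate_se^2
    lm_fit <- stats::lm(rate ~ conc_M, weights = w)
    cf <- stats::coef(lm_fit)
    X <- cbind(1, conc_M)
    se <- sqrt(diag(solve(crossprod(X, w * X))))
  } else {
    lm_fit <- stats::lm(rate ~ conc_M)
    cf <- stats::coef(lm_fit)
    # closed-form OLS covariance (avoids summary.lm's perfect-fit warning
    # on noiseless oracles)
    X <- cbind(1, conc_M)
    s2 <- sum(stats::residuals(lm_fit)^2) / (length(rate) - 2L)
    se <- sqrt(diag(s2 * solve(crossprod(X))))
  }
  structure(
    list(intercept = cf[[1L]], slope = cf[[2L]],
         intercept_se = se[[1L]], slope_se = se[[2L]],
         slope_per_mM = cf[[2L]] / 1e3, slope_per_mM_se = se[[2L]] / 1e3,
         weighted = weighted, fit = lm_fit,
         data = data.frame(conc_M = conc_M, rate = rate,
                           rate_se = if (is.null(rate_se)) NA_real_ else
                             rate_se),
         channel = channel, compound = compound, group = group,
         variant = variant),
    class = "relaxivity_fit")
}

#' @export
print.relaxivity_fit <- function(x, ...) {
  lab <- paste(Filter(nzchar, c(x$compound, x$group, x$channel, x$variant)),
               collapse = " / ")
  if (nzchar(lab)) cat(lab, "\n")
  cat(sprintf("  R(0) = %s s^-1,  r = %s M^-1 s^-1 (= %s per mM)%s\n",
              format_se(x$intercept, x$intercept_se),
              format_se(x$slope, x$slope_se),
              format_se(x$slope_per_mM, x$slope_per_mM_se),
              if (x$weighted) "  (weighted)" else ""))
  invisible(x)
}

#' @export
coef.relaxivity_fit <- function(object, ...) {
  c(`R(0)` = object$intercept, r = object$slope)
}

#' @export
summary.relaxivity_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.relaxivity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(conc_M = newdata)
  object$intercept + object$slope * newdata$conc_M
}

#' Relaxivity-ratio summary per compound
#'
#' Computes per-compound mean relaxivities of the longitudinal and LLS
#' channels and their ratio `<kappa> = <r_LLS> / <r_1>`, the headline
#' measure of how much weaker paramagnetic relaxation enhancement is for
#' long-lived order than for longitudinal magnetization.  The default
#' policy pools every available LLS relaxivity entry (all CH2 groups, SQ
#' and DQ variants alike) and every longitudinal entry of the compound.
#'
#' @param relaxivities data frame with columns `compound`, `group`,
#'   `channel` (`"longitudinal"` / `"LLS"`), `variant`, and `relaxivity`
#'   (M^-1 s^-1); see [relaxivity_reference()] for the expected shape, or
#'   supply a list of [fit_relaxivity()] results via `fits`.
#' @param fits alternative input: list of `relaxivity_fit` objects.
#' @param policy averaging policy; only `"pooled"` is implemented.
#' @return Object of class `kappa_summary`: data frame with one row per
#'   compound (`mean_r1`, `mean_rlls`, `kappa`, entry counts), with the
#'   per-group ratios in attribute `"per_group"` and the policy recorded
#'   in attribute `"policy"`.
#' @export
kappa_summary <- function(relaxivities = NULL, fits = NULL,
                          policy = "pooled") {
  policy <- match.arg(policy, "pooled")
  if (is.null(relaxivities)) {
    if (is.null(fits)) stop("supply 'relaxivities' or 'fits'", call. = FALSE)
    relaxivities <- do.call(rbind, lapply(fits, function(f) {
      data.frame(compound = f$compound, group = f$group,
                 channel = f$channel, variant = f$variant,
                 relaxivity = f$slope)
    }))
  }
  need <- c("compound", "channel", "relaxivity")
  if (!all(need %in% names(relaxivities))) {
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  compounds <- unique(relaxivities$compound)
  rows <- lapply(compounds, function(cm) {
    sub <- relaxivities[relaxivities$compound == cm, , drop = FALSE]
    r1 <- sub$relaxivity[sub$channel == "longitudinal"]
    rl <- sub$relaxivity[sub$channel == "LLS"]
    if (!length(r1) || !length(rl)) {
      stop("compound ", cm, " lacks one of the two channels", call. = FALSE)
    }
    if (mean(r1) == 0) {
      stop("zero mean longitudinal relaxivity for compound ", cm,
           ": kappa undefined", call. = FALSE)
    }
    data.frame(compound = cm, mean_r1 = mean(r1), mean_rlls = mean(rl),
               kappa = mean(rl) / mean(r1),
               n_r1 = length(r1), n_rlls = length(rl))
  })
  out <- do.call(rbind, rows)
  per_group <- NULL
  if ("group" %in% names(relaxivities)) {
    lls <- relaxivities[relaxivities$channel == "LLS", , drop = FALSE]
    lon <- relaxivities[relaxivities$channel == "longitudinal", ,
                        drop = FALSE]
    key <- function(d) paste(d$compound, d$group)
    idx <- match(key(lls), key(lon))
    ok <- !is.na(idx)
    if (any(ok)) {
      per_group <- data.frame(
        compound = lls$compound[ok], group = lls$group[ok],
        variant = if ("variant" %in% names(lls)) lls$variant[ok] else "",
        kappa = lls$relaxivity[ok] / lon$relaxivity[idx[ok]])
    }
  }
  structure(out, policy = policy, per_group = per_group,
            class = c("kappa_summary", "data.frame"))
}

#' @export
print.kappa_summary <- function(x, digits = 2, ...) {
  cat("Relaxivity ratios <kappa> = <r_LLS>/<r_1> (policy:",
      attr(x, "policy"), "entries)\n")
  y <- as.data.frame(x)
  y$kappa <- round(y$kappa, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Format a value with its standard error in parentheses
#'
#' Compact uncertainty notation: the standard error, rounded to one
#' significant digit, is printed in parentheses in units of the last
#' displayed digit of the value, e.g. `format_se(0.596, 0.006)` is
#' `"0.596(6)"`.
#'
#' @param value numeric value.
#' @param se its standard error (`NA` gives a plain format).
#' @return Character scalar.
#' @export
format_se <- function(value, se) {
  if (is.na(se) || !is.finite(se) || se < 1e-12) return(format(value))
  se1 <- signif(se, 1)
  dec <- max(0L, -floor(log10(se1)))
  paren <- round(se1 * 10^dec)
  sprintf("%.*f(%d)", dec, round(value, dec), paren)
}

#' Parse the `value(se)` notation back into numbers
#'
#' @param x character vector like `"0.596(6)"`; `"-"`/`"–"` and empty
#'   strings give `NA`.
#' @return Data frame with columns `value` and `se`.
#' @export
parse_se <- function(x) {
  out <- data.frame(value = rep(NA_real_, length(x)),
                    se = rep(NA_real_, length(x)))
  for (k in seq_along(x)) {
    s <- trimws(x[k])
    if (!nzchar(s) || s %in% c("-", "–")) next
    m <- regmatches(s, regexec("^(-?[0-9]*\\.?[0-9]+)\\(([0-9]+)\\)$", s))[[1L]]
    if (length(m) == 3L) {
      v <- as.numeric(m[2L])
      dec <- if (grepl("\\.", m[2L])) nchar(sub(".*\\.", "", m[2L])) else 0L
      out$value[k] <- v
      out$se[k] <- as.numeric(m[3L]) * 10^(-dec)
    } else {
      out$value[k] <- suppressWarnings(as.numeric(s))
    }
  }
  out
}

#' Tabulate relaxivity fits in compact notation
#'
#' One row per compound/group with `R(0)` and relaxivity per channel in
#' `value(se)` notation; cells without data show an en dash.  Relaxivities
#' are formatted on the published per-mM scale so rows can be compared to
#' [relaxivity_reference()] directly.
#'
#' @param fits list of [fit_relaxivity()] results.
#' @return Character data frame with one formatted column per
#'   channel/variant quantity.
#' @export
summarize_table <- function(fits) {
  meta <- lapply(fits, function(f) {
    data.frame(compound = f$compound, group = f$group, channel = f$channel,
               variant = f$variant,
               R0 = format_se(f$intercept, f$intercept_se),
               r = format_se(f$slope_per_mM, f$slope_per_mM_se))
  })
  long <- do.call(rbind, meta)
  keys <- unique(long[c("compound", "group")])
  col_of <- function(channel, variant) {
    if (channel == "longitudinal") c("R1(0)", "r1")
    else c(sprintf("RLLS(0) (%s)", variant), sprintf("rLLS (%s)", variant))
  }
  cols <- unique(unlist(lapply(seq_len(nrow(long)), function(i) {
    col_of(long$channel[i], long$variant[i])
  })))
  out <- data.frame(compound = keys$compound, group = keys$group,
                    check.names = FALSE)
  for (cl in cols) out[[cl]] <- "–"
  for (i in seq_len(nrow(long))) {
    k <- which(keys$compound == long$compound[i] &
                 keys$group == long$group[i])
    cls <- col_of(long$channel[i], long$variant[i])
    out[k, cls[1L]] <- long$R0[i]
    out[k, cls[2L]] <- long$r[i]
  }
  out
}
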