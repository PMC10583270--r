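test_that("decay series validate their inputs", {
  expect_error(decay_series(c(1, 2, 3), c(1, 1, 1), 0), "at least 4")
  expect_error(decay_series(c(1, 2, 2, 3), rep(1, 4), 0), "increasing")
  expect_error(decay_series(1:4, rep(1, 4), -1), "non-negative")
})

test_that("noiseless mono-exponential decays are recovered exactly", {
  tau <- seq(0.5, 20, length.out = 8)
  s <- decay_series(tau, 1 * exp(-0.144 * tau), 0)
  f <- fit_decay(s)
  expect_lt(abs(f$rate - 0.144), 1e-10)
  expect_lt(abs(f$amplitude - 1), 1e-10)
})

test_that("the fitted rate matches the two-point closed form on exact data", {
  tau <- c(1, 3, 6, 10)
  amp <- 0.8 * exp(-0.31 * tau)
  f <- fit_decay(decay_series(tau, amp, 0))
  closed <- log(amp[1] / amp[2]) / (tau[2] - tau[1])
  expect_lt(abs(f$rate - closed), 1e-9)
})

test_that("noisy decays are recovered within their standard errors", {
  set.seed(20)
  tau <- exp(seq(log(0.1 / 0.144), log(3 / 0.144), length.out = 8))
  amp <- exp(-0.144 * tau) + rnorm(8, sd = 0.01)
  f <- fit_decay(decay_series(tau, amp, 0))
  expect_lt(abs(f$rate - 0.144), 3 * f$rate_se)
  expect_gt(f$rate_se, 0)
})

test_that("rates are invariant under amplitude rescaling (kappa safety)", {
  tau <- seq(0.2, 12, length.out = 9)
  amp <- 0.05 * exp(-0.2 * tau)
  f1 <- fit_decay(decay_series(tau, amp, 0))
  f2 <- fit_decay(decay_series(tau, 40 * amp, 0))
  expect_lt(abs(f1$rate - f2$rate), 1e-10)
})

test_that("the bi-exponential option resolves two rates, reporting the slower", {
  tau <- seq(0.2, 20, length.out = 12)
  amp <- 0.6 * exp(-0.1 * tau) + 0.4 * exp(-0.6 * tau)
  f <- fit_decay(decay_series(tau, amp, 0), model = "biexponential")
  expect_lt(abs(f$rate - 0.1), 1e-6)
  expect_setequal(names(coef(f)), c("A", "R", "A2", "R2"))
})

test_that("decay fitting reports failure modes explicitly", {
  expect_error(fit_decay(decay_series(1:4, c(-1, -2, -1, -3), 0)),
               "non-positive")
})

test_that("decay_fit behaves like a model object", {
  tau <- seq(0.5, 16, length.out = 8)
  s <- decay_series(tau, 2 * exp(-0.25 * tau), 0)
  f <- fit_decay(s)
  expect_named(coef(f), c("A", "R"))
  expect_equal(predict(f, c(0, 4)), 2 * exp(-0.25 * c(0, 4)),
               tolerance = 1e-8)
  expect_lt(max(abs(residuals(f))), 1e-8)
  expect_output(print(f), "Mono-exponential")
})

test_that("relaxivity regression reproduces an exact titration line", {
  conc <- c(0, 0.5, 1, 2, 3, 4, 6) * 1e-3
  rate <- 0.596 + 0.221 * conc
  f <- fit_relaxivity(conc, rate, conc_unit = "M")
  expect_lt(abs(f$slope - 0.221), 1e-8)
  expect_lt(abs(f$intercept - 0.596), 1e-8)
  expect_lt(f$slope_se, 1e-8)
  # flat line has zero slope
  f0 <- fit_relaxivity(conc, rep(0.3, 7), conc_unit = "M")
  expect_lt(abs(f0$slope), 1e-12)
})

test_that("concentration units are explicit and converted to mol/L", {
  rate <- 0.5 + 200 * c(0, 1e-3, 2e-3, 4e-3)
  f_M <- fit_relaxivity(c(0, 1e-3, 2e-3, 4e-3), rate, conc_unit = "M")
  f_mM <- fit_relaxivity(c(0, 1, 2, 4), rate, conc_unit = "mM")
  expect_equal(f_M$slope, f_mM$slope, tolerance = 1e-10)
  expect_equal(f_mM$slope_per_mM, f_mM$slope / 1e3)
  expect_error(fit_relaxivity(c(0, 1, 2), rate[1:3], conc_unit = "nM"))
})

test_that("OLS matches the textbook closed-form estimates", {
  set.seed(9)
  x <- c(0, 0.5, 1, 2, 3, 4, 6) * 1e-3
  y <- 0.4 + 150 * x + rnorm(7, sd = 0.01)
  f <- fit_relaxivity(x, y, conc_unit = "M")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icpt <- mean(y) - slope * mean(x)
  resid <- y - icpt - slope * x
  s2 <- sum(resid^2) / (length(x) - 2)
  expect_equal(f$slope, slope, tolerance = 1e-10)
  expect_equal(f$intercept, icpt, tolerance = 1e-10)
  expect_equal(f$slope_se, sqrt(s2 / sxx), tolerance = 1e-10)
})

test_that("weighted regression uses known-variance standard errors", {
  x <- c(0, 1e-3, 2e-3, 4e-3, 6e-3)
  y <- 0.3 + 100 * x
  se <- c(0.01, 0.01, 0.02, 0.03, 0.04)
  f <- fit_relaxivity(x, y, conc_unit = "M", rate_se = se, weighted = TRUE)
  w <- 1 / se^2
  xb <- sum(w * x) / sum(w)
  expect_equal(f$slope_se, sqrt(1 / sum(w * (x - xb)^2)), tolerance = 1e-10)
  expect_error(fit_relaxivity(x, y, conc_unit = "M", weighted = TRUE),
               "rate_se")
})

test_that("degenerate designs are rejected", {
  expect_error(fit_relaxivity(c(1e-3, 1e-3, 1e-3), c(1, 2, 3),
                              conc_unit = "M"), "distinct")
})

test_that("kappa summaries reproduce the published per-compound ratios", {
  ks <- kappa_summary(relaxivity_reference())
  k <- setNames(ks$kappa, ks$compound)
  expect_equal(round(k[["I"]], 2), 0.22)
  expect_equal(round(k[["II"]], 2), 0.23)
  expect_equal(round(k[["IV"]], 2), 0.32)
  # compound IV by hand: mean(0.050, 0.049) / mean(0.162, 0.151)
  expect_equal(k[["IV"]], mean(c(0.050, 0.049)) / mean(c(0.162, 0.151)),
               tolerance = 1e-12)
  expect_identical(attr(ks, "policy"), "pooled")
})

test_that("kappa equals one for identical channels and rejects zero rates", {
  d <- data.frame(compound = "Z", group = "g",
                  channel = c("longitudinal", "LLS"),
                  variant = c("", "DQ"), relaxivity = c(0.1, 0.1))
  expect_equal(kappa_summary(d)$kappa, 1)
  d0 <- transform(d, relaxivity = c(0, 0.1))
  expect_error(kappa_summary(d0), "undefined")
  expect_error(kappa_summary(d[d$channel == "LLS", , drop = FALSE]),
               "lacks")
})

test_that("value(se) formatting follows the compact table convention", {
  expect_identical(format_se(0.596, 0.006), "0.596(6)")
  expect_identical(format_se(0.33, 0.01), "0.33(1)")
  expect_identical(format_se(0.069, 0.007), "0.069(7)")
  p <- parse_se(c("0.596(6)", "0.33(1)", "–", ""))
  expect_equal(p$value, c(0.596, 0.33, NA, NA))
  expect_equal(p$se, c(0.006, 0.01, NA, NA))
})

test_that("summary tables round-trip and mark missing channels", {
  conc <- c(0, 1, 2, 4, 6)  # mM
  mk <- function(icpt, slope_mM, ...) {
    fit_relaxivity(conc, icpt + slope_mM * conc, conc_unit = "mM", ...)
  }
  fits <- list(
    mk(0.596, 0.221, channel = "longitudinal", compound = "I",
       group = "CH2(1)"),
    mk(0.144, 0.051, channel = "LLS", variant = "SQ", compound = "I",
       group = "CH2(1)"),
    mk(0.33, 0.120, channel = "longitudinal", compound = "III",
       group = "CH2(1)"))
  tab <- summarize_table(fits)
  expect_identical(tab[tab$compound == "I", "r1"], "0.221")
  expect_identical(tab[tab$compound == "III", "rLLS (SQ)"], "–")
  got <- parse_se(tab[tab$compound == "I", "rLLS (SQ)"])
  expect_equal(got$value, 0.051)
})
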