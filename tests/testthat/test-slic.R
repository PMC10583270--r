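test_that("zero-duration pulses excite and reconvert nothing", {
  sys <- sys_2pair()
  b <- lls_basis(sys)
  sig <- simulate_excitation(sys, slic_scheme("excitation", 1, tau = 0,
                                              lac_order = 2),
                             settings_coarse(), b)
  expect_lt(frob(sig), 1e-12)
  lt <- reconversion_coefficients(sys, slic_scheme("reconversion", 1,
                                                   tau = 0, lac_order = 2),
                                  b, settings_coarse())
  expect_equal(unname(lt), rep(0, 3))
})

test_that("trace projection recovers exact mixture coefficients", {
  sys <- sys_2pair()
  b <- lls_basis(sys)
  sigma <- 0.4 * (-b$terms[[1]]) + 0.07 * (-b$terms[[3]])
  dec <- lls_decompose(sigma, b)
  expect_equal(dec$lambda, c(0.4, 0, 0.07), tolerance = 1e-12)
  # a pure -P term has unit coefficient on itself only
  dec1 <- lls_decompose(-b$terms[[2]], b)
  expect_equal(dec1$lambda, c(0, 1, 0), tolerance = 1e-12)
  # reconstruction reproduces the projected operator
  expect_lt(frob(lls_reconstruct(dec, b) - sigma), 1e-10)
})

test_that("two-pair excitation obeys the four-spin structure constraints", {
  # every tested excitation scheme gives lambda_AA' = lambda_XX' and a
  # four-spin coefficient of -8/3 times the bilinear one (the excited state
  # is the singlet-singlet vs triplet-triplet imbalance; the magnitude 8/3
  # follows from the trace norms of the two operator types)
  sys <- sys_2pair()
  b <- lls_basis(sys)
  st <- prop_settings()  # default dt
  schemes <- list(
    slic_scheme("excitation", 1, tau = 0.35, lac_order = 2),
    slic_scheme("excitation", 2, tau = 0.69, lac_order = 2),
    slic_scheme("excitation", 1:2, tau = 0.5, lac_order = 1))
  for (sch in schemes) {
    dec <- lls_decompose(simulate_excitation(sys, sch, st, b), b)
    expect_lt(abs(dec$lambda[1] - dec$lambda[2]), 1e-6)
    expect_gt(abs(dec$lambda[1]), 0.05)  # meaningful transfer
    expect_lt(abs(dec$lambda[3] / dec$lambda[1] - (-8 / 3)), 1e-6)
  }
})

test_that("full-sequence amplitude equals the sum of coefficient products", {
  sys <- sys_2pair()
  b <- lls_basis(sys)
  st <- settings_mid()
  exc <- slic_scheme("excitation", 1:2, tau = 0.4, lac_order = 1)
  rec <- slic_scheme("reconversion", 1, tau = 0.3, lac_order = 2)
  dec <- lls_decompose(simulate_excitation(sys, exc, st, b), b)
  lt <- reconversion_coefficients(sys, rec, b, st)
  eff <- cycle_efficiency(sys, exc, rec, settings = st, basis = b)
  expect_lt(abs(attr(eff, "signed") - sum(dec$lambda * lt)), 1e-8)
})

test_that("a coherent delay leaves the reconverted amplitude unchanged", {
  sys <- sys_2pair()
  b <- lls_basis(sys)
  st <- settings_coarse()
  exc <- slic_scheme("excitation", 1, tau = 0.69, lac_order = 2)
  rec <- slic_scheme("reconversion", 1, tau = 0.69, lac_order = 2)
  e0 <- cycle_efficiency(sys, exc, rec, delay = 0, settings = st, basis = b)
  e1 <- cycle_efficiency(sys, exc, rec, delay = 0.5, settings = st,
                         basis = b)
  expect_lt(abs(as.numeric(e0) - as.numeric(e1)), 1e-3)
})

test_that("single-SLIC excitation of a three-pair chain is delocalized", {
  sys <- sys_3pair()
  b <- lls_basis(sys)
  sch <- slic_scheme("excitation", 1, tau = 0.69, lac_order = 2)
  dec <- lls_decompose(simulate_excitation(sys, sch, settings_mid(), b), b)
  singles <- abs(dec$lambda[1:3])
  expect_true(all(singles > 1e-3))          # all three pairs are populated
  expect_identical(which.max(singles), 1L)  # dominated by the irradiated one
})

test_that("readout is most sensitive to the long-lived term of its own pair", {
  sys <- sys_3pair()
  b <- lls_basis(sys)
  rec <- slic_scheme("reconversion", 1, tau = 0.69, lac_order = 2)
  lt <- reconversion_coefficients(sys, rec, b, settings_mid())
  expect_gt(abs(lt[["AA'"]]), abs(lt[["XX'"]]))
})

test_that("signal contributions normalize to one and flag degeneracy", {
  co <- signal_contributions(c(a = 0.2, b = 0.1), c(0.3, -0.05))
  expect_equal(sum(co$normalized), 1, tolerance = 1e-12)
  one <- signal_contributions(c(0.5, 0), c(0.2, 0))
  expect_equal(one$normalized, c(1, 0))
  expect_error(signal_contributions(c(0, 0), c(0, 0)), "degenerate")
})

test_that("optimizer refinement never falls below its own grid optimum", {
  sys <- sys_2pair()
  exc <- slic_scheme("excitation", 1, tau = 1, lac_order = 2)
  rec <- slic_scheme("reconversion", 1, tau = 1, lac_order = 2)
  opt <- optimize_efficiency(sys, exc, rec, tau_max = 1.2, n_grid = 121,
                             nu1_spans = 0, scan_dt = 2e-4)
  expect_gte(opt$refined_efficiency, opt$grid_efficiency - 1e-12)
  expect_gt(opt$efficiency, 0.1)
})

test_that("a magnetically equivalent isolated pair supports no transfer", {
  sys <- sys_1pair()
  opt <- optimize_efficiency(sys,
                             slic_scheme("excitation", 1, 1, lac_order = 2),
                             slic_scheme("reconversion", 1, 1, lac_order = 2),
                             tau_max = 0.5, n_grid = 51, nu1_spans = 0,
                             scan_dt = 2e-4)
  expect_true(opt$flat)
  expect_identical(opt$efficiency, 0)
})

test_that("optimal durations scale inversely with vicinal inequivalence", {
  tau_opt <- function(jv) {
    sys <- spin_system(2, j_vicinal_hz = jv)
    b <- lls_basis(sys)
    sch <- slic_scheme("excitation", 1, tau = 3, lac_order = 2)
    prof <- llspin:::.excitation_profile(sys, sch, b, settings_coarse(),
                                         record_steps = seq(0, 15000, 50))
    prof$times[which.max(abs(prof$lambda[, 1]))]
  }
  t_full <- tau_opt(c(7, 6, 6, 7))          # delta J = 1 Hz
  t_half <- tau_opt(c(6.75, 6.25, 6.25, 6.75))  # delta J = 0.5 Hz
  expect_gt(t_half / t_full, 1.6)
  expect_lt(t_half / t_full, 2.4)
})

test_that("transfer maxima sit at the DQ and SQ matching conditions", {
  sys <- sys_2pair()
  b <- lls_basis(sys)
  peak_nu1 <- function(pairs, lac, nus) {
    best <- sapply(nus, function(nu) {
      sch <- slic_scheme("excitation", pairs, tau = 1.2, nu1 = nu)
      prof <- llspin:::.excitation_profile(sys, sch, b, settings_coarse(),
                                           record_steps = seq(0, 6000, 50))
      max(abs(prof$lambda[, 1]))
    })
    nus[which.max(best)]
  }
  j <- abs(sys$j_intra_hz[1])
  # double irradiation: double-quantum crossing near nu1 = |J|
  nu_dq <- peak_nu1(1:2, 1, seq(0.85, 1.15, by = 0.025) * j)
  expect_lt(abs(nu_dq - j) / j, 0.05)
  # single irradiation: single-quantum crossing near nu1 = 2|J|
  nu_sq <- peak_nu1(1, 2, seq(1.85, 2.15, by = 0.025) * j)
  expect_lt(abs(nu_sq - 2 * j) / (2 * j), 0.05)
})
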