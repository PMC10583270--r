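# SLIC excitation and reconversion of long-lived states, trace-projection
# decomposition, and full-cycle conversion efficiency.
#
# Sign conventions.  The excited long-lived state is expanded as
#   sigma_LLS = - sum_mu lambda_mu * P_mu
# (each scalar-product term enters with a minus sign), so the projection
# coefficients are lambda_mu = -Tr(P_mu^dagger sigma) / Tr(P_mu^dagger P_mu).
# The reconversion coefficient lambda~_mu is the transverse amplitude
# obtained by reconverting the unit term -P_mu alone:
#   lambda~_mu = -Tr(Ix_obs U P_mu U^dagger) / Tr(Ix_obs^2),
# which makes the end-to-end observable amplitude of a full sequence equal
# to sum_mu lambda_mu * lambda~_mu exactly (coherent dynamics, ideal T00).

#' Describe a SLIC pulse
#'
#' A (poly-)SLIC pulse irradiates one or more CH2 pairs at their
#' chemical-shift offsets with a common RF amplitude `nu1` for a common
#' duration `tau`.  The level anti-crossing matching rule is
#' `nu1 = n * |J_intra|` with `n = 1` for the double-quantum (DQ) crossing
#' and `n = 2` for the single-quantum (SQ) crossing; by default `nu1` is
#' resolved from `lac_order` and the geminal coupling of the first target
#' pair when the scheme is applied to a system.
#'
#' @param role `"excitation"` or `"reconversion"`.  Reconversion schemes
#'   irradiate exactly one pair (single-SLIC readout).
#' @param target_pairs pair indices to irradiate (non-empty).
#' @param tau pulse duration in seconds.
#' @param lac_order 1 (DQ) or 2 (SQ); ignored when `nu1` is given.
#' @param nu1 explicit RF amplitude in Hz (optional, must be positive).
#' @param phase RF phase in radians from the x axis.  The default 0 keeps
#'   the pulse collinear with magnetization created by the y-phase
#'   90-degree excitation pulse, i.e. spin-locked.
#' @return An object of class `slic_scheme`.
#' @export
slic_scheme <- function(role = c("excitation", "reconversion"),
                        target_pairs, tau, lac_order = NULL, nu1 = NULL,
                        phase = 0) {
  role <- match.arg(role)
  target_pairs <- as.integer(target_pairs)
  if (length(target_pairs) < 1L || anyDuplicated(target_pairs)) {
    stop("'target_pairs' must be a non-empty set of pair indices",
         call. = FALSE)
  }
  if (role == "reconversion" && length(target_pairs) != 1L) {
    stop("reconversion schemes irradiate exactly one pair", call. = FALSE)
  }
  if (is.null(nu1) && is.null(lac_order)) lac_order <- 2L
  if (!is.null(lac_order) && !lac_order %in% c(1L, 2L)) {
    stop("'lac_order' must be 1 (DQ) or 2 (SQ)", call. = FALSE)
  }
  if (!is.null(nu1) && (!is.finite(nu1) || nu1 <= 0)) {
    stop("'nu1' must be positive", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("'tau' must be a non-negative duration in seconds", call. = FALSE)
  }
  structure(list(role = role, target_pairs = target_pairs, tau = tau,
                 lac_order = if (is.null(lac_order)) NA_integer_ else
                   as.integer(lac_order),
                 nu1 = if (is.null(nu1)) NA_real_ else as.numeric(nu1),
                 phase = as.numeric(phase)),
            class = "slic_scheme")
}

#' @export
print.slic_scheme <- function(x, ...) {
  cat(sprintf("SLIC %s: pair(s) %s, tau = %g s, %s, phase %g rad\n",
              x$role, paste(x$target_pairs, collapse = ","), x$tau,
              if (is.na(x$nu1))
                sprintf("nu1 = %d x |J_gem| (%s LAC)", x$lac_order,
                        c("DQ", "SQ")[x$lac_order])
              else sprintf("nu1 = %g Hz", x$nu1),
              x$phase))
  invisible(x)
}

#' Resolve the RF amplitude of a scheme against a system
#'
#' @param scheme a [slic_scheme()].
#' @param sys a [spin_system()].
#' @return The nutation frequency in Hz.
#' @export
slic_nu1 <- function(scheme, sys) {
  if (!is.na(scheme$nu1)) return(scheme$nu1)
  scheme$lac_order * abs(sys$j_intra_hz[scheme$target_pairs[1L]])
}

# replace fields of a scheme (internal; used by the optimizer)
.scheme_with <- function(scheme, tau = scheme$tau, nu1 = scheme$nu1) {
  scheme$tau <- tau
  scheme$nu1 <- nu1
  scheme
}

.check_scheme_pairs <- function(sys, scheme) {
  if (any(scheme$target_pairs < 1L | scheme$target_pairs > sys$n_pairs)) {
    stop("scheme targets pairs outside the system", call. = FALSE)
  }
}

# Transverse detection operator of a reconversion scheme (observed pair =
# the irradiated pair; for a poly-SLIC readout the first target pair).
.obs_ix <- function(sys, scheme) {
  total_spin_op(sys, .spins_of_pair(scheme$target_pairs[1L]), "x")
}

# state after the non-selective 90-degree pulse: total Iz -> total Ix,
# collinear with the phase-0 SLIC field
.post_90 <- function(sys) {
  pulse_90(initial_state(sys), sys, "all", phase = "y")
}

# lambda_mu(tau) profiles for an excitation scheme over recorded steps.
# Returns a matrix [record x term].
.excitation_profile <- function(sys, scheme, basis, settings, frame_hz = NULL,
                                record_steps = NULL, tau = scheme$tau) {
  if (is.null(frame_hz)) frame_hz <- sys$offsets_hz[scheme$target_pairs[1L]]
  rho1 <- .post_90(sys)
  res <- .slic_unitaries(sys, scheme, tau, settings, frame_hz, record_steps)
  lam <- t(vapply(res$U, function(U) {
    sig <- U %*% rho1 %*% .dag(U)
    vapply(seq_along(basis$terms), function(m) {
      -Re(op_inner(basis$terms[[m]], sig)) / basis$norms[m]
    }, numeric(1L))
  }, numeric(length(basis$terms))))
  list(times = res$times, lambda = lam)
}

# lambda~_mu(tau) profiles for a reconversion scheme (Heisenberg picture:
# one propagation gives the coefficients of every basis term).
.reconversion_profile <- function(sys, scheme, basis, settings,
                                  frame_hz = NULL, record_steps = NULL,
                                  tau = scheme$tau) {
  if (is.null(frame_hz)) frame_hz <- sys$offsets_hz[scheme$target_pairs[1L]]
  Ix <- .obs_ix(sys, scheme)
  n_ix <- Re(op_inner(Ix, Ix))
  res <- .slic_unitaries(sys, scheme, tau, settings, frame_hz, record_steps)
  lam <- t(vapply(res$U, function(U) {
    B <- .dag(U) %*% Ix %*% U
    vapply(basis$terms, function(P) -Re(op_inner(B, P)) / n_ix, numeric(1L))
  }, numeric(length(basis$terms))))
  list(times = res$times, lambda = lam)
}

#' Simulate SLIC excitation of long-lived states
#'
#' Runs the excitation half of the generic sequence -- non-selective
#' 90-degree pulse, SLIC pulse(s), ideal T00 filter -- on the initial
#' longitudinal state and returns the long-lived density operator
#' `sigma_LLS` (exactly within the span of the basis terms).
#'
#' @param sys a [spin_system()].
#' @param scheme an excitation [slic_scheme()].
#' @param settings a [prop_settings()].
#' @param basis optional precomputed [lls_basis()].
#' @return Complex matrix `sigma_LLS`.
#' @export
simulate_excitation <- function(sys, scheme, settings = prop_settings(),
                                basis = NULL) {
  stopifnot(inherits(sys, "spin_system"), inherits(scheme, "slic_scheme"))
  if (scheme$role != "excitation") {
    stop("scheme role must be 'excitation'", call. = FALSE)
  }
  .check_scheme_pairs(sys, scheme)
  if (is.null(basis)) basis <- lls_basis(sys)
  rho <- .post_90(sys)
  rho <- propagate(rho, sys, scheme$tau, scheme, settings)
  t00_filter(rho, basis)
}

#' Decompose a long-lived state into basis coefficients
#'
#' Trace projection onto every basis term, with the sign convention
#' `sigma_LLS = - sum_mu lambda_mu P_mu`, so that an input of `-P_mu` has
#' coefficient 1 on term mu and 0 elsewhere.
#'
#' @param sigma complex matrix (typically from [simulate_excitation()]).
#' @param basis an [lls_basis()].
#' @return Object of class `lls_decomposition`: data frame with columns
#'   `term` and `lambda`.
#' @export
lls_decompose <- function(sigma, basis) {
  stopifnot(inherits(basis, "lls_basis"))
  if (!is.matrix(sigma) || any(dim(sigma) != basis$dim)) {
    stop("'sigma' must match the basis dimension", call. = FALSE)
  }
  lam <- vapply(seq_along(basis$terms), function(m) {
    -Re(op_inner(basis$terms[[m]], sigma)) / basis$norms[m]
  }, numeric(1L))
  structure(data.frame(term = basis$labels, lambda = lam),
            class = c("lls_decomposition", "data.frame"))
}

#' Reconstruct the operator described by a decomposition
#'
#' @param decomp an [lls_decompose()] result.
#' @param basis the matching [lls_basis()].
#' @return `sum_mu lambda_mu * (-P_mu)` as a complex matrix.
#' @export
lls_reconstruct <- function(decomp, basis) {
  out <- matrix(0 + 0i, basis$dim, basis$dim)
  for (m in seq_along(basis$terms)) {
    out <- out - decomp$lambda[m] * basis$terms[[m]]
  }
  out
}

#' Reconversion coefficients of the basis terms
#'
#' Simulates the reconversion SLIC pulse and returns, for every basis term,
#' the transverse amplitude `lambda~_mu` observed on the irradiated pair
#' when the term `-P_mu` alone is reconverted.  A single Heisenberg-picture
#' propagation of the detection operator yields all terms at once.
#'
#' @param sys a [spin_system()].
#' @param scheme a reconversion [slic_scheme()].
#' @param basis an [lls_basis()] (built from `sys` if omitted).
#' @param settings a [prop_settings()].
#' @return Named numeric vector of reconversion coefficients.
#' @export
reconversion_coefficients <- function(sys, scheme, basis = NULL,
                                      settings = prop_settings()) {
  stopifnot(inherits(sys, "spin_system"), inherits(scheme, "slic_scheme"))
  if (scheme$role != "reconversion") {
    stop("scheme role must be 'reconversion'", call. = FALSE)
  }
  .check_scheme_pairs(sys, scheme)
  if (is.null(basis)) basis <- lls_basis(sys)
  if (scheme$tau == 0) {
    out <- numeric(length(basis$terms))
    names(out) <- basis$labels
    return(out)
  }
  prof <- .reconversion_profile(sys, scheme, basis, settings)
  out <- prof$lambda[nrow(prof$lambda), ]
  names(out) <- basis$labels
  out
}

#' Per-term contributions to the observed signal
#'
#' The signal observed after a full excitation/reconversion cycle splits
#' into per-term products `S_mu = lambda_mu * lambda~_mu`.  Normalized
#' contributions (summing to 1) give the histogram of how strongly each
#' long-lived term feeds the detected magnetization.
#'
#' @param excitation an [lls_decompose()] result (or numeric lambda vector).
#' @param reconversion numeric vector of reconversion coefficients in the
#'   same term order.
#' @return Object of class `lls_contributions`: data frame with columns
#'   `term`, `lambda`, `lambda_tilde`, `product`, `normalized`.
#' @export
signal_contributions <- function(excitation, reconversion) {
  if (inherits(excitation, "lls_decomposition")) {
    terms <- excitation$term
    lam <- excitation$lambda
  } else {
    lam <- as.numeric(excitation)
    terms <- if (!is.null(names(excitation))) names(excitation) else
      paste0("term", seq_along(lam))
  }
  lt <- as.numeric(reconversion)
  if (length(lt) != length(lam)) {
    stop("excitation and reconversion coefficient lengths differ",
         call. = FALSE)
  }
  products <- lam * lt
  total <- sum(products)
  if (!is.finite(total) || abs(total) < 1e-14) {
    stop("degenerate scheme: all excitation/reconversion products vanish",
         call. = FALSE)
  }
  structure(data.frame(term = terms, lambda = lam, lambda_tilde = lt,
                       product = products, normalized = products / total),
            class = c("lls_contributions", "data.frame"))
}

#' Full-cycle conversion efficiency
#'
#' Propagates the complete sequence (90-degree pulse, excitation SLIC, T00
#' filter, optional delay, reconversion SLIC) and returns the magnitude of
#' the transverse amplitude recovered on the readout pair, normalized to
#' the amplitude a direct 90-degree readout of that pair would give.  The
#' simulation is relaxation-free, so the delay acts only through coherent
#' dynamics: long-lived terms are stationary and the delay defaults to 0.
#'
#' @param sys a [spin_system()].
#' @param excitation an excitation [slic_scheme()].
#' @param reconversion a reconversion [slic_scheme()].
#' @param delay relaxation-free delay between filter and reconversion, s.
#' @param settings a [prop_settings()].
#' @param basis optional precomputed [lls_basis()].
#' @return Efficiency in `[0, 1]`; the signed amplitude is attached as
#'   attribute `"signed"`.
#' @export
cycle_efficiency <- function(sys, excitation, reconversion, delay = 0,
                             settings = prop_settings(), basis = NULL) {
  if (is.null(basis)) basis <- lls_basis(sys)
  sigma <- simulate_excitation(sys, excitation, settings, basis)
  if (delay > 0) {
    sigma <- t00_filter(propagate(sigma, sys, delay, NULL, settings), basis)
  }
  if (reconversion$role != "reconversion") {
    stop("scheme role must be 'reconversion'", call. = FALSE)
  }
  .check_scheme_pairs(sys, reconversion)
  rho <- propagate(sigma, sys, reconversion$tau, reconversion, settings)
  Ix <- .obs_ix(sys, reconversion)
  amp <- Re(op_inner(Ix, rho)) / Re(op_inner(Ix, Ix))
  structure(abs(amp), signed = amp)
}

#' Optimize full-cycle conversion efficiency
#'
#' Deterministic grid search over the excitation and reconversion pulse
#' durations (and, within a narrow window around the level anti-crossing
#' matching rule, over the RF amplitudes, whose optimum is slightly shifted
#' by the vicinal couplings), followed by local refinement.  The search
#' exploits the exact factorization of the end-to-end amplitude into
#' per-term excitation and reconversion coefficients, so each (nu1, side)
#' combination costs a single incremental propagation.
#'
#' @param sys a [spin_system()].
#' @param excitation excitation [slic_scheme()] template (its `tau` is
#'   ignored).
#' @param reconversion reconversion [slic_scheme()] template.
#' @param tau_max upper bound of the duration scan, s.
#' @param n_grid number of duration grid points (including 0).
#' @param nu1_spans successive half-widths (relative to the matched `nu1`)
#'   of the shrinking RF-amplitude search windows; use `0` to keep `nu1`
#'   fixed at the matching condition.
#' @param nu1_points number of RF-amplitude points per window.
#' @param scan_dt time step used during the scan; the optimum is
#'   re-evaluated at `settings$dt` for the reported efficiency.
#' @param settings a [prop_settings()].
#' @return Object of class `slic_optimum` with the best efficiency, the
#'   optimizing durations and RF amplitudes, finalized schemes, and the
#'   coarse-grid optimum (`grid_efficiency`).
#' @export
optimize_efficiency <- function(sys, excitation, reconversion,
                                tau_max = 2, n_grid = 401,
                                nu1_spans = c(0.03, 0.01, 0.004, 0.0015),
                                nu1_points = 7,
                                scan_dt = 1e-4,
                                settings = prop_settings()) {
  stopifnot(inherits(sys, "spin_system"))
  if (!is.finite(tau_max) || tau_max <= 0) {
    stop("'tau_max' must be a finite positive bound", call. = FALSE)
  }
  .check_scheme_pairs(sys, excitation)
  .check_scheme_pairs(sys, reconversion)
  basis <- lls_basis(sys)
  scan <- settings; scan$dt <- scan_dt

  every <- max(1L, as.integer(round(tau_max / (n_grid - 1) / scan_dt)))
  n_steps <- every * (n_grid - 1L)
  rec_steps <- seq(0L, n_steps, by = every)

  nu1_e0 <- slic_nu1(excitation, sys)
  nu1_r0 <- slic_nu1(reconversion, sys)
  cache_e <- list(); cache_r <- list()
  profile_for <- function(side, nu1) {
    key <- sprintf("%.10g", nu1)
    cache <- if (side == "e") cache_e else cache_r
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (side == "e") {
      .excitation_profile(sys, .scheme_with(excitation, nu1 = nu1), basis,
                          scan, record_steps = rec_steps,
                          tau = n_steps * scan_dt)$lambda
    } else {
      .reconversion_profile(sys, .scheme_with(reconversion, nu1 = nu1),
                            basis, scan, record_steps = rec_steps,
                            tau = n_steps * scan_dt)$lambda
    }
    if (side == "e") cache_e[[key]] <<- val else cache_r[[key]] <<- val
    val
  }

  best <- list(val = -Inf, nu1_e = nu1_e0, nu1_r = nu1_r0,
               i = 1L, j = 1L)
  grid_val <- NA_real_
  for (stage in seq_along(nu1_spans)) {
    w <- nu1_spans[stage]
    nus_e <- if (w > 0) {
      best$nu1_e + nu1_e0 * seq(-w, w, length.out = nu1_points)
    } else nu1_e0
    nus_r <- if (w > 0) {
      best$nu1_r + nu1_r0 * seq(-w, w, length.out = nu1_points)
    } else nu1_r0
    for (ne in nus_e) for (nr in nus_r) {
      S <- profile_for("e", ne) %*% t(profile_for("r", nr))
      k <- which.max(abs(S))
      if (abs(S[k]) > best$val) {
        ij <- arrayInd(k, dim(S))
        best <- list(val = abs(S[k]), nu1_e = ne, nu1_r = nr,
                     i = ij[1L], j = ij[2L])
      }
    }
    if (stage == 1L) grid_val <- best$val
    if (w == 0) break
  }

  if (best$val < 1e-10) {
    sch_e <- .scheme_with(excitation, tau = 0, nu1 = best$nu1_e)
    sch_r <- .scheme_with(reconversion, tau = 0, nu1 = best$nu1_r)
    return(structure(list(efficiency = 0, flat = TRUE,
                          grid_efficiency = best$val,
                          tau_excitation = NA_real_,
                          tau_reconversion = NA_real_,
                          nu1_excitation = best$nu1_e,
                          nu1_reconversion = best$nu1_r,
                          excitation = sch_e, reconversion = sch_r),
                     class = "slic_optimum"))
  }

  # refine the durations at single-step resolution around the grid optimum
  fine_window <- function(side, nu1, centre_step) {
    lo <- max(0L, centre_step - every)
    hi <- min(n_steps, centre_step + every)
    steps <- seq(lo, hi)
    prof <- if (side == "e") {
      .excitation_profile(sys, .scheme_with(excitation, nu1 = nu1), basis,
                          scan, record_steps = steps, tau = hi * scan_dt)
    } else {
      .reconversion_profile(sys, .scheme_with(reconversion, nu1 = nu1),
                            basis, scan, record_steps = steps,
                            tau = hi * scan_dt)
    }
    prof
  }
  fe <- fine_window("e", best$nu1_e, rec_steps[best$i])
  fr <- fine_window("r", best$nu1_r, rec_steps[best$j])
  S <- fe$lambda %*% t(fr$lambda)
  k <- which.max(abs(S))
  ij <- arrayInd(k, dim(S))
  refined <- max(abs(S[k]), best$val)
  tau_e <- fe$times[ij[1L]]
  tau_r <- fr$times[ij[2L]]

  # re-evaluate the located optimum at the full-resolution time step
  sch_e <- .scheme_with(excitation, tau = tau_e, nu1 = best$nu1_e)
  sch_r <- .scheme_with(reconversion, tau = tau_r, nu1 = best$nu1_r)
  eff <- cycle_efficiency(sys, sch_e, sch_r, settings = settings,
                          basis = basis)
  structure(list(efficiency = as.numeric(eff), flat = FALSE,
                 grid_efficiency = grid_val, refined_efficiency = refined,
                 tau_excitation = tau_e, tau_reconversion = tau_r,
                 nu1_excitation = best$nu1_e, nu1_reconversion = best$nu1_r,
                 excitation = sch_e, reconversion = sch_r),
            class = "slic_optimum")
}

#' @export
print.slic_optimum <- function(x, ...) {
  if (isTRUE(x$flat)) {
    cat("SLIC optimization: flat landscape, no magnetization-to-LLS",
        "transfer at any scanned duration (efficiency 0)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("SLIC full-cycle optimum: efficiency %.4f (%.1f%%)\n",
                     "  excitation:  tau = %.4f s, nu1 = %.3f Hz\n",
                     "  reconversion: tau = %.4f s, nu1 = %.3f Hz\n"),
              x$efficiency, 100 * x$efficiency,
              x$tau_excitation, x$nu1_excitation,
              x$tau_reconversion, x$nu1_reconversion))
  invisible(x)
}
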