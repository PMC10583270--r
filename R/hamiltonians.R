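# Rotating-frame Hamiltonians.  All Hamiltonians are returned in angular
# frequency units (rad/s); divide by 2*pi for Hz.

#' Free-evolution Hamiltonian
#'
#' Isotropic liquid-state Hamiltonian of the chain in a frame rotating at
#' `frame_hz`:
#' `H0 = 2*pi * [ sum_k (offset_k - frame) * (Iz_k + Iz_k') + sum_{i<j} J_ij * I_i . I_j ]`
#' with the sum over couplings running over the geminal coupling of every
#' pair and all configured vicinal couplings.
#'
#' @param sys a [spin_system()].
#' @param frame_hz rotating-frame reference offset in Hz (default 0).
#' @return A Hermitian complex matrix in rad/s.
#' @export
h_free <- function(sys, frame_hz = 0) {
  stopifnot(inherits(sys, "spin_system"))
  H <- matrix(0 + 0i, sys$dim, sys$dim)
  for (k in seq_len(sys$n_pairs)) {
    s <- .spins_of_pair(k)
    d <- sys$offsets_hz[k] - frame_hz
    if (d != 0) {
      H <- H + d * (spin_op(sys, s[1L], "z") + spin_op(sys, s[2L], "z"))
    }
    H <- H + sys$j_intra_hz[k] * .dot_op(sys, s[1L], s[2L])
  }
  if (nrow(sys$j_vicinal)) {
    for (r in seq_len(nrow(sys$j_vicinal))) {
      H <- H + sys$j_vicinal$J_hz[r] *
        .dot_op(sys, sys$j_vicinal$i[r], sys$j_vicinal$j[r])
    }
  }
  2 * pi * H
}

#' Radio-frequency Hamiltonian of a SLIC scheme at time t
#'
#' Each irradiated pair `k` sees a field of amplitude `2*pi*nu1` applied to
#' both of its spins along an axis in the transverse plane that rotates at
#' the difference between the pair's resonance offset and the rotating-frame
#' reference.  With the frame placed at the offset of a single irradiated
#' pair the term is time-independent; polychromatic irradiation makes the
#' total RF Hamiltonian explicitly time-dependent.
#'
#' @param sys a [spin_system()].
#' @param scheme a [slic_scheme()].
#' @param t time within the pulse, s.
#' @param frame_hz rotating-frame reference in Hz.  Default: the offset of
#'   the scheme's first target pair.
#' @return A Hermitian complex matrix in rad/s.
#' @export
h_rf <- function(sys, scheme, t = 0, frame_hz = NULL) {
  stopifnot(inherits(sys, "spin_system"), inherits(scheme, "slic_scheme"))
  if (is.null(frame_hz)) frame_hz <- sys$offsets_hz[scheme$target_pairs[1L]]
  nu1 <- slic_nu1(scheme, sys)
  H <- matrix(0 + 0i, sys$dim, sys$dim)
  for (k in scheme$target_pairs) {
    s <- .spins_of_pair(k)
    alpha <- 2 * pi * (sys$offsets_hz[k] - frame_hz) * t + scheme$phase
    H <- H + cos(alpha) * (spin_op(sys, s[1L], "x") + spin_op(sys, s[2L], "x")) +
             sin(alpha) * (spin_op(sys, s[1L], "y") + spin_op(sys, s[2L], "y"))
  }
  2 * pi * nu1 * H
}
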