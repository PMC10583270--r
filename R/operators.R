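# Product-operator construction on the 2^(2n)-dimensional Hilbert space.
# All operators are dense complex matrices in the lexicographic Zeeman
# (alpha/beta) product basis; angular momenta are in units of hbar.

.sigma_half <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2L, 2L),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2L, 2L),
  z = diag(c(0.5, -0.5))
)

.id2 <- diag(2L)

# kron of a list of 2x2 blocks, complex
.kron_chain <- function(blocks) {
  out <- blocks[[1L]]
  for (k in seq_along(blocks)[-1L]) out <- kronecker(out, blocks[[k]])
  out
}

# 2x2 operator m on spin i, identity elsewhere
.op_single <- function(n_spins, i, m) {
  blocks <- rep(list(.id2), n_spins)
  blocks[[i]] <- m
  .kron_chain(blocks)
}

#' Single-spin angular-momentum operator
#'
#' Returns the operator `I_axis` of one spin (tensor product with identity on
#' all other spins).  Traceless, eigenvalues +/- 1/2.
#'
#' @param sys a [spin_system()].
#' @param spin 1-based spin index (`<= 2 * n_pairs`).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return A complex `dim x dim` matrix.
#' @export
spin_op <- function(sys, spin, axis = c("x", "y", "z")) {
  stopifnot(inherits(sys, "spin_system"))
  axis <- match.arg(axis)
  spin <- as.integer(spin)
  if (length(spin) != 1L || spin < 1L || spin > sys$n_spins) {
    stop("spin index out of range", call. = FALSE)
  }
  .op_single(sys$n_spins, spin, .sigma_half[[axis]])
}

#' Total angular-momentum operator over a set of spins
#'
#' @param sys a [spin_system()].
#' @param spins spin indices (default: all spins).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return A complex matrix, the sum of single-spin operators.
#' @export
total_spin_op <- function(sys, spins = NULL, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (is.null(spins)) spins <- seq_len(sys$n_spins)
  Reduce(`+`, lapply(spins, function(i) spin_op(sys, i, axis)))
}

# I_i . I_j for arbitrary spins, internal
.dot_op <- function(sys, i, j) {
  spin_op(sys, i, "x") %*% spin_op(sys, j, "x") +
    spin_op(sys, i, "y") %*% spin_op(sys, j, "y") +
    spin_op(sys, i, "z") %*% spin_op(sys, j, "z")
}

#' Scalar-product operator of one geminal pair
#'
#' The bilinear operator `I_k . I_k'` of pair `k`: Hermitian, traceless in
#' the pair space up to the identity component, with eigenvalues 1/4 (triplet,
#' triply degenerate) and -3/4 (singlet) replicated across the rest of the
#' space.  These operators are the building blocks of the long-lived
#' operator basis.
#'
#' @param sys a [spin_system()].
#' @param pair 1-based pair index.
#' @return A complex matrix.
#' @export
pair_scalar_op <- function(sys, pair) {
  stopifnot(inherits(sys, "spin_system"))
  pair <- as.integer(pair)
  if (length(pair) != 1L || pair < 1L || pair > sys$n_pairs) {
    stop("pair index out of range", call. = FALSE)
  }
  s <- .spins_of_pair(pair)
  .dot_op(sys, s[1L], s[2L])
}

#' Trace inner product of two operators
#'
#' `Tr(A^dagger B)`, the Frobenius/Hilbert-Schmidt inner product used for
#' all trace-projection decompositions.
#'
#' @param a,b conformable complex matrices.
#' @return A complex scalar (real for Hermitian arguments).
#' @export
op_inner <- function(a, b) sum(Conj(a) * b)

# commutator
.comm <- function(a, b) a %*% b - b %*% a

# Frobenius norm
.fnorm <- function(a) sqrt(sum(Mod(a)^2))

# Hermitian conjugate
.dag <- function(a) Conj(t(a))
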