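#' Complete basis of long-lived product operators
#'
#' For an `n`-pair chain the long-lived (scalar) operator span is generated
#' by the subset products `P_S = prod_{k in S} I_k . I_k'` over the
#' `2^n - 1` non-empty subsets `S` of pairs: three bilinear terms plus
#' four- and six-spin products for `n = 3` (seven terms in all), three
#' terms for `n = 2`, one singlet-triplet imbalance for an isolated pair.
#' The terms are Hermitian, traceless, and pairwise orthogonal under the
#' trace inner product.
#'
#' Canonical ordering: singleton subsets by pair index, then two-pair
#' subsets lexicographically, and so on up to the full product.
#'
#' @param sys a [spin_system()].
#' @return An object of class `lls_basis`: list with `terms` (list of
#'   matrices), `subsets`, `labels`, and `norms` (`Tr(P^dagger P)` per term).
#' @examples
#' b <- lls_basis(spin_system(2))
#' b$labels
#' @export
lls_basis <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  n <- sys$n_pairs
  subsets <- list()
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  scalar_ops <- lapply(seq_len(n), function(k) pair_scalar_op(sys, k))
  terms <- lapply(subsets, function(S) Reduce(`%*%`, scalar_ops[S]))
  labels <- vapply(subsets, function(S) paste(sys$labels[S], collapse = ""),
                   character(1L))
  norms <- vapply(terms, function(P) Re(op_inner(P, P)), numeric(1L))
  structure(list(terms = terms, subsets = subsets, labels = labels,
                 norms = norms, n_pairs = n, dim = sys$dim),
            class = "lls_basis")
}

#' @export
print.lls_basis <- function(x, ...) {
  cat(sprintf("Long-lived operator basis: %d terms on %d pairs (dim %d)\n",
              length(x$terms), x$n_pairs, x$dim))
  print(data.frame(term = x$labels,
                   spins = 2L * lengths(x$subsets),
                   norm = x$norms))
  invisible(x)
}

#' Export basis labels and norms as a delimited table
#'
#' @param basis an [lls_basis()].
#' @param path output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_lls_basis <- function(basis, path) {
  stopifnot(inherits(basis, "lls_basis"))
  tab <- data.frame(term = basis$labels,
                    spins = 2L * lengths(basis$subsets),
                    norm = basis$norms)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-lived character of the basis terms
#'
#' Frobenius norms of `[H0, P_mu]` for every basis term.  In the
#' magnetic-equivalence limit (all vicinal couplings within each
#' adjacent-group block equal) every norm vanishes: the terms are constants
#' of motion and hence immune to coherent leakage.  With inequivalent
#' vicinal couplings the singleton terms acquire nonzero commutators --
#' precisely the inequivalence that SLIC exploits -- and the returned norms
#' serve as diagnostics.
#'
#' @param basis an [lls_basis()].
#' @param sys the [spin_system()] the basis was built on.
#' @return Named numeric vector of commutator Frobenius norms (rad/s).
#' @export
long_lived_check <- function(basis, sys) {
  stopifnot(inherits(basis, "lls_basis"), inherits(sys, "spin_system"))
  H0 <- h_free(sys)
  out <- vapply(basis$terms, function(P) .fnorm(.comm(H0, P)), numeric(1L))
  names(out) <- basis$labels
  out
}

#' Idealized T00 filter
#'
#' Projects a density operator onto the span of the long-lived basis terms:
#' `rho -> sum_mu Tr(P_mu^dagger rho) / Tr(P_mu^dagger P_mu) * P_mu`.
#' Transverse magnetization, zero-quantum coherences and any identity
#' component (the deviation-operator convention) are discarded.  The
#' projection is idempotent.  This is the ideal limit of the experimental
#' gradient/phase-cycled filter; imperfections of the real filter element
#' are not emulated.
#'
#' @param rho density matrix on the same system as `basis`.
#' @param basis an [lls_basis()].
#' @return The projected matrix.
#' @export
t00_filter <- function(rho, basis) {
  stopifnot(inherits(basis, "lls_basis"))
  if (!is.matrix(rho) || any(dim(rho) != basis$dim)) {
    stop("'rho' must match the basis dimension", call. = FALSE)
  }
  out <- matrix(0 + 0i, basis$dim, basis$dim)
  for (m in seq_along(basis$terms)) {
    P <- basis$terms[[m]]
    out <- out + (op_inner(P, rho) / basis$norms[m]) * P
  }
  out
}
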