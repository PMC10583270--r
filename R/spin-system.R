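#' Define a chain of geminal proton pairs
#'
#' Builds a validated spin system of `n_pairs` CH2 groups (2 spins per
#' group).  The two protons of a group are chemically equivalent: they share
#' one chemical-shift offset.  Magnetization-to-LLS transfer by SLIC relies
#' on *magnetic* inequivalence, i.e. on unequal vicinal couplings between
#' adjacent groups, so the four couplings of each adjacent-group block can be
#' set individually.
#'
#' Spin indexing is fixed: spins `2k - 1` and `2k` (1-based) form pair `k`.
#' The four vicinal couplings of the block between pairs `k` and `k + 1` are
#' given in the order (A,X), (A,X'), (A',X), (A',X') where A/A' are the two
#' spins of pair `k` and X/X' those of pair `k + 1`.
#'
#' Defaults describe a generic aliphatic CH2 chain: geminal coupling
#' -13.5 Hz, vicinal couplings 7 and 6 Hz for the two inequivalent pathways
#' (trans/gauche pattern `c(7, 6, 6, 7)`), and adjacent groups separated by
#' 200 Hz so that selective irradiation at nutation frequencies up to
#' ~27 Hz is meaningful.
#'
#' @param n_pairs number of CH2 groups, between 1 and 4.
#' @param offsets_hz numeric vector of per-pair chemical-shift offsets in Hz
#'   (one value per pair).  Default: `200 * (0:(n_pairs - 1))`.
#' @param j_intra_hz geminal (intra-pair) J coupling(s) in Hz; scalar or one
#'   value per pair.  Must be nonzero (the SLIC matching condition
#'   `nu1 = n * |J_intra|` is undefined otherwise).
#' @param j_vicinal_hz vicinal couplings: a length-4 vector applied to every
#'   adjacent-group block, an `(n_pairs - 1) x 4` matrix, or a data frame
#'   with columns `i`, `j`, `J_hz` giving explicit spin-indexed couplings.
#' @param labels optional character vector of pair labels.  Defaults to
#'   A/M/X-style labels (`"AA'"`, `"MM'"`, `"XX'"`) for up to three pairs.
#' @param long_range set `TRUE` to allow explicit couplings between spins of
#'   non-adjacent groups (only relevant for the data-frame form of
#'   `j_vicinal_hz`).
#'
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(2)
#' sys
#' @export
spin_system <- function(n_pairs,
                        offsets_hz = NULL,
                        j_intra_hz = -13.5,
                        j_vicinal_hz = c(7, 6, 6, 7),
                        labels = NULL,
                        long_range = FALSE) {
  if (length(n_pairs) != 1L || n_pairs < 1 || n_pairs > 4 ||
      n_pairs != round(n_pairs)) {
    stop("'n_pairs' must be an integer between 1 and 4", call. = FALSE)
  }
  n_pairs <- as.integer(n_pairs)
  n_spins <- 2L * n_pairs

  if (is.null(offsets_hz)) offsets_hz <- 200 * (seq_len(n_pairs) - 1)
  offsets_hz <- as.numeric(offsets_hz)
  if (length(offsets_hz) != n_pairs || any(!is.finite(offsets_hz))) {
    stop("'offsets_hz' must be ", n_pairs, " finite values", call. = FALSE)
  }

  j_intra_hz <- rep_len(as.numeric(j_intra_hz), n_pairs)
  if (any(!is.finite(j_intra_hz)) || any(j_intra_hz == 0)) {
    stop("every pair needs a nonzero, finite geminal coupling 'j_intra_hz'",
         call. = FALSE)
  }

  vic <- .vicinal_table(n_pairs, j_vicinal_hz, long_range)

  if (is.null(labels)) {
    labels <- switch(n_pairs,
                     "AA'",
                     c("AA'", "XX'"),
                     c("AA'", "MM'", "XX'"),
                     c("AA'", "MM'", "NN'", "XX'"))
  }
  if (length(labels) != n_pairs) {
    stop("'labels' must have one entry per pair", call. = FALSE)
  }

  structure(
    list(n_pairs = n_pairs, n_spins = n_spins,
         dim = as.integer(2^n_spins),
         offsets_hz = offsets_hz, j_intra_hz = j_intra_hz,
         j_vicinal = vic, labels = labels),
    class = "spin_system")
}

# Normalize the three accepted vicinal-coupling forms into a data frame
# with columns i, j, J_hz (i < j, spin indices 1-based).
.vicinal_table <- function(n_pairs, j_vicinal_hz, long_range) {
  empty <- data.frame(i = integer(), j = integer(), J_hz = numeric())
  if (n_pairs == 1L) {
    if (is.data.frame(j_vicinal_hz) && nrow(j_vicinal_hz) > 0) {
      stop("a 1-pair system has no vicinal couplings", call. = FALSE)
    }
    return(empty)
  }

  if (is.data.frame(j_vicinal_hz)) {
    need <- c("i", "j", "J_hz")
    if (!all(need %in% names(j_vicinal_hz))) {
      stop("coupling data frame needs columns i, j, J_hz", call. = FALSE)
    }
    tab <- j_vicinal_hz[need]
  } else {
    if (is.matrix(j_vicinal_hz)) {
      if (nrow(j_vicinal_hz) != n_pairs - 1L || ncol(j_vicinal_hz) != 4L) {
        stop("coupling matrix must be (n_pairs - 1) x 4", call. = FALSE)
      }
      blocks <- j_vicinal_hz
    } else {
      if (length(j_vicinal_hz) != 4L) {
        stop("'j_vicinal_hz' vector must have 4 entries per block",
             call. = FALSE)
      }
      blocks <- matrix(rep(j_vicinal_hz, n_pairs - 1L),
                       ncol = 4L, byrow = TRUE)
    }
    rows <- lapply(seq_len(n_pairs - 1L), function(b) {
      a1 <- 2L * b - 1L; a2 <- 2L * b; x1 <- 2L * b + 1L; x2 <- 2L * b + 2L
      data.frame(i = c(a1, a1, a2, a2), j = c(x1, x2, x1, x2),
                 J_hz = as.numeric(blocks[b, ]))
    })
    tab <- do.call(rbind, rows)
  }

  tab$i <- as.integer(tab$i); tab$j <- as.integer(tab$j)
  tab$J_hz <- as.numeric(tab$J_hz)
  n_spins <- 2L * n_pairs
  if (any(tab$i < 1L | tab$j < 1L | tab$i > n_spins | tab$j > n_spins)) {
    stop("coupling indices out of range", call. = FALSE)
  }
  if (any(tab$i == tab$j)) stop("self-couplings are not allowed", call. = FALSE)
  swap <- tab$i > tab$j
  tmp <- tab$i[swap]; tab$i[swap] <- tab$j[swap]; tab$j[swap] <- tmp
  if (anyDuplicated(tab[c("i", "j")])) {
    stop("duplicate coupling entries", call. = FALSE)
  }
  pair_of <- function(s) (s + 1L) %/% 2L
  same_pair <- pair_of(tab$i) == pair_of(tab$j)
  if (any(same_pair)) {
    stop("intra-pair couplings belong in 'j_intra_hz'", call. = FALSE)
  }
  adjacent <- abs(pair_of(tab$i) - pair_of(tab$j)) == 1L
  if (!long_range && any(!adjacent)) {
    stop("couplings between non-adjacent groups require long_range = TRUE",
         call. = FALSE)
  }
  if (any(!is.finite(tab$J_hz))) stop("couplings must be finite", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("Spin system: %d CH2 pair%s (%d spins, dim %d)\n",
              x$n_pairs, if (x$n_pairs > 1) "s" else "", x$n_spins, x$dim))
  cat(sprintf("  pair %d (%s): offset %g Hz, J_gem %g Hz\n",
              seq_len(x$n_pairs), format(x$labels), x$offsets_hz,
              x$j_intra_hz), sep = "")
  if (nrow(x$j_vicinal)) {
    cat("  vicinal couplings (Hz):\n")
    apply(x$j_vicinal, 1L, function(r) {
      cat(sprintf("    J(%d,%d) = %g\n", r[["i"]], r[["j"]], r[["J_hz"]]))
    })
  }
  invisible(x)
}

#' Which pair does a spin belong to?
#' @noRd
.pair_of_spin <- function(spin) (as.integer(spin) + 1L) %/% 2L

#' Spins of one pair
#' @noRd
.spins_of_pair <- function(pair) c(2L * pair - 1L, 2L * pair)

#' Read a spin-system configuration file
#'
#' The configuration is JSON with fields `n_pairs`, `offsets_hz`,
#' `j_intra_hz` and `j_vicinal_hz` (either a vector of 4, a list of
#' per-block vectors of 4, or a list of `{i, j, J_hz}` records), plus
#' optional `labels` and `long_range`.
#'
#' @param path path to a JSON file.
#' @return A [spin_system()].
#' @examples
#' cfg <- system.file("extdata", "two-pair-chain.json", package = "llspin")
#' read_spin_system(cfg)
#' @export
read_spin_system <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$n_pairs)) stop("config lacks 'n_pairs'", call. = FALSE)
  jv <- cfg$j_vicinal_hz
  if (is.list(jv) && !is.data.frame(jv)) jv <- do.call(rbind, jv)
  args <- list(n_pairs = cfg$n_pairs)
  if (!is.null(cfg$offsets_hz)) args$offsets_hz <- cfg$offsets_hz
  if (!is.null(cfg$j_intra_hz)) args$j_intra_hz <- cfg$j_intra_hz
  if (!is.null(jv)) args$j_vicinal_hz <- jv
  if (!is.null(cfg$labels)) args$labels <- cfg$labels
  if (isTRUE(cfg$long_range)) args$long_range <- TRUE
  do.call(spin_system, args)
}

#' Write a spin-system configuration file
#'
#' @param sys a [spin_system()].
#' @param path output path for the JSON configuration.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(sys, path) {
  stopifnot(inherits(sys, "spin_system"))
  cfg <- list(n_pairs = sys$n_pairs, offsets_hz = sys$offsets_hz,
              j_intra_hz = sys$j_intra_hz, j_vicinal_hz = sys$j_vicinal,
              labels = sys$labels)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
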