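# Shipped experiment presets: the six excitation/readout combinations used
# for three-pair chains (single SLIC on each group, and triple SLIC combined
# with a single readout on each group) and the two double-SLIC schemes for
# two-pair chains.  Single-SLIC pulses run at the single-quantum matching
# condition (nu1 = 2|J_gem|), poly-SLIC pulses at the double-quantum
# condition (nu1 = |J_gem|); a single irradiated pair has no double-quantum
# crossing, so reconversion is always a single SQ pulse.  Pulse durations
# sit near the coherent-transfer maxima of the default coupling topology.

.preset_table <- list(
  `single-1` = list(n_pairs = 3L, exc_pairs = 1L, exc_lac = 2L,
                    tau_exc = 0.69, rec_pair = 1L, tau_rec = 0.69),
  `single-2` = list(n_pairs = 3L, exc_pairs = 2L, exc_lac = 2L,
                    tau_exc = 0.49, rec_pair = 2L, tau_rec = 0.49),
  `single-3` = list(n_pairs = 3L, exc_pairs = 3L, exc_lac = 2L,
                    tau_exc = 0.69, rec_pair = 3L, tau_rec = 0.69),
  `triple-1` = list(n_pairs = 3L, exc_pairs = 1:3, exc_lac = 1L,
                    tau_exc = 0.90, rec_pair = 1L, tau_rec = 0.76),
  `triple-2` = list(n_pairs = 3L, exc_pairs = 1:3, exc_lac = 1L,
                    tau_exc = 0.72, rec_pair = 2L, tau_rec = 0.50),
  `triple-3` = list(n_pairs = 3L, exc_pairs = 1:3, exc_lac = 1L,
                    tau_exc = 0.90, rec_pair = 3L, tau_rec = 0.76),
  `double-1` = list(n_pairs = 2L, exc_pairs = 1:2, exc_lac = 1L,
                    tau_exc = 1.04, rec_pair = 1L, tau_rec = 0.69),
  `double-2` = list(n_pairs = 2L, exc_pairs = 1:2, exc_lac = 1L,
                    tau_exc = 1.04, rec_pair = 2L, tau_rec = 0.69)
)

#' Names of the shipped SLIC experiment presets
#'
#' @param n_pairs optionally restrict to presets for systems of this size.
#' @return Character vector of preset names.
#' @export
slic_preset_names <- function(n_pairs = NULL) {
  nm <- names(.preset_table)
  if (!is.null(n_pairs)) {
    nm <- nm[vapply(.preset_table, function(p) p$n_pairs == n_pairs,
                    logical(1L))]
  }
  nm
}

#' Retrieve a preset excitation/reconversion scheme pair
#'
#' Presets `single-1` .. `single-3` excite with a single SQ SLIC pulse on
#' one group and read the same group out; `triple-1` .. `triple-3` excite
#' with simultaneous DQ irradiation of all three groups and read out one
#' group; `double-1`/`double-2` are the two-pair analogues with
#' simultaneous DQ excitation of both groups.
#'
#' @param name one of [slic_preset_names()].
#' @return List with elements `excitation` and `reconversion`
#'   ([slic_scheme()] objects) and `n_pairs`.
#' @export
slic_preset <- function(name) {
  p <- .preset_table[[match.arg(name, names(.preset_table))]]
  list(n_pairs = p$n_pairs,
       excitation = slic_scheme("excitation", p$exc_pairs, p$tau_exc,
                                lac_order = p$exc_lac),
       reconversion = slic_scheme("reconversion", p$rec_pair, p$tau_rec,
                                  lac_order = 2L))
}

#' Contribution tables for preset experiments
#'
#' For each requested preset, simulates excitation, computes the
#' reconversion coefficients, and tabulates per-term products and
#' normalized contributions to the observed signal (the normalized column
#' of each preset sums to 1).
#'
#' @param sys a [spin_system()] whose `n_pairs` matches the presets.
#' @param presets preset names; default: all presets matching `sys`.
#' @param settings a [prop_settings()].
#' @return A data frame with columns `preset`, `term`, `lambda`,
#'   `lambda_tilde`, `product`, `normalized`.
#' @export
contribution_table <- function(sys, presets = slic_preset_names(sys$n_pairs),
                               settings = prop_settings()) {
  stopifnot(inherits(sys, "spin_system"))
  basis <- lls_basis(sys)
  rows <- lapply(presets, function(nm) {
    p <- slic_preset(nm)
    if (p$n_pairs != sys$n_pairs) {
      stop(sprintf("preset '%s' is for %d pairs, system has %d",
                   nm, p$n_pairs, sys$n_pairs), call. = FALSE)
    }
    sigma <- simulate_excitation(sys, p$excitation, settings, basis)
    dec <- lls_decompose(sigma, basis)
    lt <- reconversion_coefficients(sys, p$reconversion, basis, settings)
    co <- signal_contributions(dec, lt)
    cbind(preset = nm, as.data.frame(co))
  })
  do.call(rbind, rows)
}

#' Write a contribution table as delimited text
#'
#' @param tab result of [contribution_table()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_contribution_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
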