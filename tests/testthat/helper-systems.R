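# Shared fixture builders.  All systems use the package's default coupling
# topology unless a test needs to vary it explicitly.

sys_1pair <- function(...) spin_system(1, ...)
sys_2pair <- function(...) spin_system(2, ...)
sys_3pair <- function(...) spin_system(3, ...)

# magnetic-equivalence limit: all four vicinal couplings of every block equal
sys_equiv <- function(n = 3) {
  spin_system(n, j_vicinal_hz = c(6.5, 6.5, 6.5, 6.5))
}

# coarse stepping for property tests where 1e-4-level accuracy suffices
settings_coarse <- function() prop_settings(dt = 2e-4)
settings_mid <- function() prop_settings(dt = 1e-4)

trace_of <- function(m) sum(diag(m))

purity_of <- function(m) Re(sum(diag(m %*% m)))

frob <- function(m) sqrt(sum(Mod(m)^2))

# random Hermitian matrix (deterministic under the caller's seed)
random_hermitian <- function(d) {
  a <- matrix(stats::rnorm(d * d), d) + 1i * matrix(stats::rnorm(d * d), d)
  (a + Conj(t(a))) / 2
}
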