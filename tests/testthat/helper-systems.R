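# Shared fixtures for the test suite, built in code.

closed_system <- function() spin_system(oxidation = "IV,IV,IV,III")
open_system <- function() spin_system(oxidation = "III,IV,IV,IV")

# Table 1 closed-cubane W1=OH- sets (J order 1-2, 1-3, 1-4, 2-3, 2-4, 3-4)
j_closed_d170 <- function() exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6))
j_closed_o4w2 <- function() exchange_couplings(c(23.7, 8.6, -0.9, 22.3, 4.9, -28.9))

zfs_total_default <- function() zfs_model("total", D = -0.445, E_over_D = 0.25)

# Small settings for unit tests where only structure, not convergence,
# matters; acceptance tests use the package defaults.
fast_settings <- function(...) {
  args <- list(n_theta = 9, n_phi = 18, n_field = 256)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(spectrum_settings, args)
}

expect_hermitian <- function(term, tol = 1e-10) {
  m <- if (inherits(term, "hamiltonian_term")) term$matrix else term
  expect_lt(max(Mod(m - Conj(t(m)))), tol * max(1, max(Mod(m))))
}
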