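#' Generate synthetic broken-symmetry configuration energies
#'
#' Forward model of the classical (Ising) energy expressions: for each of
#' the eight canonical sign classes the energy is
#' `offset + classical_config_energy(truth, system, signs) + N(0, noise_sd)`.
#' This emulates the quantum-chemical broken-symmetry energy tables that the
#' exchange-coupling fit consumes, with an additive constant of
#' hartree-scale magnitude so the fitted offset column is genuinely
#' exercised, and i.i.d. Gaussian noise standing in for the (unmodelled)
#' scatter of DFT total energies. Deterministic under `seed`.
#'
#' @param truth An [exchange_couplings]: the ground-truth J set.
#' @param system A [spin_system].
#' @param noise_sd Gaussian noise standard deviation in cm^-1 (default 0.5,
#'   small relative to published J magnitudes).
#' @param offset_cm1 Constant energy origin in cm^-1 (default -0.5 hartree
#'   expressed in cm^-1).
#' @param seed Integer seed; fixes the output exactly.
#' @param replicates Number of independent noisy tables (default 1).
#' @return A tibble with columns `replicate`, `signs`, `energy`, `unit`
#'   (`"cm-1"`) and `source` (`"synthetic"`).
#' @export
#' @examples
#' sys <- spin_system(oxidation = "IV,IV,IV,III")
#' truth <- fixture("closed_W1OH_D170axis")$couplings
#' generate_bs_energies(truth, sys, noise_sd = 0, seed = 1)
generate_bs_energies <- function(truth, system, noise_sd = 0.5,
                                 offset_cm1 = -0.5 * CM1_PER_HARTREE,
                                 seed = NULL, replicates = 1) {
  stopifnot(inherits(system, "spin_system"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  configs <- canonical_configurations()$signs
  base <- classical_config_energy(truth, system, configs) + offset_cm1
  purrr::map_dfr(seq_len(replicates), function(r) {
    tibble::tibble(
      replicate = r,
      signs = configs,
      energy = base + stats::rnorm(length(configs), sd = noise_sd),
      unit = "cm-1",
      source = "synthetic"
    )
  })
}

#' Random exchange-coupling sets for property tests
#'
#' Six (for four sites) i.i.d. Normal(0, scale) couplings, reproducible
#' under `seed`.
#'
#' @param seed Integer seed.
#' @param scale Standard deviation in cm^-1.
#' @param n_sites Number of sites (default 4).
#' @return An [exchange_couplings].
#' @export
random_couplings <- function(seed = NULL, scale = 10, n_sites = 4) {
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_sites * (n_sites - 1) / 2
  exchange_couplings(stats::rnorm(n, sd = scale), n_sites = n_sites)
}

# Published coupling sets. J order: 1-2, 1-3, 1-4, 2-3, 2-4, 3-4 (cm^-1).
# expected_g is the total-ZFS-scheme value where reported; expected_g_site
# the Mn4-site-scheme value.
fixture_table <- function() {
  tibble::tribble(
    ~name, ~conformation, ~oxidation, ~j, ~expected_ground_spin, ~expected_g, ~expected_g_site,
    "closed_W1OH_D170axis", "closed", "IV,IV,IV,III",
    c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6), 5 / 2, 4.0, 3.7,
    "closed_W1OH_O4W2axis", "closed", "IV,IV,IV,III",
    c(23.7, 8.6, -0.9, 22.3, 4.9, -28.9), 5 / 2, 4.0, 3.6,
    "closed_W2OH_W446", "closed", "IV,IV,IV,III",
    c(29.9, 8.4, 8.8, 24.0, 4.8, -18.1), 5 / 2, NA_real_, NA_real_,
    "closed_W2OH_W5", "closed", "IV,IV,IV,III",
    c(26.4, 5.7, 6.9, 24.3, -0.4, -9.9), 5 / 2, NA_real_, NA_real_,
    "closed_allH2O", "closed", "IV,IV,IV,III",
    c(26.7, -0.2, 6.3, 31.2, 0.8, -1.2), 11 / 2, NA_real_, NA_real_,
    "pantazis_fourspin", "closed", "IV,IV,IV,III",
    c(30.5, 13.0, 0, 35.5, 0, -7.6), 5 / 2, NA_real_, 2.9,
    "open_O4OH_thisstudy", "open", "III,IV,IV,IV",
    c(-17, 3, 2, 21, 1, 2), 5 / 2, 4.0, NA_real_,
    "open_O4OH_corry", "open", "III,IV,IV,IV",
    c(-15, 1, 3, 20, 0, 5), 5 / 2, 4.0, NA_real_
  )
}

#' Catalogue of published exchange-coupling fixtures
#'
#' Coupling sets for the closed-cubane S2 conformation under five W1/W2
#' protonation states, the earlier gas-phase four-spin set of Pantazis et
#' al., and two open-cubane O4 = OH- sets, together with the ground-state
#' spin and (where reported) the simulated effective g value. The open-
#' cubane rows use the Mn1(III) oxidation pattern (spins 2, 3/2, 3/2, 3/2).
#'
#' @return A tibble with one row per fixture: `name`, `conformation`,
#'   `oxidation`, J columns `j12` ... `j34` (cm^-1), `expected_ground_spin`,
#'   `expected_g` (total-ZFS scheme) and `expected_g_site` (Mn4-site
#'   scheme); `NA` where no value was reported.
#' @export
fixture_catalog <- function() {
  tab <- fixture_table()
  jm <- do.call(rbind, tab$j)
  colnames(jm) <- c("j12", "j13", "j14", "j23", "j24", "j34")
  dplyr::bind_cols(
    dplyr::select(tab, -"j"),
    tibble::as_tibble(jm)
  ) |>
    dplyr::relocate(dplyr::starts_with("j"), .after = "oxidation")
}

#' Retrieve one fixture by name
#'
#' @param name A key from [fixture_catalog()], e.g.
#'   `"closed_W1OH_D170axis"`.
#' @return A list with `name`, `system` ([spin_system]), `couplings`
#'   ([exchange_couplings]), `zfs` (the default total-scheme
#'   [zfs_model] with D = -0.445 cm^-1, E/D = 0.25), `expected_ground_spin`
#'   and `expected_g`.
#' @export
#' @examples
#' fx <- fixture("closed_W1OH_D170axis")
#' fx$couplings
fixture <- function(name) {
  tab <- fixture_table()
  hit <- tab[tab$name == name, ]
  if (nrow(hit) != 1) {
    stop(
      "unknown fixture \"", name, "\"; available: ",
      paste(tab$name, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    name = name,
    system = spin_system(oxidation = hit$oxidation),
    couplings = exchange_couplings(hit$j[[1]]),
    zfs = zfs_model("total", D = -0.445, E_over_D = 0.25),
    expected_ground_spin = hit$expected_ground_spin,
    expected_g = hit$expected_g,
    expected_g_site = hit$expected_g_site
  )
}
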