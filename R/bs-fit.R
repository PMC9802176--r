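#' Canonical broken-symmetry spin configurations
#'
#' The eight sign classes used to extract the six pairwise couplings of a
#' four-site cluster from broken-symmetry energies. Each configuration is a
#' pattern of up/down site spins; a configuration and its global flip have
#' identical classical energy and count as one class, canonicalized so the
#' first sign is up. For the closed-cubane pattern (3/2, 3/2, 3/2, 2) the
#' classes carry nominal total spins 13/2, 7/2 (x3), 5/2 and 1/2 (x3).
#'
#' @param system Optional [spin_system]; when given, the nominal total spin
#'   |sum sigma_i s_i| of each class is added.
#' @return A tibble with columns `signs` (e.g. `"+++-"`), and, when `system`
#'   is supplied, `nominal_spin`.
#' @export
canonical_configurations <- function(system = NULL) {
  signs <- c(
    "++++", "++-+", "+-++", "-+++",
    "+++-", "--++", "-+-+", "+--+"
  )
  signs <- vapply(signs, canonicalize_signs, character(1), USE.NAMES = FALSE)
  out <- tibble::tibble(signs = signs)
  if (!is.null(system)) {
    out$nominal_spin <- vapply(
      signs,
      function(s) abs(sum(parse_signs(s) * system$spins)),
      numeric(1)
    )
  }
  out
}

# "+ + + -", "+++-", or arrow notation to integer +-1 vector.
parse_signs <- function(signs) {
  if (is.numeric(signs)) {
    s <- as.integer(sign(signs))
  } else {
    chars <- strsplit(gsub("[[:space:]]", "", signs), "")[[1]]
    s <- vapply(chars, function(ch) {
      switch(ch,
        "+" = 1L,
        "-" = -1L,
        "↑" = 1L,
        "↓" = -1L,
        stop("unrecognised sign character: \"", ch, "\"", call. = FALSE)
      )
    }, integer(1), USE.NAMES = FALSE)
  }
  if (any(s == 0L)) stop("signs must be +-1", call. = FALSE)
  s
}

format_signs <- function(sigma) paste(ifelse(sigma > 0, "+", "-"), collapse = "")

# Canonical class representative: first sign up.
canonicalize_signs <- function(signs) {
  s <- parse_signs(signs)
  if (s[1] < 0) s <- -s
  format_signs(s)
}

#' Classical (Ising) energy of a broken-symmetry configuration
#'
#' Under the classical spin approximation each site spin is replaced by its
#' maximal projection `sigma_i * s_i`, and the Heisenberg exchange energy of
#' the configuration reduces to
#' \deqn{E(\sigma) = \sum_{i<j} (-2 J_{ij}) \sigma_i \sigma_j s_i s_j,}
#' which for the (3/2, 3/2, 3/2, 2) pattern yields the familiar +-9/2
#' coefficients for IV-IV pairs and +-6 for IV-III pairs. This is exactly
#' the expectation value of the quantum exchange Hamiltonian in the product
#' state with those maximal projections.
#'
#' @param couplings An [exchange_couplings] (cm^-1).
#' @param system A [spin_system].
#' @param signs A sign pattern (string like `"+++-"`, +-1 vector) or a
#'   character vector / tibble with a `signs` column for several at once.
#' @return Numeric vector of energies in cm^-1.
#' @export
#' @examples
#' sys <- spin_system(oxidation = "IV,IV,IV,III")
#' j <- exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6))
#' classical_config_energy(j, sys, "+++-") # -502.35
classical_config_energy <- function(couplings, system, signs) {
  stopifnot(inherits(system, "spin_system"))
  if (!inherits(couplings, "exchange_couplings")) {
    couplings <- exchange_couplings(couplings, n_sites = length(system$spins))
  }
  if (is.data.frame(signs)) signs <- signs$signs
  if (is.character(signs) && length(signs) > 1) {
    return(vapply(signs, function(s) {
      classical_config_energy(couplings, system, s)
    }, numeric(1), USE.NAMES = FALSE))
  }
  sigma <- parse_signs(signs)
  if (length(sigma) != length(system$spins)) {
    stop("sign pattern length does not match the number of sites", call. = FALSE)
  }
  idx <- pair_indices(couplings)
  coef <- -2 * sigma[idx[, 1]] * sigma[idx[, 2]] *
    system$spins[idx[, 1]] * system$spins[idx[, 2]]
  sum(coef * as.numeric(couplings))
}

#' Classical excitation gap between spin configurations
#'
#' Minimum classical energy difference between a set of competitor
#' configurations and a reference configuration — e.g. the lowest nominal
#' S = 7/2 configuration relative to the S = 5/2 ground configuration, the
#' isolation criterion for the g ~ 4 signal.
#'
#' @param couplings,system As in [classical_config_energy()].
#' @param reference Reference sign pattern.
#' @param competitors Character vector of competitor sign patterns.
#' @return Minimum of `E(competitor) - E(reference)` in cm^-1.
#' @export
#' @examples
#' sys <- spin_system(oxidation = "IV,IV,IV,III")
#' j <- exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6))
#' classical_gap(j, sys, "+++-", c("++-+", "+-++", "-+++")) # 252.6
classical_gap <- function(couplings, system, reference, competitors) {
  if (length(competitors) == 0) {
    stop("`competitors` must not be empty", call. = FALSE)
  }
  e_ref <- classical_config_energy(couplings, system, reference)
  e_comp <- classical_config_energy(couplings, system, competitors)
  min(e_comp) - e_ref
}

# Design matrix of the linear model E = c0 + A J over configurations.
# Row per configuration, column per pair; entry -2 sigma_i sigma_j s_i s_j.
bs_design_matrix <- function(system, signs) {
  pairs <- pair_names(length(system$spins))
  idx <- do.call(rbind, lapply(strsplit(pairs, "-"), as.integer))
  A <- t(vapply(signs, function(s) {
    sigma <- parse_signs(s)
    -2 * sigma[idx[, 1]] * sigma[idx[, 2]] *
      system$spins[idx[, 1]] * system$spins[idx[, 2]]
  }, numeric(nrow(idx))))
  dimnames(A) <- list(signs, pairs)
  A
}

#' Fit pairwise exchange couplings to broken-symmetry energies
#'
#' Solves the linear system `E_sc = c0 + sum_{i<j} (-2 sigma_i sigma_j s_i
#' s_j) J_ij` in the least-squares sense by singular value decomposition,
#' with a free constant offset c0 absorbing the spin-independent part of the
#' quantum-chemical total energies. Singular values below `sv_cutoff` times
#' the largest are zeroed (pseudo-inverse). With the eight canonical
#' configurations the J block of the design matrix has rank 6, so all six
#' couplings of a four-site cluster are determined.
#'
#' @param energies A tibble/data.frame with columns `signs` and `energy`
#'   (and optionally `unit`, `"cm-1"` (default) or `"hartree"`), e.g. from
#'   [generate_bs_energies()] or [read_energy_table()].
#' @param system A [spin_system].
#' @param sv_cutoff Relative singular-value cutoff (default 1e-10).
#' @return An object of class `bs_fit`: list with `couplings`
#'   ([exchange_couplings]), `offset_cm1`, `residuals_cm1` (per
#'   configuration, fit order), `design_rank` (rank of the J block),
#'   `configurations` (canonical sign strings used) and `energies_cm1`.
#' @export
fit_exchange_couplings <- function(energies, system, sv_cutoff = 1e-10) {
  stopifnot(inherits(system, "spin_system"))
  energies <- tibble::as_tibble(energies)
  if (!all(c("signs", "energy") %in% names(energies))) {
    stop("`energies` needs columns `signs` and `energy`", call. = FALSE)
  }
  unit <- if ("unit" %in% names(energies)) energies$unit else "cm-1"
  e <- convert_energy_cm1(energies$energy, unit)
  signs <- vapply(energies$signs, canonicalize_signs, character(1),
    USE.NAMES = FALSE
  )
  if (anyDuplicated(signs)) {
    # replicates of the same class are averaged (the fit is linear, so this
    # equals fitting all rows; it keeps the residual bookkeeping per class)
    e <- as.numeric(tapply(e, signs, mean)[unique(signs)])
    signs <- unique(signs)
  }
  A <- bs_design_matrix(system, signs)
  X <- cbind(A, c0 = 1)
  sv <- svd(X)
  keep <- sv$d > sv_cutoff * max(sv$d)
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], e)) / sv$d[keep])
  coef <- drop(coef)
  names(coef) <- colnames(X)
  n_pairs <- ncol(A)
  sva <- svd(A, nu = 0, nv = n_pairs)
  j_rank <- sum(sva$d > sv_cutoff * max(sva$d))
  if (j_rank < n_pairs) {
    ns <- sva$v[, seq(j_rank + 1, n_pairs), drop = FALSE]
    combos <- apply(ns, 2, function(v) {
      paste(sprintf("%+.3f %s", v[abs(v) > 1e-8], colnames(A)[abs(v) > 1e-8]),
        collapse = " "
      )
    })
    stop(
      "underdetermined: the supplied configurations cannot resolve the ",
      "coupling combination(s): ", paste(combos, collapse = "; "),
      call. = FALSE
    )
  }
  fitted <- drop(X %*% coef)
  structure(
    list(
      couplings = exchange_couplings(coef[seq_len(n_pairs)],
        n_sites = length(system$spins)
      ),
      offset_cm1 = unname(coef["c0"]),
      residuals_cm1 = e - fitted,
      design_rank = j_rank,
      configurations = signs,
      energies_cm1 = e,
      system = system
    ),
    class = "bs_fit"
  )
}

convert_energy_cm1 <- function(energy, unit) {
  unit <- tolower(unit)
  if (length(unit) == 1) unit <- rep(unit, length(energy))
  ok <- unit %in% c("cm-1", "cm1", "cm^-1", "hartree")
  if (!all(ok)) {
    stop("unknown energy unit(s): ", paste(unique(unit[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  ifelse(unit == "hartree", energy * CM1_PER_HARTREE, energy)
}

#' @export
print.bs_fit <- function(x, ...) {
  cat("<bs_fit> couplings (cm^-1):\n")
  print(stats::setNames(as.numeric(x$couplings), names(x$couplings)))
  cat(
    "offset c0 =", format(x$offset_cm1), "cm^-1; design rank",
    x$design_rank, "; RMS residual",
    format(sqrt(mean(x$residuals_cm1^2))), "cm^-1\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.bs_fit <- function(x, ...) {
  tibble::tibble(pair = names(x$couplings), estimate = as.numeric(x$couplings))
}

#' @export
glance.bs_fit <- function(x, ...) {
  tibble::tibble(
    design_rank = x$design_rank,
    offset_cm1 = x$offset_cm1,
    rms_residual_cm1 = sqrt(mean(x$residuals_cm1^2)),
    n_configurations = length(x$configurations)
  )
}
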