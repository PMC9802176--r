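#' Settings for a field-swept EPR simulation
#'
#' Collects every tunable of the powder simulation with X-band defaults:
#' 9.50 GHz microwave frequency, Gaussian linewidth Delta = 0.033 cm^-1
#' (about 350 G at g = 2, standing in for unresolved Mn hyperfine
#' structure), isotropic g = 2, a 50-6000 G sweep (g from roughly 1.1 to
#' beyond 40), a sin(theta)-weighted 31 x 62 hemisphere orientation grid,
#' and truncation to the lowest 6 zero-field sublevels (the isolated
#' S = 5/2 multiplet). Transitions are weighted equally by default; setting
#' a `temperature` applies Boltzmann population differences instead.
#'
#' @param freq_ghz Microwave frequency in GHz.
#' @param linewidth Gaussian width Delta in cm^-1 (> 0).
#' @param g_iso Isotropic g value.
#' @param field_min,field_max Field sweep limits in Gauss.
#' @param n_field Number of field points (>= 2).
#' @param n_theta,n_phi Orientation-grid counts over the hemisphere.
#' @param n_sublevels Zero-field sublevels retained (>= 2).
#' @param temperature Kelvin, or `NULL` for equal transition weights.
#' @return A list of class `spectrum_settings`.
#' @export
spectrum_settings <- function(freq_ghz = 9.50, linewidth = 0.033, g_iso = 2,
                              field_min = 50, field_max = 6000, n_field = 512,
                              n_theta = 31, n_phi = 62, n_sublevels = 6,
                              temperature = NULL) {
  if (freq_ghz <= 0 || linewidth <= 0) {
    stop("`freq_ghz` and `linewidth` must be positive", call. = FALSE)
  }
  if (field_max <= field_min || n_field < 2) {
    stop("field grid must contain at least two increasing points", call. = FALSE)
  }
  if (n_sublevels < 2) stop("`n_sublevels` must be >= 2", call. = FALSE)
  structure(
    list(
      freq_ghz = freq_ghz, linewidth = linewidth, g_iso = g_iso,
      field_min = field_min, field_max = field_max, n_field = n_field,
      n_theta = n_theta, n_phi = n_phi, n_sublevels = n_sublevels,
      temperature = temperature
    ),
    class = "spectrum_settings"
  )
}

field_grid <- function(settings) {
  seq(settings$field_min, settings$field_max, length.out = settings$n_field)
}

#' Orientation grid over the hemisphere
#'
#' Midpoint product grid in (theta, phi) with sin(theta) quadrature weights,
#' covering the upper hemisphere (sufficient by the inversion symmetry of
#' the spin Hamiltonian); weights sum to 1.
#'
#' @param n_theta,n_phi Node counts.
#' @return A tibble with columns `theta`, `phi`, `weight`.
#' @export
orientation_grid <- function(n_theta = 31, n_phi = 62) {
  stopifnot(n_theta >= 1, n_phi >= 1)
  theta <- (seq_len(n_theta) - 0.5) * (pi / 2) / n_theta
  phi <- (seq_len(n_phi) - 0.5) * (2 * pi) / n_phi
  grid <- expand.grid(theta = theta, phi = phi)
  w <- sin(grid$theta)
  tibble::tibble(theta = grid$theta, phi = grid$phi, weight = w / sum(w))
}

#' Golden-rule transition intensities at one field and orientation
#'
#' Given the eigen-decomposition of the (projected) spin Hamiltonian at a
#' fixed field and orientation, returns the contribution of every state
#' pair: the squared microwave matrix element averaged analytically over
#' the two polarizations of B1 perpendicular to B0, times a normalized
#' Gaussian in |E_k - E_n| - h nu of width `linewidth`. The overall
#' intensity scale is arbitrary (constant prefactors are dropped).
#'
#' This is the reference R implementation of the quantity the compiled
#' powder kernel accumulates; it is exposed for inspection and testing.
#'
#' @param values Eigenvalues in cm^-1 (ascending).
#' @param vectors Matrix of eigenvectors (columns, same order).
#' @param s_perp1,s_perp2 Spin-component operators (same basis as
#'   `vectors`) along two orthonormal directions perpendicular to B0.
#' @param settings A [spectrum_settings] (uses `freq_ghz`, `linewidth`,
#'   `temperature`).
#' @return A tibble with columns `n`, `k` (state indices, n < k),
#'   `delta_e_cm1`, `rho`, `amplitude` and `intensity` (= rho * amplitude *
#'   population weight).
#' @export
transition_intensity <- function(values, vectors, s_perp1, s_perp2, settings) {
  stopifnot(inherits(settings, "spectrum_settings"))
  quantum <- ghz_to_cm1(settings$freq_ghz)
  delta <- settings$linewidth
  m1 <- crossprod(Conj(vectors), s_perp1 %*% vectors)
  m2 <- crossprod(Conj(vectors), s_perp2 %*% vectors)
  nn <- length(values)
  pairs <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  n <- pairs[, 1]
  k <- pairs[, 2]
  de <- values[k] - values[n]
  x <- abs(de) - quantum
  rho <- exp(-x^2 / (2 * delta^2)) / sqrt(2 * pi * delta^2)
  amp <- 0.5 * (Mod(m1[pairs])^2 + Mod(m2[pairs])^2)
  pw <- 1
  if (!is.null(settings$temperature) && settings$temperature > 0) {
    pop <- exp(-(values - min(values)) / (KB_CM1_PER_K * settings$temperature))
    pop <- pop / sum(pop)
    pw <- pop[n] - pop[k]
  }
  tibble::tibble(
    n = n, k = k, delta_e_cm1 = de, rho = rho,
    amplitude = amp, intensity = rho * amp * pw
  )
}

# Zero-field projection shared by powder_spectrum() and level_diagram():
# exchange + optional ZFS, truncated to the lowest n sublevels, with the
# projected total-spin component operators.
projected_system <- function(system, couplings, zfs, n_sublevels) {
  H0 <- if (is.null(couplings)) {
    new_hamiltonian_term(
      matrix(0 + 0i, system$dim, system$dim), "exchange", system
    )
  } else {
    build_exchange(system, couplings)
  }
  if (!is.null(zfs)) H0 <- H0 + build_zfs(system, zfs)
  n_sublevels <- min(n_sublevels, system$dim)
  proj <- project_low_energy(H0, n_sublevels)
  tot <- total_spin_operators(system)
  list(
    h0 = diag(proj$values - proj$values[1]) + 0i,
    Sx = proj$project(tot$Sx),
    Sy = proj$project(tot$Sy),
    Sz = proj$project(tot$Sz),
    n = proj$n,
    zero_field = proj$values - proj$values[1]
  )
}

#' Powder-averaged EPR absorption spectrum
#'
#' Simulates the field-swept absorption spectrum of the exchange-coupled
#' cluster: the zero-field Hamiltonian (exchange + ZFS) is diagonalized
#' once and truncated to the lowest `n_sublevels` states; then for every
#' orientation node and field value the Zeeman term is added in the reduced
#' basis, the Hamiltonian re-diagonalized, and golden-rule transition
#' intensities accumulated with sin(theta) weights (see
#' [transition_intensity()] for the per-pair quantity). Absorption is in
#' arbitrary units; the spectrum is non-negative by construction.
#'
#' @param system A [spin_system].
#' @param couplings An [exchange_couplings], or `NULL` for an uncoupled
#'   (single-multiplet) system.
#' @param zfs A [zfs_model], or `NULL` for no anisotropy.
#' @param settings A [spectrum_settings].
#' @return A tibble of class `epr_spectrum` with columns `field_G`,
#'   `absorption` and `derivative` (centred finite difference). Attributes:
#'   `settings`, `n_sublevels_used`, `zero_field_levels`.
#' @export
#' @examples
#' \donttest{
#' fx <- fixture("closed_W1OH_D170axis")
#' sp <- powder_spectrum(fx$system, fx$couplings, fx$zfs, spectrum_settings())
#' effective_g(sp) # ~ 4.0
#' }
powder_spectrum <- function(system, couplings, zfs = NULL,
                            settings = spectrum_settings()) {
  stopifnot(inherits(settings, "spectrum_settings"))
  ps <- projected_system(system, couplings, zfs, settings$n_sublevels)
  grid <- orientation_grid(settings$n_theta, settings$n_phi)
  fields <- field_grid(settings)
  absorb <- powder_sweep_cpp(
    ps$h0, ps$Sx, ps$Sy, ps$Sz,
    grid$theta, grid$phi, grid$weight,
    fields,
    settings$g_iso * MU_B_CM1_PER_G,
    ghz_to_cm1(settings$freq_ghz),
    settings$linewidth,
    if (is.null(settings$temperature)) -1 else settings$temperature
  )
  out <- tibble::tibble(
    field_G = fields,
    absorption = as.numeric(absorb),
    derivative = finite_derivative(fields, as.numeric(absorb))
  )
  structure(out,
    class = c("epr_spectrum", class(out)),
    settings = settings,
    n_sublevels_used = ps$n,
    zero_field_levels = ps$zero_field
  )
}

finite_derivative <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' Effective g value of a spectral feature
#'
#' Reads off g = (h nu) / (muB * B*) with B* the field of the absorption
#' maximum (default) or the derivative zero-crossing between the extrema of
#' the first-derivative trace. The peak position is refined by parabolic
#' interpolation through the three grid points around the maximum.
#'
#' @param spectrum An `epr_spectrum`.
#' @param mode `"absorption_max"` or `"derivative_zero"`.
#' @return The dimensionless effective g (NA with a warning if the maximum
#'   sits on the grid boundary).
#' @export
effective_g <- function(spectrum, mode = c("absorption_max", "derivative_zero")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "epr_spectrum"))
  settings <- attr(spectrum, "settings")
  b <- spectrum$field_G
  a <- spectrum$absorption
  if (max(a) <= 0) stop("spectrum has no positive absorption", call. = FALSE)
  i <- which.max(a)
  if (i == 1 || i == length(a)) {
    warning("absorption maximum lies on the field-grid boundary; widen the sweep",
      call. = FALSE
    )
    return(NA_real_)
  }
  if (mode == "absorption_max") {
    b_star <- parabolic_peak(b[(i - 1):(i + 1)], a[(i - 1):(i + 1)])
  } else {
    d <- spectrum$derivative
    lo <- which.max(d)
    hi <- which.min(d)
    if (lo >= hi) {
      warning("no derivative-down-crossing between the derivative extrema",
        call. = FALSE
      )
      return(NA_real_)
    }
    seg <- lo:hi
    j <- seg[which(diff(sign(d[seg])) < 0)[1]]
    if (is.na(j)) {
      warning("no derivative zero-crossing found", call. = FALSE)
      return(NA_real_)
    }
    # linear interpolation of the zero crossing
    b_star <- b[j] - d[j] * (b[j + 1] - b[j]) / (d[j + 1] - d[j])
  }
  ghz_to_cm1(settings$freq_ghz) / (MU_B_CM1_PER_G * b_star)
}

#' Effective g at the resonance line position
#'
#' The Gaussian width of the lineshape stands in for unresolved hyperfine
#' broadening. Because a powder envelope is asymmetric, broadening shifts
#' its absorption maximum away from the underlying resonance feature, so
#' the g read at the maximum of the broadened spectrum depends on the
#' width. The line position — the quantity conventionally quoted as "the g
#' value" of a signal — is the mode of the resonance-field distribution,
#' which this function estimates by running the identical powder integral
#' with the lineshape width replaced by a small numerical resolution (so
#' each orientation contributes essentially at its resonance field) and
#' reading g at the resulting maximum. The estimate is stable under
#' halving or doubling of `resolution` and of the orientation grid.
#'
#' @param system,couplings,zfs,settings As in [powder_spectrum()].
#' @param resolution Numerical width in cm^-1 used in place of
#'   `settings$linewidth` (default 0.002, about one field-grid step at
#'   g ~ 4 for the default grid).
#' @return The dimensionless effective g at the line position.
#' @export
#' @examples
#' \donttest{
#' fx <- fixture("closed_W1OH_D170axis")
#' resonance_g(fx$system, fx$couplings, fx$zfs) # 4.00
#' }
resonance_g <- function(system, couplings, zfs = NULL,
                        settings = spectrum_settings(), resolution = 0.002) {
  narrow <- settings
  narrow$linewidth <- resolution
  sp <- powder_spectrum(system, couplings, zfs, narrow)
  effective_g(sp)
}

parabolic_peak <- function(x, y) {
  # vertex of the parabola through three points (equally spaced or not)
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0) {
    return(x[2])
  }
  (x[1] + x[2]) / 2 - d21 / (2 * curv)
}

#' Zeeman level diagram along a fixed field direction
#'
#' Eigenvalues of the projected Hamiltonian as a function of field magnitude
#' for a single field direction (e.g. B0 parallel to the ZFS z axis).
#' Levels are continuity-ordered across the sweep by maximal eigenvector
#' overlap with the previous field point, so avoided crossings track
#' adiabatically.
#'
#' @param system,couplings,zfs As in [powder_spectrum()].
#' @param field_axis `"x"`, `"y"`, `"z"` or a 3-vector (lab frame).
#' @param fields Field values in Gauss (default 0-6000 G, 121 points).
#' @param n_sublevels Sublevels retained.
#' @param g_iso Isotropic g value.
#' @return A tibble of class `level_diagram` with columns `field_G`, `level`
#'   (integer track id) and `energy_cm1`.
#' @export
level_diagram <- function(system, couplings, zfs = NULL, field_axis = "z",
                          fields = seq(0, 6000, length.out = 121),
                          n_sublevels = 6, g_iso = 2) {
  if (is.character(field_axis)) {
    field_axis <- switch(match.arg(field_axis, c("x", "y", "z")),
      x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1)
    )
  }
  u <- field_axis / sqrt(sum(field_axis^2))
  ps <- projected_system(system, couplings, zfs, n_sublevels)
  Su <- u[1] * ps$Sx + u[2] * ps$Sy + u[3] * ps$Sz
  n <- ps$n
  energies <- matrix(NA_real_, length(fields), n)
  prev <- NULL
  for (i in seq_along(fields)) {
    H <- ps$h0 + g_iso * MU_B_CM1_PER_G * fields[i] * Su
    eig <- eigen(H, symmetric = TRUE)
    vals <- rev(eig$values)
    vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
    if (!is.null(prev)) {
      ov <- Mod(crossprod(Conj(prev), vecs))^2
      assign_track <- apply(ov, 2, which.max)
      if (anyDuplicated(assign_track)) assign_track <- seq_len(n) # fall back to energy order
      ord <- order(assign_track)
      vals <- vals[ord]
      vecs <- vecs[, ord, drop = FALSE]
    }
    energies[i, ] <- vals
    prev <- vecs
  }
  out <- tibble::tibble(
    field_G = rep(fields, times = n),
    level = rep(seq_len(n), each = length(fields)),
    energy_cm1 = as.numeric(energies)
  )
  structure(out,
    class = c("level_diagram", class(out)),
    zero_field_levels = ps$zero_field, field_axis = u
  )
}
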