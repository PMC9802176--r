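#' Effective two-spin model of the cluster
#'
#' Reduction of the four-Mn system to two coupled spins: a cubane
#' super-spin S_A (default 9/2, the ferromagnetically aligned Mn(IV)3 cube)
#' and the dangling-Mn spin S_B (default 2 for Mn(III)), joined by a single
#' exchange coupling J_eff under `H = -2 J_eff S_A . S_B`. The anisotropy
#' sits on the dangler as a site-scheme ZFS tensor. Used to ask how strong
#' |J_eff| must be before the two-spin picture reproduces a given effective
#' g.
#'
#' @param s_cubane Cubane effective spin (default 9/2).
#' @param s_dangler Dangler spin (default 2).
#' @param j_eff Exchange coupling in cm^-1.
#' @param zfs A [zfs_model]; defaults to the site scheme on the dangler
#'   with d4 = -0.445 cm^-1, e4/d4 = 0.25.
#' @return A list of class `two_spin_model` with the assembled
#'   [spin_system] and [exchange_couplings].
#' @export
two_spin_model <- function(s_cubane = 9 / 2, s_dangler = 2, j_eff = -2.3,
                           zfs = NULL) {
  system <- spin_system(c(s_cubane, s_dangler))
  if (is.null(zfs)) {
    zfs <- zfs_model("site", D = -0.445, E_over_D = 0.25, site = 2)
  }
  structure(
    list(
      system = system,
      couplings = exchange_couplings(c("1-2" = j_eff)),
      j_eff = j_eff,
      zfs = zfs
    ),
    class = "two_spin_model"
  )
}

#' @export
print.two_spin_model <- function(x, ...) {
  cat(
    "<two_spin_model> S_A =", format(x$system$spins[1]),
    ", S_B =", format(x$system$spins[2]),
    ", J_eff =", format(x$j_eff), "cm^-1\n"
  )
  invisible(x)
}

#' Scan the effective g value over a grid of J_eff
#'
#' For each J_eff the two-spin powder spectrum is simulated and the
#' effective g read at the absorption maximum; the |J_eff| at which g first
#' reaches `g_target` (scanning from weak to strong coupling) is located by
#' linear interpolation on the (|J_eff|, g) curve.
#'
#' @param j_grid Monotone vector of J_eff values in cm^-1 (typically
#'   negative, antiferromagnetic cube-dangler coupling).
#' @param settings A [spectrum_settings].
#' @param g_target Threshold g (default 4).
#' @param s_cubane,s_dangler,zfs Passed to [two_spin_model()].
#' @return A tibble of class `two_spin_scan` with columns `j_eff`,
#'   `abs_j_eff`, `g`. Attribute `j_eff_threshold` holds the interpolated
#'   |J_eff| where g first reaches `g_target` (NA if the grid does not
#'   bracket it).
#' @export
two_spin_g_scan <- function(j_grid, settings = spectrum_settings(),
                            g_target = 4, s_cubane = 9 / 2, s_dangler = 2,
                            zfs = NULL) {
  if (is.unsorted(j_grid) && is.unsorted(rev(j_grid))) {
    stop("`j_grid` must be monotone", call. = FALSE)
  }
  g <- vapply(j_grid, function(j) {
    m <- two_spin_model(s_cubane, s_dangler, j_eff = j, zfs = zfs)
    sp <- powder_spectrum(m$system, m$couplings, m$zfs, settings)
    suppressWarnings(effective_g(sp))
  }, numeric(1))
  out <- tibble::tibble(j_eff = j_grid, abs_j_eff = abs(j_grid), g = g)
  out <- out[order(out$abs_j_eff), ]
  thr <- NA_real_
  cross <- which(!is.na(out$g[-1]) & !is.na(out$g[-nrow(out)]) &
    (out$g[-nrow(out)] - g_target) * (out$g[-1] - g_target) <= 0)
  if (length(cross)) {
    i <- cross[1]
    g1 <- out$g[i]
    g2 <- out$g[i + 1]
    thr <- out$abs_j_eff[i] +
      (g_target - g1) * (out$abs_j_eff[i + 1] - out$abs_j_eff[i]) / (g2 - g1)
  }
  structure(out,
    class = c("two_spin_scan", class(out)),
    j_eff_threshold = thr, g_target = g_target
  )
}
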