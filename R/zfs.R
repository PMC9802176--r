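#' Zero-field-splitting model
#'
#' Parameterizes the anisotropy term of the spin Hamiltonian in one of two
#' schemes compared for the Mn4CaO5 cluster:
#' \describe{
#'   \item{total}{the whole cluster carries one ZFS tensor acting on the
#'     total spin: \eqn{D[\hat S_{z,tot}^2 - \hat S_{tot}^2/3] +
#'     E(\hat S_{x,tot}^2 - \hat S_{y,tot}^2)};}
#'   \item{site}{a single Mn site (by default the dangling Mn4(III)) carries
#'     the tensor, with onsite parameters d4, e4 in place of D, E.}
#' }
#' The axial parameter `D` and rhombic parameter `E` are in cm^-1. On
#' construction the tensor is canonicalized to the standard rhombicity
#' convention 0 <= |E/D| <= 1/3 by permuting principal axes; the permutation
#' is folded into the stored orientation so the physical tensor is unchanged.
#'
#' @param scheme `"total"` or `"site"`.
#' @param D Axial ZFS parameter in cm^-1 (d4 for the site scheme).
#' @param E Rhombic ZFS parameter in cm^-1 (e4 for the site scheme). Give
#'   either `E` or `E_over_D`.
#' @param E_over_D Rhombicity E/D, used when `E` is missing.
#' @param site Site index carrying the tensor when `scheme = "site"`.
#' @param euler Z-Y-Z Euler angles (radians) of the tensor principal frame in
#'   the laboratory frame; default identity (principal frame = lab frame).
#' @return An object of class `zfs_model` with elements `scheme`, `D`, `E`,
#'   `site`, `rotation` (3x3 proper rotation whose columns are the principal
#'   axes in the lab frame).
#' @export
#' @examples
#' zfs_model("total", D = -0.445, E_over_D = 0.25)
zfs_model <- function(scheme = c("total", "site"), D = 0, E = NULL,
                      E_over_D = NULL, site = NULL, euler = c(0, 0, 0)) {
  scheme <- match.arg(scheme)
  if (is.null(E)) {
    E <- if (is.null(E_over_D)) 0 else E_over_D * D
  }
  stopifnot(is.finite(D), is.finite(E), length(euler) == 3)
  if (scheme == "site" && is.null(site)) {
    stop("scheme = \"site\" requires a `site` index", call. = FALSE)
  }
  R <- euler_zyz(euler[1], euler[2], euler[3])
  can <- canonicalize_zfs(D, E, R)
  structure(
    list(
      scheme = scheme, D = can$D, E = can$E, site = site,
      rotation = can$rotation, euler_input = euler
    ),
    class = "zfs_model"
  )
}

#' @export
print.zfs_model <- function(x, ...) {
  ratio <- if (x$D != 0) sprintf(", E/D = %.4g", x$E / x$D) else ""
  cat(
    "<zfs_model> scheme = ", x$scheme,
    if (x$scheme == "site") paste0(" (site ", x$site, ")") else "",
    ": D = ", format(x$D), " cm^-1, E = ", format(x$E), " cm^-1", ratio, "\n",
    sep = ""
  )
  invisible(x)
}

# Active Z-Y-Z rotation matrix.
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) {
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Canonicalize (D, E, rotation) to 0 <= E/D <= 1/3 (E >= 0 taken with the
# sign convention that E/D is non-negative when D != 0). Works through the
# traceless principal values (-D/3 + E, -D/3 - E, 2D/3): the z axis is
# reassigned to the principal value of largest magnitude and x/y ordered so
# the rhombicity is non-negative; axis permutations are proper rotations
# folded into `rotation`.
canonicalize_zfs <- function(D, E, rotation) {
  if (D == 0 && E == 0) {
    return(list(D = 0, E = 0, rotation = rotation))
  }
  pv <- c(x = -D / 3 + E, y = -D / 3 - E, z = 2 * D / 3)
  perms <- list(
    c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
    c(2, 1, 3), c(1, 3, 2), c(3, 2, 1)
  )
  best <- NULL
  for (p in perms) {
    v <- pv[p] # v = principal values assigned to new (x, y, z)
    Dn <- 1.5 * v[3]
    En <- (v[1] - v[2]) / 2
    if (abs(v[3]) >= max(abs(v)) - 1e-12 &&
      (Dn == 0 || En / Dn >= -1e-12)) {
      best <- list(perm = p, D = unname(Dn), E = unname(En))
      break
    }
  }
  stopifnot(!is.null(best)) # one of the six assignments always qualifies
  P <- matrix(0, 3, 3)
  P[cbind(best$perm, 1:3)] <- 1 # new axis k is old axis perm[k]
  if (det(P) < 0) P[, 2] <- -P[, 2] # keep the rotation proper
  list(D = best$D, E = best$E, rotation = rotation %*% P)
}

#' Build the zero-field-splitting Hamiltonian
#'
#' Constructs the traceless ZFS term for either scheme of [zfs_model],
#' using operators along the tensor's principal axes (columns of the stored
#' rotation). The zero-field spectrum is invariant under the orientation;
#' the orientation only matters once a field direction is singled out.
#'
#' @param system A [spin_system].
#' @param zfs A [zfs_model].
#' @return A `hamiltonian_term` of kind `"zfs"` (Hermitian, traceless).
#' @export
build_zfs <- function(system, zfs) {
  stopifnot(inherits(system, "spin_system"), inherits(zfs, "zfs_model"))
  if (zfs$scheme == "site") {
    if (is.null(zfs$site) || zfs$site < 1 || zfs$site > length(system$spins)) {
      stop("site scheme requires a valid `site` index", call. = FALSE)
    }
    ops <- site_operators(system)[[zfs$site]]
    S <- list(Sx = ops$Sx, Sy = ops$Sy, Sz = ops$Sz)
    s <- system$spins[zfs$site]
    S2 <- diag(s * (s + 1) + 0i, system$dim)
  } else {
    S <- total_spin_operators(system)
    S2 <- total_spin_squared(system) + 0i
  }
  R <- zfs$rotation
  axis_op <- function(k) R[1, k] * S$Sx + R[2, k] * S$Sy + R[3, k] * S$Sz
  Sxp <- axis_op(1)
  Syp <- axis_op(2)
  Szp <- axis_op(3)
  H <- zfs$D * (Szp %*% Szp - S2 / 3) +
    zfs$E * (Sxp %*% Sxp - Syp %*% Syp)
  new_hamiltonian_term(H, "zfs", system)
}
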