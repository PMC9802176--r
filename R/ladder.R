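#' Zero-field spin ladder of an exchange Hamiltonian
#'
#' Diagonalizes an exchange-only Hamiltonian exactly in the full product
#' space, groups eigenstates into degenerate levels, and labels each level
#' with its total spin S from the expectation value of S^2_total (which the
#' exchange Hamiltonian commutes with, so every state has a sharp S). The
#' lowest level defines the ground-state spin — the quantity that decides
#' whether a cluster conformation can carry the high-spin g ~ 4 EPR signal.
#'
#' @param system A [spin_system], or a `hamiltonian_term` of kind
#'   `"exchange"` (in which case `couplings` is ignored).
#' @param couplings An [exchange_couplings] for `system`.
#' @param tol Energy tolerance (cm^-1) for grouping states into one level.
#' @return A tibble of class `spin_ladder` with columns `energy_cm1`
#'   (relative to the ground level), `S` (half-integer label), `degeneracy`
#'   and `label_residual` (|<S^2> - S(S+1)| of the worst state in the level).
#'   Attribute `ground_spin` holds the S of the lowest level.
#' @export
#' @examples
#' sys <- spin_system(oxidation = "IV,IV,IV,III")
#' j <- exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6))
#' ground_spin(spin_ladder(sys, j)) # 5/2
spin_ladder <- function(system, couplings = NULL, tol = 1e-6) {
  if (inherits(system, "hamiltonian_term")) {
    term <- system
    system <- term$system
    if (!term$kind %in% "exchange") {
      stop("spin_ladder() needs an exchange-only Hamiltonian", call. = FALSE)
    }
  } else {
    term <- build_exchange(system, couplings)
  }
  H <- Re(term$matrix) # exchange is real in the product basis
  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  S2 <- total_spin_squared(system)
  s2_exp <- colSums(vecs * (S2 %*% vecs))
  s_cont <- (-1 + sqrt(1 + 4 * s2_exp)) / 2
  s_lab <- round(2 * s_cont) / 2
  resid <- abs(s2_exp - s_lab * (s_lab + 1))
  if (max(resid) > 1e-3) {
    stop(
      "total-spin labelling residual ", format(max(resid)),
      " > 1e-3: the Hamiltonian mixes total-spin multiplets ",
      "(a non-exchange term leaked in?)",
      call. = FALSE
    )
  }
  grp <- cumsum(c(TRUE, diff(vals) > tol))
  lev <- tibble::tibble(
    energy_cm1 = as.numeric(tapply(vals, grp, min)) - min(vals),
    S = as.numeric(tapply(s_lab, grp, function(x) x[1])),
    degeneracy = as.integer(tapply(vals, grp, length)),
    label_residual = as.numeric(tapply(resid, grp, max))
  )
  structure(lev,
    class = c("spin_ladder", class(lev)),
    ground_spin = lev$S[1]
  )
}

#' Ground-state total spin of a ladder
#'
#' @param ladder A `spin_ladder`.
#' @return The half-integer S of the lowest level.
#' @export
ground_spin <- function(ladder) {
  stopifnot(inherits(ladder, "spin_ladder"))
  attr(ladder, "ground_spin")
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.spin_ladder <- function(x, ...) {
  tibble::tibble(
    ground_spin = attr(x, "ground_spin"),
    n_levels = nrow(x),
    first_gap_cm1 = if (nrow(x) > 1) x$energy_cm1[2] else NA_real_,
    max_label_residual = max(x$label_residual)
  )
}

#' Project onto the low-energy zero-field subspace
#'
#' Diagonalizes the zero-field Hamiltonian (exchange + ZFS) once and retains
#' the lowest `n_sublevels` eigenstates. EPR transitions at X band involve
#' only sublevels within ~1 cm^-1 windows of each other, so field sweeps can
#' be run in this reduced basis at a small fraction of the full-space cost.
#' If the requested cut would split a degenerate level, `n_sublevels` is
#' extended to the multiplet boundary with a warning.
#'
#' @param term A `hamiltonian_term` (typically exchange + zfs).
#' @param n_sublevels Number of lowest eigenstates to keep (>= 1).
#' @param degeneracy_tol Gap below which adjacent states count as degenerate.
#' @return A list with `values` (retained zero-field eigenvalues, cm^-1),
#'   `basis` (dim x n matrix of eigenvectors), `n` (possibly extended), and
#'   `project(M)`, a function projecting any operator matrix (or
#'   `hamiltonian_term`) into the retained basis.
#' @export
project_low_energy <- function(term, n_sublevels, degeneracy_tol = 1e-6) {
  stopifnot(inherits(term, "hamiltonian_term"))
  d <- nrow(term$matrix)
  if (!is.numeric(n_sublevels) || n_sublevels < 1) {
    stop("`n_sublevels` must be a positive count", call. = FALSE)
  }
  n_sublevels <- as.integer(n_sublevels)
  if (n_sublevels > d) {
    stop("`n_sublevels` exceeds the Hilbert dimension ", d, call. = FALSE)
  }
  eig <- eigen(term$matrix, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  n <- n_sublevels
  while (n < d && vals[n + 1] - vals[n] < degeneracy_tol) n <- n + 1L
  if (n != n_sublevels) {
    warning(
      "n_sublevels = ", n_sublevels, " splits a degenerate level; ",
      "extended to ", n, call. = FALSE
    )
  }
  basis <- vecs[, seq_len(n), drop = FALSE]
  project <- function(M) {
    if (inherits(M, "hamiltonian_term")) M <- M$matrix
    crossprod(Conj(basis), M %*% basis)
  }
  list(values = vals[seq_len(n)], basis = basis, n = n, project = project)
}
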