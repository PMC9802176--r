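#' Pairwise exchange couplings
#'
#' Holds the Heisenberg exchange couplings J_ij (cm^-1) for every unordered
#' site pair, under the convention
#' \deqn{H_{ex} = -\sum_{i<j} 2 J_{ij} \, \hat S_i \cdot \hat S_j,}
#' so a positive J is ferromagnetic (favours parallel spins). This sign
#' convention matters: published J values under `+J S.S` or `-J S.S`
#' conventions must be rescaled before use.
#'
#' @param values Named numeric vector with names `"i-j"` (i < j), e.g.
#'   `c("1-2" = 24.1, ...)`, or an unnamed numeric vector of length
#'   n(n-1)/2 taken in lexicographic pair order (1-2, 1-3, 1-4, 2-3, ...).
#' @param n_sites Number of sites; inferred from the vector length or pair
#'   names when omitted.
#' @return An object of class `exchange_couplings`: a named numeric vector
#'   with attribute `n_sites`.
#' @export
#' @examples
#' exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6)) # Mn 4-site order
exchange_couplings <- function(values, n_sites = NULL) {
  stopifnot(is.numeric(values))
  if (!all(is.finite(values))) stop("couplings must be finite", call. = FALSE)
  if (is.null(names(values))) {
    if (is.null(n_sites)) {
      # invert n(n-1)/2 = length
      n_sites <- (1 + sqrt(1 + 8 * length(values))) / 2
      if (abs(n_sites - round(n_sites)) > 1e-9) {
        stop("length of `values` is not n(n-1)/2 for any n; give names or n_sites",
          call. = FALSE
        )
      }
      n_sites <- round(n_sites)
    }
    names(values) <- pair_names(n_sites)
  } else {
    idx <- do.call(rbind, lapply(strsplit(names(values), "-"), as.integer))
    if (any(is.na(idx)) || any(idx[, 1] >= idx[, 2])) {
      stop("pair names must be \"i-j\" with i < j", call. = FALSE)
    }
    if (is.null(n_sites)) n_sites <- max(idx)
    values <- values[order(idx[, 1], idx[, 2])]
  }
  expected <- pair_names(n_sites)
  if (!identical(names(values), expected)) {
    missing <- setdiff(expected, names(values))
    stop(
      "incomplete couplings: missing pair(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(as.numeric(`names<-`(values, expected)),
    names = expected, n_sites = n_sites, class = "exchange_couplings"
  )
}

#' Lexicographic pair labels for n sites
#'
#' @param n_sites Number of sites.
#' @return Character vector `"1-2", "1-3", ...` of length n(n-1)/2.
#' @export
pair_names <- function(n_sites) {
  if (n_sites < 2) stop("need at least two sites", call. = FALSE)
  p <- utils::combn(n_sites, 2)
  paste0(p[1, ], "-", p[2, ])
}

pair_indices <- function(couplings) {
  do.call(rbind, lapply(strsplit(names(couplings), "-"), as.integer))
}

#' @export
print.exchange_couplings <- function(x, ...) {
  cat("<exchange_couplings> (cm^-1, H = -sum 2J S.S)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.exchange_couplings <- function(x, ...) {
  tibble::tibble(pair = names(x), value_cm1 = as.numeric(x))
}

#' Sum a subset of couplings
#'
#' Convenience for composite quantities such as the dangler sum
#' J14 + J24 + J34 used to characterise cube-dangler coupling strength.
#'
#' @param couplings An [exchange_couplings] object.
#' @param pairs Character vector of pair names, e.g. `c("1-4", "2-4", "3-4")`.
#' @return The arithmetic sum in cm^-1 (0 for an empty list).
#' @export
#' @examples
#' j <- exchange_couplings(c(24.1, 7.6, 1.0, 24.2, 1.8, -44.6))
#' coupling_sum(j, c("1-4", "2-4", "3-4")) # -41.8
coupling_sum <- function(couplings, pairs) {
  if (length(pairs) == 0) {
    return(0)
  }
  unknown <- setdiff(pairs, names(couplings))
  if (length(unknown)) {
    stop("unknown pair(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(as.numeric(couplings[pairs]))
}

new_hamiltonian_term <- function(matrix, kind, system) {
  structure(
    list(matrix = matrix, kind = kind, system = system),
    class = "hamiltonian_term"
  )
}

#' @export
print.hamiltonian_term <- function(x, ...) {
  cat(
    "<hamiltonian_term> kind =", x$kind, ", dim =",
    nrow(x$matrix), "x", ncol(x$matrix), "(cm^-1)\n"
  )
  invisible(x)
}

#' @export
`+.hamiltonian_term` <- function(e1, e2) {
  stopifnot(inherits(e1, "hamiltonian_term"), inherits(e2, "hamiltonian_term"))
  new_hamiltonian_term(e1$matrix + e2$matrix, "sum", e1$system)
}

#' Build the Heisenberg exchange Hamiltonian
#'
#' Assembles \eqn{-\sum_{i<j} 2 J_{ij} \hat S_i \cdot \hat S_j} in the full
#' product space by Kronecker embedding of the site operators. The result
#' commutes with the total spin, so its eigenstates form (2S+1)-degenerate
#' multiplets — the spin ladder.
#'
#' @param system A [spin_system].
#' @param couplings An [exchange_couplings] covering every pair of `system`.
#' @return A `hamiltonian_term` of kind `"exchange"` (Hermitian, real).
#' @export
build_exchange <- function(system, couplings) {
  stopifnot(inherits(system, "spin_system"))
  if (!inherits(couplings, "exchange_couplings")) {
    couplings <- exchange_couplings(couplings, n_sites = length(system$spins))
  }
  n <- length(system$spins)
  if (attr(couplings, "n_sites") != n) {
    stop("couplings are for ", attr(couplings, "n_sites"), " sites but system has ",
      n,
      call. = FALSE
    )
  }
  ops <- site_operators(system)
  d <- system$dim
  H <- matrix(0 + 0i, d, d)
  idx <- pair_indices(couplings)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    dot <- ops[[i]]$Sz %*% ops[[j]]$Sz +
      (ops[[i]]$Sp %*% ops[[j]]$Sm + ops[[i]]$Sm %*% ops[[j]]$Sp) / 2
    H <- H - 2 * couplings[[k]] * dot
  }
  new_hamiltonian_term(H, "exchange", system)
}

#' Build the Zeeman Hamiltonian
#'
#' Isotropic electronic Zeeman term \eqn{g \mu_B \mathbf{B}_0 \cdot \hat
#' S_{total}} with a single scalar g shared by all Mn sites (the standard
#' approximation for Mn(III)/Mn(IV) clusters at X band, g = 2).
#'
#' @param system A [spin_system].
#' @param b0 Magnetic field 3-vector in Gauss (laboratory frame).
#' @param g_iso Isotropic g value (default 2).
#' @return A `hamiltonian_term` of kind `"zeeman"` in cm^-1.
#' @export
build_zeeman <- function(system, b0, g_iso = 2) {
  stopifnot(inherits(system, "spin_system"))
  b0 <- as.numeric(b0)
  if (length(b0) != 3 || !all(is.finite(b0))) {
    stop("`b0` must be a finite 3-vector in Gauss", call. = FALSE)
  }
  tot <- total_spin_operators(system)
  H <- g_iso * MU_B_CM1_PER_G *
    (b0[1] * tot$Sx + b0[2] * tot$Sy + b0[3] * tot$Sz)
  new_hamiltonian_term(H, "zeeman", system)
}
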