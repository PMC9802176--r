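#' Declare an exchange-coupled spin system
#'
#' A spin system is an ordered set of local spin magnitudes, one per
#' paramagnetic site. For the S2-state Mn4CaO5 cluster the magnitudes follow
#' the Mn oxidation pattern: Mn(IV) carries s = 3/2 and Mn(III) carries s = 2,
#' so the closed-cubane pattern (IV, IV, IV, III) gives spins
#' (3/2, 3/2, 3/2, 2) and a 320-dimensional product Hilbert space.
#'
#' @param spins Numeric vector of positive half-integer spin magnitudes,
#'   one per site (Mn1..Mn4 order for the cluster). Ignored if `oxidation`
#'   is supplied.
#' @param oxidation Optional character vector (or single comma-separated
#'   string) of oxidation tags `"III"`/`"IV"`, mapped as IV -> 3/2,
#'   III -> 2.
#' @return An object of class `spin_system`: a list with elements `spins`,
#'   `oxidation` (possibly `NULL`) and `dim` (the product-space dimension).
#' @export
#' @examples
#' spin_system(oxidation = "IV,IV,IV,III")
#' spin_system(c(3 / 2, 3 / 2, 3 / 2, 2))
spin_system <- function(spins = NULL, oxidation = NULL) {
  if (!is.null(oxidation)) {
    if (length(oxidation) == 1L && grepl(",", oxidation)) {
      oxidation <- trimws(strsplit(oxidation, ",")[[1]])
    }
    if (!all(oxidation %in% c("III", "IV"))) {
      stop("oxidation tags must be \"III\" or \"IV\"", call. = FALSE)
    }
    mapped <- ifelse(oxidation == "IV", 3 / 2, 2)
    if (!is.null(spins) && !isTRUE(all.equal(unname(spins), mapped))) {
      stop("`spins` is inconsistent with `oxidation` (IV -> 3/2, III -> 2)",
        call. = FALSE
      )
    }
    spins <- mapped
  }
  if (is.null(spins) || length(spins) == 0) {
    stop("supply `spins` or `oxidation`", call. = FALSE)
  }
  check_half_integer_spin(spins)
  structure(
    list(
      spins = as.numeric(spins),
      oxidation = oxidation,
      dim = prod(2 * spins + 1)
    ),
    class = "spin_system"
  )
}

check_half_integer_spin <- function(s) {
  ok <- is.numeric(s) & is.finite(s) & s > 0 & abs(2 * s - round(2 * s)) < 1e-9
  if (!all(ok)) {
    stop("spin magnitudes must be positive multiples of 1/2", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.spin_system <- function(x, ...) {
  lab <- if (is.null(x$oxidation)) "" else paste0(" (", paste(x$oxidation, collapse = ","), ")")
  cat(
    "<spin_system> ", length(x$spins), " sites", lab, ": s = ",
    paste(format(x$spins), collapse = ", "),
    "; Hilbert dimension ", x$dim, "\n",
    sep = ""
  )
  invisible(x)
}

#' Single-site angular-momentum matrices
#'
#' Standard dense spin matrices for one site of magnitude `s`, in units of
#' hbar, built from the ladder operators in the |s, m> basis ordered
#' m = s, s-1, ..., -s. They satisfy `[Sx, Sy] = i Sz` and cyclic
#' permutations.
#'
#' @param s Positive half-integer spin magnitude.
#' @return A list with complex matrices `Sx`, `Sy`, `Sz`, `Sp` (raising) and
#'   `Sm` (lowering), each of dimension `2s + 1`.
#' @export
#' @examples
#' site_spin_operators(1 / 2)$Sz # diag(1/2, -1/2)
site_spin_operators <- function(s) {
  check_half_integer_spin(s)
  m <- seq(s, -s)
  n <- length(m)
  Sz <- diag(m, n, n)
  Sp <- matrix(0, n, n)
  # S+ |s, m> = sqrt(s(s+1) - m(m+1)) |s, m+1>; basis is descending in m,
  # so the raising operator populates the superdiagonal.
  if (n > 1) {
    k <- seq_len(n - 1)
    Sp[cbind(k, k + 1)] <- sqrt(s * (s + 1) - m[k + 1] * (m[k + 1] + 1))
  }
  Sm <- t(Sp)
  Sx <- (Sp + Sm) / 2
  Sy <- (Sp - Sm) / (2i)
  list(
    Sx = Sx + 0i, Sy = Sy, Sz = Sz + 0i,
    Sp = Sp + 0i, Sm = Sm + 0i
  )
}

# Embed a single-site operator into the product space by Kronecker products
# with identities on the remaining sites.
embed_site_operator <- function(system, site, op) {
  dims <- 2 * system$spins + 1
  out <- matrix(1 + 0i, 1, 1)
  for (k in seq_along(dims)) {
    blk <- if (k == site) op else diag(1 + 0i, dims[k])
    out <- kronecker(out, blk)
  }
  out
}

# All embedded site operators; real parts are kept complex for uniformity.
# Returns list indexed [[site]]$Sx etc.
site_operators <- function(system) {
  lapply(seq_along(system$spins), function(i) {
    ops <- site_spin_operators(system$spins[i])
    lapply(ops, function(op) embed_site_operator(system, i, op))
  })
}

# Total-spin component operators (sum over sites) in the product space.
total_spin_operators <- function(system, ops = site_operators(system)) {
  add <- function(name) Reduce(`+`, lapply(ops, `[[`, name))
  list(Sx = add("Sx"), Sy = add("Sy"), Sz = add("Sz"))
}

# S^2_total as a real symmetric matrix:
# S^2 = sum_i s_i(s_i+1) I + 2 sum_{i<j} S_i . S_j, with the dot product
# written via ladder operators so everything stays real.
total_spin_squared <- function(system, ops = site_operators(system)) {
  n <- length(system$spins)
  d <- system$dim
  out <- diag(sum(system$spins * (system$spins + 1)), d, d)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      out <- out + 2 * Re(
        ops[[i]]$Sz %*% ops[[j]]$Sz +
          (ops[[i]]$Sp %*% ops[[j]]$Sm + ops[[i]]$Sm %*% ops[[j]]$Sp) / 2
      )
    }
  }
  out
}
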