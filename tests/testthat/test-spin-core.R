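test_that("single-site operators satisfy the angular-momentum algebra", {
  for (s in c(1 / 2, 1, 3 / 2, 2, 5 / 2)) {
    ops <- site_spin_operators(s)
    n <- 2 * s + 1
    expect_equal(dim(ops$Sx), c(n, n))
    expect_equal(Re(diag(ops$Sz)), seq(s, -s))
    comm <- ops$Sx %*% ops$Sy - ops$Sy %*% ops$Sx - 1i * ops$Sz
    expect_lt(max(Mod(comm)), 1e-12)
    casimir <- ops$Sx %*% ops$Sx + ops$Sy %*% ops$Sy + ops$Sz %*% ops$Sz
    expect_equal(Re(diag(casimir)), rep(s * (s + 1), n), tolerance = 1e-12)
  }
  expect_error(site_spin_operators(0.3), "multiples of 1/2")
  expect_error(site_spin_operators(-1), "multiples of 1/2")
})

test_that("spin-1/2 operators are the Pauli matrices over two", {
  ops <- site_spin_operators(1 / 2)
  expect_equal(Re(ops$Sz), diag(c(1 / 2, -1 / 2)), tolerance = 1e-15)
  expect_equal(Re(ops$Sx), matrix(c(0, 1 / 2, 1 / 2, 0), 2), tolerance = 1e-15)
})

test_that("spin system validates its spins and dimension", {
  sys <- closed_system()
  expect_equal(sys$spins, c(3 / 2, 3 / 2, 3 / 2, 2))
  expect_equal(sys$dim, 320)
  expect_error(spin_system(c(0.4, 1)), "multiples of 1/2")
  expect_error(spin_system(oxidation = "IV,II"), "III")
  expect_error(
    spin_system(c(2, 2, 2, 2), oxidation = "IV,IV,IV,III"),
    "inconsistent"
  )
})

test_that("exchange term: Hermitian, commutes with total spin, Lande ladder", {
  # two-site closed form E(S) = -J [S(S+1) - s1(s1+1) - s2(s2+1)]
  cases <- list(
    list(s = c(1 / 2, 1 / 2), J = 5),
    list(s = c(3 / 2, 2), J = -44.6),
    list(s = c(1, 3 / 2), J = 2.7)
  )
  for (cs in cases) {
    sys <- spin_system(cs$s)
    H <- build_exchange(sys, exchange_couplings(c("1-2" = cs$J)))
    expect_hermitian(H)
    vals <- sort(eigen(H$matrix, symmetric = TRUE, only.values = TRUE)$values)
    s1 <- cs$s[1]
    s2 <- cs$s[2]
    S_range <- seq(abs(s1 - s2), s1 + s2)
    lande <- -cs$J * (S_range * (S_range + 1) - s1 * (s1 + 1) - s2 * (s2 + 1))
    expected <- sort(rep(lande, times = 2 * S_range + 1))
    expect_equal(vals, expected, tolerance = 1e-9)
  }
  # singlet-triplet gap 2J for two spins 1/2, J = +5
  sys2 <- spin_system(c(1 / 2, 1 / 2))
  v <- sort(eigen(build_exchange(sys2, c(5))$matrix,
    symmetric = TRUE, only.values = TRUE
  )$values)
  expect_equal(v[4] - v[1], 10, tolerance = 1e-10)
})

test_that("exchange Hamiltonian commutes with S^2 and Sz of the total spin", {
  sys <- closed_system()
  H <- build_exchange(sys, j_closed_d170())$matrix
  S2 <- total_spin_squared(sys)
  tot <- oecspin:::total_spin_operators(sys)
  nrm <- max(Mod(H))
  expect_lt(max(Mod(H %*% S2 - S2 %*% H)), 1e-8 * nrm)
  expect_lt(max(Mod(H %*% tot$Sz - tot$Sz %*% H)), 1e-8 * nrm)
})

test_that("product-state expectation of the exchange operator is classical", {
  sys <- closed_system()
  H <- build_exchange(sys, j_closed_d170())$matrix
  # |+++-> = all sites at maximal |m|, site 4 anti-aligned: basis index of
  # (m1,m2,m3,m4) = (3/2, 3/2, 3/2, -2) in the kron ordering
  dims <- 2 * sys$spins + 1
  idx <- 1 + ((1 - 1) * dims[2] + (1 - 1)) * dims[3] * dims[4] +
    (1 - 1) * dims[4] + (dims[4] - 1)
  e <- Re(H[idx, idx])
  expect_equal(e, -502.35, tolerance = 1e-9)
  # all sign patterns, random couplings: quantum diagonal equals Ising energy
  j <- random_couplings(seed = 42, scale = 10)
  Hr <- build_exchange(sys, j)$matrix
  for (signs in canonical_configurations()$signs) {
    sigma <- oecspin:::parse_signs(signs)
    pos <- ifelse(sigma > 0, 1, dims) # first basis state is m = +s, last m = -s
    k <- ((pos[1] - 1) * dims[2] * dims[3] * dims[4]) +
      ((pos[2] - 1) * dims[3] * dims[4]) + ((pos[3] - 1) * dims[4]) + pos[4]
    expect_equal(Re(Hr[k, k]),
      classical_config_energy(j, sys, signs),
      tolerance = 1e-9
    )
  }
})

test_that("missing pairs and zero couplings are handled", {
  sys <- closed_system()
  expect_error(
    exchange_couplings(c("1-2" = 1, "1-3" = 2), n_sites = 4),
    "missing pair"
  )
  H0 <- build_exchange(sys, exchange_couplings(rep(0, 6)))
  expect_equal(max(Mod(H0$matrix)), 0)
})

test_that("zeeman term is linear in field and matches the resonance closed form", {
  sys <- spin_system(1 / 2)
  b <- resonance_field(2, 9.50)
  H <- build_zeeman(sys, c(0, 0, b), g_iso = 2)
  split <- diff(range(Re(eigen(H$matrix, symmetric = TRUE, only.values = TRUE)$values)))
  expect_equal(split, ghz_to_cm1(9.50), tolerance = 1e-10)
  # zero field -> zero matrix; doubling the field doubles the eigenvalues
  expect_equal(max(Mod(build_zeeman(sys, c(0, 0, 0))$matrix)), 0)
  H2 <- build_zeeman(sys, c(0, 0, 2 * b), g_iso = 2)
  expect_equal(H2$matrix, 2 * H$matrix, tolerance = 1e-12)
  H3 <- build_zeeman(sys, c(0, 0, b), g_iso = 4)
  expect_equal(H3$matrix, 2 * H$matrix, tolerance = 1e-12)
  expect_error(build_zeeman(sys, c(1, 2)), "3-vector")
})

test_that("zfs term is traceless, Hermitian, orientation-invariant at zero field", {
  sys <- closed_system()
  zfs <- zfs_total_default()
  H <- build_zfs(sys, zfs)
  expect_hermitian(H)
  expect_lt(Mod(sum(diag(H$matrix))), 1e-8)
  # spectrum does not depend on the Euler orientation
  v0 <- eigen(H$matrix, symmetric = TRUE, only.values = TRUE)$values
  zrot <- zfs_model("total",
    D = -0.445, E_over_D = 0.25,
    euler = c(0.3, 1.1, -0.7)
  )
  v1 <- eigen(build_zfs(sys, zrot)$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(v0, v1, tolerance = 1e-8)
  # D = E = 0 -> zero matrix
  expect_equal(max(Mod(build_zfs(sys, zfs_model("total", D = 0))$matrix)), 0)
  # site scheme requires a site
  expect_error(zfs_model("site", D = -0.445), "site")
})

test_that("total-scheme axial ZFS splits a pure S=5/2 multiplet as D m^2", {
  sys <- spin_system(5 / 2)
  D <- -0.445
  H <- build_zfs(sys, zfs_model("total", D = D))
  v <- sort(eigen(H$matrix, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- diff(unique(round(v, 9)))
  # |m| = 5/2, 3/2, 1/2 levels: spacings 4|D| then 2|D| from the bottom
  expect_equal(sort(abs(gaps)), c(2 * abs(D), 4 * abs(D)), tolerance = 1e-9)
})

test_that("rhombicity canonicalization enforces 0 <= E/D <= 1/3", {
  z <- zfs_model("total", D = 1, E = 0.8) # |E/D| > 1/3 input
  expect_true(abs(z$E / z$D) <= 1 / 3 + 1e-12)
  expect_gte(z$E / z$D, 0)
  # canonicalization must not change the physical tensor spectrum
  sys <- spin_system(5 / 2)
  raw <- function(D, E) {
    ops <- site_spin_operators(5 / 2)
    D * (ops$Sz %*% ops$Sz - (5 / 2 * 7 / 2 / 3) * diag(6)) +
      E * (ops$Sx %*% ops$Sx - ops$Sy %*% ops$Sy)
  }
  v_raw <- sort(Re(eigen(raw(1, 0.8), only.values = TRUE)$values))
  v_can <- sort(eigen(build_zfs(sys, z)$matrix, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(v_can, v_raw, tolerance = 1e-9)
})

test_that("spin ladder labels multiplets with 2S+1 degeneracies", {
  sys <- closed_system()
  lad <- spin_ladder(sys, j_closed_d170())
  expect_s3_class(lad, "spin_ladder")
  expect_equal(lad$energy_cm1[1], 0)
  expect_true(all(diff(lad$energy_cm1) > 0))
  expect_equal(lad$degeneracy, as.integer(2 * lad$S + 1))
  expect_equal(sum(lad$degeneracy), 320)
  expect_lt(max(lad$label_residual), 1e-6)
  # uniformly ferromagnetic couplings align everything: S = 13/2
  ferro <- spin_ladder(sys, exchange_couplings(rep(10, 6)))
  expect_equal(ground_spin(ferro), 13 / 2)
})

test_that("projection onto the low-energy subspace is exact and guarded", {
  sys <- closed_system()
  H0 <- build_exchange(sys, j_closed_d170()) + build_zfs(sys, zfs_total_default())
  proj <- project_low_energy(H0, 6)
  expect_equal(proj$n, 6L)
  # projecting the zero-field Hamiltonian reproduces its lowest eigenvalues
  hp <- proj$project(H0)
  expect_equal(sort(Re(diag(hp))), proj$values, tolerance = 1e-8)
  expect_lt(max(Mod(hp - diag(Re(diag(hp))))), 1e-8)
  # retained states all carry S = 5/2
  S2 <- total_spin_squared(sys)
  s2 <- Re(diag(proj$project(S2 + 0i)))
  expect_equal(s2, rep(5 / 2 * 7 / 2, 6), tolerance = 1e-3)
  # full-dimension projection is the identity transformation
  full <- project_low_energy(H0, 320)
  expect_equal(sort(Re(diag(full$project(H0)))), full$values, tolerance = 1e-7)
  # cutting through a Kramers doublet extends with a warning
  expect_warning(p5 <- project_low_energy(H0, 5), "degenerate")
  expect_equal(p5$n, 6L)
  expect_error(project_low_energy(H0, 0), "positive")
  expect_error(project_low_energy(H0, 321), "dimension")
})

test_that("spin_ladder refuses Hamiltonians that mix total spin", {
  sys <- spin_system(c(1, 1))
  Hx <- build_exchange(sys, exchange_couplings(c("1-2" = 3)))
  Hz <- build_zfs(sys, zfs_model("site", D = 1, E = 0.2, site = 1))
  mixed <- oecspin:::new_hamiltonian_term(Hx$matrix + Hz$matrix, "exchange", sys)
  expect_error(spin_ladder(mixed), "residual|mixes")
})
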