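ANG <- 1.889726124565062

test_that("pair_exponent: identities, symmetry, errors", {
  expect_equal(pair_exponent(1.3, 1.3), 1 / (1.3 * sqrt(2)))
  expect_equal(pair_exponent(0.7, 0), pair_exponent(0, 0.7))
  expect_equal(pair_exponent(3, 4), 0.2)
  expect_error(pair_exponent(0, 0), "pointlike")
})

test_that("damping kernels: limits and oracle-pinned value at s = 1", {
  d0 <- damping(0, 2.5)
  expect_equal(d0$f_e, 0)
  expect_equal(d0$f_t, 0)
  dinf <- damping(50, 1)
  expect_equal(dinf$f_e, 1, tolerance = 1e-14)
  expect_equal(dinf$f_t, 1, tolerance = 1e-14)
  ## frozen from independent oracles: f_e by quadrature of the Gaussian
  ## density's enclosed charge, f_t by the numerical Hessian of erf(r)/r
  d1 <- damping(1, 1)
  expect_equal(d1$f_e, 0.427593295529, tolerance = 1e-10)
  expect_equal(d1$f_t, 0.150854966031, tolerance = 1e-6)
  ## kernel ordering invariant over a range of s
  s <- seq(0.01, 8, length.out = 200)
  dd <- damping(s, 1)
  ## f_e < 1 for finite s mathematically; at large s it rounds to 1 in
  ## double precision, so the numerical assertion is <= 1
  expect_true(all(dd$f_t <= dd$f_e & dd$f_e <= 1 & dd$f_t >= 0))
  expect_true(all(damping(seq(0.01, 3, by = 0.01), 1)$f_e < 1))
  expect_error(damping(-1, 1))
})

test_that("dipole field tensor: point limit, symmetry, gradient oracle", {
  Ri <- 0.7; Rj <- 0.6
  r <- 100 * (Ri + Rj)
  Tff <- dipole_field_tensor(c(r, 0, 0), c(0, 0, 0), Ri, Rj)
  expect_equal(Tff, diag(c(-2, 1, 1) / r^3), tolerance = 1e-12)

  ri <- c(0.3, -0.2, 1.1); rj <- c(-0.5, 0.8, 0.2)
  expect_equal(dipole_field_tensor(ri, rj, Ri, Rj),
               dipole_field_tensor(rj, ri, Rj, Ri))

  ## T = -Hessian of the Gaussian-charge potential erf(beta r)/r: the
  ## numerical Jacobian of the dipole's field wrt the dipole vector
  beta <- pair_exponent(Ri, Rj)
  phi <- function(x) {
    rr <- sqrt(sum((x - rj)^2))
    erf_ <- function(z) 2 * pnorm(z * sqrt(2)) - 1
    erf_(beta * rr) / rr
  }
  h <- 1e-4
  Hnum <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    ea <- c(0, 0, 0); ea[a] <- h; eb <- c(0, 0, 0); eb[b] <- h
    Hnum[a, b] <- (phi(ri + ea + eb) - phi(ri + ea - eb) -
                   phi(ri - ea + eb) + phi(ri - ea - eb)) / (4 * h^2)
  }
  expect_equal(dipole_field_tensor(ri, rj, Ri, Rj), -Hnum, tolerance = 1e-6)

  expect_error(dipole_field_tensor(ri, ri, Ri, Rj), "coincident")
})

test_that("build_A: single atom, symmetry, far-field block diagonality", {
  m1 <- molecule_model(rbind(c(0, 0, 0)), "O", charges = 0,
                       polarizabilities = 0.465, gauss_radii = 0.7)
  A1 <- build_A(m1)
  expect_equal(A1, diag(3) / (0.465 * ANG^3), tolerance = 1e-14)

  m3 <- rand_system(4, seed = 11)
  A <- build_A(m3)
  expect_equal(A, t(A))

  mfar <- molecule_model(rbind(c(0, 0, 0), c(2e4, 0, 0)), c("C", "C"),
                         polarizabilities = c(0.8, 0.8),
                         gauss_radii = c(0.8, 0.8))
  Afar <- build_A(mfar)
  offdiag <- Afar[1:3, 4:6]
  expect_lt(max(abs(offdiag)), 1e-12 / (0.8 * ANG^3))

  bad <- m1; bad$polarizabilities <- 0
  expect_error(build_A(bad), "polarizabilities")
})

test_that("static_field: zero sources, point limit, finite-difference oracle", {
  mol <- rand_system(3, seed = 5)
  mol$charges[] <- 0
  expect_equal(static_field(mol), numeric(9))

  ## unit source charge far from a probe atom: |E| -> 1/r^2 a.u.
  d <- 60
  m2 <- molecule_model(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"),
                       charges = c(1, 0), polarizabilities = c(0.8, 0.8),
                       gauss_radii = c(0.8, 0.8))
  E <- static_field(m2)
  expect_equal(sqrt(sum(E[4:6]^2)), 1 / (d * ANG)^2, tolerance = 1e-10)

  ## every component is minus the gradient of the damped interaction
  ## potential, central differences around each atom site
  mol <- rand_system(4, seed = 21)
  E <- static_field(mol)
  pos <- mol$positions * ANG; R <- mol$gauss_radii * ANG
  erf_ <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  for (i in 1:4) {
    pot <- function(x) {   # x in Bohr; damped potential seen by atom i
      v <- 0
      for (j in seq_len(4)[-i]) {
        r <- sqrt(sum((x - pos[j, ])^2))
        v <- v + mol$charges[j] * erf_(r / sqrt(R[i]^2 + R[j]^2)) / r
      }
      v
    }
    Enum <- -num_grad(pot, pos[i, ], h = 1e-5)
    expect_equal(E[(3 * i - 2):(3 * i)], Enum, tolerance = 1e-6)
  }
})

test_that("solve_induced: trivial cases and Jacobi fixed-point oracle", {
  m1 <- molecule_model(rbind(c(0, 0, 0)), "O", polarizabilities = 0.465,
                       gauss_radii = 0.7)
  A1 <- build_A(m1)
  E1 <- c(0.01, -0.02, 0.03)
  expect_equal(solve_induced(A1, E1), 0.465 * ANG^3 * E1, tolerance = 1e-12)
  expect_equal(solve_induced(A1, numeric(3)), numeric(3))

  mol <- rand_system(3, seed = 33)
  A <- build_A(mol)
  E <- static_field(mol)
  mu <- solve_induced(A, E)
  ## damped Jacobi iteration to self-consistency as independent oracle
  alpha <- mol$polarizabilities * ANG^3
  mu_j <- numeric(9)
  for (it in 1:10000) {
    mu_new <- numeric(9)
    for (i in 1:3) {
      ri <- (3 * i - 2):(3 * i)
      field <- E[ri]
      for (j in seq_len(3)[-i]) {
        rj <- (3 * j - 2):(3 * j)
        field <- field - A[ri, rj] %*% mu_j[rj]
      }
      mu_new[ri] <- alpha[i] * field
    }
    mu_new <- 0.5 * mu_j + 0.5 * mu_new
    if (max(abs(mu_new - mu_j)) < 1e-14) { mu_j <- mu_new; break }
    mu_j <- mu_new
  }
  expect_equal(mu, mu_j, tolerance = 1e-9)

  expect_error(solve_induced(matrix(c(1, 2, 2, 1), 2), c(1, 1)), "eigenvalue")
})

test_that("model_esp: point limit, center value, superposition", {
  m1 <- molecule_model(rbind(c(0, 0, 0)), "O", charges = 1,
                       gauss_radii = 0.5)
  rfar <- 50
  V <- model_esp(m1, grid = rbind(c(rfar, 0, 0)))
  expect_equal(V, 1 / (rfar * ANG), tolerance = 1e-12)

  ## value at the atom center: 2 q beta / sqrt(pi), beta = 1/R (a.u.)
  V0 <- model_esp(m1, grid = rbind(c(0, 0, 0)))
  beta_au <- 1 / (0.5 * ANG)
  expect_equal(V0, 2 * beta_au / sqrt(pi), tolerance = 1e-12)
  ## cross-check by series limit at r = 1e-6
  Veps <- model_esp(m1, grid = rbind(c(1e-6, 0, 0)))
  expect_equal(Veps, V0, tolerance = 1e-10)

  ## superposition over sources is exact
  m2 <- molecule_model(rbind(c(0, 0, 0), c(1.4, 0, 0)), c("C", "O"),
                       charges = c(0.37, -0.82), gauss_radii = c(0.8, 0.7))
  grid <- rbind(c(2.5, 1, 0), c(-1, 2, 1.3), c(0.2, -3, 0.5))
  only <- function(k) {
    mm <- m2; mm$charges <- ifelse(seq_len(2) == k, m2$charges, 0)
    model_esp(mm, grid = grid)
  }
  expect_equal(model_esp(m2, grid = grid), only(1) + only(2))
})

test_that("cbv frame: diatomic, rotation equivariance, hand-summed toy", {
  dia <- molecule_model(rbind(c(0, 0, 0), c(0, 0, 1.2)), c("C", "O"),
                        bonds = rbind(c(1L, 2L)),
                        gauss_radii = c(0.8, 0.7))
  dia$cbv_coefficients <- list(0.25, 0)
  F <- cbv_frame_matrix(dia)
  p <- drop(F %*% c(0.25, 0))
  expect_equal(p[1:3], c(0, 0, 0.25))
  expect_equal(apply(F, 2, function(v) sqrt(sum(v^2))), c(1, 1))

  ## rotating the molecule rotates every column vector identically
  mol <- rand_system(4, seed = 44, with_cbv = TRUE)
  Q <- random_rotation(7)
  Fr <- cbv_frame_matrix(rotate_molecule(mol, Q, shift = c(3, -1, 2)))
  F0 <- cbv_frame_matrix(mol)
  n <- nrow(mol$positions)
  blockQ <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) blockQ[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- Q
  expect_equal(Fr, blockQ %*% F0, tolerance = 1e-12)

  ## water-like toy: global dipole from CBV coefficients vs hand vector sum
  ang <- 104.52 * pi / 180
  w <- molecule_model(rbind(c(0, 0, 0), c(0.9572, 0, 0),
                            c(0.9572 * cos(ang), 0.9572 * sin(ang), 0)),
                      c("O", "H", "H"),
                      bonds = rbind(c(1L, 2L), c(1L, 3L)),
                      gauss_radii = c(0.7, 0.4, 0.4))
  w$cbv_coefficients <- list(c(0.06, 0.06), -0.04, -0.04)
  Fw <- cbv_frame_matrix(w)
  p <- drop(Fw %*% c(0.06, 0.06, -0.04, -0.04))
  u12 <- c(1, 0, 0)                       # O -> H1
  u13 <- c(cos(ang), sin(ang), 0)         # O -> H2
  hand <- c(0.06 * u12 + 0.06 * u13,      # on O
            -0.04 * -u12,                 # on H1, toward O
            -0.04 * -u13)                 # on H2
  expect_equal(p, hand, tolerance = 1e-12)

  bad <- dia; bad$positions[2, ] <- bad$positions[1, ]
  expect_error(cbv_frame_matrix(bad), "zero-length")
})
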