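#' Gaussian pair exponent
#'
#' Combined exponent of two interacting spherical Gaussian densities,
#' \eqn{\beta_{ij} = 1/\sqrt{R_i^2 + R_j^2}}.  For the interaction of a
#' Gaussian density with a bare point (an ESP grid point, or a point surface
#' charge) pass the second radius as 0.  Unit-agnostic: radii in any length
#' unit give the exponent in that inverse length.
#'
#' @param R_i,R_j Gaussian radii (>= 0, not both 0).
#' @return \eqn{\beta_{ij}}, symmetric in its arguments.
#' @export
pair_exponent <- function(R_i, R_j) {
  if (any(R_i < 0) || any(R_j < 0)) stop("Gaussian radii must be >= 0")
  if (any(R_i == 0 & R_j == 0)) stop("pointlike pair has no Gaussian exponent")
  1 / sqrt(R_i^2 + R_j^2)
}

#' Thole-type damping kernels of the Gaussian multipole model
#'
#' Distance-dependent attenuation factors for charge-field (`f_e`) and
#' dipole-tensor (`f_t`) interactions between Gaussian densities.  With the
#' reduced distance \eqn{s = \beta r}:
#' \deqn{f_e = erf(s) - (2s/\sqrt\pi) e^{-s^2}}
#' \deqn{f_t = erf(s) - (2s/\sqrt\pi)(1 + 2s^2/3) e^{-s^2}}
#' These are exactly the kernels for which the Gaussian-charge potential
#' \eqn{q\,erf(s)/r} has field \eqn{q f_e/r^2} and field gradient given by
#' the damped dipole tensor; the consistency is enforced by numerical
#' differentiation in the test suite.  Both kernels rise from 0 at contact
#' to 1 in the point-multipole limit, which is what prevents the
#' polarization catastrophe of undamped point-dipole models.
#'
#' @param r distance(s), >= 0.
#' @param beta Gaussian pair exponent (inverse length), > 0.
#' @return list with numeric components `f_e`, `f_t` and `s` (= beta * r),
#'   vectorized over `r`.
#' @export
damping <- function(r, beta) {
  if (any(r < 0)) stop("distance must be >= 0")
  if (any(beta <= 0)) stop("beta must be > 0")
  s <- beta * r
  g <- (2 * s / sqrt(pi)) * exp(-s^2)
  f_e <- erf(s) - g
  f_t <- f_e - g * (2 * s^2 / 3)
  list(f_e = f_e, f_t = f_t, s = s)
}

## dipole field tensor in the units of the inputs (1/length^3).
## Convention (global): the field at x_i due to a dipole p at x_j is
## E_i = -T_ij %*% p, and the dipole-dipole interaction energy is
## p_i' T_ij p_j.  T_ij = (f_e/r^3) I - (3 f_t/r^5) r r'.
tensor_raw <- function(dvec, r, f_e, f_t) {
  (f_e / r^3) * diag(3) - (3 * f_t / r^5) * tcrossprod(dvec)
}

#' Damped dipole field tensor
#'
#' The 3x3 interaction tensor \eqn{T_{ij}} between Gaussian dipoles at
#' `r_i` and `r_j`:
#' \deqn{T_{ij} = (f_e/r^3)\,I - (3 f_t/r^5)\, r r^T}
#' with the damping kernels of [damping()] evaluated at
#' \eqn{s = \beta_{ij} r}.  Sign convention (used consistently throughout
#' the package): the electric field at `r_i` produced by a dipole `p` at
#' `r_j` is `-T_ij %*% p`, and the dipole-dipole interaction energy is
#' `p_i' T_ij p_j`.  The tensor is symmetric in i and j.  Unit-agnostic:
#' inputs in a common length unit give the tensor in that inverse cubed
#' length.
#'
#' @param r_i,r_j positions (length-3 numeric).
#' @param R_i,R_j Gaussian radii of the two sites.
#' @return 3 x 3 symmetric matrix.
#' @export
dipole_field_tensor <- function(r_i, r_j, R_i, R_j) {
  dvec <- as.numeric(r_i) - as.numeric(r_j)
  r <- sqrt(sum(dvec^2))
  if (r < 1e-12) stop("dipole field tensor undefined for coincident points")
  dk <- damping(r, pair_exponent(R_i, R_j))
  tensor_raw(dvec, r, dk$f_e, dk$f_t)
}

## ---- internal atomic-unit geometry ------------------------------------

mol_au <- function(mol) {
  list(pos = mol$positions * ANG_TO_BOHR,
       R = mol$gauss_radii * ANG_TO_BOHR,
       alpha = mol$polarizabilities * ANG_TO_BOHR^3)
}

surf_au <- function(surface) {
  list(pos = surface$positions * ANG_TO_BOHR,
       R = surface$radii * ANG_TO_BOHR,
       q = surface$charges)
}

## potential column of one Gaussian (or point, R = 0) charge at many targets.
## pos, pts in Bohr; returns erf(beta r)/r, finite at r = 0 (2 beta/sqrt(pi)).
charge_potential_column <- function(pos, R, pts) {
  d <- sweep(pts, 2L, pos)
  r <- sqrt(rowSums(d^2))
  if (R > 0) {
    beta <- 1 / R
    out <- ifelse(r < 1e-10, 2 * beta / sqrt(pi), erf(beta * r) / r)
  } else {
    if (any(r < 1e-10)) stop("point charge potential singular at a target")
    out <- 1 / r
  }
  out
}

## G x 3 dipole-potential block of one Gaussian dipole site: row j is
## f_e/r^3 * (pt_j - pos)', to be dotted with the site's dipole vector.
dipole_potential_block <- function(pos, R, pts) {
  d <- sweep(pts, 2L, pos)
  r <- sqrt(rowSums(d^2))
  if (R > 0) {
    fe <- damping(r, 1 / R)$f_e
    coef <- ifelse(r < 1e-10, 0, fe / r^3)
  } else {
    if (any(r < 1e-10)) stop("point dipole potential singular at a target")
    coef <- 1 / r^3
  }
  d * coef
}

## 3 x m field block: field at 'target' from unit charges at rows of 'src'
## (Gaussian-damped, f_e with pair exponents).  Columns are sources.
charge_field_block <- function(target_pos, target_R, src_pos, src_R) {
  m <- nrow(src_pos)
  if (m == 0L) return(matrix(0, 3L, 0L))
  d <- sweep(src_pos, 2L, target_pos, FUN = function(a, b) b - a) # src -> target
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-12)) stop("coincident charge and field site")
  beta <- 1 / sqrt(target_R^2 + src_R^2)
  fe <- damping(r, beta)$f_e
  t(d * (fe / r^3))
}

#' Field matrices of the induced-dipole equations
#'
#' Assembles the three matrices that map static sources to the electric
#' field at every atom site (3n rows, atomic units): `C` (3n x n) for the
#' atomic monopoles, `D` (3n x 3n) for permanent dipoles (blocks are
#' `-T_ij`, zero on the diagonal), and `Cs` (3n x m) for the continuum
#' surface charges.  The static field entering the induced-dipole solve is
#' `E = C q + D p + Cs q_s`.
#'
#' @param molecule a [molecule_model()].
#' @param surface a [surface_charge_set()]; default empty.
#' @return list with components `C`, `D`, `Cs`.
#' @export
field_matrices <- function(molecule, surface = surface_charge_set()) {
  au <- mol_au(molecule)
  sau <- surf_au(surface)
  n <- nrow(au$pos)
  m <- nrow(sau$pos)
  C <- matrix(0, 3L * n, n)
  D <- matrix(0, 3L * n, 3L * n)
  Cs <- matrix(0, 3L * n, m)
  for (i in seq_len(n)) {
    ri <- (3L * i - 2L):(3L * i)
    for (j in seq_len(n)) {
      if (i == j) next
      dvec <- au$pos[i, ] - au$pos[j, ]
      r <- sqrt(sum(dvec^2))
      dk <- damping(r, pair_exponent(au$R[i], au$R[j]))
      C[ri, j] <- dk$f_e * dvec / r^3
      D[ri, (3L * j - 2L):(3L * j)] <- -tensor_raw(dvec, r, dk$f_e, dk$f_t)
    }
    if (m > 0L)
      Cs[ri, ] <- charge_field_block(au$pos[i, ], au$R[i], sau$pos, sau$R)
  }
  list(C = C, D = D, Cs = Cs)
}

#' Static electric field at the atom sites
#'
#' Evaluates `E = C q + D p + Cs q_s` (atomic units) at every atom,
#' combining the Gaussian-damped fields of the molecule's own monopoles, its
#' permanent CBV dipoles, and the continuum surface charges.  The component
#' matrices are available separately from [field_matrices()] for use in the
#' fitting design matrix.
#'
#' @inheritParams field_matrices
#' @return numeric 3n-vector (atom-major: x1,y1,z1,x2,...).
#' @export
static_field <- function(molecule, surface = surface_charge_set()) {
  fm <- field_matrices(molecule, surface)
  p <- cbv_global_dipoles(molecule) * ANG_TO_BOHR  # e.Angstrom -> e.Bohr
  E <- drop(fm$C %*% molecule$charges + fm$D %*% p)
  if (ncol(fm$Cs) > 0L) E <- E + drop(fm$Cs %*% surface$charges)
  E
}

#' Polarizability interaction matrix
#'
#' The symmetric 3n x 3n matrix `A` of the induced-dipole linear system
#' `A mu = E`: diagonal 3x3 blocks are \eqn{(1/\alpha_i) I}, off-diagonal
#' blocks are the damped dipole tensors \eqn{T_{ij}} of
#' [dipole_field_tensor()].  Atomic units.  All atoms passed must be
#' polarizable; callers exclude \eqn{\alpha_i = 0} atoms beforehand (the
#' fitting machinery does this automatically).
#'
#' @param molecule a [molecule_model()] with all polarizabilities > 0.
#' @return 3n x 3n matrix (1/Bohr^3); a warning is issued if it is not
#'   positive definite.
#' @export
build_A <- function(molecule) {
  au <- mol_au(molecule)
  if (any(au$alpha <= 0))
    stop("build_A requires all polarizabilities > 0; exclude alpha = 0 atoms")
  n <- nrow(au$pos)
  A <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n)) {
    ri <- (3L * i - 2L):(3L * i)
    A[ri, ri] <- diag(3) / au$alpha[i]
    for (j in seq_len(n)) {
      if (j == i) next
      dvec <- au$pos[i, ] - au$pos[j, ]
      r <- sqrt(sum(dvec^2))
      dk <- damping(r, pair_exponent(au$R[i], au$R[j]))
      A[ri, (3L * j - 2L):(3L * j)] <- tensor_raw(dvec, r, dk$f_e, dk$f_t)
    }
  }
  ev_ok <- tryCatch({ chol(A); TRUE }, error = function(e) FALSE)
  if (!ev_ok)
    warning("polarizability matrix is not positive definite; ",
            "check geometry and polarizabilities")
  A
}

#' Solve the induced-dipole linear system
#'
#' Dense symmetric solve of `A mu = E`.  The residual is verified to
#' satisfy \eqn{\|A\mu - E\|_\infty < 10^{-10} \max(1, \|E\|_\infty)}.
#'
#' @param A matrix from [build_A()].
#' @param E static field vector (atomic units), e.g. from [static_field()]
#'   restricted to the polarizable atoms.
#' @return induced dipoles `mu` (e.Bohr), same length as `E`.
#' @export
solve_induced <- function(A, E) {
  ch <- tryCatch(chol(A), error = function(e) e)
  if (inherits(ch, "error")) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    stop("induced-dipole system is singular or indefinite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  }
  mu <- drop(chol2inv(ch) %*% E)
  res <- max(abs(A %*% mu - E))
  if (res >= 1e-10 * max(1, max(abs(E))))
    stop("induced-dipole solve residual too large: ", format(res))
  mu
}

#' Covalent-bond-vector frame matrix
#'
#' The 3n x B matrix `F` mapping local CBV permanent-dipole coefficients
#' `p_loc` to global Cartesian atomic dipoles `p = F p_loc`.  Column
#' (atom i, incident bond k) holds the unit vector from atom i toward its
#' k-th bonded neighbor in rows 3i-2..3i and zeros elsewhere, so the frame
#' rotates with the molecule and the coefficients are conformation-local.
#' Slot order follows [cbv_slots()].
#'
#' @param molecule a [molecule_model()].
#' @return 3n x B matrix with unit-norm columns (dimensionless).
#' @export
cbv_frame_matrix <- function(molecule) {
  slots <- cbv_slots(molecule)
  n <- nrow(molecule$positions)
  F <- matrix(0, 3L * n, nrow(slots))
  for (k in seq_len(nrow(slots))) {
    i <- slots$atom[k]; j <- slots$neighbor[k]
    v <- molecule$positions[j, ] - molecule$positions[i, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-12) stop("zero-length bond between atoms ", i, " and ", j)
    F[(3L * i - 2L):(3L * i), k] <- v / len
  }
  F
}

## global Cartesian permanent dipoles (e.Angstrom), zeros if no CBV set
cbv_global_dipoles <- function(molecule) {
  n <- nrow(molecule$positions)
  if (is.null(molecule$cbv_coefficients)) return(numeric(3L * n))
  ploc <- unlist(molecule$cbv_coefficients, use.names = FALSE)
  if (length(ploc) == 0L) return(numeric(3L * n))
  drop(cbv_frame_matrix(molecule) %*% ploc)
}

#' Model electrostatic potential on a grid
#'
#' Evaluates the model ESP (atomic units) at each grid point:
#' monopole terms \eqn{q_i\,erf(\beta_i r_{ij})/r_{ij}} with
#' \eqn{\beta_i = 1/R_i}, Gaussian-damped dipole terms from the permanent
#' (CBV) plus induced dipoles, and optionally the direct potential of the
#' continuum surface charges.  Every term is finite everywhere, including at
#' atom centers where the monopole potential tends to
#' \eqn{2 q \beta/\sqrt\pi}.
#'
#' @param molecule a [molecule_model()] (its `charges` and CBV coefficients
#'   are the static sources).
#' @param mu induced dipoles as a 3n-vector in atomic units (e.Bohr), as
#'   produced by [solve_induced()] (zeros for non-polarizable atoms), or
#'   `NULL` for none.
#' @param surface a [surface_charge_set()] or `NULL`.
#' @param grid an [esp_grid()] or a G x 3 matrix of points (Angstrom).
#' @param include_direct_surface logical; add the direct surface-charge
#'   potential to the returned values (default `TRUE` when a non-empty
#'   surface is given).
#' @param point_charges logical; treat the monopoles as undamped point
#'   charges (the RESP model kind) instead of Gaussian densities.
#' @return numeric G-vector of potentials (Hartree/e).
#' @export
model_esp <- function(molecule, mu = NULL, surface = NULL, grid,
                      include_direct_surface = TRUE, point_charges = FALSE) {
  pts <- if (inherits(grid, "esp_grid")) grid$points else as.matrix(grid)
  pts_au <- pts * ANG_TO_BOHR
  au <- mol_au(molecule)
  n <- nrow(au$pos)
  V <- numeric(nrow(pts_au))
  radii <- if (point_charges) numeric(n) else au$R
  for (i in seq_len(n)) {
    V <- V + molecule$charges[i] *
      charge_potential_column(au$pos[i, ], radii[i], pts_au)
  }
  p <- cbv_global_dipoles(molecule) * ANG_TO_BOHR
  if (!is.null(mu)) {
    if (length(mu) != 3L * n)
      stop("'mu' must have length 3n (zeros for non-polarizable atoms)")
    p <- p + mu
  }
  if (any(p != 0)) {
    for (i in seq_len(n)) {
      pi_ <- p[(3L * i - 2L):(3L * i)]
      if (all(pi_ == 0)) next
      V <- V + drop(dipole_potential_block(au$pos[i, ], au$R[i], pts_au) %*% pi_)
    }
  }
  if (!is.null(surface) && include_direct_surface &&
      nrow(surface$positions) > 0L) {
    sau <- surf_au(surface)
    for (l in seq_len(nrow(sau$pos))) {
      V <- V + sau$q[l] * charge_potential_column(sau$pos[l, ], sau$R[l], pts_au)
    }
  }
  V
}
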