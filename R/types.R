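#' Construct a molecule model
#'
#' The central container for a molecule being parametrized: geometry,
#' covalent bonds, and the per-atom electrostatic parameters of the
#' polarizable Gaussian multipole (pGM) family — monopoles \eqn{q_i},
#' isotropic polarizabilities \eqn{\alpha_i} and Gaussian radii \eqn{R_i} —
#' plus, for models with permanent dipoles, the covalent-bond-vector (CBV)
#' coefficients \eqn{p^{loc}} (one scalar per incident bond of each atom).
#'
#' @param positions numeric n x 3 matrix of atomic coordinates (Angstrom).
#' @param elements character vector of length n (element symbols).
#' @param bonds integer matrix with two columns; each row one covalent bond
#'   (1-based atom indices).  May have zero rows.
#' @param total_charge integer net molecular charge (e).
#' @param charges numeric length-n monopoles (e); default all zero.
#' @param polarizabilities numeric length-n \eqn{\alpha_i} (Angstrom^3),
#'   all >= 0; atoms with \eqn{\alpha_i = 0} are excluded from the
#'   induced-dipole system.  Default all zero (static model).
#' @param gauss_radii numeric length-n pGM Gaussian radii (Angstrom), > 0.
#' @param cbv_coefficients list of length n; element i holds the CBV
#'   permanent-dipole coefficients of atom i, one per incident bond in bond
#'   order (e.Angstrom).  `NULL` (the default) means no permanent dipoles
#'   (RESP and pGM-ind model kinds).
#' @param equivalence_groups list of integer vectors partitioning fit
#'   parameter indices (1..n are the atomic charges, n+1..n+B the CBV
#'   slots in [cbv_slots()] order) into chemically equivalent sets.
#'   Parameters not mentioned are free singletons.
#'
#' @return an object of class `molecule_model`.
#' @seealso [cbv_frame_matrix()], [fit_esp()], [read_molecule()]
#' @export
molecule_model <- function(positions, elements, bonds = NULL,
                           total_charge = 0L, charges = NULL,
                           polarizabilities = NULL, gauss_radii = NULL,
                           cbv_coefficients = NULL,
                           equivalence_groups = NULL) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L || nrow(positions) < 1L)
    stop("'positions' must be a numeric n x 3 matrix with n >= 1")
  n <- nrow(positions)
  elements <- as.character(elements)
  if (length(elements) != n) stop("'elements' must have one symbol per atom")
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
  }
  if (nrow(bonds) > 0L) {
    if (any(bonds < 1L | bonds > n))
      stop("bond references an atom index outside 1..", n)
    if (any(bonds[, 1L] == bonds[, 2L]))
      stop("bond must join two distinct atoms")
    key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                 pmax(bonds[, 1L], bonds[, 2L]))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  }
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(polarizabilities)) polarizabilities <- numeric(n)
  if (is.null(gauss_radii)) gauss_radii <- rep(0.8, n)
  charges <- as.numeric(charges)
  polarizabilities <- as.numeric(polarizabilities)
  gauss_radii <- as.numeric(gauss_radii)
  if (length(charges) != n || length(polarizabilities) != n ||
      length(gauss_radii) != n)
    stop("per-atom parameter vectors must all have length ", n)
  if (any(polarizabilities < 0)) stop("polarizabilities must be >= 0")
  if (any(gauss_radii <= 0)) stop("Gaussian radii must be > 0")
  mol <- structure(list(
    positions = positions, elements = elements, bonds = bonds,
    total_charge = as.integer(total_charge), charges = charges,
    polarizabilities = polarizabilities, gauss_radii = gauss_radii,
    cbv_coefficients = cbv_coefficients,
    equivalence_groups = equivalence_groups
  ), class = "molecule_model")
  if (!is.null(cbv_coefficients)) {
    deg <- atom_degrees(mol)
    if (length(cbv_coefficients) != n)
      stop("'cbv_coefficients' must be a length-n list")
    bad <- which(vapply(cbv_coefficients, length, 1L) != deg)
    if (length(bad))
      stop("CBV coefficient count must equal bond degree for atom ", bad[1L])
  }
  mol
}

## neighbor lists in bond order: element i = atom indices bonded to atom i
atom_neighbors <- function(mol) {
  n <- nrow(mol$positions)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1L]; j <- b[k, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(x) if (is.null(x)) integer(0) else x)
}

atom_degrees <- function(mol) {
  lengths(atom_neighbors(mol))
}

#' Enumerate the CBV coefficient slots of a molecule
#'
#' Every (atom, incident-bond) pair is one permanent-dipole coefficient slot
#' of the pGM-perm model.  Slots are ordered by atom, then by that atom's
#' bonds in the order they appear in the bond list.
#'
#' @param molecule a [molecule_model()].
#' @return data frame with columns `atom` and `neighbor` (atom indices), one
#'   row per slot; zero rows for an unbonded molecule.
#' @export
cbv_slots <- function(molecule) {
  nb <- atom_neighbors(molecule)
  atom <- rep(seq_along(nb), lengths(nb))
  data.frame(atom = atom, neighbor = unlist(nb, use.names = FALSE)[seq_along(atom)])
}

#' Construct a set of continuum-solvent surface charges
#'
#' Apparent surface charges of a polarizable continuum model (PCM).  They are
#' static sources during fitting: they polarize the solute and add a constant
#' offset to the model ESP, but are never fit parameters.  An empty set
#' (`m = 0`) represents the gas phase.
#'
#' @param positions numeric m x 3 matrix (Angstrom); may have zero rows.
#' @param charges numeric length-m surface charges (e).
#' @param radii numeric length-m Gaussian radii of the surface charges
#'   (Angstrom); 0 means a point charge.  Default 0.
#' @param weights numeric length-m per-point area weights (Angstrom^2),
#'   carried as metadata.  Default 1.
#' @return an object of class `surface_charge_set`.
#' @export
surface_charge_set <- function(positions = matrix(numeric(0), ncol = 3L),
                               charges = numeric(0), radii = NULL,
                               weights = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), ncol = 3L)
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns")
  m <- nrow(positions)
  if (length(charges) != m) stop("'charges' must match the number of points")
  if (is.null(radii)) radii <- numeric(m)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(radii) != m || length(weights) != m)
    stop("'radii' and 'weights' must match the number of points")
  if (any(radii < 0)) stop("surface radii must be >= 0")
  structure(list(positions = positions, charges = as.numeric(charges),
                 radii = as.numeric(radii), weights = as.numeric(weights)),
            class = "surface_charge_set")
}

#' Construct an ESP evaluation grid
#'
#' Grid points outside the molecular envelope carrying the reference
#' (quantum-mechanical) electrostatic potential that fitting targets.
#'
#' @param points numeric G x 3 matrix (Angstrom).
#' @param qm_potentials numeric length-G reference ESP values (atomic units,
#'   Hartree/e).
#' @param point_weights numeric length-G positive fitting weights; default 1.
#' @return an object of class `esp_grid`.
#' @export
esp_grid <- function(points, qm_potentials, point_weights = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L)
    stop("'points' must be a G x 3 matrix, G >= 1")
  G <- nrow(points)
  if (length(qm_potentials) != G)
    stop("'qm_potentials' must have one value per grid point")
  if (is.null(point_weights)) point_weights <- rep(1, G)
  if (length(point_weights) != G || any(point_weights <= 0))
    stop("'point_weights' must be positive, one per grid point")
  structure(list(points = points, qm_potentials = as.numeric(qm_potentials),
                 point_weights = as.numeric(point_weights)),
            class = "esp_grid")
}

#' Bundle one medium's ESP data
#'
#' One dielectric medium's fitting data for a molecule: the grid with QM
#' potentials, the PCM surface charges (empty in gas phase), the medium label
#' and dielectric constant, and the molecular geometry the data refer to.
#'
#' @param molecule the [molecule_model()] (geometry carrier).
#' @param grid an [esp_grid()].
#' @param surface a [surface_charge_set()]; default empty (gas phase).
#' @param medium character label, e.g. `"WAT"`.
#' @param epsilon dielectric constant (>= 1).
#' @return an object of class `esp_dataset`.
#' @export
esp_dataset <- function(molecule, grid, surface = surface_charge_set(),
                        medium = "GAS", epsilon = 1) {
  stopifnot(inherits(molecule, "molecule_model"), inherits(grid, "esp_grid"),
            inherits(surface, "surface_charge_set"))
  if (epsilon < 1) stop("dielectric constant must be >= 1")
  ## QM reference is not meaningful on top of a nucleus
  d2 <- vapply(seq_len(nrow(molecule$positions)), function(i) {
    min(rowSums(sweep(grid$points, 2L, molecule$positions[i, ])^2))
  }, 0)
  if (any(d2 < 1e-12))
    stop("grid point coincides with an atom position (within 1e-6 Angstrom)")
  structure(list(molecule = molecule, grid = grid, surface = surface,
                 medium = as.character(medium), epsilon = as.numeric(epsilon)),
            class = "esp_dataset")
}

#' @export
print.molecule_model <- function(x, ...) {
  n <- nrow(x$positions)
  cat("<molecule_model> ", n, " atoms (", paste(x$elements, collapse = " "),
      "), ", nrow(x$bonds), " bonds, net charge ", x$total_charge, "\n",
      sep = "")
  cat("  sum(q) = ", format(sum(x$charges), digits = 6),
      "; polarizable atoms: ", sum(x$polarizabilities > 0), "/", n, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.esp_dataset <- function(x, ...) {
  cat("<esp_dataset> medium ", x$medium, " (eps = ", x$epsilon, "): ",
      nrow(x$grid$points), " grid points, ", nrow(x$surface$positions),
      " surface charges\n", sep = "")
  invisible(x)
}

## identical geometry check used by dual-solvent and transfer code
same_conformation <- function(a, b, tol = 1e-6) {
  nrow(a$positions) == nrow(b$positions) &&
    max(abs(a$positions - b$positions)) <= tol
}
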