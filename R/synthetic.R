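#' The five reference dielectric media
#'
#' Gas phase and four solvents spanning the dielectric range commonly used
#' to probe cross-solvent transferability: diethyl ether, dichloroethane,
#' acetone and water.
#'
#' @return data frame with columns `label` and `epsilon`.
#' @export
pcm_media <- function() {
  data.frame(label = c("GAS", "ETH", "EDC", "ACT", "WAT"),
             epsilon = c(1, 4.24, 10.125, 20.493, 78.3553))
}

#' Bondi van der Waals radii
#'
#' Radii (Angstrom) after Bondi (1964), used to build ESP grid shells and
#' solvent-accessible surfaces.  Configurable wherever consumed.
#'
#' @param elements character vector of element symbols.
#' @return named numeric vector of radii.
#' @export
bondi_radii <- function(elements) {
  tab <- c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
           Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
           I = 1.98)
  out <- tab[elements]
  if (anyNA(out))
    stop("no van der Waals radius tabulated for: ",
         paste(unique(elements[is.na(out)]), collapse = ", "))
  stats::setNames(as.numeric(out), elements)
}

#' Deterministic Fibonacci sphere covering
#'
#' `n` near-uniform points on the unit sphere from the golden-angle spiral
#' lattice — a deterministic replacement for Lebedev grids in the synthetic
#' surface and grid generators.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Generate an ESP fitting grid on van der Waals shells
#'
#' Connolly-style construction: for every shell scale, points are laid on
#' each atom's scaled vdW sphere with a per-sphere budget of
#' `ceiling(density * sphere area)` and discarded when strictly inside any
#' other atom's sphere at the same scale.  Defaults follow the conventional
#' ESP grid recipe: shells at 1.4, 1.6, 1.8 and 2.0 times the vdW radii
#' with 6 points per Angstrom^2.  Fully deterministic.
#'
#' @param molecule a [molecule_model()].
#' @param shell_scales numeric vector of shell scale factors (>= 1).
#' @param density points per Angstrom^2 (> 0).
#' @param vdw_radii optional named radii (Angstrom) overriding
#'   [bondi_radii()].
#' @return G x 3 matrix of grid points (Angstrom).
#' @export
generate_grid <- function(molecule, shell_scales = c(1.4, 1.6, 1.8, 2.0),
                          density = 6, vdw_radii = NULL) {
  if (any(shell_scales < 1)) stop("shell scales must be >= 1")
  if (density <= 0) stop("grid density must be > 0")
  vdw <- vdw_radii %||% bondi_radii(molecule$elements)
  pos <- molecule$positions
  n <- nrow(pos)
  out <- list()
  for (s in shell_scales) {
    rs <- s * vdw
    for (a in seq_len(n)) {
      R <- rs[a]
      npts <- ceiling(density * 4 * pi * R^2)
      pts <- sweep(fibonacci_sphere(npts) * R, 2L, pos[a, ], `+`)
      keep <- rep(TRUE, npts)
      for (b in seq_len(n)) {
        if (b == a) next
        d2 <- rowSums(sweep(pts, 2L, pos[b, ])^2)
        keep <- keep & d2 >= (rs[b] - 1e-9)^2
      }
      out[[length(out) + 1L]] <- pts[keep, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

## Gaussian radius giving a surface point the COSMO-consistent
## self-interaction 1.07 * sqrt(4 pi / area)
SURFACE_RADIUS_COEF <- sqrt(2) / (2 * 1.07 * pi)

#' Generate a solvent-accessible surface point set
#'
#' A single shell at `vdW radius + probe offset` per atom with a
#' deterministic Fibonacci covering at the requested density (default
#' 5 points per Angstrom^2, the conventional PCM cavity density).  Points
#' falling strictly inside another atom's shell are culled.  Each retained
#' point carries an area weight `sphere area / points generated on that
#' sphere`, so the weights of retained points sum to approximately the
#' exposed cavity area, and a Gaussian radius proportional to the square
#' root of its area weight (COSMO-consistent smoothing; see the package
#' vignette).
#'
#' @param molecule a [molecule_model()].
#' @param density points per Angstrom^2 (> 0).
#' @param probe_radius probe offset added to every vdW radius (Angstrom).
#' @param vdw_radii optional named radii overriding [bondi_radii()].
#' @return a [surface_charge_set()] with zero charges (fill them with
#'   [polarize_surface()]).
#' @export
generate_surface <- function(molecule, density = 5, probe_radius = 0.4,
                             vdw_radii = NULL) {
  if (density <= 0) stop("surface density must be > 0")
  vdw <- vdw_radii %||% bondi_radii(molecule$elements)
  pos <- molecule$positions
  n <- nrow(pos)
  rs <- vdw + probe_radius
  pts <- list(); wts <- list()
  for (a in seq_len(n)) {
    R <- rs[a]
    area <- 4 * pi * R^2
    npts <- ceiling(density * area)
    p <- sweep(fibonacci_sphere(npts) * R, 2L, pos[a, ], `+`)
    keep <- rep(TRUE, npts)
    for (b in seq_len(n)) {
      if (b == a) next
      keep <- keep & rowSums(sweep(p, 2L, pos[b, ])^2) >= (rs[b] - 1e-9)^2
    }
    pts[[a]] <- p[keep, , drop = FALSE]
    wts[[a]] <- rep(area / npts, sum(keep))
  }
  w <- unlist(wts)
  surface_charge_set(positions = do.call(rbind, pts),
                     charges = numeric(length(w)),
                     radii = SURFACE_RADIUS_COEF * sqrt(w), weights = w)
}

## Gaussian-smoothed surface self-interaction matrix (atomic units)
surface_self_matrix <- function(surface) {
  sau <- surf_au(surface)
  m <- nrow(sau$pos)
  if (any(sau$R <= 0))
    stop("surface self-interaction needs positive Gaussian radii")
  S <- matrix(0, m, m)
  for (k in seq_len(m)) {
    d <- sweep(sau$pos, 2L, sau$pos[k, ])
    r <- sqrt(rowSums(d^2))
    beta <- 1 / sqrt(sau$R[k]^2 + sau$R^2)
    col <- ifelse(r < 1e-10, 2 * beta / sqrt(pi), erf(beta * r) / r)
    S[, k] <- col
  }
  S
}

#' Continuum-solvent surface polarization stand-in
#'
#' Conductor-like screening model producing apparent surface charges from
#' the solute's potential on the cavity:
#' \deqn{q_s = -f(\epsilon)\, S^{-1} \Phi_{solute},\qquad
#'       f(\epsilon) = (\epsilon - 1)/\epsilon}
#' with `S` the Gaussian-smoothed surface self-interaction matrix.  By
#' Gauss's law the total induced charge approaches
#' \eqn{-f(\epsilon) Q_{solute}} for a well-resolved closed surface.  This
#' is a deliberately simple stand-in for a quantum-chemistry PCM solver and
#' is documented as such; it is not IEF-PCM.
#'
#' @param molecule the solute [molecule_model()] (its charges and CBV
#'   dipoles are the sources).
#' @param surface_points a [surface_charge_set()] giving positions, radii
#'   and weights (charges ignored), e.g. from [generate_surface()].
#' @param epsilon dielectric constant >= 1; 1 returns all-zero charges.
#' @param mu optional induced atomic dipoles (3n a.u. vector) included in
#'   the solute potential, for self-consistent solute--surface polarization.
#' @param point_charges treat solute monopoles as points (RESP kind).
#' @return a [surface_charge_set()] with the induced charges filled in.
#' @export
polarize_surface <- function(molecule, surface_points, epsilon, mu = NULL,
                             point_charges = FALSE) {
  if (epsilon < 1) stop("dielectric constant must be >= 1")
  out <- surface_points
  m <- nrow(out$positions)
  if (epsilon == 1 || m == 0L) {
    out$charges <- numeric(m)
    return(out)
  }
  phi <- model_esp(molecule, mu = mu, surface = NULL,
                   grid = out$positions, point_charges = point_charges)
  S <- surface_self_matrix(out)
  ch <- tryCatch(chol(S), error = function(e) e)
  if (inherits(ch, "error"))
    stop("surface self-interaction matrix is singular ",
         "(duplicate surface points?)")
  f <- (epsilon - 1) / epsilon
  out$charges <- -f * drop(chol2inv(ch) %*% phi)
  out
}

#' Describe a synthetic ESP benchmark world
#'
#' Bundles a truth molecule (from a named template or supplied directly),
#' the generating model kind, the media list and the grid/surface/noise
#' settings into one reproducible specification.  Same spec + seed give
#' bitwise-identical datasets.
#'
#' @param template `"water"`, `"diatomic"`, `"alkane"`, `"random"`, or a
#'   [molecule_model()] used as-is.
#' @param n chain length (alkane template) or atom count (random template).
#' @param model_kind generating model: `"resp"`, `"pgm-ind"` or
#'   `"pgm-perm"` (adds truth CBV dipoles).
#' @param media data frame with `label`, `epsilon`; default [pcm_media()].
#' @param grid_scales,grid_density ESP shell scales and density
#'   (defaults 1.4/1.6/1.8/2.0 and 6 per Angstrom^2).
#' @param surface_density,probe_radius cavity density (default 5 per
#'   Angstrom^2) and probe offset (default 0.4 Angstrom).
#' @param noise i.i.d. Gaussian noise s.d. added to grid potentials (a.u.,
#'   default 0).
#' @param seed integer seed controlling the random template and the noise.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(template = "water", n = 4L,
                           model_kind = c("pgm-ind", "resp", "pgm-perm"),
                           media = pcm_media(),
                           grid_scales = c(1.4, 1.6, 1.8, 2.0),
                           grid_density = 6, surface_density = 5,
                           probe_radius = 0.4, noise = 0, seed = 1L) {
  model_kind <- match.arg(model_kind)
  mol <- if (inherits(template, "molecule_model")) template
         else template_molecule(template, n = n, seed = seed,
                                with_cbv = model_kind == "pgm-perm")
  if (model_kind != "pgm-perm") mol$cbv_coefficients <- NULL
  structure(list(molecule = mol, model_kind = model_kind, media = media,
                 grid_scales = grid_scales, grid_density = grid_density,
                 surface_density = surface_density,
                 probe_radius = probe_radius, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Built-in truth-molecule templates
#'
#' Small, physically plausible molecules with literature-style parameters:
#' a water-like bent triatomic (TIP3P-like charges, Applequist
#' polarizabilities), a carbon-monoxide-like diatomic, an all-atom
#' alkane-like chain with two methyl ends, and a random heavy-atom chain.
#' Gaussian radii are covalent-scale values (H 0.4, C 0.8, N 0.75,
#' O 0.7 Angstrom).
#'
#' @param template one of `"water"`, `"diatomic"`, `"alkane"`, `"random"`.
#' @param n chain length (alkane: number of carbons >= 2; random: atoms).
#' @param seed seed for the random template.
#' @param with_cbv attach small truth CBV permanent-dipole coefficients.
#' @return a [molecule_model()]; alkane molecules carry an attribute
#'   `methyl_hydrogens` (list of the two methyl H index vectors).
#' @export
template_molecule <- function(template = c("water", "diatomic", "alkane",
                                           "random"),
                              n = 4L, seed = 1L, with_cbv = FALSE) {
  template <- match.arg(template)
  Rtab <- c(H = 0.4, C = 0.8, N = 0.75, O = 0.7)
  Atab <- c(H = 0.135, C = 0.878, N = 0.530, O = 0.465)  # Applequist-like
  if (template == "water") {
    ang <- 104.52 * pi / 180
    pos <- rbind(c(0, 0, 0), c(0.9572, 0, 0),
                 c(0.9572 * cos(ang), 0.9572 * sin(ang), 0))
    el <- c("O", "H", "H")
    mol <- molecule_model(pos, el, bonds = rbind(c(1L, 2L), c(1L, 3L)),
                          total_charge = 0L,
                          charges = c(-0.834, 0.417, 0.417),
                          polarizabilities = Atab[el], gauss_radii = Rtab[el],
                          equivalence_groups = list(c(2L, 3L)))
    if (with_cbv)
      mol$cbv_coefficients <- list(c(0.06, 0.06), -0.04, -0.04)
    return(mol)
  }
  if (template == "diatomic") {
    pos <- rbind(c(0, 0, 0), c(1.128, 0, 0))
    el <- c("C", "O")
    mol <- molecule_model(pos, el, bonds = rbind(c(1L, 2L)),
                          total_charge = 0L, charges = c(0.2, -0.2),
                          polarizabilities = Atab[el], gauss_radii = Rtab[el])
    if (with_cbv) mol$cbv_coefficients <- list(0.08, 0.05)
    return(mol)
  }
  if (template == "alkane") {
    nc <- max(2L, as.integer(n))
    th <- 109.47 * pi / 180
    dx <- 1.54 * sin(th / 2); dy <- 1.54 * cos(th / 2)
    cpos <- cbind((seq_len(nc) - 1) * dx, rep(c(0, dy), length.out = nc), 0)
    pos <- cpos; el <- rep("C", nc)
    bonds <- if (nc > 1) cbind(seq_len(nc - 1L), 2:nc) else NULL
    hof <- function(cidx, v) {
      pos <<- rbind(pos, cpos[cidx, ] + v)
      el <<- c(el, "H")
      bonds <<- rbind(bonds, c(cidx, nrow(pos)))
      nrow(pos)
    }
    methyl <- list()
    for (k in seq_len(nc)) {
      side <- if (k %% 2L == 1L) 1 else -1
      h1 <- hof(k, c(0, side * 0.52, 0.89))
      h2 <- hof(k, c(0, side * 0.52, -0.89))
      ids <- c(h1, h2)
      if (k == 1L) ids <- c(ids, hof(k, c(-1.09, 0, 0)))
      if (k == nc) ids <- c(ids, hof(k, c(1.09, 0, 0)))
      if (k %in% c(1L, nc)) methyl[[length(methyl) + 1L]] <- ids
    }
    nH <- vapply(seq_len(nc), function(k) sum(bonds[, 1L] == k & el[bonds[, 2L]] == "H"), 0L)
    q <- c(-0.06 * nH, rep(0.06, length(el) - nc))
    mol <- molecule_model(pos, el, bonds = bonds, total_charge = 0L,
                          charges = q, polarizabilities = Atab[el],
                          gauss_radii = Rtab[el])
    if (with_cbv) {
      deg <- atom_degrees(mol)
      mol$cbv_coefficients <- lapply(seq_along(el), function(i)
        rep(if (el[i] == "H") -0.02 else 0.03, deg[i]))
    }
    attr(mol, "methyl_hydrogens") <- methyl
    return(mol)
  }
  ## random heavy-atom chain
  set.seed(seed)
  natoms <- max(2L, as.integer(n))
  el <- sample(c("C", "N", "O"), natoms, replace = TRUE)
  pos <- matrix(0, natoms, 3L)
  for (k in 2:natoms) {
    repeat {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[k - 1L, ] + u * stats::runif(1, 1.3, 1.6)
      if (all(sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE],
                                 2L, cand)^2)) > 1.0)) break
    }
    pos[k, ] <- cand
  }
  q <- stats::runif(natoms, -0.4, 0.4)
  q <- q - mean(q)                      # neutral truth
  mol <- molecule_model(pos, el, bonds = cbind(seq_len(natoms - 1L), 2:natoms),
                        total_charge = 0L, charges = q,
                        polarizabilities = Atab[el], gauss_radii = Rtab[el])
  if (with_cbv) {
    deg <- atom_degrees(mol)
    mol$cbv_coefficients <- lapply(deg, function(d)
      stats::runif(d, -0.05, 0.05))
  }
  mol
}

#' Forward-model ESP dataset for one medium
#'
#' Builds the grid and (for solvated media) the cavity surface, solves the
#' mutual solute--surface polarization to self-consistency (surface charges
#' respond to the solute potential including induced dipoles, which in turn
#' respond to the surface charges), evaluates the exact model ESP of the
#' truth parameters on the grid, and optionally adds i.i.d. Gaussian noise.
#' The truth parameters are recorded in the dataset attribute `"truth"` for
#' recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param medium a label present in `spec$media`, or a
#'   `list(label =, epsilon =)`.
#' @return an [esp_dataset()].
#' @export
forward_esp_dataset <- function(spec, medium) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.character(medium)) {
    i <- match(medium, spec$media$label)
    if (is.na(i)) stop("unknown medium label: ", medium)
    medium <- list(label = spec$media$label[i], epsilon = spec$media$epsilon[i])
  }
  mol <- spec$molecule
  kind <- spec$model_kind
  pts <- generate_grid(mol, spec$grid_scales, spec$grid_density)
  eps <- medium$epsilon
  if (eps > 1) {
    surf <- generate_surface(mol, spec$surface_density, spec$probe_radius)
    S <- surface_self_matrix(surf)
    Sinv <- chol2inv(chol(S))
    f <- (eps - 1) / eps
    qs <- numeric(nrow(surf$positions))
    mu <- NULL
    for (it in seq_len(200L)) {
      phi <- model_esp(mol, mu = mu, surface = NULL, grid = surf$positions,
                       point_charges = kind == "resp")
      qs_new <- -f * drop(Sinv %*% phi)
      surf$charges <- qs_new
      if (kind != "resp") mu <- induced_dipoles(mol, kind, surf)
      if (max(abs(qs_new - qs)) < 1e-8) break
      qs <- qs_new
    }
  } else {
    surf <- surface_charge_set()
  }
  ## dataset potentials come from the same linear model the fit inverts
  proto <- esp_dataset(mol, esp_grid(pts, numeric(nrow(pts))), surf,
                       medium = medium$label, epsilon = eps)
  V <- predict_esp(mol, kind, proto)
  if (spec$noise > 0) {
    set.seed(spec$seed + round(eps * 1000) %% 100000L)
    V <- V + stats::rnorm(length(V), sd = spec$noise)
  }
  ds <- esp_dataset(mol, esp_grid(pts, V), surf,
                    medium = medium$label, epsilon = eps)
  attr(ds, "truth") <- list(charges = mol$charges,
                            cbv_coefficients = mol$cbv_coefficients,
                            model_kind = kind)
  ds
}

#' Generate the packaged five-media benchmark
#'
#' One call producing a named list of datasets for every medium in the
#' spec — the fixed-seed benchmark driving the transferability tests.
#'
#' @param spec a [synthetic_spec()].
#' @return named list of [esp_dataset()]s (names = medium labels).
#' @export
synthetic_benchmark <- function(spec) {
  out <- lapply(seq_len(nrow(spec$media)), function(i)
    forward_esp_dataset(spec, list(label = spec$media$label[i],
                                   epsilon = spec$media$epsilon[i])))
  stats::setNames(out, spec$media$label)
}
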