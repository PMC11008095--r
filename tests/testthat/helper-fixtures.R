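## Fixtures are generated in code; nothing binary ships with the package.

## random small polarizable system for property tests: chain-bonded heavy
## atoms with plausible radii/polarizabilities, neutral by construction
rand_system <- function(n, seed, with_cbv = FALSE) {
  set.seed(seed)
  pos <- matrix(0, n, 3L)
  for (k in seq_len(n)[-1]) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[k - 1L, ] + u * runif(1, 1.3, 1.7)
      if (all(sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE],
                                 2L, cand)^2)) > 1.1)) break
    }
    pos[k, ] <- cand
  }
  q <- runif(n, -0.5, 0.5); q <- q - mean(q)
  mol <- molecule_model(
    pos, sample(c("C", "N", "O"), n, replace = TRUE),
    bonds = if (n > 1) cbind(seq_len(n - 1L), 2:n) else NULL,
    total_charge = 0L, charges = q,
    polarizabilities = runif(n, 0.2, 0.9),
    gauss_radii = runif(n, 0.55, 0.9))
  if (with_cbv)
    mol$cbv_coefficients <- lapply(atom_degrees_t(mol), function(d)
      runif(d, -0.06, 0.06))
  mol
}

atom_degrees_t <- function(mol) {
  n <- nrow(mol$positions)
  tabulate(c(mol$bonds[, 1L], mol$bonds[, 2L]), n)
}

## reduced-resolution synthetic world for fast unit tests (acceptance tests
## use the full stated defaults)
tiny_spec <- function(template = "water", model_kind = "pgm-ind", seed = 1L,
                      noise = 0, ...) {
  synthetic_spec(template, model_kind = model_kind, seed = seed,
                 grid_scales = c(1.4, 2.0), grid_density = 1.5,
                 surface_density = 2, noise = noise, ...)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3L)))
}

rotate_molecule <- function(mol, Q, shift = c(0, 0, 0)) {
  out <- mol
  out$positions <- sweep(mol$positions %*% t(Q), 2L, shift, `+`)
  out
}

## central-difference gradient of a scalar field f(x), x length-3
num_grad <- function(f, x, h = 1e-5) {
  vapply(1:3, function(i) {
    e <- c(0, 0, 0); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}
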