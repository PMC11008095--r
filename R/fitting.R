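`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit configuration
#'
#' Collects every tunable of the restrained, constrained least-squares fit.
#'
#' @param model_kind `"resp"` (undamped point monopoles, no polarization),
#'   `"pgm-ind"` (Gaussian monopoles + induced dipoles) or `"pgm-perm"`
#'   (additionally permanent CBV dipoles).
#' @param restraint list with elements `a` (hyperbolic restraint strength in
#'   a.u., default 0.0005 for stage 1), `a_stage2` (default 0.001), `b`
#'   (tightness, e, default 0.1), and `apply_to` (`"non-hydrogen"`, the
#'   convention, or `"all"`).  `a = 0` disables the restraint.  The
#'   restraint acts on monopoles only; permanent dipole coefficients are
#'   unrestrained.
#' @param stage 1 or 2 (bookkeeping; [two_stage_fit()] drives stage 2).
#' @param equivalence_groups list of integer vectors over fit-parameter
#'   indices forced equal; `NULL` uses the molecule's own groups.
#' @param frozen_parameters `NULL`, or list with integer `indices` and
#'   numeric `values` held fixed during the fit.
#' @param charge_constraints list of `list(atoms =, total =)` linear
#'   equality constraints on charge subsets, in addition to the always-on
#'   total-charge constraint (disable the latter with
#'   `total_charge_constraint = FALSE`).
#' @param total_charge_constraint logical, default `TRUE`.
#' @param dataset_weights numeric, one positive weight per dataset
#'   (default 1 each).
#' @param max_restraint_iterations,restraint_tolerance controls of the
#'   linearized-restraint fixed-point loop (defaults 50 and 1e-8 e).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(model_kind = c("resp", "pgm-ind", "pgm-perm"),
                       restraint = list(), stage = 1L,
                       equivalence_groups = NULL, frozen_parameters = NULL,
                       charge_constraints = list(),
                       total_charge_constraint = TRUE,
                       dataset_weights = NULL,
                       max_restraint_iterations = 50L,
                       restraint_tolerance = 1e-8) {
  model_kind <- match.arg(model_kind)
  r <- list(a = restraint$a %||% 5e-4, a_stage2 = restraint$a_stage2 %||% 1e-3,
            b = restraint$b %||% 0.1,
            apply_to = restraint$apply_to %||% "non-hydrogen")
  if (!r$apply_to %in% c("non-hydrogen", "all"))
    stop("restraint$apply_to must be 'non-hydrogen' or 'all'")
  if (r$b <= 0) stop("restraint tightness b must be > 0")
  structure(list(model_kind = model_kind, restraint = r,
                 stage = as.integer(stage),
                 equivalence_groups = equivalence_groups,
                 frozen_parameters = frozen_parameters,
                 charge_constraints = charge_constraints,
                 total_charge_constraint = isTRUE(total_charge_constraint),
                 dataset_weights = dataset_weights,
                 max_restraint_iterations = as.integer(max_restraint_iterations),
                 restraint_tolerance = restraint_tolerance),
            class = "fit_config")
}

## ---- linear ESP operator ----------------------------------------------
## V_model = Bq %*% q + Bp %*% p_loc + offset for one dataset; the exact
## linear map the least-squares fit inverts.  A^-1 applications go through a
## Cholesky factorization, never an explicit inverse of the design pipeline.
esp_operator <- function(molecule, kind, dataset, include_direct = TRUE) {
  grid <- dataset$grid
  surface <- dataset$surface
  au <- mol_au(molecule)
  pts_au <- grid$points * ANG_TO_BOHR
  n <- nrow(au$pos)
  m <- nrow(surface$positions)
  G <- nrow(pts_au)
  nslots <- if (kind == "pgm-perm") nrow(cbv_slots(molecule)) else 0L

  radii <- if (kind == "resp") numeric(n) else au$R
  X <- matrix(0, G, n)
  for (i in seq_len(n))
    X[, i] <- charge_potential_column(au$pos[i, ], radii[i], pts_au)

  Sdir <- NULL
  offset <- numeric(G)
  if (m > 0L && include_direct) {
    sau <- surf_au(surface)
    for (l in seq_len(m))
      offset <- offset + sau$q[l] *
        charge_potential_column(sau$pos[l, ], sau$R[l], pts_au)
  }

  if (kind == "resp") {
    return(list(Bq = X, Bp = matrix(0, G, 0L), offset = offset,
                polidx = integer(0)))
  }

  Y <- matrix(0, G, 3L * n)
  for (i in seq_len(n))
    Y[, (3L * i - 2L):(3L * i)] <-
      dipole_potential_block(au$pos[i, ], au$R[i], pts_au)

  polidx <- which(au$alpha > 0)
  Bq <- X
  Bp <- if (nslots > 0L) Y %*% cbv_frame_matrix(molecule) * ANG_TO_BOHR
        else matrix(0, G, 0L)
  if (length(polidx) > 0L) {
    fm <- field_matrices(molecule, surface)
    ridx <- as.vector(rbind(3L * polidx - 2L, 3L * polidx - 1L, 3L * polidx))
    sub <- molecule
    sub$positions <- molecule$positions[polidx, , drop = FALSE]
    sub$gauss_radii <- molecule$gauss_radii[polidx]
    sub$polarizabilities <- molecule$polarizabilities[polidx]
    A <- suppressWarnings(build_A(sub))
    ch <- chol(A)
    Ypol <- Y[, ridx, drop = FALSE]
    AinvC <- backsolve(ch, forwardsolve(t(ch), fm$C[ridx, , drop = FALSE]))
    Bq <- X + Ypol %*% AinvC
    if (nslots > 0L) {
      AinvD <- backsolve(ch, forwardsolve(t(ch), fm$D[ridx, , drop = FALSE]))
      Bp <- (Y + Ypol %*% AinvD) %*% cbv_frame_matrix(molecule) * ANG_TO_BOHR
    }
    if (m > 0L) {
      Esurf <- drop(fm$Cs[ridx, , drop = FALSE] %*% surface$charges)
      musurf <- backsolve(ch, forwardsolve(t(ch), Esurf))
      offset <- offset + drop(Ypol %*% musurf)
    }
  }
  list(Bq = Bq, Bp = Bp, offset = offset, polidx = polidx)
}

## induced dipoles (3n a.u. vector, zeros on alpha = 0 atoms) of a molecule
## with given static parameters in a given surface environment
induced_dipoles <- function(molecule, kind, surface) {
  n <- nrow(molecule$positions)
  mu <- numeric(3L * n)
  if (kind == "resp") return(mu)
  polidx <- which(molecule$polarizabilities > 0)
  if (length(polidx) == 0L) return(mu)
  E <- static_field(molecule, surface)
  ridx <- as.vector(rbind(3L * polidx - 2L, 3L * polidx - 1L, 3L * polidx))
  sub <- molecule
  sub$positions <- molecule$positions[polidx, , drop = FALSE]
  sub$gauss_radii <- molecule$gauss_radii[polidx]
  sub$polarizabilities <- molecule$polarizabilities[polidx]
  A <- suppressWarnings(build_A(sub))
  mu[ridx] <- solve_induced(A, E[ridx])
  mu
}

## model ESP of a parametrized molecule in a dataset's environment
predict_esp <- function(molecule, kind, dataset, include_direct = TRUE) {
  mu <- induced_dipoles(molecule, kind, dataset$surface)
  if (kind == "pgm-perm") {
    V <- model_esp(molecule, mu = mu, surface = dataset$surface,
                   grid = dataset$grid,
                   include_direct_surface = include_direct)
  } else {
    tmp <- molecule
    tmp$cbv_coefficients <- NULL
    V <- model_esp(tmp, mu = mu, surface = dataset$surface,
                   grid = dataset$grid,
                   include_direct_surface = include_direct,
                   point_charges = (kind == "resp"))
  }
  V
}

#' Assemble the fitting design matrix
#'
#' Builds the exact linear map from the free parameters (charges `q`, and
#' CBV coefficients `p_loc` for the pGM-perm kind) to the model ESP stacked
#' over one or more datasets, with the per-dataset constant offset carrying
#' the surface-charge contributions (their direct potential plus the ESP of
#' the surface-induced atomic dipoles).  Rows are scaled by
#' `sqrt(point_weight * dataset_weight)`.  All applications of the
#' polarizability matrix inverse go through a Cholesky factorization.
#'
#' @param molecule a [molecule_model()].
#' @param datasets an [esp_dataset()] or list of them (identical geometry).
#' @param config a [fit_config()].
#' @return list with `design` (rows x n_par), `offset`, scaled `target`
#'   (QM ESP minus offset), `weights` (per stacked row), `row_dataset`
#'   (dataset index per row) and `n_charge` (number of charge columns).
#' @export
build_design <- function(molecule, datasets, config) {
  if (inherits(datasets, "esp_dataset")) datasets <- list(datasets)
  nd <- length(datasets)
  if (nd < 1L) stop("at least one dataset is required")
  for (d in datasets) {
    if (!inherits(d, "esp_dataset")) stop("datasets must be esp_dataset objects")
    if (!same_conformation(molecule, d$molecule))
      stop("dataset geometry differs from the molecule being fitted ",
           "(conformations must be identical across media)")
  }
  dw <- config$dataset_weights %||% rep(1, nd)
  if (length(dw) != nd || any(dw < 0))
    stop("dataset_weights must be non-negative, one per dataset")
  kind <- config$model_kind
  ops <- lapply(datasets, function(d) esp_operator(molecule, kind, d))
  n <- nrow(molecule$positions)
  blocks <- vector("list", nd)
  targets <- vector("list", nd)
  weights <- vector("list", nd)
  rowd <- vector("list", nd)
  for (k in seq_len(nd)) {
    op <- ops[[k]]
    w <- datasets[[k]]$grid$point_weights * dw[k]
    sw <- sqrt(w)
    blocks[[k]] <- cbind(op$Bq, op$Bp) * sw
    targets[[k]] <- (datasets[[k]]$grid$qm_potentials - op$offset) * sw
    weights[[k]] <- w
    rowd[[k]] <- rep(k, length(sw))
  }
  list(design = do.call(rbind, blocks),
       offset = unlist(lapply(ops, `[[`, "offset")),
       target = unlist(targets), weights = unlist(weights),
       row_dataset = unlist(rowd), n_charge = n,
       operators = ops)
}

## equivalence/freezing reduction: full parameter vector u = M theta + u0
reduction_map <- function(npar, groups, frozen) {
  u0 <- numeric(npar)
  fixed <- logical(npar)
  if (!is.null(frozen) && length(frozen$indices)) {
    idx <- as.integer(frozen$indices)
    if (any(idx < 1L | idx > npar)) stop("frozen parameter index out of range")
    u0[idx] <- frozen$values
    fixed[idx] <- TRUE
  }
  rep_of <- seq_len(npar)
  for (g in groups %||% list()) {
    g <- as.integer(g)
    g <- g[g <= npar]                  # groups may address absent CBV slots
    if (length(g) < 2L) next
    if (any(fixed[g]) && !all(fixed[g]))
      stop("equivalence group mixes frozen and free parameters")
    rep_of[g] <- min(g)
  }
  free_reps <- sort(unique(rep_of[!fixed]))
  col_of <- match(rep_of, free_reps)
  M <- matrix(0, npar, length(free_reps))
  live <- !fixed
  M[cbind(which(live), col_of[live])] <- 1
  list(M = M, u0 = u0, free_reps = free_reps, fixed = fixed)
}

## constraint rows over the full parameter vector
constraint_system <- function(molecule, config, npar) {
  rows <- list(); rhs <- numeric(0)
  n <- nrow(molecule$positions)
  if (config$total_charge_constraint) {
    r <- numeric(npar); r[seq_len(n)] <- 1
    rows <- c(rows, list(r)); rhs <- c(rhs, molecule$total_charge)
  }
  for (cc in config$charge_constraints) {
    idx <- as.integer(cc$atoms)
    if (any(idx < 1L | idx > n)) stop("charge constraint references bad atom")
    r <- numeric(npar); r[idx] <- 1
    rows <- c(rows, list(r)); rhs <- c(rhs, cc$total)
  }
  list(G = if (length(rows)) do.call(rbind, rows) else
         matrix(0, 0L, npar), g = rhs)
}

## small rolling hash for provenance stamps (not cryptographic)
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

#' Restrained, constrained least-squares ESP fit
#'
#' Minimizes the weighted sum of squared deviations between model and
#' reference ESP over all datasets, plus the hyperbolic charge restraint
#' \eqn{a \sum_i (\sqrt{q_i^2 + b^2} - b)}, subject to equality constraints
#' (total charge, optional subset charges) imposed exactly via Lagrange
#' multipliers.  Chemical equivalence is imposed by parameter reduction, so
#' equivalenced parameters are bitwise equal in the result.  The restraint
#' is linearized and iterated to self-consistency in the standard RESP
#' manner; charges start from zero (or the frozen values), matching the
#' two-stage protocol's initialization.
#'
#' @param molecule a [molecule_model()].
#' @param datasets an [esp_dataset()] or list of them sharing the geometry.
#' @param config a [fit_config()].
#' @return object of class `esp_fit` with the fitted molecule, per-dataset
#'   `rmse`/`rrmse` (atomic units / fraction), restraint `iterations`,
#'   condition diagnostics and provenance.
#' @export
fit_esp <- function(molecule, datasets, config = fit_config()) {
  if (inherits(datasets, "esp_dataset")) datasets <- list(datasets)
  kind <- config$model_kind
  des <- build_design(molecule, datasets, config)
  n <- des$n_charge
  npar <- ncol(des$design)

  groups <- config$equivalence_groups %||% molecule$equivalence_groups
  red <- reduction_map(npar, groups, config$frozen_parameters)
  M <- red$M; u0 <- red$u0
  nfree <- ncol(M)
  if (nrow(des$design) < nfree)
    warning("fewer ESP points (", nrow(des$design), ") than free parameters (",
            nfree, "); the unrestrained fit is under-determined")

  cs <- constraint_system(molecule, config, npar)
  Gr <- cs$G %*% M
  gr <- cs$g - drop(cs$G %*% u0)
  if (nrow(Gr) > 0L) {
    zero_row <- rowSums(abs(Gr)) < 1e-14
    if (any(zero_row & abs(gr) > 1e-9))
      stop("constraint involves only frozen parameters and is inconsistent")
    Gr <- Gr[!zero_row, , drop = FALSE]
    gr <- gr[!zero_row]
    if (nrow(Gr) > 0L && qr(Gr)$rank < nrow(Gr))
      stop("constraint rows are linearly dependent; remove redundant rows")
  }

  ## normal equations in reduced coordinates
  y <- des$target - des$design %*% u0
  DM <- des$design %*% M
  H <- crossprod(DM)
  cvec <- crossprod(DM, y)

  a_stage <- if (config$stage >= 2L) config$restraint$a_stage2
             else config$restraint$a
  a_atom <- numeric(npar)
  restrained <- seq_len(n)
  if (config$restraint$apply_to == "non-hydrogen")
    restrained <- restrained[molecule$elements != "H"]
  a_atom[restrained] <- a_stage
  b <- config$restraint$b

  ncon <- nrow(Gr)
  theta <- numeric(nfree)
  u <- drop(M %*% theta) + u0
  iters <- 0L
  restrained_on <- any(a_atom > 0)
  repeat {
    iters <- iters + 1L
    if (restrained_on) {
      w_restr <- a_atom / sqrt(u^2 + b^2)
      Hr <- H + crossprod(M * sqrt(w_restr))
    } else Hr <- H
    K <- rbind(cbind(Hr, t(Gr)), cbind(Gr, matrix(0, ncon, ncon)))
    rhs <- c(cvec, gr)
    qrk <- qr(K)
    if (qrk$rank < nrow(K))
      stop("constrained normal equations are rank deficient ",
           "(null-space dimension ", nrow(K) - qrk$rank, "); ",
           "parameters are not identifiable from the supplied ESP data")
    sol <- solve(qrk, rhs)
    theta <- sol[seq_len(nfree)]
    u_new <- drop(M %*% theta) + u0
    dq <- if (restrained_on) max(abs((u_new - u)[a_atom > 0])) else 0
    u <- u_new
    if (!restrained_on || dq < config$restraint_tolerance) break
    if (iters >= config$max_restraint_iterations)
      stop("restraint iteration did not converge after ", iters,
           " iterations (last max charge change ", format(dq), " e)")
  }
  kappa <- kappa_estimate(H)

  fitted <- molecule
  fitted$charges <- u[seq_len(n)]
  if (kind == "pgm-perm") {
    slots <- cbv_slots(molecule)
    ploc <- u[n + seq_len(nrow(slots))]
    fitted$cbv_coefficients <- split(ploc, factor(slots$atom, levels = seq_len(n)))
    fitted$cbv_coefficients <- lapply(fitted$cbv_coefficients, as.numeric)
  } else {
    fitted$cbv_coefficients <- NULL
  }

  media <- vapply(datasets, `[[`, "", "medium")
  rmse <- rrmse <- stats::setNames(numeric(length(datasets)), media)
  for (k in seq_along(datasets)) {
    op <- des$operators[[k]]
    Vm <- drop(op$Bq %*% u[seq_len(n)]) + op$offset
    if (ncol(op$Bp) > 0L)
      Vm <- Vm + drop(op$Bp %*% u[n + seq_len(ncol(op$Bp))])
    e <- rmse_rrmse(Vm, datasets[[k]]$grid$qm_potentials,
                    datasets[[k]]$grid$point_weights)
    rmse[k] <- e[["rmse"]]; rrmse[k] <- e[["rrmse"]]
  }

  prov <- fnv1a_hash(c(kind, format(u0, digits = 15), media,
                       vapply(datasets, function(d) nrow(d$grid$points), 0),
                       format(unlist(config$restraint), digits = 15)))
  structure(list(molecule = fitted, model_kind = kind,
                 charges = fitted$charges,
                 cbv_coefficients = fitted$cbv_coefficients,
                 rmse = rmse, rrmse = rrmse, iterations = iters,
                 condition = kappa, media = media, config = config,
                 provenance = prov, free_parameters = theta,
                 ssr = sum((des$design %*% u - des$target)^2)),
            class = "esp_fit")
}

kappa_estimate <- function(H) {
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

#' @export
print.esp_fit <- function(x, ...) {
  cat("<esp_fit> model", x$model_kind, "| media:",
      paste(x$media, collapse = ", "), "\n")
  cat("  charges:", paste(format(x$charges, digits = 4), collapse = " "), "\n")
  cat("  rrmse:", paste(sprintf("%s=%.4f", names(x$rrmse), x$rrmse),
                        collapse = " "), "\n")
  cat("  restraint iterations:", x$iterations, "\n")
  invisible(x)
}

#' Two-stage fitting protocol
#'
#' Stage 1 fits all parameters from zero initial monopoles (and zero
#' permanent dipoles for pGM-perm), with the supplied equivalencing.  Stage
#' 2 refits only the atoms in `stage2_refit_groups` — conventionally the
#' methyl/methylene groups, whose near-free rotation justifies equivalencing
#' their hydrogens — with equivalence imposed within each listed group,
#' while every other parameter (charges and CBV coefficients alike) is
#' frozen bitwise at its stage-1 value.  The stage-2 restraint strength
#' `restraint$a_stage2` applies.
#'
#' @param molecule a [molecule_model()].
#' @param datasets dataset or list of datasets, as in [fit_esp()].
#' @param stage1_config a [fit_config()] for stage 1.
#' @param stage2_refit_groups list of integer vectors of atom indices; each
#'   vector is refit as one chemically equivalent group.  Empty list means
#'   no stage 2 (the stage-1 result is returned).
#' @return an `esp_fit` for the final parameters, with the stage-1 result
#'   attached as `$stage1`.
#' @export
two_stage_fit <- function(molecule, datasets, stage1_config = fit_config(),
                          stage2_refit_groups = list()) {
  s1 <- fit_esp(molecule, datasets, stage1_config)
  if (length(stage2_refit_groups) == 0L) return(s1)
  n <- nrow(molecule$positions)
  refit_atoms <- sort(unique(unlist(stage2_refit_groups)))
  if (any(refit_atoms < 1L | refit_atoms > n))
    stop("stage-2 refit group references an atom outside the molecule")
  for (cc in stage1_config$charge_constraints) {
    if (!any(cc$atoms %in% refit_atoms))
      stop("stage-2 refit conflicts with a charge constraint whose atoms ",
           "are all frozen")
  }
  nslots <- if (stage1_config$model_kind == "pgm-perm")
    nrow(cbv_slots(molecule)) else 0L
  npar <- n + nslots
  u1 <- c(s1$charges,
          if (nslots > 0L) unlist(s1$cbv_coefficients, use.names = FALSE))
  frozen_idx <- setdiff(seq_len(n), refit_atoms)
  if (nslots > 0L) {
    slots <- cbv_slots(molecule)
    frozen_idx <- c(frozen_idx, n + which(!(slots$atom %in% refit_atoms)))
  }
  cfg2 <- stage1_config
  cfg2$stage <- 2L
  cfg2$equivalence_groups <- stage2_refit_groups
  cfg2$frozen_parameters <- list(indices = frozen_idx,
                                 values = u1[frozen_idx])
  s2 <- fit_esp(molecule, datasets, cfg2)
  s2$stage1 <- s1
  s2
}

#' Dual-solvent combined fit
#'
#' Fits a single parameter set simultaneously to the ESP data of two media,
#' stacking the two systems exactly as multi-conformation RESP stacks
#' conformations.  Dataset weights default to equal and are normalized to
#' sum to one, so fitting a medium against a duplicate of itself reproduces
#' the single-solvent fit exactly (restraint included).
#'
#' @param molecule a [molecule_model()].
#' @param dataset_A,dataset_B two [esp_dataset()]s of the same molecule in
#'   the identical conformation (checked to 1e-6 Angstrom per coordinate).
#' @param config a [fit_config()]; its `dataset_weights` (length 2) are
#'   normalized to sum to 1.
#' @return an `esp_fit`.
#' @export
dual_solvent_fit <- function(molecule, dataset_A, dataset_B,
                             config = fit_config()) {
  if (!same_conformation(dataset_A$molecule, dataset_B$molecule))
    stop("dual-solvent fit requires the identical conformation in both media")
  dw <- config$dataset_weights %||% c(1, 1)
  if (length(dw) != 2L || any(dw < 0) || sum(dw) == 0)
    stop("dual-solvent dataset_weights must be two non-negative numbers")
  config$dataset_weights <- dw / sum(dw)
  fit_esp(molecule, list(dataset_A, dataset_B), config)
}
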