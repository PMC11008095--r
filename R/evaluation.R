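#' RMSE and relative RMSE between model and reference ESP
#'
#' \deqn{RMSE = \sqrt{\sum w (V_m - V_q)^2 / \sum w}}
#' \deqn{RRMSE = RMSE / \sqrt{\sum w V_q^2 / \sum w}}
#' The RRMSE denominator is the (weighted) root-mean-square of the reference
#' ESP — the standard relative-RMSE convention.  Note this convention when
#' comparing percentages across programs; other denominators are in use.
#'
#' @param model_esp,qm_esp numeric vectors of equal length G >= 1 (a.u.).
#' @param weights optional positive weights, default 1.
#' @return named numeric vector `c(rmse =, rrmse =)` (a.u., fraction).
#' @export
rmse_rrmse <- function(model_esp, qm_esp, weights = NULL) {
  G <- length(qm_esp)
  if (G < 1L || length(model_esp) != G)
    stop("model and reference ESP must have equal positive length")
  if (is.null(weights)) weights <- rep(1, G)
  if (length(weights) != G || any(weights <= 0))
    stop("weights must be positive, one per point")
  w <- weights / sum(weights)
  rmse <- sqrt(sum(w * (model_esp - qm_esp)^2))
  qrms <- sqrt(sum(w * qm_esp^2))
  if (qrms == 0) {
    if (rmse > 0)
      stop("RRMSE undefined: reference ESP is identically zero")
    return(c(rmse = 0, rrmse = 0))
  }
  c(rmse = rmse, rrmse = rmse / qrms)
}

#' Evaluate fitted parameters in another medium
#'
#' Applies a fit's static parameters (charges, permanent CBV dipoles) in the
#' environment of `target_dataset`: the induced dipoles are re-solved with
#' the target medium's surface charges — the polarization responds to the
#' new environment — and the model ESP is compared to the target's QM
#' reference.  With the target equal to the fitting dataset this reproduces
#' the fitting errors exactly.
#'
#' @param params_from an `esp_fit` from [fit_esp()] and friends.
#' @param target_dataset an [esp_dataset()] of the same molecule in the
#'   identical conformation.
#' @return named numeric vector `c(rmse =, rrmse =)`.
#' @export
transfer_evaluate <- function(params_from, target_dataset) {
  stopifnot(inherits(params_from, "esp_fit"),
            inherits(target_dataset, "esp_dataset"))
  if (!same_conformation(params_from$molecule, target_dataset$molecule))
    stop("parameter molecule does not match the target dataset's molecule")
  V <- predict_esp(params_from$molecule, params_from$model_kind,
                   target_dataset)
  rmse_rrmse(V, target_dataset$grid$qm_potentials,
             target_dataset$grid$point_weights)
}

#' Cross-medium transfer matrix
#'
#' Fills the full source x target grid of RMSE/RRMSE values: each row is a
#' medium (or medium combination) whose fit supplied the parameters, each
#' column a medium whose ESP is predicted.  Diagonal cells of a
#' single-solvent report equal the fitting errors.  Averages are computed
#' per source, per target and overall, with and without the gas phase
#' (identified by `epsilon == 1`).
#'
#' @param results_by_medium named list of `esp_fit` objects (names = source
#'   media labels).
#' @param datasets_by_medium named list of [esp_dataset()]s (names = target
#'   media labels).
#' @return object of class `transfer_report` with `rmse` and `rrmse`
#'   matrices, `row_means`, `col_means`, `overall`, `overall_excl_gas`.
#' @export
transfer_matrix <- function(results_by_medium, datasets_by_medium) {
  src <- names(results_by_medium)
  tgt <- names(datasets_by_medium)
  if (is.null(src) || is.null(tgt))
    stop("both lists must be named by medium label")
  rmse <- rrmse <- matrix(NA_real_, length(src), length(tgt),
                          dimnames = list(source = src, target = tgt))
  for (s in src) for (t in tgt) {
    fit <- results_by_medium[[s]]
    ds <- datasets_by_medium[[t]]
    if (is.null(fit) || is.null(ds)) {
      message("transfer cell (", s, " -> ", t, ") absent; excluded from averages")
      next
    }
    e <- transfer_evaluate(fit, ds)
    rmse[s, t] <- e[["rmse"]]; rrmse[s, t] <- e[["rrmse"]]
  }
  gas <- vapply(datasets_by_medium, function(d) d$epsilon == 1, TRUE)
  keep <- tgt[!gas]
  structure(list(
    rmse = rmse, rrmse = rrmse,
    row_means = rowMeans(rrmse, na.rm = TRUE),
    col_means = colMeans(rrmse, na.rm = TRUE),
    overall = mean(rrmse, na.rm = TRUE),
    overall_excl_gas = if (length(keep))
      mean(rrmse[, keep, drop = FALSE], na.rm = TRUE) else NA_real_,
    gas_targets = tgt[gas]
  ), class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, digits = 4, ...) {
  cat("<transfer_report> RRMSE (rows: parametrization medium; ",
      "columns: tested medium)\n", sep = "")
  print(round(x$rrmse, digits))
  cat("overall mean RRMSE:", format(x$overall, digits = digits),
      "| excluding gas targets:",
      format(x$overall_excl_gas, digits = digits), "\n")
  invisible(x)
}

#' Molecular dipole moment
#'
#' Total molecular dipole \eqn{\sum_i q_i r_i + \sum_i p_i + \sum_i \mu_i}
#' in Debye (1 e.Angstrom = 4.803204 D).  Origin-independent exactly when
#' the net charge is zero; for charged species the geometric center of the
#' atoms is used as origin (documented convention).
#'
#' @param molecule a [molecule_model()] carrying charges and CBV dipoles.
#' @param mu optional induced dipoles, 3n-vector in atomic units (e.Bohr)
#'   as returned by [solve_induced()].
#' @return length-3 numeric vector (Debye).
#' @export
molecular_dipole <- function(molecule, mu = NULL) {
  pos <- molecule$positions
  n <- nrow(pos)
  origin <- if (abs(sum(molecule$charges)) > 1e-12) colMeans(pos) else c(0, 0, 0)
  d <- drop(crossprod(sweep(pos, 2L, origin), molecule$charges))
  p <- cbv_global_dipoles(molecule)              # e.Angstrom
  d <- d + colSums(matrix(p, ncol = 3L, byrow = TRUE))
  if (!is.null(mu)) {
    if (length(mu) != 3L * n) stop("'mu' must have length 3n")
    d <- d + colSums(matrix(mu, ncol = 3L, byrow = TRUE)) / ANG_TO_BOHR
  }
  d * EA_TO_DEBYE
}

#' Summary statistics of per-molecule dipole magnitudes
#'
#' The average (AVE), root-mean-square magnitude (RMS) and, against a
#' reference column, root-mean-square deviation (RMSD) of dipole-moment
#' magnitudes — the conventions used to compare models and media.
#'
#' @param magnitudes numeric vector of dipole magnitudes (Debye).
#' @param reference optional numeric vector of reference magnitudes.
#' @return named vector `c(ave =, rms =, rmsd =)` (`rmsd` is `NA` without a
#'   reference).
#' @export
dipole_stats <- function(magnitudes, reference = NULL) {
  out <- c(ave = mean(magnitudes), rms = sqrt(mean(magnitudes^2)),
           rmsd = NA_real_)
  if (!is.null(reference)) {
    if (length(reference) != length(magnitudes))
      stop("reference must match length of magnitudes")
    out[["rmsd"]] <- sqrt(mean((magnitudes - reference)^2))
  }
  out
}
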