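no_restraint <- function(kind) fit_config(kind, restraint = list(a = 0))

test_that("design matrix equals the end-to-end model (oracle)", {
  spec <- tiny_spec("water", model_kind = "pgm-perm", seed = 2)
  ds <- forward_esp_dataset(spec, "ACT")
  mol <- spec$molecule
  des <- build_design(mol, ds, fit_config("pgm-perm"))
  op <- des$operators[[1]]
  n <- nrow(mol$positions)

  set.seed(42)
  u <- runif(n + ncol(op$Bp), -0.6, 0.6)
  V_lin <- drop(op$Bq %*% u[1:n] + op$Bp %*% u[-(1:n)]) + op$offset

  trial <- mol
  trial$charges <- u[1:n]
  slots <- cbv_slots(mol)
  trial$cbv_coefficients <- split(u[n + seq_len(nrow(slots))],
                                  factor(slots$atom, levels = 1:n))
  V_full <- pcmresp:::predict_esp(trial, "pgm-perm", ds)
  expect_equal(V_lin, V_full, tolerance = 1e-10)
})

test_that("noise-free recovery for every model kind; constraints exact", {
  for (kind in c("resp", "pgm-ind", "pgm-perm")) {
    spec <- tiny_spec("water", model_kind = kind, seed = 3)
    ds <- forward_esp_dataset(spec, "EDC")
    fit <- fit_esp(spec$molecule, ds, no_restraint(kind))
    expect_lt(max(abs(fit$charges - spec$molecule$charges)), 1e-6)
    if (kind == "pgm-perm") {
      expect_lt(max(abs(unlist(fit$cbv_coefficients) -
                        unlist(spec$molecule$cbv_coefficients))), 1e-6)
    }
    ## total-charge constraint to 1e-10; equivalenced charges bitwise equal
    expect_lt(abs(sum(fit$charges) - spec$molecule$total_charge), 1e-10)
    expect_identical(fit$charges[2], fit$charges[3])
    expect_equal(fit$rrmse[["EDC"]], 0, tolerance = 1e-7)
  }
})

test_that("dataset weighting algebra: two halves equal one whole", {
  spec <- tiny_spec("water", seed = 4)
  ds <- forward_esp_dataset(spec, "WAT")
  cfg1 <- fit_config("pgm-ind")
  f1 <- fit_esp(spec$molecule, ds, cfg1)
  cfg2 <- fit_config("pgm-ind", dataset_weights = c(0.5, 0.5))
  f2 <- fit_esp(spec$molecule, list(ds, ds), cfg2)
  expect_equal(f2$charges, f1$charges, tolerance = 1e-10)
})

test_that("extra charge constraints hold exactly; redundant rows rejected", {
  spec <- tiny_spec("water", seed = 5)
  ds <- forward_esp_dataset(spec, "GAS")
  cfg <- fit_config("pgm-ind", restraint = list(a = 0),
                    equivalence_groups = list(),
                    charge_constraints = list(list(atoms = c(1L, 2L),
                                                   total = -0.4)))
  fit <- fit_esp(spec$molecule, ds, cfg)
  expect_lt(abs(fit$charges[1] + fit$charges[2] + 0.4), 1e-10)

  cfg_bad <- fit_config("pgm-ind",
                        charge_constraints = list(
                          list(atoms = 1:3, total = 0)))  # duplicates total
  expect_error(fit_esp(spec$molecule, ds, cfg_bad), "linearly dependent")
})

test_that("under-determined fits warn; collinear CBV columns error", {
  spec <- tiny_spec("water", model_kind = "resp", seed = 6)
  ds <- forward_esp_dataset(spec, "GAS")
  small <- ds
  small$grid <- esp_grid(ds$grid$points[1:2, ], ds$grid$qm_potentials[1:2])
  expect_warning(
    fit_esp(spec$molecule, small,
            fit_config("resp", restraint = list(a = 0),
                       equivalence_groups = list())),
    "free parameters")

  ## 3 collinear atoms: the middle atom's two CBV columns are exact
  ## negatives of each other -> rank deficiency must be reported
  mol <- molecule_model(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                        c("C", "C", "C"),
                        bonds = rbind(c(1L, 2L), c(2L, 3L)),
                        charges = c(0.1, -0.2, 0.1),
                        polarizabilities = rep(0, 3),
                        gauss_radii = rep(0.8, 3),
                        cbv_coefficients = list(0.05, c(0.02, -0.02), 0.05))
  spec2 <- synthetic_spec(mol, model_kind = "pgm-perm",
                          grid_scales = c(1.4, 2.0), grid_density = 1.5,
                          surface_density = 2, seed = 6)
  ds2 <- forward_esp_dataset(spec2, "GAS")
  expect_error(fit_esp(mol, ds2, no_restraint("pgm-perm")),
               "rank deficient|null-space")
})

test_that("restraint: monotone ESP residual, shrinkage, iteration count", {
  spec <- tiny_spec("water", seed = 7)
  ds <- forward_esp_dataset(spec, "ETH")
  f0 <- fit_esp(spec$molecule, ds, no_restraint("pgm-ind"))
  f1 <- fit_esp(spec$molecule, ds,
                fit_config("pgm-ind", restraint = list(a = 0.01)))
  expect_gte(f1$ssr, f0$ssr)
  expect_gt(f1$iterations, 1)

  ## single-parameter toy: restrained |q| below unrestrained |q|
  m1 <- molecule_model(rbind(c(0, 0, 0)), "C", charges = 0.3,
                       gauss_radii = 0.8)
  s1 <- synthetic_spec(m1, model_kind = "resp", grid_scales = c(1.4, 2.0),
                       grid_density = 2, surface_density = 2, seed = 8)
  d1 <- forward_esp_dataset(s1, "GAS")
  base <- fit_config("resp", restraint = list(a = 0),
                     total_charge_constraint = FALSE)
  rest <- fit_config("resp", restraint = list(a = 0.005),
                     total_charge_constraint = FALSE)
  q_free <- fit_esp(m1, d1, base)$charges
  q_rest <- fit_esp(m1, d1, rest)$charges
  expect_lte(abs(q_rest), abs(q_free) + 1e-12)
})

test_that("nested models: SSR(pgm-perm) <= SSR(pgm-ind) on identical data", {
  spec <- tiny_spec("water", model_kind = "pgm-perm", seed = 9)
  ds <- forward_esp_dataset(spec, "WAT")
  f_ind <- fit_esp(spec$molecule, ds, no_restraint("pgm-ind"))
  f_perm <- fit_esp(spec$molecule, ds, no_restraint("pgm-perm"))
  expect_lte(f_perm$ssr, f_ind$ssr + 1e-14)
})

test_that("fit is invariant to rigid rotation of the entire input", {
  spec <- tiny_spec("water", model_kind = "pgm-perm", seed = 10)
  ds <- forward_esp_dataset(spec, "ACT")
  cfg <- no_restraint("pgm-perm")
  f0 <- fit_esp(spec$molecule, ds, cfg)

  Q <- random_rotation(12); shift <- c(0.4, 2.2, -1.0)
  molr <- rotate_molecule(spec$molecule, Q, shift)
  surfr <- ds$surface
  surfr$positions <- sweep(ds$surface$positions %*% t(Q), 2L, shift, `+`)
  dsr <- esp_dataset(molr,
                     esp_grid(sweep(ds$grid$points %*% t(Q), 2L, shift, `+`),
                              ds$grid$qm_potentials),
                     surfr, medium = ds$medium, epsilon = ds$epsilon)
  fr <- fit_esp(molr, dsr, cfg)
  expect_equal(fr$charges, f0$charges, tolerance = 1e-8)
  ## CBV coefficients are frame-local, hence unchanged
  expect_equal(unlist(fr$cbv_coefficients), unlist(f0$cbv_coefficients),
               tolerance = 1e-8)
})

test_that("two-stage protocol: freezing, equivalencing, residual ordering", {
  spec <- tiny_spec("alkane", model_kind = "resp", seed = 11)
  ds <- forward_esp_dataset(spec, "GAS")
  mol <- spec$molecule
  methyl <- attr(mol, "methyl_hydrogens")
  cfg1 <- fit_config("resp", restraint = list(a = 0, a_stage2 = 0),
                     equivalence_groups = list())
  s1 <- fit_esp(mol, ds, cfg1)

  ## empty refit set: stage-2 result is the stage-1 result
  expect_identical(two_stage_fit(mol, ds, cfg1, list())$charges, s1$charges)

  hyd <- sort(unlist(methyl))
  s2 <- two_stage_fit(mol, ds, cfg1, list(hyd))
  frozen <- setdiff(seq_along(s2$charges), hyd)
  expect_identical(s2$charges[frozen], s1$charges[frozen])  # bitwise
  expect_length(unique(s2$charges[hyd]), 1L)                # one shared H charge
  expect_gte(s2$ssr, s1$ssr - 1e-12)
  expect_lt(abs(sum(s2$charges)), 1e-10)

  ## refitting everything with the same equivalencing equals one stage
  all_single <- as.list(seq_len(nrow(mol$positions)))
  s_all <- two_stage_fit(mol, ds, cfg1, all_single)
  expect_equal(s_all$charges, s1$charges, tolerance = 1e-8)
})

test_that("dual-solvent combined fit: degenerate cases and shared truth", {
  spec <- tiny_spec("water", seed = 12)
  dsA <- forward_esp_dataset(spec, "ETH")
  dsB <- forward_esp_dataset(spec, "WAT")
  cfg <- fit_config("pgm-ind")

  single <- fit_esp(spec$molecule, dsA, cfg)
  dupl <- dual_solvent_fit(spec$molecule, dsA, dsA, cfg)
  expect_equal(dupl$charges, single$charges, tolerance = 1e-10)

  wA <- fit_config("pgm-ind", dataset_weights = c(1, 0))
  onlyA <- dual_solvent_fit(spec$molecule, dsA, dsB, wA)
  expect_equal(onlyA$charges, single$charges, tolerance = 1e-10)

  both <- dual_solvent_fit(spec$molecule, dsA, dsB, no_restraint("pgm-ind"))
  expect_lt(max(abs(both$charges - spec$molecule$charges)), 1e-6)

  shifted <- dsB
  shifted$molecule$positions[1, 1] <- shifted$molecule$positions[1, 1] + 1e-3
  expect_error(dual_solvent_fit(spec$molecule, dsA, shifted, cfg),
               "identical conformation")
})
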