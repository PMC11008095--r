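## Native, versioned text formats.  The quantum-chemistry pipeline this
## package stands in for emits ESP points and PCM surface charges in
## vendor-specific logs; rather than parsing those (version-fragile, out of
## scope) we define documented plain-text grammars and leave vendor
## conversion to external adapter scripts.
##
## ESP dataset grammar (one file per molecule per medium):
##   PCMRESP-ESP 1
##   units {angstrom|bohr}
##   medium <label> <epsilon>
##   counts <natoms> <ngrid> <nsurface>
##   ATOMS                        # element x y z
##   GRID                         # V x y z        (V always in a.u.)
##   SURFACE                      # q x y z radius weight
##   END
##
## Molecule grammar:
##   PCMRESP-MOL 1
##   units {angstrom|bohr}
##   total_charge <integer>
##   counts <natoms> <nbonds>
##   ATOMS                        # element x y z charge alpha radius
##   BONDS                        # i j           (1-based)
##   EQUIV                        # one group of parameter indices per line
##   CBV                          # atom c1 c2 ... (one per incident bond)
##   END
## EQUIV and CBV blocks are optional.
##
## Parameter grammar: see write_parameters().

fmt_num <- function(x) sprintf("% .12e", x)

io_stop <- function(path, lineno, msg) {
  stop(basename(path), ":", lineno, ": ", msg, call. = FALSE)
}

parse_fields <- function(line, n_numeric, path, lineno, lead_char = FALSE) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  want <- n_numeric + as.integer(lead_char)
  if (length(f) != want)
    io_stop(path, lineno, sprintf("expected %d fields, found %d", want,
                                  length(f)))
  vals <- suppressWarnings(as.numeric(f[(1 + lead_char):length(f)]))
  if (anyNA(vals)) io_stop(path, lineno, "malformed numeric field")
  list(lead = if (lead_char) f[1] else NULL, vals = vals)
}

read_header <- function(lines, magic, path) {
  h <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(h) != 2L || h[1] != magic)
    io_stop(path, 1L, paste0("not a ", magic, " file"))
  if (h[2] != "1") io_stop(path, 1L, paste0("unknown format version ", h[2]))
  u <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(u) != 2L || u[1] != "units" || !u[2] %in% c("angstrom", "bohr"))
    io_stop(path, 2L, "expected 'units angstrom' or 'units bohr'")
  list(scale = if (u[2] == "bohr") 1 / ANG_TO_BOHR else 1)
}

#' Write / read an ESP dataset file
#'
#' Serializes one medium's data — geometry, grid with QM potentials, and
#' the PCM surface-charge block (empty in gas phase) — in the package's
#' versioned plain-text grammar (see the source header of `R/io.R` and the
#' vignette).  Coordinates are written in Angstrom; files declaring
#' `units bohr` are normalized on read.  Potentials and charges are always
#' atomic units / e.  Round trips are lossless at 13 significant digits.
#'
#' @param dataset an [esp_dataset()].
#' @param path file path.
#' @return `write_esp_dataset` returns `path` invisibly;
#'   `read_esp_dataset` returns an [esp_dataset()] whose molecule carries
#'   geometry and elements only (parameters live in molecule files).
#' @export
write_esp_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "esp_dataset"))
  mol <- dataset$molecule; g <- dataset$grid; s <- dataset$surface
  n <- nrow(mol$positions); G <- nrow(g$points); m <- nrow(s$positions)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("PCMRESP-ESP 1", "units angstrom",
               paste("medium", dataset$medium, fmt_num(dataset$epsilon)),
               paste("counts", n, G, m), "ATOMS"), con)
  for (i in seq_len(n))
    writeLines(paste(mol$elements[i],
                     paste(fmt_num(mol$positions[i, ]), collapse = " ")), con)
  writeLines("GRID", con)
  for (j in seq_len(G))
    writeLines(paste(fmt_num(g$qm_potentials[j]),
                     paste(fmt_num(g$points[j, ]), collapse = " ")), con)
  writeLines("SURFACE", con)
  for (l in seq_len(m))
    writeLines(paste(fmt_num(s$charges[l]),
                     paste(fmt_num(s$positions[l, ]), collapse = " "),
                     fmt_num(s$radii[l]), fmt_num(s$weights[l])), con)
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_esp_dataset
#' @export
read_esp_dataset <- function(path) {
  lines <- readLines(path)
  hd <- read_header(lines, "PCMRESP-ESP", path)
  med <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(med) != 3L || med[1] != "medium")
    io_stop(path, 3L, "expected 'medium <label> <epsilon>'")
  cnt <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  if (length(cnt) != 4L || cnt[1] != "counts")
    io_stop(path, 4L, "expected 'counts <natoms> <ngrid> <nsurface>'")
  n <- as.integer(cnt[2]); G <- as.integer(cnt[3]); m <- as.integer(cnt[4])
  ln <- 5L
  expect_tag <- function(tag) {
    if (ln > length(lines) || trimws(lines[ln]) != tag)
      io_stop(path, ln, paste0("expected '", tag, "' block marker"))
    ln <<- ln + 1L
  }
  expect_tag("ATOMS")
  el <- character(n); pos <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    p <- parse_fields(lines[ln], 3L, path, ln, lead_char = TRUE)
    el[i] <- p$lead; pos[i, ] <- p$vals; ln <- ln + 1L
  }
  expect_tag("GRID")
  V <- numeric(G); pts <- matrix(0, G, 3L)
  for (j in seq_len(G)) {
    p <- parse_fields(lines[ln], 4L, path, ln)
    V[j] <- p$vals[1]; pts[j, ] <- p$vals[2:4]; ln <- ln + 1L
  }
  expect_tag("SURFACE")
  q <- r <- w <- numeric(m); sp <- matrix(0, m, 3L)
  for (l in seq_len(m)) {
    p <- parse_fields(lines[ln], 6L, path, ln)
    q[l] <- p$vals[1]; sp[l, ] <- p$vals[2:4]
    r[l] <- p$vals[5]; w[l] <- p$vals[6]; ln <- ln + 1L
  }
  expect_tag("END")
  mol <- molecule_model(pos * hd$scale, el)
  esp_dataset(mol, esp_grid(pts * hd$scale, V),
              surface_charge_set(sp * hd$scale, q, r * hd$scale, w),
              medium = med[2], epsilon = as.numeric(med[3]))
}

#' Write / read a molecule definition file
#'
#' Serializes a [molecule_model()] — geometry, bonds, total charge,
#' per-atom charges / polarizabilities / Gaussian radii, equivalence groups
#' and CBV coefficients — in the package's versioned text grammar.
#' Equivalence groups are supplied in the file, not perceived: automatic
#' symmetry detection is a job for input generators.
#'
#' @param molecule a [molecule_model()].
#' @param path file path.
#' @return `write_molecule` returns `path` invisibly; `read_molecule`
#'   returns a validated [molecule_model()].
#' @export
write_molecule <- function(molecule, path) {
  stopifnot(inherits(molecule, "molecule_model"))
  n <- nrow(molecule$positions); nb <- nrow(molecule$bonds)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("PCMRESP-MOL 1", "units angstrom",
               paste("total_charge", molecule$total_charge),
               paste("counts", n, nb), "ATOMS"), con)
  for (i in seq_len(n))
    writeLines(paste(molecule$elements[i],
                     paste(fmt_num(molecule$positions[i, ]), collapse = " "),
                     fmt_num(molecule$charges[i]),
                     fmt_num(molecule$polarizabilities[i]),
                     fmt_num(molecule$gauss_radii[i])), con)
  writeLines("BONDS", con)
  for (k in seq_len(nb))
    writeLines(paste(molecule$bonds[k, 1L], molecule$bonds[k, 2L]), con)
  if (!is.null(molecule$equivalence_groups) &&
      length(molecule$equivalence_groups)) {
    writeLines("EQUIV", con)
    for (g in molecule$equivalence_groups)
      writeLines(paste(g, collapse = " "), con)
  }
  if (!is.null(molecule$cbv_coefficients)) {
    writeLines("CBV", con)
    for (i in seq_len(n)) {
      co <- molecule$cbv_coefficients[[i]]
      if (length(co))
        writeLines(paste(i, paste(fmt_num(co), collapse = " ")), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_molecule
#' @export
read_molecule <- function(path) {
  lines <- readLines(path)
  hd <- read_header(lines, "PCMRESP-MOL", path)
  tc <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(tc) != 2L || tc[1] != "total_charge")
    io_stop(path, 3L, "expected 'total_charge <integer>'")
  cnt <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  if (length(cnt) != 3L || cnt[1] != "counts")
    io_stop(path, 4L, "expected 'counts <natoms> <nbonds>'")
  n <- as.integer(cnt[2]); nb <- as.integer(cnt[3])
  ln <- 5L
  if (trimws(lines[ln]) != "ATOMS") io_stop(path, ln, "expected 'ATOMS'")
  ln <- ln + 1L
  el <- character(n); pos <- matrix(0, n, 3L)
  q <- al <- R <- numeric(n)
  for (i in seq_len(n)) {
    p <- parse_fields(lines[ln], 6L, path, ln, lead_char = TRUE)
    el[i] <- p$lead; pos[i, ] <- p$vals[1:3]
    q[i] <- p$vals[4]; al[i] <- p$vals[5]; R[i] <- p$vals[6]
    ln <- ln + 1L
  }
  if (trimws(lines[ln]) != "BONDS") io_stop(path, ln, "expected 'BONDS'")
  ln <- ln + 1L
  bonds <- matrix(integer(0), ncol = 2L)
  if (nb > 0L) {
    bonds <- matrix(0L, nb, 2L)
    for (k in seq_len(nb)) {
      p <- parse_fields(lines[ln], 2L, path, ln)
      if (any(p$vals != round(p$vals)))
        io_stop(path, ln, "bond indices must be integers")
      if (any(p$vals < 1 | p$vals > n))
        io_stop(path, ln, "bond references a non-existent atom")
      bonds[k, ] <- as.integer(p$vals); ln <- ln + 1L
    }
  }
  groups <- NULL; cbv <- NULL
  while (ln <= length(lines) && trimws(lines[ln]) != "END") {
    tag <- trimws(lines[ln]); ln <- ln + 1L
    if (tag == "EQUIV") {
      groups <- list()
      while (ln <= length(lines) &&
             !trimws(lines[ln]) %in% c("CBV", "END")) {
        p <- parse_fields(lines[ln], length(strsplit(trimws(lines[ln]),
                                                     "\\s+")[[1]]), path, ln)
        if (any(p$vals != round(p$vals)) || any(p$vals < 1))
          io_stop(path, ln, "malformed equivalence group")
        groups[[length(groups) + 1L]] <- as.integer(p$vals)
        ln <- ln + 1L
      }
    } else if (tag == "CBV") {
      cbv <- rep(list(numeric(0)), n)
      while (ln <= length(lines) && trimws(lines[ln]) != "END") {
        f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
        p <- parse_fields(lines[ln], length(f) - 1L, path, ln,
                          lead_char = TRUE)
        i <- suppressWarnings(as.integer(p$lead))
        if (is.na(i) || i < 1L || i > n)
          io_stop(path, ln, "CBV line references a non-existent atom")
        cbv[[i]] <- p$vals; ln <- ln + 1L
      }
    } else io_stop(path, ln - 1L, paste0("unexpected block '", tag, "'"))
  }
  if (ln > length(lines)) io_stop(path, ln, "missing 'END'")
  if (any(R <= 0)) io_stop(path, 5L, "Gaussian radii must be positive")
  molecule_model(pos * hd$scale, el, bonds = bonds,
                 total_charge = as.integer(tc[2]), charges = q,
                 polarizabilities = al, gauss_radii = R * hd$scale,
                 cbv_coefficients = cbv, equivalence_groups = groups)
}

## block-wise provenance hashes let verification name the edited section
param_body_lines <- function(fit) {
  mol <- fit$molecule
  n <- nrow(mol$positions)
  blocks <- list(
    CHARGES = fmt_num(fit$charges),
    ALPHA = fmt_num(mol$polarizabilities),
    RADII = fmt_num(mol$gauss_radii))
  if (!is.null(fit$cbv_coefficients)) {
    cl <- character(0)
    for (i in seq_len(n)) {
      co <- fit$cbv_coefficients[[i]]
      if (length(co)) cl <- c(cl, paste(i, paste(fmt_num(co), collapse = " ")))
    }
    blocks$CBV <- cl
  }
  eg <- fit$config$equivalence_groups %||% mol$equivalence_groups
  if (!is.null(eg) && length(eg))
    blocks$EQUIV <- vapply(eg, paste, "", collapse = " ")
  blocks
}

#' Write / read fitted parameters
#'
#' Lossless round trip of the fitted charges, CBV coefficients,
#' polarizabilities, Gaussian radii and equivalence groups, at 13
#' significant digits in a fixed column order.  The header carries
#' per-block provenance hashes; `read_parameters(..., verify = TRUE)`
#' recomputes them and warns naming any block whose content was edited.
#'
#' @param fit an `esp_fit` from [fit_esp()].
#' @param path file path.
#' @param verify logical; check provenance hashes on read.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a list with `model_kind`, `charges`, `polarizabilities`,
#'   `gauss_radii`, `cbv_coefficients`, `equivalence_groups`,
#'   `provenance`.
#' @export
write_parameters <- function(fit, path) {
  stopifnot(inherits(fit, "esp_fit"))
  blocks <- param_body_lines(fit)
  ## hashes are taken over whitespace-trimmed lines, matching the reader
  hashes <- vapply(names(blocks), function(b)
    paste0(b, ":", fnv1a_hash(trimws(blocks[[b]]))), "")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("PCMRESP-PAR 1",
               paste("model", fit$model_kind),
               paste("provenance", paste(hashes, collapse = " ")),
               paste("natoms", nrow(fit$molecule$positions))), con)
  for (b in names(blocks)) writeLines(c(b, blocks[[b]]), con)
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path, verify = FALSE) {
  lines <- readLines(path)
  h <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(h) != 2L || h[1] != "PCMRESP-PAR")
    io_stop(path, 1L, "not a PCMRESP-PAR file")
  if (h[2] != "1") io_stop(path, 1L, paste0("unknown format version ", h[2]))
  model <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (model[1] != "model") io_stop(path, 2L, "expected 'model <kind>'")
  prov <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (prov[1] != "provenance") io_stop(path, 3L, "expected 'provenance ...'")
  nat <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n <- as.integer(nat[2])
  ln <- 5L
  blocks <- list(); cur <- NULL
  while (ln <= length(lines) && trimws(lines[ln]) != "END") {
    line <- trimws(lines[ln])
    if (line %in% c("CHARGES", "ALPHA", "RADII", "CBV", "EQUIV")) {
      cur <- line; blocks[[cur]] <- character(0)
    } else {
      if (is.null(cur)) io_stop(path, ln, "content before a block marker")
      blocks[[cur]] <- c(blocks[[cur]], line)
    }
    ln <- ln + 1L
  }
  if (ln > length(lines)) io_stop(path, ln, "missing 'END'")
  if (verify) {
    stored <- prov[-1]
    for (s in stored) {
      kv <- strsplit(s, ":")[[1]]
      if (!kv[1] %in% names(blocks)) {
        warning("provenance names absent block '", kv[1], "'")
        next
      }
      if (fnv1a_hash(blocks[[kv[1]]]) != kv[2])
        warning("block '", kv[1], "' does not match its provenance hash; ",
                "the file was edited after writing")
    }
  }
  num_block <- function(b, required = TRUE) {
    if (is.null(blocks[[b]])) {
      if (required) io_stop(path, 1L, paste0("missing block '", b, "'"))
      return(NULL)
    }
    v <- suppressWarnings(as.numeric(blocks[[b]]))
    if (anyNA(v) || length(v) != n)
      io_stop(path, 1L, paste0("block '", b, "' must hold ", n, " numbers"))
    v
  }
  cbv <- NULL
  if (!is.null(blocks$CBV)) {
    cbv <- rep(list(numeric(0)), n)
    for (line in blocks$CBV) {
      f <- strsplit(line, "\\s+")[[1]]
      i <- as.integer(f[1])
      cbv[[i]] <- as.numeric(f[-1])
    }
  }
  groups <- NULL
  if (!is.null(blocks$EQUIV))
    groups <- lapply(blocks$EQUIV,
                     function(l) as.integer(strsplit(l, "\\s+")[[1]]))
  list(model_kind = model[2], charges = num_block("CHARGES"),
       polarizabilities = num_block("ALPHA"), gauss_radii = num_block("RADII"),
       cbv_coefficients = cbv, equivalence_groups = groups,
       provenance = paste(prov[-1], collapse = " "))
}

#' Write a transfer report as CSV tables
#'
#' Emits `<prefix>_rrmse.csv` and `<prefix>_rmse.csv` (source x target
#' matrices) plus `<prefix>_long.csv` in long format with one row per
#' (source, target) cell.
#'
#' @param report a `transfer_report` from [transfer_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_transfer_report <- function(report, prefix) {
  stopifnot(inherits(report, "transfer_report"))
  p1 <- paste0(prefix, "_rrmse.csv"); p2 <- paste0(prefix, "_rmse.csv")
  p3 <- paste0(prefix, "_long.csv")
  utils::write.csv(report$rrmse, p1)
  utils::write.csv(report$rmse, p2)
  long <- expand.grid(source = rownames(report$rrmse),
                      target = colnames(report$rrmse),
                      stringsAsFactors = FALSE)
  long$rmse <- as.vector(report$rmse)
  long$rrmse <- as.vector(report$rrmse)
  utils::write.csv(long, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a fit configuration file
#'
#' Debian-control-style (`key: value`) configuration consumed by the
#' command line.  Recognized keys: `model_kind`, `stage`, `restraint_a`,
#' `restraint_a_stage2`, `restraint_b`, `restraint_apply_to`,
#' `dataset_weights` (comma separated), `total_charge_constraint`
#' (`yes`/`no`).  Missing keys take the [fit_config()] defaults.
#'
#' @param path file path.
#' @return a [fit_config()].
#' @export
read_fit_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(k) if (!is.null(d[[k]])) as.numeric(d[[k]]) else NULL
  fit_config(
    model_kind = d$model_kind %||% "resp",
    restraint = list(a = num("restraint_a"),
                     a_stage2 = num("restraint_a_stage2"),
                     b = num("restraint_b"),
                     apply_to = d$restraint_apply_to),
    stage = as.integer(d$stage %||% 1L),
    dataset_weights = if (!is.null(d$dataset_weights))
      as.numeric(strsplit(d$dataset_weights, ",")[[1]]) else NULL,
    total_charge_constraint = is.null(d$total_charge_constraint) ||
      tolower(d$total_charge_constraint) %in% c("yes", "true", "1"))
}
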