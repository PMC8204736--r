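#' Read a molecule with conformers
#'
#' XYZ input needs a side-car bond list (`bonds` argument: a file of
#' `i j [order]` lines, or a matrix); SDF V2000 carries its own bonds.
#' Multi-record files (multi-frame XYZ, multi-record SDF with matching
#' atom sequences) yield multiple conformers of one molecule.
#'
#' @param path input file.
#' @param format `"xyz"` or `"sdf"`.
#' @param bonds for XYZ: path to a bond-list file or an integer matrix;
#'   if omitted, bonds are perceived from distances (heuristic,
#'   covalent-radius sum x 1.2) with a warning.
#' @param net_charge net molecular charge (e).
#' @param name molecule name; defaults to the file title line.
#' @return list with `molecule` and `conformers`.
#' @export
read_molecule <- function(path, format = c("xyz", "sdf"), bonds = NULL,
                          net_charge = 0L, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") read_xyz_molecule(path, bonds, net_charge, name)
  else read_sdf_molecule(path, net_charge, name)
}

read_xyz_molecule <- function(path, bonds, net_charge, name) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    title <- if (i + 1L <= length(lines)) trimws(lines[i + 1L]) else ""
    block <- lines[seq.int(i + 2L, length.out = nat)]
    if (length(block) < nat || anyNA(block)) stop("truncated XYZ record")
    tok <- strsplit(trimws(block), "\\s+")
    elements <- vapply(tok, `[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(elements = elements, xyz = xyz,
                                          title = title)
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("no XYZ records found")
  elements <- frames[[1L]]$elements
  for (f in frames) {
    if (!identical(f$elements, elements)) {
      stop("atom sequence mismatch across XYZ records")
    }
  }
  bond_mat <- if (is.null(bonds)) {
    warning("no bond list supplied; perceiving bonds from distances (heuristic)")
    perceive_bonds(elements, frames[[1L]]$xyz)
  } else if (is.character(bonds)) {
    read_bond_list(bonds)
  } else {
    as.matrix(bonds)
  }
  if (is.null(name)) {
    name <- if (nzchar(frames[[1L]]$title)) frames[[1L]]$title else
      sub("\\.[^.]*$", "", basename(path))
  }
  mol <- molecule(elements, bond_mat, net_charge, name)
  list(molecule = mol,
       conformers = lapply(frames, function(f) conformer(mol, f$xyz)))
}

#' Read / write a side-car bond list
#'
#' Plain text, one bond per line: `i j [order]`, 1-based atom indices;
#' `#` comments allowed.
#'
#' @param path file path.
#' @return integer matrix with columns i, j, order.
#' @export
read_bond_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(matrix(integer(0), ncol = 3L))
  tok <- strsplit(lines, "\\s+")
  m <- t(vapply(tok, function(t) {
    v <- as.integer(t)
    if (length(v) == 2L) v <- c(v, 1L)
    if (length(v) != 3L || anyNA(v)) stop("malformed bond line")
    v
  }, integer(3)))
  colnames(m) <- c("i", "j", "order")
  m
}

#' Write a molecule as XYZ plus bond list
#'
#' @param conformers list of [conformer()]s (written as successive frames).
#' @param path output XYZ path.
#' @param bonds_path optional output path for the side-car bond list.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(conformers, path, bonds_path = NULL) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  mol <- conformers[[1L]]$molecule
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    writeLines(c(as.character(nrow(cf$coordinates)), mol$name), con)
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", mol$elements,
                       cf$coordinates[, 1], cf$coordinates[, 2],
                       cf$coordinates[, 3]), con)
  }
  if (!is.null(bonds_path)) {
    writeLines(c("# i j order",
                 sprintf("%d %d %d", mol$bonds[, "i"], mol$bonds[, "j"],
                         mol$bonds[, "order"])), bonds_path)
  }
  invisible(path)
}

read_sdf_molecule <- function(path, net_charge, name) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(TRUE, utils::head(lines, -1) == "$$$$")))
  frames <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (all(!nzchar(trimws(rec)))) next
    if (length(rec) < 4L) stop("truncated SDF record")
    counts <- rec[4L]
    nat <- as.integer(substr(counts, 1L, 3L))
    nbd <- as.integer(substr(counts, 4L, 6L))
    if (is.na(nat) || is.na(nbd)) stop("malformed SDF counts line")
    atom_lines <- rec[seq.int(5L, length.out = nat)]
    xyz <- t(vapply(atom_lines, function(l) {
      as.numeric(c(substr(l, 1L, 10L), substr(l, 11L, 20L),
                   substr(l, 21L, 30L)))
    }, numeric(3), USE.NAMES = FALSE))
    elements <- trimws(substr(atom_lines, 32L, 34L))
    bond_lines <- rec[seq.int(5L + nat, length.out = nbd)]
    bnd <- if (nbd > 0L) {
      t(vapply(bond_lines, function(l) {
        as.integer(c(substr(l, 1L, 3L), substr(l, 4L, 6L), substr(l, 7L, 9L)))
      }, integer(3), USE.NAMES = FALSE))
    } else matrix(integer(0), ncol = 3L)
    frames[[length(frames) + 1L]] <- list(elements = elements, xyz = xyz,
                                          bonds = bnd, title = trimws(rec[1L]))
  }
  if (length(frames) == 0L) stop("no SDF records found")
  elements <- frames[[1L]]$elements
  for (f in frames) {
    if (!identical(f$elements, elements)) {
      stop("atom sequence mismatch across SDF records")
    }
  }
  if (is.null(name)) {
    name <- if (nzchar(frames[[1L]]$title)) frames[[1L]]$title else
      sub("\\.[^.]*$", "", basename(path))
  }
  mol <- molecule(elements, frames[[1L]]$bonds, net_charge, name)
  list(molecule = mol,
       conformers = lapply(frames, function(f) conformer(mol, f$xyz)))
}

#' Read and write ESP grids
#'
#' Two dialects: `"fourcol"` — a single file with a `#`-comment header and
#' four columns x y z V (Bohr, Hartree/e; three columns if the grid has no
#' values); `"twofile"` — a psi4-style pair of files, a whitespace-separated
#' x y z points file plus a one-value-per-line ESP file (`values_path`).
#' Numbers are written with 12 significant digits, so write/read
#' round-trips are exact at that precision.
#'
#' @param grid an [esp_grid()].
#' @param path points (or combined) file path.
#' @param dialect `"fourcol"` or `"twofile"`.
#' @param values_path ESP-values file for the two-file dialect.
#' @return `write_esp_grid()` invisibly returns `path`; `read_esp_grid()`
#'   returns an [esp_grid()].
#' @export
write_esp_grid <- function(grid, path, dialect = c("fourcol", "twofile"),
                           values_path = NULL) {
  stopifnot(inherits(grid, "esp_grid"))
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.12e", x)
  if (dialect == "fourcol") {
    header <- c("# ESP grid: coordinates in Bohr, potential in Hartree/e",
                paste0("# phase: ", if (is.na(grid$phase)) "unset" else grid$phase),
                paste0("# provenance: ", paste(grid$provenance, collapse = " | ")))
    body <- if (is.null(grid$values)) {
      paste(fmt(grid$points[, 1]), fmt(grid$points[, 2]), fmt(grid$points[, 3]))
    } else {
      paste(fmt(grid$points[, 1]), fmt(grid$points[, 2]), fmt(grid$points[, 3]),
            fmt(grid$values))
    }
    writeLines(c(header, body), path)
  } else {
    writeLines(paste(fmt(grid$points[, 1]), fmt(grid$points[, 2]),
                     fmt(grid$points[, 3])), path)
    if (!is.null(grid$values)) {
      if (is.null(values_path)) stop("values_path required for twofile dialect")
      writeLines(fmt(grid$values), values_path)
    }
  }
  invisible(path)
}

#' @rdname write_esp_grid
#' @param phase phase tag to assign when reading the two-file dialect.
#' @export
read_esp_grid <- function(path, dialect = c("fourcol", "twofile"),
                          values_path = NULL, phase = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "fourcol") {
    lines <- readLines(path)
    header <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    tok <- strsplit(trimws(body), "\\s+")
    ncol_body <- unique(lengths(tok))
    if (length(ncol_body) != 1L || !ncol_body %in% c(3L, 4L)) {
      stop("fourcol grid file must have 3 or 4 numeric columns")
    }
    num <- t(vapply(tok, as.numeric, numeric(ncol_body)))
    if (anyNA(num) || !all(is.finite(num))) stop("non-finite value in grid file")
    phase_line <- grep("^# phase:", header, value = TRUE)
    if (length(phase_line) == 1L) {
      p <- trimws(sub("^# phase:", "", phase_line))
      if (p %in% c("gas", "aqueous")) phase <- p
    }
    esp_grid(num[, 1:3, drop = FALSE],
             if (ncol_body == 4L) num[, 4L] else NULL,
             phase, paste("read from", basename(path)))
  } else {
    pts <- as.matrix(utils::read.table(path))
    if (ncol(pts) != 3L) stop("points file must have 3 columns")
    vals <- NULL
    if (!is.null(values_path)) {
      vals <- scan(values_path, quiet = TRUE)
      if (length(vals) != nrow(pts)) {
        stop("ESP file length (", length(vals),
             ") does not match point count (", nrow(pts), ")")
      }
    }
    esp_grid(pts, vals, phase, paste("read from", basename(path)))
  }
}

#' Write and read charge sets
#'
#' JSON layout: molecule name, per-atom elements and charges, phase, delta
#' and fit metadata. The mol2 writer emits a minimal TRIPOS block with the
#' charges in the atom-record charge column and a comment line
#' `RESP2 delta=<delta>`; [read_mol2_charges()] recovers the charge column.
#'
#' @param charges a [charge_set()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_charge_json <- function(charges, path) {
  stopifnot(inherits(charges, "charge_set"))
  obj <- list(molecule = charges$molecule_name,
              net_charge = charges$net_charge,
              phase = charges$phase,
              elements = charges$elements,
              charges = charges$charges,
              metadata = charges$metadata)
  if (!is.null(charges$delta)) obj$delta <- charges$delta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_charge_json
#' @export
read_charge_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mol <- structure(list(name = obj$molecule,
                        elements = obj$elements,
                        bonds = matrix(integer(0), ncol = 3L),
                        net_charge = as.integer(obj$net_charge)),
                   class = "molecule")
  charge_set(obj$charges, obj$phase, mol,
             delta = obj$delta,
             metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' @rdname write_charge_json
#' @param conf a [conformer()] supplying coordinates for the mol2 record.
#' @export
write_mol2_charges <- function(charges, conf, path) {
  stopifnot(inherits(charges, "charge_set"), inherits(conf, "conformer"))
  mol <- conf$molecule
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  delta_tag <- if (charges$phase == "mixed") sprintf("%g", charges$delta)
               else charges$phase
  lines <- c(
    sprintf("# charge type: RESP2 delta=%s", delta_tag),
    "@<TRIPOS>MOLECULE",
    mol$name,
    sprintf("%5d %5d 0 0 0", n, nb),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s 1 %-8s %14.10f",
            seq_len(n), paste0(mol$elements, seq_len(n)),
            conf$coordinates[, 1], conf$coordinates[, 2],
            conf$coordinates[, 3], mol$elements, mol$name,
            charges$charges),
    "@<TRIPOS>BOND")
  if (nb > 0L) {
    lines <- c(lines, sprintf("%6d %5d %5d %d", seq_len(nb),
                              mol$bonds[, "i"], mol$bonds[, "j"],
                              mol$bonds[, "order"]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_charge_json
#' @export
read_mol2_charges <- function(path) {
  lines <- readLines(path)
  a0 <- which(lines == "@<TRIPOS>ATOM")
  if (length(a0) != 1L) stop("no @<TRIPOS>ATOM block")
  out <- list()
  i <- a0 + 1L
  while (i <= length(lines) && !startsWith(lines[i], "@<TRIPOS>")) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    out[[length(out) + 1L]] <- as.numeric(tok[length(tok)])
    i <- i + 1L
  }
  unlist(out)
}

#' Write and read trajectory summaries as delimited text
#'
#' Tab-separated with unit-bearing column headers: `energy_kJ_mol`, and
#' optionally `volume_nm3`, `dipole_x_e_nm`, `dipole_y_e_nm`,
#' `dipole_z_e_nm`; box metadata in `#` header comments.
#'
#' @param summary a [trajectory_summary()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_trajectory_summary <- function(summary, path) {
  stopifnot(inherits(summary, "trajectory_summary"))
  df <- data.frame(energy_kJ_mol = summary$energies)
  if (!is.null(summary$volumes)) df$volume_nm3 <- summary$volumes
  if (!is.null(summary$dipoles)) {
    df$dipole_x_e_nm <- summary$dipoles[, 1]
    df$dipole_y_e_nm <- summary$dipoles[, 2]
    df$dipole_z_e_nm <- summary$dipoles[, 3]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_molecules=%d temperature_K=%.6g pressure_atm=%.6g molar_mass_g_mol=%.8g",
                     summary$n_molecules, summary$temperature,
                     summary$pressure, summary$molar_mass), con)
  utils::write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_summary
#' @export
read_trajectory_summary <- function(path) {
  lines <- readLines(path, n = 1L)
  meta <- list(n_molecules = 1L, temperature = 298, pressure = 1,
               molar_mass = NA_real_)
  if (startsWith(lines[1L], "#")) {
    kv <- strsplit(trimws(sub("^#", "", lines[1L])), "\\s+")[[1L]]
    for (pair in strsplit(kv, "=")) {
      key <- pair[1L]; val <- as.numeric(pair[2L])
      if (key == "n_molecules") meta$n_molecules <- as.integer(val)
      if (key == "temperature_K") meta$temperature <- val
      if (key == "pressure_atm") meta$pressure <- val
      if (key == "molar_mass_g_mol") meta$molar_mass <- val
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  dip <- NULL
  if (all(c("dipole_x_e_nm", "dipole_y_e_nm", "dipole_z_e_nm") %in% names(df))) {
    dip <- as.matrix(df[c("dipole_x_e_nm", "dipole_y_e_nm", "dipole_z_e_nm")])
  }
  trajectory_summary(df$energy_kJ_mol,
                     volumes = df$volume_nm3,
                     dipoles = dip,
                     n_molecules = meta$n_molecules,
                     temperature = meta$temperature,
                     pressure = meta$pressure,
                     molar_mass = meta$molar_mass)
}

#' Flat key=value run configuration
#'
#' @param path file path.
#' @param config named list of scalar values (numerics, strings, logicals);
#'   numeric vectors are comma-separated.
#' @return `read_run_config()` returns a named list with numeric-looking
#'   values converted.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, digits = 15, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", l)
    key <- trimws(substr(l, 1L, eq - 1L))
    val <- trimws(substr(l, eq + 1L, nchar(l)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
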