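# Parameterized-complex container and plain-text I/O (PDB subset + CSV).

#' Construct a parameterized protein--ligand complex
#'
#' A \code{parameterized_complex} bundles one ligand and one protein, each
#' atom carrying coordinates (\enc{Å}{Angstrom}), a partial charge (e), and
#' AMBER-style Lennard-Jones parameters (\code{rmin_half} in \enc{Å}{A},
#' \code{epsilon} in kcal/mol). Protein atoms are grouped into residues
#' indexed consecutively from 0.
#'
#' @param complex_id character scalar identifying the complex.
#' @param atoms data frame with columns \code{atom_name}, \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{charge}, \code{rmin_half},
#'   \code{epsilon}, \code{residue_index} (0-based for protein atoms, \code{NA}
#'   for ligand atoms) and \code{role} (\code{"protein"} or \code{"ligand"}).
#' @param residue_labels character vector of protein residue labels, one per
#'   residue index; used to name descriptor columns.
#' @return object of class \code{parameterized_complex}.
#' @export
parameterized_complex <- function(complex_id, atoms, residue_labels) {
  required <- c("atom_name", "element", "x", "y", "z", "charge",
                "rmin_half", "epsilon", "residue_index", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stopf("atoms table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  if (!all(atoms$role %in% c("protein", "ligand"))) {
    stopf("atom role must be 'protein' or 'ligand'")
  }
  prot <- atoms[atoms$role == "protein", , drop = FALSE]
  lig <- atoms[atoms$role == "ligand", , drop = FALSE]
  if (nrow(prot) < 1L) stopf("complex '%s' has no protein atoms", complex_id)
  if (nrow(lig) < 1L) stopf("complex '%s' has no ligand atoms", complex_id)
  num <- c("x", "y", "z", "charge", "rmin_half", "epsilon")
  if (!all(vapply(atoms[num], function(v) all(is.finite(v)), logical(1)))) {
    stopf("non-finite coordinate, charge or LJ parameter in complex '%s'", complex_id)
  }
  if (any(atoms$epsilon < 0)) stopf("lj epsilon must be >= 0")
  if (any(atoms$rmin_half <= 0)) stopf("lj rmin_half must be > 0")
  ridx <- sort(unique(prot$residue_index))
  if (!identical(as.integer(ridx), seq_along(ridx) - 1L)) {
    stopf("protein residue indices must be consecutive from 0; got {%s}",
          paste(ridx, collapse = ","))
  }
  if (length(residue_labels) != length(ridx)) {
    stopf("expected %d residue labels, got %d", length(ridx), length(residue_labels))
  }
  structure(
    list(complex_id = as.character(complex_id),
         atoms = atoms,
         residue_labels = as.character(residue_labels)),
    class = "parameterized_complex"
  )
}

#' @export
print.parameterized_complex <- function(x, ...) {
  cat(sprintf("<parameterized_complex '%s': %d residues (%d protein atoms), %d ligand atoms>\n",
              x$complex_id, n_residues(x), nrow(protein_atoms(x)), nrow(ligand_atoms(x))))
  invisible(x)
}

#' Number of protein residues in a complex
#' @param complex a \code{parameterized_complex}.
#' @return integer count \eqn{n_p}.
#' @export
n_residues <- function(complex) length(complex$residue_labels)

#' @rdname n_residues
#' @export
protein_atoms <- function(complex) {
  complex$atoms[complex$atoms$role == "protein", , drop = FALSE]
}

#' @rdname n_residues
#' @export
ligand_atoms <- function(complex) {
  complex$atoms[complex$atoms$role == "ligand", , drop = FALSE]
}

# ---------------------------------------------------------------------------
# PDB subset parsing. Fixed-column ATOM/HETATM records only; minimized
# single-model structures are assumed. First altloc kept, others dropped.

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) stopf("no ATOM/HETATM records in '%s'", path)
  lines <- lines[keep]
  df <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = as.integer(substr(lines, 7, 11)),
    atom_name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    res_seq = as.integer(substr(lines, 23, 26)),
    icode = substr(lines, 27, 27),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    stopf("malformed coordinate field in '%s'", path)
  }
  # derive element from the atom name when columns 77-78 are blank
  blank <- df$element == ""
  df$element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", df$atom_name[blank])
  # keep the first altloc of each (chain, residue, atom name) group
  key <- paste(df$chain, df$res_seq, df$icode, df$atom_name, sep = "|")
  dup <- duplicated(key) & df$altloc != " "
  if (any(dup)) {
    warnf("dropping %d alternate-location atom(s) in '%s' (first altloc kept)",
          sum(dup), path)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

read_param_sidecar <- function(params_path) {
  if (grepl("\\.json$", params_path, ignore.case = TRUE)) {
    tab <- as.data.frame(jsonlite::fromJSON(params_path))
  } else {
    tab <- read.csv(params_path, stringsAsFactors = FALSE)
  }
  need <- c("charge_e", "rmin_half_A", "epsilon_kcal_mol")
  if (!all(need %in% names(tab))) {
    stopf("parameter sidecar '%s' must have columns %s plus atom_serial (or atom_name + res_seq)",
          params_path, paste(need, collapse = ", "))
  }
  if (!("atom_serial" %in% names(tab)) &&
      !all(c("atom_name", "res_seq") %in% names(tab))) {
    stopf("parameter sidecar '%s' must identify atoms by atom_serial or by atom_name + res_seq",
          params_path)
  }
  tab
}

#' Read a parameterized complex from a PDB file and a parameter sidecar
#'
#' Parses fixed-column \code{ATOM}/\code{HETATM} records, joins per-atom
#' partial charges and Lennard-Jones parameters from a CSV or JSON sidecar
#' (columns \code{atom_serial} or \code{atom_name}+\code{res_seq}, plus
#' \code{charge_e}, \code{rmin_half_A}, \code{epsilon_kcal_mol}), and groups
#' protein atoms by PDB residue, re-indexed consecutively from 0. The ligand
#' is selected by residue name; any other non-protein species (waters, ions)
#' are excluded with a warning.
#'
#' @param structure_path path to a PDB file.
#' @param params_path path to the sidecar (CSV or JSON).
#' @param ligand_name residue name identifying the ligand (default
#'   \code{"LIG"}).
#' @param complex_id identifier; defaults to the structure file stem.
#' @return a \code{\link{parameterized_complex}}.
#' @export
read_complex <- function(structure_path, params_path, ligand_name = "LIG",
                         complex_id = NULL) {
  if (is.null(complex_id)) {
    complex_id <- sub("\\.[^.]*$", "", basename(structure_path))
  }
  pdb <- parse_pdb_atoms(structure_path)
  params <- read_param_sidecar(params_path)

  is_lig <- pdb$res_name == ligand_name
  if (!any(is_lig)) {
    stopf("no atoms with ligand residue name '%s' in '%s'", ligand_name, structure_path)
  }
  is_prot <- !is_lig & pdb$record == "ATOM"
  other <- !is_lig & !is_prot
  if (any(other)) {
    warnf("excluding %d HETATM atom(s) of non-ligand species (%s) from '%s'",
          sum(other), paste(unique(pdb$res_name[other]), collapse = ","),
          structure_path)
    pdb <- pdb[!other, , drop = FALSE]
    is_lig <- pdb$res_name == ligand_name
    is_prot <- !is_lig
  }

  if ("atom_serial" %in% names(params)) {
    m <- match(pdb$serial, params$atom_serial)
  } else {
    m <- match(paste(pdb$atom_name, pdb$res_seq),
               paste(params$atom_name, params$res_seq))
  }
  if (anyNA(m)) {
    bad <- pdb[is.na(m), , drop = FALSE]
    stopf("parameter sidecar is missing %d atom(s): %s",
          nrow(bad),
          paste(sprintf("serial %d (%s %s%d)", bad$serial, bad$atom_name,
                        bad$res_name, bad$res_seq), collapse = "; "))
  }

  prot <- pdb[is_prot, , drop = FALSE]
  rkey <- paste(prot$chain, prot$res_seq, prot$icode, sep = "|")
  ukey <- unique(rkey)              # order of appearance
  ridx <- match(rkey, ukey) - 1L
  first <- match(ukey, rkey)
  labels <- ifelse(trimws(prot$chain[first]) == "",
                   paste0(prot$res_name[first], prot$res_seq[first]),
                   paste0(prot$res_name[first], trimws(prot$chain[first]),
                          prot$res_seq[first]))
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = ".")

  atoms <- data.frame(
    atom_name = pdb$atom_name,
    element = pdb$element,
    x = pdb$x, y = pdb$y, z = pdb$z,
    charge = params$charge_e[m],
    rmin_half = params$rmin_half_A[m],
    epsilon = params$epsilon_kcal_mol[m],
    residue_index = NA_integer_,
    role = ifelse(is_lig, "ligand", "protein"),
    stringsAsFactors = FALSE
  )
  atoms$residue_index[is_prot] <- ridx
  parameterized_complex(complex_id, atoms, labels)
}

#' Write a parameterized complex to PDB + sidecar files
#'
#' Inverse of \code{\link{read_complex}} up to PDB coordinate precision
#' (3 decimals, i.e. 1e-3 \enc{Å}{A}). Protein atoms are written as
#' \code{ATOM} records, ligand atoms as \code{HETATM} with residue name
#' \code{ligand_name}.
#'
#' @inheritParams read_complex
#' @param complex a \code{\link{parameterized_complex}}.
#' @return invisibly, the structure path.
#' @export
write_complex <- function(complex, structure_path, params_path,
                          ligand_name = "LIG") {
  at <- complex$atoms
  prot <- at$role == "protein"
  res_seq <- ifelse(prot, at$residue_index + 1L, max(at$residue_index[prot], 0L) + 2L)
  res_name <- character(nrow(at))
  # recover a 3-char residue name from the stored label (strip trailing digits)
  lab <- complex$residue_labels[at$residue_index + 1L]
  res_name[prot] <- substr(sub("[A-Za-z]?[0-9.]+$", "", lab[prot]), 1, 3)
  res_name[!prot] <- ligand_name
  res_name[res_name == ""] <- "RES"
  rec <- ifelse(prot, "ATOM", "HETATM")
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(at)), substr(at$atom_name, 1, 4), " ",
                   res_name, "A", res_seq, " ", at$x, at$y, at$z, 1, 0,
                   substr(at$element, 1, 2))
  writeLines(c(lines, "END"), structure_path)
  side <- data.frame(atom_serial = seq_len(nrow(at)),
                     charge_e = at$charge,
                     rmin_half_A = at$rmin_half,
                     epsilon_kcal_mol = at$epsilon)
  write_numeric_csv(side, params_path)
  invisible(structure_path)
}

#' Assign toy force-field parameters to a bare structure
#'
#' Deterministically maps each element to a (charge, Rmin/2, epsilon) triple
#' from a user-supplied rules table. This stands in for real force-field
#' assignment when building fixtures; the resulting parameters are
#' fixture-quality, not force-field-accurate.
#'
#' @inheritParams read_complex
#' @param rules data frame with columns \code{element}, \code{charge},
#'   \code{rmin_half}, \code{epsilon}; one row per element.
#' @return a \code{\link{parameterized_complex}}.
#' @export
toy_parameterize <- function(structure_path, rules, ligand_name = "LIG",
                             complex_id = NULL) {
  if (is.null(complex_id)) {
    complex_id <- sub("\\.[^.]*$", "", basename(structure_path))
  }
  need <- c("element", "charge", "rmin_half", "epsilon")
  if (!all(need %in% names(rules))) {
    stopf("rules table must have columns %s", paste(need, collapse = ", "))
  }
  pdb <- parse_pdb_atoms(structure_path)
  is_lig <- pdb$res_name == ligand_name
  if (!any(is_lig)) stopf("no ligand ('%s') atoms in '%s'", ligand_name, structure_path)
  m <- match(pdb$element, rules$element)
  if (anyNA(m)) {
    stopf("no parameter rule for element(s): %s",
          paste(unique(pdb$element[is.na(m)]), collapse = ", "))
  }
  prot <- !is_lig
  rkey <- paste(pdb$chain, pdb$res_seq, pdb$icode, sep = "|")[prot]
  ukey <- unique(rkey)
  atoms <- data.frame(
    atom_name = pdb$atom_name, element = pdb$element,
    x = pdb$x, y = pdb$y, z = pdb$z,
    charge = rules$charge[m],
    rmin_half = rules$rmin_half[m],
    epsilon = rules$epsilon[m],
    residue_index = NA_integer_,
    role = ifelse(is_lig, "ligand", "protein"),
    stringsAsFactors = FALSE
  )
  atoms$residue_index[prot] <- match(rkey, ukey) - 1L
  first <- match(ukey, rkey)
  labels <- paste0(pdb$res_name[prot][first], pdb$res_seq[prot][first])
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = ".")
  parameterized_complex(complex_id, atoms, labels)
}

# ---------------------------------------------------------------------------
# Kinetic dataset and descriptor-matrix CSV I/O.

#' Construct a kinetic dataset
#'
#' @param complex_id character vector of unique complex identifiers.
#' @param pkoff numeric vector of \eqn{-\log_{10} k_{off}} labels.
#' @param pkd optional numeric vector of \eqn{-\log_{10} K_d} affinities
#'   (\code{NA} allowed).
#' @return data frame of class \code{kinetic_dataset}.
#' @export
kinetic_dataset <- function(complex_id, pkoff, pkd = NULL) {
  complex_id <- as.character(complex_id)
  if (anyDuplicated(complex_id)) {
    stopf("duplicate complex_id: %s",
          paste(unique(complex_id[duplicated(complex_id)]), collapse = ", "))
  }
  if (!is.numeric(pkoff) || !all(is.finite(pkoff))) {
    stopf("pkoff must be finite numeric")
  }
  if (length(pkoff) != length(complex_id)) stopf("length mismatch: complex_id vs pkoff")
  d <- data.frame(complex_id = complex_id, pkoff = as.numeric(pkoff),
                  stringsAsFactors = FALSE)
  if (!is.null(pkd)) {
    if (length(pkd) != length(complex_id)) stopf("length mismatch: complex_id vs pkd")
    d$pkd <- as.numeric(pkd)
  }
  class(d) <- c("kinetic_dataset", "data.frame")
  d
}

#' Read / write kinetic datasets as CSV
#'
#' CSV columns: \code{complex_id}, \code{pkoff}, optional \code{pkd}.
#' @param csv_path file path.
#' @return \code{read_dataset} returns a \code{\link{kinetic_dataset}}.
#' @export
read_dataset <- function(csv_path) {
  d <- read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "pkoff") %in% names(d))) {
    stopf("dataset CSV '%s' must have columns complex_id, pkoff", csv_path)
  }
  if (!is.numeric(d$pkoff)) stopf("non-numeric pkoff in '%s'", csv_path)
  kinetic_dataset(d$complex_id, d$pkoff, if ("pkd" %in% names(d)) d$pkd)
}

#' @rdname read_dataset
#' @param dataset a \code{\link{kinetic_dataset}}.
#' @export
write_dataset <- function(dataset, csv_path) {
  write_numeric_csv(as.data.frame(dataset), csv_path)
  invisible(csv_path)
}

# full-precision CSV writer (round-trips doubles well below 1e-9 rel. tol.)
write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read / write an interaction-energy matrix as CSV
#'
#' The matrix has one row per complex and \eqn{2 n_p} columns: the van der
#' Waals block (\code{vdw_<residue>}) followed by the electrostatic block
#' (\code{elec_<residue>}). Values are kcal/mol. Written at full double
#' precision so \code{read_matrix(write_matrix(X))} reproduces \code{X} to
#' better than 1e-9 relative tolerance.
#'
#' @param X numeric matrix with complex ids as row names and
#'   \code{vdw_}/\code{elec_} column names.
#' @param csv_path file path.
#' @return \code{read_matrix} returns the matrix.
#' @export
write_matrix <- function(X, csv_path) {
  df <- data.frame(complex_id = rownames(X), as.data.frame(X),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_numeric_csv(df, csv_path)
  invisible(csv_path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(csv_path) {
  d <- read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "complex_id") stopf("matrix CSV '%s' must start with complex_id", csv_path)
  if (anyDuplicated(d$complex_id)) stopf("duplicate complex_id in '%s'", csv_path)
  X <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(X)) stopf("non-numeric descriptor values in '%s'", csv_path)
  rownames(X) <- d$complex_id
  X
}
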