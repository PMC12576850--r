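#' Build an atomic structure table
#'
#' A `qr_structure` is a tibble of atom records — one row per atom — with the
#' columns `serial`, `atom_name`, `element`, `residue_name`, `residue_number`
#' (author numbering), `chain_id`, `x`, `y`, `z` (Angstrom), `occupancy`,
#' `b_iso` (Angstrom^2) and `formal_charge`. All internal selections use
#' (chain, residue number, atom name).
#'
#' @param atoms Data frame with (at least) the columns above; missing
#'   bookkeeping columns get defaults (occupancy 1, b 20, charge 0).
#' @param id Structure identifier (e.g. a PDB code).
#' @param source_path Where the structure came from, if anywhere.
#' @return A `qr_structure` tibble.
#' @export
qr_structure <- function(atoms, id = "", source_path = "") {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(serial = seq_len(nrow(atoms)), occupancy = 1, b_iso = 20,
                   formal_charge = 0L)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  req <- c("serial", "atom_name", "element", "residue_name", "residue_number",
           "chain_id", "x", "y", "z", "occupancy", "b_iso", "formal_charge")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "qrsite_structure_error")
  }
  atoms <- atoms[, req]
  atoms$element <- toupper(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom positions must be finite", class = "qrsite_structure_error")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort("occupancy must lie in [0, 1]", class = "qrsite_structure_error")
  }
  if (any(atoms$b_iso < 0)) {
    abort("b_iso must be >= 0", class = "qrsite_structure_error")
  }
  key <- atom_key(atoms)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate atom identifier(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
          class = "qrsite_structure_error")
  }
  structure(atoms, id = id, source_path = source_path,
            class = c("qr_structure", class(atoms)))
}

#' @export
print.qr_structure <- function(x, ...) {
  cat(sprintf("<qr_structure> '%s': %d atoms, %d residues\n",
              attr(x, "id"), nrow(x), length(unique(residue_key(x)))))
  NextMethod()
}

element_from_name <- function(atom_name, residue_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  known2 <- c("CU", "ZN", "FE", "MG", "MN", "NA", "CL", "CA", "NI", "CO", "BR")
  ifelse(two %in% known2 & toupper(residue_name) %in% c(two, "CU", "ZN", "FE", "HEM", "MG"),
         two, substr(gsub("[^A-Z]", "", nm), 1, 1))
}

#' Read an atomic model (PDB or mmCIF)
#'
#' Parsing is delegated to bio3d; records are normalised into a
#' [qr_structure]. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by altloc letter order). The element is taken from
#' the element column where present, falling back to atom-name heuristics.
#'
#' @param path File path.
#' @param dialect `"pdb"` or `"mmcif"`; default guessed from the extension.
#' @return A [qr_structure].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path), class = "qrsite_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse ", dialect, " file ", path, ": ",
                                     conditionMessage(e)),
                              class = "qrsite_format_error"))
  at <- parsed$atom
  elem <- trimws(at$elesy %||% "")
  elem[is.na(elem) | elem == ""] <- NA_character_
  fallback <- element_from_name(at$elety, at$resid)
  elem <- ifelse(is.na(elem), fallback, toupper(elem))
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = elem,
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_iso = ifelse(is.na(at$b), 20, at$b),
    formal_charge = 0L
  )
  # altloc policy: keep the highest-occupancy conformer, ties by letter order
  atoms <- atoms |>
    dplyr::group_by(.data$chain_id, .data$residue_number, .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial) |>
    dplyr::select(-"altloc")
  qr_structure(atoms, id = sub("\\.[^.]*$", "", basename(path)), source_path = path)
}

#' Write a structure in PDB format
#'
#' Coordinates are written to 3 decimals, occupancy and B to 2; re-reading
#' reproduces the fields to that precision.
#'
#' @param s A [qr_structure] (or compatible atom data frame).
#' @param path Output path.
#' @export
write_structure <- function(s, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path),
                                            class = "qrsite_io_error"))
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("REMARK   written by qrsite %s",
                     as.character(utils::packageVersion("qrsite"))), con)
  if (nrow(s) > 0) {
    std_res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                 "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                 "TYR", "VAL")
    rec <- ifelse(s$residue_name %in% std_res, "ATOM  ", "HETATM")
    name4 <- vapply(seq_len(nrow(s)), function(i) {
      nm <- s$atom_name[i]
      if (nchar(s$element[i]) == 2 || nchar(nm) >= 4) formatC(nm, width = -4) else
        paste0(" ", formatC(nm, width = -3))
    }, character(1))
    lines <- sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, s$serial %% 100000L, name4, "", s$residue_name,
                     substr(s$chain_id, 1, 1), s$residue_number %% 10000L, "",
                     s$x, s$y, s$z, s$occupancy, s$b_iso, s$element)
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by (chain, residue number, atom name)
#'
#' @param s Atom table.
#' @param chain,residue_number,atom_name Selector components; `atom_name`
#'   may be `NULL` for a whole residue.
#' @return The matching rows.
#' @export
select_atoms <- function(s, chain, residue_number, atom_name = NULL) {
  out <- s[s$chain_id == chain & s$residue_number == residue_number, , drop = FALSE]
  if (!is.null(atom_name)) out <- out[out$atom_name %in% atom_name, , drop = FALSE]
  out
}
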