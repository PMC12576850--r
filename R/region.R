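#' Specify a metal site and its chemical interpretation
#'
#' A `site_spec` names the residues forming the carved region, the metal
#' atom(s), and the interpretation under which the site is modelled. The
#' interpretation gives one label per metal atom from
#' `Cu(I)`, `Cu(II)`, `water` (the metal replaced by a water molecule) or
#' `absent` (the metal removed, e.g. a dinuclear site remodelled as
#' mononuclear).
#'
#' @param site_name Site label (e.g. `"CuA"`).
#' @param members Data frame with columns `chain`, `residue_number` and
#'   optionally `backbone` (logical; keep the whole residue including the
#'   backbone, e.g. for an amino-terminal ligand). Waters and metal residues
#'   are always kept whole.
#' @param metals Data frame with `chain`, `residue_number`, `atom_name`
#'   selecting each metal atom.
#' @param interpretation Character vector, one label per metal row.
#' @param label Optional display label; defaults to the collapsed
#'   interpretation.
#' @return A `qr_site_spec`.
#' @export
site_spec <- function(site_name, members, metals, interpretation, label = NULL) {
  members <- tibble::as_tibble(members)
  metals <- tibble::as_tibble(metals)
  if (!("backbone" %in% names(members))) members$backbone <- FALSE
  allowed <- c("Cu(I)", "Cu(II)", "water", "absent")
  if (nrow(metals) > 0) {
    if (length(interpretation) != nrow(metals)) {
      abort("interpretation must name one state per metal atom",
            class = "qrsite_spec_error")
    }
    bad <- setdiff(interpretation, allowed)
    if (length(bad) > 0) {
      abort(paste0("unknown interpretation label(s): ", paste(bad, collapse = ", ")),
            class = "qrsite_spec_error")
    }
  } else {
    interpretation <- character(0)
  }
  structure(list(site_name = site_name, members = members, metals = metals,
                 interpretation = interpretation,
                 label = label %||% paste(if (length(interpretation) == 0) "apo"
                                          else interpretation, collapse = "/")),
            class = "qr_site_spec")
}

metal_charge <- function(label) {
  switch(label, "Cu(I)" = 1L, "Cu(II)" = 2L, "water" = 0L, "absent" = 0L,
         abort(paste0("unknown interpretation: ", label), class = "qrsite_spec_error"))
}

#' Apply a site interpretation to a structure
#'
#' Metal atoms labelled `water` are replaced by a water oxygen at the metal
#' position; metals labelled `absent` are removed. Other atoms are untouched.
#'
#' @param s A [qr_structure].
#' @param spec A [site_spec].
#' @return The modified structure.
#' @export
apply_interpretation <- function(s, spec) {
  if (nrow(spec$metals) == 0) return(s)
  for (i in seq_len(nrow(spec$metals))) {
    m <- spec$metals[i, ]
    row <- which(s$chain_id == m$chain & s$residue_number == m$residue_number &
                   s$atom_name == m$atom_name)
    if (length(row) != 1) {
      abort(sprintf("metal selector %s/%s/%s resolves to %d atoms",
                    m$chain, m$residue_number, m$atom_name, length(row)),
            class = "qrsite_selection_error")
    }
    lab <- spec$interpretation[i]
    if (lab == "water") {
      s$atom_name[row] <- "O"
      s$element[row] <- "O"
      s$residue_name[row] <- "HOH"
    } else if (lab == "absent") {
      s <- s[-row, , drop = FALSE]
    }
  }
  qr_structure(s, id = attr(s, "id") %||% "", source_path = attr(s, "source_path") %||% "")
}

# interpretation labels for metal atoms that survive apply_interpretation()
surviving_metals <- function(spec) {
  keep <- spec$interpretation != "absent"
  metals <- spec$metals[keep, , drop = FALSE]
  labs <- spec$interpretation[keep]
  is_metal <- labs %in% c("Cu(I)", "Cu(II)")
  list(metals = metals[is_metal, , drop = FALSE], labels = labs[is_metal])
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

#' Carve the refined subsystem around a site
#'
#' Side chains of member residues are severed at the C-alpha/C-beta bond
#' (whole residues kept when `backbone = TRUE`); waters and metals are
#' included whole. One hydrogen link atom is recorded per severed covalent
#' bond. Apply the interpretation (metal/water substitutions) with
#' [apply_interpretation()] before carving.
#'
#' @param s A [qr_structure] (with the site's interpretation already applied
#'   via [apply_interpretation()]).
#' @param spec A [site_spec].
#' @return A `qr_region`: atom table (`is_link`, `is_added_h` flags), link
#'   atom records, net charge and spin multiplicity.
#' @export
carve_region <- function(s, spec) {
  keys <- residue_key(s)
  kept_idx <- integer(0)
  for (i in seq_len(nrow(spec$members))) {
    mem <- spec$members[i, ]
    rows <- which(s$chain_id == mem$chain & s$residue_number == mem$residue_number)
    if (length(rows) == 0) {
      abort(sprintf("member residue %s/%s not found", mem$chain, mem$residue_number),
            class = "qrsite_selection_error")
    }
    resname <- s$residue_name[rows[1]]
    whole <- isTRUE(mem$backbone) || resname %in% c("HOH", "WAT") ||
      any(is_metal_element(s$element[rows]))
    if (!whole) rows <- rows[!(s$atom_name[rows] %in% BACKBONE_ATOMS)]
    if (length(rows) == 0) {
      abort(sprintf("member residue %s/%s has no side-chain atoms", mem$chain,
                    mem$residue_number), class = "qrsite_selection_error")
    }
    kept_idx <- c(kept_idx, rows)
  }
  kept_idx <- sort(unique(kept_idx))
  bonds <- detect_bonds(s$element, coords_matrix(s))
  in_region <- seq_len(nrow(s)) %in% kept_idx
  sever <- bonds[xor(in_region[bonds$i], in_region[bonds$j]), , drop = FALSE]
  # orphan check: a kept atom whose every covalent bond is severed
  if (nrow(bonds) > 0) {
    for (a in kept_idx) {
      arows <- bonds$i == a | bonds$j == a
      if (any(arows) && !any(arows & in_region[bonds$i] & in_region[bonds$j]) &&
          !is_metal_element(s$element[a]) && !(s$residue_name[a] %in% c("HOH", "WAT"))) {
        abort(sprintf("severing would orphan kept atom %s %s%d/%s",
                      s$atom_name[a], s$chain_id[a], s$residue_number[a],
                      s$residue_name[a]),
              class = "qrsite_topology_error")
      }
    }
  }
  link <- tibble::tibble(
    qm_chain = character(0), qm_residue_number = integer(0), qm_atom = character(0),
    mm_chain = character(0), mm_residue_number = integer(0), mm_atom = character(0),
    bond_length = numeric(0))
  if (nrow(sever) > 0) {
    qm <- ifelse(in_region[sever$i], sever$i, sever$j)
    mm <- ifelse(in_region[sever$i], sever$j, sever$i)
    link <- tibble::tibble(
      qm_chain = s$chain_id[qm], qm_residue_number = s$residue_number[qm],
      qm_atom = s$atom_name[qm],
      mm_chain = s$chain_id[mm], mm_residue_number = s$residue_number[mm],
      mm_atom = s$atom_name[mm],
      bond_length = link_xh_length(s$element[qm]))
  }
  atoms <- tibble::as_tibble(s[kept_idx, , drop = FALSE])
  atoms$is_link <- FALSE
  atoms$is_added_h <- FALSE
  sm <- surviving_metals(spec)
  net_charge <- sum(residue_formal_charge(atoms)) +
    sum(vapply(spec$interpretation, metal_charge, integer(1)))
  region <- structure(list(atoms = atoms, link_atoms = link,
                           net_charge = as.integer(net_charge),
                           spin_multiplicity = 1L + sum(sm$labels == "Cu(II)"),
                           spec = spec),
                      class = "qr_region")
  place_link_atoms(region, s)
}

# nominal X-H distance for a link atom on a kept atom of the given element
link_xh_length <- function(element) {
  len <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)
  out <- unname(len[toupper(element)])
  out[is.na(out)] <- 1.09
  out
}

residue_formal_charge <- function(atoms) {
  res <- atoms[!duplicated(residue_key(atoms)), , drop = FALSE]
  ifelse(res$residue_name %in% c("ASP", "GLU"), -1L,
         ifelse(res$residue_name %in% c("LYS", "ARG"), 1L, 0L))
}

#' @export
print.qr_region <- function(x, ...) {
  cat(sprintf("<qr_region> %s [%s]: %d atoms (%d link H, %d added H), charge %+d, multiplicity %d\n",
              x$spec$site_name, x$spec$label, nrow(x$atoms),
              sum(x$atoms$is_link), sum(x$atoms$is_added_h),
              x$net_charge, x$spin_multiplicity))
  invisible(x)
}

#' Place (or refresh) hydrogen link atoms
#'
#' Each link hydrogen is positioned on the qm-host to mm-host segment at the
#' configured X-H distance from the qm host. Call again whenever either host
#' has moved.
#'
#' @param region A `qr_region`.
#' @param s The parent structure (supplies mm-host coordinates).
#' @return The region with link-atom rows appended/updated.
#' @export
place_link_atoms <- function(region, s) {
  la <- region$link_atoms
  atoms <- region$atoms[!region$atoms$is_link, , drop = FALSE]
  if (nrow(la) > 0) {
    rows <- vector("list", nrow(la))
    for (i in seq_len(nrow(la))) {
      qm <- select_atoms(atoms, la$qm_chain[i], la$qm_residue_number[i], la$qm_atom[i])
      mm <- select_atoms(s, la$mm_chain[i], la$mm_residue_number[i], la$mm_atom[i])
      if (nrow(qm) != 1 || nrow(mm) != 1) {
        abort("link-atom host could not be resolved", class = "qrsite_selection_error")
      }
      d <- c(mm$x - qm$x, mm$y - qm$y, mm$z - qm$z)
      if (vnorm(d) < 1e-6) {
        abort("link-atom hosts are coincident", class = "qrsite_geometry_error")
      }
      p <- c(qm$x, qm$y, qm$z) + la$bond_length[i] * unitv(d)
      h <- qm
      h$atom_name <- paste0("HL", i)
      h$element <- "H"
      h$x <- p[1]; h$y <- p[2]; h$z <- p[3]
      h$is_link <- TRUE
      h$is_added_h <- FALSE
      h$serial <- max(s$serial, atoms$serial) + i
      rows[[i]] <- h
    }
    atoms <- dplyr::bind_rows(atoms, dplyr::bind_rows(rows))
  }
  region$atoms <- atoms
  region
}

#' Protonate a carved region
#'
#' Adds hydrogens with standard geometric placement: waters get two H; a His
#' that coordinates a metal through one ring N is protonated on the other ring
#' N (non-coordinating His defaults to the NE2 tautomer); Asn amide nitrogens
#' get two in-plane H. Asp/Glu stay deprotonated and Lys/Arg protonated, both
#' counted through formal charges. Net charge and spin multiplicity are
#' updated from the residue charges and metal oxidation states.
#'
#' @param region A `qr_region`.
#' @param s Parent structure (for link-host geometry refresh).
#' @param coordination_cutoff Metal-N distance (Angstrom) below which a ring N
#'   counts as coordinating (default 2.6).
#' @return The protonated region.
#' @export
protonate_region <- function(region, s, coordination_cutoff = 2.6) {
  atoms <- region$atoms[!region$atoms$is_added_h, , drop = FALSE]
  metals <- atoms[is_metal_element(atoms$element) & !atoms$is_link, , drop = FALSE]
  added <- list()
  resk <- unique(residue_key(atoms))
  serial_next <- max(atoms$serial) + 100L
  mk_h <- function(parent, name, pos) {
    h <- parent
    h$atom_name <- name
    h$element <- "H"
    h$x <- pos[1]; h$y <- pos[2]; h$z <- pos[3]
    h$b_iso <- parent$b_iso
    h$is_link <- FALSE
    h$is_added_h <- TRUE
    h$serial <- serial_next
    serial_next <<- serial_next + 1L
    h
  }
  for (rk in resk) {
    res <- atoms[residue_key(atoms) == rk & !atoms$is_link, , drop = FALSE]
    if (nrow(res) == 0) next
    rn <- res$residue_name[1]
    if (rn %in% c("HOH", "WAT")) {
      o <- res[res$element == "O", , drop = FALSE]
      if (nrow(o) != 1) next
      added <- c(added, water_hydrogens(o, atoms, mk_h))
    } else if (rn == "HIS") {
      added <- c(added, his_ring_hydrogen(res, metals, coordination_cutoff, mk_h))
    } else if (rn == "ASN") {
      nd <- res[res$atom_name == "ND2", , drop = FALSE]
      cg <- res[res$atom_name == "CG", , drop = FALSE]
      od <- res[res$atom_name == "OD1", , drop = FALSE]
      if (nrow(nd) == 1 && nrow(cg) == 1 && nrow(od) == 1) {
        added <- c(added, amide_hydrogens(nd, cg, od, mk_h))
      }
    }
  }
  if (length(added) > 0) {
    atoms <- dplyr::bind_rows(atoms, dplyr::bind_rows(added))
  }
  region$atoms <- atoms
  spec <- region$spec
  sm <- surviving_metals(spec)
  region$net_charge <- as.integer(sum(residue_formal_charge(
    atoms[!atoms$is_link & !atoms$is_added_h, , drop = FALSE])) +
      sum(vapply(spec$interpretation, metal_charge, integer(1))))
  region$spin_multiplicity <- 1L + sum(sm$labels == "Cu(II)")
  place_link_atoms(region, s)
}

water_hydrogens <- function(o, atoms, mk_h) {
  op <- c(o$x, o$y, o$z)
  others <- atoms[!(atoms$chain_id == o$chain_id &
                      atoms$residue_number == o$residue_number), , drop = FALSE]
  acc <- others[others$element %in% c("N", "O"), , drop = FALSE]
  # deterministic donor ordering in water-water pairs: a water donates only
  # to lower-numbered waters, so mutual face-to-face donation cannot occur
  is_wat <- acc$residue_name %in% c("HOH", "WAT")
  acc <- acc[!is_wat | acc$residue_number < o$residue_number, , drop = FALSE]
  if (nrow(acc) > 0) {
    d <- sqrt((acc$x - op[1])^2 + (acc$y - op[2])^2 + (acc$z - op[3])^2)
    acc <- acc[order(d), , drop = FALSE]
    d <- sort(d)
    acc <- acc[d < 4.0, , drop = FALSE]
  }
  u1 <- if (nrow(acc) >= 1) unitv(c(acc$x[1], acc$y[1], acc$z[1]) - op) else c(1, 0, 0)
  ax <- if (nrow(acc) >= 2) {
    v2 <- unitv(c(acc$x[2], acc$y[2], acc$z[2]) - op)
    n <- pracma_cross(u1, v2)
    if (vnorm(n) < 1e-6) perp_vector(u1) else unitv(n)
  } else perp_vector(u1)
  u2 <- as.numeric(rotate_about(matrix(u1, 1), ax, 104.5 * pi / 180))
  list(mk_h(o, "H1", op + 0.96 * u1), mk_h(o, "H2", op + 0.96 * u2))
}

his_ring_hydrogen <- function(res, metals, cutoff, mk_h) {
  ringn <- res[res$atom_name %in% c("ND1", "NE2"), , drop = FALSE]
  if (nrow(ringn) == 0) return(list())
  coordin <- vapply(seq_len(nrow(ringn)), function(i) {
    if (nrow(metals) == 0) return(FALSE)
    d <- sqrt((metals$x - ringn$x[i])^2 + (metals$y - ringn$y[i])^2 +
                (metals$z - ringn$z[i])^2)
    any(d <= cutoff)
  }, logical(1))
  if (all(coordin) && nrow(ringn) == 2) {
    abort(sprintf("His %s%d: both ring N atoms are within the coordination cutoff (%s)",
                  res$chain_id[1], res$residue_number[1],
                  paste(ringn$atom_name, collapse = ", ")),
          class = "qrsite_ambiguity_error")
  }
  target <- if (any(coordin)) ringn$atom_name[!coordin] else
    intersect("NE2", ringn$atom_name)
  if (length(target) == 0) target <- ringn$atom_name[1]
  out <- list()
  for (tn in target) {
    n <- res[res$atom_name == tn, , drop = FALSE]
    nb_names <- if (tn == "ND1") c("CG", "CE1") else c("CE1", "CD2")
    nb <- res[res$atom_name %in% nb_names, , drop = FALSE]
    if (nrow(nb) < 2) next
    np <- c(n$x, n$y, n$z)
    u <- unitv(unitv(np - c(nb$x[1], nb$y[1], nb$z[1])) +
                 unitv(np - c(nb$x[2], nb$y[2], nb$z[2])))
    out <- c(out, list(mk_h(n, paste0("H", tn), np + 1.01 * u)))
  }
  out
}

amide_hydrogens <- function(nd, cg, od, mk_h) {
  np <- c(nd$x, nd$y, nd$z)
  cp <- c(cg$x, cg$y, cg$z)
  normal <- pracma_cross(c(od$x, od$y, od$z) - cp, np - cp)
  if (vnorm(normal) < 1e-6) normal <- perp_vector(np - cp)
  # sp2 N-H directions: 120 deg from the N->CG bond, i.e. +-60 deg from the
  # CG->N extension
  u0 <- unitv(np - cp)
  h1 <- as.numeric(rotate_about(matrix(u0, 1), normal, 60 * pi / 180))
  h2 <- as.numeric(rotate_about(matrix(u0, 1), normal, -60 * pi / 180))
  list(mk_h(nd, "HD21", np + 1.01 * h1), mk_h(nd, "HD22", np + 1.01 * h2))
}

#' Export a region as a standalone structure fragment
#'
#' Returns the carved region (including added and link hydrogens) as a
#' [qr_structure] suitable for writing with [write_structure()].
#'
#' @param region A `qr_region`.
#' @return A [qr_structure].
#' @export
region_to_structure <- function(region) {
  a <- region$atoms
  a$serial <- seq_len(nrow(a))
  qr_structure(a[, !(names(a) %in% c("is_link", "is_added_h"))],
               id = paste0(region$spec$site_name, "_region"))
}
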