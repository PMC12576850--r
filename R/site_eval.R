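#' Strain energy of a site
#'
#' The engine energy of the region at the model coordinates (with only the
#' added hydrogens relaxed, heavy atoms and link hydrogens fixed) minus the
#' energy at the link-atom-fixed optimum (everything free except link
#' hydrogens). Both energies and their difference are reported in kJ/mol.
#' The relaxed state is the engine optimum under the same constraints, so the
#' strain is non-negative up to optimiser tolerance.
#'
#' @param region A protonated `qr_region`.
#' @param engine A `qr_engine` over the region's atoms (defaults to the
#'   surrogate).
#' @param coords Optional region coordinate matrix (defaults to the region's
#'   current coordinates).
#' @param tol,max_iter Optimiser settings.
#' @return A one-row tibble (class `qr_strain`): `interpretation`, `e_model`,
#'   `e_relaxed`, `delta_e_str` (kJ/mol), convergence flags.
#' @export
strain_energy <- function(region, engine = NULL, coords = NULL, tol = 1e-3,
                          max_iter = 3000) {
  if (is.null(engine)) engine <- surrogate_engine(region)
  atoms <- region$atoms
  if (is.null(coords)) coords <- coords_matrix(atoms)
  to_kj <- function(e) engine_kcal(engine, e) * KCAL_TO_KJ
  # model state: relax added hydrogens only
  fixed_model <- !(atoms$is_added_h)
  om <- tryCatch(
    optimize_geometry(engine, coords, fixed = fixed_model, tol = tol,
                      max_iter = max_iter, partial = TRUE),
    error = function(e) abort(paste0("strain: model-state optimisation failed: ",
                                     conditionMessage(e)),
                              class = "qrsite_strain_error"))
  # relaxed state: everything free except link hydrogens
  fixed_rel <- atoms$is_link
  orx <- tryCatch(
    optimize_geometry(engine, om$coords, fixed = fixed_rel, tol = tol,
                      max_iter = max_iter, partial = TRUE),
    error = function(e) abort(paste0("strain: relaxed-state optimisation failed: ",
                                     conditionMessage(e)),
                              class = "qrsite_strain_error"))
  out <- tibble::tibble(
    interpretation = region$spec$label,
    e_model = to_kj(om$energy),
    e_relaxed = to_kj(orx$energy),
    delta_e_str = to_kj(om$energy) - to_kj(orx$energy),
    model_converged = om$converged,
    relaxed_converged = orx$converged)
  class(out) <- c("qr_strain", class(out))
  out
}

#' Weight-scan selection rule
#'
#' Scanning the weight grid upward, the selected `w_x` is the highest value
#' reached before the strain energy starts to increase (by more than
#' `rel_tol` relative to the previous grid point) or the average RSCC starts
#' to decrease (by more than `abs_tol`). A flat table selects the maximum of
#' the grid.
#'
#' @param table Data frame with columns `w_x`, `avg_rscc`, `delta_e_str`,
#'   sorted or sortable ascending in `w_x`.
#' @param rel_tol Relative tolerance on strain increase (default 10%).
#' @param abs_tol Absolute tolerance on RSCC decrease (default 0.01).
#' @param strain_floor Absolute strain slack (kJ/mol, default 1): increases
#'   below this never count as "strain started to increase" — near the engine
#'   optimum the strain is close to zero and purely relative comparisons
#'   would trip on chemically meaningless sub-kJ changes.
#' @return The selected `w_x` (an element of the grid).
#' @export
select_weight <- function(table, rel_tol = 0.1, abs_tol = 0.01,
                          strain_floor = 1) {
  tb <- table[order(table$w_x), , drop = FALSE]
  if (nrow(tb) == 0) abort("empty scan table", class = "qrsite_scan_error")
  sel <- tb$w_x[1]
  for (i in seq_len(nrow(tb))[-1]) {
    strain_ok <- tb$delta_e_str[i] <=
      tb$delta_e_str[i - 1] * (1 + rel_tol) + strain_floor
    rscc_ok <- tb$avg_rscc[i] >= tb$avg_rscc[i - 1] - abs_tol
    if (!strain_ok || !rscc_ok) break
    sel <- tb$w_x[i]
  }
  sel
}

#' Scan the map weight and select its working value
#'
#' Runs one refinement per grid value of `w_x` (identical protocol and seed),
#' records the average RSCC and strain energy of each refined site, and
#' applies [select_weight()].
#'
#' @inheritParams refine
#' @param grid Ascending weight grid; the default spans 0-100 in ten values.
#' @param rel_tol,abs_tol Selection-rule tolerances (see [select_weight()]).
#' @return A `qr_weight_scan`: the scan table with attributes `selected_w_x`,
#'   `rel_tol`, `abs_tol`.
#' @export
weight_scan <- function(s, region, exp_map, engine = NULL, topo = NULL,
                        cfg = refinement_config(),
                        grid = c(0, 1, 3, 5, 10, 20, 30, 50, 75, 100),
                        rel_tol = 0.1, abs_tol = 0.01, strain_floor = 1) {
  if (is.unsorted(grid)) abort("weight grid must be ascending", class = "qrsite_scan_error")
  if (is.null(engine)) engine <- surrogate_engine(region)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg_i <- cfg
    cfg_i$w_x <- grid[i]
    fit <- tryCatch(refine(s, region, exp_map, engine = engine, topo = topo, cfg = cfg_i),
                    error = function(e) abort(
                      sprintf("weight scan failed at w_x = %g: %s", grid[i],
                              conditionMessage(e)),
                      class = "qrsite_scan_error"))
    st <- strain_energy(fit$region, engine = engine)
    rows[[i]] <- tibble::tibble(w_x = grid[i],
                                avg_rscc = average_rscc(fit$map_score),
                                delta_e_str = st$delta_e_str)
  }
  tb <- dplyr::bind_rows(rows)
  structure(tb, selected_w_x = select_weight(tb, rel_tol, abs_tol, strain_floor),
            rel_tol = rel_tol, abs_tol = abs_tol,
            class = c("qr_weight_scan", class(tb)))
}

#' Selected weight of a scan
#' @param scan A `qr_weight_scan`.
#' @return The selected `w_x`.
#' @export
selected_weight <- function(scan) attr(scan, "selected_w_x")

#' Compare chemical interpretations of a site
#'
#' Each variant (a [site_spec]) is applied to the structure, carved,
#' protonated, refined with the same configuration (identical `w_x`,
#' protocol and seed — ranking runs with differing `w_x` is refused by
#' construction) and scored by average RSCC, strain energy and a geometry
#' report. Ranking favours low strain among variants whose RSCC is within
#' `rscc_tol` of the best; both values are always reported. Chemically
#' anomalous geometry (metal-carbon contacts, ligand-free metals) is flagged.
#'
#' @param s The deposited/observed [qr_structure].
#' @param variants Named list of [site_spec] variants (names = labels).
#' @param exp_map Experimental [qr_map].
#' @param cfg Shared [refinement_config()].
#' @param params Surrogate-engine parameters.
#' @param rscc_tol RSCC comparability tolerance for the ranking rule.
#' @param strain_tol Strain energies within this (kJ/mol) count as tied and
#'   are ordered by RSCC instead; a wrongly assigned interpretation often
#'   relaxes toward its own energy optimum, leaving only a small strain
#'   difference while the map misfit shows up in the RSCC.
#' @return A `qr_site_report`: scores table (one row per variant, ranked),
#'   per-variant refinements and geometry reports.
#' @export
compare_interpretations <- function(s, variants, exp_map,
                                    cfg = refinement_config(),
                                    params = surrogate_params(),
                                    rscc_tol = 0.05, strain_tol = 2) {
  if (is.null(names(variants)) || any(names(variants) == "")) {
    names(variants) <- vapply(variants, function(v) v$label, character(1))
  }
  ord <- order(names(variants))   # deterministic, input-order invariant
  variants <- variants[ord]
  rows <- vector("list", length(variants))
  fits <- list()
  geos <- list()
  for (i in seq_along(variants)) {
    spec <- variants[[i]]
    lab <- names(variants)[i]
    sv <- apply_interpretation(s, spec)
    region <- carve_region(sv, spec)
    region <- protonate_region(region, sv)
    engine <- surrogate_engine(region, params)
    fit <- refine(sv, region, exp_map, engine = engine, cfg = cfg)
    st <- strain_energy(fit$region, engine = engine)
    geo <- geometry_report(fit$structure, spec)
    flags <- geometry_flags(geo, spec)
    rows[[i]] <- tibble::tibble(
      variant = lab, interpretation = spec$label,
      avg_rscc = average_rscc(fit$map_score),
      delta_e_str = st$delta_e_str,
      e_model = st$e_model, e_relaxed = st$e_relaxed,
      n_region_atoms = nrow(region$atoms),
      flags = paste(flags, collapse = "; "))
    fits[[lab]] <- fit
    geos[[lab]] <- geo
  }
  tb <- dplyr::bind_rows(rows)
  best_rscc <- max(tb$avg_rscc, na.rm = TRUE)
  comparable <- tb$avg_rscc >= best_rscc - rscc_tol
  # primary: low strain among RSCC-comparable variants; strains closer than
  # strain_tol form a tie broken by RSCC (then label, for determinism)
  ord1 <- order(!comparable, tb$delta_e_str)
  cluster <- cumsum(c(1, diff(tb$delta_e_str[ord1]) > strain_tol |
                        diff(!comparable[ord1]) != 0))
  rank_ord <- ord1[order(cluster, -tb$avg_rscc[ord1], tb$variant[ord1])]
  tb <- tb[rank_ord, , drop = FALSE]
  tb$rank <- seq_len(nrow(tb))
  tb$rscc_comparable <- comparable[rank_ord]
  ties <- duplicated(round(tb$delta_e_str, 6)) &
    duplicated(round(tb$avg_rscc, 6))
  tb$tie_with_previous <- ties
  out <- list(site_name = variants[[1]]$site_name, scores = tb,
              refinements = fits, geometry = geos, config = cfg,
              rscc_tol = rscc_tol)
  class(out) <- "qr_site_report"
  out
}

#' Top-ranked interpretation of a site report
#' @param report A `qr_site_report`.
#' @return The variant label ranked first.
#' @export
ranked_first <- function(report) report$scores$variant[1]

#' @export
print.qr_site_report <- function(x, ...) {
  cat(sprintf("<qr_site_report> site %s (%d variants, w_x = %g)\n",
              x$site_name, nrow(x$scores), x$config$w_x))
  df <- as.data.frame(x$scores[, c("rank", "variant", "avg_rscc", "delta_e_str", "flags")])
  df$avg_rscc <- round(df$avg_rscc, 3)
  df$delta_e_str <- round(df$delta_e_str, 1)
  print(df, row.names = FALSE)
  cat("ranking favours low strain at comparable RSCC; inspect both columns.\n")
  invisible(x)
}

geometry_flags <- function(geo, spec) {
  flags <- character(0)
  bonds <- geo[geo$type == "bond", , drop = FALSE]
  for (m in unique(bonds$metal[!is.na(bonds$metal)])) {
    mb <- bonds[bonds$metal == m, , drop = FALSE]
    if (any(mb$partner_element == "C" & mb$value < 2.6)) {
      flags <- c(flags, paste0(m, ": metal-carbon contact"))
    }
    if (!any(mb$partner_element %in% c("N", "O", "S") & mb$value <= 2.6)) {
      flags <- c(flags, paste0(m, ": no ligands within bonding distance"))
    }
  }
  flags
}

#' Geometry report for a metal site
#'
#' All metal-neighbour distances within `cutoff`, donor-metal-donor angles
#' for donors within the bond threshold, coordination numbers, and
#' water hydrogen-bond (O to N/O) distances.
#'
#' @param s A [qr_structure] (interpretation applied).
#' @param site A [site_spec].
#' @param cutoff Neighbour search radius (Angstrom).
#' @param bond_threshold Coordination-number bond threshold (Angstrom).
#' @return A tibble (class `qr_geometry`) with columns `type`
#'   (`bond`/`angle`/`coordination`/`hbond`), `metal`, `partner`,
#'   `partner_element`, `value`, `unit`.
#' @export
geometry_report <- function(s, site, cutoff = 3.5, bond_threshold = 2.6) {
  out <- list()
  m <- coords_matrix(s)
  label_of <- function(i) sprintf("%s %s%d/%s", s$atom_name[i], s$chain_id[i],
                                  s$residue_number[i], s$residue_name[i])
  sm <- surviving_metals(site)
  metal_rows <- integer(0)
  if (nrow(sm$metals) > 0) {
    metal_rows <- vapply(seq_len(nrow(sm$metals)), function(i) {
      hit <- which(s$chain_id == sm$metals$chain[i] &
                     s$residue_number == sm$metals$residue_number[i] &
                     s$atom_name == sm$metals$atom_name[i])
      if (length(hit) != 1) {
        abort("metal selector does not resolve", class = "qrsite_selection_error")
      }
      hit
    }, integer(1))
  }
  for (k in seq_along(metal_rows)) {
    mi <- metal_rows[k]
    mlab <- label_of(mi)
    d <- sqrt(rowSums(sweep(m, 2, m[mi, ], "-")^2))
    nb <- which(d <= cutoff & d > 0.05)
    nb <- nb[order(d[nb])]
    for (j in nb) {
      out[[length(out) + 1]] <- tibble::tibble(
        type = "bond", metal = mlab, partner = label_of(j),
        partner_element = s$element[j], value = d[j], unit = "A")
    }
    donors <- nb[d[nb] <= bond_threshold & s$element[nb] %in% c("N", "O", "S")]
    out[[length(out) + 1]] <- tibble::tibble(
      type = "coordination", metal = mlab, partner = NA_character_,
      partner_element = NA_character_, value = length(donors), unit = "count")
    if (length(donors) >= 2) {
      pr <- utils::combn(donors, 2)
      for (cx in seq_len(ncol(pr))) {
        out[[length(out) + 1]] <- tibble::tibble(
          type = "angle", metal = mlab,
          partner = paste(label_of(pr[1, cx]), label_of(pr[2, cx]), sep = " - "),
          partner_element = NA_character_,
          value = angle_deg(m[pr[1, cx], ], m[mi, ], m[pr[2, cx], ]),
          unit = "deg")
      }
    }
  }
  # water hydrogen-bond distances
  waters <- which(s$residue_name %in% c("HOH", "WAT") & s$element == "O")
  member_keys <- paste(site$members$chain, site$members$residue_number, sep = "|")
  waters <- waters[residue_key(s)[waters] %in% member_keys]
  for (wi in waters) {
    d <- sqrt(rowSums(sweep(m, 2, m[wi, ], "-")^2))
    acc <- which(s$element %in% c("N", "O") & d <= 3.5 & d > 0.05 &
                   residue_key(s) != residue_key(s)[wi])
    for (j in acc) {
      out[[length(out) + 1]] <- tibble::tibble(
        type = "hbond", metal = NA_character_,
        partner = paste(label_of(wi), label_of(j), sep = " - "),
        partner_element = s$element[j], value = d[j], unit = "A")
    }
  }
  tb <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble::tibble(type = character(0), metal = character(0),
                   partner = character(0), partner_element = character(0),
                   value = numeric(0), unit = character(0))
  structure(tb, cutoff = cutoff, bond_threshold = bond_threshold,
            class = c("qr_geometry", class(tb)))
}
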