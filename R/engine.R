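#' Energy engine contract
#'
#' An engine evaluates an energy and its per-atom gradient for the coordinates
#' of a carved region. Engines declare their units; the built-in surrogate
#' reports kcal/mol. External quantum-chemistry programs can be wrapped with
#' [external_engine_config()] + a user-supplied runner; they are optional and
#' never exercised in automated tests.
#'
#' @param eval Function `coords (n x 3) -> list(value, gradient (n x 3))`.
#' @param units `"kcal/mol"` or `"kJ/mol"`.
#' @param method Free-text method descriptor.
#' @param n_atoms Number of atoms the engine expects.
#' @return A `qr_engine`.
#' @export
qr_engine <- function(eval, units = c("kcal/mol", "kJ/mol"), method = "custom",
                      n_atoms = NA_integer_) {
  units <- match.arg(units)
  structure(list(eval = eval, units = units, method = method,
                 n_atoms = as.integer(n_atoms)),
            class = "qr_engine")
}

#' @export
print.qr_engine <- function(x, ...) {
  cat(sprintf("<qr_engine> %s [%s]\n", x$method, x$units))
  invisible(x)
}

#' Evaluate an engine
#'
#' @param engine A `qr_engine`.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return List with `value` (engine units) and `gradient` (n x 3).
#' @export
engine_energy <- function(engine, coords) {
  coords <- rbind3(coords)
  if (!is.na(engine$n_atoms) && nrow(coords) != engine$n_atoms) {
    abort(sprintf("engine expects %d atoms, got %d", engine$n_atoms, nrow(coords)),
          class = "qrsite_engine_error")
  }
  engine$eval(coords)
}

# energy expressed in kcal/mol regardless of the engine's native units
engine_kcal <- function(engine, value) {
  if (engine$units == "kJ/mol") value / KCAL_TO_KJ else value
}

#' External engine configuration
#'
#' Describes how an external quantum-chemistry program would be called; the
#' defaults name a meta-GGA functional with dispersion correction, a small
#' split-valence basis and an optional continuum solvent with dielectric 4.
#' This is a configuration contract only — no program is bundled or invoked.
#'
#' @param program,method,dispersion,basis Free-text descriptors.
#' @param solvent `"none"` or `"cpcm"`.
#' @param dielectric Continuum dielectric constant when `solvent = "cpcm"`.
#' @param grad_tol Convergence threshold passed to the program.
#' @return An `qr_external_engine_config`.
#' @export
external_engine_config <- function(program = "orca", method = "TPSS",
                                   dispersion = "D4", basis = "def2-SV(P)",
                                   solvent = c("none", "cpcm"), dielectric = 4,
                                   grad_tol = 1e-4) {
  solvent <- match.arg(solvent)
  structure(list(program = program, method = method, dispersion = dispersion,
                 basis = basis, solvent = solvent, dielectric = dielectric,
                 grad_tol = grad_tol),
            class = "qr_external_engine_config")
}

#' Surrogate engine parameters
#'
#' Force constants (kcal/mol/A^2 or kcal/mol/rad^2) and oxidation-state
#' dependent metal-ligand reference lengths (Angstrom) for the built-in
#' harmonic site-energy engine. Cu(I) prefers short bonds and linear
#' two-coordination; Cu(II) slightly longer bonds with a square-planar-like
#' angular preference.
#'
#' @param ... Overrides for individual defaults.
#' @return Named list of parameters.
#' @export
surrogate_params <- function(...) {
  p <- list(
    k_bond = 300,        # ligand-internal heavy-atom springs
    k_bond_h = 450,      # X-H springs
    k_13 = 60,           # 1-3 (angle surrogate) springs
    k_metal = c("Cu(I)" = 40, "Cu(II)" = 60),
    k_metal_angle = c("Cu(I)" = 25, "Cu(II)" = 15),
    k_hbond = 10,
    k_rep = 60,
    hbond_ideal = 1.85,
    hbond_search = 2.6,
    donor_cutoff = 2.9,
    vdw_scale = 0.75,
    metal_metal_min = 3.0,
    ref_length = list(
      "Cu(I)" = c(N = 1.90, O = 2.15, S = 2.25),
      "Cu(II)" = c(N = 2.00, O = 2.05, S = 2.30))
  )
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Build the surrogate site-energy engine for a region
#'
#' A harmonic stand-in for a quantum-chemical description of the carved site,
#' satisfying the engine contract (exact analytic gradient, rigid-motion
#' invariance, minimum energy 0 at its own reference geometry). Terms:
#' ligand-internal bond and 1-3 springs (reference lengths from the idealised
#' fragment templates where known, else the construction geometry),
#' oxidation-state-dependent metal-donor springs, metal angular-preference
#' terms, hydrogen-bond springs for polar hydrogens, and a one-sided
#' short-range repulsion.
#'
#' @param region A protonated `qr_region`.
#' @param params See [surrogate_params()].
#' @return A `qr_engine` (kcal/mol) over the region's atoms in table order.
#' @export
surrogate_engine <- function(region, params = surrogate_params()) {
  atoms <- region$atoms
  n <- nrow(atoms)
  m0 <- coords_matrix(atoms)
  elem <- atoms$element
  metal <- is_metal_element(elem)
  spec <- region$spec
  sm <- surviving_metals(spec)

  bonds_i <- integer(0); bonds_j <- integer(0); bonds_k <- numeric(0); bonds_d0 <- numeric(0)
  add_bond <- function(i, j, k, d0) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
    bonds_k <<- c(bonds_k, k); bonds_d0 <<- c(bonds_d0, d0)
  }

  # ligand-internal springs (bonded + 1-3), template reference where known
  cb <- detect_bonds(elem, m0)
  dict_cache <- list()
  lookup_ideal <- function(i, j, fallback) {
    rn <- atoms$residue_name[i]
    if (atoms$residue_name[j] != rn ||
        residue_key(atoms)[i] != residue_key(atoms)[j]) return(fallback)
    if (is.null(dict_cache[[rn]])) dict_cache[[rn]] <<- template_distance_dict(rn)
    key <- paste(sort(c(atoms$atom_name[i], atoms$atom_name[j])), collapse = "|")
    dict_cache[[rn]][[key]] %||% fallback
  }
  for (r in seq_len(nrow(cb))) {
    i <- cb$i[r]; j <- cb$j[r]
    kk <- if (elem[i] == "H" || elem[j] == "H") params$k_bond_h else params$k_bond
    d0 <- if (elem[i] == "H" || elem[j] == "H") {
      heavy <- if (elem[i] == "H") j else i
      link_xh_length(elem[heavy])
    } else lookup_ideal(i, j, cb$d[r])
    add_bond(i, j, kk, d0)
  }
  onethree <- character(0)
  if (nrow(cb) > 0) {
    adj <- split(c(cb$j, cb$i), c(cb$i, cb$j))
    for (mid in names(adj)) {
      nb <- sort(unique(adj[[mid]]))
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        for (cx in seq_len(ncol(pr))) {
          i <- pr[1, cx]; j <- pr[2, cx]
          d <- vnorm(m0[i, ] - m0[j, ])
          add_bond(i, j, params$k_13, lookup_ideal(i, j, d))
          onethree <- c(onethree, paste(min(i, j), max(i, j)))
        }
      }
    }
  }

  # metal-donor springs and angular preference
  angle_terms <- list()
  metal_rows <- which(metal)
  donor_pairs <- character(0)
  ox_of <- function(row) {
    if (nrow(sm$metals) == 0) return(NA_character_)
    hit <- which(sm$metals$chain == atoms$chain_id[row] &
                   sm$metals$residue_number == atoms$residue_number[row] &
                   sm$metals$atom_name == atoms$atom_name[row])
    if (length(hit) == 1) sm$labels[hit] else NA_character_
  }
  for (mrow in metal_rows) {
    ox <- ox_of(mrow)
    if (is.na(ox)) ox <- "Cu(II)"  # metal present but unlabelled: treat as divalent
    refs <- params$ref_length[[ox]]
    if (is.null(refs)) {
      abort(paste0("no surrogate parameters for oxidation state ", ox),
            class = "qrsite_parameterization_error")
    }
    d <- sqrt(rowSums(sweep(m0, 2, m0[mrow, ], "-")^2))
    cand <- which(elem %in% c("N", "O", "S") & d <= params$donor_cutoff & d > 0.1)
    for (dn in cand) {
      d0 <- refs[[elem[dn]]]
      if (is.null(d0) || is.na(d0)) {
        abort(paste0("no metal-ligand reference length for element ", elem[dn]),
              class = "qrsite_parameterization_error")
      }
      add_bond(mrow, dn, unname(params$k_metal[[ox]]), d0)
      donor_pairs <- c(donor_pairs, paste(min(mrow, dn), max(mrow, dn)))
    }
    if (length(cand) >= 2) {
      kang <- unname(params$k_metal_angle[[ox]])
      if (ox == "Cu(I)") {
        two <- cand[order(d[cand])][1:2]
        angle_terms[[length(angle_terms) + 1]] <-
          list(i = two[1], j = mrow, k = two[2], ideal = 180, kf = kang)
      } else {
        pr <- utils::combn(cand, 2)
        for (cx in seq_len(ncol(pr))) {
          th <- angle_deg(m0[pr[1, cx], ], m0[mrow, ], m0[pr[2, cx], ])
          angle_terms[[length(angle_terms) + 1]] <-
            list(i = pr[1, cx], j = mrow, k = pr[2, cx],
                 ideal = if (th < 135) 90 else 180, kf = kang)
        }
      }
    }
  }

  # hydrogen bonds: each polar H to its nearest other-residue acceptor
  hb_pairs <- character(0)
  rk <- residue_key(atoms)
  for (h in which(elem == "H" & !atoms$is_link)) {
    acc <- which(elem %in% c("N", "O") & rk != rk[h])
    if (length(acc) == 0) next
    d <- sqrt(rowSums(sweep(m0[acc, , drop = FALSE], 2, m0[h, ], "-")^2))
    best <- which.min(d)
    if (d[best] <= params$hbond_search) {
      add_bond(h, acc[best], params$k_hbond, params$hbond_ideal)
      hb_pairs <- c(hb_pairs, paste(min(h, acc[best]), max(h, acc[best])))
    }
  }

  # short-range repulsion for everything not otherwise bound
  excl <- c(paste(pmin(bonds_i, bonds_j), pmax(bonds_i, bonds_j)), onethree,
            donor_pairs, hb_pairs)
  rep_i <- integer(0); rep_j <- integer(0); rep_dmin <- numeric(0)
  if (n >= 2) {
    pr <- close_pairs(m0, 5.0)
    key <- paste(pr$i, pr$j)
    pr <- pr[!(key %in% excl), , drop = FALSE]
    if (nrow(pr) > 0) {
      dmin <- ifelse(metal[pr$i] & metal[pr$j], params$metal_metal_min,
                     params$vdw_scale * (vdw_radius(elem[pr$i]) + vdw_radius(elem[pr$j])))
      rep_i <- pr$i; rep_j <- pr$j; rep_dmin <- dmin
    }
  }

  eval_fn <- function(coords) {
    e <- 0
    g <- matrix(0, n, 3)
    if (length(bonds_i) > 0) {
      dv <- coords[bonds_i, , drop = FALSE] - coords[bonds_j, , drop = FALSE]
      d <- sqrt(rowSums(dv^2))
      dev <- d - bonds_d0
      e <- e + sum(bonds_k * dev^2)
      coef <- 2 * bonds_k * dev / pmax(d, 1e-12)
      gv <- dv * coef
      g <- accumulate_rows(g, bonds_i, gv)
      g <- accumulate_rows(g, bonds_j, -gv)
    }
    for (at in angle_terms) {
      ag <- angle_grad(coords[at$i, ], coords[at$j, ], coords[at$k, ])
      dev <- (ag$theta_deg - at$ideal) * pi / 180
      e <- e + at$kf * dev^2
      coef <- 2 * at$kf * dev
      g[at$i, ] <- g[at$i, ] + coef * ag$d1
      g[at$j, ] <- g[at$j, ] + coef * ag$d2
      g[at$k, ] <- g[at$k, ] + coef * ag$d3
    }
    if (length(rep_i) > 0) {
      dv <- coords[rep_i, , drop = FALSE] - coords[rep_j, , drop = FALSE]
      d <- sqrt(rowSums(dv^2))
      viol <- d < rep_dmin
      if (any(viol)) {
        dev <- rep_dmin[viol] - d[viol]
        e <- e + params$k_rep * sum(dev^2)
        coef <- -2 * params$k_rep * dev / pmax(d[viol], 1e-12)
        gv <- dv[viol, , drop = FALSE] * coef
        g <- accumulate_rows(g, rep_i[viol], gv)
        g <- accumulate_rows(g, rep_j[viol], -gv)
      }
    }
    list(value = e, gradient = g)
  }

  qr_engine(eval_fn, units = "kcal/mol",
            method = sprintf("surrogate harmonic site energy (%s)", spec$label),
            n_atoms = n)
}

#' Single-spring toy engine
#'
#' One harmonic term `k (d - d0)^2` between two atoms; used for closed-form
#' calibration of strain energies.
#'
#' @param k Force constant (kcal/mol/A^2).
#' @param d0 Reference length (Angstrom).
#' @param i,j Atom indices.
#' @param n_atoms Total atom count.
#' @return A `qr_engine`.
#' @export
spring_engine <- function(k, d0, i = 1, j = 2, n_atoms = 2) {
  eval_fn <- function(coords) {
    dv <- coords[i, ] - coords[j, ]
    d <- vnorm(dv)
    dev <- d - d0
    g <- matrix(0, n_atoms, 3)
    gv <- 2 * k * dev * dv / max(d, 1e-12)
    g[i, ] <- gv; g[j, ] <- -gv
    list(value = k * dev^2, gradient = g)
  }
  qr_engine(eval_fn, units = "kcal/mol", method = sprintf("single spring k=%g", k),
            n_atoms = n_atoms)
}
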