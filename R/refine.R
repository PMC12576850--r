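#' Refinement configuration
#'
#' Defaults reproduce the reference protocol: map weight `w_x` scanned or
#' fixed, engine scale `w_qm` = 7.5 mol/kcal, three coordinate macrocycles
#' followed by one ADP (isotropic B) macrocycle, and self-reference restraints
#' of sigma 0.01 Angstrom tying surrounding atoms to their starting positions.
#'
#' @param w_x Map weight (>= 0).
#' @param w_qm Engine energy scale in mol/kcal (makes kcal/mol energies
#'   commensurate with the dimensionless restraints).
#' @param coordinate_macrocycles,adp_macrocycles Protocol counters.
#' @param self_reference_sigma Sigma (Angstrom) of the harmonic self-reference
#'   restraints on refined atoms outside the carved region.
#' @param shell_radius Atoms within this distance (Angstrom) of the region
#'   also move, under restraints + self-reference; 0 = region only.
#' @param tol Gradient tolerance per coordinate (target units / Angstrom).
#' @param max_iter Optimiser iteration cap per macrocycle.
#' @param mask_radius RSCC mask radius (Angstrom).
#' @param render_cutoff Model-map rendering truncation radius (Angstrom).
#' @param random_seed Recorded seed (the refinement itself is deterministic).
#' @return A `qr_refinement_config`.
#' @export
refinement_config <- function(w_x = 10, w_qm = 7.5, coordinate_macrocycles = 3,
                              adp_macrocycles = 1, self_reference_sigma = 0.01,
                              shell_radius = 0, tol = 1e-3, max_iter = 400,
                              mask_radius = 2.0, render_cutoff = 4.0,
                              random_seed = 1L) {
  if (w_x < 0) abort("w_x must be >= 0", class = "qrsite_config_error")
  if (w_qm <= 0) abort("w_qm must be > 0", class = "qrsite_config_error")
  structure(list(w_x = w_x, w_qm = w_qm,
                 coordinate_macrocycles = as.integer(coordinate_macrocycles),
                 adp_macrocycles = as.integer(adp_macrocycles),
                 self_reference_sigma = self_reference_sigma,
                 shell_radius = shell_radius, tol = tol,
                 max_iter = as.integer(max_iter), mask_radius = mask_radius,
                 render_cutoff = render_cutoff,
                 random_seed = as.integer(random_seed)),
            class = "qr_refinement_config")
}

# Merge a region's added hydrogens into the structure; returns the augmented
# atom table plus index bookkeeping. Link hydrogens stay dependent atoms.
augment_structure <- function(s, region) {
  s_aug <- tibble::as_tibble(s)
  region_rows_s <- integer(0)
  region_map <- integer(0)      # s_aug row for each non-link region atom row
  if (!is.null(region)) {
    ratoms <- region$atoms
    real <- ratoms[!ratoms$is_link & !ratoms$is_added_h, , drop = FALSE]
    idx <- match(atom_key(real), atom_key(s_aug))
    if (anyNA(idx)) {
      abort("region atoms missing from structure", class = "qrsite_selection_error")
    }
    added <- ratoms[ratoms$is_added_h, , drop = FALSE]
    if (nrow(added) > 0) {
      add <- added[, !(names(added) %in% c("is_link", "is_added_h"))]
      add$serial <- max(s_aug$serial) + seq_len(nrow(add))
      s_aug <- dplyr::bind_rows(s_aug, add)
    }
    nonlink <- ratoms[!ratoms$is_link, , drop = FALSE]
    region_map <- match(atom_key(nonlink), atom_key(s_aug))
    region_rows_s <- region_map
  }
  list(s_aug = s_aug, region_rows = region_rows_s)
}

# Build the combined-target evaluator over the moving atoms of s_aug.
make_combined_target <- function(s_aug, region, exp_map, engine, topo, cfg,
                                 moving) {
  n <- nrow(s_aug)
  coords0 <- coords_matrix(s_aug)
  in_region <- rep(FALSE, n)
  region_rows <- integer(0)
  link_info <- NULL
  region_order_nonlink <- integer(0)
  if (!is.null(region) && nrow(region$atoms) > 0) {
    ratoms <- region$atoms
    nonlink_rows <- which(!ratoms$is_link)
    region_order_nonlink <- match(atom_key(ratoms[nonlink_rows, ]), atom_key(s_aug))
    if (anyNA(region_order_nonlink)) {
      abort("region atoms missing from structure", class = "qrsite_selection_error")
    }
    in_region[region_order_nonlink] <- TRUE
    region_rows <- region_order_nonlink
    la <- region$link_atoms
    link_rows_region <- which(ratoms$is_link)
    if (nrow(la) > 0) {
      qm_idx <- vapply(seq_len(nrow(la)), function(i) {
        match(paste(la$qm_chain[i], la$qm_residue_number[i], la$qm_atom[i], sep = "|"),
              atom_key(s_aug))
      }, integer(1))
      mm_idx <- vapply(seq_len(nrow(la)), function(i) {
        match(paste(la$mm_chain[i], la$mm_residue_number[i], la$mm_atom[i], sep = "|"),
              atom_key(s_aug))
      }, integer(1))
      link_info <- list(qm = qm_idx, mm = mm_idx, len = la$bond_length,
                        region_row = link_rows_region)
    }
    # engine atom order: region$atoms row order; map each row to either an
    # s_aug row (non-link) or a link record
    engine_src <- integer(nrow(ratoms))
    engine_src[nonlink_rows] <- region_order_nonlink
    engine_src[link_rows_region] <- -seq_len(length(link_rows_region))
  } else {
    ratoms <- NULL
    engine_src <- integer(0)
  }
  moving <- sort(unique(moving))
  selfref_rows <- moving[!in_region[moving]]
  x0_selfref <- coords0[selfref_rows, , drop = FALSE]
  sigma2 <- cfg$self_reference_sigma^2
  map_w <- default_map_weights(s_aug)[moving]

  # restraint terms: at least one moving atom, not entirely inside the region
  sub_topo <- NULL
  if (!is.null(topo)) {
    keep_term <- function(idx_cols) {
      any_moving <- Reduce(`|`, lapply(idx_cols, function(v) v %in% moving))
      all_region <- Reduce(`&`, lapply(idx_cols, function(v) in_region[v]))
      any_moving & !all_region
    }
    b <- topo$bonds;   b <- b[keep_term(list(b$i, b$j)), , drop = FALSE]
    a <- topo$angles;  a <- a[keep_term(list(a$i, a$j, a$k)), , drop = FALSE]
    tt <- topo$torsions
    tt <- tt[keep_term(list(tt$i, tt$j, tt$k, tt$l)), , drop = FALSE]
    nb <- topo$nonbonded; nb <- nb[keep_term(list(nb$i, nb$j)), , drop = FALSE]
    sub_topo <- restraint_topology(bonds = b, angles = a, torsions = tt,
                                   nonbonded = nb, n_atoms = n)
  }

  fn <- function(x) {
    coords <- coords0
    coords[moving, ] <- matrix(x, ncol = 3)
    g <- matrix(0, n, 3)
    comp <- c(t_map = 0, e_engine = 0, t_restr = 0, t_selfref = 0)

    if (cfg$w_x > 0 && length(moving) > 0) {
      ip <- interpolate_map(exp_map, coords[moving, , drop = FALSE],
                            gradient = TRUE, method = "cubic")
      comp["t_map"] <- -sum(map_w * ip$value)
      g[moving, ] <- g[moving, ] - cfg$w_x * ip$gradient * map_w
    }

    if (!is.null(ratoms)) {
      rc <- matrix(0, nrow(ratoms), 3)
      rc[engine_src > 0, ] <- coords[engine_src[engine_src > 0], , drop = FALSE]
      link_pos <- NULL
      if (!is.null(link_info)) {
        dq <- coords[link_info$mm, , drop = FALSE] - coords[link_info$qm, , drop = FALSE]
        rr <- sqrt(rowSums(dq^2))
        u <- dq / rr
        link_pos <- coords[link_info$qm, , drop = FALSE] + link_info$len * u
        rc[link_info$region_row, ] <- link_pos
      }
      ev <- engine_energy(engine, rc)
      e_kcal <- engine_kcal(engine, ev$value)
      grad_scale <- if (engine$units == "kJ/mol") 1 / KCAL_TO_KJ else 1
      ge <- ev$gradient * grad_scale
      comp["e_engine"] <- e_kcal
      # direct terms for real region atoms
      g[engine_src[engine_src > 0], ] <- g[engine_src[engine_src > 0], ] +
        cfg$w_qm * ge[engine_src > 0, , drop = FALSE]
      # chain rule for link hydrogens onto both hosts
      if (!is.null(link_info)) {
        for (li in seq_along(link_info$qm)) {
          gh <- cfg$w_qm * ge[link_info$region_row[li], ]
          q <- link_info$qm[li]; mmi <- link_info$mm[li]
          dv <- coords[mmi, ] - coords[q, ]
          r <- vnorm(dv)
          uu <- dv / r
          A <- link_info$len[li] / r * (diag(3) - outer(uu, uu))
          g[mmi, ] <- g[mmi, ] + as.numeric(A %*% gh)
          g[q, ] <- g[q, ] + as.numeric((diag(3) - A) %*% gh)
        }
      }
    }

    if (!is.null(sub_topo)) {
      re <- restraint_energy(sub_topo, coords)
      comp["t_restr"] <- re$value
      g <- g + re$gradient
    }

    if (length(selfref_rows) > 0) {
      dv <- coords[selfref_rows, , drop = FALSE] - x0_selfref
      comp["t_selfref"] <- sum(dv^2) / sigma2
      g[selfref_rows, ] <- g[selfref_rows, ] + 2 * dv / sigma2
    }

    total <- cfg$w_x * comp[["t_map"]] + cfg$w_qm * comp[["e_engine"]] +
      comp[["t_restr"]] + comp[["t_selfref"]]
    list(value = total, gradient = as.numeric(g[moving, , drop = FALSE]),
         components = comp)
  }
  list(fn = fn, moving = moving, n = n)
}

#' Evaluate the combined refinement target
#'
#' Composes `w_x * T_map + w_qm * E_engine(region incl. link H) +
#' T_restr (minus region-internal terms) + self-reference` at the structure's
#' current coordinates. With an empty region the value reduces exactly to the
#' classical map + restraints target plus the self-reference term; with
#' `w_x = 0` the map term vanishes. Link-atom forces are redistributed to both
#' hosts by the chain rule.
#'
#' @param s A [qr_structure] (with the region's interpretation applied).
#' @param region A `qr_region`, or `NULL` for the classical limit.
#' @param exp_map Experimental [qr_map].
#' @param engine A `qr_engine` for the region (ignored when `region` is NULL).
#' @param topo Optional `qr_topology` over the augmented structure; built from
#'   geometry when NULL.
#' @param cfg A [refinement_config()].
#' @param moving Row indices of moving atoms in the augmented structure;
#'   defaults to region + shell (all atoms when region is NULL).
#' @return List with `value`, `gradient` (moving x 3), `components`,
#'   `moving` indices.
#' @export
combined_target <- function(s, region = NULL, exp_map, engine = NULL,
                            topo = NULL, cfg = refinement_config(),
                            moving = NULL) {
  aug <- augment_structure(s, region)
  s_aug <- aug$s_aug
  if (is.null(moving)) moving <- default_moving(s_aug, aug$region_rows, cfg)
  if (is.null(topo)) topo <- build_topology(s_aug)
  if (is.null(engine) && !is.null(region)) engine <- surrogate_engine(region)
  tgt <- make_combined_target(s_aug, region, exp_map, engine, topo, cfg, moving)
  res <- tgt$fn(as.numeric(coords_matrix(s_aug)[tgt$moving, , drop = FALSE]))
  list(value = res$value, gradient = matrix(res$gradient, ncol = 3),
       components = res$components, moving = tgt$moving)
}

default_moving <- function(s_aug, region_rows, cfg) {
  if (length(region_rows) == 0) return(seq_len(nrow(s_aug)))
  moving <- region_rows
  if (cfg$shell_radius > 0) {
    m <- coords_matrix(s_aug)
    others <- setdiff(seq_len(nrow(s_aug)), region_rows)
    for (o in others) {
      d2 <- rowSums(sweep(m[region_rows, , drop = FALSE], 2, m[o, ], "-")^2)
      if (min(d2) <= cfg$shell_radius^2) moving <- c(moving, o)
    }
  }
  sort(moving)
}

#' Run a site-focused quantum-refinement-style refinement
#'
#' Runs `coordinate_macrocycles` minimisations of the combined target over the
#' region (plus shell) atoms, then `adp_macrocycles` of isotropic-B refinement
#' with coordinates frozen. The experimental map is z-score normalised
#' internally (scores are scale-invariant; the map is never recomputed from
#' the model). Deterministic given the configuration and inputs.
#'
#' @inheritParams combined_target
#' @return A `qr_refinement` with the refined structure, updated region,
#'   per-macrocycle component log, convergence record and final per-residue
#'   map score.
#' @export
refine <- function(s, region, exp_map, engine = NULL, topo = NULL,
                   cfg = refinement_config()) {
  if (is.null(engine) && !is.null(region)) engine <- surrogate_engine(region)
  norm <- normalize_map(exp_map)
  aug <- augment_structure(s, region)
  s_aug <- aug$s_aug
  moving <- default_moving(s_aug, aug$region_rows, cfg)
  if (is.null(topo)) topo <- build_topology(s_aug)
  tgt <- make_combined_target(s_aug, region, norm, engine, topo, cfg, moving)
  coords <- coords_matrix(s_aug)
  start_ip <- interpolate_map(norm, coords[moving, , drop = FALSE], gradient = TRUE)
  if (any(start_ip$outside)) {
    warn(sprintf("%d refined atom(s) start outside the map support and contribute 0 to the map term",
                 sum(start_ip$outside)))
  }
  log_rows <- list()
  prev_total <- Inf
  for (mc in seq_len(cfg$coordinate_macrocycles)) {
    res <- bfgs_minimize(function(x) {
      r <- tgt$fn(x)
      list(value = r$value, gradient = r$gradient)
    }, as.numeric(coords[moving, , drop = FALSE]),
    tol = cfg$tol, max_iter = cfg$max_iter)
    coords[moving, ] <- matrix(res$par, ncol = 3)
    final <- tgt$fn(res$par)
    comp <- final$components
    total <- final$value
    if (total > prev_total + 1e-6) {
      abort(sprintf("refinement diverged in macrocycle %d (total %.6g -> %.6g)",
                    mc, prev_total, total),
            class = "qrsite_refinement_error")
    }
    prev_total <- total
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      macrocycle = mc, stage = "coordinates", iterations = res$iterations,
      converged = res$converged, total = total,
      w_map = cfg$w_x * comp[["t_map"]], t_map = comp[["t_map"]],
      w_engine = cfg$w_qm * comp[["e_engine"]], e_engine_kcal = comp[["e_engine"]],
      t_restr = comp[["t_restr"]], t_selfref = comp[["t_selfref"]])
  }
  s_aug <- set_coords(s_aug, coords)
  region_new <- update_region_coords(region, s_aug)
  for (ac in seq_len(cfg$adp_macrocycles)) {
    s_aug <- adp_refine(s_aug, norm, region = region_new,
                        mask_radius = max(cfg$mask_radius, 2.5),
                        cutoff = cfg$render_cutoff)
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      macrocycle = cfg$coordinate_macrocycles + ac, stage = "adp",
      iterations = attr(s_aug, "adp_iterations") %||% NA_integer_,
      converged = TRUE, total = prev_total,
      w_map = NA_real_, t_map = NA_real_, w_engine = NA_real_,
      e_engine_kcal = NA_real_, t_restr = NA_real_, t_selfref = NA_real_)
  }
  score_atoms <- s_aug[residue_key(s_aug) %in%
                         unique(residue_key(s_aug)[aug$region_rows]), , drop = FALSE]
  model <- render_model_map(score_atoms, norm, cutoff = cfg$render_cutoff)
  score <- rscc(model, norm, score_atoms, radius = cfg$mask_radius)
  out <- list(structure = qr_structure(s_aug, id = attr(s, "id") %||% ""),
              region = region_new, config = cfg,
              log = dplyr::bind_rows(log_rows), map_score = score,
              engine_method = if (!is.null(engine)) engine$method else "none",
              moving = moving)
  class(out) <- "qr_refinement"
  out
}

normalize_map <- function(m) {
  v <- as.numeric(m$values)
  s <- sd(v)
  if (s == 0) s <- 1
  qr_map((m$values - mean(v)) / s, origin = m$origin, voxel_size = m$voxel_size,
         axis_order = m$axis_order)
}

update_region_coords <- function(region, s_aug) {
  if (is.null(region)) return(NULL)
  ratoms <- region$atoms
  nonlink <- which(!ratoms$is_link)
  idx <- match(atom_key(ratoms[nonlink, ]), atom_key(s_aug))
  ratoms$x[nonlink] <- s_aug$x[idx]
  ratoms$y[nonlink] <- s_aug$y[idx]
  ratoms$z[nonlink] <- s_aug$z[idx]
  ratoms$b_iso[nonlink] <- s_aug$b_iso[idx]
  region$atoms <- ratoms
  place_link_atoms(region, s_aug)
}

#' @export
print.qr_refinement <- function(x, ...) {
  cat(sprintf("<qr_refinement> %s | w_x = %g, w_qm = %g\n",
              x$engine_method, x$config$w_x, x$config$w_qm))
  cat(sprintf("  %d macrocycles logged; final total %.4f; average RSCC %.3f\n",
              nrow(x$log), tail(stats::na.omit(x$log$total), 1),
              average_rscc(x$map_score)))
  invisible(x)
}

#' Isotropic B-factor refinement against the map
#'
#' With coordinates fixed, per-atom isotropic B-factors of the region atoms
#' are adjusted to minimise the squared residual between the rendered model
#' map and the experimental map over the region mask, after an optimal affine
#' (scale + offset) match; B is clamped to [2, 200] Angstrom^2 and clamping
#' is flagged via the `adp_clamped` attribute.
#'
#' @param s Atom table (coordinates fixed).
#' @param exp_map Experimental [qr_map].
#' @param region A `qr_region` naming the atoms whose B is refined; NULL = all.
#' @param mask_radius Mask radius (Angstrom) around the refined atoms.
#' @param cutoff Rendering truncation radius.
#' @param b_bounds Clamp range (Angstrom^2).
#' @return `s` with updated `b_iso`.
#' @export
adp_refine <- function(s, exp_map, region = NULL, mask_radius = 2.5,
                       cutoff = 4.0, b_bounds = c(2, 200)) {
  if (is.null(region)) {
    rows <- seq_len(nrow(s))
  } else {
    nonlink <- region$atoms[!region$atoms$is_link, , drop = FALSE]
    rows <- match(atom_key(nonlink), atom_key(s))
    rows <- rows[!is.na(rows)]
  }
  if (length(rows) == 0) return(s)
  idx <- mask_indices(exp_map, s[rows, , drop = FALSE], mask_radius)
  if (length(idx) < 10) return(s)
  d <- dim(exp_map$values)
  sub <- arrayInd(idx, d)
  world <- cbind(exp_map$origin[1] + (sub[, 1] - 1) * exp_map$voxel_size[1],
                 exp_map$origin[2] + (sub[, 2] - 1) * exp_map$voxel_size[2],
                 exp_map$origin[3] + (sub[, 3] - 1) * exp_map$voxel_size[3])
  ev <- exp_map$values[idx]
  # context atoms: fixed-B background within reach of the mask
  all_d2min <- vapply(seq_len(nrow(s)), function(i) {
    min(rowSums(sweep(world, 2, c(s$x[i], s$y[i], s$z[i]), "-")^2))
  }, numeric(1))
  context <- setdiff(which(all_d2min <= cutoff^2), rows)
  bg <- if (length(context) > 0) {
    render_on_points(s[context, , drop = FALSE], world, s$b_iso[context], cutoff)$value
  } else 0
  atoms_v <- s[rows, , drop = FALSE]
  obj <- function(B) {
    r <- render_on_points(atoms_v, world, B, cutoff)
    mv <- r$value + bg
    fit <- stats::lm.fit(cbind(1, mv), ev)
    a <- fit$coefficients[2]
    if (!is.finite(a)) a <- 0
    resid <- fit$residuals
    grad <- -2 * a * as.numeric(crossprod(r$dvalue_dB, resid))
    list(value = sum(resid^2), gradient = grad)
  }
  opt <- optim(pmin(pmax(atoms_v$b_iso, b_bounds[1]), b_bounds[2]),
               fn = function(B) obj(B)$value,
               gr = function(B) obj(B)$gradient,
               method = "L-BFGS-B", lower = b_bounds[1], upper = b_bounds[2],
               control = list(maxit = 200))
  Bnew <- opt$par
  s$b_iso[rows] <- Bnew
  clamped <- Bnew <= b_bounds[1] + 1e-6 | Bnew >= b_bounds[2] - 1e-6
  if (any(clamped)) {
    warn(sprintf("ADP refinement clamped %d atom(s) at the B bounds", sum(clamped)))
  }
  attr(s, "adp_clamped") <- which(clamped)
  attr(s, "adp_iterations") <- opt$counts[["function"]]
  s
}

# density (and dB-derivative) of atoms evaluated at arbitrary points
render_on_points <- function(atoms, points, B, cutoff) {
  co <- scattering_coeffs(atoms$element)
  np <- nrow(points)
  val <- numeric(np)
  dB <- matrix(0, np, nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    d2 <- rowSums(sweep(points, 2, c(atoms$x[i], atoms$y[i], atoms$z[i]), "-")^2)
    sel <- which(d2 <= cutoff^2)
    if (length(sel) == 0) next
    for (gg in 1:5) {
      beta <- co$b[i, gg] + B[i]
      rho <- co$a[i, gg] * (FOURPI2 / pi / beta)^1.5 *
        exp(-FOURPI2 * d2[sel] / beta)
      val[sel] <- val[sel] + atoms$occupancy[i] * rho
      dB[sel, i] <- dB[sel, i] + atoms$occupancy[i] * rho *
        (-1.5 / beta + FOURPI2 * d2[sel] / beta^2)
    }
  }
  list(value = val, dvalue_dB = dB)
}
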