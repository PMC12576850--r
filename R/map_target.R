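# Real-space density rendering in the Gaussian electron-scattering model:
# each atom contributes occ * sum_g a_g (4*pi/beta_g)^{3/2} exp(-4*pi^2 r^2 / beta_g)
# with beta_g = b_g + B_iso, so that the integral of one atom's density equals
# its total forward scattering amplitude times the occupancy.

FOURPI2 <- 4 * pi * pi

#' Render a model map from atoms
#'
#' Atoms contribute occupancy-weighted Gaussians broadened by their isotropic
#' B-factor, truncated at `cutoff` Angstrom, accumulated on the geometry of
#' `grid` (an existing [qr_map], typically the experimental one).
#'
#' @param atoms Atom table (`element`, coordinates, `occupancy`, `b_iso`).
#' @param grid A [qr_map] supplying dimensions, origin and voxel size.
#' @param table Scattering table (defaults to the built-in neutral-atom one).
#' @param cutoff Truncation radius (Angstrom).
#' @param b_add Extra B added to every atom (resolution blur).
#' @return A [qr_map] on the same grid.
#' @export
render_model_map <- function(atoms, grid, table = NULL, cutoff = 4, b_add = 0) {
  d <- dim(grid$values)
  vals <- array(0, d)
  if (nrow(atoms) > 0) {
    co <- scattering_coeffs(atoms$element)
    ax <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel_size[1]
    ay <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel_size[2]
    az <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel_size[3]
    for (i in seq_len(nrow(atoms))) {
      p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
      rng <- function(axis_vals, c0) which(axis_vals >= c0 - cutoff & axis_vals <= c0 + cutoff)
      ix <- rng(ax, p[1]); iy <- rng(ay, p[2]); iz <- rng(az, p[3])
      if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) next
      dx2 <- (ax[ix] - p[1])^2
      dy2 <- (ay[iy] - p[2])^2
      dz2 <- (az[iz] - p[3])^2
      r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      beta <- co$b[i, ] + atoms$b_iso[i] + b_add
      dens <- array(0, dim(r2))
      for (gg in 1:5) {
        dens <- dens + co$a[i, gg] * (FOURPI2 / pi / beta[gg])^1.5 *
          exp(-FOURPI2 * r2 / beta[gg])
      }
      vals[ix, iy, iz] <- as.numeric(vals[ix, iy, iz]) +
        atoms$occupancy[i] * as.numeric(dens)
    }
  }
  qr_map(vals, origin = grid$origin, voxel_size = grid$voxel_size,
         axis_order = grid$axis_order)
}

# linear voxel indices within `radius` of any of the given atom positions
mask_indices <- function(grid, atoms, radius) {
  d <- dim(grid$values)
  ax <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel_size[1]
  ay <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel_size[2]
  az <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel_size[3]
  hit <- logical(prod(d))
  for (i in seq_len(nrow(atoms))) {
    p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    ix <- which(abs(ax - p[1]) <= radius)
    iy <- which(abs(ay - p[2]) <= radius)
    iz <- which(abs(az - p[3]) <= radius)
    if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) next
    r2 <- outer(outer((ax[ix] - p[1])^2, (ay[iy] - p[2])^2, "+"), (az[iz] - p[3])^2, "+")
    sub <- which(r2 <= radius^2, arr.ind = TRUE)
    if (nrow(sub) > 0) {
      lin <- ix[sub[, 1]] + d[1] * (iy[sub[, 2]] - 1) + d[1] * d[2] * (iz[sub[, 3]] - 1)
      hit[lin] <- TRUE
    }
  }
  which(hit)
}

#' Per-residue real-space correlation coefficient
#'
#' For each residue containing any of the given atoms, the Pearson
#' correlation between the two maps over the union of voxels within `radius`
#' of that residue's atoms. Residues with an empty or constant mask get an
#' undefined score (NA, excluded from the average, flagged).
#'
#' @param model_map,exp_map Two [qr_map]s on the same grid.
#' @param atoms Atom table defining the scored residues (all atoms of any
#'   residue present in this table are used for masking).
#' @param radius Mask radius (Angstrom).
#' @return A tibble (class `qr_map_score`) with one row per residue
#'   (`chain_id`, `residue_number`, `residue_name`, `n_voxels`, `rscc`);
#'   attributes `average_rscc` and `mask_radius`.
#' @export
rscc <- function(model_map, exp_map, atoms, radius = 2.0) {
  if (!identical(dim(model_map$values), dim(exp_map$values))) {
    abort("maps must share a grid", class = "qrsite_map_error")
  }
  rk <- residue_key(atoms)
  out <- vector("list", length(unique(rk)))
  for (u in seq_along(unique(rk))) {
    key <- unique(rk)[u]
    res <- atoms[rk == key, , drop = FALSE]
    idx <- mask_indices(exp_map, res, radius)
    score <- NA_real_
    if (length(idx) >= 2) {
      mv <- model_map$values[idx]
      ev <- exp_map$values[idx]
      if (sd(mv) > 0 && sd(ev) > 0) score <- cor(mv, ev)
    }
    if (is.na(score)) {
      warn(sprintf("RSCC undefined for residue %s (empty or constant mask)", key))
    }
    out[[u]] <- tibble::tibble(chain_id = res$chain_id[1],
                               residue_number = res$residue_number[1],
                               residue_name = res$residue_name[1],
                               n_voxels = length(idx), rscc = score)
  }
  tb <- dplyr::bind_rows(out)
  structure(tb, average_rscc = mean(tb$rscc, na.rm = TRUE), mask_radius = radius,
            class = c("qr_map_score", class(tb)))
}

#' Average RSCC of a map score
#' @param score A `qr_map_score` from [rscc()].
#' @return Unweighted mean over the scored residues.
#' @export
average_rscc <- function(score) attr(score, "average_rscc")

#' Map-fit target: negative interpolated density sum
#'
#' `T_map = -sum_i w_i rho_exp(x_i)` with per-atom weights proportional to
#' the element's total scattering amplitude (relative to carbon) and the
#' occupancy. Lower is better; the gradient is the exact derivative of the
#' trilinear interpolant. Atoms outside the map support contribute 0 and are
#' flagged.
#'
#' @param exp_map The experimental [qr_map] (never recomputed from a model).
#' @param atoms Atom table.
#' @param weights Optional per-atom weights (overrides the default).
#' @param method Interpolation method; the C1 `"cubic"` default keeps the
#'   target optimiser-friendly (see [interpolate_map()]).
#' @return List with `value`, `gradient` (n x 3), `outside` flags.
#' @export
map_fit_target <- function(exp_map, atoms, weights = NULL,
                           method = c("cubic", "trilinear")) {
  method <- match.arg(method)
  if (nrow(atoms) == 0) {
    return(list(value = 0, gradient = matrix(0, 0, 3), outside = logical(0)))
  }
  w <- weights %||% default_map_weights(atoms)
  ip <- interpolate_map(exp_map, coords_matrix(atoms), gradient = TRUE,
                        method = method)
  list(value = -sum(w * ip$value),
       gradient = -ip$gradient * w,
       outside = ip$outside)
}

default_map_weights <- function(atoms) {
  amp <- scattering_coeffs(atoms$element)$amplitude
  amp_c <- scattering_coeffs("C")$amplitude
  atoms$occupancy * amp / amp_c
}
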