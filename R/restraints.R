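#' Stereochemical restraint topology
#'
#' Holds the dimensionless (sigma-normalised) restraint terms: bonds, angles,
#' torsions and one-sided nonbonded minimum-approach pairs. Indices refer to
#' rows of the atom table the topology was built for.
#'
#' @param bonds Tibble `i, j, ideal, sigma` (Angstrom).
#' @param angles Tibble `i, j, k, ideal, sigma` (degrees; `j` is the vertex).
#' @param torsions Tibble `i, j, k, l, ideal, period, sigma` (degrees).
#' @param nonbonded Tibble `i, j, dmin, sigma` (Angstrom; one-sided below `dmin`).
#' @param n_atoms Number of atoms the indices refer to.
#' @return A `qr_topology`.
#' @export
restraint_topology <- function(bonds = NULL, angles = NULL, torsions = NULL,
                               nonbonded = NULL, n_atoms) {
  empty <- function(cols) {
    tibble::as_tibble(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  bonds <- tibble::as_tibble(bonds %||% empty(c("i", "j", "ideal", "sigma")))
  angles <- tibble::as_tibble(angles %||% empty(c("i", "j", "k", "ideal", "sigma")))
  torsions <- tibble::as_tibble(torsions %||%
                                  empty(c("i", "j", "k", "l", "ideal", "period", "sigma")))
  nonbonded <- tibble::as_tibble(nonbonded %||% empty(c("i", "j", "dmin", "sigma")))
  for (tb in list(bonds, angles, torsions)) {
    if (nrow(tb) > 0 && any(tb$sigma <= 0)) {
      abort("restraint sigmas must be > 0", class = "qrsite_topology_error")
    }
  }
  if (nrow(bonds) > 0 && nrow(nonbonded) > 0) {
    bk <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    nk <- paste(pmin(nonbonded$i, nonbonded$j), pmax(nonbonded$i, nonbonded$j))
    if (any(nk %in% bk)) {
      abort("a bonded pair cannot also be a nonbonded pair", class = "qrsite_topology_error")
    }
  }
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 nonbonded = nonbonded, n_atoms = as.integer(n_atoms)),
            class = "qr_topology")
}

#' Build a restraint topology from a structure's geometry
#'
#' Bonds come from a covalent-radius bond detector; angles from bonded
#' triples. Ideal values are taken from the input geometry (self-restraint
#' style) with standard-library-like sigmas; nonbonded minimum-approach pairs
#' use 0.75 x the sum of van der Waals radii. Torsion terms are supported by
#' [restraint_energy()] but not emitted here.
#'
#' @param atoms Atom table (with `element`, coordinates).
#' @param bond_sigma,angle_sigma Restraint sigmas (Angstrom / degrees).
#' @param nonbonded_scale Scale on the vdW-sum minimum approach.
#' @param nonbonded_range Only pairs closer than this (Angstrom) at build time
#'   get a nonbonded term (keeps the term list site-sized).
#' @return A `qr_topology` over `nrow(atoms)` atoms.
#' @export
build_topology <- function(atoms, bond_sigma = 0.02, angle_sigma = 3,
                           nonbonded_scale = 0.75, nonbonded_range = 4.0) {
  m <- coords_matrix(atoms)
  rk <- residue_key(atoms)
  dicts <- list()
  tpl_dist <- function(i, j) {
    rn <- atoms$residue_name[i]
    if (atoms$residue_name[j] != rn || rk[i] != rk[j]) return(NULL)
    if (is.null(dicts[[rn]])) dicts[[rn]] <<- template_distance_dict(rn)
    dicts[[rn]][[paste(sort(c(atoms$atom_name[i], atoms$atom_name[j])), collapse = "|")]]
  }
  b <- detect_bonds(atoms$element, m)
  ideal_b <- b$d
  for (r in seq_len(nrow(b))) {
    td <- tpl_dist(b$i[r], b$j[r])
    if (!is.null(td)) ideal_b[r] <- td
  }
  bonds <- tibble::tibble(i = b$i, j = b$j, ideal = ideal_b, sigma = bond_sigma)
  # angles: for every atom with >= 2 bonded neighbours
  ai <- aj <- ak <- integer(0)
  if (nrow(b) > 0) {
    adj <- split(c(b$j, b$i), c(b$i, b$j))
    for (mid in names(adj)) {
      nb <- sort(unique(adj[[mid]]))
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        ai <- c(ai, pr[1, ]); aj <- c(aj, rep(as.integer(mid), ncol(pr))); ak <- c(ak, pr[2, ])
      }
    }
  }
  angles <- NULL
  if (length(ai) > 0) {
    ideal <- vapply(seq_along(ai), function(r) {
      ta <- template_angle(atoms, rk, ai[r], aj[r], ak[r])
      ta %||% angle_deg(m[ai[r], ], m[aj[r], ], m[ak[r], ])
    }, numeric(1))
    angles <- tibble::tibble(i = ai, j = aj, k = ak, ideal = ideal, sigma = angle_sigma)
  }
  # nonbonded: pairs not 1-2/1-3, within range
  excl <- character(0)
  if (nrow(bonds) > 0) excl <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  if (length(ai) > 0) excl <- c(excl, paste(pmin(ai, ak), pmax(ai, ak)))
  nb <- close_pairs(m, nonbonded_range)
  if (nrow(nb) > 0) {
    key <- paste(nb$i, nb$j)
    nb <- nb[!(key %in% excl), , drop = FALSE]
  }
  nonbonded <- NULL
  if (nrow(nb) > 0) {
    # metal contacts are essentially unrestrained (repulsion only at very
    # short range): halve the minimum approach for metal-involving pairs
    met <- is_metal_element(atoms$element[nb$i]) | is_metal_element(atoms$element[nb$j])
    scale <- ifelse(met, nonbonded_scale * 0.65, nonbonded_scale)
    dmin <- scale * (vdw_radius(atoms$element[nb$i]) +
                       vdw_radius(atoms$element[nb$j]))
    nonbonded <- tibble::tibble(i = nb$i, j = nb$j, dmin = dmin, sigma = 0.2)
  }
  restraint_topology(bonds = bonds, angles = angles, nonbonded = nonbonded,
                     n_atoms = nrow(atoms))
}

close_pairs <- function(m, range) {
  n <- nrow(m)
  ii <- jj <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      d2 <- (m[js, 1] - m[i, 1])^2 + (m[js, 2] - m[i, 2])^2 + (m[js, 3] - m[i, 3])^2
      hit <- js[d2 < range^2]
      ii <- c(ii, rep(i, length(hit))); jj <- c(jj, hit)
    }
  }
  tibble::tibble(i = ii, j = jj)
}

# ideal angle from the residue's fragment template, if all three atoms belong
# to the same templated residue; NULL otherwise
template_angle <- function(atoms, rk, i, j, k) {
  rn <- atoms$residue_name[j]
  if (rk[i] != rk[j] || rk[k] != rk[j]) return(NULL)
  tpl <- fragment_template(rn)
  if (is.null(tpl)) return(NULL)
  idx <- match(c(atoms$atom_name[i], atoms$atom_name[j], atoms$atom_name[k]),
               tpl$atom_name)
  if (anyNA(idx)) return(NULL)
  mm <- cbind(tpl$x, tpl$y, tpl$z)
  angle_deg(mm[idx[1], ], mm[idx[2], ], mm[idx[3], ])
}

angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Dimensionless restraint energy and analytic gradient
#'
#' Sum over terms of ((observed - ideal)/sigma)^2 for bonds, angles and
#' torsions, plus a one-sided quadratic repulsion below the nonbonded
#' minimum-approach distance. Dimensionless by construction.
#'
#' @param topo A `qr_topology`.
#' @param coords n x 3 coordinate matrix matching the topology's atom count.
#' @return List with `value` and `gradient` (n x 3).
#' @export
restraint_energy <- function(topo, coords) {
  coords <- rbind3(coords)
  if (nrow(coords) < topo$n_atoms) {
    abort("coordinate matrix smaller than the topology's atom count",
          class = "qrsite_topology_error")
  }
  e <- 0
  g <- matrix(0, nrow(coords), 3)
  b <- topo$bonds
  if (nrow(b) > 0) {
    dv <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    dev <- (d - b$ideal) / b$sigma
    e <- e + sum(dev^2)
    coef <- 2 * dev / (b$sigma * pmax(d, 1e-12))
    gv <- dv * coef
    g <- accumulate_rows(g, b$i, gv)
    g <- accumulate_rows(g, b$j, -gv)
  }
  a <- topo$angles
  if (nrow(a) > 0) {
    for (r in seq_len(nrow(a))) {
      ag <- angle_grad(coords[a$i[r], ], coords[a$j[r], ], coords[a$k[r], ])
      dev <- (ag$theta_deg - a$ideal[r]) / a$sigma[r]
      e <- e + dev^2
      coef <- 2 * dev / a$sigma[r] * 180 / pi
      g[a$i[r], ] <- g[a$i[r], ] + coef * ag$d1
      g[a$j[r], ] <- g[a$j[r], ] + coef * ag$d2
      g[a$k[r], ] <- g[a$k[r], ] + coef * ag$d3
    }
  }
  tt <- topo$torsions
  if (nrow(tt) > 0) {
    for (r in seq_len(nrow(tt))) {
      tg <- torsion_grad(coords[tt$i[r], ], coords[tt$j[r], ],
                         coords[tt$k[r], ], coords[tt$l[r], ])
      span <- 360 / tt$period[r]
      dev_deg <- (tg$phi_deg - tt$ideal[r]) %% span
      if (dev_deg > span / 2) dev_deg <- dev_deg - span
      dev <- dev_deg / tt$sigma[r]
      e <- e + dev^2
      coef <- 2 * dev / tt$sigma[r] * 180 / pi
      g[tt$i[r], ] <- g[tt$i[r], ] + coef * tg$d1
      g[tt$j[r], ] <- g[tt$j[r], ] + coef * tg$d2
      g[tt$k[r], ] <- g[tt$k[r], ] + coef * tg$d3
      g[tt$l[r], ] <- g[tt$l[r], ] + coef * tg$d4
    }
  }
  nb <- topo$nonbonded
  if (nrow(nb) > 0) {
    dv <- coords[nb$i, , drop = FALSE] - coords[nb$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    viol <- d < nb$dmin
    if (any(viol)) {
      dev <- (nb$dmin[viol] - d[viol]) / nb$sigma[viol]
      e <- e + sum(dev^2)
      coef <- -2 * dev / (nb$sigma[viol] * pmax(d[viol], 1e-12))
      gv <- dv[viol, , drop = FALSE] * coef
      g <- accumulate_rows(g, nb$i[viol], gv)
      g <- accumulate_rows(g, nb$j[viol], -gv)
    }
  }
  list(value = e, gradient = g)
}

accumulate_rows <- function(g, idx, add) {
  for (col in 1:3) {
    g[, col] <- g[, col] + unname(tapply_add(add[, col], idx, nrow(g)))
  }
  g
}

tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# gradient of the angle (radians) at vertex p2
angle_grad <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- vnorm(u); nv <- vnorm(v)
  uh <- u / nu; vh <- v / nv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(1e-12, 1 - ct^2))
  d1 <- (ct * uh - vh) / (nu * st)
  d3 <- (ct * vh - uh) / (nv * st)
  list(theta_deg = acos(ct) * 180 / pi, d1 = d1, d2 = -(d1 + d3), d3 = d3)
}

# signed dihedral (degrees) and gradients (radians per Angstrom)
torsion_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  nb2 <- vnorm(b2)
  phi <- atan2(sum(pracma_cross(n1, n2) * b2) / nb2, sum(n1 * n2))
  n1sq <- max(sum(n1 * n1), 1e-12)
  n2sq <- max(sum(n2 * n2), 1e-12)
  d1 <- -nb2 / n1sq * n1
  d4 <- nb2 / n2sq * n2
  f12 <- sum(b1 * b2) / (nb2^2)
  f32 <- sum(b3 * b2) / (nb2^2)
  d2 <- -(1 + f12) * d1 + f32 * d4
  d3 <- f12 * d1 - (1 + f32) * d4
  list(phi_deg = phi * 180 / pi, d1 = d1, d2 = d2, d3 = d3, d4 = d4)
}
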