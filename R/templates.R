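# Idealised ligand fragment templates used by both the toy-site generator and
# the surrogate engine (internal reference distances). Coordinates are built
# programmatically; all fragments are local (anchor-centred) tibbles.

# Imidazole ring as a regular pentagon (side 1.37 A) in the xy-plane with CB
# attached radially to CG (1.50 A) and CA extending further out (1.52 A).
template_his <- function() {
  s <- 1.37
  R <- s / (2 * sin(pi / 5))
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  ring <- c("CG", "ND1", "CE1", "NE2", "CD2")
  elem <- c("C", "N", "C", "N", "C")
  xy <- cbind(R * cos(ang), R * sin(ang), 0)
  cg <- xy[1, ]
  cb <- cg * (1 + 1.50 / R)
  ca <- cg * (1 + (1.50 + 1.52) / R)
  tibble::tibble(
    atom_name = c(ring, "CB", "CA"),
    element = c(elem, "C", "C"),
    x = c(xy[, 1], cb[1], ca[1]),
    y = c(xy[, 2], cb[2], ca[2]),
    z = c(xy[, 3], cb[3], ca[3])
  )
}

# Carboxylate side chain (Asp-like): CG at origin, O-C-O 126 deg, C-O 1.25 A.
template_asp <- function() {
  half <- 126 / 2 * pi / 180
  tibble::tibble(
    atom_name = c("CG", "OD1", "OD2", "CB", "CA"),
    element = c("C", "O", "O", "C", "C"),
    x = c(0, 1.25 * sin(half), -1.25 * sin(half), 0, 0),
    y = c(0, 1.25 * cos(half), 1.25 * cos(half), -1.52, -1.52 - 1.52),
    z = c(0, 0, 0, 0, 0)
  )
}

# Amide side chain (Asn-like): CG at origin, C=O 1.23 A, C-N 1.33 A, sp2.
template_asn <- function() {
  a <- 60 * pi / 180
  tibble::tibble(
    atom_name = c("CG", "OD1", "ND2", "CB", "CA"),
    element = c("C", "O", "N", "C", "C"),
    x = c(0, 1.23 * sin(a), -1.33 * sin(a), 0, 0),
    y = c(0, 1.23 * cos(a), 1.33 * cos(a), -1.52, -1.52 - 1.52),
    z = c(0, 0, 0, 0, 0)
  )
}

fragment_template <- function(residue_name) {
  switch(toupper(residue_name),
         HIS = template_his(),
         ASP = template_asp(),
         ASN = template_asn(),
         HOH = tibble::tibble(atom_name = "O", element = "O", x = 0, y = 0, z = 0),
         NULL)
}

# Reference internal distances (bonded and 1-3 pairs) per template residue,
# keyed "NAME1|NAME2" with sorted names. Used as surrogate-engine ideals.
template_distance_dict <- function(residue_name) {
  tpl <- fragment_template(residue_name)
  if (is.null(tpl)) return(list())
  m <- cbind(tpl$x, tpl$y, tpl$z)
  bonds <- detect_bonds(tpl$element, m)
  out <- list()
  keyof <- function(i, j) paste(sort(c(tpl$atom_name[i], tpl$atom_name[j])), collapse = "|")
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    out[[keyof(i, j)]] <- vnorm(m[i, ] - m[j, ])
  }
  # 1-3 pairs
  adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  for (mid in names(adj)) {
    nb <- adj[[mid]]
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      for (cidx in seq_len(ncol(pr))) {
        i <- pr[1, cidx]; j <- pr[2, cidx]
        k <- keyof(i, j)
        if (is.null(out[[k]])) out[[k]] <- vnorm(m[i, ] - m[j, ])
      }
    }
  }
  out
}

# Rigidly place a fragment template so that `anchor` sits at
# `center + dist * v` with the anchor's outward lone-pair direction pointing
# back at `center`; `normal` orients the fragment plane.
place_fragment <- function(template, anchor, center, v, dist,
                           normal = NULL, ref_atom = NULL) {
  v <- unitv(v)
  if (is.null(normal)) normal <- perp_vector(v)
  m <- cbind(template$x, template$y, template$z)
  ai <- match(anchor, template$atom_name)
  if (is.na(ai)) abort(paste0("anchor atom not in template: ", anchor),
                       class = "qrsite_geometry_error")
  # outward direction in template: from reference point (ring/CG centroid) to anchor
  if (is.null(ref_atom)) {
    heavy <- template$atom_name %in% c("CG", "ND1", "CE1", "NE2", "CD2", "OD1", "OD2")
    ref <- if (any(heavy)) colMeans(m[heavy, , drop = FALSE]) else colMeans(m)
  } else {
    ref <- m[match(ref_atom, template$atom_name), ]
  }
  w <- m[ai, ] - ref
  if (vnorm(w) < 1e-8) w <- c(0, 0, 1)
  Rm <- frame_rotation(unitv(w), c(0, 0, 1), -v, unitv(normal))
  m2 <- t(Rm %*% t(sweep(m, 2, m[ai, ], "-")))
  m2 <- sweep(m2, 2, center + dist * v, "+")
  out <- template
  out$x <- m2[, 1]; out$y <- m2[, 2]; out$z <- m2[, 3]
  out
}

# Rodrigues rotation of points about unit axis through origin.
rotate_about <- function(m, axis, theta) {
  k <- unitv(axis)
  m <- rbind3(m)
  ct <- cos(theta); st <- sin(theta)
  kx <- t(apply(m, 1, function(p) pracma_cross(k, p)))
  kdot <- as.numeric(m %*% k)
  m * ct + kx * st + outer(kdot * (1 - ct), k)
}

# Covalent bond detection among non-metal atoms: d <= r_i + r_j + 0.45 A,
# with hydrogens restricted to a single bond (their nearest heavy atom).
detect_bonds <- function(elements, coords, tol = 0.45) {
  n <- length(elements)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), d = numeric()))
  rc <- covalent_radius(elements)
  metal <- is_metal_element(elements)
  ii <- jj <- integer(); dd <- numeric()
  for (i in seq_len(n - 1)) {
    if (metal[i]) next
    js <- (i + 1):n
    js <- js[!metal[js]]
    if (length(js) == 0) next
    d <- sqrt((coords[js, 1] - coords[i, 1])^2 +
                (coords[js, 2] - coords[i, 2])^2 +
                (coords[js, 3] - coords[i, 3])^2)
    hit <- d <= (rc[i] + rc[js] + tol) & d > 0.1
    ii <- c(ii, rep(i, sum(hit))); jj <- c(jj, js[hit]); dd <- c(dd, d[hit])
  }
  b <- tibble::tibble(i = ii, j = jj, d = dd)
  # hydrogens keep only their closest partner
  h <- which(toupper(elements) == "H")
  if (length(h) > 0 && nrow(b) > 0) {
    keep <- rep(TRUE, nrow(b))
    for (a in h) {
      rows <- which(b$i == a | b$j == a)
      if (length(rows) > 1) {
        best <- rows[which.min(b$d[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    b <- b[keep, , drop = FALSE]
  }
  b
}
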