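#' Generate a ground-truth toy metal site
#'
#' Builds a small copper (or water) site from idealised ligand fragments at
#' the surrogate engine's reference geometry, embedded in an inert ~40-atom
#' carbon scaffold (one `SCF` residue on a sphere around the site, frozen in
#' all refinements). Deterministic for a given seed.
#'
#' Archetypes:
#' * `bis-his` — Cu with two imidazoles, N-Cu-N linear (Cu(I)-like, 1.90 A).
#' * `his2-asp` — Cu with two imidazoles and a monodentate carboxylate in a
#'   T-shaped/square arrangement (Cu(II)-like, 2.00-2.05 A).
#' * `his-brace` — Cu with three imidazoles (T-shaped, one open position).
#' * `water-cluster` — no metal: two waters hydrogen-bonded to a carboxylate
#'   and an amide.
#' * `dinuclear` — two Cu bridged by a carboxylate, one imidazole each.
#'
#' @param archetype One of the archetypes above.
#' @param seed Integer seed (scaffold jitter).
#' @param n_scaffold Scaffold atom count.
#' @param scaffold_radius Scaffold sphere radius (Angstrom).
#' @return A [qr_structure]; attribute `site_residues` lists the non-scaffold
#'   residues.
#' @export
generate_toy_site <- function(archetype = c("bis-his", "his2-asp", "his-brace",
                                            "water-cluster", "dinuclear"),
                              seed = 1, n_scaffold = 40, scaffold_radius = 8.5) {
  archetype <- match.arg(archetype)
  frags <- list()
  add <- function(df, resname, resno, chain = "A") {
    df$residue_name <- resname
    df$residue_number <- as.integer(resno)
    df$chain_id <- chain
    frags[[length(frags) + 1]] <<- df
  }
  his_at <- function(v, d, normal = c(0, 0, 1)) {
    place_fragment(template_his(), "ND1", c(0, 0, 0), unitv(v), d, normal = normal)
  }
  cu_atom <- function(pos, resno) {
    tibble::tibble(atom_name = "CU", element = "CU",
                   x = pos[1], y = pos[2], z = pos[3],
                   residue_name = "CU", residue_number = as.integer(resno),
                   chain_id = "A")
  }
  water_at <- function(pos, resno) {
    tibble::tibble(atom_name = "O", element = "O",
                   x = pos[1], y = pos[2], z = pos[3],
                   residue_name = "HOH", residue_number = as.integer(resno),
                   chain_id = "A")
  }
  if (archetype == "bis-his") {
    frags <- list()
    add(cu_atom(c(0, 0, 0), 200), "CU", 200)
    add(his_at(c(1, 0, 0), 1.90), "HIS", 101)
    add(his_at(c(-1, 0, 0), 1.90, normal = c(0, 1, 1)), "HIS", 102)
  } else if (archetype == "his2-asp") {
    frags <- list()
    add(cu_atom(c(0, 0, 0), 200), "CU", 200)
    add(his_at(c(1, 0, 0), 2.00, normal = c(0, 0, -1)), "HIS", 101)
    add(his_at(c(0, 1, 0), 2.00, normal = c(1, 0, 1)), "HIS", 102)
    add(place_fragment(template_asp(), "OD1", c(0, 0, 0), c(-1, 0, 0), 2.05,
                       normal = c(0, 1, 0), ref_atom = "CG"), "ASP", 103)
  } else if (archetype == "his-brace") {
    frags <- list()
    add(cu_atom(c(0, 0, 0), 200), "CU", 200)
    add(his_at(c(1, 0, 0), 2.00, normal = c(0, 0, -1)), "HIS", 101)
    add(his_at(c(-1, 0, 0), 2.00, normal = c(0, 1, 1)), "HIS", 102)
    add(his_at(c(0, 1, 0), 2.00, normal = c(1, 0, 1)), "HIS", 103)
  } else if (archetype == "water-cluster") {
    frags <- list()
    add(water_at(c(0, 0, 0), 301), "HOH", 301)
    add(water_at(c(0.4, 0.9, 2.6), 302), "HOH", 302)
    add(place_fragment(template_asp(), "OD1", c(0, 0, 0), c(1, 0, 0), 2.75,
                       normal = c(0, 1, 0), ref_atom = "CG"), "ASP", 103)
    add(place_fragment(template_asn(), "OD1", c(0, 0, 0), c(0, -1, 0.2), 2.75,
                       normal = c(1, 0, 0), ref_atom = "CG"), "ASN", 104)
  } else { # dinuclear
    frags <- list()
    add(cu_atom(c(0, 0, 0), 200), "CU", 200)
    add(cu_atom(c(3.3, 0, 0), 201), "CU", 201)
    add(his_at(c(-1, 0, 0), 2.00), "HIS", 101)
    add(place_fragment(template_his(), "ND1", c(3.3, 0, 0), c(1, 0, 0), 2.00),
        "HIS", 102)
    # bridging carboxylate built explicitly: OD1 near Cu1, OD2 near Cu2
    od1 <- c(0.55, 1.90, 0); od2 <- c(2.75, 1.90, 0)
    mid <- (od1 + od2) / 2
    cg <- c(mid[1], mid[2] + sqrt(max(1e-6, 1.25^2 - (vnorm(od2 - od1) / 2)^2)), 0)
    asp <- tibble::tibble(
      atom_name = c("CG", "OD1", "OD2", "CB", "CA"),
      element = c("C", "O", "O", "C", "C"),
      x = c(cg[1], od1[1], od2[1], cg[1], cg[1]),
      y = c(cg[2], od1[2], od2[2], cg[2] + 1.52, cg[2] + 3.04),
      z = 0)
    add(asp, "ASP", 103)
  }
  site <- dplyr::bind_rows(frags)
  scaffold <- withr::with_seed(seed, {
    i <- seq_len(n_scaffold)
    phi <- acos(1 - 2 * (i - 0.5) / n_scaffold)
    theta <- pi * (1 + sqrt(5)) * i
    p <- scaffold_radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    p <- p + matrix(stats::runif(3 * n_scaffold, -0.3, 0.3), ncol = 3)
    tibble::tibble(atom_name = sprintf("C%02d", i), element = "C",
                   x = p[, 1], y = p[, 2], z = p[, 3],
                   residue_name = "SCF", residue_number = 1L, chain_id = "S")
  })
  atoms <- dplyr::bind_rows(site, scaffold)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$occupancy <- 1
  atoms$b_iso <- 20
  atoms$formal_charge <- 0L
  s <- qr_structure(atoms, id = paste0("toy-", archetype))
  attr(s, "site_residues") <- unique(tibble::tibble(
    chain = site$chain_id, residue_number = site$residue_number,
    residue_name = site$residue_name))
  s
}

#' Render a synthetic noisy map from a ground-truth structure
#'
#' The truth is rendered with `blur_B` added to every atom's B (resolution
#' blurring), then i.i.d. Gaussian noise with standard deviation
#' `noise_sigma` x (pre-noise map sd) is added. Fully seeded.
#'
#' @param truth A [qr_structure]; scaffold (`SCF`) atoms are excluded from the
#'   map footprint box but not from rendering.
#' @param voxel Voxel size (Angstrom), in (0.3, 2.0).
#' @param noise_sigma Relative noise level (0 = clean).
#' @param blur_B Extra B (Angstrom^2) emulating finite resolution; by the
#'   B ~ 4 d^2 rule of thumb the default 22 corresponds to ~2.35 Angstrom,
#'   the middle of the 2.1-2.6 Angstrom range of current cryo-EM structures
#'   of this kind.
#' @param seed Integer seed for the noise.
#' @param pad Padding (Angstrom) around the site bounding box.
#' @return A [qr_map].
#' @export
simulate_map <- function(truth, voxel = 0.5, noise_sigma = 0.1, blur_B = 22,
                         seed = 1, pad = 4.0) {
  if (voxel <= 0.3 || voxel >= 2.0) {
    abort("voxel size must lie in (0.3, 2.0) Angstrom", class = "qrsite_map_error")
  }
  site <- truth[truth$residue_name != "SCF", , drop = FALSE]
  lo <- c(min(site$x), min(site$y), min(site$z)) - pad
  hi <- c(max(site$x), max(site$y), max(site$z)) + pad
  dims <- pmax(8L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  grid <- qr_map(array(0, dims), origin = lo, voxel_size = rep(voxel, 3))
  clean <- render_model_map(truth, grid, cutoff = 4 + voxel, b_add = blur_B)
  if (noise_sigma > 0) {
    s0 <- sd(as.numeric(clean$values))
    noise <- withr::with_seed(seed, rnorm(length(clean$values), 0, noise_sigma * s0))
    clean$values <- clean$values + array(noise, dims)
  }
  clean
}

#' Build an ambiguity scenario
#'
#' Packages a ground truth, a (possibly mis-modelled) observed model, a
#' simulated map, and ready-made interpretation variants for
#' [compare_interpretations()]. Regenerating with the same seed reproduces
#' everything bit-identically.
#'
#' Kinds:
#' * `correct-metal` — truth is a Cu(II) site; observed = truth perturbed by
#'   0.3 A RMSD over the site atoms. Variants: Cu(II) / Cu(I) / water.
#' * `spurious-metal-over-water` — truth is a water cluster; the observed
#'   model places a Cu ion on the water peak. Variants: Cu(II) / water.
#' * `dinuclear-over-mononuclear` — truth is a mononuclear His-brace Cu site;
#'   the observed model adds a second Cu 2.3 A away. Variants: dinuclear /
#'   mononuclear.
#' * `wrong-oxidation` — truth is a linear Cu(I) bis-His site; the observed
#'   model is correct geometry. Variants: Cu(I) / Cu(II).
#'
#' @param kind Scenario kind.
#' @param seed Integer seed (scaffold jitter, map noise, perturbation).
#' @param noise_sigma,blur_B,voxel Map simulation settings.
#' @return A `qr_scenario`: `truth`, `observed`, `map`, `variants` (named
#'   list of [site_spec]), `true_label`, `seed`.
#' @export
make_scenario <- function(kind = c("correct-metal", "spurious-metal-over-water",
                                   "dinuclear-over-mononuclear", "wrong-oxidation"),
                          seed = 1, noise_sigma = 0.1, blur_B = 22, voxel = 0.5) {
  kind <- match.arg(kind)
  members_of <- function(s, exclude_resno = integer(0)) {
    sr <- attr(s, "site_residues")
    sr <- sr[!(sr$residue_number %in% exclude_resno), , drop = FALSE]
    tibble::tibble(chain = sr$chain, residue_number = sr$residue_number,
                   backbone = FALSE)
  }
  metal_sel <- function(resno) {
    tibble::tibble(chain = "A", residue_number = as.integer(resno), atom_name = "CU")
  }
  if (kind == "correct-metal") {
    truth <- generate_toy_site("his2-asp", seed = seed)
    observed <- perturb_site(truth, rmsd_target = 0.3, seed = seed + 1000L)
    mem <- members_of(truth)
    variants <- list(
      "Cu(II)" = site_spec("toy", mem, metal_sel(200), "Cu(II)"),
      "Cu(I)" = site_spec("toy", mem, metal_sel(200), "Cu(I)"),
      "water" = site_spec("toy", mem, metal_sel(200), "water"))
    true_label <- "Cu(II)"
  } else if (kind == "spurious-metal-over-water") {
    truth <- generate_toy_site("water-cluster", seed = seed)
    observed <- truth
    w1 <- which(observed$residue_number == 301 & observed$atom_name == "O")
    observed$atom_name[w1] <- "CU"
    observed$element[w1] <- "CU"
    observed$residue_name[w1] <- "CU"
    observed <- qr_structure(observed, id = "toy-spurious-metal")
    attr(observed, "site_residues") <- attr(truth, "site_residues")
    mem <- members_of(truth)
    variants <- list(
      "Cu(II)" = site_spec("toy", mem, metal_sel(301), "Cu(II)"),
      "water" = site_spec("toy", mem, metal_sel(301), "water"))
    true_label <- "water"
  } else if (kind == "dinuclear-over-mononuclear") {
    truth <- generate_toy_site("his-brace", seed = seed)
    observed <- truth
    cu1 <- which(observed$residue_number == 200 & observed$atom_name == "CU")
    extra <- observed[cu1, , drop = FALSE]
    extra$residue_number <- 201L
    extra$serial <- max(observed$serial) + 1L
    # second Cu initialised 2.3 A from the first, in the open direction
    extra$y <- extra$y - 2.3
    observed <- qr_structure(dplyr::bind_rows(tibble::as_tibble(observed), extra),
                             id = "toy-dinuclear")
    sr <- rbind(attr(truth, "site_residues"),
                tibble::tibble(chain = "A", residue_number = 201L,
                               residue_name = "CU"))
    attr(observed, "site_residues") <- sr
    mem_di <- tibble::tibble(chain = sr$chain, residue_number = sr$residue_number,
                             backbone = FALSE)
    mem_mono <- mem_di
    variants <- list(
      "dinuclear" = site_spec("toy", mem_di,
                              rbind(metal_sel(200), metal_sel(201)),
                              c("Cu(II)", "Cu(II)"), label = "Cu(II)Cu(II)"),
      "mononuclear" = site_spec("toy",
                                mem_mono[mem_mono$residue_number != 201L, ],
                                rbind(metal_sel(200), metal_sel(201)),
                                c("Cu(II)", "absent"), label = "Cu(II)/absent"))
    true_label <- "mononuclear"
  } else { # wrong-oxidation
    truth <- generate_toy_site("bis-his", seed = seed)
    observed <- perturb_site(truth, rmsd_target = 0.1, seed = seed + 1000L)
    mem <- members_of(truth)
    variants <- list(
      "Cu(I)" = site_spec("toy", mem, metal_sel(200), "Cu(I)"),
      "Cu(II)" = site_spec("toy", mem, metal_sel(200), "Cu(II)"))
    true_label <- "Cu(I)"
  }
  map <- simulate_map(truth, voxel = voxel, noise_sigma = noise_sigma,
                      blur_B = blur_B, seed = seed)
  structure(list(name = kind, truth = truth, observed = observed, map = map,
                 variants = variants, true_label = true_label,
                 noise_sigma = noise_sigma, resolution_blur = blur_B,
                 seed = as.integer(seed)),
            class = "qr_scenario")
}

#' @export
print.qr_scenario <- function(x, ...) {
  cat(sprintf("<qr_scenario> %s (seed %d): truth '%s', %d variants, map %s\n",
              x$name, x$seed, x$true_label, length(x$variants),
              paste(dim(x$map$values), collapse = "x")))
  invisible(x)
}

# Perturb the site atoms to an exact RMSD (Angstrom). Scaffold and backbone
# stub atoms stay put: the scenarios emulate a questionably modelled site in
# an otherwise settled structure, whose surroundings are held by
# self-reference restraints anyway. Displacements are per-residue rigid
# shifts plus small per-atom jitter — model errors misplace whole groups
# rather than scrambling their internal geometry.
perturb_site <- function(s, rmsd_target = 0.3, seed = 1) {
  site_rows <- which(s$residue_name != "SCF" & !(s$atom_name %in% BACKBONE_ATOMS))
  rk <- residue_key(s)[site_rows]
  disp <- withr::with_seed(seed, {
    shift <- matrix(rnorm(3 * length(unique(rk))), ncol = 3,
                    dimnames = list(unique(rk), NULL))
    shift[rk, , drop = FALSE] + 0.2 * matrix(rnorm(3 * length(site_rows)), ncol = 3)
  })
  disp <- disp * rmsd_target / sqrt(mean(rowSums(disp^2)))
  s$x[site_rows] <- s$x[site_rows] + disp[, 1]
  s$y[site_rows] <- s$y[site_rows] + disp[, 2]
  s$z[site_rows] <- s$z[site_rows] + disp[, 3]
  attr(s, "id") <- paste0(attr(s, "id"), "-perturbed")
  s
}

#' Write a scenario's artifacts to a directory
#'
#' Writes `truth.pdb`, `observed.pdb`, `map.mrc` and `manifest.json`.
#'
#' @param scenario A `qr_scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(scenario$truth, file.path(dir, "truth.pdb"))
  write_structure(scenario$observed, file.path(dir, "observed.pdb"))
  write_map(scenario$map, file.path(dir, "map.mrc"))
  manifest <- list(kind = scenario$name, seed = scenario$seed,
                   true_label = scenario$true_label,
                   noise_sigma = scenario$noise_sigma,
                   resolution_blur = scenario$resolution_blur,
                   variants = names(scenario$variants))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
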