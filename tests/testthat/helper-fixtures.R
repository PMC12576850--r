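# Shared fixtures, built in code at test time.

# finite-difference gradient of an (value, gradient) evaluator over coords
fd_gradient <- function(fn, coords, h = 1e-6) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (k in 1:3) {
      cp <- coords; cp[i, k] <- cp[i, k] + h
      cm <- coords; cm[i, k] <- cm[i, k] - h
      g[i, k] <- (fn(cp)$value - fn(cm)$value) / (2 * h)
    }
  }
  g
}

# a carved + protonated region over a toy site, with its surrogate engine
toy_region <- function(archetype = "his2-asp", interpretation = "Cu(II)",
                       seed = 1) {
  s <- generate_toy_site(archetype, seed = seed)
  sr <- attr(s, "site_residues")
  members <- tibble::tibble(chain = sr$chain, residue_number = sr$residue_number,
                            backbone = FALSE)
  metals <- tibble::tibble(chain = "A", residue_number = 200L, atom_name = "CU")
  spec <- site_spec("toy", members, metals, interpretation)
  region <- protonate_region(carve_region(s, spec), s)
  list(structure = s, spec = spec, region = region,
       engine = surrogate_engine(region))
}

site_heavy_atoms <- function(s) {
  s[s$residue_name != "SCF" & !(s$atom_name %in% c("N", "CA", "C", "O")) &
      s$element != "H", , drop = FALSE]
}

rmsd_between <- function(a, b) {
  key <- paste(a$chain_id, a$residue_number, a$atom_name)
  idx <- match(key, paste(b$chain_id, b$residue_number, b$atom_name))
  stopifnot(!anyNA(idx))
  da <- cbind(a$x, a$y, a$z)
  db <- cbind(b$x[idx], b$y[idx], b$z[idx])
  sqrt(mean(rowSums((da - db)^2)))
}
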