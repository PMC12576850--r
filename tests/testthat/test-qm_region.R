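test_that("carving severs side chains at CB-CA and records one link per bond", {
  tr <- toy_region("his2-asp", "Cu(II)")
  region <- tr$region
  # no backbone atoms inside the region
  expect_false(any(region$atoms$atom_name %in% c("CA", "N", "C", "O")))
  # link-atom count equals the brute-force severed-bond count
  s <- tr$structure
  bonds <- qrsite:::detect_bonds(s$element, cbind(s$x, s$y, s$z))
  kept <- paste(region$atoms$chain_id[!region$atoms$is_link &
                                        !region$atoms$is_added_h],
                region$atoms$residue_number[!region$atoms$is_link &
                                              !region$atoms$is_added_h],
                region$atoms$atom_name[!region$atoms$is_link &
                                         !region$atoms$is_added_h])
  allk <- paste(s$chain_id, s$residue_number, s$atom_name)
  inreg <- allk %in% kept
  n_severed <- sum(xor(inreg[bonds$i], inreg[bonds$j]))
  expect_equal(sum(region$atoms$is_link), n_severed)
  expect_equal(nrow(region$link_atoms), n_severed)
})

test_that("a region of one water and one metal has no link atoms", {
  s <- qr_structure(tibble::tibble(
    atom_name = c("CU", "O"), element = c("CU", "O"),
    residue_name = c("CU", "HOH"), residue_number = c(1L, 2L), chain_id = "A",
    x = c(0, 2.2), y = 0, z = 0))
  spec <- site_spec("w", tibble::tibble(chain = "A", residue_number = 1:2),
                    tibble::tibble(chain = "A", residue_number = 1L,
                                   atom_name = "CU"), "Cu(I)")
  region <- carve_region(s, spec)
  expect_equal(sum(region$atoms$is_link), 0)
  expect_equal(nrow(region$link_atoms), 0)
})

test_that("unresolvable selectors raise selection errors", {
  tr <- toy_region()
  bad <- tr$spec
  bad$members <- dplyr::bind_rows(bad$members,
                                  tibble::tibble(chain = "Z", residue_number = 9L,
                                                 backbone = FALSE))
  expect_error(carve_region(tr$structure, bad), class = "qrsite_selection_error")
})

test_that("region export is carve-idempotent", {
  tr <- toy_region("bis-his", "Cu(I)")
  frag <- region_to_structure(tr$region)
  frag <- frag[frag$element != "H" | !grepl("^HL", frag$atom_name), ]
  spec2 <- tr$spec
  region2 <- carve_region(qr_structure(frag), spec2)
  # same heavy atoms, no new link atoms beyond hydrogens already present
  h1 <- tr$region$atoms[!tr$region$atoms$is_link, ]
  expect_setequal(paste(region2$atoms$atom_name[!region2$atoms$is_link],
                        region2$atoms$residue_number[!region2$atoms$is_link]),
                  paste(h1$atom_name, h1$residue_number))
  expect_equal(nrow(region2$link_atoms), 0)
})

test_that("His coordinating through ND1 is protonated on NE2", {
  tr <- toy_region("bis-his", "Cu(I)")
  h <- tr$region$atoms[tr$region$atoms$is_added_h, ]
  his_h <- h[h$residue_name == "HIS", ]
  expect_equal(nrow(his_h), 2)
  expect_true(all(his_h$atom_name == "HNE2"))
  # placed H sits ~1.01 A from its nitrogen
  for (i in seq_len(nrow(his_h))) {
    n <- tr$region$atoms[tr$region$atoms$residue_number == his_h$residue_number[i] &
                           tr$region$atoms$atom_name == "NE2", ]
    d <- sqrt((n$x - his_h$x[i])^2 + (n$y - his_h$y[i])^2 + (n$z - his_h$z[i])^2)
    expect_equal(d, 1.01, tolerance = 1e-6)
  }
})

test_that("waters get two hydrogens at 0.96 A and 104.5 degrees", {
  s <- generate_toy_site("water-cluster", seed = 2)
  sr <- attr(s, "site_residues")
  spec <- site_spec("w", tibble::tibble(chain = sr$chain,
                                        residue_number = sr$residue_number,
                                        backbone = FALSE),
                    tibble::tibble(chain = character(0),
                                   residue_number = integer(0),
                                   atom_name = character(0)),
                    character(0))
  region <- protonate_region(carve_region(s, spec), s)
  for (w in c(301L, 302L)) {
    res <- region$atoms[region$atoms$residue_number == w, ]
    hs <- res[res$element == "H", ]
    o <- res[res$element == "O", ]
    expect_equal(nrow(hs), 2)
    d <- sqrt((hs$x - o$x)^2 + (hs$y - o$y)^2 + (hs$z - o$z)^2)
    expect_equal(d, c(0.96, 0.96), tolerance = 1e-6)
    u1 <- c(hs$x[1] - o$x, hs$y[1] - o$y, hs$z[1] - o$z) / 0.96
    u2 <- c(hs$x[2] - o$x, hs$y[2] - o$y, hs$z[2] - o$z) / 0.96
    expect_equal(acos(sum(u1 * u2)) * 180 / pi, 104.5, tolerance = 0.1)
  }
})

test_that("charge and spin bookkeeping follows residues and oxidation states", {
  # Cu(II) + 2 neutral imidazoles + Asp(-1): net +1, doublet
  tr2 <- toy_region("his2-asp", "Cu(II)")
  expect_equal(tr2$region$net_charge, 1L)
  expect_equal(tr2$region$spin_multiplicity, 2L)
  # Cu(I), no anions: net +1, singlet
  tr1 <- toy_region("bis-his", "Cu(I)")
  expect_equal(tr1$region$net_charge, 1L)
  expect_equal(tr1$region$spin_multiplicity, 1L)
  # Cu(II) -> Cu(I) lowers the charge by 1; Cu -> water by the full charge
  trw <- toy_region("his2-asp", "water")
  tr1b <- toy_region("his2-asp", "Cu(I)")
  expect_equal(tr2$region$net_charge - tr1b$region$net_charge, 1L)
  expect_equal(tr1b$region$net_charge - trw$region$net_charge, 1L)
  expect_equal(trw$region$spin_multiplicity, 1L)
})

test_that("link atoms sit on the host segment and move equivariantly", {
  tr <- toy_region("his2-asp", "Cu(II)")
  region <- tr$region
  s <- tr$structure
  la <- region$link_atoms
  for (i in seq_len(nrow(la))) {
    qm <- s[s$chain_id == la$qm_chain[i] & s$residue_number == la$qm_residue_number[i] &
              s$atom_name == la$qm_atom[i], ]
    mm <- s[s$chain_id == la$mm_chain[i] & s$residue_number == la$mm_residue_number[i] &
              s$atom_name == la$mm_atom[i], ]
    h <- region$atoms[region$atoms$is_link, ][i, ]
    u <- c(mm$x - qm$x, mm$y - qm$y, mm$z - qm$z)
    u <- u / sqrt(sum(u^2))
    expect_equal(c(h$x, h$y, h$z),
                 c(qm$x, qm$y, qm$z) + la$bond_length[i] * u, tolerance = 1e-9)
  }
  # rigid rotation of the whole structure rotates link H identically
  R <- qrsite:::rotate_about(diag(3), c(1, 1, 0), 0.6)
  s2 <- s
  m <- cbind(s$x, s$y, s$z) %*% t(R)
  s2$x <- m[, 1]; s2$y <- m[, 2]; s2$z <- m[, 3]
  region2 <- region
  a2 <- region2$atoms
  ma <- cbind(a2$x, a2$y, a2$z) %*% t(R)
  a2$x <- ma[, 1]; a2$y <- ma[, 2]; a2$z <- ma[, 3]
  region2$atoms <- a2
  region2 <- place_link_atoms(region2, s2)
  h_rot <- qrsite:::coords_matrix(region$atoms[region$atoms$is_link, ]) %*% t(R)
  expect_equal(qrsite:::coords_matrix(region2$atoms[region2$atoms$is_link, ]),
               h_rot, tolerance = 1e-9)
})

test_that("coincident link hosts raise a geometry error", {
  tr <- toy_region("bis-his", "Cu(I)")
  region <- tr$region
  s <- tr$structure
  la1 <- region$link_atoms[1, ]
  qmrow <- which(s$chain_id == la1$qm_chain & s$residue_number == la1$qm_residue_number &
                   s$atom_name == la1$qm_atom)
  mmrow <- which(s$chain_id == la1$mm_chain & s$residue_number == la1$mm_residue_number &
                   s$atom_name == la1$mm_atom)
  s$x[mmrow] <- s$x[qmrow]; s$y[mmrow] <- s$y[qmrow]; s$z[mmrow] <- s$z[qmrow]
  expect_error(place_link_atoms(region, s), class = "qrsite_geometry_error")
})

test_that("apply_interpretation substitutes water and removes absent metals", {
  s <- generate_toy_site("dinuclear", seed = 1)
  mem <- tibble::tibble(chain = "A", residue_number = c(101L, 102L, 103L, 200L, 201L))
  metals <- tibble::tibble(chain = "A", residue_number = c(200L, 201L),
                           atom_name = "CU")
  spec_w <- site_spec("d", mem, metals, c("Cu(II)", "water"))
  sw <- apply_interpretation(s, spec_w)
  w <- sw[sw$residue_number == 201L & sw$chain_id == "A", ]
  expect_identical(w$element, "O")
  expect_identical(w$residue_name, "HOH")
  spec_a <- site_spec("d", mem[mem$residue_number != 201L, ], metals,
                      c("Cu(II)", "absent"))
  sa <- apply_interpretation(s, spec_a)
  expect_equal(nrow(sa), nrow(s) - 1)
  expect_error(site_spec("d", mem, metals, c("Cu(III)", "water")),
               class = "qrsite_spec_error")
})
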