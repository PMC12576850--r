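test_that("strain is zero at the constrained optimum and k*delta^2 on a spring", {
  # relaxed region: strain ~ 0
  tr <- toy_region("bis-his", "Cu(I)")
  st0 <- strain_energy(tr$region, engine = tr$engine, tol = 1e-5)
  expect_lt(abs(st0$delta_e_str), 0.5)         # kJ/mol
  expect_gte(st0$delta_e_str, -1e-6)
  # single Cu-N spring, k = 100 kcal/mol/A^2, stretched 0.1 A:
  # delta = 100 * 0.01 kcal/mol exactly (in kJ: * 4.184)
  eng <- spring_engine(k = 100, d0 = 2.0)
  region <- list(
    atoms = tibble::tibble(
      atom_name = c("CU", "ND1"), element = c("CU", "N"),
      residue_name = c("CU", "HIS"), residue_number = c(1L, 2L), chain_id = "A",
      x = c(0, 2.1), y = 0, z = 0, occupancy = 1, b_iso = 20,
      formal_charge = 0L, serial = 1:2, is_link = FALSE,
      is_added_h = FALSE),
    link_atoms = tibble::tibble(), net_charge = 1L, spin_multiplicity = 1L,
    spec = site_spec("spring", tibble::tibble(chain = "A", residue_number = 1:2),
                     tibble::tibble(chain = "A", residue_number = 1L,
                                    atom_name = "CU"), "Cu(I)"))
  class(region) <- "qr_region"
  st <- strain_energy(region, engine = eng, tol = 1e-7)
  expect_equal(st$e_model, 100 * 0.01 * 4.184, tolerance = 1e-6)
  expect_equal(st$e_relaxed, 0, tolerance = 1e-8)
  expect_equal(st$delta_e_str, 100 * 0.01 * 4.184, tolerance = 1e-6)
})

test_that("strain is non-negative for perturbed regions across seeds", {
  for (seed in 1:5) {
    tr <- toy_region("his2-asp", "Cu(II)", seed = seed)
    region <- tr$region
    withr::with_seed(seed + 77, {
      m <- qrsite:::coords_matrix(region$atoms)
      m <- m + matrix(rnorm(length(m), sd = 0.1), ncol = 3)
    })
    region$atoms <- qrsite:::set_coords(region$atoms, m)
    st <- strain_energy(region, engine = tr$engine)
    expect_gte(st$delta_e_str, -1e-4)
    expect_gt(st$delta_e_str, 1)     # a 0.1 A scramble is visibly strained
  }
})

test_that("the weight-scan selector implements the highest-before-worse rule", {
  # strain flat to w = 10 then rising; RSCC falls after 10 -> select 10
  tb <- tibble::tibble(
    w_x = c(0, 1, 3, 5, 10, 20, 30, 50, 75, 100),
    avg_rscc = c(0.80, 0.82, 0.84, 0.85, 0.86, 0.84, 0.82, 0.80, 0.78, 0.75),
    delta_e_str = c(5, 5, 5, 5.2, 5.3, 9, 15, 25, 40, 80))
  expect_equal(select_weight(tb), 10)
  # flat table: the maximum of the grid
  flat <- tibble::tibble(w_x = c(0, 1, 3, 10, 100),
                         avg_rscc = 0.8, delta_e_str = 5)
  expect_equal(select_weight(flat), 100)
  # early strain jump stops the scan immediately
  early <- tibble::tibble(w_x = c(0, 3, 10), avg_rscc = c(0.8, 0.8, 0.9),
                          delta_e_str = c(5, 50, 4))
  expect_equal(select_weight(early), 0)
  # RSCC decrease within abs_tol is tolerated
  tol_ok <- tibble::tibble(w_x = c(1, 3, 10), avg_rscc = c(0.800, 0.795, 0.791),
                           delta_e_str = 5)
  expect_equal(select_weight(tol_ok), 10)
  expect_error(select_weight(tol_ok[0, ]), class = "qrsite_scan_error")
})

test_that("a short real weight scan returns a grid member and the full table", {
  tr <- toy_region("bis-his", "Cu(I)")
  mp <- simulate_map(tr$structure, noise_sigma = 0.05, seed = 3)
  cfg <- refinement_config(max_iter = 150)
  scan <- suppressWarnings(
    weight_scan(tr$structure, tr$region, mp, cfg = cfg, grid = c(0, 3, 10, 30)))
  expect_equal(nrow(scan), 4)
  expect_true(selected_weight(scan) %in% c(0, 3, 10, 30))
  expect_error(weight_scan(tr$structure, tr$region, mp, grid = c(10, 3)),
               class = "qrsite_scan_error")
  td <- tidy(scan)
  expect_equal(sum(td$selected), 1)
})

test_that("interpretation comparison ranks byte-identical variants as ties", {
  sc <- make_scenario("wrong-oxidation", seed = 3)
  variants <- list(a = sc$variants[[1]], b = sc$variants[[1]])
  rep <- suppressWarnings(compare_interpretations(sc$observed, variants, sc$map))
  expect_equal(rep$scores$delta_e_str[1], rep$scores$delta_e_str[2],
               tolerance = 1e-9)
  expect_true(rep$scores$tie_with_previous[2])
})

test_that("ranking is invariant to variant ordering and rigid transformation", {
  sc <- make_scenario("spurious-metal-over-water", seed = 2)
  r1 <- suppressWarnings(compare_interpretations(sc$observed, sc$variants, sc$map))
  r2 <- suppressWarnings(compare_interpretations(sc$observed, rev(sc$variants), sc$map))
  expect_identical(r1$scores$variant, r2$scores$variant)
  expect_equal(r1$scores$delta_e_str, r2$scores$delta_e_str, tolerance = 1e-9)
  # rigid translation of all inputs preserves scores exactly
  shift <- c(3, -2, 1)
  obs2 <- sc$observed
  obs2 <- qrsite:::set_coords(obs2, sweep(qrsite:::coords_matrix(obs2), 2,
                                          shift, "+"))
  map2 <- sc$map
  map2$origin <- sc$map$origin + shift
  r3 <- suppressWarnings(compare_interpretations(obs2, sc$variants, map2))
  expect_identical(r1$scores$variant, r3$scores$variant)
  # optimiser paths differ in the last floating-point digits after a shift
  expect_equal(r1$scores$delta_e_str, r3$scores$delta_e_str, tolerance = 1e-3)
})

test_that("geometry report lists metal contacts, angles and coordination", {
  s <- generate_toy_site("his2-asp", seed = 1)
  spec <- site_spec("toy",
                    tibble::tibble(chain = "A",
                                   residue_number = c(101L, 102L, 103L, 200L),
                                   backbone = FALSE),
                    tibble::tibble(chain = "A", residue_number = 200L,
                                   atom_name = "CU"), "Cu(II)")
  geo <- geometry_report(s, spec)
  bonds <- geo[geo$type == "bond", ]
  expect_true(all(bonds$value <= 3.5))
  # coordination number equals the brute-force neighbour count at 2.6 A
  cu <- s[s$atom_name == "CU", ]
  d <- sqrt((s$x - cu$x)^2 + (s$y - cu$y)^2 + (s$z - cu$z)^2)
  brute <- sum(d <= 2.6 & d > 0.05 & s$element %in% c("N", "O", "S"))
  expect_equal(geo$value[geo$type == "coordination"], brute)
  # donor angles present for >= 2 donors
  expect_gt(sum(geo$type == "angle"), 0)
  # two-atom structure: exactly one distance row
  s2 <- qr_structure(tibble::tibble(
    atom_name = c("CU", "O"), element = c("CU", "O"),
    residue_name = c("CU", "HOH"), residue_number = 1:2, chain_id = "A",
    x = c(0, 2.2), y = 0, z = 0))
  spec2 <- site_spec("w", tibble::tibble(chain = "A", residue_number = 1:2),
                     tibble::tibble(chain = "A", residue_number = 1L,
                                    atom_name = "CU"), "Cu(II)")
  geo2 <- geometry_report(s2, spec2)
  expect_equal(sum(geo2$type == "bond"), 1)
  expect_equal(geo2$value[geo2$type == "bond"], 2.2, tolerance = 1e-9)
})

test_that("site report tidiers and strain of refined <= strain of start", {
  sc <- make_scenario("spurious-metal-over-water", seed = 4)
  rep <- suppressWarnings(compare_interpretations(sc$observed, sc$variants, sc$map))
  td <- tidy(rep)
  expect_true(all(c("rank", "variant", "avg_rscc", "delta_e_str") %in% names(td)))
  gl <- glance(rep)
  expect_identical(gl$ranked_first, ranked_first(rep))
  # refinement (which includes the engine term) does not increase strain
  spec <- sc$variants[["Cu(II)"]]
  sv <- apply_interpretation(sc$observed, spec)
  region <- protonate_region(carve_region(sv, spec), sv)
  engine <- surrogate_engine(region)
  st_start <- strain_energy(region, engine = engine)
  st_refined <- rep$scores$delta_e_str[rep$scores$variant == "Cu(II)"]
  expect_lte(st_refined, st_start$delta_e_str + 1e-6)
})
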