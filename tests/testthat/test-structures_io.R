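test_that("structure round trip preserves atoms, chains and numbering", {
  s <- generate_toy_site("bis-his", seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path, dialect = "pdb")
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$chain_id, s$chain_id)
  expect_equal(s2$residue_number, s$residue_number)
  expect_equal(s2$atom_name, s$atom_name)
  expect_equal(s2$element, s$element)
  expect_equal(s2$x, round(s$x, 3))          # written to 3 decimals
  expect_equal(s2$y, round(s$y, 3))
  expect_equal(s2$occupancy, round(s$occupancy, 2))
  expect_equal(s2$b_iso, round(s$b_iso, 2))
})

test_that("written PDB has fixed-format coordinates and copper element", {
  s <- qr_structure(tibble::tibble(
    atom_name = c("CU", "O"), element = c("CU", "O"),
    residue_name = c("CU", "HOH"), residue_number = c(1L, 2L),
    chain_id = "A", x = c(1.234, 0), y = c(5.678, 0), z = c(9.012, 0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  lines <- readLines(path)
  cu <- grep("^HETATM", lines, value = TRUE)[1]
  expect_identical(substr(cu, 31, 54), "   1.234   5.678   9.012")
  expect_identical(trimws(substr(cu, 77, 78)), "CU")
  s2 <- read_structure(path)
  expect_identical(s2$element[1], "CU")
  expect_equal(s2$occupancy[1], 1)
})

test_that("empty structure writes a header/END-only file", {
  s <- qr_structure(tibble::tibble(
    atom_name = character(0), element = character(0),
    residue_name = character(0), residue_number = integer(0),
    chain_id = character(0), x = numeric(0), y = numeric(0), z = numeric(0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  lines <- readLines(path)
  expect_length(grep("^(ATOM|HETATM)", lines), 0)
  expect_identical(tail(lines, 1), "END")
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 1.0)
  expect_equal(s$occupancy, 0.6)
})

test_that("structure validation rejects bad records", {
  base <- tibble::tibble(atom_name = "CA", element = "C", residue_name = "ALA",
                         residue_number = 1L, chain_id = "A",
                         x = 0, y = 0, z = 0)
  bad_occ <- base; bad_occ$occupancy <- 1.5
  expect_error(qr_structure(bad_occ), class = "qrsite_structure_error")
  bad_b <- base; bad_b$b_iso <- -1
  expect_error(qr_structure(bad_b), class = "qrsite_structure_error")
  dup <- dplyr::bind_rows(base, base)
  expect_error(qr_structure(dup), class = "qrsite_structure_error")
  expect_error(read_structure(tempfile()), class = "qrsite_io_error")
})

test_that("map round trip is bit-identical and honours axis order", {
  vals <- array(rnorm(9 * 11 * 7), c(9, 11, 7))
  m <- qr_map(vals, origin = c(-2, 3.5, 1), voxel_size = c(0.5, 0.75, 1),
              axis_order = c(2L, 3L, 1L))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  m2 <- read_map(path)
  expect_equal(dim(m2$values), dim(vals))
  expect_equal(m2$values, vals, tolerance = 1e-6)     # float32 storage
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_identical(m2$axis_order, c(2L, 3L, 1L))
})

test_that("non-identity axis order yields the same world-coordinate field", {
  vals <- array(rnorm(8^3), c(8, 8, 8))
  tmp1 <- withr::local_tempfile(fileext = ".mrc")
  tmp2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(qr_map(vals, voxel_size = c(1, 1, 1)), tmp1)
  write_map(qr_map(vals, voxel_size = c(1, 1, 1), axis_order = c(3L, 1L, 2L)), tmp2)
  m1 <- read_map(tmp1); m2 <- read_map(tmp2)
  withr::with_seed(11, {
    pts <- matrix(runif(300, 1, 6), ncol = 3)
  })
  expect_equal(interpolate_map(m1, pts), interpolate_map(m2, pts),
               tolerance = 1e-6)
})

test_that("an all-zero map reads back as all zeros", {
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(qr_map(array(0, c(8, 8, 8))), path)
  expect_true(all(read_map(path)$values == 0))
})

test_that("read_map rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(1, 4000)), path)
  expect_error(read_map(path), class = "qrsite_format_error")
  expect_error(read_map(tempfile()), class = "qrsite_io_error")
})

test_that("world/grid transforms are mutual inverses", {
  m <- qr_map(array(0, c(5, 6, 7)), origin = c(-1, 2, 0.5),
              voxel_size = c(0.4, 0.5, 0.6))
  withr::with_seed(7, pts <- matrix(rnorm(90), ncol = 3))
  expect_lt(max(abs(grid_to_world(m, world_to_grid(m, pts)) - pts)), 1e-9)
  nodes <- as.matrix(expand.grid(1:5, 1:6, 1:7))
  expect_lt(max(abs(world_to_grid(m, grid_to_world(m, nodes)) - nodes)), 1e-9)
})

test_that("trilinear interpolation is exact at nodes and on linear ramps", {
  d <- c(8, 8, 8)
  ramp <- array(rep(seq_len(d[1]) - 1, times = prod(d[2:3])), d)
  m <- qr_map(ramp, origin = c(0, 0, 0), voxel_size = c(1, 1, 1))
  nodes <- withr::with_seed(2, as.matrix(expand.grid(0:7, 0:7, 0:7))[sample(512, 50), ])
  expect_equal(interpolate_map(m, nodes), nodes[, 1], tolerance = 1e-12)
  withr::with_seed(3, pts <- matrix(runif(300, 0, 7), ncol = 3))
  expect_equal(interpolate_map(m, pts), pts[, 1], tolerance = 1e-10)
  # uniform map: constant everywhere
  mu <- qr_map(array(4.2, d), voxel_size = c(1, 1, 1))
  expect_equal(interpolate_map(mu, pts), rep(4.2, nrow(pts)))
  # out of support: flagged zero, not an error
  out <- interpolate_map(m, matrix(c(100, 0, 0), 1), gradient = TRUE)
  expect_equal(out$value, 0)
  expect_true(out$outside)
})

test_that("cubic interpolation matches nodes and has a continuous gradient", {
  withr::with_seed(5, vals <- array(rnorm(10^3), c(10, 10, 10)))
  m <- qr_map(vals, voxel_size = c(1, 1, 1))
  nodes <- withr::with_seed(4, as.matrix(expand.grid(3:7, 3:7, 3:7))[sample(125, 30), ])
  expect_equal(interpolate_map(m, nodes - 1, method = "cubic"),
               vals[nodes], tolerance = 1e-10)
  # continuity across a voxel face
  p <- c(5, 5.3, 5.7)
  left <- interpolate_map(m, rbind(p - c(1e-8, 0, 0)), gradient = TRUE,
                          method = "cubic")
  right <- interpolate_map(m, rbind(p + c(1e-8, 0, 0)), gradient = TRUE,
                           method = "cubic")
  expect_lt(max(abs(left$gradient - right$gradient)), 1e-5)
})

test_that("interpolation is numerically continuous in the step size", {
  withr::with_seed(9, vals <- array(rnorm(8^3), c(8, 8, 8)))
  m <- qr_map(vals, voxel_size = c(1, 1, 1))
  p <- matrix(c(3.2, 4.7, 2.9), 1)
  v0 <- interpolate_map(m, p)
  for (delta in 10^(-(3:7))) {
    v <- interpolate_map(m, p + delta)
    expect_lt(abs(v - v0), 10 * delta * max(abs(vals)))
  }
})
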