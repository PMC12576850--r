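grid64 <- function(n = 24, voxel = 0.5) {
  qr_map(array(0, c(n, n, n)), origin = rep(-(n - 1) * voxel / 2, 3),
         voxel_size = rep(voxel, 3))
}

one_atom <- function(element = "C", b = 20, occ = 1, pos = c(0, 0, 0)) {
  tibble::tibble(atom_name = element, element = element, residue_name = "X",
                 residue_number = 1L, chain_id = "A",
                 x = pos[1], y = pos[2], z = pos[3], occupancy = occ, b_iso = b)
}

test_that("rendering zero atoms gives an all-zero map", {
  g <- grid64(12)
  m <- render_model_map(one_atom()[0, ], g)
  expect_true(all(m$values == 0))
})

test_that("the rendered Gaussian mass matches the analytic integral within 1%", {
  g <- grid64(40, 0.4)
  for (el in c("C", "CU")) {
    m <- render_model_map(one_atom(el, b = 25), g, cutoff = 7)
    total <- sum(m$values) * prod(g$voxel_size)
    analytic <- scattering_table(el)$amplitude
    expect_equal(total, analytic, tolerance = 0.01)
  }
})

test_that("increasing B strictly decreases the peak density", {
  g <- grid64(24)
  peaks <- sapply(c(10, 20, 40, 80), function(b) {
    max(render_model_map(one_atom(b = b), g)$values)
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("occupancy scales the rendered density linearly", {
  g <- grid64(16)
  full <- render_model_map(one_atom(occ = 1), g)
  half <- render_model_map(one_atom(occ = 0.5), g)
  expect_equal(half$values, full$values / 2, tolerance = 1e-12)
})

test_that("rendering an unknown element raises a scattering error", {
  g <- grid64(8)
  expect_error(render_model_map(one_atom("XX"), g),
               class = "qrsite_scattering_error")
})

test_that("masked RSCC equals a brute-force masked Pearson on a 16^3 toy", {
  g <- qr_map(array(0, c(16, 16, 16)), origin = c(-4, -4, -4),
              voxel_size = c(0.5, 0.5, 0.5))
  atoms <- dplyr::bind_rows(
    one_atom("C", pos = c(-1, 0, 0)),
    one_atom("N", pos = c(1.2, 0.4, 0)))
  atoms$residue_number <- c(1L, 2L)
  model <- render_model_map(atoms, g)
  withr::with_seed(31, {
    expm <- model
    expm$values <- expm$values + array(rnorm(length(expm$values), sd = 0.02),
                                       dim(expm$values))
  })
  sc <- rscc(model, expm, atoms, radius = 2.0)
  # brute force: enumerate voxels within radius of each residue's atoms
  d <- dim(g$values)
  world <- as.matrix(expand.grid(
    g$origin[1] + (seq_len(d[1]) - 1) * 0.5,
    g$origin[2] + (seq_len(d[2]) - 1) * 0.5,
    g$origin[3] + (seq_len(d[3]) - 1) * 0.5))
  # expand.grid varies the first column fastest, matching array linear order
  for (r in seq_len(nrow(sc))) {
    res_atoms <- atoms[atoms$residue_number == sc$residue_number[r], ]
    inmask <- rep(FALSE, nrow(world))
    for (i in seq_len(nrow(res_atoms))) {
      p <- c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
      inmask <- inmask | (rowSums(sweep(world, 2, p, "-")^2) <= 4)
    }
    expect_equal(sc$n_voxels[r], sum(inmask))
    expect_equal(sc$rscc[r],
                 cor(model$values[inmask], expm$values[inmask]),
                 tolerance = 1e-12)
  }
})

test_that("self-correlation is 1, anti-correlation -1, and empty masks flag NA", {
  g <- grid64(16)
  atoms <- one_atom("C")
  model <- render_model_map(atoms, g)
  self <- rscc(model, model, atoms, radius = 2)
  expect_equal(self$rscc, 1, tolerance = 1e-12)
  neg <- model
  neg$values <- -neg$values
  anti <- rscc(model, neg, atoms, radius = 2)
  expect_equal(anti$rscc, -1, tolerance = 1e-12)
  # atom far outside the grid: empty mask -> NA, excluded from the average
  far <- one_atom("C", pos = c(100, 100, 100))
  far$residue_number <- 2L
  both <- dplyr::bind_rows(atoms, far)
  suppressWarnings(sc <- rscc(model, model, both, radius = 2))
  expect_true(is.na(sc$rscc[sc$residue_number == 2]))
  expect_equal(average_rscc(sc), 1, tolerance = 1e-12)
})

test_that("RSCC is invariant to affine rescaling of either map", {
  g <- grid64(16)
  atoms <- one_atom("C")
  model <- render_model_map(atoms, g)
  withr::with_seed(41, {
    expm <- model
    expm$values <- expm$values + array(rnorm(length(expm$values), sd = 0.05),
                                       dim(expm$values))
  })
  base <- average_rscc(rscc(model, expm, atoms))
  scaled <- expm
  scaled$values <- 3.7 * scaled$values + 11
  expect_equal(average_rscc(rscc(model, scaled, atoms)), base, tolerance = 1e-12)
  mscaled <- model
  mscaled$values <- 0.2 * mscaled$values - 5
  expect_equal(average_rscc(rscc(mscaled, expm, atoms)), base, tolerance = 1e-12)
})

test_that("RSCC against increasingly noisy copies decreases in expectation", {
  g <- grid64(20)
  atoms <- one_atom("C")
  model <- render_model_map(atoms, g)
  sds <- c(0.01, 0.05, 0.2, 0.8)
  means <- sapply(sds, function(sg) {
    mean(sapply(1:5, function(seed) {
      withr::with_seed(100 * seed, {
        noisy <- model
        noisy$values <- noisy$values + array(rnorm(length(noisy$values), sd = sg),
                                             dim(noisy$values))
      })
      average_rscc(rscc(model, noisy, atoms))
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("map-fit target: empty selection, stationary peak, FD gradient", {
  g <- grid64(24)
  atoms <- one_atom("C", b = 30)
  expm <- render_model_map(atoms, g)
  empty <- map_fit_target(expm, atoms[0, ])
  expect_equal(empty$value, 0)
  expect_equal(nrow(empty$gradient), 0)
  # single atom exactly at the smooth map's maximum: gradient ~ 0
  at_peak <- map_fit_target(expm, atoms)
  expect_lt(sqrt(sum(at_peak$gradient^2)), 1e-6)
  # analytic vs central differences at 50 random placements
  withr::with_seed(51, offs <- matrix(runif(150, -2, 2), ncol = 3))
  worst <- 0
  for (r in seq_len(nrow(offs))) {
    a <- one_atom("C", pos = offs[r, ])
    ev <- map_fit_target(expm, a)
    fn <- function(co) {
      a2 <- a; a2$x <- co[1, 1]; a2$y <- co[1, 2]; a2$z <- co[1, 3]
      map_fit_target(expm, a2)
    }
    gfd <- fd_gradient(fn, matrix(offs[r, ], 1))
    worst <- max(worst, max(abs(gfd - ev$gradient)) / max(abs(gfd), 1e-8))
  }
  expect_lt(worst, 1e-4)
})

test_that("the map term improves when an atom moves up the density gradient", {
  g <- grid64(24)
  expm <- render_model_map(one_atom("C", b = 30), g)
  a <- one_atom("C", pos = c(1.1, 0, 0))   # off-peak
  t0 <- map_fit_target(expm, a)$value
  gr <- map_fit_target(expm, a)$gradient
  step <- -0.05 * gr / sqrt(sum(gr^2))     # descend the target
  a2 <- a; a2$x <- a$x + step[1]; a2$y <- a$y + step[2]; a2$z <- a$z + step[3]
  expect_lt(map_fit_target(expm, a2)$value, t0)
})
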