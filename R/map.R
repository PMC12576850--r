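#' Construct a 3-D scalar map
#'
#' A `qr_map` holds a 3-D scalar field (typically a cryo-EM ESP map, or a map
#' rendered from a model) on an orthogonal grid. Internally the value array is
#' always stored in x,y,z axis order; `axis_order` records the storage order of
#' the file it came from (or should be written with).
#'
#' @param values 3-D numeric array, indexed along world x, y, z.
#' @param origin Position (Angstrom) of the centre of voxel `[1,1,1]`.
#' @param voxel_size Voxel edge lengths (Angstrom), length 3, all > 0.
#' @param axis_order Permutation of 1:3 giving the file storage order
#'   (column-fastest axis first). Purely metadata for I/O.
#' @return A `qr_map` object.
#' @export
qr_map <- function(values, origin = c(0, 0, 0), voxel_size = c(1, 1, 1),
                   axis_order = c(1L, 2L, 3L)) {
  if (length(dim(values)) != 3) abort("values must be a 3-D array", class = "qrsite_map_error")
  if (!all(is.finite(values))) abort("map values must be finite", class = "qrsite_map_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) abort("voxel_size components must be > 0", class = "qrsite_map_error")
  if (!identical(sort(as.integer(axis_order)), 1:3)) {
    abort("axis_order must be a permutation of 1:3", class = "qrsite_map_error")
  }
  structure(list(values = values,
                 origin = as.numeric(origin),
                 voxel_size = voxel_size,
                 axis_order = as.integer(axis_order)),
            class = "qr_map")
}

#' @export
print.qr_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<qr_map> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' World to fractional grid coordinates (1-based) and back
#'
#' @param m A `qr_map`.
#' @param points n x 3 matrix of world coordinates (Angstrom) or fractional
#'   grid indices.
#' @return n x 3 matrix.
#' @export
world_to_grid <- function(m, points) {
  points <- rbind3(points)
  sweep(sweep(points, 2, m$origin, "-"), 2, m$voxel_size, "/") + 1
}

#' @rdname world_to_grid
#' @export
grid_to_world <- function(m, points) {
  points <- rbind3(points)
  sweep(sweep(points - 1, 2, m$voxel_size, "*"), 2, m$origin, "+")
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points
}

#' Trilinear interpolation of a map
#'
#' Evaluates the trilinear interpolant of the map at arbitrary world points.
#' Points outside the grid support return 0 and are flagged (refinement must
#' not be driven by extrapolated density). With `gradient = TRUE` the exact
#' spatial gradient of the interpolant is returned as well.
#'
#' @param m A `qr_map`.
#' @param points n x 3 matrix of world coordinates (Angstrom).
#' @param gradient Also return the analytic gradient?
#' @param method `"trilinear"` (exact at nodes, C0) or `"cubic"`
#'   (Catmull-Rom cubic convolution, exact at nodes, C1 — used by the
#'   refinement target, whose optimiser needs a continuous gradient).
#' @return Numeric vector of interpolated values, or (with `gradient = TRUE`)
#'   a list with `value`, `gradient` (n x 3, units map-value per Angstrom) and
#'   `outside` (logical flags).
#' @export
interpolate_map <- function(m, points, gradient = FALSE,
                            method = c("trilinear", "cubic")) {
  method <- match.arg(method)
  if (method == "cubic") return(interpolate_map_cubic(m, points, gradient))
  g <- world_to_grid(m, points)
  d <- dim(m$values)
  n <- nrow(g)
  i0 <- floor(g)
  # points exactly on the upper boundary node belong to the last cell
  for (k in 1:3) i0[, k] <- pmin(i0[, k], d[k] - 1)
  tfr <- g - i0
  inside <- g[, 1] >= 1 & g[, 1] <= d[1] &
    g[, 2] >= 1 & g[, 2] <= d[2] &
    g[, 3] >= 1 & g[, 3] <= d[3]
  val <- numeric(n)
  grad <- matrix(0, n, 3)
  if (any(inside)) {
    ii <- which(inside)
    x0 <- i0[ii, 1]; y0 <- i0[ii, 2]; z0 <- i0[ii, 3]
    tx <- tfr[ii, 1]; ty <- tfr[ii, 2]; tz <- tfr[ii, 3]
    idx <- function(dx, dy, dz) {
      (x0 + dx) + d[1] * ((y0 + dy) - 1) + d[1] * d[2] * ((z0 + dz) - 1)
    }
    v <- m$values
    c000 <- v[idx(0, 0, 0)]; c100 <- v[idx(1, 0, 0)]
    c010 <- v[idx(0, 1, 0)]; c110 <- v[idx(1, 1, 0)]
    c001 <- v[idx(0, 0, 1)]; c101 <- v[idx(1, 0, 1)]
    c011 <- v[idx(0, 1, 1)]; c111 <- v[idx(1, 1, 1)]
    c00 <- c000 * (1 - tx) + c100 * tx
    c10 <- c010 * (1 - tx) + c110 * tx
    c01 <- c001 * (1 - tx) + c101 * tx
    c11 <- c011 * (1 - tx) + c111 * tx
    c0 <- c00 * (1 - ty) + c10 * ty
    c1 <- c01 * (1 - ty) + c11 * ty
    val[ii] <- c0 * (1 - tz) + c1 * tz
    if (gradient) {
      dx00 <- c100 - c000; dx10 <- c110 - c010
      dx01 <- c101 - c001; dx11 <- c111 - c011
      dfdx <- ((dx00 * (1 - ty) + dx10 * ty) * (1 - tz) +
                 (dx01 * (1 - ty) + dx11 * ty) * tz) / m$voxel_size[1]
      dfdy <- ((c10 - c00) * (1 - tz) + (c11 - c01) * tz) / m$voxel_size[2]
      dfdz <- (c1 - c0) / m$voxel_size[3]
      grad[ii, ] <- cbind(dfdx, dfdy, dfdz)
    }
  }
  if (!gradient) return(val)
  list(value = val, gradient = grad, outside = !inside)
}

# Separable Catmull-Rom cubic-convolution interpolation: interpolates node
# values exactly and is C1, so refinement targets built on it have continuous
# gradients (a piecewise-trilinear target has gradient kinks at voxel faces
# that stall quasi-Newton descent). Border cells replicate edge values.
interpolate_map_cubic <- function(m, points, gradient = FALSE) {
  g <- world_to_grid(m, points)
  d <- dim(m$values)
  n <- nrow(g)
  i0 <- floor(g)
  for (k in 1:3) i0[, k] <- pmin(i0[, k], d[k] - 1)
  tfr <- g - i0
  inside <- g[, 1] >= 1 & g[, 1] <= d[1] &
    g[, 2] >= 1 & g[, 2] <= d[2] &
    g[, 3] >= 1 & g[, 3] <= d[3]
  val <- numeric(n)
  grad <- matrix(0, n, 3)
  ii <- which(inside)
  if (length(ii) > 0) {
    cw <- function(t) {
      t2 <- t * t; t3 <- t2 * t
      cbind(0.5 * (-t3 + 2 * t2 - t),
            0.5 * (3 * t3 - 5 * t2 + 2),
            0.5 * (-3 * t3 + 4 * t2 + t),
            0.5 * (t3 - t2))
    }
    cdw <- function(t) {
      t2 <- t * t
      cbind(0.5 * (-3 * t2 + 4 * t - 1),
            0.5 * (9 * t2 - 10 * t),
            0.5 * (-9 * t2 + 8 * t + 1),
            0.5 * (3 * t2 - 2 * t))
    }
    wx <- cw(tfr[ii, 1]); wy <- cw(tfr[ii, 2]); wz <- cw(tfr[ii, 3])
    dwx <- cdw(tfr[ii, 1]); dwy <- cdw(tfr[ii, 2]); dwz <- cdw(tfr[ii, 3])
    clampi <- function(v, dmax) pmin(pmax(v, 1), dmax)
    v <- m$values
    acc <- numeric(length(ii))
    gx <- gy <- gz <- numeric(length(ii))
    for (a in 0:3) {
      ix <- clampi(i0[ii, 1] + a - 1, d[1])
      for (b in 0:3) {
        iy <- clampi(i0[ii, 2] + b - 1, d[2])
        wxy <- wx[, a + 1] * wy[, b + 1]
        dxy <- dwx[, a + 1] * wy[, b + 1]
        xdy <- wx[, a + 1] * dwy[, b + 1]
        for (cc in 0:3) {
          iz <- clampi(i0[ii, 3] + cc - 1, d[3])
          f <- v[ix + d[1] * (iy - 1) + d[1] * d[2] * (iz - 1)]
          acc <- acc + f * wxy * wz[, cc + 1]
          if (gradient) {
            gx <- gx + f * dxy * wz[, cc + 1]
            gy <- gy + f * xdy * wz[, cc + 1]
            gz <- gz + f * wxy * dwz[, cc + 1]
          }
        }
      }
    }
    val[ii] <- acc
    if (gradient) {
      grad[ii, ] <- cbind(gx / m$voxel_size[1], gy / m$voxel_size[2],
                          gz / m$voxel_size[3])
    }
  }
  if (!gradient) return(val)
  list(value = val, gradient = grad, outside = !inside)
}

# ---- MRC2014 / CCP4 I/O -----------------------------------------------------
# No installed R package reads MRC volumes, so the (simple, fixed-layout)
# MRC2014 header and mode-2 float data are read/written directly.

#' Read an MRC2014/CCP4 map file
#'
#' Honours the header origin, cell, start offsets and axis order; the value
#' array is re-ordered into x,y,z storage. Only orthogonal cells and data
#' modes 0 (int8), 1 (int16), 2 (float32) are supported.
#'
#' @param path Path to a `.mrc`/`.map` file.
#' @return A [qr_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(paste0("map file not found: ", path), class = "qrsite_io_error")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little") # dmin dmax dmean
  readBin(con, "integer", 1, size = 4, endian = "little") # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 24, size = 4, endian = "little") # extra words 26-49
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  maptag <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little") # machst
  readBin(con, "numeric", 1, size = 4, endian = "little") # rms
  readBin(con, "integer", 1, size = 4, endian = "little") # nlabl
  readBin(con, "raw", 800)                                 # labels
  if (!(mode %in% c(0L, 1L, 2L))) {
    abort(sprintf("unsupported MRC data mode %d in %s", mode, path),
          class = "qrsite_format_error")
  }
  if (any(nxyz <= 0) || any(mxyz <= 0)) {
    abort(paste0("bad MRC header dimensions in ", path), class = "qrsite_format_error")
  }
  if (!identical(sort(mapcrs), 1:3)) {
    abort(paste0("bad MRC axis order in ", path), class = "qrsite_format_error")
  }
  if (any(abs(cellb - 90) > 1e-3)) {
    abort("only orthogonal map cells are supported", class = "qrsite_format_error")
  }
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"))
  if (length(vals) != nvox) {
    abort(paste0("truncated MRC data block in ", path), class = "qrsite_format_error")
  }
  a <- array(vals, dim = nxyz)                # [cols, rows, sections]
  perm <- match(1:3, mapcrs)                  # where world axis j lives in file order
  b <- aperm(a, perm)                         # -> [x, y, z]
  voxel <- cella / mxyz                       # cell is along world x,y,z
  nstart_world <- nstart[perm]
  orig_world <- origin + nstart_world * voxel
  qr_map(b, origin = orig_world, voxel_size = voxel, axis_order = mapcrs)
}

#' Write a map as MRC2014 (mode 2, float32)
#'
#' The value array is written in the map's `axis_order`; re-reading reproduces
#' the values bit-identically (float32 storage). Header cell/axis metadata of
#' an input map are preserved through the `qr_map` fields.
#'
#' @param m A [qr_map].
#' @param path Output path.
#' @export
write_map <- function(m, path) {
  d <- dim(m$values)
  ord <- m$axis_order
  a <- aperm(m$values, ord)                   # file storage order
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(paste0("cannot write map: ", path),
                                            class = "qrsite_io_error"))
  on.exit(close(con), add = TRUE)
  nxyz <- dim(a)
  mxyz <- d
  cella <- d * m$voxel_size
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz); wi(2L); wi(c(0L, 0L, 0L)); wi(mxyz)
  wf(cella); wf(c(90, 90, 90)); wi(ord)
  wf(c(min(m$values), max(m$values), mean(m$values)))
  wi(1L); wi(0L); wi(rep(0L, 24))
  wf(m$origin)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sd(as.numeric(m$values))); wi(0L)
  writeBin(raw(800), con)
  wf(as.numeric(a))
  invisible(path)
}
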