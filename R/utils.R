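#' @importFrom rlang abort warn .data
#' @importFrom stats optim rnorm sd cor setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector", class = "qrsite_geometry_error")
  v / n
}

# Rotation matrix aligning orthonormal frame (u1,u2) to (v1,v2).
# u2/v2 are orthogonalised against u1/v1 internally.
frame_rotation <- function(u1, u2, v1, v2) {
  orth <- function(a, b) unitv(b - sum(a * b) * a)
  u1 <- unitv(u1); v1 <- unitv(v1)
  u2 <- orth(u1, u2); v2 <- orth(v1, v2)
  u3 <- pracma_cross(u1, u2); v3 <- pracma_cross(v1, v2)
  U <- cbind(u1, u2, u3)
  V <- cbind(v1, v2, v3)
  V %*% t(U)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Any unit vector perpendicular to v.
perp_vector <- function(v) {
  v <- unitv(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(pracma_cross(v, ref))
}

coords_matrix <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  dimnames(m) <- NULL
  m
}

set_coords <- function(atoms, m) {
  atoms$x <- m[, 1]
  atoms$y <- m[, 2]
  atoms$z <- m[, 3]
  atoms
}

rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

KCAL_TO_KJ <- 4.184

covalent_radius <- function(element) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
         CU = 1.32, ZN = 1.22, FE = 1.32)
  out <- unname(r[toupper(element)])
  if (anyNA(out)) {
    bad <- unique(element[is.na(out)])
    abort(paste0("no covalent radius for element(s): ", paste(bad, collapse = ", ")),
          class = "qrsite_element_error")
  }
  out
}

vdw_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         CU = 1.40, ZN = 1.39, FE = 1.40)
  out <- unname(r[toupper(element)])
  if (anyNA(out)) {
    bad <- unique(element[is.na(out)])
    abort(paste0("no van der Waals radius for element(s): ", paste(bad, collapse = ", ")),
          class = "qrsite_element_error")
  }
  out
}

is_metal_element <- function(element) toupper(element) %in% c("CU", "ZN", "FE", "NI", "MN", "CO")

atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, sep = "|")
}

residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, sep = "|")
}
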