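#' Neutral-atom electron scattering table
#'
#' Five-Gaussian parameterisations of the electron scattering factor
#' \eqn{f(s) = \sum_i a_i \exp(-b_i s^2)} (with \eqn{s = \sin\theta/\lambda} in
#' 1/Angstrom) for neutral atoms, in the standard published parameterisation
#' used for cryo-EM model maps. Charged species are not supported: map scores
#' always use the neutral-atom factors.
#'
#' @param elements Optional character vector of element symbols to look up.
#' @return A tibble with columns `element`, `a1..a5`, `b1..b5` and the total
#'   forward amplitude `amplitude` (= sum of the `a_i`).
#' @export
#' @examples
#' scattering_table(c("C", "Cu"))
scattering_table <- function(elements = NULL) {
  tab <- tibble::tribble(
    ~element, ~a1, ~a2, ~a3, ~a4, ~a5, ~b1, ~b2, ~b3, ~b4, ~b5,
    "H",  0.0349, 0.1201, 0.1970, 0.0573, 0.1195, 0.5347,  3.5867, 12.3471, 18.9525, 38.6269,
    "C",  0.0893, 0.2563, 0.7570, 1.0487, 0.3575, 0.2465,  1.7100,  6.4094, 18.6113, 50.2523,
    "N",  0.1022, 0.3219, 0.7982, 0.8197, 0.1715, 0.2451,  1.7481,  6.1925, 17.3894, 48.1431,
    "O",  0.0974, 0.2921, 0.6910, 0.6990, 0.2039, 0.2067,  1.3815,  4.6943, 12.7105, 32.4726,
    "S",  0.2497, 0.5628, 1.3899, 2.1865, 0.7715, 0.2681,  1.6711,  7.0267, 19.5377, 50.3888,
    "CU", 0.4314, 1.3208, 1.5236, 1.4671, 0.8562, 0.2694,  1.9223,  7.3474, 28.9892, 90.6246
  )
  tab$amplitude <- tab$a1 + tab$a2 + tab$a3 + tab$a4 + tab$a5
  if (!is.null(elements)) {
    key <- toupper(elements)
    miss <- setdiff(unique(key), tab$element)
    if (length(miss) > 0) {
      abort(paste0("no electron scattering parameters for element(s): ",
                   paste(miss, collapse = ", ")),
            class = "qrsite_scattering_error")
    }
    tab <- tab[match(key, tab$element), , drop = FALSE]
  }
  tab
}

# a and b coefficient matrices (rows follow `elements`)
scattering_coeffs <- function(elements) {
  tab <- scattering_table(elements)
  list(a = as.matrix(tab[, paste0("a", 1:5)]),
       b = as.matrix(tab[, paste0("b", 1:5)]),
       amplitude = tab$amplitude)
}
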