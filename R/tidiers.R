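#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a refinement: the per-macrocycle component log
#'
#' One row per macrocycle with the target components (`w_map`, `w_engine`,
#' `t_restr`, `t_selfref`, `total`), iteration counts and convergence flags.
#'
#' @param x A `qr_refinement`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qr_refinement <- function(x, ...) x$log

#' One-row refinement summary
#'
#' @param x A `qr_refinement`.
#' @param ... Unused.
#' @return A tibble with the final total, average RSCC, protocol counters and
#'   convergence.
#' @export
glance.qr_refinement <- function(x, ...) {
  coord <- x$log[x$log$stage == "coordinates", , drop = FALSE]
  tibble::tibble(
    total = tail(coord$total, 1),
    avg_rscc = average_rscc(x$map_score),
    w_x = x$config$w_x, w_qm = x$config$w_qm,
    coordinate_macrocycles = nrow(coord),
    adp_macrocycles = sum(x$log$stage == "adp"),
    converged = all(coord$converged),
    n_moving = length(x$moving))
}

#' Tidy a site report: the ranked scores table
#' @param x A `qr_site_report`.
#' @param ... Unused.
#' @return A tibble (one row per interpretation variant).
#' @export
tidy.qr_site_report <- function(x, ...) tibble::as_tibble(x$scores)

#' One-row site-report summary
#' @param x A `qr_site_report`.
#' @param ... Unused.
#' @return A tibble with the winning variant and score spreads.
#' @export
glance.qr_site_report <- function(x, ...) {
  tibble::tibble(
    site = x$site_name,
    n_variants = nrow(x$scores),
    ranked_first = ranked_first(x),
    best_rscc = max(x$scores$avg_rscc),
    min_strain = min(x$scores$delta_e_str),
    strain_spread = diff(range(x$scores$delta_e_str)))
}

#' Tidy a weight scan
#' @param x A `qr_weight_scan`.
#' @param ... Unused.
#' @return The scan table with a `selected` flag column.
#' @export
tidy.qr_weight_scan <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tb$selected <- tb$w_x == selected_weight(x)
  tb
}
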