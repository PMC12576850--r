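#' Run a full site evaluation from a configuration
#'
#' Orchestrates the end-to-end pipeline: read model and map, optionally scan
#' the map weight on the first variant, refine every interpretation variant
#' with the shared configuration, score strain / RSCC / geometry, rank, and
#' write artifacts (refined models, score tables, scan table, manifest with a
#' config hash). All randomness flows from the single config seed.
#'
#' @param config A configuration list, or the path to a YAML file with the
#'   same shape. Fields: `model` (PDB/mmCIF path), `map` (MRC path), `site`
#'   (list: `name`, `members` = list of `{chain, residue_number, backbone?}`,
#'   `metals` = list of `{chain, residue_number, atom_name}`, `variants` =
#'   named list of per-metal interpretation vectors), optional `w_x`,
#'   `seed`, `scan` (logical or a numeric grid), `outdir`, plus any
#'   [refinement_config()] overrides under `refinement`.
#' @return A `qr_site_report` (invisibly when writing artifacts).
#' @export
run_site_evaluation <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config), class = "qrsite_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  for (field in c("model", "map", "site")) {
    if (is.null(config[[field]])) {
      abort(paste0("config is missing required field: ", field),
            class = "qrsite_config_error")
    }
  }
  for (p in c(config$model, config$map)) {
    if (!file.exists(p)) {
      abort(paste0("input file not found: ", p), class = "qrsite_io_error")
    }
  }
  s <- read_structure(config$model)
  exp_map <- read_map(config$map)
  site <- config$site
  members <- dplyr::bind_rows(lapply(site$members, tibble::as_tibble))
  if (!("backbone" %in% names(members))) members$backbone <- FALSE
  metals <- dplyr::bind_rows(lapply(site$metals, tibble::as_tibble))
  variants <- lapply(names(site$variants), function(lab) {
    interp <- unlist(site$variants[[lab]])
    keep <- !(interp == "absent")
    mem <- members
    if (any(!keep)) {
      drop_res <- metals$residue_number[!keep]
      mem <- mem[!(mem$residue_number %in% drop_res), , drop = FALSE]
    }
    site_spec(site$name %||% "site", mem, metals, interp, label = lab)
  })
  names(variants) <- names(site$variants)
  seed <- as.integer(config$seed %||% 1L)
  ref_over <- config$refinement %||% list()
  cfg <- do.call(refinement_config,
                 c(list(w_x = config$w_x %||% 10, random_seed = seed), ref_over))
  scan_result <- NULL
  if (isTRUE(config$scan) || is.numeric(config$scan)) {
    spec1 <- variants[[1]]
    sv <- apply_interpretation(s, spec1)
    region <- protonate_region(carve_region(sv, spec1), sv)
    grid <- if (is.numeric(config$scan)) sort(config$scan) else
      c(0, 1, 3, 5, 10, 20, 30, 50, 75, 100)
    scan_result <- weight_scan(sv, region, exp_map, cfg = cfg, grid = grid)
    cfg$w_x <- selected_weight(scan_result)
  }
  report <- compare_interpretations(s, variants, exp_map, cfg = cfg)
  report$scan <- scan_result
  report$seed <- seed
  report$config_hash <- rlang::hash(config)
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(report$scores),
                       file.path(outdir, "site_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(scan_result)) {
      utils::write.table(as.data.frame(scan_result),
                         file.path(outdir, "weight_scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (lab in names(report$refinements)) {
      safe <- gsub("[^A-Za-z0-9_()-]", "_", lab)
      write_structure(report$refinements[[lab]]$structure,
                      file.path(outdir, paste0("refined_", safe, ".pdb")))
    }
    manifest <- list(config_hash = report$config_hash, seed = seed,
                     w_x = cfg$w_x, w_qm = cfg$w_qm,
                     engine = report$refinements[[1]]$engine_method,
                     selected_w_x = if (!is.null(scan_result))
                       selected_weight(scan_result) else NULL,
                     ranked_first = ranked_first(report),
                     package_version = as.character(utils::packageVersion("qrsite")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(report))
  }
  report
}
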