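#' Run the full tiling-screen analysis pipeline
#'
#' Drives the whole analysis from a YAML configuration: load (or simulate)
#' a screen, score guides, filter flagged guides, fit per-gene profiles,
#' call regions, optionally annotate them, and write all outputs plus a
#' run manifest (parameters, seeds, convexity check, config hash) to the
#' output directory. The convexity gate is checked before any fitting and
#' a violation aborts the run.
#'
#' Config keys (all optional unless noted): `simulate:` (a [sim_config()]
#' parameter block) or `library:`/`counts:`/`samples:` file paths;
#' `solver:` ([solver_config()] parameters); `baseline` (`"library"` or
#' `"ntc"`); `drop` (flags to drop, default tttt+yrich); `tau`;
#' `method`; `annotations:`/`conservation:` paths; `seed`.
#'
#' @param config_file Path to a YAML config, or a config list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly. Writes `scores.tsv`, `fits.tsv`,
#'   `regions.tsv`, `regions.bed`, optionally `regions_annotated.tsv`,
#'   and `manifest.json`.
#' @export
run_pipeline <- function(config_file, out_dir) {
  cfg <- if (is.character(config_file)) {
    yaml::read_yaml(config_file)
  } else {
    config_file
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 0L

  solver_args <- cfg$solver %||% list()
  scfg <- do.call(solver_config, solver_args)
  convex_ok <- check_convexity(scfg)
  abort_if(!convex_ok,
           "convexity condition 1 - a0*lambda0 - 4*a1*lambda1 >= 0 violated")

  if (!is.null(cfg$simulate)) {
    sim <- simulate_screen(do.call(sim_config, cfg$simulate), seed = seed)
    library_tbl <- sim$library
    counts <- sim$counts
  } else {
    abort_if(is.null(cfg$library) || is.null(cfg$counts) || is.null(cfg$samples),
             "config needs either simulate: or library:/counts:/samples:")
    library_tbl <- read_library_table(cfg$library)
    counts <- read_count_matrix(cfg$counts, cfg$samples, library = library_tbl)
  }

  baseline <- cfg$baseline %||% "library"
  scores <- score_guides(counts, library_tbl, baseline = baseline)
  drop <- cfg$drop %||% c("tttt", "yrich")
  mean_z <- guide_mean_z(scores)
  mean_z_f <- filter_guides(mean_z, library_tbl, drop = drop)

  method <- cfg$method %||% "tivex"
  tau <- cfg$tau %||% 1.0
  fits <- fit_profiles(mean_z_f, library_tbl, scfg, method = method)
  ntc_scores <- mean_z$mean_z[mean_z$gene == "NTC"]
  ntc_sd <- if (length(ntc_scores) > 1) sd(ntc_scores) else NULL
  regions <- call_regions(fits, tau = tau, ntc_sd = ntc_sd)

  genes_tbl <- call_gene_essentiality(scores)
  readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
  readr::write_tsv(purrr::map_dfr(fits, tidy),
                   file.path(out_dir, "fits.tsv"), progress = FALSE)
  readr::write_tsv(genes_tbl, file.path(out_dir, "gene_calls.tsv"),
                   progress = FALSE)
  write_regions(regions, file.path(out_dir, "regions.tsv"), format = "tsv")
  write_regions(regions, file.path(out_dir, "regions.bed"), format = "bed")

  if (!is.null(cfg$annotations)) {
    ann <- read_annotations(cfg$annotations)
    regions <- categorize_regions(regions, ann)
    if (!is.null(cfg$conservation)) {
      track <- read_conservation(cfg$conservation)
      regions <- conservation_score(regions, track)
    }
    flat <- regions
    flat$categories <- vapply(flat$categories, paste, character(1),
                              collapse = ",")
    readr::write_tsv(flat, file.path(out_dir, "regions_annotated.tsv"),
                     progress = FALSE)
  }

  cfg_chr <- yaml::as.yaml(cfg)
  manifest <- list(
    package = "tilescan",
    version = as.character(utils::packageVersion("tilescan")),
    seed = seed,
    baseline = baseline,
    method = method,
    tau = tau,
    solver = scfg[c("lambda0", "lambda1", "a0", "a1", "tol", "max_iter")],
    convexity_ok = convex_ok,
    n_guides = nrow(library_tbl),
    n_regions = nrow(regions),
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_chr) *
                                        (seq_along(utf8ToInt(cfg_chr)) %% 97 + 1)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
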