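# Stage runners: simulate -> mpai -> compare -> enrich, with file handoffs,
# a machine-readable run manifest and the seed recorded in every TSV header.
# A thin command-line wrapper over these functions ships in inst/cli/mpai.R.

.default_config <- function() {
  list(seed = 1L, out_dir = "mpai_out",
       pos_threshold = 1.0, neg_threshold = -1.0,
       n_perm = 1000L, min_size = 5L, max_size = 500L, alpha = 0.01,
       dialect = "native", id_map = NULL,
       orientation = list(exp1 = "control-heavy", exp2 = "control-light"),
       sim = list())
}

#' Read a pipeline configuration file
#'
#' Flat YAML key-value file; unknown keys are an error so typos never pass
#' silently. Keys mirror the arguments of the stage runners; the `sim` block
#' holds [sim_config()] fields and `orientation` maps run labels to
#' `control-heavy`/`control-light`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s'", unknown[1]), call. = FALSE)
  utils::modifyList(cfg, user)
}

.write_manifest <- function(out_dir, stage, cfg, files, extra = list()) {
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("mpaiR")),
                     files = as.list(stats::setNames(
                       unname(tools::md5sum(files)), basename(files)))),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.quant_path <- function(out_dir, fraction, run) {
  file.path(out_dir, sprintf("quant_%s_%s.tsv", fraction, run))
}

#' Stage 1: simulate a study and write its files
#'
#' Writes the four quantification tables (native dialect), the truth table,
#' the gene-set collection (GMT) and a manifest into `out_dir`.
#'
#' @param config pipeline configuration list ([read_pipeline_config()]); the
#'   `sim` block parameterizes [sim_config()], with the pipeline `seed` as the
#'   default simulation seed.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config = read_pipeline_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$sim
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  sc <- do.call(sim_config, sim_args)
  study <- generate_study(sc)
  sets <- generate_gene_sets(sc, study$truth)
  files <- character(0)
  for (fr in FRACTIONS) for (run in RUN_LABELS) {
    f <- .quant_path(out_dir, fr, run)
    write_results(study$tables[[fr]][[run]], f,
                  comments = c(sprintf("seed=%d", sc$seed),
                               sprintf("orientation=%s", attr(study$tables[[fr]][[run]], "orientation"))))
    files <- c(files, f)
  }
  truth_f <- file.path(out_dir, "truth.tsv")
  write_results(study$truth, truth_f, comments = sprintf("seed=%d", sc$seed))
  gmt_f <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(sets, gmt_f)
  .write_manifest(out_dir, "simulate", config, c(files, truth_f, gmt_f),
                  extra = list(n_proteins = sc$n_proteins))
  invisible(out_dir)
}

.read_study_tables <- function(config) {
  out <- list()
  for (fr in FRACTIONS) {
    out[[fr]] <- list()
    for (run in RUN_LABELS) {
      out[[fr]][[run]] <- read_protein_quant(
        .quant_path(config$out_dir, fr, run), dialect = config$dialect,
        orientation = config$orientation[[run]], run_label = run, fraction = fr)
    }
  }
  out
}

#' Stage 2: per-fraction mPAI tables and fit summary
#'
#' Reads the four quantification tables from `out_dir`, computes the
#' per-fraction mPAI profiles and writes `mpai_<fraction>.tsv` plus
#' `fit_summary.tsv` (fraction, mu, sigma, n) and a manifest.
#'
#' @inheritParams run_simulate
#' @return named list of the two profiles, invisibly.
#' @export
run_mpai <- function(config = read_pipeline_config()) {
  tabs <- .read_study_tables(config)
  id_map <- if (!is.null(config$id_map)) read_id_map(config$id_map) else NULL
  profiles <- list(); files <- character(0); fits <- list()
  for (fr in FRACTIONS) {
    prof <- mpai_profile(tabs[[fr]]$exp1, tabs[[fr]]$exp2,
                         pos_threshold = config$pos_threshold,
                         neg_threshold = config$neg_threshold, id_map = id_map)
    f <- file.path(config$out_dir, sprintf("mpai_%s.tsv", fr))
    write_results(prof, f, comments = sprintf("seed=%d", config$seed))
    profiles[[fr]] <- prof
    fits[[fr]] <- attr(prof, "fit")
    files <- c(files, f)
  }
  fit_tab <- data.frame(fraction = FRACTIONS,
                        mu = vapply(fits, `[[`, numeric(1), "mu"),
                        sigma = vapply(fits, `[[`, numeric(1), "sigma"),
                        n = vapply(fits, `[[`, integer(1), "n"))
  fit_f <- file.path(config$out_dir, "fit_summary.tsv")
  write_results(fit_tab, fit_f, comments = sprintf("seed=%d", config$seed))
  .write_manifest(config$out_dir, "mpai", config, c(files, fit_f),
                  extra = list(n_excluded = lapply(profiles, attr, "n_excluded")))
  invisible(profiles)
}

#' Stage 3: quadrant table and browser JSON
#'
#' Joins the two per-fraction mPAI tables written by [run_mpai()], writes the
#' quadrant table, the quadrant count summary and the scatter-browser JSON
#' payload.
#'
#' @inheritParams run_simulate
#' @return the quadrant data.frame, invisibly.
#' @export
run_compare <- function(config = read_pipeline_config()) {
  prof <- lapply(FRACTIONS, function(fr)
    read_results(file.path(config$out_dir, sprintf("mpai_%s.tsv", fr))))
  names(prof) <- FRACTIONS
  quad <- join_fractions(prof$cytosol, prof$chromatin,
                         threshold = config$pos_threshold)
  quad_f <- file.path(config$out_dir, "quadrants.tsv")
  write_results(quad, quad_f, comments = sprintf("seed=%d", config$seed))
  counts <- summarize_quadrants(quad)
  cnt_f <- file.path(config$out_dir, "quadrant_counts.tsv")
  write_results(data.frame(quadrant = names(counts), n = as.integer(counts)),
                cnt_f, comments = sprintf("seed=%d", config$seed))
  gmt_f <- file.path(config$out_dir, "gene_sets.gmt")
  sets <- if (file.exists(gmt_f)) read_gmt(gmt_f) else NULL
  json_f <- file.path(config$out_dir, "mpai_browser.json")
  write_browser_json(quad, sets, json_f)
  .write_manifest(config$out_dir, "compare", config, c(quad_f, cnt_f, json_f),
                  extra = list(n_joined = nrow(quad)))
  invisible(quad)
}

#' Stage 4: per-fraction enrichment tables
#'
#' Runs preranked enrichment of each fraction's mPAI table against the
#' gene-set collection in `out_dir` and writes
#' `enrichment_<fraction>_<direction>.tsv`.
#'
#' @inheritParams run_simulate
#' @return named list of enrichment results per fraction, invisibly.
#' @export
run_enrich <- function(config = read_pipeline_config()) {
  sets <- read_gmt(file.path(config$out_dir, "gene_sets.gmt"))
  out <- list(); files <- character(0)
  for (fr in FRACTIONS) {
    prof <- read_results(file.path(config$out_dir, sprintf("mpai_%s.tsv", fr)))
    res <- run_enrichment(prof, sets, min_size = config$min_size,
                          max_size = config$max_size, n_perm = config$n_perm,
                          seed = config$seed, alpha = config$alpha)
    for (dir in c("positive", "negative")) {
      f <- file.path(config$out_dir, sprintf("enrichment_%s_%s.tsv", fr, dir))
      write_results(res[[dir]], f, comments = sprintf("seed=%d", config$seed))
      files <- c(files, f)
    }
    out[[fr]] <- res
  }
  .write_manifest(config$out_dir, "enrich", config, files)
  invisible(out)
}

#' Run the full pipeline
#'
#' `simulate -> mpai -> compare -> enrich` with file handoffs in
#' `config$out_dir`. Deterministic under a fixed seed: rerunning yields
#' byte-identical numeric outputs.
#'
#' @inheritParams run_simulate
#' @return `config$out_dir`, invisibly.
#' @export
run_all <- function(config = read_pipeline_config()) {
  run_simulate(config)
  run_mpai(config)
  run_compare(config)
  run_enrich(config)
  invisible(config$out_dir)
}
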