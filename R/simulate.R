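#' Default effect classes for simulated studies
#'
#' One row per effect class. Fold changes are multiplicative effects of the
#' perturbed state (control relative to knockdown) on protein abundance in each
#' fraction, so `fold > 1` means the protein tracks the perturbation
#' positively. The four classes populate the four off-center quadrants of the
#' cytosol-by-chromatin scatter, including the relocalization phenotypes
#' (e.g. chromatin-positive / cytosol-negative, the PARP1-like pattern).
#'
#' @param fold positive fold change used for the "up" direction; the "down"
#'   direction uses `1/fold`.
#' @return data.frame with columns `class`, `fold_cytosol`, `fold_chromatin`.
#' @export
default_effect_classes <- function(fold = 4) {
  stopifnot(is.numeric(fold), length(fold) == 1L, fold > 1)
  data.frame(
    class = c("double_positive", "double_negative",
              "chromatin_pos_cytosol_neg", "cytosol_pos_chromatin_neg"),
    fold_cytosol = c(fold, 1 / fold, 1 / fold, fold),
    fold_chromatin = c(fold, 1 / fold, fold, 1 / fold),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a simulated reciprocal-SILAC study
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe a realistic null-dominated study: per-run log2 H/L noise with
#' standard deviation 0.65 (so the null mPAI standard deviation is
#' `sqrt(2) * 0.65 = 0.92`, matching the scale observed in real
#' fractionation data), 20% per-run dropout (giving roughly 3200 of 5000
#' proteins quantified in both runs of a fraction, and roughly 2000 in the
#' cytosol-by-chromatin intersection), and 5% of proteins carrying a true
#' fraction-specific effect.
#'
#' @param n_proteins number of simulated proteins.
#' @param frac_affected proportion of proteins in `[0, 1]` carrying a true
#'   effect; affected proteins are assigned to `effect_classes` round-robin.
#' @param effect_classes data.frame as returned by [default_effect_classes()]:
#'   columns `class`, `fold_cytosol`, `fold_chromatin` with positive folds
#'   whose direction is consistent with the class label.
#' @param noise_sd standard deviation of per-run log2 H/L noise for null
#'   proteins; must be positive.
#' @param dropout_rate probability in `[0, 1)` that a protein is missing from
#'   any one run, independently per protein, run and fraction.
#' @param n_gene_sets number of random (null) gene sets to generate.
#' @param set_size_range length-2 integer vector, min and max random-set size.
#' @param signal_set_size size of the designated signal set drawn from
#'   double-positive proteins (default 6, the size of the MCM2-7 helicase).
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 5000,
                       frac_affected = 0.05,
                       effect_classes = default_effect_classes(),
                       noise_sd = 0.65,
                       dropout_rate = 0.2,
                       n_gene_sets = 50,
                       set_size_range = c(10, 50),
                       signal_set_size = 6,
                       seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1)
    stop_config("n_proteins", "must be a single count >= 1")
  if (!is.numeric(frac_affected) || frac_affected < 0 || frac_affected > 1)
    stop_config("frac_affected", "must be a proportion in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_config("noise_sd", "must be > 0")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate", "must be in [0, 1)")
  if (!is.numeric(n_gene_sets) || n_gene_sets < 0)
    stop_config("n_gene_sets", "must be a count >= 0")
  if (!is.numeric(set_size_range) || length(set_size_range) != 2L ||
      any(set_size_range < 1) || set_size_range[1] > set_size_range[2])
    stop_config("set_size_range", "must be (min, max) with 1 <= min <= max")
  if (!is.numeric(signal_set_size) || signal_set_size < 1)
    stop_config("signal_set_size", "must be a count >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("seed", "must be a single integer")
  if (!is.data.frame(effect_classes) ||
      !all(c("class", "fold_cytosol", "fold_chromatin") %in% names(effect_classes)))
    stop_config("effect_classes",
                "must be a data.frame with columns class, fold_cytosol, fold_chromatin")
  if (any(effect_classes$fold_cytosol <= 0) || any(effect_classes$fold_chromatin <= 0))
    stop_config("effect_classes", "fold changes must be > 0")
  bad <- !effect_classes$class %in% QUADRANTS[1:4]
  if (any(bad))
    stop_config("effect_classes",
                paste("unknown class label:", effect_classes$class[bad][1]))
  # direction of each fold must agree with the class label
  expect_sign <- list(
    double_positive = c(1, 1), double_negative = c(-1, -1),
    chromatin_pos_cytosol_neg = c(-1, 1), cytosol_pos_chromatin_neg = c(1, -1)
  )
  for (i in seq_len(nrow(effect_classes))) {
    s <- expect_sign[[effect_classes$class[i]]]
    got <- sign(log2(c(effect_classes$fold_cytosol[i], effect_classes$fold_chromatin[i])))
    if (!all(got == s))
      stop_config("effect_classes",
                  paste("fold directions inconsistent with class", effect_classes$class[i]))
  }
  structure(
    list(n_proteins = as.integer(n_proteins), frac_affected = frac_affected,
         effect_classes = effect_classes, noise_sd = noise_sd,
         dropout_rate = dropout_rate, n_gene_sets = as.integer(n_gene_sets),
         set_size_range = as.integer(set_size_range),
         signal_set_size = as.integer(signal_set_size), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a reciprocal-SILAC study with known ground truth
#'
#' Generates the four quantification tables of a label-swap design (two runs
#' by two fractions) plus a truth table. For a protein with true fold change
#' `f` in a fraction, the exp1 run (control cells heavy) draws
#' `H/L = f * 2^N(0, noise_sd^2)` and the reciprocal exp2 run (control cells
#' light) draws `H/L = (1/f) * 2^N(0, noise_sd^2)`; null proteins use `f = 1`.
#' Each protein is dropped from each run independently with probability
#' `dropout_rate`. The resulting mPAI of a spiked protein is centered on
#' `2 * log2(f)` with variance `2 * noise_sd^2`.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `tables` (nested list
#'   `tables[[fraction]][[run]]` of quantification data.frames in the native
#'   dialect, each carrying `orientation` as an attribute) and `truth`
#'   (data.frame with `protein_id`, `gene_symbol`, `lfc_cytosol`,
#'   `lfc_chromatin` — true log2 fold changes, exactly 0 for null proteins —
#'   and `effect_class`, `"null"` for unaffected proteins).
#' @seealso [generate_gene_sets()] for the matching gene-set collection.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_proteins
  wid <- max(5L, nchar(as.character(n)))
  protein_id <- sprintf("SIMP%0*d", wid, seq_len(n))
  gene_symbol <- sprintf("GENE%0*d", wid, seq_len(n))

  n_aff <- round(config$frac_affected * n)
  effect_class <- rep("null", n)
  lfc_cyt <- numeric(n)
  lfc_chr <- numeric(n)
  if (n_aff > 0) {
    cls <- config$effect_classes
    idx <- rep(seq_len(nrow(cls)), length.out = n_aff)
    effect_class[seq_len(n_aff)] <- cls$class[idx]
    lfc_cyt[seq_len(n_aff)] <- log2(cls$fold_cytosol[idx])
    lfc_chr[seq_len(n_aff)] <- log2(cls$fold_chromatin[idx])
  }
  truth <- data.frame(protein_id = protein_id, gene_symbol = gene_symbol,
                      lfc_cytosol = lfc_cyt, lfc_chromatin = lfc_chr,
                      effect_class = effect_class, stringsAsFactors = FALSE)

  tables <- with_seed(config$seed, {
    lfc <- list(cytosol = lfc_cyt, chromatin = lfc_chr)
    out <- list()
    for (fr in FRACTIONS) {
      out[[fr]] <- list()
      for (run in RUN_LABELS) {
        eps <- stats::rnorm(n, 0, config$noise_sd)
        # exp1: control heavy, H/L tracks f; exp2: labels swapped, H/L tracks 1/f
        f <- if (run == "exp1") 2^lfc[[fr]] else 2^(-lfc[[fr]])
        ratio <- f * 2^eps
        keep <- stats::runif(n) >= config$dropout_rate
        npep <- 2L + stats::rpois(n, 3)
        tab <- data.frame(
          protein_id = protein_id[keep], gene_symbol = gene_symbol[keep],
          ratio_hl = ratio[keep], n_peptides_ratio = npep[keep],
          run_label = run, fraction = fr, stringsAsFactors = FALSE
        )
        attr(tab, "orientation") <- if (run == "exp1") "control-heavy" else "control-light"
        out[[fr]][[run]] <- tab
      }
    }
    out
  })
  list(tables = tables, truth = truth)
}

#' Generate a gene-set collection for a simulated study
#'
#' Emits `n_gene_sets` random sets drawn from all simulated genes (sizes
#' uniform in `set_size_range`) plus one designated signal set,
#' `"SIGNAL_DOUBLE_POSITIVE"`, composed of `signal_set_size` genes spiked as
#' double-positive — a stand-in for a coherent complex such as MCM2-7 that an
#' enrichment analysis should recover.
#'
#' @param config a [sim_config()] object.
#' @param truth the truth table from [generate_study()].
#' @return named list of character vectors of gene symbols, with a
#'   `descriptions` attribute; serializable with [write_gmt()].
#' @export
generate_gene_sets <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dp <- truth$gene_symbol[truth$effect_class == "double_positive"]
  if (length(dp) < config$signal_set_size)
    stop(sprintf(
      "signal set of size %d requested but only %d double_positive proteins available",
      config$signal_set_size, length(dp)), call. = FALSE)
  genes <- truth$gene_symbol
  with_seed(config$seed + 1000L, {
    sets <- list(SIGNAL_DOUBLE_POSITIVE = sort(sample(dp, config$signal_set_size)))
    if (config$n_gene_sets > 0) {
      szs <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
      wid <- max(4L, nchar(as.character(config$n_gene_sets)))
      for (i in seq_len(config$n_gene_sets)) {
        sets[[sprintf("RANDOM_SET_%0*d", wid, i)]] <- sort(sample(genes, szs[i]))
      }
    }
    attr(sets, "descriptions") <- stats::setNames(
      c("spiked double-positive signal set",
        rep("random null set", length(sets) - 1L)), names(sets))
    sets
  })
}
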