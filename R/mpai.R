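# Core statistic: pair the reciprocal runs, compute per-protein mPAI, fit the
# normal null, standardize and classify.

#' Pair the two reciprocal runs of one fraction
#'
#' Inner-joins the two quantification tables on `protein_id`. The formula
#' needs both H/L ratios, so proteins quantified in only one run are excluded
#' (and counted); no imputation is attempted. The table whose orientation is
#' `control-heavy` supplies `ratio_exp1` regardless of argument order; two
#' tables with the same orientation are a configuration error, not a label
#' swap.
#'
#' @param exp1,exp2 quantification tables from [read_protein_quant()] (or the
#'   simulator), from the same fraction, with opposite `orientation`
#'   attributes.
#' @return data.frame with columns `protein_id`, `gene_symbol`, `ratio_exp1`,
#'   `ratio_exp2`, `fraction`; attribute `n_excluded` counts proteins present
#'   in only one run.
#' @export
pair_experiments <- function(exp1, exp2) {
  o1 <- attr(exp1, "orientation"); o2 <- attr(exp2, "orientation")
  if (is.null(o1) || is.null(o2))
    stop("both tables must carry an 'orientation' attribute", call. = FALSE)
  if (o1 == o2)
    stop(sprintf("both runs have orientation '%s'; reciprocal runs must be labeled oppositely", o1),
         call. = FALSE)
  if (o1 == "control-light") { tmp <- exp1; exp1 <- exp2; exp2 <- tmp }
  fr1 <- unique(exp1$fraction); fr2 <- unique(exp2$fraction)
  if (length(fr1) != 1L || length(fr2) != 1L || fr1 != fr2)
    stop("both tables must come from the same single fraction", call. = FALSE)

  common <- intersect(exp1$protein_id, exp2$protein_id)
  n_excluded <- (nrow(exp1) - length(common)) + (nrow(exp2) - length(common))
  if (length(common) == 0L)
    warning("no proteins are quantified in both reciprocal runs", call. = FALSE)
  i1 <- match(common, exp1$protein_id)
  i2 <- match(common, exp2$protein_id)
  gene <- exp1$gene_symbol[i1]
  gene[!nzchar(gene)] <- exp2$gene_symbol[i2][!nzchar(gene)]
  out <- data.frame(protein_id = common, gene_symbol = gene,
                    ratio_exp1 = exp1$ratio_hl[i1], ratio_exp2 = exp2$ratio_hl[i2],
                    fraction = rep(fr1, length(common)), stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Compute the association index from a reciprocal ratio pair
#'
#' The index is `log2(ratio_exp1) - log2(ratio_exp2)`, where `ratio_exp1` is
#' the normalized H/L ratio of the run with heavy-labeled control cells and
#' `ratio_exp2` that of the label-swapped run. A protein unaffected by the
#' perturbation has both ratios near one and an index near zero; a protein
#' whose abundance tracks the perturbation at fold `f` has expectation
#' `2 * log2(f)`. The function is antisymmetric in its arguments and invariant
#' under a common rescaling of both ratios.
#'
#' @param ratio_exp1,ratio_exp2 positive numeric vectors (recycled).
#' @return numeric vector of mPAI values in log2-fold-change units.
#' @export
compute_mpai <- function(ratio_exp1, ratio_exp2) {
  if (any(!is.finite(ratio_exp1)) || any(!is.finite(ratio_exp2)) ||
      any(ratio_exp1 <= 0) || any(ratio_exp2 <= 0))
    stop("H/L ratios must be finite and > 0", call. = FALSE)
  log2(ratio_exp1) - log2(ratio_exp2)
}

#' Collapse per-protein mPAI values to one value per gene
#'
#' When several table entries map to the same gene symbol, their mPAI values
#' are averaged arithmetically on the mPAI (log2) scale; `n_entries_averaged`
#' records the multiplicity.
#'
#' @param records data.frame with columns `gene_symbol`, `mpai` and a single
#'   `fraction`.
#' @return data.frame with one row per gene: `gene_symbol`, `fraction`,
#'   `mpai`, `n_entries_averaged`.
#' @export
collapse_by_gene <- function(records) {
  stopifnot(all(c("gene_symbol", "mpai") %in% names(records)))
  fr <- unique(records$fraction)
  if (length(fr) > 1L)
    stop("collapse_by_gene expects records from a single fraction", call. = FALSE)
  agg <- stats::aggregate(records$mpai, by = list(gene_symbol = records$gene_symbol),
                          FUN = mean)
  cnt <- table(records$gene_symbol)
  data.frame(gene_symbol = agg$gene_symbol,
             fraction = if (length(fr)) fr else NA_character_,
             mpai = agg$x,
             n_entries_averaged = as.integer(cnt[agg$gene_symbol]),
             stringsAsFactors = FALSE)
}

#' Fit a normal distribution to an index population
#'
#' Sample mean and sample standard deviation (n-1 denominator). In a
#' null-dominated study the fitted curve describes the unaffected majority,
#' so it serves as the reference for z-scores.
#'
#' @param values numeric vector, at least 2 finite values with positive
#'   spread.
#' @return object of class `mpai_fit`: list with `mu`, `sigma`, `n`.
#' @export
fit_normal <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values to fit", call. = FALSE)
  sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate sample: zero variance", call. = FALSE)
  structure(list(mu = mean(values), sigma = sigma, n = n), class = "mpai_fit")
}

#' @export
print.mpai_fit <- function(x, ...) {
  cat(sprintf("normal fit: mu = %.4g, sigma = %.4g (n = %d)\n", x$mu, x$sigma, x$n))
  invisible(x)
}

#' Standardize an index value against a fitted null
#'
#' @param mpai numeric vector.
#' @param fit an `mpai_fit` from [fit_normal()].
#' @return z-scores `(mpai - mu) / sigma`.
#' @export
standardize_mpai <- function(mpai, fit) {
  if (!is.numeric(fit$sigma) || fit$sigma <= 0)
    stop("fit sigma must be > 0", call. = FALSE)
  (mpai - fit$mu) / fit$sigma
}

#' Classify index values into significance classes
#'
#' Strictly above `pos_threshold` is `positive`, strictly below
#' `neg_threshold` is `negative`, everything else (boundaries included) is
#' `neutral`. The default +/-1 cut is roughly one null standard deviation when
#' the per-run log2 noise sd is near 0.65.
#'
#' @param mpai numeric vector.
#' @param pos_threshold,neg_threshold cut points, `pos_threshold >
#'   neg_threshold`.
#' @return character vector in `{"positive", "negative", "neutral"}`.
#' @export
classify_mpai <- function(mpai, pos_threshold = 1.0, neg_threshold = -1.0) {
  if (pos_threshold <= neg_threshold)
    stop("pos_threshold must exceed neg_threshold", call. = FALSE)
  out <- rep("neutral", length(mpai))
  out[mpai > pos_threshold] <- "positive"
  out[mpai < neg_threshold] <- "negative"
  out
}

#' Per-fraction mPAI profile from a reciprocal run pair
#'
#' The full per-fraction computation: pair the runs, compute per-protein mPAI,
#' collapse to genes, fit the normal null on the collapsed values, standardize
#' and classify. With `threshold_mode = "fit"` the cut points are `mu +/- k *
#' sigma` of the fitted null instead of the fixed values.
#'
#' @param exp1,exp2 quantification tables of one fraction (opposite
#'   orientations).
#' @param pos_threshold,neg_threshold fixed classification cuts.
#' @param threshold_mode `"fixed"` (default) or `"fit"` (derive cuts from the
#'   fitted null as `mu +/- k * sigma`).
#' @param k multiplier for `threshold_mode = "fit"`.
#' @param median_center if `TRUE`, subtract the median log2 ratio from each
#'   run before pairing (off by default: ratios are taken as already
#'   normalized upstream).
#' @param id_map optional named vector from [read_id_map()] applied to
#'   `protein_id` before gene collapsing, for tables without usable gene
#'   symbols.
#' @return data.frame with columns `gene_symbol`, `fraction`, `mpai`, `z`,
#'   `sig_class`, `n_entries_averaged`; attributes `fit` (the `mpai_fit`),
#'   `thresholds`, and `n_excluded` from pairing.
#' @export
mpai_profile <- function(exp1, exp2, pos_threshold = 1.0, neg_threshold = -1.0,
                         threshold_mode = c("fixed", "fit"), k = 1.0,
                         median_center = FALSE, id_map = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (median_center) {
    recenter <- function(tab) {
      tab$ratio_hl <- tab$ratio_hl / 2^stats::median(log2(tab$ratio_hl))
      tab
    }
    exp1 <- recenter(exp1); exp2 <- recenter(exp2)
  }
  pairs <- pair_experiments(exp1, exp2)
  if (!is.null(id_map)) {
    mapped <- apply_id_map(pairs$protein_id, id_map)
    pairs$gene_symbol <- as.character(mapped)
  }
  pairs$gene_symbol[!nzchar(pairs$gene_symbol)] <-
    pairs$protein_id[!nzchar(pairs$gene_symbol)]
  pairs$mpai <- compute_mpai(pairs$ratio_exp1, pairs$ratio_exp2)
  collapsed <- collapse_by_gene(pairs)
  fit <- fit_normal(collapsed$mpai)
  if (threshold_mode == "fit") {
    pos_threshold <- fit$mu + k * fit$sigma
    neg_threshold <- fit$mu - k * fit$sigma
  }
  collapsed$z <- standardize_mpai(collapsed$mpai, fit)
  collapsed$sig_class <- classify_mpai(collapsed$mpai, pos_threshold, neg_threshold)
  collapsed <- collapsed[, c("gene_symbol", "fraction", "mpai", "z",
                             "sig_class", "n_entries_averaged")]
  attr(collapsed, "fit") <- fit
  attr(collapsed, "thresholds") <- c(positive = pos_threshold, negative = neg_threshold)
  attr(collapsed, "n_excluded") <- attr(pairs, "n_excluded")
  collapsed
}
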