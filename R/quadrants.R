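# Two-fraction comparison: join the cytosol and chromatin mPAI profiles and
# assign each gene to a quadrant of the scatter.

#' Assign quadrants in the cytosol-by-chromatin plane
#'
#' A gene with both coordinates inside the `+/- threshold` box is `center`
#' (unaffected by the perturbation in either fraction). Outside the box the
#' quadrant is the sign pair (cytosol = x, chromatin = y): `(+,+)`
#' double_positive, `(-,+)` chromatin_pos_cytosol_neg, `(-,-)`
#' double_negative, `(+,-)` cytosol_pos_chromatin_neg. A coordinate of exactly
#' zero on a non-center point counts as positive (a documented tie-break; at
#' double precision it is essentially unreachable with real data).
#'
#' @param mpai_cytosol,mpai_chromatin numeric vectors (recycled).
#' @param threshold positive half-width of the center box.
#' @return character vector of quadrant labels.
#' @export
assign_quadrant <- function(mpai_cytosol, mpai_chromatin, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  n <- max(length(mpai_cytosol), length(mpai_chromatin))
  x <- rep_len(mpai_cytosol, n); y <- rep_len(mpai_chromatin, n)
  out <- rep("center", n)
  off <- abs(x) > threshold | abs(y) > threshold
  xp <- x >= 0; yp <- y >= 0
  out[off & xp & yp] <- "double_positive"
  out[off & !xp & yp] <- "chromatin_pos_cytosol_neg"
  out[off & !xp & !yp] <- "double_negative"
  out[off & xp & !yp] <- "cytosol_pos_chromatin_neg"
  out
}

#' Join the cytosol and chromatin mPAI profiles
#'
#' Inner join on gene symbol: only genes quantified in both fractions get a
#' point in the scatter (genes seen in a single fraction remain in that
#' fraction's own profile and are counted here). Inputs must already be
#' gene-collapsed; duplicated genes are a data error, not something to fix
#' silently.
#'
#' @param cytosol,chromatin gene-collapsed mPAI tables from [mpai_profile()]
#'   (or any data.frame with `gene_symbol` and `mpai`).
#' @param threshold half-width of the center box passed to
#'   [assign_quadrant()]; also defines the `significant` flag (outside the box
#'   on at least one axis).
#' @return data.frame with columns `gene_symbol`, `mpai_cytosol`,
#'   `mpai_chromatin`, `quadrant`, `significant`; attribute `n_excluded` =
#'   `c(cytosol_only, chromatin_only)`.
#' @export
join_fractions <- function(cytosol, chromatin, threshold = 1.0) {
  for (nm in c("cytosol", "chromatin")) {
    tab <- get(nm)
    if (anyDuplicated(tab$gene_symbol))
      stop(sprintf("duplicated gene_symbol in %s input: collapse by gene before joining", nm),
           call. = FALSE)
  }
  common <- intersect(cytosol$gene_symbol, chromatin$gene_symbol)
  if (length(common) == 0L)
    warning("cytosol and chromatin profiles share no genes", call. = FALSE)
  ic <- match(common, cytosol$gene_symbol)
  ih <- match(common, chromatin$gene_symbol)
  out <- data.frame(gene_symbol = common,
                    mpai_cytosol = cytosol$mpai[ic],
                    mpai_chromatin = chromatin$mpai[ih],
                    stringsAsFactors = FALSE)
  out$quadrant <- assign_quadrant(out$mpai_cytosol, out$mpai_chromatin, threshold)
  out$significant <- abs(out$mpai_cytosol) > threshold | abs(out$mpai_chromatin) > threshold
  attr(out, "n_excluded") <- c(cytosol_only = nrow(cytosol) - length(common),
                               chromatin_only = nrow(chromatin) - length(common))
  out
}

#' Tabulate quadrant membership
#'
#' @param records data.frame from [join_fractions()].
#' @return named integer vector over all five quadrant labels plus a `total`
#'   entry; the five counts sum to `total`.
#' @export
summarize_quadrants <- function(records) {
  counts <- vapply(QUADRANTS, function(q) sum(records$quadrant == q), integer(1))
  c(counts, total = nrow(records))
}
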