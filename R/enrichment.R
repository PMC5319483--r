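# Preranked gene-set enrichment on the mPAI-ranked list: weighted
# Kolmogorov-Smirnov running-sum enrichment score, gene-label permutation
# null, sign-matched normalization and nominal p-values.

#' Rank a gene-collapsed mPAI table
#'
#' Descending by mPAI; ties broken lexicographically by gene symbol so the
#' ranking is fully deterministic.
#'
#' @param records data.frame with `gene_symbol` and `mpai` (one row per gene).
#' @return data.frame of class `ranked_list` with columns `gene`, `score`.
#' @export
rank_by_mpai <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot rank an empty table", call. = FALSE)
  if (anyDuplicated(records$gene_symbol))
    stop("duplicated gene_symbol: collapse by gene before ranking", call. = FALSE)
  ord <- order(-records$mpai, records$gene_symbol)
  structure(data.frame(gene = records$gene_symbol[ord], score = records$mpai[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Enrichment score from hit positions only. The running sum is piecewise
# linear and decreasing between hits, so its extrema occur just before or just
# after a hit (or at the end, where it returns to 0); evaluating those O(k)
# breakpoints reproduces the full O(N) scan exactly. Ties in magnitude between
# the positive and negative extremum resolve to the positive one.
.es_from_positions <- function(positions, abs_w, N) {
  k <- length(positions)
  if (k == N) return(1)
  nr <- sum(abs_w)
  w <- if (nr > 0) abs_w / nr else rep(1 / k, k)
  miss <- 1 / (N - k)
  cw <- cumsum(w)
  d <- (positions - seq_len(k)) * miss
  top <- cw - d               # running sum just after each hit
  bot <- c(0, cw[-k]) - d     # running sum just before each hit
  maxp <- max(top)
  minn <- min(bot, 0)         # the final value is always 0
  if (maxp + minn >= -1e-9) maxp else minn
}

#' Weighted running-sum enrichment score
#'
#' The classic preranked statistic: walking down the ranked list, set members
#' ("hits") increment the running sum by `|score|^p / N_R` (with `N_R` the sum
#' of `|score|^p` over hits) and non-members decrement it by `1 / (N - N_H)`.
#' The enrichment score is the extremum of largest magnitude, in `[-1, 1]`;
#' magnitude ties between the positive and negative extremum (to within 1e-9,
#' so the choice is robust to accumulation order) resolve positive. When the
#' hit scores are all zero (possible with `p > 0`), hits fall back to equal
#' increments `1 / N_H`. A set covering the whole list has `es = 1` by
#' convention.
#'
#' @param ranked a `ranked_list` from [rank_by_mpai()].
#' @param gene_set character vector of gene symbols; must intersect the list.
#' @param p weight exponent on `|score|` (default 1, the weighted statistic;
#'   0 gives the unweighted Kolmogorov-Smirnov form).
#' @return list with `es`, `running_sum` (length-N trace), `leading_edge`
#'   (members at or before the positive extremum, or at or after the negative
#'   extremum).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop("gene set has no overlap with the ranked list", call. = FALSE)
  inc <- numeric(N)
  if (k == N) {
    w <- abs(ranked$score)^p
    inc[] <- if (sum(w) > 0) w / sum(w) else 1 / N
    running <- cumsum(inc)
    return(list(es = 1, running_sum = running, leading_edge = ranked$gene))
  }
  w <- abs(ranked$score[hit])^p
  nr <- sum(w)
  inc[hit] <- if (nr > 0) w / nr else 1 / k
  inc[!hit] <- -1 / (N - k)
  running <- cumsum(inc)
  maxr <- max(running)
  minr <- min(running)
  # magnitude ties (to 1e-9) resolve to the positive extremum
  es <- if (maxr + minr >= -1e-9) maxr else minr
  if (es >= 0) {
    peak <- which.max(running)[1]
    leading <- ranked$gene[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    trough <- which.min(running)[1]
    idx <- seq(trough, N)
    leading <- ranked$gene[idx][hit[idx]]
  }
  list(es = es, running_sum = running, leading_edge = leading)
}

#' Permutation null for the enrichment score
#'
#' Gene-label permutation: draws `n_perm` random gene sets of the given size
#' from the ranked list (without replacement within a draw) and returns their
#' enrichment scores. This is the only permutation scheme compatible with a
#' preranked single statistic per gene.
#'
#' @param ranked a `ranked_list`.
#' @param set_size size of each random set; must not exceed the list length.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#' @param p weight exponent, as in [enrichment_score()].
#' @return numeric vector of `n_perm` null enrichment scores in `[-1, 1]`.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, seed = NULL, p = 1) {
  N <- nrow(ranked)
  if (set_size > N) stop("set_size exceeds the ranked list length", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  absp <- abs(ranked$score)^p
  draw <- function() {
    pos <- sort(sample.int(N, set_size))
    .es_from_positions(pos, absp[pos], N)
  }
  if (is.null(seed)) {
    vapply(seq_len(n_perm), function(i) draw(), numeric(1))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i) draw(), numeric(1)))
  }
}

#' Nominal p-value and normalized score against a permutation null
#'
#' One-sided against the same-sign half of the null, with the add-one
#' correction: `p = (1 + #{same-sign null with |null| >= |es|}) / (1 +
#' #{same-sign null})`. The normalized score is `nes = es / mean(|same-sign
#' null es|)`. An observed score of exactly zero gets `p = 1`; if the null
#' contains no same-sign values, `p = 1` with a warning.
#'
#' @param es observed enrichment score.
#' @param null_sample numeric vector from [permutation_null()].
#' @return list with `p` and `nes`.
#' @export
nominal_p <- function(es, null_sample) {
  if (length(null_sample) == 0L) stop("empty null sample", call. = FALSE)
  if (es == 0) return(list(p = 1, nes = 0))
  same <- if (es > 0) null_sample[null_sample > 0] else null_sample[null_sample < 0]
  if (length(same) == 0L) {
    warning("no same-sign null scores; p set to 1", call. = FALSE)
    return(list(p = 1, nes = NA_real_))
  }
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(p = p, nes = es / mean(abs(same)))
}

#' Run preranked enrichment over a gene-set collection
#'
#' Ranks the table, filters sets to those whose overlap with the ranked
#' universe lies in `[min_size, max_size]`, computes each set's enrichment
#' score, a gene-label permutation null (shared across sets of equal overlap
#' size — the null depends only on the size), the nominal p-value and the
#' sign-matched normalized score, and splits the results by direction.
#'
#' @param records gene-collapsed mPAI table ([mpai_profile()] output).
#' @param collection named list of gene sets (from [read_gmt()] or
#'   [generate_gene_sets()]).
#' @param min_size,max_size overlap-size filter.
#' @param n_perm permutations per null.
#' @param seed integer seed for the permutation null.
#' @param alpha nominal significance cut for the `flagged` column.
#' @param p weight exponent of the running-sum statistic.
#' @return list with data.frames `positive` and `negative` (columns
#'   `set_name`, `set_size`, `es`, `nes`, `p_nominal`, `direction`, `flagged`,
#'   `leading_edge`), each sorted by `p_nominal` then decreasing `|nes|`;
#'   attribute `n_filtered` counts sets dropped by the size filter.
#' @export
run_enrichment <- function(records, collection, min_size = 5, max_size = 500,
                           n_perm = 1000, seed = 1L, alpha = 0.01, p = 1) {
  ranked <- rank_by_mpai(records)
  universe <- ranked$gene
  overlap <- lapply(collection, function(s) intersect(s, universe))
  sizes <- lengths(overlap)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stop("no gene set passes the size filter against the ranked universe", call. = FALSE)
  overlap <- overlap[keep]; sizes <- sizes[keep]

  # one shared null per distinct overlap size, all drawn from one seeded stream
  null_by_size <- with_seed(seed, {
    usz <- sort(unique(sizes))
    stats::setNames(
      lapply(usz, function(k) permutation_null(ranked, k, n_perm, seed = NULL, p = p)),
      as.character(usz))
  })

  rows <- lapply(seq_along(overlap), function(i) {
    sc <- enrichment_score(ranked, overlap[[i]], p = p)
    np <- nominal_p(sc$es, null_by_size[[as.character(sizes[i])]])
    data.frame(set_name = names(overlap)[i], set_size = sizes[i],
               es = sc$es, nes = np$nes, p_nominal = np$p,
               direction = if (sc$es >= 0) "positive" else "negative",
               flagged = np$p < alpha,
               leading_edge = paste(sc$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  split_sorted <- function(dir) {
    part <- res[res$direction == dir, , drop = FALSE]
    part <- part[order(part$p_nominal, -abs(part$nes)), , drop = FALSE]
    rownames(part) <- NULL
    part
  }
  structure(list(positive = split_sorted("positive"),
                 negative = split_sorted("negative")),
            n_filtered = sum(!keep))
}
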