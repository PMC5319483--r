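test_that("ranking is descending with deterministic lexicographic tie-breaks", {
  rec <- data.frame(gene_symbol = c("B", "A", "C"), mpai = c(1, 2, 1))
  rk <- rank_by_mpai(rec)
  expect_identical(rk$gene, c("A", "B", "C"))
  neg <- rank_by_mpai(transform(rec, mpai = -mpai))
  # negation reverses the order of the distinct scores
  expect_identical(neg$gene[3], "A")
  expect_error(rank_by_mpai(rec[0, ]), "empty")
  expect_error(rank_by_mpai(rbind(rec, rec[1, ])), "duplicated")
})

test_that("degenerate sets hit the documented ES conventions", {
  rec <- data.frame(gene_symbol = paste0("G", 1:10), mpai = 10:1)
  rk <- rank_by_mpai(rec)
  expect_equal(enrichment_score(rk, rk$gene)$es, 1)        # whole list
  expect_equal(enrichment_score(rk, rk$gene[1])$es, 1)     # single top hit
  expect_error(enrichment_score(rk, "ABSENT"), "no overlap")
})

test_that("the ES matches the brute-force running-sum oracle on a fixed case", {
  rec <- data.frame(gene_symbol = paste0("G", sprintf("%02d", 1:10)), mpai = 10:1)
  rk <- rank_by_mpai(rec)
  set <- rk$gene[1:3]
  expect_equal(enrichment_score(rk, set)$es,
               es_bruteforce(rk$score, rk$gene, set), tolerance = 1e-12)
})

test_that("the breakpoint kernel and the full trace agree on random cases", {
  set.seed(33)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    rk <- rank_by_mpai(data.frame(gene_symbol = sprintf("G%03d", 1:N),
                                  mpai = rnorm(N)))
    k <- sample(2:min(15, N - 1), 1)
    set <- sample(rk$gene, k)
    pos <- which(rk$gene %in% set)
    es_trace <- enrichment_score(rk, set)$es
    es_kernel <- mpaiR:::.es_from_positions(pos, abs(rk$score[pos]), N)
    expect_equal(es_kernel, es_trace, tolerance = 1e-12)
  }
})

test_that("the ES agrees with an independent reference implementation", {
  set.seed(44)
  for (i in 1:20) {
    N <- sample(50:300, 1)
    rk <- rank_by_mpai(data.frame(gene_symbol = sprintf("G%03d", 1:N),
                                  mpai = rnorm(N)))
    set <- sample(rk$gene, sample(3:20, 1))
    pos <- which(rk$gene %in% set)
    ref <- fgsea::calcGseaStat(stats::setNames(rk$score, rk$gene),
                               selectedStats = pos, gseaParam = 1)
    es <- enrichment_score(rk, set)$es
    expect_equal(abs(es), abs(ref), tolerance = 1e-10)
    # signs may legitimately differ only on an exact magnitude tie between
    # the positive and negative extremum
    expect_true(sign(es) == sign(ref) || abs(es + ref) < 1e-9)
  }
})

test_that("negating all scores and reversing the list negates the ES", {
  set.seed(21)
  for (i in 1:20) {
    N <- 60
    scores <- sort(rnorm(N), decreasing = TRUE)  # distinct almost surely
    genes <- sprintf("G%03d", 1:N)
    rk <- structure(data.frame(gene = genes, score = scores),
                    class = c("ranked_list", "data.frame"))
    rk_rev <- structure(data.frame(gene = rev(genes), score = rev(-scores)),
                        class = c("ranked_list", "data.frame"))
    set <- sample(genes, 8)
    es_f <- enrichment_score(rk, set)$es
    es_r <- enrichment_score(rk_rev, set)$es
    if (abs(abs(es_f) - abs(es_r)) < 1e-12 && es_f * es_r < 0) {
      expect_equal(es_r, -es_f, tolerance = 1e-12)
    } else {
      # magnitude ties can resolve to the positive side in both orientations
      expect_equal(abs(es_r), abs(es_f), tolerance = 1e-12)
    }
  }
})

test_that("the permutation null is seeded, bounded and centered", {
  rec <- data.frame(gene_symbol = sprintf("G%03d", 1:200), mpai = rnorm(200))
  rk_in <- rec
  null1 <- permutation_null(rank_by_mpai(rk_in), set_size = 10, n_perm = 200, seed = 5)
  null2 <- permutation_null(rank_by_mpai(rk_in), set_size = 10, n_perm = 200, seed = 5)
  expect_identical(null1, null2)
  expect_true(all(null1 >= -1 & null1 <= 1))
  expect_lt(abs(mean(null1)), 0.15)
  expect_error(permutation_null(rank_by_mpai(rk_in), set_size = 1000), "exceeds")
})

test_that("nominal p follows the add-one estimator and is monotone in |es|", {
  null <- c(0.5, 0.3, -0.4, 0.2, -0.1)
  top <- nominal_p(0.9, null)
  expect_equal(top$p, 1 / (3 + 1))            # 3 positive nulls, none >= 0.9
  expect_equal(top$nes, 0.9 / mean(c(0.5, 0.3, 0.2)))
  expect_equal(nominal_p(0, null)$p, 1)
  expect_warning(res <- nominal_p(-0.5, c(0.1, 0.2)), "same-sign")
  expect_equal(res$p, 1)
  ps <- vapply(seq(0.05, 0.6, by = 0.05),
               function(e) nominal_p(e, null)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("run_enrichment filters, splits by direction and respects alpha", {
  set.seed(66)
  rec <- data.frame(gene_symbol = sprintf("G%03d", 1:150), mpai = rnorm(150))
  coll <- list(TOO_SMALL = rec$gene_symbol[1:2],
               SETA = rec$gene_symbol[1:12],
               SETB = rec$gene_symbol[100:120],
               NO_OVERLAP = c("X1", "X2", "X3", "X4", "X5"))
  res <- run_enrichment(rec, coll, min_size = 5, n_perm = 100, seed = 3)
  found <- c(res$positive$set_name, res$negative$set_name)
  expect_setequal(found, c("SETA", "SETB"))
  expect_equal(attr(res, "n_filtered"), 2)
  all_rows <- rbind(res$positive, res$negative)
  expect_true(all(all_rows$es >= -1 & all_rows$es <= 1))
  expect_identical(all_rows$flagged, all_rows$p_nominal < 0.01)

  none <- run_enrichment(rec, coll, min_size = 5, n_perm = 100, seed = 3, alpha = 0)
  expect_false(any(rbind(none$positive, none$negative)$flagged))
  expect_error(run_enrichment(rec, list(S = c("X1", "X2")), min_size = 5),
               "size filter")

  rerun <- run_enrichment(rec, coll, min_size = 5, n_perm = 100, seed = 3)
  expect_identical(res, rerun)
})
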