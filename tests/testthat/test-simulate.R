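test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_proteins = 0), "n_proteins")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(dropout_rate = 1), "dropout_rate")
  expect_error(sim_config(frac_affected = 1.2), "frac_affected")
  expect_error(sim_config(set_size_range = c(10, 2)), "set_size_range")
  bad <- data.frame(class = "double_positive", fold_cytosol = 0.5, fold_chromatin = 2)
  expect_error(sim_config(effect_classes = bad), "effect_classes")
})

test_that("an identical seed gives a bit-identical study", {
  sc <- sim_config(n_proteins = 200, frac_affected = 0.2, seed = 11)
  a <- generate_study(sc)
  b <- generate_study(sc)
  expect_identical(a, b)
  expect_identical(generate_gene_sets(sc, a$truth), generate_gene_sets(sc, b$truth))
})

test_that("the noise-free limit reproduces the reciprocal design exactly", {
  cls <- data.frame(class = "double_positive", fold_cytosol = 2, fold_chromatin = 2)
  sc <- sim_config(n_proteins = 1, frac_affected = 1, effect_classes = cls,
                   noise_sd = 1e-12, dropout_rate = 0, seed = 1)
  st <- generate_study(sc)
  r1 <- st$tables$cytosol$exp1$ratio_hl
  r2 <- st$tables$cytosol$exp2$ratio_hl
  expect_equal(r1, 2, tolerance = 1e-9)
  expect_equal(r2, 0.5, tolerance = 1e-9)
  expect_equal(compute_mpai(r1, r2), 2, tolerance = 1e-9)
})

test_that("null proteins have exactly zero true fold change and spikes one class", {
  sc <- sim_config(n_proteins = 400, frac_affected = 0.1, seed = 3)
  st <- generate_study(sc)
  null_rows <- st$truth$effect_class == "null"
  expect_identical(st$truth$lfc_cytosol[null_rows], rep(0, sum(null_rows)))
  expect_identical(st$truth$lfc_chromatin[null_rows], rep(0, sum(null_rows)))
  expect_equal(sum(!null_rows), 40)
  expect_true(all(st$truth$effect_class %in%
                    c("null", default_effect_classes()$class)))
})

test_that("dropout thins each run at the configured binomial rate", {
  sc <- sim_config(n_proteins = 10000, frac_affected = 0, dropout_rate = 0.5, seed = 5)
  st <- generate_study(sc)
  sd3 <- 3 * sqrt(10000 * 0.5 * 0.5)
  for (fr in c("cytosol", "chromatin")) {
    for (run in c("exp1", "exp2")) {
      expect_lt(abs(nrow(st$tables[[fr]][[run]]) - 5000), sd3)
    }
  }
})

test_that("a pure-null study passes a KS normality check against N(0, 2*sd^2)", {
  sc <- sim_config(n_proteins = 5000, frac_affected = 0, dropout_rate = 0, seed = 19)
  st <- generate_study(sc)
  pairs <- pair_experiments(st$tables$cytosol$exp1, st$tables$cytosol$exp2)
  mpai <- compute_mpai(pairs$ratio_exp1, pairs$ratio_exp2)
  ks <- stats::ks.test(mpai, "pnorm", 0, sqrt(2) * 0.65)
  expect_gt(ks$p.value, 0.01)
})

test_that("swapping the reciprocal tables negates every mPAI exactly", {
  sc <- sim_config(n_proteins = 300, frac_affected = 0.2, seed = 8)
  st <- generate_study(sc)
  e1 <- st$tables$chromatin$exp1
  e2 <- st$tables$chromatin$exp2
  # relabel orientations so the swapped pair is still a valid reciprocal design
  attr(e1, "orientation") <- "control-light"
  attr(e2, "orientation") <- "control-heavy"
  fwd <- pair_experiments(st$tables$chromatin$exp1, st$tables$chromatin$exp2)
  rev <- pair_experiments(e1, e2)
  rev <- rev[match(fwd$protein_id, rev$protein_id), ]
  expect_identical(compute_mpai(fwd$ratio_exp1, fwd$ratio_exp2),
                   -compute_mpai(rev$ratio_exp1, rev$ratio_exp2))
})

test_that("spiked proteins recover 2*log2(f) in expectation", {
  cls <- data.frame(class = "double_positive", fold_cytosol = 3, fold_chromatin = 3)
  sc <- sim_config(n_proteins = 4000, frac_affected = 0.25, effect_classes = cls,
                   dropout_rate = 0, seed = 21)
  st <- generate_study(sc)
  pairs <- pair_experiments(st$tables$cytosol$exp1, st$tables$cytosol$exp2)
  pairs$mpai <- compute_mpai(pairs$ratio_exp1, pairs$ratio_exp2)
  spiked <- st$truth$protein_id[st$truth$effect_class == "double_positive"]
  vals <- pairs$mpai[pairs$protein_id %in% spiked]
  sem <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 2 * log2(3)), 3 * sem)
})

test_that("gene-set generation honours the signal-set contract", {
  sc <- sim_config(n_proteins = 500, frac_affected = 0.2, n_gene_sets = 10,
                   set_size_range = c(5, 20), seed = 13)
  st <- generate_study(sc)
  sets <- generate_gene_sets(sc, st$truth)
  sig <- sets$SIGNAL_DOUBLE_POSITIVE
  expect_length(sig, 6)
  dp <- st$truth$gene_symbol[st$truth$effect_class == "double_positive"]
  expect_true(all(sig %in% dp))
  expect_length(sets, 11)

  only_sig <- generate_gene_sets(sim_config(n_proteins = 500, frac_affected = 0.2,
                                            n_gene_sets = 0, seed = 13), st$truth)
  expect_identical(names(only_sig), "SIGNAL_DOUBLE_POSITIVE")

  tiny <- sim_config(n_proteins = 50, frac_affected = 0.02, seed = 1)
  tiny_truth <- generate_study(tiny)$truth  # 1 affected protein only
  expect_error(generate_gene_sets(tiny, tiny_truth), "double_positive")
})
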