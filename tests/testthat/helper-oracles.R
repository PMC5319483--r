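# Shared fixtures and independent oracles, all built in code.

# Brute-force running-sum oracle for the enrichment score: a literal
# element-by-element walk down the ranked list, independent of the package's
# cumsum/breakpoint implementations.
es_bruteforce <- function(scores, genes, set, p = 1) {
  N <- length(scores)
  hit <- genes %in% set
  NH <- sum(hit)
  NR <- sum(abs(scores[hit])^p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + if (NR > 0) abs(scores[i])^p / NR else 1 / NH
    } else {
      cur <- cur - 1 / (N - NH)
    }
    run[i] <- cur
  }
  mx <- max(run); mn <- min(run)
  if (mx + mn >= -1e-9) mx else mn  # same tie rule as the package kernel
}

# Minimal native-dialect quantification table.
make_quant <- function(ids, ratios, genes = ids, npep = 3L,
                       run = "exp1", fraction = "cytosol",
                       orientation = if (run == "exp1") "control-heavy" else "control-light") {
  tab <- data.frame(protein_id = ids, gene_symbol = genes, ratio_hl = ratios,
                    n_peptides_ratio = npep, run_label = run, fraction = fraction,
                    stringsAsFactors = FALSE)
  attr(tab, "orientation") <- orientation
  tab
}

write_native_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
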