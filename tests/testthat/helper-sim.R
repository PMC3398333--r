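# Small simulation configurations reused across test files.

tiny_config <- function(n_genes = 200, seed = 42, ...) {
  simulation_config(
    n_genes = n_genes,
    library_totals = c(mixed = 1e5, stage1 = 1e5, stage2 = 1e5,
                       stage3 = 1e5),
    seed = seed, ...)
}

tiny_study <- function(n_genes = 200, seed = 42, ...) {
  cfg <- tiny_config(n_genes = n_genes, seed = seed, ...)
  catalog <- generate_catalog(cfg)
  sim <- simulate_counts(catalog, cfg)
  list(config = cfg, catalog = catalog, counts = sim$counts,
       truth = sim$truth)
}

# Naive double-ranking Mutual Rank: the brute-force oracle the fast
# implementation is checked against.
naive_mutual_rank <- function(corr) {
  genes <- sort(rownames(corr))
  n <- length(genes)
  rk <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (a in genes) {
    others <- setdiff(genes, a)
    pccs <- corr[a, others]
    for (b in others) {
      rk[a, b] <- sum(pccs > pccs[b]) +
        sum(pccs == pccs[b] & others < b) + 1
    }
  }
  pairs <- t(utils::combn(genes, 2))
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             pcc = corr[pairs],
             mr = sqrt(rk[pairs] * rk[pairs[, 2:1, drop = FALSE]]))
}

# Naive union-rule top-k retention over a mutual_rank() edge table.
naive_topk_edges <- function(edges, k) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  keep <- rep(FALSE, nrow(edges))
  for (g in genes) {
    inc <- which(edges$gene_a == g | edges$gene_b == g)
    partner <- ifelse(edges$gene_a[inc] == g, edges$gene_b[inc],
                      edges$gene_a[inc])
    o <- inc[order(edges$mr[inc], partner)]
    keep[o[seq_len(min(k, length(o)))]] <- TRUE
  }
  edges[keep, , drop = FALSE]
}

random_corr <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  cc <- (m + t(m)) / 2
  diag(cc) <- NA_real_
  dimnames(cc) <- list(sprintf("g%03d", seq_len(n)),
                       sprintf("g%03d", seq_len(n)))
  cc
}
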