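#' Pairwise Pearson correlation of expression trajectories
#'
#' Computes the Pearson correlation coefficient (PCC) between every pair of
#' gene expression trajectories across the stage columns. Genes with any
#' zero RPKM are filtered out first, and genes with a constant trajectory
#' (undefined correlation) are dropped with a warning.
#'
#' @param rpkm RPKM matrix, genes in rows.
#' @param stages Columns to correlate over (default: all; at least 3).
#' @return Symmetric correlation matrix over the retained genes, in gene-id
#'   order, with `NA` on the diagonal (self-correlation excluded).
#' @export
pairwise_pcc <- function(rpkm, stages = colnames(rpkm)) {
  stopifnot(length(stages) >= 3)
  m <- rpkm[, stages, drop = FALSE]
  keep <- rowSums(m == 0) == 0
  m <- m[keep, , drop = FALSE]
  const <- apply(m, 1, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " gene(s) with constant expression dropped ",
            "(correlation undefined)", call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  cc <- stats::cor(t(m), method = "pearson")
  diag(cc) <- NA_real_
  cc
}

#' Mutual Rank transformation of a correlation table
#'
#' For each ordered pair, `rank_a->b` is the rank of gene b among gene a's
#' neighbors sorted by descending PCC (rank 1 = most correlated; ties broken
#' by gene-id order). The Mutual Rank of a pair is the geometric mean
#' `sqrt(rank_a->b * rank_b->a)`; lower means more strongly co-expressed.
#'
#' @param corr Symmetric correlation matrix from [pairwise_pcc()].
#' @return Data frame of class `coexpression_edges`: one row per unordered
#'   pair, columns `gene_a`, `gene_b`, `pcc`, `mr`.
#' @export
mutual_rank <- function(corr) {
  genes <- rownames(corr)
  ord <- order(genes)
  corr <- corr[ord, ord, drop = FALSE]  # id order makes stable sorts tie-break by id
  genes <- genes[ord]
  n <- nrow(corr)
  if (n < 2) {
    return(structure(data.frame(gene_a = character(0), gene_b = character(0),
                                pcc = numeric(0), mr = numeric(0)),
                     class = c("coexpression_edges", "data.frame")))
  }
  rk <- matrix(NA_real_, n, n, dimnames = dimnames(corr))
  for (a in seq_len(n)) {
    others <- seq_len(n)[-a]
    # radix sort is stable, so equal pcc fall back to gene-id order
    o <- others[order(-corr[a, others], method = "radix")]
    rk[a, o] <- seq_along(o)
  }
  ij <- which(upper.tri(corr), arr.ind = TRUE)
  structure(data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                       pcc = corr[ij],
                       mr = sqrt(rk[ij] * rk[ij[, c(2, 1), drop = FALSE]]),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("coexpression_edges", "data.frame"))
}

#' Top-k neighbor co-expression network
#'
#' Keeps an edge if either endpoint lists the other among its `k` nearest
#' neighbors by ascending Mutual Rank (ties broken by gene-id order). The
#' result is an undirected graph with no self-loops; every gene of the
#' filtered set keeps at least its own top-k, so no node is isolated when
#' `n >= 2`.
#'
#' @param edges Edge table from [mutual_rank()].
#' @param k Neighbors retained per gene (default 12).
#' @return An igraph graph with edge attributes `pcc` and `mr`.
#' @export
build_topk_network <- function(edges, k = 12) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n_e <- nrow(edges)
  if (n_e == 0) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(genes))
  }
  # each undirected edge is incident to both endpoints; rank incidences per
  # gene by (mr, partner id) and keep each gene's first k
  eidx <- rep(seq_len(n_e), 2L)
  gene <- c(edges$gene_a, edges$gene_b)
  partner <- c(edges$gene_b, edges$gene_a)
  mr <- rep(edges$mr, 2L)
  o <- order(gene, mr, partner, method = "radix")
  pos <- stats::ave(seq_along(o), gene[o], FUN = seq_along)
  keep_idx <- unique(eidx[o][pos <= k])
  kept <- edges[sort(keep_idx), , drop = FALSE]
  igraph::graph_from_data_frame(kept, directed = FALSE, vertices = genes)
}

#' Seeded sub-network extraction
#'
#' Induced subgraph on a set of seed genes plus all their direct neighbors
#' (the first-neighbor branch of the network around the seeds). Seeds absent
#' from the network are reported and skipped.
#'
#' @param network Graph from [build_topk_network()].
#' @param seed_genes Character vector of seed gene ids.
#' @return An igraph subgraph.
#' @export
extract_subnetwork <- function(network, seed_genes) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(seed_genes, nodes)
  if (length(missing) > 0) {
    message("skipping ", length(missing), " seed gene(s) not in network: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  seeds <- intersect(seed_genes, nodes)
  nbr <- unique(unlist(lapply(igraph::adjacent_vertices(network, seeds),
                              names)))
  igraph::induced_subgraph(network, union(seeds, nbr))
}

#' Export a co-expression network as an edge-list table
#'
#' @param network Graph from [build_topk_network()].
#' @return Data frame `gene_a`, `gene_b`, `pcc`, `mr`.
#' @export
network_edge_table <- function(network) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  el
}
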