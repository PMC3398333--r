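test_that("pairwise PCC matches the textbook formula and filters zeros", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 7), g3 = c(2, 4, 6),
             g4 = c(0, 5, 9))
  colnames(m) <- paste0("s", 1:3)
  cc <- pairwise_pcc(m)
  # the zero-containing gene is filtered before correlation
  expect_false("g4" %in% rownames(cc))
  v1 <- c(1, 2, 3); v2 <- c(2, 4, 7)
  hand <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(cc["g1", "g2"], hand)
  expect_equal(cc["g1", "g3"], 1)  # exact linear copy
  expect_true(is.na(cc["g1", "g1"]))
  # negation around the mean gives -1
  m2 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  colnames(m2) <- paste0("s", 1:3)
  expect_equal(pairwise_pcc(m2)["a", "b"], -1)
})

test_that("constant trajectories are dropped with a warning", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 3, 9))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(cc <- pairwise_pcc(m), "constant")
  expect_setequal(rownames(cc), c("a", "c"))
})

test_that("mutual rank is the geometric mean of directed ranks", {
  # mutual top neighbors get MR 1
  m <- rbind(a = c(1, 2, 3.05), b = c(1, 2, 3.1), c = c(9, 2, 1),
             d = c(8, 3, 1.2))
  colnames(m) <- paste0("s", 1:3)
  ed <- mutual_rank(pairwise_pcc(m))
  mr_ab <- ed$mr[ed$gene_a == "a" & ed$gene_b == "b"]
  expect_equal(mr_ab, 1)
  expect_true(all(ed$mr >= 1))
  # ranks 1 and 4 give MR 2 by definition
  expect_equal(sqrt(1 * 4), 2)
})

test_that("mutual rank equals brute-force double ranking", {
  for (n in c(3, 5, 8, 10)) {
    cc <- random_corr(n, seed = 100 + n)
    fast <- mutual_rank(cc)
    slow <- naive_mutual_rank(cc)
    o <- order(fast$gene_a, fast$gene_b)
    os <- order(slow$gene_a, slow$gene_b)
    expect_equal(fast$mr[o], slow$mr[os], label = sprintf("n=%d", n))
    expect_equal(fast$pcc[o], slow$pcc[os])
  }
})

test_that("top-k retention follows the union rule", {
  # k >= n-1 keeps the complete graph
  cc <- random_corr(6, seed = 1)
  ed <- mutual_rank(cc)
  g <- build_topk_network(ed, k = 5)
  expect_equal(igraph::ecount(g), choose(6, 2))

  # every node keeps at least its own top-k: no isolated nodes
  cc <- random_corr(12, seed = 2)
  g1 <- build_topk_network(mutual_rank(cc), k = 1)
  expect_true(all(igraph::degree(g1) >= 1))

  # matches the naive per-gene retention on random instances
  for (s in 1:5) {
    cc <- random_corr(9, seed = 200 + s)
    ed <- mutual_rank(cc)
    fast <- network_edge_table(build_topk_network(ed, k = 3))
    slow <- naive_topk_edges(ed, k = 3)
    key <- function(d) sort(paste(pmin(d$gene_a, d$gene_b),
                                  pmax(d$gene_a, d$gene_b)))
    expect_equal(key(fast), key(slow))
  }
})

test_that("seeded subnetworks contain seeds plus direct neighbors", {
  # star: hub h connected to leaves
  ed <- data.frame(gene_a = "h", gene_b = paste0("l", 1:4),
                   pcc = 0.9, mr = 1:4)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  sub <- extract_subnetwork(g, "h")
  expect_setequal(igraph::V(sub)$name, c("h", paste0("l", 1:4)))
  # leaf seed pulls in only the hub
  sub2 <- extract_subnetwork(g, "l1")
  expect_setequal(igraph::V(sub2)$name, c("l1", "h"))
  # all nodes as seeds reproduce the whole network
  sub3 <- extract_subnetwork(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(sub3), igraph::ecount(g))
  # unknown seeds are skipped with a message
  expect_message(extract_subnetwork(g, c("h", "zz")), "skipping")
})
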