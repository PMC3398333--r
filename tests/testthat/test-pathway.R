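test_that("KO aggregation sums members exactly", {
  cat <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    length_bp = c(500L, 500L, 1000L, 800L),
                    ko_id = c("K00001", "K00001", "K00002", NA))
  m <- matrix(c(10L, 20L, 5L, 7L,
                30L, 40L, 6L, 8L,
                50L, 60L, 7L, 9L), nrow = 4,
              dimnames = list(cat$gene_id, c("stage1", "stage2", "stage3")))
  cm <- count_matrix(m, c(stage1 = 1e5, stage2 = 1e5, stage3 = 1e5))
  rpkm <- compute_rpkm(cm, cat)
  fam <- aggregate_by_ko(rpkm, cm, cat)
  expect_equal(fam$ko_id, c("K00001", "K00002"))
  expect_equal(fam$n_members, c(2L, 1L))
  expect_equal(fam$count_stage1, c(10 + 20, 5))
  expect_equal(fam$count_stage3, c(50 + 60, 7))
  expect_equal(fam$rpkm_stage2, unname(c(sum(rpkm[1:2, "stage2"]),
                                         rpkm[3, "stage2"])))
  expect_setequal(fam$members[[1]], c("g1", "g2"))
  # single-member family equals the gene itself
  expect_equal(fam$rpkm_stage1[2], unname(rpkm["g3", "stage1"]))
})

test_that("aggregation matches a naive group-by oracle on synthetic data", {
  st <- tiny_study(n_genes = 300, seed = 8)
  rpkm <- compute_rpkm(st$counts, st$catalog)
  fam <- aggregate_by_ko(rpkm, st$counts, st$catalog)
  ann <- st$catalog[!is.na(st$catalog$ko_id), ]
  for (ko in sample(fam$ko_id, min(10, nrow(fam)))) {
    members <- ann$gene_id[ann$ko_id == ko]
    expect_equal(fam$rpkm_stage2[fam$ko_id == ko],
                 sum(rpkm[members, "stage2"]))
    expect_equal(fam$count_stage3[fam$ko_id == ko],
                 sum(st$counts$counts[members, "stage3"]))
  }
})

test_that("aggregation without KO annotation warns and returns empty", {
  st <- tiny_study(n_genes = 50, seed = 4, ko_fraction = 0)
  rpkm <- compute_rpkm(st$counts, st$catalog)
  expect_warning(fam <- aggregate_by_ko(rpkm, st$counts, st$catalog),
                 "no KO")
  expect_equal(nrow(fam), 0)
})

test_that("family regulation distinguishes none, up, down and irregular", {
  mk_fam <- function(c1, c2, c3, n_pad = 60) {
    # pad with stable families so BH adjustment behaves as in real tables
    data.frame(ko_id = sprintf("K%05d", seq_len(n_pad + 1)),
               n_members = 1L,
               rpkm_stage1 = c(c1, rep(50, n_pad)) / 10,
               rpkm_stage2 = c(c2, rep(50, n_pad)) / 10,
               rpkm_stage3 = c(c3, rep(50, n_pad)) / 10,
               count_stage1 = c(c1, rep(500, n_pad)),
               count_stage2 = c(c2, rep(500, n_pad)),
               count_stage3 = c(c3, rep(500, n_pad)))
  }
  cm <- count_matrix(matrix(1L, 1, 3, dimnames = list("g", paste0("stage", 1:3))),
                     c(stage1 = 1e6, stage2 = 1e6, stage3 = 1e6))
  reg <- function(f) as.character(classify_family_regulation(f, cm)$regulation[1])
  expect_equal(reg(mk_fam(500, 520, 505)), "none")
  expect_equal(reg(mk_fam(100, 420, 1600)), "up")
  expect_equal(reg(mk_fam(1600, 420, 100)), "down")
  expect_equal(reg(mk_fam(100, 900, 110)), "irregular")
  # one significant transition is enough for a direction call
  expect_equal(reg(mk_fam(100, 450, 460)), "up")
})

test_that("family regulation is coherent with member-level screening", {
  st <- tiny_study(n_genes = 500, seed = 55, de_fraction = 0.2,
                   effect_log2_choices = c(3, 4))
  rpkm <- compute_rpkm(st$counts, st$catalog)
  fam <- aggregate_by_ko(rpkm, st$counts, st$catalog)
  fam <- classify_family_regulation(fam, st$counts)
  de12 <- de_test(st$counts, st$catalog, "stage1", "stage2")
  de23 <- de_test(st$counts, st$catalog, "stage2", "stage3")
  up_members <- intersect(de12$gene_id[de12$significant & de12$log2_ratio > 0],
                          de23$gene_id[de23$significant & de23$log2_ratio > 0])
  all_up <- vapply(seq_len(nrow(fam)), function(i) {
    length(fam$members[[i]]) > 0 && all(fam$members[[i]] %in% up_members)
  }, logical(1))
  expect_false(any(fam$regulation[all_up] == "down"))
})

test_that("pathway selection export colors by magnitude bin and regulation", {
  fam <- data.frame(ko_id = c("K00001", "K00002"),
                    rpkm_stage1 = c(5, 3000),
                    regulation = factor(c("up", "none"),
                                        levels = c("none", "up", "down",
                                                   "irregular")))
  lines <- export_pathway_selection(fam, mode = "magnitude",
                                    stage = "stage1")
  expect_match(lines[2], paste0("K00001 ", magnitude_palette()[1], " W10"),
               fixed = TRUE)
  expect_match(lines[3], paste0("K00002 ", magnitude_palette()[10], " W10"),
               fixed = TRUE)
  lines2 <- export_pathway_selection(fam, mode = "change")
  expect_match(lines2[2], regulation_palette()[["up"]], fixed = TRUE)
  # empty input yields only the header comment
  empty <- export_pathway_selection(fam[0, ], mode = "change")
  expect_length(empty, 1)
  expect_match(empty, "^#")
  tf <- withr::local_tempfile(fileext = ".txt")
  export_pathway_selection(fam, tf, mode = "magnitude", stage = "stage1")
  expect_equal(length(readLines(tf)), 3)
})
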