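test_that("catalog generation honors cardinality, lengths and KO coverage", {
  cfg <- tiny_config(n_genes = 3, seed = 1)
  cat3 <- generate_catalog(cfg)
  expect_equal(nrow(cat3), 3)
  expect_equal(anyDuplicated(cat3$gene_id), 0)

  no_ko <- generate_catalog(tiny_config(n_genes = 50, ko_fraction = 0))
  expect_true(all(is.na(no_ko$ko_id)))

  cfg <- tiny_config(n_genes = 10000, seed = 3)
  big <- generate_catalog(cfg)
  expect_true(all(big$length_bp >= 100))
  # mean within 3 SE of the configured truncated-normal mean; truncation at
  # 100 bp shifts the 531/250 normal mean by ~+2 bp, inside the band
  se <- cfg$length_sd_bp / sqrt(nrow(big))
  expect_lt(abs(mean(big$length_bp) - 531), 3 * se + 3)

  expect_error(simulation_config(n_genes = 0), "positive")
})

test_that("count simulation is deterministic and respects planted truth", {
  a <- tiny_study(seed = 11)
  b <- tiny_study(seed = 11)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  null <- tiny_study(seed = 5, de_fraction = 0)
  expect_length(null$truth$de_genes, 0)

  st <- tiny_study(seed = 9, de_fraction = 0.2)
  expect_true(all(st$truth$de_genes %in% st$catalog$gene_id))
  expect_equal(length(st$truth$de_genes), round(0.2 * 200))
  expect_setequal(unique(unname(st$truth$direction)),
                  intersect(c("up", "down", "irregular"),
                            unique(unname(st$truth$direction))))
  expect_true(all(st$truth$effect_log2 > 0))

  expect_error(simulate_counts(data.frame(), tiny_config()), "empty")
})

test_that("null column sums stay within sampling noise of library totals", {
  cfg <- simulation_config(
    n_genes = 2000,
    library_totals = c(mixed = 1e6, stage1 = 1e6, stage2 = 1e6,
                       stage3 = 1e6),
    de_fraction = 0, seed = 21)
  st <- simulate_counts(generate_catalog(cfg), cfg)
  sums <- colSums(st$counts$counts)
  # Poisson column sum has mean N, sd sqrt(N)
  expect_true(all(abs(sums - 1e6) < 3 * sqrt(1e6)))
})

test_that("planted trajectories are geometric across stages in expectation", {
  cfg <- simulation_config(
    n_genes = 3000,
    library_totals = c(mixed = 1e6, stage1 = 1e6, stage2 = 1e6,
                       stage3 = 1e6),
    seed = 13, de_fraction = 0.1, effect_log2_choices = 3)
  st <- list(catalog = generate_catalog(cfg))
  sim <- simulate_counts(st$catalog, cfg)
  up <- names(sim$truth$direction)[sim$truth$direction == "up"]
  up <- up[sim$truth$stage1_expected_count[up] > 20]
  null_genes <- setdiff(st$catalog$gene_id, sim$truth$de_genes)
  null_genes <- null_genes[sim$truth$stage1_expected_count[null_genes] > 20]
  step <- function(genes, s1, s2) {
    m <- sim$counts$counts[genes, , drop = FALSE]
    median(log2(pmax(m[, s2], 1) / pmax(m[, s1], 1)))
  }
  # planted log2 step relative to the unplanted background (which absorbs
  # the per-library renormalization) is the configured +3 at every stage
  expect_lt(abs(step(up, "stage1", "stage2") -
                  step(null_genes, "stage1", "stage2") - 3), 0.5)
  expect_lt(abs(step(up, "stage2", "stage3") -
                  step(null_genes, "stage2", "stage3") - 3), 0.5)
})

test_that("overdispersed counts exceed Poisson variance", {
  base <- simulation_config(n_genes = 4000,
                            library_totals = c(mixed = 2e6, stage1 = 2e6,
                                               stage2 = 2e6, stage3 = 2e6),
                            de_fraction = 0, seed = 31)
  od <- base; od$dispersion <- 0.5
  cat0 <- generate_catalog(base)
  stages <- c("mixed", "stage1", "stage2", "stage3")
  # under the null all four libraries share each gene's expected count, so
  # the per-gene variance-to-mean ratio across libraries estimates the
  # dispersion index: ~1 for Poisson, 1 + dispersion * mu for gamma-Poisson
  disp_index <- function(m) {
    mu <- rowMeans(m)
    keep <- mu > 5
    mean(apply(m[keep, ], 1, var) / mu[keep])
  }
  pois <- disp_index(simulate_counts(cat0, base)$counts$counts[, stages])
  gp <- disp_index(simulate_counts(cat0, od)$counts$counts[, stages])
  expect_lt(abs(pois - 1), 0.2)
  expect_gt(gp, 5)
})

test_that("colorimetry simulation is reproducible with forced cardinality", {
  a <- simulate_colorimetry(stages = 3, fruits_per_stage = 10,
                            reps_per_fruit = 4, seed = 2)
  b <- simulate_colorimetry(stages = 3, fruits_per_stage = 10,
                            reps_per_fruit = 4, seed = 2)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 10 * 4)
  expect_equal(sum(a$stage == 2), 40)

  quietd <- simulate_colorimetry(stages = 2, fruits_per_stage = 3,
                                 reps_per_fruit = 5, noise_sd = 0, seed = 1)
  one <- quietd[quietd$stage == 1 & quietd$fruit == 2, ]
  expect_equal(length(unique(one$L_star)), 1)

  expect_error(simulate_colorimetry(stages = 0), ">= 1")
})
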