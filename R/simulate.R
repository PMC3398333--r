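#' Simulation configuration for the synthetic ripening study
#'
#' Defines the conditions under which synthetic UniGene catalogs and
#' tag-count libraries are generated: four libraries (one mixed-tissue
#' reference plus three ordered ripening stages) of about 5.3 million clean
#' reads each, gene lengths of a few hundred bp, a lognormal baseline
#' expression distribution, and a planted differentially expressed subset
#' with geometric stage trajectories.
#'
#' @param n_genes Number of UniGenes.
#' @param library_totals Positive clean-read totals, one per library. The
#'   first library is the mixed-tissue reference, the rest the ordered
#'   ripening stages.
#' @param length_mean_bp,length_sd_bp Mean and sd of the normal gene-length
#'   distribution, truncated below at 100 bp and rounded to integers.
#' @param baseline_log_mean,baseline_log_sd Meanlog and sdlog of the
#'   lognormal baseline expression distribution (arbitrary units; only the
#'   relative proportions matter).
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param effect_log2_choices Nonzero log2 per-stage effect steps sampled for
#'   planted genes.
#' @param profile_mix Named proportions over `up`, `down`, `irregular`
#'   summing to 1.
#' @param dispersion Gamma-Poisson overdispersion; 0 gives Poisson counts.
#' @param ko_fraction Fraction of genes carrying a KO (KEGG Orthology) id.
#' @param n_ko_families Size of the synthetic KO vocabulary, so several genes
#'   share each family.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 40000,
                              library_totals = c(mixed = 5.3e6,
                                                 stage1 = 5.3e6,
                                                 stage2 = 5.3e6,
                                                 stage3 = 5.3e6),
                              length_mean_bp = 531,
                              length_sd_bp = 250,
                              baseline_log_mean = 0,
                              baseline_log_sd = 1.5,
                              de_fraction = 0.1,
                              effect_log2_choices = c(1, 2, 3, 4),
                              profile_mix = c(up = 0.25, down = 0.40,
                                              irregular = 0.35),
                              dispersion = 0,
                              ko_fraction = 0.3,
                              n_ko_families = 400,
                              seed = 1) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    stop("'n_genes' must be a positive integer", call. = FALSE)
  }
  if (any(library_totals <= 0)) {
    stop("'library_totals' must all be positive", call. = FALSE)
  }
  if (length(library_totals) < 2) {
    stop("at least one mixed and one stage library are required",
         call. = FALSE)
  }
  if (is.null(names(library_totals))) {
    names(library_totals) <- c("mixed",
                               paste0("stage", seq_along(library_totals)[-1] - 1))
  }
  stopifnot(length_mean_bp > 0, length_sd_bp > 0,
            de_fraction >= 0, de_fraction <= 1,
            all(effect_log2_choices != 0),
            dispersion >= 0, ko_fraction >= 0, ko_fraction <= 1)
  profile_mix <- profile_mix[c("up", "down", "irregular")]
  if (any(is.na(profile_mix)) || abs(sum(profile_mix) - 1) > 1e-8) {
    stop("'profile_mix' must give proportions for up, down and irregular summing to 1",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 library_totals = library_totals,
                 length_mean_bp = length_mean_bp, length_sd_bp = length_sd_bp,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 de_fraction = de_fraction,
                 effect_log2_choices = effect_log2_choices,
                 profile_mix = profile_mix,
                 dispersion = dispersion,
                 ko_fraction = ko_fraction,
                 n_ko_families = as.integer(n_ko_families),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic UniGene catalog
#'
#' Draws unique gene ids, integer lengths from a truncated normal
#' distribution (minimum 100 bp), and assigns KO ids to a `ko_fraction`
#' subset from a small synthetic vocabulary so families have several members.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `gene_id`, `length_bp`, `ko_id` (NA when
#'   unannotated) and `label`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  # shift the pre-truncation location so the truncated-normal mean lands on
  # length_mean_bp despite the 100 bp floor
  mu <- config$length_mean_bp
  sd <- config$length_sd_bp
  for (it in 1:20) {
    z <- (100 - mu) / sd
    mu_new <- config$length_mean_bp -
      sd * stats::dnorm(z) / stats::pnorm(z, lower.tail = FALSE)
    if (abs(mu_new - mu) < 1e-8) break
    mu <- mu_new
  }
  len <- round(stats::rnorm(n, mu, sd))
  # redraw sub-minimum lengths rather than clamping (exact truncated draw)
  while (any(len < 100)) {
    i <- which(len < 100)
    len[i] <- round(stats::rnorm(length(i), mu, sd))
  }
  ko <- rep(NA_character_, n)
  n_ko <- round(config$ko_fraction * n)
  if (n_ko > 0) {
    idx <- sample.int(n, n_ko)
    vocab <- sprintf("K%05d", seq_len(config$n_ko_families))
    ko[idx] <- sample(vocab, n_ko, replace = TRUE)
  }
  data.frame(gene_id = sprintf("UG%06d", seq_len(n)),
             length_bp = as.integer(len),
             ko_id = ko,
             label = NA_character_,
             stringsAsFactors = FALSE)
}

# Per-gene multipliers across the stage libraries for one planted gene.
# Trajectories are geometric (constant log2 step per stage transition) and
# centered on their geometric mean so the planted subset perturbs profile
# shapes without inflating any single library's composition.
.stage_multipliers <- function(direction, effect_log2, n_stages, flip) {
  steps <- switch(direction,
    up = rep(effect_log2, n_stages - 1),
    down = rep(-effect_log2, n_stages - 1),
    irregular = {
      half <- (n_stages - 1) %/% 2
      s <- c(rep(effect_log2, n_stages - 1 - half), rep(-effect_log2, half))
      if (flip) -s else s
    })
  m <- 2^cumsum(c(0, steps))
  m / exp(mean(log(m)))
}

#' Simulate tag counts with planted differential expression
#'
#' Draws per-library counts with expected value `N * p_g`, where `p_g` is
#' proportional to baseline expression x stage effect multiplier x gene
#' length, normalized per library. Planted `up` genes multiply their
#' expression by `2^effect` at each successive stage, `down` genes divide,
#' and `irregular` genes rise then fall (or the reverse); each trajectory is
#' centered on its geometric mean so planting changes profile shapes, not
#' overall library composition. The mixed-tissue library carries no effect
#' multipliers. `dispersion = 0` gives Poisson counts; `dispersion > 0`
#' gamma-mixed (overdispersed) counts.
#'
#' @param catalog Catalog from [generate_catalog()].
#' @param config The same [simulation_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (a
#'   `simulation_truth` object recording planted genes, directions, effects
#'   and expected stage-1 counts).
#' @export
simulate_counts <- function(catalog, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- nrow(catalog)
  libs <- names(config$library_totals)
  n_stages <- length(libs) - 1L

  base <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  direction <- character(0)
  effect <- numeric(0)
  mult <- matrix(1, n, n_stages)
  if (n_de > 0) {
    direction <- sample(names(config$profile_mix), n_de, replace = TRUE,
                        prob = config$profile_mix)
    choices <- abs(config$effect_log2_choices)
    effect <- choices[sample.int(length(choices), n_de, replace = TRUE)]
    flip <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
    for (j in seq_len(n_de)) {
      mult[de_idx[j], ] <- .stage_multipliers(direction[j], effect[j],
                                              n_stages, flip[j])
    }
  }

  weight_base <- base * catalog$length_bp
  counts <- matrix(0, n, length(libs),
                   dimnames = list(catalog$gene_id, libs))
  mu1 <- NULL
  for (ell in seq_along(libs)) {
    w <- if (ell == 1) weight_base else weight_base * mult[, ell - 1L]
    p <- w / sum(w)
    lambda <- config$library_totals[ell] * p
    if (ell == 2) mu1 <- lambda
    if (config$dispersion > 0) {
      shape <- 1 / config$dispersion
      lambda <- stats::rgamma(n, shape = shape, rate = shape / lambda)
    }
    counts[, ell] <- stats::rpois(n, lambda)
  }

  truth <- structure(list(de_genes = catalog$gene_id[de_idx],
                          direction = stats::setNames(direction,
                                                      catalog$gene_id[de_idx]),
                          effect_log2 = stats::setNames(effect,
                                                        catalog$gene_id[de_idx]),
                          stage1_expected_count = stats::setNames(mu1,
                                                                  catalog$gene_id),
                          seed = config$seed),
                     class = "simulation_truth")

  cm <- count_matrix(counts, config$library_totals,
                     stage_libraries = libs[-1], mixed_library = libs[1])
  list(counts = cm, truth = truth)
}

#' Simulate CIELAB colorimeter readings over ripening
#'
#' Emulates repeated colorimeter measurements of ripening fruit: per stage,
#' `fruits_per_stage` fruit are each measured `reps_per_fruit` times. Stage
#' mean trajectories darken (falling L*) and redden (rising a*, falling b*),
#' so the CIRG index increases with stage; replicates add Gaussian noise.
#'
#' @param stages Number of ripening stages (>= 1; trajectories are
#'   interpolated across them).
#' @param fruits_per_stage,reps_per_fruit Positive counts.
#' @param noise_sd Gaussian measurement noise sd applied to each channel.
#' @param seed Integer seed.
#' @return Data frame with columns `stage`, `fruit`, `replicate`, `L_star`,
#'   `a_star`, `b_star`.
#' @export
simulate_colorimetry <- function(stages = 3, fruits_per_stage = 10,
                                 reps_per_fruit = 4, noise_sd = 1,
                                 seed = 1) {
  if (stages < 1 || fruits_per_stage < 1 || reps_per_fruit < 1) {
    stop("'stages', 'fruits_per_stage' and 'reps_per_fruit' must be >= 1",
         call. = FALSE)
  }
  set.seed(seed)
  # endpoint means: unripe (light, yellow-green tinge) -> dark red
  ends <- rbind(L = c(30, 15), a = c(14, 13), b = c(20, 2.5))
  frac <- if (stages == 1) 0 else (seq_len(stages) - 1) / (stages - 1)
  means <- apply(ends, 1, function(e) e[1] + frac * (e[2] - e[1]))
  means <- matrix(means, nrow = stages,
                  dimnames = list(NULL, c("L", "a", "b")))
  # mid-ripening chroma swings red before darkening completes
  if (stages >= 3) means[-c(1, stages), "a"] <- means[-c(1, stages), "a"] + 6

  grid <- expand.grid(replicate = seq_len(reps_per_fruit),
                      fruit = seq_len(fruits_per_stage),
                      stage = seq_len(stages))[, 3:1]
  fruit_eff <- matrix(stats::rnorm(stages * fruits_per_stage * 3,
                                   sd = noise_sd),
                      ncol = 3)
  fi <- (grid$stage - 1) * fruits_per_stage + grid$fruit
  noise <- matrix(stats::rnorm(nrow(grid) * 3, sd = noise_sd / 2), ncol = 3)
  data.frame(stage = grid$stage, fruit = grid$fruit,
             replicate = grid$replicate,
             L_star = means[grid$stage, "L"] + fruit_eff[fi, 1] + noise[, 1],
             a_star = means[grid$stage, "a"] + fruit_eff[fi, 2] + noise[, 2],
             b_star = means[grid$stage, "b"] + fruit_eff[fi, 3] + noise[, 3])
}
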