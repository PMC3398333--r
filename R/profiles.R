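#' Sign-quadrant expression-profile groups
#'
#' Classifies a differentially expressed gene from its two consecutive
#' stage-to-stage log2 RPKM ratios `r1` (stage2/stage1) and `r2`
#' (stage3/stage2) into four groups: I (up-regulated, both ratios >= 0),
#' II and III (irregular: up-then-down and down-then-up), IV (down-regulated,
#' both <= 0). A ratio of exactly 0 satisfies both signs, so ties are
#' resolved by the fixed precedence I > II > III > IV, making the four groups
#' a partition of the plane.
#'
#' @param r1,r2 Finite numeric vectors of log2 ratios (recycled).
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @examples
#' classify_profile(c(1, -1, 0), c(2, -1, 0))  # I, IV, I
#' @export
classify_profile <- function(r1, r2) {
  if (any(!is.finite(r1)) || any(!is.finite(r2))) {
    stop("'r1' and 'r2' must be finite", call. = FALSE)
  }
  n <- max(length(r1), length(r2))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  g <- ifelse(r1 >= 0 & r2 >= 0, "I",
       ifelse(r1 >= 0 & r2 <= 0, "II",
       ifelse(r1 <= 0 & r2 >= 0, "III", "IV")))
  factor(g, levels = c("I", "II", "III", "IV"))
}

#' Profile assignment table for a DE gene set
#'
#' Computes `r1 = log2(RPKM_stage2 / RPKM_stage1)` and
#' `r2 = log2(RPKM_stage3 / RPKM_stage2)` (zeros floored) and the group of
#' each gene.
#'
#' @param rpkm RPKM matrix with the three stage columns.
#' @param genes Gene ids to classify (default: all rows).
#' @param stages The three ordered stage column names (default: first three
#'   columns of `rpkm` if not named by a count matrix).
#' @param rpkm_floor Floor substituted for zero RPKM (default 0.01).
#' @return Data frame `gene_id`, `r1`, `r2`, `group`.
#' @export
profile_assignments <- function(rpkm, genes = rownames(rpkm),
                                stages = colnames(rpkm)[seq_len(3)],
                                rpkm_floor = 0.01) {
  stopifnot(length(stages) == 3, all(stages %in% colnames(rpkm)))
  m <- pmax(rpkm[genes, stages, drop = FALSE], rpkm_floor)
  r1 <- log2(m[, 2] / m[, 1])
  r2 <- log2(m[, 3] / m[, 2])
  data.frame(gene_id = genes, r1 = r1, r2 = r2,
             group = classify_profile(r1, r2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Visualization filter on maximum fold change
#'
#' Retains genes whose largest absolute stage-to-stage log2 ratio stays below
#' `log2(max_fold)`; genes changing 32-fold (2^5) or more between any two
#' consecutive stages are excluded from the global visualization (they remain
#' in group counts).
#'
#' @param assignments Data frame from [profile_assignments()] (columns `r1`,
#'   `r2`, `gene_id`).
#' @param max_fold Fold-change bound (default 32).
#' @return Character vector of retained gene ids.
#' @export
filter_for_visualization <- function(assignments, max_fold = 32) {
  if (nrow(assignments) == 0) return(character(0))
  keep <- pmax(abs(assignments$r1), abs(assignments$r2)) < log2(max_fold)
  assignments$gene_id[keep]
}

#' K-means clustering of expression trajectories
#'
#' Groups DE-gene trajectories into `k` clusters of similar expression
#' trends. Rows are log2(RPKM + 1)-transformed and standardized per gene
#' (constant rows map to zero), then clustered by Euclidean k-means with 10
#' random restarts, keeping the best objective; deterministic given `seed`.
#'
#' @param rpkm RPKM matrix restricted to the genes to cluster, with the stage
#'   columns.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param stages Stage column names (default: all columns).
#' @return Named integer vector of cluster indices in `1..k`, one per gene.
#' @export
kmeans_profiles <- function(rpkm, k = 10, seed = 1,
                            stages = colnames(rpkm)) {
  m <- rpkm[, stages, drop = FALSE]
  if (nrow(m) < k) {
    stop(sprintf("need at least k = %d genes, got %d", k, nrow(m)),
         call. = FALSE)
  }
  z <- log2(m + 1)
  mu <- rowMeans(z)
  sd <- apply(z, 1, stats::sd)
  z <- (z - mu) / ifelse(sd > 0, sd, 1)
  set.seed(seed)
  fit <- stats::kmeans(z, centers = k, nstart = 10, iter.max = 100)
  stats::setNames(fit$cluster, rownames(m))
}
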