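#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * n / j)`, restored to input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted FDR values in `(0, 1]`, same order as the input.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Exact-test differential expression between two libraries
#'
#' Runs the exact two-library test gene by gene between two libraries of a
#' count matrix, computes the log2 RPKM ratio (library 2 over library 1, with
#' an RPKM floor substituted for zeros so ratios stay finite), adjusts
#' p-values across genes by Benjamini-Hochberg, and flags significance at
#' `FDR < fdr_threshold` (strict) and `|log2Ratio| >= lfc_threshold`.
#'
#' @param counts A [count_matrix()].
#' @param catalog Catalog data frame with `gene_id` and `length_bp`.
#' @param lib1,lib2 Library (column) ids to compare; the ratio and test are
#'   oriented `lib2` vs `lib1`.
#' @param fdr_threshold Strict FDR cutoff (default 0.001).
#' @param lfc_threshold Non-strict absolute log2-ratio cutoff (default 1).
#' @param rpkm_floor Value substituted for zero RPKM in the ratio
#'   (default 0.01).
#' @return Data frame of class `de_result`: `gene_id`, `x`, `y`, `rpkm1`,
#'   `rpkm2`, `log2_ratio`, `p`, `fdr`, `significant`, with the comparison in
#'   `attr(, "comparison")`.
#' @export
de_test <- function(counts, catalog, lib1, lib2,
                    fdr_threshold = 0.001, lfc_threshold = 1,
                    rpkm_floor = 0.01) {
  stopifnot(inherits(counts, "count_matrix"),
            lib1 %in% colnames(counts$counts),
            lib2 %in% colnames(counts$counts))
  rpkm <- compute_rpkm(counts, catalog)
  x <- counts$counts[, lib1]
  y <- counts$counts[, lib2]
  n1 <- counts$library_totals[[lib1]]
  n2 <- counts$library_totals[[lib2]]
  p <- two_sided_p(x, y, n1, n2)
  lfc <- log2(pmax(rpkm[, lib2], rpkm_floor) / pmax(rpkm[, lib1], rpkm_floor))
  res <- data.frame(gene_id = rownames(counts$counts),
                    x = as.integer(x), y = as.integer(y),
                    rpkm1 = rpkm[, lib1], rpkm2 = rpkm[, lib2],
                    log2_ratio = lfc, p = p,
                    fdr = adjust_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- screen_de(res, fdr_threshold, lfc_threshold)
  attr(res, "comparison") <- c(lib1, lib2)
  class(res) <- c("de_result", class(res))
  res
}

#' Significance screen for differential expression
#'
#' Sets the `significant` flag: `fdr < fdr_threshold` (strict inequality) and
#' `|log2_ratio| >= lfc_threshold` (non-strict), as the screening rule is
#' stated.
#'
#' @param results Data frame with columns `fdr` and `log2_ratio`.
#' @param fdr_threshold,lfc_threshold Cutoffs (defaults 0.001 and 1).
#' @return `results` with a logical `significant` column (re)computed.
#' @export
screen_de <- function(results, fdr_threshold = 0.001, lfc_threshold = 1) {
  stopifnot(all(c("fdr", "log2_ratio") %in% names(results)))
  results$significant <- results$fdr < fdr_threshold &
    abs(results$log2_ratio) >= lfc_threshold
  results
}

#' Union of significant genes over pairwise comparisons
#'
#' @param ... `de_result` data frames (or a single list of them), or
#'   character vectors of gene ids.
#' @return Character vector: the union of significant gene ids, in first-seen
#'   order.
#' @export
union_pairwise <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  ids <- lapply(parts, function(p) {
    if (is.data.frame(p)) p$gene_id[p$significant] else as.character(p)
  })
  unique(unlist(ids, use.names = FALSE))
}

#' All pairwise stage comparisons of a count matrix
#'
#' Runs [de_test()] for every ordered pair of successive-and-skipping stage
#' libraries (stage1-vs-2, 1-vs-3, 2-vs-3 for three stages); the mixed
#' library, if any, is excluded.
#'
#' @inheritParams de_test
#' @return Named list of `de_result` data frames, names like
#'   `"stage1_vs_stage2"`.
#' @export
de_all_pairs <- function(counts, catalog, fdr_threshold = 0.001,
                         lfc_threshold = 1, rpkm_floor = 0.01) {
  stages <- counts$stage_libraries
  pairs <- utils::combn(stages, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    de_test(counts, catalog, pr[1], pr[2], fdr_threshold, lfc_threshold,
            rpkm_floor)
  })
  names(res) <- vapply(pairs, function(pr) paste0(pr[1], "_vs_", pr[2]), "")
  res
}
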