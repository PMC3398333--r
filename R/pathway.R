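#' Aggregate expression to KEGG-Orthology families
#'
#' Sums RPKM and raw mapped-read counts over all catalog members sharing a KO
#' id, per stage library. Genes without a KO id are ignored.
#'
#' @param rpkm RPKM matrix (genes x libraries).
#' @param counts A [count_matrix()].
#' @param catalog Catalog data frame with `gene_id` and `ko_id`.
#' @return Data frame with one row per KO: `ko_id`, `n_members`,
#'   `rpkm_<stage>` and `count_<stage>` columns for each stage library, and a
#'   `members` list-column of member gene ids.
#' @export
aggregate_by_ko <- function(rpkm, counts, catalog) {
  stopifnot(inherits(counts, "count_matrix"))
  stages <- counts$stage_libraries
  annotated <- catalog[!is.na(catalog$ko_id), c("gene_id", "ko_id")]
  annotated <- annotated[annotated$gene_id %in% rownames(rpkm), ]
  if (nrow(annotated) == 0) {
    warning("no KO-annotated genes; returning empty aggregation",
            call. = FALSE)
    out <- data.frame(ko_id = character(0), n_members = integer(0))
    for (s in stages) out[[paste0("rpkm_", s)]] <- numeric(0)
    for (s in stages) out[[paste0("count_", s)]] <- numeric(0)
    out$members <- list()
    return(out)
  }
  kos <- sort(unique(annotated$ko_id))
  f <- factor(annotated$ko_id, levels = kos)
  sum_by <- function(m) {
    rowsum(m[annotated$gene_id, stages, drop = FALSE], f)
  }
  rs <- sum_by(rpkm)
  cs <- sum_by(counts$counts)
  out <- data.frame(ko_id = kos,
                    n_members = as.integer(table(f)),
                    stringsAsFactors = FALSE)
  for (s in stages) out[[paste0("rpkm_", s)]] <- rs[, s]
  for (s in stages) out[[paste0("count_", s)]] <- cs[, s]
  out$members <- unname(split(annotated$gene_id, f))
  out
}

#' Classify the regulation of KO families over ripening
#'
#' Runs the exact two-library test on the family's summed raw counts for each
#' successive stage transition (stage1 to 2, stage2 to 3), with
#' Benjamini-Hochberg adjustment across families per transition, at the same
#' screen as for single genes (`FDR < fdr_threshold` and summed-RPKM
#' `|log2 ratio| >= lfc_threshold`). Families with no significant transition
#' are `none`; families whose significant transitions all rise are `up`, all
#' fall `down`, and disagreeing signs `irregular`.
#'
#' @param families Data frame from [aggregate_by_ko()].
#' @param counts The [count_matrix()] the families were aggregated from
#'   (provides library totals and stage order).
#' @param fdr_threshold,lfc_threshold,rpkm_floor As in [de_test()].
#' @return `families` with added columns `regulation` (factor none/up/down/
#'   irregular) and per-transition `p_`/`fdr_`/`lfc_` columns.
#' @export
classify_family_regulation <- function(families, counts,
                                       fdr_threshold = 0.001,
                                       lfc_threshold = 1,
                                       rpkm_floor = 0.01) {
  stages <- counts$stage_libraries
  totals <- counts$library_totals
  if (nrow(families) == 0) {
    families$regulation <- factor(character(0),
                                  levels = c("none", "up", "down", "irregular"))
    return(families)
  }
  sig_dir <- matrix(0, nrow(families), length(stages) - 1)
  for (t in seq_len(length(stages) - 1)) {
    s1 <- stages[t]; s2 <- stages[t + 1]
    x <- round(families[[paste0("count_", s1)]])
    y <- round(families[[paste0("count_", s2)]])
    p <- two_sided_p(x, y, totals[[s1]], totals[[s2]])
    fdr <- adjust_fdr(p)
    lfc <- log2(pmax(families[[paste0("rpkm_", s2)]], rpkm_floor) /
                  pmax(families[[paste0("rpkm_", s1)]], rpkm_floor))
    sig <- fdr < fdr_threshold & abs(lfc) >= lfc_threshold
    tag <- paste0(s1, "_", s2)
    families[[paste0("p_", tag)]] <- p
    families[[paste0("fdr_", tag)]] <- fdr
    families[[paste0("lfc_", tag)]] <- lfc
    sig_dir[, t] <- ifelse(sig, sign(lfc), 0)
  }
  reg <- apply(sig_dir, 1, function(d) {
    d <- d[d != 0]
    if (length(d) == 0) "none"
    else if (all(d > 0)) "up"
    else if (all(d < 0)) "down"
    else "irregular"
  })
  families$regulation <- factor(reg,
                                levels = c("none", "up", "down", "irregular"))
  families
}

#' Fixed 10-entry blue-to-red magnitude palette
#'
#' Hex colors indexing the 10 RPKM magnitude bins of
#' [assign_expression_bin()], coolest blue (bin 1) to warmest red (bin 10).
#'
#' @return Character vector of 10 hex colors.
#' @export
magnitude_palette <- function() {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(10)
}

#' Regulation-class colors for pathway maps
#'
#' Green for no significant change, red for up-regulated, blue for
#' down-regulated and yellow for irregular regulation.
#'
#' @return Named character vector of 4 hex colors.
#' @export
regulation_palette <- function() {
  c(none = "#1B9E77", up = "#D62728", down = "#1F77B4", irregular = "#E6B800")
}

#' Export a pathway-map selection file
#'
#' Writes one line per KO family in the three-column selection dialect
#' accepted by interactive pathway viewers: KO id, hex color, line-width
#' token. In `magnitude` mode the color indexes the 10-bin scale of the
#' stage-1 family RPKM; in `change` mode it encodes the regulation class.
#'
#' @param families Classified family table from
#'   [classify_family_regulation()].
#' @param path Output file path (or `""` for a character vector return).
#' @param mode `"magnitude"` or `"change"`.
#' @param stage Stage library whose RPKM drives the magnitude view (default:
#'   first `rpkm_` column).
#' @param width Line-width token (default `"W10"`).
#' @return Invisibly, the selection lines.
#' @export
export_pathway_selection <- function(families, path = "",
                                     mode = c("magnitude", "change"),
                                     stage = NULL, width = "W10") {
  mode <- match.arg(mode)
  header <- sprintf("# pathway selection (%s view)", mode)
  if (nrow(families) == 0) {
    lines <- header
  } else if (mode == "magnitude") {
    rpkm_cols <- grep("^rpkm_", names(families), value = TRUE)
    col <- if (is.null(stage)) rpkm_cols[1] else paste0("rpkm_", stage)
    stopifnot(col %in% names(families))
    bins <- assign_expression_bin(families[[col]])
    lines <- c(header,
               sprintf("%s %s %s", families$ko_id,
                       magnitude_palette()[bins], width))
  } else {
    stopifnot("regulation" %in% names(families))
    lines <- c(header,
               sprintf("%s %s %s", families$ko_id,
                       regulation_palette()[as.character(families$regulation)],
                       width))
  }
  if (nzchar(path)) {
    writeLines(lines, path)
    invisible(lines)
  } else {
    invisible(lines)
  }
}
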