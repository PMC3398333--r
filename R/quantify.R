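#' RPKM normalization of a tag-count matrix
#'
#' Converts raw mapped clean-read counts to RPKM (reads per kilobase of
#' transcript per million mapped reads):
#' \deqn{\mathrm{RPKM}_{g\ell} = \frac{10^9 \, c_{g\ell}}{N_\ell \, L_g}}
#' where `c` is the raw count, `N` the library's total clean reads and `L`
#' the gene length in bp.
#'
#' @param counts A count matrix object from [count_matrix()] (or
#'   [simulate_counts()]).
#' @param catalog A UniGene catalog data frame with columns `gene_id` and
#'   `length_bp`; every gene in `counts` must be present.
#' @return Numeric matrix of RPKM values, genes x libraries, with the same
#'   dimnames as the count matrix.
#' @examples
#' cat <- data.frame(gene_id = "g1", length_bp = 1000)
#' cm <- count_matrix(matrix(100, 1, 1, dimnames = list("g1", "lib1")),
#'                    library_totals = c(lib1 = 1e6))
#' compute_rpkm(cm, cat)  # 100
#' @export
compute_rpkm <- function(counts, catalog) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- rownames(counts$counts)
  missing <- setdiff(genes, catalog$gene_id)
  if (length(missing) > 0) {
    stop("genes missing from catalog: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  len <- catalog$length_bp[match(genes, catalog$gene_id)]
  rpkm <- 1e9 * sweep(counts$counts, 2, counts$library_totals, "/") / len
  dimnames(rpkm) <- dimnames(counts$counts)
  rpkm
}

#' Map RPKM magnitude to the 10-bin expression scale
#'
#' Bands are 0-10, 10-20, 20-40, 40-80, 80-160, 160-320, 320-640, 640-1280,
#' 1280-2560 and over 2560, indexed 1 to 10. Intervals are half-open
#' `[lo, hi)`; the top bin is `[2560, Inf)`.
#'
#' @param rpkm Nonnegative numeric vector of RPKM values.
#' @return Integer bin indices in `1..10`.
#' @examples
#' assign_expression_bin(c(0, 15, 2560))  # 1, 2, 10
#' @export
assign_expression_bin <- function(rpkm) {
  if (any(!is.finite(rpkm)) || any(rpkm < 0)) {
    stop("'rpkm' must be finite and nonnegative", call. = FALSE)
  }
  edges <- c(0, 10 * 2^(0:8), Inf)
  bin <- findInterval(rpkm, edges, rightmost.closed = FALSE)
  as.integer(pmin(bin, 10L))
}

#' Construct a tag-count matrix container
#'
#' Bundles a genes x libraries matrix of raw mapped-read counts with the
#' per-library totals of clean reads (the `N1`/`N2` denominators of the exact
#' test and of RPKM), and records which libraries are the ordered ripening
#' stages versus an optional mixed-tissue reference library.
#'
#' @param counts Nonnegative integer matrix, genes in rows (rownames are gene
#'   ids), libraries in columns (colnames are library ids).
#' @param library_totals Named positive numeric vector, one total per column
#'   of `counts`.
#' @param stage_libraries Character vector of column names that are the
#'   ordered ripening-stage libraries. Defaults to all columns.
#' @param mixed_library Optional column name of a mixed-tissue library that
#'   is quantified but excluded from stage comparisons.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_totals,
                         stage_libraries = colnames(counts),
                         mixed_library = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have gene rownames and library colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  library_totals <- library_totals[colnames(counts)]
  if (any(is.na(library_totals)) || any(library_totals <= 0)) {
    stop("'library_totals' must name every library with a positive total",
         call. = FALSE)
  }
  bad <- counts > rep(library_totals, each = nrow(counts))
  if (any(bad)) stop("a gene count exceeds its library total", call. = FALSE)
  stopifnot(all(stage_libraries %in% colnames(counts)),
            is.null(mixed_library) || mixed_library %in% colnames(counts))
  structure(list(counts = counts, library_totals = library_totals,
                 stage_libraries = stage_libraries,
                 mixed_library = mixed_library),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  stages:", paste(x$stage_libraries, collapse = ", "), "\n")
  if (!is.null(x$mixed_library)) cat("  mixed: ", x$mixed_library, "\n")
  cat("  totals:", paste(format(x$library_totals, big.mark = ","),
                         collapse = ", "), "\n")
  invisible(x)
}
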