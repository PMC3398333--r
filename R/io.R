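#' Read and write pipeline tables
#'
#' All interchange is plain tab-separated text with a header row.
#' `write_counts()` stores the count matrix as `<stem>.tsv` (gene_id plus one
#' column per library) and the per-library clean-read totals and roles as
#' `<stem>_libraries.tsv`; `read_counts()` reassembles the pair into a
#' [count_matrix()].
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv()` a data frame; writers return the path invisibly.
#' @export
write_tsv <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list], vapply, paste, "", collapse = ",")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @param counts A [count_matrix()].
#' @param stem Path stem (no extension) for the count-matrix file pair.
#' @export
write_counts <- function(counts, stem) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene_id = rownames(counts$counts),
                   counts$counts, check.names = FALSE)
  write_tsv(df, paste0(stem, ".tsv"))
  role <- ifelse(colnames(counts$counts) %in% counts$stage_libraries,
                 "stage", "other")
  if (!is.null(counts$mixed_library)) {
    role[colnames(counts$counts) == counts$mixed_library] <- "mixed"
  }
  libs <- data.frame(library_id = colnames(counts$counts),
                     total_reads = unname(counts$library_totals),
                     role = role)
  write_tsv(libs, paste0(stem, "_libraries.tsv"))
  invisible(stem)
}

#' @rdname write_tsv
#' @export
read_counts <- function(stem) {
  df <- read_tsv(paste0(stem, ".tsv"))
  libs <- read_tsv(paste0(stem, "_libraries.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  mixed <- libs$library_id[libs$role == "mixed"]
  count_matrix(m,
               stats::setNames(libs$total_reads, libs$library_id),
               stage_libraries = libs$library_id[libs$role == "stage"],
               mixed_library = if (length(mixed)) mixed[1] else NULL)
}
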