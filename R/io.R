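#' Read a gene x sample count matrix from TSV
#'
#' Expects genes in rows (first column = gene id) and a header row of sample
#' ids.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  .check_counts(m)
}

#' Write a count matrix as TSV
#' @param counts genes x samples matrix.
#' @param path output file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Requires columns \code{sample}, \code{genotype}, \code{treatment} (and
#' optionally \code{replicate}).
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "genotype", "treatment")
  if (!all(req %in% names(df)))
    stop("design file needs columns: ", paste(req, collapse = ", "))
  df
}

#' Write a contrast result as TSV
#' @param result a \code{contrast_result}.
#' @param path output file path.
#' @export
write_contrast_tsv <- function(result, path) {
  cols <- c("gene", "baseMean", "log2FoldChange", "lfcSE", "stat",
            "pvalue", "padj")
  utils::write.table(result[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
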