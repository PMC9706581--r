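#' Construct an expression matrix with an explicit scale tag
#'
#' A thin wrapper around a numeric genes x samples matrix that records whether
#' values are TPM (linear scale) or log-normalized. The tag exists so that the
#' log transform cannot be applied twice silently and so that scoring functions
#' can insist on the scale they are defined on.
#'
#' @param mat Numeric matrix, genes in rows (unique rownames = gene symbols),
#'   samples in columns (unique colnames = sample IDs).
#' @param scale Either `"tpm"` (non-negative linear values) or `"log"`.
#' @return The matrix with class `expr_matrix` and attribute `scale_tag`.
#' @export
expression_matrix <- function(mat, scale = c("tpm", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("'mat' must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicated gene symbols in expression matrix rows", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicated sample IDs in expression matrix columns", call. = FALSE)
  }
  if (anyNA(mat)) stop("expression matrix contains NA values", call. = FALSE)
  if (scale == "tpm" && any(mat < 0)) {
    stop("TPM expression matrix contains negative values", call. = FALSE)
  }
  structure(mat, scale_tag = scale, class = c("expr_matrix", class(mat)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  invisible(x)
}

expr_scale <- function(expr) {
  attr(expr, "scale_tag") %||% stop(
    "expression matrix has no scale tag; build it with expression_matrix()",
    call. = FALSE
  )
}

#' Log-normalize a TPM expression matrix
#'
#' Applies `log2(x + 1)` elementwise, the conventional log-normalization for
#' TPM before rank-based enrichment scoring. Refuses to transform a matrix
#' already tagged as log scale.
#'
#' @param expr An [expression_matrix()] tagged `"tpm"`.
#' @return The matrix on log scale, tagged `"log"`.
#' @export
log_normalize <- function(expr) {
  if (!inherits(expr, "expr_matrix")) {
    stop("'expr' must be an expression_matrix()", call. = FALSE)
  }
  if (expr_scale(expr) != "tpm") {
    stop("expression matrix is already log scale; refusing to transform twice",
         call. = FALSE)
  }
  out <- log2(unclass(expr) + 1)
  expression_matrix(out, scale = "log")
}

#' Write / read an expression matrix as TSV
#'
#' Genes x samples, first column `gene`, header row of sample IDs.
#'
#' @param expr An [expression_matrix()].
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @param scale Scale tag to attach on read (`"tpm"` or `"log"`).
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, scale = c("tpm", "log")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) {
    stop("expression TSV must have a 'gene' first column", call. = FALSE)
  }
  mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(mat) <- df$gene
  expression_matrix(mat, scale = scale)
}
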