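#' Construct an expression dataset
#'
#' Bundles a normalized (log2-scale) genes-by-samples matrix with a binary
#' phenotype label per sample. This is the container every downstream stage
#' consumes: differential expression, diagnostic screening and classification.
#'
#' @param mat numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames), values on log2 scale.
#' @param labels character vector of length `ncol(mat)` with values `"case"`
#'   or `"control"`; recycled names are taken from `colnames(mat)`.
#' @param name dataset identifier used in reports.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `gene_ids`, `sample_labels` and `name`.
#' @examples
#' m <- matrix(rnorm(30), nrow = 5,
#'             dimnames = list(paste0("G", 1:5), paste0("S", 1:6)))
#' ds <- expression_dataset(m, rep(c("case", "control"), each = 3), "toy")
#' @export
expression_dataset <- function(mat, labels, name = "dataset") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_invalid("`mat` must be a numeric matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_invalid("gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop_invalid("sample identifiers (colnames) must be present and unique")
  labels <- as.character(labels)
  if (length(labels) != ncol(mat))
    stop_invalid("need one label per sample: got %d labels for %d samples",
                 length(labels), ncol(mat))
  if (!all(labels %in% c("case", "control")))
    stop_invalid("labels must be 'case' or 'control'")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 3L))
    stop_invalid("each phenotype needs at least 3 samples")
  names(labels) <- colnames(mat)
  structure(
    list(matrix = mat, gene_ids = rownames(mat), sample_labels = labels,
         name = as.character(name)[1L]),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(x$sample_labels)
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%d case / %d control)\n",
              x$name, nrow(x$matrix), ncol(x$matrix),
              tab[["case"]], tab[["control"]]))
  invisible(x)
}
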