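#' Read an expression matrix and its phenotype labels from TSV files
#'
#' The expression file has the gene identifier in the first column and one
#' column per sample; the label file has columns `sample` and `phenotype`
#' (`case`/`control`). Samples are matched by identifier; the expression
#' columns are reordered to the label file if needed.
#'
#' @param expr_path,labels_path file paths.
#' @param name dataset identifier (default: expression file stem).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(expr_path, labels_path,
                            name = sub("\\.[^.]*$", "", basename(expr_path))) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_invalid("expression file needs gene + sample columns")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(tab[[1]])
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "phenotype") %in% names(lab)))
    stop_invalid("label file needs 'sample' and 'phenotype' columns")
  missing <- setdiff(lab$sample, colnames(mat))
  if (length(missing) > 0)
    stop_invalid("labeled sample(s) absent from expression matrix: %s",
                 paste(utils::head(missing, 3), collapse = ", "))
  mat <- mat[, lab$sample, drop = FALSE]
  expression_dataset(mat, lab$phenotype, name)
}

#' Read a survival table (`sample`, `time_days`, `event`)
#'
#' @param path TSV path.
#' @return data.frame with validated columns; `event` coerced to 0/1.
#' @export
read_survival <- function(path) {
  surv <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time_days", "event") %in% names(surv)))
    stop_invalid("survival file needs 'sample', 'time_days', 'event' columns")
  if (any(surv$time_days < 0)) stop_invalid("negative follow-up time")
  if (!all(surv$event %in% c(0, 1)))
    stop_invalid("event indicator must be 0 (censored) or 1 (death)")
  surv$event <- as.integer(surv$event)
  surv
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_invalid("empty GMT file: %s", path)
  sets <- lapply(strsplit(lines, "\t"), function(x) {
    if (length(x) < 3) stop_invalid("GMT line with fewer than 3 fields")
    unique(trimws(x[-(1:2)]))
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' Read a bipartite regulator-target table (TRRUST-style TSV)
#'
#' First column regulator (TF or receptor), second column target gene;
#' extra columns (mode of regulation, PMIDs, ...) are ignored, as are
#' `#`-comment lines. A header line is detected and skipped when its first
#' two fields are the literal column names.
#'
#' @param path TSV path.
#' @return data.frame `feature`, `gene` with duplicate pairs removed.
#' @export
read_bipartite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_invalid("empty network file: %s", path)
  parts <- strsplit(lines, "\t")
  if (any(vapply(parts, length, 1L) < 2L))
    stop_invalid("bipartite network lines need >= 2 columns")
  first <- tolower(trimws(parts[[1]][1:2]))
  if (all(first %in% c("feature", "tf", "receptor", "regulator",
                       "gene", "target", "partner")))
    parts <- parts[-1]
  edges <- data.frame(
    feature = vapply(parts, function(x) trimws(x[1]), ""),
    gene = vapply(parts, function(x) trimws(x[2]), ""),
    stringsAsFactors = FALSE)
  unique(edges)
}
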