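#' Case-control expression datasets
#'
#' An `expression_dataset` couples a genes-by-samples matrix of expression
#' values (log2 intensities for microarray, log2 counts-per-million for
#' RNA-seq) with a case/control condition for every sample, the measurement
#' platform, and the identifier of the dataset's target pathway (the disease
#' pathway the dataset is paired with in the benchmark).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param condition named character vector mapping each sample id to
#'   `"case"` or `"control"`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param target_pathway pathway id the dataset targets (may be `NA`).
#' @param id dataset identifier.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, condition, platform = "microarray",
                               target_pathway = NA_character_,
                               id = "dataset") {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("expression matrix needs gene rownames and sample colnames")
  platform <- match.arg(platform, c("microarray", "rnaseq"))
  samples <- colnames(values)
  if (!all(samples %in% names(condition)))
    stop_fmt("sample missing from design: %s",
             samples[!samples %in% names(condition)][1])
  condition <- condition[samples]
  bad <- !condition %in% c("case", "control")
  if (any(bad))
    stop_fmt("unknown condition label '%s' for sample %s",
             condition[bad][1], samples[bad][1])
  if (length(unique(condition)) < 2)
    stop_fmt("both case and control samples are required")
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na)) {
    warn_fmt("dropping %d gene(s) with entirely missing values", sum(all_na))
    values <- values[!all_na, , drop = FALSE]
  }
  structure(
    list(id = id, values = values,
         genes = rownames(values), samples = samples,
         condition = condition, platform = platform,
         target_pathway = target_pathway),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d genes x %d samples (%d case / %d control), %s\n",
              x$id, nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control"),
              x$platform))
  if (!is.na(x$target_pathway))
    cat(sprintf("  target pathway: %s\n", x$target_pathway))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix and its design file
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample. The design TSV has columns `sample` and `condition`
#' (case/control); optional comment header lines `# platform: ...`,
#' `# target_pathway: ...` and `# id: ...` carry dataset metadata.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param design_path path to the design TSV.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, design_path) {
  mat <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"

  hdr <- readLines(design_path, warn = FALSE)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(design)))
    stop_fmt("design file needs columns sample, condition")
  missing <- setdiff(design$sample, colnames(mat))
  if (length(missing))
    stop_fmt("design sample absent from matrix: %s", missing[1])
  condition <- stats::setNames(design$condition, design$sample)
  expression_dataset(mat[, design$sample, drop = FALSE], condition,
                     platform = meta$platform %||% "microarray",
                     target_pathway = meta$target_pathway %||% NA_character_,
                     id = meta$id %||% basename(matrix_path))
}

#' Write an expression dataset as matrix + design TSVs
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,design_path output file paths.
#' @export
write_expression <- function(dataset, matrix_path, design_path) {
  df <- data.frame(gene = dataset$genes, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(design_path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# id: %s", dataset$id),
               sprintf("# platform: %s", dataset$platform),
               sprintf("# target_pathway: %s", dataset$target_pathway)), con)
  utils::write.table(data.frame(sample = dataset$samples,
                                condition = unname(dataset$condition)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}
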