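## TSV interchange formats.
## Expression: header row of sample ids, first column `gene_id`, one row per
## gene. Design: columns sample_id, treatment, replicate. Numeric values are
## written with 17 significant digits so read(write(x)) round-trips exactly.

fmt_num <- function(x) sprintf("%.17g", x)

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("file not found:", path))
  if (file.size(path) == 0) stop_field("path", paste("empty file:", path))
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write an expression matrix as TSV
#'
#' @param path file path. The file must have a `gene_id` first column and
#'   one numeric column per sample.
#' @return `read_expression_tsv`: numeric matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L || names(df)[1] != "gene_id") {
    stop_field("path", "expected a 'gene_id' column followed by sample columns")
  }
  ids <- as.character(df[[1]])
  dup <- anyDuplicated(ids)
  if (dup) {
    stop_field("path", sprintf("duplicate gene id '%s' (line %d)", ids[dup], dup + 1L))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop_field("path", sprintf("non-numeric value in column '%s' (line %d)",
                                 names(vals)[j], bad + 1L))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname read_expression_tsv
#' @param m numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(m, path) {
  check_expression_matrix(m, "m", require_cols = 1L)
  df <- data.frame(gene_id = rownames(m),
                   apply(m, 2L, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a factorial design table as TSV
#'
#' @param path file path with columns `sample_id`, `treatment`, `replicate`.
#' @return `read_design_tsv`: validated design data.frame.
#' @export
read_design_tsv <- function(path) {
  df <- read_tsv_checked(path)
  validate_design(df)
  df$treatment <- as.character(df$treatment)
  df
}

#' @rdname read_design_tsv
#' @param design design data.frame.
#' @export
write_design_tsv <- function(design, path) {
  design <- validate_design(design)
  design$treatment <- as.character(design$treatment)
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic per-gene table (e.g. truth or synergy tables) as TSV
#'
#' Numeric columns are written at full precision.
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best-effort reader for a GEO series-matrix file
#'
#' Extracts the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a (decompressed) GEO series matrix into the package's standard
#' expression-matrix form. Sample-to-treatment assignment is *not*
#' inferred; build the design table from the accession's metadata yourself.
#'
#' @param path path to a decompressed series matrix TXT file.
#' @return numeric matrix, probe/gene ids as rownames, GSM ids as colnames.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop_field("path", "no series matrix table block found")
  }
  block <- lines[(beg + 1L):(end - 1L)]
  df <- utils::read.delim(text = block, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}
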