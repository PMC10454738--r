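# Registered TSV schemas for the evidence tables the pipeline consumes.
# Each entry: required columns and their types ("chr" or "num"); extra columns
# are preserved. "expression_matrix" is special-cased (gene column + numeric
# sample grid of arbitrary width).
.table_schemas <- list(
  interaction_scores = c(lncrna = "chr", protein = "chr",
                         protein_transcript = "chr", score = "num",
                         cancer_type = "chr"),
  rpi_scores         = c(lncrna = "chr", protein = "chr",
                         rf_score = "num", svm_score = "num"),
  compartments       = c(symbol = "chr", compartments = "chr"),
  cn_expression      = c(symbol = "chr", cytoplasmic = "num", nuclear = "num"),
  expression_labels  = c(gene_symbol = "chr", label = "chr"),
  band_intensities   = c(lane = "chr", condition = "chr",
                         full_length_intensity = "num", stop_intensity = "num"),
  gene_map           = c(transcript_id = "chr", gene_symbol = "chr"),
  oligos             = c(name = "chr", sequence = "chr", reference_g_score = "num")
)

#' Read and validate a tab-separated evidence table
#'
#' The header must contain every column of the registered schema
#' (`interaction_scores`, `rpi_scores`, `compartments`, `cn_expression`,
#' `expression_labels`, `expression_matrix`, `band_intensities`, `gene_map`,
#' `oligos`); numeric columns are parsed with `.` as the decimal separator and
#' unparseable cells are reported with their row number. Row order is
#' preserved.
#'
#' @param path TSV path (UTF-8, header row).
#' @param schema_name one of the registered schema names.
#' @return data.frame with typed columns.
#' @export
read_table <- function(path, schema_name) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (identical(schema_name, "expression_matrix")) {
    return(.parse_expression_matrix(raw, path))
  }
  schema <- .table_schemas[[schema_name]]
  if (is.null(schema)) {
    stop(sprintf("unknown table schema '%s' (registered: %s)", schema_name,
                 paste(c(names(.table_schemas), "expression_matrix"), collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing column(s) %s; expected header: %s",
                 schema_name, paste(missing, collapse = ", "),
                 paste(names(schema), collapse = "\t")), call. = FALSE)
  }
  for (col in names(schema)[schema == "num"]) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & nzchar(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("schema '%s': unparseable numeric cell '%s' in column '%s', row %d",
                   schema_name, raw[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (identical(schema_name, "expression_labels")) {
    vocab <- c("upregulated", "downregulated", "differential")
    bad <- which(!raw$label %in% vocab)
    if (length(bad)) {
      stop(sprintf("expression label '%s' (row %d) not in {%s}", raw$label[bad[1]],
                   bad[1], paste(vocab, collapse = ", ")), call. = FALSE)
    }
  }
  raw
}

.parse_expression_matrix <- function(raw, path) {
  if (ncol(raw) < 2L) {
    stop(sprintf("expression_matrix '%s' needs a gene column plus >=1 sample column", path),
         call. = FALSE)
  }
  genes <- raw[[1L]]
  vals <- raw[-1L]
  for (col in names(vals)) {
    num <- suppressWarnings(as.numeric(vals[[col]]))
    bad <- which(is.na(num) & nzchar(vals[[col]]))
    if (length(bad)) {
      stop(sprintf("expression_matrix: unparseable numeric cell '%s' in column '%s', row %d",
                   vals[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    vals[[col]] <- num
  }
  out <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE), vals)
  names(out)[1] <- names(raw)[1]
  out
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
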