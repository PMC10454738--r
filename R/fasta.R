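#' Read transcript records from a FASTA file
#'
#' Headers follow the convention `transcript_id|gene_symbol`; when the `|`
#' field is absent the gene symbol falls back to the transcript id. A mapping
#' table (`transcript_id`, `gene_symbol`) may override the header convention
#' for FASTA dialects that carry no gene field. Sequences are normalized to
#' the `{A,C,G,T}` alphabet via [normalize_alphabet()] unless `normalize =
#' FALSE`. Entry order is preserved; an empty file yields a zero-row table.
#'
#' @param path FASTA file path.
#' @param gene_map optional data.frame (or TSV path) with columns
#'   `transcript_id`, `gene_symbol` overriding header-derived gene symbols.
#' @param source_tag provenance label recorded for every record.
#' @param normalize normalize sequences (default TRUE).
#' @return data.frame with columns `transcript_id`, `gene_symbol`, `sequence`,
#'   `source_tags` (semicolon-joined set), `length_nt`.
#' @export
read_fasta <- function(path, gene_map = NULL, source_tag = NA_character_,
                       normalize = TRUE) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(transcript_records(character(0), character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a '>' header", nonblank[1]),
         call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  headers <- names(set)
  ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[`, character(1), 1L)
  genes <- vapply(strsplit(headers, "|", fixed = TRUE), function(x) {
    if (length(x) >= 2L && nzchar(x[2L])) x[2L] else x[1L]
  }, character(1))
  ids <- trimws(ids); genes <- trimws(genes)
  seqs <- as.character(set)
  if (normalize) {
    seqs <- vapply(seq_along(seqs), function(i) {
      tryCatch(normalize_alphabet(seqs[i]),
               error = function(e) stop(sprintf("record '%s': %s", ids[i],
                                                conditionMessage(e)), call. = FALSE))
    }, character(1))
  }
  rec <- transcript_records(ids, genes, seqs, source_tag)
  if (!is.null(gene_map)) {
    if (is.character(gene_map)) gene_map <- read_table(gene_map, "gene_map")
    idx <- match(rec$transcript_id, gene_map$transcript_id)
    hit <- !is.na(idx)
    rec$gene_symbol[hit] <- gene_map$gene_symbol[idx[hit]]
  }
  rec
}

#' Construct a transcript-record table
#'
#' @param transcript_id,gene_symbol,sequence character vectors of equal length.
#' @param source_tags provenance tag(s), recycled; multiple tags per record are
#'   semicolon-joined.
#' @return data.frame of transcript records.
#' @export
transcript_records <- function(transcript_id, gene_symbol, sequence,
                               source_tags = NA_character_) {
  stopifnot(length(transcript_id) == length(gene_symbol),
            length(gene_symbol) == length(sequence))
  data.frame(
    transcript_id = as.character(transcript_id),
    gene_symbol = as.character(gene_symbol),
    sequence = as.character(sequence),
    source_tags = rep_len(as.character(source_tags), length(transcript_id)),
    length_nt = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

#' Write transcript records to FASTA
#'
#' Headers are written as `transcript_id|gene_symbol`, so
#' `read_fasta(write_fasta(x))` round-trips ids, gene symbols and sequences.
#'
#' @param records transcript-record data.frame from [read_fasta()] or
#'   [transcript_records()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- paste0(records$transcript_id, "|", records$gene_symbol)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
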