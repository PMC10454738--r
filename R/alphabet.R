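#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases the input, maps U to T and strips all whitespace. The scanner is
#' alphabet-agnostic over G-runs, so RNA oligonucleotides are handled in the
#' DNA alphabet; RNA-ness is metadata, not sequence content. Any character
#' outside `{A,C,G,T,U}` (including IUPAC ambiguity codes such as N) is
#' rejected with the offending symbol and its 1-based position in the
#' whitespace-stripped sequence.
#'
#' @param raw_sequence character scalar; may contain lowercase, U, whitespace.
#' @return character scalar over `{A,C,G,T}`.
#' @examples
#' normalize_alphabet("gggUUAggg")     # "GGGTTAGGG"
#' normalize_alphabet("GGG TTA GGG")   # "GGGTTAGGG"
#' @export
normalize_alphabet <- function(raw_sequence) {
  stopifnot(is.character(raw_sequence), length(raw_sequence) == 1L)
  s <- gsub("[[:space:]]", "", raw_sequence)
  s <- toupper(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U"))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (alphabet is A/C/G/T/U)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  chartr("U", "T", s)
}
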