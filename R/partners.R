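#' Rank lncRNA-protein interaction scores (top-down channel)
#'
#' Interaction-score tables are treated as ordinal evidence: rows are sorted
#' by descending score with a deterministic `(lncrna, protein)` lexicographic
#' tie-break, and duplicate `(lncrna, protein, score)` rows are collapsed.
#'
#' @param scores data.frame with columns `lncrna`, `protein`, `score` (and
#'   optionally `protein_transcript`, `cancer_type`).
#' @return sorted, deduplicated data.frame; empty input yields zero rows.
#' @export
rank_topdown <- function(scores) {
  if (nrow(scores) == 0L) return(scores)
  if (any(scores$score < 0)) stop("interaction scores must be >= 0", call. = FALSE)
  key <- paste(scores$lncrna, scores$protein, scores$score)
  scores <- scores[!duplicated(key), , drop = FALSE]
  out <- scores[order(-scores$score, scores$lncrna, scores$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter classifier score pairs (bottom-up channel)
#'
#' Retains pairs whose random-forest and SVM interaction probabilities both
#' exceed the threshold (strict inequality; a score of exactly 0.5 is
#' rejected at the default threshold). `mode = "either"` relaxes the
#' requirement to one classifier.
#'
#' @param pairs data.frame with columns `lncrna`, `protein`, `rf_score`,
#'   `svm_score`, both scores in `[0, 1]`.
#' @param threshold probability cutoff in `(0, 1)`, default 0.5.
#' @param mode `"both"` (default) or `"either"`.
#' @return subset of `pairs`.
#' @export
filter_bottomup <- function(pairs, threshold = 0.5, mode = c("both", "either")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  if (any(pairs$rf_score < 0 | pairs$rf_score > 1 |
          pairs$svm_score < 0 | pairs$svm_score > 1)) {
    stop("rf_score and svm_score must lie in [0, 1]", call. = FALSE)
  }
  keep <- if (mode == "both") {
    pairs$rf_score > threshold & pairs$svm_score > threshold
  } else {
    pairs$rf_score > threshold | pairs$svm_score > threshold
  }
  out <- pairs[keep, , drop = FALSE]
  qgr_log("bottomup", nrow(pairs), nrow(out))
  out
}

#' Expression covariation between two genes
#'
#' Pearson correlation over the samples where both genes have finite values
#' (the covariation heatmaps this emulates describe linear correlation on a
#' -1..+1 scale).
#'
#' @param matrix expression matrix data.frame: first column gene identifiers,
#'   remaining columns numeric sample values.
#' @param gene_a,gene_b gene identifiers present in the matrix.
#' @return list with `gene_a`, `gene_b`, `r`, `n`.
#' @export
covariation <- function(matrix, gene_a, gene_b) {
  genes <- matrix[[1L]]
  for (g in c(gene_a, gene_b)) {
    if (!g %in% genes) stop(sprintf("gene '%s' not present in expression matrix", g),
                            call. = FALSE)
  }
  xa <- as.numeric(matrix[match(gene_a, genes), -1L, drop = TRUE])
  xb <- as.numeric(matrix[match(gene_b, genes), -1L, drop = TRUE])
  ok <- is.finite(xa) & is.finite(xb)
  if (sum(ok) < 3L) stop("covariation requires >= 3 shared finite samples", call. = FALSE)
  xa <- xa[ok]; xb <- xb[ok]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop(sprintf("correlation undefined: zero variance for '%s'",
                 if (stats::sd(xa) == 0) gene_a else gene_b), call. = FALSE)
  }
  list(gene_a = gene_a, gene_b = gene_b,
       r = stats::cor(xa, xb, method = "pearson"), n = sum(ok))
}

# Controlled compartment vocabulary and the parent mapping used for
# convergence: sub-compartments collapse to nucleus or cytoplasm.
.compartment_parent <- c(
  nucleus = "nucleus", nucleoplasm = "nucleus", nucleoli = "nucleus",
  cytoplasm = "cytoplasm", cytosol = "cytoplasm", perinuclear = "cytoplasm"
)

.parse_compartments <- function(x) {
  parts <- tolower(trimws(unlist(strsplit(x, ";", fixed = TRUE))))
  parts <- parts[nzchar(parts)]
  bad <- setdiff(parts, names(.compartment_parent))
  if (length(bad)) {
    stop(sprintf("unknown compartment '%s' (vocabulary: %s)", bad[1],
                 paste(names(.compartment_parent), collapse = ", ")), call. = FALSE)
  }
  unique(unname(.compartment_parent[parts]))
}

#' Annotate pairs with subcellular colocalization
#'
#' Binding requires the lncRNA and the protein to occupy convergent
#' compartments; convergence is evaluated at parent level (nucleoplasm and
#' nucleoli count as nucleus; cytosol and perinuclear as cytoplasm) because
#' localization resources mix granularities. A symbol absent from its
#' compartment table yields a warning and `NA` (excluded from downstream
#' calls).
#'
#' @param pairs data.frame with columns `lncrna`, `protein`.
#' @param lnc_compartments,protein_compartments data.frames with columns
#'   `symbol`, `compartments` (semicolon-separated vocabulary terms).
#' @return `pairs` with a logical `colocalized` column.
#' @export
colocalization_filter <- function(pairs, lnc_compartments, protein_compartments) {
  lookup <- function(tab, symbol, what) {
    i <- match(symbol, tab$symbol)
    if (is.na(i)) {
      warning(sprintf("no compartment annotation for %s '%s'", what, symbol),
              call. = FALSE)
      return(NULL)
    }
    .parse_compartments(tab$compartments[i])
  }
  pairs$colocalized <- vapply(seq_len(nrow(pairs)), function(i) {
    lc <- lookup(lnc_compartments, pairs$lncrna[i], "lncRNA")
    pc <- lookup(protein_compartments, pairs$protein[i], "protein")
    if (is.null(lc) || is.null(pc)) return(NA)
    length(intersect(lc, pc)) > 0L
  }, logical(1))
  pairs
}

#' Integrate evidence channels into partner calls
#'
#' Takes the union of `(lncrna, protein)` pairs across the top-down ranking,
#' the filtered bottom-up pairs and the colocalization annotation, and counts
#' the evidence channels supporting each pair (0-3: top-down score present,
#' bottom-up pass, colocalized). Pairs whose colocalization is unknown (`NA`)
#' are kept but contribute no colocalization evidence.
#'
#' @param topdown ranked interaction table ([rank_topdown()]) or NULL.
#' @param bottomup filtered score pairs ([filter_bottomup()]) or NULL.
#' @param colocalization pairs annotated by [colocalization_filter()] or NULL.
#' @return data.frame `lncrna`, `protein`, `topdown_score`, `bottomup_pass`,
#'   `colocalized`, `evidence_count`, sorted by descending evidence count then
#'   descending top-down score.
#' @export
call_partners <- function(topdown = NULL, bottomup = NULL, colocalization = NULL) {
  pair_key <- function(df) if (is.null(df) || nrow(df) == 0L) character(0) else
    paste(df$lncrna, df$protein, sep = "\r")
  keys <- unique(c(pair_key(topdown), pair_key(bottomup), pair_key(colocalization)))
  if (!length(keys)) {
    return(data.frame(lncrna = character(0), protein = character(0),
                      topdown_score = numeric(0), bottomup_pass = logical(0),
                      colocalized = logical(0), evidence_count = integer(0)))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(lncrna = parts[, 1], protein = parts[, 2],
                    stringsAsFactors = FALSE)
  k <- paste(out$lncrna, out$protein, sep = "\r")
  out$topdown_score <- if (is.null(topdown)) NA_real_ else {
    idx <- match(k, pair_key(topdown))
    ifelse(is.na(idx), NA_real_, topdown$score[idx])
  }
  out$bottomup_pass <- k %in% pair_key(bottomup)
  out$colocalized <- if (is.null(colocalization)) NA else {
    colocalization$colocalized[match(k, pair_key(colocalization))]
  }
  out$evidence_count <- as.integer(!is.na(out$topdown_score)) +
    as.integer(out$bottomup_pass) +
    as.integer(!is.na(out$colocalized) & out$colocalized)
  ord <- order(-out$evidence_count, -ifelse(is.na(out$topdown_score), -Inf,
                                            out$topdown_score),
               out$lncrna, out$protein)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
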