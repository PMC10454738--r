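#' Collapse identical transcript variants and drop conflicting entries
#'
#' Within a gene, records with byte-identical sequences are merged into one
#' record whose `source_tags` is the union of the merged tags. When the same
#' `transcript_id` is reported with two different sequences (typically by two
#' source databases), confidence in the sequence architecture is low: all
#' records for that id are dropped and the conflict is logged. The operation
#' is idempotent.
#'
#' @param records transcript-record data.frame.
#' @return deduplicated transcript-record data.frame, first-occurrence order.
#' @export
collapse_identical <- function(records) {
  n_in <- nrow(records)
  if (n_in == 0L) return(records)
  seq_per_id <- tapply(records$sequence, records$transcript_id,
                       function(s) length(unique(s)))
  conflicts <- names(seq_per_id)[seq_per_id > 1L]
  if (length(conflicts)) {
    qgr_log("collapse/conflicts", n_in, n_in - sum(records$transcript_id %in% conflicts))
    records <- records[!records$transcript_id %in% conflicts, , drop = FALSE]
  }
  key <- paste(records$gene_symbol, records$sequence, sep = "\r")
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    first <- records[idx[1L], , drop = FALSE]
    tags <- unlist(strsplit(records$source_tags[idx], ";", fixed = TRUE))
    tags <- unique(tags[!is.na(tags) & nzchar(tags) & tags != "NA"])
    first$source_tags <- if (length(tags)) paste(tags, collapse = ";") else NA_character_
    first
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  qgr_log("collapse", n_in, nrow(out))
  out
}

#' Group deduplicated transcripts into gene-level lncRNA clusters
#'
#' Every lncRNA gene together with all its transcript variants forms one
#' cluster — the unit of analysis for PQS summaries. Clusters are sorted by
#' gene symbol; member order within a cluster is preserved.
#'
#' @param records deduplicated transcript-record data.frame.
#' @return named list of clusters; each cluster is a list with `gene_symbol`
#'   and `members` (transcript-record data.frame).
#' @export
build_clusters <- function(records) {
  if (nrow(records) == 0L) return(structure(list(), names = character(0)))
  genes <- sort(unique(records$gene_symbol))
  out <- lapply(genes, function(g) {
    list(gene_symbol = g,
         members = records[records$gene_symbol == g, , drop = FALSE])
  })
  names(out) <- genes
  qgr_log("cluster", nrow(records), length(out))
  out
}

#' Summarize PQS content of one cluster
#'
#' @param cluster a cluster from [build_clusters()].
#' @param hits hit table from [scan_transcripts()] over the cluster members.
#' @param labels optional expression-label table (`gene_symbol`, `label`);
#'   an absent gene yields a warning and `NA` expression.
#' @return the cluster with `pqs_isoform_count` (distinct members with at
#'   least one hit), `max_g_score` (`NA` when no member has a hit) and
#'   `expression` attached.
#' @export
summarize_cluster <- function(cluster, hits, labels = NULL) {
  mine <- hits[hits$transcript_id %in% cluster$members$transcript_id, , drop = FALSE]
  cluster$pqs_isoform_count <- length(unique(mine$transcript_id))
  cluster$max_g_score <- if (nrow(mine)) max(mine$g_score) else NA_integer_
  cluster$expression <- NA_character_
  if (!is.null(labels)) {
    i <- match(cluster$gene_symbol, labels$gene_symbol)
    if (is.na(i)) {
      warning(sprintf("no expression label for gene '%s'", cluster$gene_symbol),
              call. = FALSE)
    } else {
      cluster$expression <- labels$label[i]
    }
  }
  cluster
}

#' Cluster summary table
#'
#' One row per cluster with the columns of a screening report: gene, member
#' count, PQS-containing isoform count, expression label and maximum G-score.
#'
#' @param clusters list from [build_clusters()].
#' @inheritParams summarize_cluster
#' @return data.frame sorted by gene symbol.
#' @export
summarize_clusters <- function(clusters, hits, labels = NULL) {
  rows <- lapply(clusters, function(cl) {
    s <- summarize_cluster(cl, hits, labels)
    data.frame(gene = s$gene_symbol, n_members = nrow(s$members),
               pqs_isoforms = s$pqs_isoform_count, expression = s$expression,
               max_g_score = s$max_g_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_members = integer(0),
                      pqs_isoforms = integer(0), expression = character(0),
                      max_g_score = integer(0))
  }
  out
}
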