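#' Bundled cervical-cancer lncRNA study tables
#'
#' Small literature-curated tables for the four experimentally characterized
#' G4-bearing lncRNA clusters of cervical cancer (MEG3, CRNDE, LINP1, SNHG20)
#' and the TERRA positive control:
#'
#' * `oligos` — the six RNA oligonucleotides used for in vitro G4 validation
#'   (DNA alphabet) with their reference G-scores under the default scan
#'   parameters.
#' * `interaction_scores` — lncRNA-protein interaction scores (top-down
#'   channel), as published, including duplicated rows.
#' * `rpi_scores` — RF/SVM interaction probabilities for the candidate
#'   G4-binding proteins (bottom-up channel), 27 pairs.
#' * `protein_compartments`, `lnc_compartments` — subcellular localization
#'   annotations.
#' * `expression_labels` — dysregulation labels for the 14 screened lncRNA
#'   clusters.
#'
#' @param name one of the table names above.
#' @return data.frame (typed via [read_table()]).
#' @export
study_table <- function(name = c("oligos", "interaction_scores", "rpi_scores",
                                 "protein_compartments", "lnc_compartments",
                                 "expression_labels")) {
  name <- match.arg(name)
  file <- c(oligos = "reference_oligos.tsv",
            interaction_scores = "interaction_scores.tsv",
            rpi_scores = "rpi_scores.tsv",
            protein_compartments = "protein_compartments.tsv",
            lnc_compartments = "lnc_compartments.tsv",
            expression_labels = "expression_labels.tsv")[[name]]
  schema <- c(oligos = "oligos", interaction_scores = "interaction_scores",
              rpi_scores = "rpi_scores", protein_compartments = "compartments",
              lnc_compartments = "compartments",
              expression_labels = "expression_labels")[[name]]
  path <- system.file("extdata", file, package = "qgrscan", mustWork = TRUE)
  read_table(path, schema)
}
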