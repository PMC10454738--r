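# Seed fan-out: one global seed derives a per-generator sub-seed as
# (seed * 1000 + k) mod 2147483647, so fixtures are reproducible file-by-file.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
}

.sample_flank <- function(n, alphabet = c("A", "C", "T")) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a transcript with a planted PQS
#'
#' Builds `flank + G{t} loop1 G{t} loop2 G{t} loop3 G{t} + flank` with G-free
#' flanks and loops, so the planted parse is the unique QGRS-admissible region
#' and its recovery can be asserted exactly. `n_decoys` optionally plants
#' isolated 3-G decoy runs in the flanks ("hostile" mode); decoys are spaced
#' more than `max_length` from the plant and from each other, so they can
#' never complete a four-group candidate and the planted parse stays unique.
#'
#' @param tetrad tetrad size t (>= `params$min_g_group`).
#' @param loops integer vector of three loop lengths, each within the loop
#'   bounds of `params`; total span must respect `params$max_length`.
#' @param flank_length G-free flank length on each side.
#' @param seed integer seed (deterministic output for fixed arguments).
#' @param n_decoys decoy G-runs per flank (requires long flanks).
#' @param params [scan_params()] used to validate the spec.
#' @param transcript_id,gene_symbol identifiers for the record.
#' @return list with `record` (one-row transcript table) and `truth`
#'   (planted parse: `t`, `loops`, `start`, `end` 1-based, `g_score`).
#' @export
gen_transcript <- function(tetrad = 3L, loops = c(1L, 1L, 1L), flank_length = 50L,
                           seed = 1L, n_decoys = 0L, params = scan_params(),
                           transcript_id = "SYN1", gene_symbol = "SYNG") {
  tetrad <- as.integer(tetrad); loops <- as.integer(loops)
  stopifnot(length(loops) == 3L)
  if (tetrad < params$min_g_group) stop("tetrad below min_g_group", call. = FALSE)
  if (any(loops < params$loop_min | loops > params$loop_max)) {
    stop("loop lengths violate the configured loop bounds", call. = FALSE)
  }
  span <- 4L * tetrad + sum(loops)
  if (span > params$max_length) stop("planted span exceeds max_length", call. = FALSE)
  set.seed(sub_seed(seed, 1L))
  g <- strrep("G", tetrad)
  motif <- paste0(g, .sample_flank(loops[1]), g, .sample_flank(loops[2]),
                  g, .sample_flank(loops[3]), g)
  left <- .sample_flank(flank_length)
  right <- .sample_flank(flank_length)
  if (n_decoys > 0L) {
    # decoy runs must sit further than loop_max from each other and from the
    # plant, so no four-group candidate can recruit them
    spacing <- params$loop_max + tetrad + 2L
    if (flank_length < n_decoys * spacing + params$loop_max + 3L) {
      stop("flanks too short to host isolated decoy runs", call. = FALSE)
    }
    ch <- strsplit(left, "", fixed = TRUE)[[1]]
    for (p in seq_len(n_decoys) * spacing) ch[p:(p + 2L)] <- "G"
    left <- paste(ch, collapse = "")
  }
  seqn <- paste0(left, motif, right)
  record <- transcript_records(transcript_id, gene_symbol, seqn, "synthetic")
  truth <- list(t = tetrad, loops = loops, start = flank_length + 1L,
                end = flank_length + span, span = span,
                g_score = .g_score(tetrad, loops[1], loops[2], loops[3]))
  list(record = record, truth = truth)
}

#' Generate a batch of random planted-PQS transcripts
#'
#' Random specs drawn under a fixed seed: tetrad size 3-4 and loop triples
#' within bounds, constrained so the planted parse scores above the default
#' reporting threshold (total loop length <= 25 nt).
#'
#' @param n number of transcripts.
#' @param seed integer seed.
#' @param params [scan_params()].
#' @param flank_length flank length per side.
#' @return list of [gen_transcript()] results.
#' @export
gen_transcript_batch <- function(n, seed = 1L, params = scan_params(),
                                 flank_length = 50L) {
  lapply(seq_len(n), function(i) {
    set.seed(sub_seed(seed, 100L + i))
    tetrad <- sample(3:4, 1L)
    budget <- min(params$loop_max, 25L)
    repeat {
      loops <- sample(seq.int(params$loop_min, budget), 3L, replace = TRUE)
      if (sum(loops) <= min(25L, params$max_length - 4L * tetrad)) break
    }
    gen_transcript(tetrad, loops, flank_length, seed = sub_seed(seed, 200L + i),
                   params = params, transcript_id = sprintf("SYN%03d", i),
                   gene_symbol = sprintf("SYNG%03d", i))
  })
}

#' Generate schema-valid evidence tables with planted ground truth
#'
#' Emulates the four evidence inputs of the partner-nomination stage:
#' interaction scores (top-down), RF/SVM classifier pairs (bottom-up, full
#' lncRNA x protein cross), compartment annotations and cytoplasmic/nuclear
#' expression. One recorded pair is constructed to pass all three evidence
#' channels, and one to fail the bottom-up filter (rf = 0.3).
#'
#' @param n_lnc,n_prot numbers of lncRNAs and proteins (>= 1).
#' @param seed integer seed.
#' @return list of tables `interaction`, `rpi`, `lnc_compartments`,
#'   `protein_compartments`, `cn_expression`, `labels`, plus `truth` with the
#'   planted pairs.
#' @export
gen_evidence_tables <- function(n_lnc = 4L, n_prot = 8L, seed = 1L) {
  stopifnot(n_lnc >= 1L, n_prot >= 1L)
  lncs <- sprintf("LNC%02d", seq_len(n_lnc))
  prots <- sprintf("PROT%02d", seq_len(n_prot))
  grid <- expand.grid(lncrna = lncs, protein = prots, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lncrna, grid$protein), , drop = FALSE]

  set.seed(sub_seed(seed, 11L))
  interaction <- data.frame(
    lncrna = grid$lncrna, protein = grid$protein,
    protein_transcript = paste0(grid$protein, "-001"),
    score = round(stats::runif(nrow(grid), 50, 350), 2),
    cancer_type = "SYNTH", stringsAsFactors = FALSE)

  set.seed(sub_seed(seed, 12L))
  rpi <- data.frame(
    lncrna = grid$lncrna, protein = grid$protein,
    rf_score = round(stats::runif(nrow(grid)), 3),
    svm_score = round(stats::runif(nrow(grid)), 3), stringsAsFactors = FALSE)

  set.seed(sub_seed(seed, 13L))
  lnc_loc <- sample(c("nucleus", "cytoplasm"), n_lnc, replace = TRUE)
  prot_loc <- sample(c("nucleoplasm", "nucleoli", "cytosol", "perinuclear",
                       "nucleoplasm;cytosol"), n_prot, replace = TRUE)
  # planted all-channel pair: first lncRNA x first protein
  planted <- c(lncrna = lncs[1], protein = prots[1])
  i <- which(rpi$lncrna == planted["lncrna"] & rpi$protein == planted["protein"])
  rpi$rf_score[i] <- 0.8; rpi$svm_score[i] <- 0.9
  lnc_loc[1] <- "nucleus"; prot_loc[1] <- "nucleoplasm"
  # planted bottom-up failure: first lncRNA x second protein (when available)
  fail <- NULL
  if (n_prot >= 2L) {
    fail <- c(lncrna = lncs[1], protein = prots[2])
    j <- which(rpi$lncrna == fail["lncrna"] & rpi$protein == fail["protein"])
    rpi$rf_score[j] <- 0.3
  }

  set.seed(sub_seed(seed, 14L))
  cyt <- round(stats::runif(n_lnc, 0, 20), 3)
  nuc <- ifelse(lnc_loc == "nucleus", cyt * stats::runif(n_lnc, 4, 10),
                cyt / stats::runif(n_lnc, 4, 10))
  set.seed(sub_seed(seed, 15L))
  labels <- data.frame(
    gene_symbol = lncs,
    label = sample(c("upregulated", "downregulated", "differential"),
                   n_lnc, replace = TRUE), stringsAsFactors = FALSE)

  list(
    interaction = interaction, rpi = rpi,
    lnc_compartments = data.frame(symbol = lncs, compartments = lnc_loc,
                                  stringsAsFactors = FALSE),
    protein_compartments = data.frame(symbol = prots, compartments = prot_loc,
                                      stringsAsFactors = FALSE),
    cn_expression = data.frame(symbol = lncs, cytoplasmic = cyt,
                               nuclear = round(nuc, 3), stringsAsFactors = FALSE),
    labels = labels,
    truth = list(all_channel = planted, bottomup_fail = fail)
  )
}

#' Generate correlated expression for two genes
#'
#' Bivariate normal samples with population correlation `rho`, returned in
#' expression-matrix shape (two gene rows, `n` sample columns).
#'
#' @param rho population Pearson correlation in `[-1, 1]`.
#' @param n sample count (>= 3).
#' @param seed integer seed.
#' @param genes length-2 character vector of gene names.
#' @return expression-matrix data.frame.
#' @export
gen_covariation_pair <- function(rho = -0.6, n = 500L, seed = 1L,
                                 genes = c("GENE_A", "GENE_B")) {
  stopifnot(abs(rho) <= 1, n >= 3L, length(genes) == 2L)
  set.seed(sub_seed(seed, 21L))
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  mat <- rbind(x, y)
  for (j in seq_len(n)) out[[sprintf("S%03d", j)]] <- mat[, j]
  out
}

#' Generate a synthetic CD spectrum of known topology
#'
#' Gaussian bands at the canonical positions (parallel: +265 / -240 nm;
#' antiparallel: +295 / -260 nm; peak amplitude 10, trough amplitude 5 mdeg,
#' bandwidth sigma 6 nm) on a 220-350 nm grid, plus seeded Gaussian noise.
#' Classification is recoverable at noise levels up to about 10% of the peak
#' amplitude.
#'
#' @param topology `"parallel"`, `"antiparallel"` or `"none"`.
#' @param noise_sd standard deviation of additive noise, mdeg.
#' @param seed integer seed.
#' @param condition,ion_mM ionic-condition metadata.
#' @return a [spectrum()] object of kind `"cd"`.
#' @export
gen_spectrum <- function(topology = c("parallel", "antiparallel", "none"),
                         noise_sd = 0, seed = 1L, condition = "no_ion",
                         ion_mM = 0) {
  topology <- match.arg(topology)
  wl <- 220:350
  band <- function(center, amp, sigma = 6) amp * exp(-(wl - center)^2 / (2 * sigma^2))
  base <- switch(topology,
                 parallel = band(265, 10) - band(240, 5),
                 antiparallel = band(295, 10) - band(260, 5),
                 none = rep(0, length(wl)))
  set.seed(sub_seed(seed, 31L))
  noise <- if (noise_sd > 0) stats::rnorm(length(wl), 0, noise_sd) else 0
  spectrum(wl, base + noise, kind = "cd", condition = condition, ion_mM = ion_mM)
}

#' Write a complete fixture set to disk
#'
#' Emits FASTA transcripts with planted PQS, every evidence TSV, a CD
#' spectrum CSV per topology, an RT-stop band table and a ground-truth JSON
#' manifest. Preset `"paper-shape"` uses 4 lncRNAs x 8 proteins and four
#' planted transcripts; `"stress"` plants decoy G-runs and generates 20
#' transcripts.
#'
#' @param out_dir output directory (created if missing).
#' @param preset `"paper-shape"` or `"stress"`.
#' @param seed integer seed.
#' @return `out_dir`, invisibly.
#' @export
write_fixtures <- function(out_dir, preset = c("paper-shape", "stress"), seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_tx <- if (preset == "stress") 20L else 4L
  decoys <- if (preset == "stress") 1L else 0L
  flank <- if (preset == "stress") 120L else 50L
  batch <- if (preset == "stress") {
    lapply(seq_len(n_tx), function(i) {
      gen_transcript(3L, sample(1:7, 3L, replace = TRUE), flank,
                     seed = sub_seed(seed, 300L + i), n_decoys = decoys,
                     transcript_id = sprintf("SYN%03d", i),
                     gene_symbol = sprintf("SYNG%03d", i))
    })
  } else {
    gen_transcript_batch(n_tx, seed = seed, flank_length = flank)
  }
  records <- do.call(rbind, lapply(batch, `[[`, "record"))
  write_fasta(records, file.path(out_dir, "transcripts.fasta"))
  ev <- gen_evidence_tables(4L, 8L, seed)
  write_table(ev$interaction, file.path(out_dir, "interaction_scores.tsv"))
  write_table(ev$rpi, file.path(out_dir, "rpi_scores.tsv"))
  write_table(ev$lnc_compartments, file.path(out_dir, "lnc_compartments.tsv"))
  write_table(ev$protein_compartments, file.path(out_dir, "protein_compartments.tsv"))
  write_table(ev$cn_expression, file.path(out_dir, "cn_expression.tsv"))
  write_table(ev$labels, file.path(out_dir, "expression_labels.tsv"))
  for (topo in c("parallel", "antiparallel", "none")) {
    s <- gen_spectrum(topo, noise_sd = 0.5, seed = seed)
    utils::write.csv(data.frame(wavelength_nm = s$wavelengths,
                                intensity = s$intensities),
                     file.path(out_dir, sprintf("cd_%s.csv", topo)),
                     row.names = FALSE)
  }
  bands <- data.frame(lane = c("L1", "L2", "L3"),
                      condition = c("no_ion", "K", "Li"),
                      full_length_intensity = c(80, 40, 60),
                      stop_intensity = c(20, 60, 40))
  write_table(bands, file.path(out_dir, "band_intensities.tsv"))
  manifest <- list(
    preset = preset, seed = seed,
    transcripts = lapply(batch, function(b) {
      c(list(transcript_id = b$record$transcript_id), b$truth)
    }),
    evidence_truth = ev$truth,
    rt_stop_fractions = list(no_ion = 0.2, K = 0.6, Li = 0.4)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
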