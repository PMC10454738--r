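#' Scan parameter set for the QGRS-style PQS scanner
#'
#' Defaults are the study settings: maximum PQS length 45 nt, minimum G-group
#' 3, loop lengths 1-14, and a G-score threshold of 60 (hits must score
#' strictly above it). `max_length` must accommodate four minimal G-groups and
#' three minimal loops.
#'
#' @param max_length maximum admissible PQS span in nt.
#' @param min_g_group minimum G-group (tetrad) size.
#' @param loop_min,loop_max inclusive bounds on each of the three loops, nt.
#' @param score_threshold hits require `g_score > score_threshold`.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(max_length = 45L, min_g_group = 3L, loop_min = 1L,
                        loop_max = 14L, score_threshold = 60L) {
  p <- list(max_length = as.integer(max_length),
            min_g_group = as.integer(min_g_group),
            loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
            score_threshold = as.integer(score_threshold))
  if (p$min_g_group < 2L) stop("min_g_group must be >= 2", call. = FALSE)
  if (p$loop_min < 0L) stop("loop_min must be >= 0", call. = FALSE)
  if (p$loop_min > p$loop_max) stop("loop_min must be <= loop_max", call. = FALSE)
  if (p$max_length < 4L * p$min_g_group + 3L * p$loop_min) {
    stop("max_length too small for four G-groups and three loops", call. = FALSE)
  }
  structure(p, class = "scan_params")
}

#' Find maximal G-runs in a normalized sequence
#'
#' @param sequence normalized `{A,C,G,T}` string.
#' @param min_g_group minimum run length reported.
#' @return data.frame with 0-based `start` and `length` of every maximal run
#'   of at least `min_g_group` consecutive guanines, left to right.
#' @export
find_g_runs <- function(sequence, min_g_group = 3L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!length(chars)) return(data.frame(start = integer(0), length = integer(0)))
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based
  keep <- r$values & r$lengths >= min_g_group
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Vectorized G-score. Calibrated against the six reference oligonucleotides
# bundled with the package (see the methods vignette): a tetrad-count term,
# a penalty growing with total loop length, and an adjustment for the loop
# pattern whose two shortest loops are equal while the third is longer.
# Integer-valued; non-increasing when any single loop is lengthened without
# changing the loop-equality pattern.
.g_score <- function(t, l1, l2, l3) {
  lsum <- l1 + l2 + l3
  lo <- pmin(l1, l2, l3)
  hi <- pmax(l1, l2, l3)
  mid <- lsum - lo - hi
  eq_adj <- as.integer(lo == mid & mid < hi)
  as.integer(15L * t + 27L - pmax(0L, as.integer(floor(7 * (lsum - 10) / 10))) - eq_adj)
}

#' Score a QGRS candidate
#'
#' Deterministic integer G-score of a four-G-group parse. Higher scores mark
#' parses more likely to fold into a stable quadruplex: more tetrads score
#' higher, and longer loops score lower. The scheme is calibrated so that the
#' six reference oligonucleotides bundled with the package reproduce their
#' literature G-scores under the default [scan_params()].
#'
#' @param candidate list or one-row data.frame with fields `t`, `l1`, `l2`,
#'   `l3` (tetrad size and the three loop lengths, nt).
#' @param params a [scan_params()] object (reserved for recalibration;
#'   the default calibration does not depend on it).
#' @return integer G-score (>= 0 for admissible candidates).
#' @export
score_qgrs <- function(candidate, params = scan_params()) {
  .g_score(as.integer(candidate$t), as.integer(candidate$l1),
           as.integer(candidate$l2), as.integer(candidate$l3))
}

# Enumerate candidates in seq[chars], offsets relative to `shift` (0-based).
.enumerate_block <- function(chars, params, shift = 0L) {
  n <- length(chars)
  empty <- data.frame(t = integer(0), s1 = integer(0), s2 = integer(0),
                      s3 = integer(0), s4 = integer(0), l1 = integer(0),
                      l2 = integer(0), l3 = integer(0), span = integer(0),
                      g_score = integer(0))
  runs <- find_g_runs(paste(chars, collapse = ""), params$min_g_group)
  if (nrow(runs) == 0L) return(empty)
  t_max <- max(runs$length)
  rows <- vector("list", 256L); nr <- 0L
  for (t in params$min_g_group:t_max) {
    if (4L * t + 3L * params$loop_min > params$max_length) break
    ok <- runs$length >= t
    if (!any(ok)) next
    blocks <- unlist(lapply(which(ok), function(i) {
      runs$start[i]:(runs$start[i] + runs$length[i] - t)
    }), use.names = FALSE)
    blocks <- sort(blocks)
    if (length(blocks) < 4L) next
    lo <- params$loop_min; hi <- params$loop_max
    for (a in blocks) {
      for (b in blocks[blocks >= a + t + lo & blocks <= a + t + hi]) {
        for (cc in blocks[blocks >= b + t + lo & blocks <= b + t + hi]) {
          for (d in blocks[blocks >= cc + t + lo & blocks <= cc + t + hi]) {
            span <- d + t - a
            if (span > params$max_length) break
            nr <- nr + 1L
            if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
            rows[[nr]] <- c(t, a, b, cc, d, b - a - t, cc - b - t, d - cc - t, span)
          }
        }
      }
    }
  }
  if (nr == 0L) return(empty)
  m <- do.call(rbind, rows[seq_len(nr)])
  out <- data.frame(t = m[, 1], s1 = m[, 2] + shift, s2 = m[, 3] + shift,
                    s3 = m[, 4] + shift, s4 = m[, 5] + shift,
                    l1 = m[, 6], l2 = m[, 7], l3 = m[, 8], span = m[, 9])
  out$g_score <- .g_score(out$t, out$l1, out$l2, out$l3)
  out
}

# All candidates of a sequence of any length. Long sequences are streamed in
# sliding windows of 2*max_length with max_length overlap; every candidate
# (span <= max_length) falls entirely inside at least one window, and
# duplicates across window seams are removed before selection.
.all_candidates <- function(sequence, params) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  w <- 2L * params$max_length
  if (n <= w) {
    cand <- .enumerate_block(chars, params, 0L)
  } else {
    offsets <- seq.int(0L, n - 1L, by = params$max_length)
    pieces <- lapply(offsets, function(off) {
      end <- min(n, off + w)
      if (end - off < 4L * params$min_g_group + 3L * params$loop_min) return(NULL)
      .enumerate_block(chars[(off + 1L):end], params, off)
    })
    cand <- do.call(rbind, pieces)
    if (is.null(cand) || nrow(cand) == 0L) return(.enumerate_block(character(0), params))
    key <- paste(cand$t, cand$s1, cand$s2, cand$s3, cand$s4)
    cand <- cand[!duplicated(key), , drop = FALSE]
  }
  cand[order(cand$s1, cand$span, -cand$g_score, -cand$t, cand$s2, cand$s3, cand$s4), ,
       drop = FALSE]
}

#' Enumerate all QGRS candidates of a sequence
#'
#' Every choice of four equal-size G-groups (size `t`,
#' `min_g_group <= t <=` the hosting run lengths, groups positionable anywhere
#' inside maximal G-runs) whose three loops respect `[loop_min, loop_max]` and
#' whose span does not exceed `max_length`. Ordering is deterministic: by
#' start, then span, then descending score.
#'
#' @param sequence normalized sequence.
#' @param params [scan_params()].
#' @return data.frame with columns `t`, `s1..s4` (0-based group starts),
#'   `l1..l3` (loop lengths), `span`, `g_score`; zero rows when no candidate
#'   exists.
#' @export
enumerate_qgrs <- function(sequence, params = scan_params()) {
  out <- .all_candidates(sequence, params)
  rownames(out) <- NULL
  out
}

#' Best-scoring QGRS parse of a sequence
#'
#' Ties on score are broken by smaller span, then leftmost start, then larger
#' tetrad size, then lexicographically earliest group starts.
#'
#' @inheritParams enumerate_qgrs
#' @return one-row data.frame (same columns as [enumerate_qgrs()]) or `NULL`
#'   when the sequence admits no candidate.
#' @export
best_parse <- function(sequence, params = scan_params()) {
  cand <- .all_candidates(sequence, params)
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(-cand$g_score, cand$span, cand$s1, -cand$t, cand$s2, cand$s3, cand$s4)
  out <- cand[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact maximum-weight selection of non-overlapping intervals by dynamic
# programming over candidates sorted by (start, end). Ties in total score are
# resolved by preferring to take the earlier candidate, which yields the
# lexicographically earliest optimal selection under the sort order.
.select_nonoverlapping <- function(start0, end0, score) {
  n <- length(start0)
  if (n == 0L) return(integer(0))
  nxt <- vapply(seq_len(n), function(i) {
    findInterval(end0[i] - 0.5, start0) + 1L
  }, integer(1))
  f <- numeric(n + 1L)
  take <- logical(n)
  for (i in n:1) {
    with_i <- score[i] + f[nxt[i]]
    without <- f[i + 1L]
    take[i] <- with_i >= without
    f[i] <- max(with_i, without)
  }
  sel <- integer(0)
  i <- 1L
  while (i <= n) {
    if (take[i]) { sel <- c(sel, i); i <- nxt[i] } else i <- i + 1L
  }
  sel
}

#' Scan a transcript for non-overlapping PQS hits
#'
#' Enumerates QGRS candidates (streaming long transcripts in sliding windows),
#' keeps those with `g_score > score_threshold`, and reports the
#' maximum-total-score set of pairwise non-overlapping hits (exact weighted
#' interval selection with deterministic tie-breaks). Each hit is annotated
#' with the stricter canonical-motif cross-check (see
#' [canonical_motif_check()]).
#'
#' @param record one-row transcript-record data.frame (or list with
#'   `transcript_id`, `gene_symbol`, `sequence`).
#' @param params [scan_params()].
#' @return data.frame of hits sorted by start: `transcript_id`, `gene_symbol`,
#'   `start`, `end` (1-based inclusive), `motif`, `g_score`,
#'   `passed_motif_check`.
#' @export
scan_transcript <- function(record, params = scan_params()) {
  sequence <- record$sequence[[1L]]
  tid <- record$transcript_id[[1L]]
  gene <- if (!is.null(record$gene_symbol)) record$gene_symbol[[1L]] else tid
  cand <- .all_candidates(sequence, params)
  cand <- cand[cand$g_score > params$score_threshold, , drop = FALSE]
  hits0 <- data.frame(transcript_id = character(0), gene_symbol = character(0),
                      start = integer(0), end = integer(0), motif = character(0),
                      g_score = integer(0), passed_motif_check = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(hits0)
  # one candidate per interval: the best-scoring parse (larger t on ties)
  end0 <- cand$s1 + cand$span
  ord <- order(cand$s1, end0, -cand$g_score, -cand$t)
  cand <- cand[ord, , drop = FALSE]
  end0 <- end0[ord]
  key <- paste(cand$s1, end0)
  keep <- !duplicated(key)
  cand <- cand[keep, , drop = FALSE]
  end0 <- end0[keep]
  sel <- .select_nonoverlapping(cand$s1, end0, cand$g_score)
  cand <- cand[sel, , drop = FALSE]
  end0 <- end0[sel]
  motif <- substring(sequence, cand$s1 + 1L, end0)
  data.frame(
    transcript_id = tid, gene_symbol = gene,
    start = cand$s1 + 1L, end = end0,
    motif = motif, g_score = cand$g_score,
    passed_motif_check = canonical_motif_check(motif, params$min_g_group),
    stringsAsFactors = FALSE
  )
}

#' Scan many transcripts
#'
#' @param records transcript-record data.frame.
#' @param params [scan_params()].
#' @return row-bound hit table across records (see [scan_transcript()]), with
#'   a stage log of transcripts in / hits out.
#' @export
scan_transcripts <- function(records, params = scan_params()) {
  hits <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    scan_transcript(records[i, , drop = FALSE], params)
  }))
  if (is.null(hits)) hits <- scan_transcript(list(transcript_id = "x", sequence = "A"), params)
  rownames(hits) <- NULL
  qgr_log("scan", nrow(records), nrow(hits))
  hits
}

#' Canonical-motif cross-check
#'
#' Independent second validation layer for reported motifs: TRUE iff the motif
#' matches `G{t} N{1-7} G{t} N{1-7} G{t} N{1-7} G{t}` for some `t >=
#' min_g_group` — a stricter loop bound (1-7 nt) than the scanner admits.
#' The loop bound is configurable because the pass criterion of such
#' secondary screens varies between resources.
#'
#' @param motif character vector of motif strings.
#' @param min_g_group minimum tetrad size (default 3).
#' @param loop_bounds length-2 integer vector, inclusive loop bounds.
#' @return logical vector.
#' @export
canonical_motif_check <- function(motif, min_g_group = 3L, loop_bounds = c(1L, 7L)) {
  vapply(motif, function(m) {
    n <- nchar(m)
    t_hi <- n %/% 4L
    if (t_hi < min_g_group) return(FALSE)
    for (t in min_g_group:t_hi) {
      pat <- sprintf("^G{%d}([ACGT]{%d,%d}G{%d}){3}$", t, loop_bounds[1], loop_bounds[2], t)
      if (grepl(pat, m)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}
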