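# Independent brute-force oracle for the PQS scanner. Enumerates candidates
# by direct position-wise inspection (no G-run bookkeeping, no windowing),
# re-derives the G-score from its definition, and selects non-overlapping
# hits by memoized recursion over the exhaustive candidate set. Kept separate
# from the package implementation on purpose.

oracle_score <- function(t, l1, l2, l3) {
  s <- sort(c(l1, l2, l3))
  pen <- floor(7 * (l1 + l2 + l3 - 10) / 10)
  if (pen < 0) pen <- 0
  adj <- if (s[1] == s[2] && s[2] < s[3]) 1 else 0
  15 * t + 27 - pen - adj
}

oracle_enumerate <- function(sequence, max_length = 45, min_g = 3,
                             loop_min = 1, loop_max = 14) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_block <- function(i, t) i >= 1 && i + t - 1 <= n && all(ch[i:(i + t - 1)] == "G")
  rows <- list()
  t <- min_g
  while (4 * t + 3 * loop_min <= max_length && t <= n %/% 4) {
    starts <- Filter(function(i) is_block(i, t), seq_len(n))
    after <- function(p) starts[starts >= p + t + loop_min & starts <= p + t + loop_max]
    for (a in starts) for (b in after(a)) for (cc in after(b)) for (d in after(cc)) {
      l1 <- b - a - t; l2 <- cc - b - t; l3 <- d - cc - t
      span <- d + t - a
      if (span > max_length) next
      rows[[length(rows) + 1]] <- data.frame(
        t = t, s1 = a - 1, s2 = b - 1, s3 = cc - 1, s4 = d - 1,
        l1 = l1, l2 = l2, l3 = l3, span = span,
        g_score = oracle_score(t, l1, l2, l3))
    }
    t <- t + 1
  }
  if (!length(rows)) return(data.frame(t = integer(0), s1 = integer(0),
                                       span = integer(0), g_score = integer(0)))
  do.call(rbind, rows)
}

# Exhaustive-set selection: candidates above threshold, reduced to the best
# parse per interval, then maximum-total-score non-overlapping subset found
# by recursion (ties prefer taking the earlier candidate in sort order).
oracle_scan <- function(sequence, max_length = 45, min_g = 3, loop_min = 1,
                        loop_max = 14, threshold = 60) {
  cand <- oracle_enumerate(sequence, max_length, min_g, loop_min, loop_max)
  cand <- cand[cand$g_score > threshold, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(start = integer(0), end = integer(0), g_score = integer(0)))
  }
  cand$end0 <- cand$s1 + cand$span
  cand <- cand[order(cand$s1, cand$end0, -cand$g_score, -cand$t), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$s1, cand$end0)), , drop = FALSE]
  n <- nrow(cand)
  memo <- rep(NA_real_, n + 1)
  memo[n + 1] <- 0
  best_from <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    nxt <- which(cand$s1 >= cand$end0[i])
    nxt <- nxt[nxt > i]
    take <- cand$g_score[i] + best_from(if (length(nxt)) min(nxt) else n + 1)
    skip <- best_from(i + 1)
    memo[i] <<- max(take, skip)
    memo[i]
  }
  sel <- integer(0)
  i <- 1
  while (i <= n) {
    nxt <- which(cand$s1 >= cand$end0[i])
    nxt <- nxt[nxt > i]
    j <- if (length(nxt)) min(nxt) else n + 1
    if (cand$g_score[i] + best_from(j) >= best_from(i + 1)) {
      sel <- c(sel, i)
      i <- j
    } else {
      i <- i + 1
    }
  }
  out <- cand[sel, , drop = FALSE]
  data.frame(start = out$s1 + 1, end = out$end0, g_score = out$g_score)
}

# Brute-force splitter for the canonical motif pattern
# G{t} N{lo..hi} G{t} N{lo..hi} G{t} N{lo..hi} G{t} (full match).
oracle_canonical <- function(motif, min_g = 3, lo = 1, hi = 7) {
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  n <- length(ch)
  gs <- function(i, t) all(ch[i:(i + t - 1)] == "G")
  for (t in min_g:max(min_g, n %/% 4)) {
    if (4 * t + 3 * lo > n) break
    for (a in lo:hi) for (b in lo:hi) for (cc in lo:hi) {
      if (4 * t + a + b + cc != n) next
      p1 <- 1; p2 <- p1 + t + a; p3 <- p2 + t + b; p4 <- p3 + t + cc
      if (gs(p1, t) && gs(p2, t) && gs(p3, t) && gs(p4, t)) return(TRUE)
    }
  }
  FALSE
}

# Random test sequence with tunable G richness.
random_sequence <- function(len, g_prob = 0.4) {
  other <- (1 - g_prob) / 3
  paste(sample(c("G", "A", "C", "T"), len, replace = TRUE,
               prob = c(g_prob, other, other, other)), collapse = "")
}

scan_as_frame <- function(sequence, params = scan_params()) {
  h <- scan_transcript(list(transcript_id = "t", gene_symbol = "g",
                            sequence = sequence), params)
  data.frame(start = h$start, end = h$end, g_score = h$g_score)
}
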