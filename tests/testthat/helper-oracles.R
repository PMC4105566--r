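# Independent oracles used across the suite. Each is a deliberately plain
# implementation, separate from the package's code paths.

# Affine-gap local alignment (Gotoh) optimal score, pure-R dynamic program.
# Scores: match/mismatch per column (N never matches), gap of length L costs
# gap_open + L * gap_extend. Returns the optimal local score (0 if none
# positive). Single strand.
oracle_sw_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -3, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  h_prev <- numeric(m + 1)           # H[i-1, ]
  e_prev <- rep(NEG, m + 1)          # E[i-1, ] (gap in b / vertical)
  best <- 0
  go_ge <- gap_open + gap_extend
  for (i in seq_len(n)) {
    # E (vertical gaps) depends only on the previous row: vectorized
    e_cur <- pmax(h_prev + go_ge, e_prev + gap_extend)
    sub_i <- ifelse(bv == av[i] & av[i] != "N", match, mismatch)
    h_cur <- numeric(m + 1)
    f <- NEG                          # F[i, j] (gap in a / horizontal)
    for (j in seq_len(m)) {
      f <- f + gap_extend
      f2 <- h_cur[j] + go_ge
      if (f2 > f) f <- f2
      h <- h_prev[j] + sub_i[j]
      e <- e_cur[j + 1]
      if (e > h) h <- e
      if (f > h) h <- f
      if (h < 0) h <- 0
      h_cur[j + 1] <- h
      if (h > best) best <- h
    }
    h_prev <- h_cur
    e_prev <- e_cur
  }
  best
}

oracle_sw_score_2strand <- function(a, b, ...) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  max(oracle_sw_score(a, b, ...), oracle_sw_score(a, rc, ...))
}

# Per-residue bitmap subject coverage for one set of 1-based inclusive
# subject spans.
oracle_bitmap_coverage <- function(sstart, send, slen) {
  hit <- logical(slen)
  for (k in seq_along(sstart)) hit[sstart[k]:send[k]] <- TRUE
  sum(hit) / slen
}

# Exhaustive perfect-tandem-repeat enumerator: every start, motif length
# 2-6, maximal rightward extension, primitive motifs meeting min_units;
# overlaps resolved leftmost-first then longest (same tie policy the
# detector documents, independently coded).
oracle_find_ssrs <- function(seq, min_units = c(di = 6L, tri = 4L, tetra = 3L,
                                                penta = 3L, hexa = 3L)) {
  cls_of <- c("2" = "di", "3" = "tri", "4" = "tetra", "5" = "penta", "6" = "hexa")
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  prim <- function(x) {
    L <- nchar(x)
    !any(vapply(seq_len(L - 1), function(d) {
      L %% d == 0 && x == strrep(substr(x, 1, d), L / d)
    }, logical(1)))
  }
  rows <- list()
  for (st in seq_len(n)) {
    for (m in 2:6) {
      if (st + 2 * m - 1 > n) next
      mot <- ch[st:(st + m - 1)]
      if (any(!mot %in% c("A", "C", "G", "T"))) next
      k <- 1L
      while (st + (k + 1L) * m - 1L <= n &&
             all(ch[(st + k * m):(st + (k + 1L) * m - 1L)] == mot)) k <- k + 1L
      ms <- paste(mot, collapse = "")
      if (!prim(ms)) next
      if (k < min_units[[cls_of[[as.character(m)]]]]) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = st + k * m - 1L, motif = ms,
        n_repeats = k, class = cls_of[[as.character(m)]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      n_repeats = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), ]
  kept <- cand[0, ]
  frontier <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > frontier) {
      kept <- rbind(kept, cand[i, ])
      frontier <- cand$end[i]
    }
  }
  rownames(kept) <- NULL
  kept
}

# Brute-force canonical motif: smallest string over rotations of the motif
# and of its reverse complement.
oracle_canonical_motif <- function(motif) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  m <- nchar(motif)
  rots <- function(s) vapply(seq_len(m), function(i) {
    paste0(substr(s, i, m), substr(s, 1, i - 1))
  }, character(1))
  min(c(rots(motif), rots(rc)))
}

# Column-by-column affine rescoring of a gapped alignment (validates that a
# reported alignment attains the optimal score).
rescore_alignment <- function(qa, sa, match = 1, mismatch = -2,
                              gap_open = -3, gap_extend = -1) {
  q <- strsplit(qa, "")[[1]]
  s <- strsplit(sa, "")[[1]]
  sc <- 0
  in_gap <- FALSE
  for (k in seq_along(q)) {
    if (q[k] == "-" || s[k] == "-") {
      sc <- sc + gap_extend + if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      in_gap <- FALSE
      sc <- sc + if (q[k] == s[k] && q[k] != "N") match else mismatch
    }
  }
  sc
}

count_ident <- function(qa, sa) {
  q <- strsplit(qa, "")[[1]]
  s <- strsplit(sa, "")[[1]]
  sum(q == s & q != "-" & q != "N")
}

# Random DNA helpers for property tests.
rand_dna <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

rand_reads_tbl <- function(n, len_range = c(30, 120)) {
  tibble::tibble(
    id = sprintf("rr%03d", seq_len(n)),
    seq = vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                 rand_dna, character(1)),
    masked = replicate(n, matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))),
                       simplify = FALSE)
  )
}
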