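# Shared internal helpers: sequence checks, interval arithmetic, RNG scoping.

DNA_LETTERS <- c("A", "C", "G", "T", "N")

normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N} (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Intervals are 0-based half-open integer matrices with columns start, end.
empty_intervals <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# Merge overlapping/adjacent half-open intervals; returns sorted matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(empty_intervals())
  r <- IRanges::reduce(IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2]))
  out <- cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  out[order(out[, 1]), , drop = FALSE]
}

interval_total <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  sum(iv[, 2] - iv[, 1])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so generators never leak
# randomness into (or out of) user sessions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}
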