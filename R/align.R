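# Local pairwise alignment engine behind the consistency metrics. An exact
# affine-gap (Gotoh) local alignment with a 5-letter DNA scoring matrix in
# which N scores as a mismatch and never counts toward identity.

align_submat <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N never matches, not even itself
  m
}

#' Optimal local alignment of two DNA sequences
#'
#' Exact local alignment under an affine gap scheme (a gap of length L costs
#' `gap_open + L * gap_extend`). With `both_strands = TRUE` the reverse
#' complement of `b` is also tried and the higher-scoring strand reported
#' (ties go to the plus strand). Spans are 0-based half-open on the original
#' (input-orientation) sequences.
#'
#' @param a,b Non-empty DNA strings over `A,C,G,T,N`.
#' @param match,mismatch Per-column scores (defaults +1 / -2). `N` columns
#'   always score `mismatch`.
#' @param gap_open,gap_extend Affine gap penalties (defaults -3 / -1), so a
#'   single-base gap costs -4.
#' @param both_strands Also consider the reverse complement of `b`.
#' @param keep_alignment Also return the gapped alignment rows (`q_aln`,
#'   `s_aln`; on the minus strand they refer to the reverse complement of
#'   `b`).
#' @return A one-row tibble with `q_start, q_end, s_start, s_end` (0-based
#'   half-open), `n_ident`, `aln_cols`, `score`, `identity_frac`, `strand`;
#'   or `NULL` when no positive-scoring pair exists (optimal score below
#'   `match`).
#' @export
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = -3,
                        gap_extend = -1, both_strands = TRUE,
                        keep_alignment = FALSE) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  a <- normalize_seq(a); b <- normalize_seq(b)
  assert_dna(c(a, b))
  fwd <- align_one_strand(a, b, match, mismatch, gap_open, gap_extend,
                          keep_alignment)
  best <- fwd
  strand <- "+"
  if (both_strands) {
    rev <- align_one_strand(a, revcomp(b), match, mismatch, gap_open, gap_extend,
                            keep_alignment)
    if (!is.null(rev) && (is.null(fwd) || rev$score > fwd$score)) {
      best <- rev
      strand <- "-"
      nb <- nchar(b)
      s_start <- nb - best$s_end
      best$s_end <- nb - best$s_start
      best$s_start <- s_start
    }
  }
  if (is.null(best)) return(NULL)
  best$strand <- strand
  best
}

align_one_strand <- function(a, b, match, mismatch, gap_open, gap_extend,
                             keep_alignment = FALSE) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = align_submat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend
  )
  sc <- Biostrings::score(aln)
  if (sc < match) return(NULL)
  q_aln <- as.character(Biostrings::alignedPattern(aln))
  s_aln <- as.character(Biostrings::alignedSubject(aln))
  pa <- strsplit(q_aln, "")[[1]]
  sa <- strsplit(s_aln, "")[[1]]
  n_ident <- sum(pa == sa & pa != "N" & pa != "-")
  cols <- length(pa)
  out <- tibble(
    q_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
    s_end = Biostrings::end(Biostrings::subject(aln)),
    n_ident = n_ident,
    aln_cols = cols,
    score = sc,
    identity_frac = n_ident / cols
  )
  if (keep_alignment) {
    out$q_aln <- q_aln
    out$s_aln <- s_aln
  }
  out
}

#' Local alignment score of two sequences
#'
#' Convenience wrapper around [local_align()] returning just the optimal
#' score (0 when no positive-scoring alignment exists).
#'
#' @inheritParams local_align
#' @export
local_align_score <- function(a, b, ..., both_strands = TRUE) {
  aln <- local_align(a, b, ..., both_strands = both_strands)
  if (is.null(aln)) 0 else aln$score
}
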