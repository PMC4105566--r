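# Adapter masking and largest-unmasked-substring clipping. Reads arrive as
# FASTA with library adapters still attached; masking flags every
# bounded-mismatch adapter occurrence (either strand) and clipping keeps the
# longest contiguous unmasked run per read.

#' Mask adapter occurrences in reads
#'
#' Scans each read for occurrences of each adapter and of its reverse
#' complement, allowing a bounded mismatch fraction, and records matched
#' stretches in the `masked` list-column (0-based half-open intervals,
#' merged when overlapping). Partial adapter occurrences hanging off either
#' read end are masked when the overlap is at least `min_match` bases.
#'
#' @param reads Read tibble from [read_fasta()] (columns `id`, `seq`,
#'   `masked`).
#' @param adapters Character vector of adapter sequences, or a tibble with a
#'   `seq` column.
#' @param max_mismatch_frac Maximum mismatching fraction of the matched
#'   stretch (default 0.1).
#' @param min_match Minimum matched stretch length in bases (default 10);
#'   adapters shorter than this must match in full.
#' @return `reads` with updated `masked` intervals.
#' @export
mask_adapters <- function(reads, adapters, max_mismatch_frac = 0.1, min_match = 10) {
  if (is.data.frame(adapters)) adapters <- adapters$seq
  adapters <- normalize_seq(adapters)
  if (length(adapters) == 0) abort("`adapters` must be non-empty")
  assert_dna(adapters, "adapter")
  probes <- unique(c(adapters, revcomp(adapters)))
  reads$masked <- purrr::map2(reads$seq, reads$masked, function(s, m0) {
    merge_intervals(rbind(m0, scan_adapters(s, probes, max_mismatch_frac, min_match)))
  })
  reads
}

# Bounded-mismatch sliding scan of every probe over one read, including
# probe prefixes/suffixes overhanging the read ends. Returns a raw (unmerged)
# interval matrix.
scan_adapters <- function(seq, probes, max_mismatch_frac, min_match) {
  n <- nchar(seq)
  s <- charToRaw(seq)
  out <- empty_intervals()
  for (p in probes) {
    m <- nchar(p)
    pr <- charToRaw(p)
    min_ov <- min(min_match, m)
    for (off in seq.int(-(m - min_ov), n - min_ov)) {
      lo <- max(0L, off)                 # read coords, half-open
      hi <- min(n, off + m)
      ov <- hi - lo
      if (ov < min_ov) next
      rs <- s[(lo + 1L):hi]
      ps <- pr[(lo - off + 1L):(hi - off)]
      mm <- sum(rs != ps | rs == charToRaw("N"))
      if (mm <= floor(max_mismatch_frac * ov)) {
        out <- rbind(out, c(lo, hi))
      }
    }
  }
  out
}

#' Clip a read table to the largest unmasked substring
#'
#' For every read, keeps the longest maximal run of unmasked bases (ties
#' broken toward the 5' end). Reads whose best run is shorter than `min_len`
#' are removed. Clipped reads keep their id with a `/clip` suffix; reads
#' with no masked bases pass through unchanged.
#'
#' @param reads Read tibble with populated `masked` intervals.
#' @param min_len Minimum kept length in bases (default 20).
#' @return Tibble of surviving reads (`id`, `seq`, empty `masked`), with the
#'   per-read clipping bookkeeping in columns `source_id` and `clipped`.
#' @export
clip_reads <- function(reads, min_len = 20) {
  clipped <- purrr::pmap(list(reads$id, reads$seq, reads$masked), clip_one, min_len = min_len)
  keep <- !vapply(clipped, is.null, logical(1))
  out <- dplyr::bind_rows(clipped[keep])
  if (nrow(out) == 0) {
    out <- tibble(id = character(), seq = character(), masked = list(),
                  source_id = character(), clipped = logical())
  }
  out
}

clip_one <- function(id, seq, masked, min_len) {
  n <- nchar(seq)
  masked <- merge_intervals(masked)
  if (nrow(masked) == 0) {
    return(tibble(id = id, seq = seq, masked = list(empty_intervals()),
                  source_id = id, clipped = FALSE))
  }
  # complement of the mask: candidate unmasked runs, 5'-most first
  bounds <- c(0L, t(masked), n)
  runs <- matrix(bounds, ncol = 2, byrow = TRUE)
  lens <- runs[, 2] - runs[, 1]
  best <- which.max(lens)  # ties: first (= 5'-most)
  if (lens[best] < min_len) return(NULL)
  tibble(
    id = paste0(id, "/clip"),
    seq = substr(seq, runs[best, 1] + 1L, runs[best, 2]),
    masked = list(empty_intervals()),
    source_id = id, clipped = TRUE
  )
}

#' Mask and clip a batch of reads, with a cleaning report
#'
#' Runs [mask_adapters()] then [clip_reads()] and aggregates the cleaning
#' summary (counts, bases, mean lengths before/after).
#'
#' @inheritParams mask_adapters
#' @inheritParams clip_reads
#' @return A list with `reads` (clean read tibble) and `report` (one-row
#'   tibble: `n_input`, `n_clean`, `n_removed`, `bases_input`, `bases_clean`,
#'   `mean_len_before`, `mean_len_after`).
#' @export
clip_batch <- function(reads, adapters, max_mismatch_frac = 0.1, min_match = 10,
                       min_len = 20) {
  masked <- mask_adapters(reads, adapters,
                          max_mismatch_frac = max_mismatch_frac,
                          min_match = min_match)
  clean <- clip_reads(masked, min_len = min_len)
  report <- tibble(
    n_input = nrow(reads),
    n_clean = nrow(clean),
    n_removed = nrow(reads) - nrow(clean),
    bases_input = sum(nchar(reads$seq)),
    bases_clean = sum(nchar(clean$seq)),
    mean_len_before = if (nrow(reads)) mean(nchar(reads$seq)) else NA_real_,
    mean_len_after = if (nrow(clean)) mean(nchar(clean$seq)) else NA_real_
  )
  list(reads = clean, report = report)
}
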