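# Readers and writers for the external formats the toolkit touches:
# FASTA, 12/14-column tabular homology hits, read->contig membership
# (two-column TSV or minimal ACE).

#' Read a FASTA file into a read table
#'
#' Sequences are uppercased and `U` is mapped to `T`. The returned tibble is
#' the package's standard read container: one row per record with an empty
#' `masked` interval set (see [mask_adapters()]).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `seq` (uppercase DNA over
#'   `A,C,G,T,N`) and `masked` (list of 0-based half-open interval matrices
#'   flagging adapter stretches; empty on load).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgtu"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0 || !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warn(sprintf("FASTA file %s has no records", path))
    return(tibble(id = character(), seq = character(), masked = list()))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- normalize_seq(as.character(ss))
  assert_dna(seqs, sprintf("FASTA file %s", path))
  if (any(nchar(seqs) == 0)) abort("FASTA records must have length >= 1")
  tibble(id = unname(ids), seq = unname(seqs), masked = rep(list(empty_intervals()), length(ids)))
}

#' Write sequences to a FASTA file
#'
#' Accepts any tibble carrying an `id` column and either a `seq` or a
#' `consensus` sequence column, so both read tables and contig tables
#' round-trip through [read_fasta()].
#'
#' @param x Tibble with `id` and `seq` (or `consensus`) columns.
#' @param path Output path.
#' @param width Line width for sequence wrapping (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(width >= 1)
  seq_col <- if ("seq" %in% names(x)) "seq" else if ("consensus" %in% names(x)) "consensus" else
    abort("`x` must have a `seq` or `consensus` column")
  lines <- character(0)
  if (nrow(x) > 0) {
    wrapped <- purrr::map2(x[[seq_col]], x$id, function(s, id) {
      starts <- seq(1, nchar(s), by = width)
      c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
    })
    lines <- unlist(wrapped)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular homology hits (12 or 14 columns)
#'
#' Parses the standard tab-separated output of protein/nucleotide homology
#' searches (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore [qlen slen]`). Lines starting with `#` are
#' skipped. Subject coordinates are normalized so `sstart <= send`, with the
#' original orientation kept in `sstrand` (`"+"` or `"-"`).
#'
#' @param path Path to the tab-separated hit file.
#' @param n_cols Expected column count, 12 or 14; `NULL` autodetects from the
#'   first data line.
#' @return A tibble with columns `qid, sid, pident, aln_len, mismatches,
#'   gapopens, qstart, qend, sstart, send, evalue, bitscore, sstrand` and,
#'   for 14-column input, `qlen, slen`. Coordinates are 1-based inclusive.
#' @export
read_tabular_hits <- function(path, n_cols = NULL) {
  if (!file.exists(path)) abort(sprintf("hit file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0) return(hits_skeleton(n_cols %||% 12))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  counts <- lengths(fields)
  if (is.null(n_cols)) n_cols <- counts[1]
  if (!n_cols %in% c(12L, 14L)) abort("`n_cols` must be 12 or 14")
  bad <- which(counts != n_cols)
  if (length(bad) > 0) {
    abort(sprintf(
      "line %d of %s has %d columns, expected %d",
      lineno[bad[1]], path, counts[bad[1]], n_cols
    ))
  }
  m <- matrix(unlist(fields), ncol = n_cols, byrow = TRUE)
  hits <- tibble(
    qid = m[, 1], sid = m[, 2],
    pident = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gapopens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (n_cols == 14L) {
    hits$qlen <- as.integer(m[, 13])
    hits$slen <- as.integer(m[, 14])
  }
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) abort("unparseable or negative e-value")
  if (any(hits$qstart > hits$qend)) abort("qstart > qend is not allowed")
  if (any(hits$pident < 0 | hits$pident > 100)) abort("pident outside [0, 100]")
  rev <- hits$sstart > hits$send
  hits$sstrand <- ifelse(rev, "-", "+")
  tmp <- hits$sstart[rev]
  hits$sstart[rev] <- hits$send[rev]
  hits$send[rev] <- tmp
  hits
}

hits_skeleton <- function(n_cols) {
  h <- tibble(
    qid = character(), sid = character(), pident = numeric(),
    aln_len = integer(), mismatches = integer(), gapopens = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    evalue = numeric(), bitscore = numeric()
  )
  if (n_cols == 14L) {
    h$qlen <- integer()
    h$slen <- integer()
  }
  h$sstrand <- character()
  h
}

#' Write tabular hits in standard 12/14-column form
#'
#' Inverse of [read_tabular_hits()]: rows with `sstrand == "-"` are emitted
#' with `sstart > send`, restoring the native strand-by-coordinate-order
#' convention.
#'
#' @param hits Hit tibble as returned by [read_tabular_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  s1 <- ifelse(hits$sstrand == "-", hits$send, hits$sstart)
  s2 <- ifelse(hits$sstrand == "-", hits$sstart, hits$send)
  cols <- list(
    hits$qid, hits$sid, hits$pident, hits$aln_len, hits$mismatches,
    hits$gapopens, hits$qstart, hits$qend, s1, s2,
    format(hits$evalue, scientific = TRUE, trim = TRUE), hits$bitscore
  )
  if (all(c("qlen", "slen") %in% names(hits))) cols <- c(cols, list(hits$qlen, hits$slen))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a read-to-contig membership table
#'
#' Two dialects are understood: a two-column TSV (`read_id<TAB>contig_id`)
#' and a minimal ACE subset in which only `CO` (contig header) and `AF`
#' (read placement) lines are interpreted.
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"ace"`.
#' @return A tibble with columns `read_id`, `contig_id`; each read id appears
#'   at most once.
#' @export
read_membership <- function(path, dialect = c("tsv", "ace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("membership file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2)) {
      abort(sprintf("line %d: membership TSV must have exactly 2 columns",
                    which(lengths(fields) != 2)[1]))
    }
    out <- tibble(
      read_id = vapply(fields, `[[`, character(1), 1),
      contig_id = vapply(fields, `[[`, character(1), 2)
    )
  } else {
    current <- NA_character_
    read_id <- character(0)
    contig_id <- character(0)
    for (ln in lines) {
      if (startsWith(ln, "CO ")) {
        current <- strsplit(ln, " ", fixed = TRUE)[[1]][2]
      } else if (startsWith(ln, "AF ")) {
        if (is.na(current)) abort("ACE 'AF' line before any 'CO' line")
        read_id <- c(read_id, strsplit(ln, " ", fixed = TRUE)[[1]][2])
        contig_id <- c(contig_id, current)
      }
    }
    out <- tibble(read_id = read_id, contig_id = contig_id)
  }
  out <- dplyr::distinct(out)
  dup <- out$read_id[duplicated(out$read_id)]
  if (length(dup) > 0) {
    abort(sprintf("read(s) mapped to more than one contig: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write a membership table as two-column TSV
#'
#' @param membership Tibble with `read_id`, `contig_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path) {
  writeLines(paste(membership$read_id, membership$contig_id, sep = "\t"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
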