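# Best-hit functional annotation summaries and reference-proteome coverage:
# e-value filtering, per-query best hits, interval-union subject coverage
# and the >= 90% single-query full-length gene rule.

#' Filter hits by e-value
#'
#' Keeps hits with `evalue <= evalue_max` (the cutoff is inclusive), in
#' stable input order.
#'
#' @param hits Hit tibble from [read_tabular_hits()].
#' @param evalue_max Maximum e-value (default `1e-5`).
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5) {
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Best hit per query
#'
#' For each query, the hit with the highest bit score; ties are broken by
#' lowest e-value, then lexicographically smallest subject id.
#'
#' @param hits Hit tibble (any number of queries).
#' @return Tibble with one row per distinct `qid`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits %>%
    dplyr::arrange(.data$qid, dplyr::desc(.data$bitscore), .data$evalue, .data$sid) %>%
    dplyr::distinct(.data$qid, .keep_all = TRUE)
}

#' Annotation summary against one database
#'
#' Counts the distinct queries with at least one hit passing the e-value
#' cutoff and reports the annotated percentage (rounded to the nearest
#' integer, as conventional in annotation tables).
#'
#' @param hits Hit tibble.
#' @param n_unigenes Total number of unigenes searched.
#' @param db_name Database label for the report row.
#' @param evalue_max Inclusive e-value cutoff (default `1e-5`).
#' @return One-row tibble: `db_name, n_unigenes, n_annotated, n_unannotated,
#'   pct_annotated`.
#' @export
annotation_summary <- function(hits, n_unigenes, db_name = "db", evalue_max = 1e-5) {
  n_annot <- dplyr::n_distinct(filter_hits(hits, evalue_max)$qid)
  if (n_annot > n_unigenes) {
    abort(sprintf("%d annotated queries exceed n_unigenes = %d", n_annot, n_unigenes))
  }
  tibble(
    db_name = db_name,
    n_unigenes = as.integer(n_unigenes),
    n_annotated = as.integer(n_annot),
    n_unannotated = as.integer(n_unigenes - n_annot),
    pct_annotated = round(100 * n_annot / n_unigenes)
  )
}

#' Subject coverage of one query/subject pair
#'
#' Merges the subject-side spans of all HSPs of a single `(qid, sid)` pair
#' and returns the merged length as a fraction of the subject length.
#'
#' @param hits Hit tibble restricted to one `(qid, sid)` pair.
#' @param slen Subject length in residues.
#' @return Coverage fraction in `[0, 1]`.
#' @export
subject_coverage <- function(hits, slen) {
  stopifnot(slen > 0)
  if (nrow(hits) == 0) return(0)
  if (dplyr::n_distinct(hits$qid) > 1 || dplyr::n_distinct(hits$sid) > 1) {
    abort("subject_coverage() expects hits of a single (qid, sid) pair")
  }
  if (any(hits$sstart < 1 | hits$send > slen)) {
    abort(sprintf("subject span outside [1, %d] for subject %s", slen, hits$sid[1]))
  }
  iv <- cbind(hits$sstart - 1L, hits$send)  # to half-open
  interval_total(merge_intervals(iv)) / slen
}

#' Count reference proteins fully covered by single queries
#'
#' A subject (reference protein) counts as full-length when the best single
#' query covers at least `threshold` of its length, HSPs of that one
#' query/subject pair being interval-merged on the subject. The threshold is
#' inclusive. Set `union_queries = TRUE` to merge intervals across all
#' queries of a subject instead (off by default).
#'
#' @param hits Hit tibble (already e-value filtered if desired).
#' @param slen_table Named integer vector or two-column tibble
#'   (`sid`, `slen`) giving subject lengths in residues.
#' @param threshold Minimum coverage fraction (default 0.90, inclusive).
#' @param union_queries Merge coverage across queries (default `FALSE`).
#' @return A list with `n_full_length` (count) and `records`, a tibble of
#'   class with one row per subject: `sid, slen, best_qid,
#'   best_coverage_frac, is_full_length`.
#' @export
count_full_length <- function(hits, slen_table, threshold = 0.90,
                              union_queries = FALSE) {
  slen_of <- as_slen_lookup(slen_table)
  if (nrow(hits) == 0) {
    return(list(n_full_length = 0L, records = tibble(
      sid = character(), slen = integer(), best_qid = character(),
      best_coverage_frac = numeric(), is_full_length = logical()
    )))
  }
  missing <- setdiff(unique(hits$sid), names(slen_of))
  if (length(missing) > 0) {
    abort(sprintf("subject length missing for: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  pair_cov <- hits %>%
    dplyr::group_by(.data$sid, qid = if (union_queries) "*union*" else .data$qid) %>%
    dplyr::group_modify(function(g, key) {
      sl <- slen_of[[key$sid]]
      if (any(g$sstart < 1 | g$send > sl)) {
        abort(sprintf("subject span outside [1, %d] for subject %s", sl, key$sid))
      }
      iv <- cbind(g$sstart - 1L, g$send)
      tibble(coverage_frac = interval_total(merge_intervals(iv)) / sl)
    }) %>%
    dplyr::ungroup()
  records <- pair_cov %>%
    dplyr::arrange(.data$sid, dplyr::desc(.data$coverage_frac), .data$qid) %>%
    dplyr::distinct(.data$sid, .keep_all = TRUE) %>%
    dplyr::transmute(
      sid = .data$sid,
      slen = as.integer(unname(slen_of[.data$sid])),
      best_qid = .data$qid,
      best_coverage_frac = .data$coverage_frac,
      is_full_length = .data$coverage_frac >= threshold
    )
  list(n_full_length = sum(records$is_full_length), records = records)
}

as_slen_lookup <- function(slen_table) {
  if (is.data.frame(slen_table)) {
    stats::setNames(as.integer(slen_table$slen), slen_table$sid)
  } else {
    v <- slen_table
    storage.mode(v) <- "integer"
    v
  }
}

#' Transcriptome coverage counts
#'
#' Distinct queries with a passing hit and distinct subjects hit, after the
#' e-value filter.
#'
#' @param hits Hit tibble.
#' @param evalue_max Inclusive e-value cutoff (default `1e-5`).
#' @return One-row tibble: `n_queries_with_hit, n_subjects_hit`.
#' @export
transcriptome_coverage <- function(hits, evalue_max = 1e-5) {
  f <- filter_hits(hits, evalue_max)
  tibble(
    n_queries_with_hit = dplyr::n_distinct(f$qid),
    n_subjects_hit = dplyr::n_distinct(f$sid)
  )
}

#' Tally best-hit descriptions by gene-family keyword
#'
#' Counts, per family, the queries whose best-hit description contains any
#' of the family's patterns (case-insensitive fixed substrings). A query may
#' count toward several families.
#'
#' @param annotations Tibble with columns `qid` and `description` (one row
#'   per query, e.g. best-hit descriptions).
#' @param families Named list mapping family label to a character vector of
#'   patterns.
#' @return Tibble with columns `family`, `n`.
#' @export
keyword_tally <- function(annotations, families) {
  purrr::imap_dfr(families, function(patterns, fam) {
    hit <- Reduce(`|`, lapply(patterns, function(p) {
      stringr::str_detect(annotations$description, stringr::fixed(p, ignore_case = TRUE))
    }), init = rep(FALSE, nrow(annotations)))
    tibble(family = fam, n = sum(hit))
  })
}
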