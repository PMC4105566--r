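# Perfect microsatellite (SSR) detection for di- through hexanucleotide
# motifs, canonical motif grouping (minimal rotation over both strands),
# class/motif frequency summaries and annotated marker-candidate selection.

DEFAULT_MIN_UNITS <- c(di = 6L, tri = 4L, tetra = 3L, penta = 3L, hexa = 3L)
SSR_CLASSES <- stats::setNames(names(DEFAULT_MIN_UNITS), 2:6)

#' Find perfect SSRs in sequences
#'
#' Detects maximal perfect tandem repeats with motif lengths 2-6
#' (mononucleotide runs are out of scope: on 454-style data they are
#' dominated by homopolymer sequencing artifacts). Runs containing `N` are
#' never part of a locus. Overlapping candidates are resolved leftmost
#' first, then longest; the motif is reported in the phase of its first
#' occurrence and is always primitive (not itself a tandem repeat of a
#' shorter motif).
#'
#' @param seqs Tibble with `id` and `seq` columns (or a named character
#'   vector of sequences).
#' @param min_units Named integer vector of minimum repeat units per class
#'   (default `c(di = 6, tri = 4, tetra = 3, penta = 3, hexa = 3)`).
#' @return Tibble with columns `seq_id, start, end` (1-based inclusive),
#'   `motif, canonical_motif, n_repeats, class`.
#' @export
#' @examples
#' find_ssrs(c(u1 = "GGACACACACACACGG"))
find_ssrs <- function(seqs, min_units = DEFAULT_MIN_UNITS) {
  if (!is.data.frame(seqs)) seqs <- tibble(id = names(seqs), seq = unname(seqs))
  stopifnot(all(names(DEFAULT_MIN_UNITS) %in% names(min_units)))
  seqs$seq <- normalize_seq(seqs$seq)
  assert_dna(seqs$seq)
  out <- purrr::map2_dfr(seqs$id, seqs$seq, find_ssrs_one, min_units = min_units)
  if (nrow(out) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  motif = character(), canonical_motif = character(),
                  n_repeats = integer(), class = character()))
  }
  out
}

# Candidates are enumerated at every start position via the period vector
# pm[i] = (seq[i] == seq[i + m]): a start i supports
# 1 + floor(run_of_true(pm, i) / m) whole repeat units. Enumerating every
# phase matters: a qualifying run can begin one base after an equally long
# phase-shifted run that loses the overlap resolution, and only the
# all-starts candidate set resolves such junctions correctly.
find_ssrs_one <- function(seq_id, seq, min_units) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cand <- purrr::map_dfr(2:6, function(m) {
    if (n < 2 * m) return(NULL)
    np <- n - m
    pm <- ch[1:np] == ch[(m + 1):n] & ch[1:np] != "N" & ch[(m + 1):n] != "N"
    run <- integer(np + 1)                 # true-run length starting at i
    for (i in np:1) run[i] <- if (pm[i]) run[i + 1] + 1L else 0L
    starts <- seq_len(n - 2 * m + 1)
    units <- run[starts] %/% m + 1L
    thr <- min_units[[SSR_CLASSES[[as.character(m)]]]]
    keep <- starts[units >= thr]
    if (length(keep) == 0) return(NULL)
    motif <- substring(seq, keep, keep + m - 1)
    ok <- vapply(motif, is_primitive, logical(1), USE.NAMES = FALSE)
    if (!any(ok)) return(NULL)
    tibble(start0 = keep[ok] - 1L, len = units[match(keep[ok], starts)] * m,
           motif = motif[ok], motif_len = m,
           n_repeats = units[match(keep[ok], starts)])
  })
  if (nrow(cand) == 0) return(NULL)
  # leftmost-first, then longest, greedy non-overlapping resolution
  # (stable order keeps the shortest motif length on full ties)
  cand <- cand[order(cand$start0, -cand$len), , drop = FALSE]
  kept <- logical(nrow(cand))
  frontier <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start0[i] >= frontier) {
      kept[i] <- TRUE
      frontier <- cand$start0[i] + cand$len[i]
    }
  }
  cand <- cand[kept, , drop = FALSE]
  tibble(
    seq_id = seq_id,
    start = cand$start0 + 1L,
    end = cand$start0 + cand$len,
    motif = cand$motif,
    canonical_motif = canonical_motif(cand$motif),
    n_repeats = cand$n_repeats,
    class = unname(SSR_CLASSES[as.character(cand$motif_len)])
  )
}

is_primitive <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m - 1)) {
    if (m %% d == 0 &&
        motif == strrep(substr(motif, 1, d), m / d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest string among all rotations of the motif
#' and all rotations of its reverse complement, so that e.g. `TA`, `AT` and
#' `GT`-on-the-other-strand all group under one label. Vectorized.
#'
#' @param motif Character vector of primitive motifs, lengths 2-6.
#' @return Character vector of canonical motifs.
#' @export
#' @examples
#' canonical_motif(c("TA", "GT", "AT"))
canonical_motif <- function(motif) {
  vapply(motif, function(x) {
    m <- nchar(x)
    if (m < 2 || m > 6) abort("motif length must be 2-6")
    if (!is_primitive(x)) abort(sprintf("motif '%s' is not primitive", x))
    both <- c(x, revcomp(x))
    rots <- unlist(lapply(both, function(s) {
      d <- strrep(s, 2)
      substring(d, 1:m, m:(2 * m - 1))
    }))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Class and motif frequency summary of SSR loci
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @return An object of class `ssr_summary`: a list with `by_class`
#'   (`class, n, pct`) and `by_motif` (`class, canonical_motif, n,
#'   pct_of_class`), percentages to 2 decimals.
#' @export
ssr_summary <- function(loci) {
  classes <- unname(SSR_CLASSES)
  n_total <- nrow(loci)
  by_class <- tibble(class = classes) %>%
    dplyr::left_join(dplyr::count(loci, .data$class), by = "class") %>%
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pct = if (n_total > 0) round(100 * .data$n / n_total, 2) else 0
    )
  by_motif <- loci %>%
    dplyr::count(.data$class, .data$canonical_motif) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(pct_of_class = round(100 * .data$n / sum(.data$n), 2)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$class, dplyr::desc(.data$n), .data$canonical_motif)
  structure(list(n_total = n_total, by_class = by_class, by_motif = by_motif),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("<ssr_summary> %d loci\n", x$n_total))
  print(x$by_class)
  invisible(x)
}

#' SSR class frequencies as a tibble
#' @param x An `ssr_summary`.
#' @param ... Unused.
#' @method tidy ssr_summary
#' @export
tidy.ssr_summary <- function(x, ...) x$by_class

#' SSR class frequency bar chart
#' @param object An `ssr_summary`.
#' @param ... Unused.
#' @method autoplot ssr_summary
#' @export
autoplot.ssr_summary <- function(object, ...) {
  d <- object$by_class
  d$class <- factor(d$class, levels = unname(SSR_CLASSES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "motif class", y = "% of SSR loci",
                  title = sprintf("%d SSR loci", object$n_total))
}

#' Annotated SSR-bearing sequences: microsatellite marker candidates
#'
#' Sequencing artifacts (homopolymer over/undercall in particular) can
#' masquerade as repeats; an SSR inside a functionally annotated sequence is
#' far less likely to be a sequencing error, so the intersection of
#' SSR-bearing and annotated ids is the marker candidate set.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param annotated_ids Character vector of annotated sequence ids.
#' @return Sorted character vector of candidate sequence ids.
#' @export
marker_candidates <- function(loci, annotated_ids) {
  sort(intersect(unique(loci$seq_id), annotated_ids))
}
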