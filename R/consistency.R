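# Internal and External Consistency Indexes (ICI/ECI): the reference-free
# assembly evaluation at the heart of the package.
#
# ICI scores how completely and identically a member read maps back onto its
# contig consensus: 100 means the entire read aligned at 100% identity, and
# the denominator is the full read length so partial mapping is penalized.
# ECI scores how similar two distinct contigs are: a contig aligned
# perfectly against a copy of itself scores 100, and values above 75 flag
# consensus pairs so close that they likely represent one gene split across
# contigs.

#' Internal consistency of one read against a consensus
#'
#' `ICI = 100 * n_ident / nchar(read)` from the best local alignment of the
#' read against the consensus (both strands); 0 when no positive-scoring
#' alignment exists.
#'
#' @param read_seq Read sequence (non-empty DNA string).
#' @param consensus Consensus sequence of the read's contig.
#' @param ... Scoring parameters passed to [local_align()].
#' @return ICI score in `[0, 100]`.
#' @export
read_ici <- function(read_seq, consensus, ...) {
  if (!nzchar(read_seq)) abort("empty read")
  aln <- local_align(read_seq, consensus, ...)
  if (is.null(aln)) return(0)
  min(100, 100 * aln$n_ident / nchar(read_seq))
}

#' Internal Consistency Index of an assembly
#'
#' Scores every read that is a member of a contig (singletons are excluded:
#' a singleton trivially maps onto itself at 100 and would swamp the mean)
#' and averages the per-read scores.
#'
#' @param assembly A [assembly()] object.
#' @param reads Read tibble (`id`, `seq`) covering at least all clustered
#'   reads.
#' @param membership Optional `read_id -> contig_id` tibble; defaults to the
#'   membership recorded in the assembly's contigs.
#' @param ... Scoring parameters passed to [local_align()].
#' @return An object of class `ici_result`; see [tidy.ici_result()] and
#'   [glance.ici_result()].
#' @export
assembly_ici <- function(assembly, reads, membership = NULL, ...) {
  if (nrow(assembly$contigs) == 0) abort("nothing to score: assembly has no contigs")
  membership <- membership %||% assembly_membership(assembly)
  membership <- membership[membership$contig_id %in% assembly$contigs$id, ]
  missing <- setdiff(membership$read_id, reads$id)
  if (length(missing) > 0) {
    abort(sprintf("membership references unknown read(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  seq_of <- stats::setNames(reads$seq, reads$id)
  cons_of <- stats::setNames(assembly$contigs$consensus, assembly$contigs$id)
  score_one <- function(r, ctg) read_ici(seq_of[[r]], cons_of[[ctg]], ...)
  per_read <- membership %>%
    dplyr::mutate(ici = purrr::map2_dbl(.data$read_id, .data$contig_id, score_one))
  structure(
    list(
      assembly_name = assembly$name,
      per_read = per_read,
      mean_ici = mean(per_read$ici),
      n_reads_scored = nrow(per_read)
    ),
    class = "ici_result"
  )
}

#' External consistency of a pair of contigs
#'
#' `ECI = 100 * identity_frac * (aln_cols / min(len(a), len(b)))` from the
#' best local alignment of the two consensi: the product of alignment
#' identity and the fraction of the shorter contig covered by the overlap.
#' A contig fully contained in another at perfect identity scores 100.
#'
#' @param a,b Consensus sequences of two distinct contigs.
#' @param ... Scoring parameters passed to [local_align()].
#' @return ECI score in `[0, 100]` (0 when no alignment exists).
#' @export
pair_eci <- function(a, b, ...) {
  aln <- local_align(a, b, ...)
  if (is.null(aln)) return(0)
  min(100, 100 * aln$identity_frac * (aln$aln_cols / min(nchar(a), nchar(b))))
}

#' External Consistency Index of an assembly
#'
#' For each contig, the ECI against its best-scoring other contig. Contigs
#' with no positive-scoring partner contribute 0 to the mean. Contigs whose
#' best ECI exceeds `merge_threshold` are flagged as likely fragments of a
#' single gene that the assembler failed to merge.
#'
#' @param assembly A [assembly()] object.
#' @param merge_threshold Flagging threshold on the 0-100 ECI scale
#'   (default 75).
#' @param kmer_prefilter If `TRUE`, skip contig pairs sharing no 11-mer (on
#'   either strand) without aligning them. This can only miss pairs whose
#'   best alignment is below 11 matched bases, i.e. ECI contributions of a
#'   few points at most; it is off by default so reported scores are exact.
#' @param ... Scoring parameters passed to [local_align()].
#' @return An object of class `eci_result`; see [tidy.eci_result()] and
#'   [glance.eci_result()].
#' @export
assembly_eci <- function(assembly, merge_threshold = 75, kmer_prefilter = FALSE, ...) {
  contigs <- assembly$contigs
  if (nrow(contigs) < 2) {
    warn("fewer than 2 contigs: ECI undefined, reporting 0")
    per_contig <- tibble(contig_id = contigs$id,
                         best_partner = NA_character_,
                         eci = rep(0, nrow(contigs)),
                         flagged = rep(FALSE, nrow(contigs)))
    return(structure(
      list(assembly_name = assembly$name, per_contig = per_contig,
           mean_eci = 0, n_flagged = 0L, merge_threshold = merge_threshold),
      class = "eci_result"
    ))
  }
  n <- nrow(contigs)
  kmers <- NULL
  if (kmer_prefilter) kmers <- lapply(contigs$consensus, canonical_kmer_set, k = 11L)
  eci_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (kmer_prefilter && length(intersect(kmers[[i]], kmers[[j]])) == 0) next
      e <- pair_eci(contigs$consensus[i], contigs$consensus[j], ...)
      eci_mat[i, j] <- e
      eci_mat[j, i] <- e
    }
  }
  best_j <- apply(eci_mat, 1, which.max)
  best_e <- eci_mat[cbind(seq_len(n), best_j)]
  per_contig <- tibble(
    contig_id = contigs$id,
    best_partner = ifelse(best_e > 0, contigs$id[best_j], NA_character_),
    eci = best_e,
    flagged = best_e > merge_threshold
  )
  structure(
    list(
      assembly_name = assembly$name,
      per_contig = per_contig,
      mean_eci = mean(per_contig$eci),
      n_flagged = sum(per_contig$flagged),
      merge_threshold = merge_threshold
    ),
    class = "eci_result"
  )
}

canonical_kmer_set <- function(seq, k = 11L) {
  if (nchar(seq) < k) return(character(0))
  km <- substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
  km <- km[!grepl("N", km, fixed = TRUE)]
  unique(pmin(km, revcomp(km)))
}

#' Evaluate and rank candidate assemblies
#'
#' Computes, per candidate, the clustering summary (contig and unigene
#' counts and mean lengths), mean ICI, mean ECI and - when a hit table or a
#' pre-computed count is supplied - the number of annotated unigenes.
#' Candidates are ranked by mean ICI (highest first), ties by annotated
#' unigene count, final ties by lowest mean ECI; all three criteria are
#' reported so the ranking can be overridden.
#'
#' @param candidates Named list; each element is a list with fields
#'   `assembly` (a [assembly()] object), `reads` (read tibble), optional
#'   `membership`, and optional `hits` (tabular hit tibble) or `n_annotated`
#'   (count).
#' @param merge_threshold ECI flagging threshold (default 75).
#' @param evalue_max E-value cutoff applied to `hits` when counting
#'   annotated unigenes (default 1e-5, inclusive).
#' @param ... Scoring parameters passed to [local_align()].
#' @return A tibble of class `assembly_evaluation`, one row per candidate in
#'   rank order, with columns `rank, assembly, n_clustered, n_contigs,
#'   mean_contig_len, n_unigenes, mean_unigene_len, mean_ici, mean_eci,
#'   n_annotated`.
#' @export
evaluate_assemblies <- function(candidates, merge_threshold = 75,
                                evalue_max = 1e-5, ...) {
  if (length(candidates) < 1) abort("at least one candidate is required")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- paste0("assembly", seq_along(candidates))
  }
  rows <- purrr::imap(candidates, function(cand, nm) {
    asm <- cand$assembly
    reads <- cand$reads
    ici <- assembly_ici(asm, reads, membership = cand$membership, ...)
    eci <- assembly_eci(asm, merge_threshold = merge_threshold, ...)
    n_annot <- cand$n_annotated
    if (is.null(n_annot) && !is.null(cand$hits)) {
      n_annot <- dplyr::n_distinct(filter_hits(cand$hits, evalue_max)$qid)
    }
    read_len <- stats::setNames(nchar(reads$seq), reads$id)
    singleton_lens <- read_len[intersect(asm$singletons, reads$id)]
    uni_lens <- c(nchar(asm$contigs$consensus), singleton_lens)
    tibble(
      assembly = asm$name %||% nm,
      n_clustered = ici$n_reads_scored,
      n_contigs = nrow(asm$contigs),
      mean_contig_len = mean(nchar(asm$contigs$consensus)),
      n_unigenes = n_unigenes(asm),
      mean_unigene_len = mean(uni_lens),
      mean_ici = ici$mean_ici,
      mean_eci = eci$mean_eci,
      n_annotated = if (is.null(n_annot)) NA_integer_ else as.integer(n_annot)
    )
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$mean_ici,
               -ifelse(is.na(out$n_annotated), -Inf, out$n_annotated),
               out$mean_eci,
               out$assembly)
  out <- out[ord, ]
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("assembly_evaluation", class(out))
  out
}

#' @export
print.ici_result <- function(x, ...) {
  cat(sprintf("<ici_result '%s'> mean ICI %.2f over %d clustered reads\n",
              x$assembly_name, x$mean_ici, x$n_reads_scored))
  invisible(x)
}

#' @export
print.eci_result <- function(x, ...) {
  cat(sprintf("<eci_result '%s'> mean ECI %.2f; %d contig(s) above %.0f\n",
              x$assembly_name, x$mean_eci, x$n_flagged, x$merge_threshold))
  invisible(x)
}

#' Per-read ICI scores as a tibble
#' @param x An `ici_result`.
#' @param ... Unused.
#' @method tidy ici_result
#' @export
tidy.ici_result <- function(x, ...) x$per_read

#' One-row ICI summary
#' @param x An `ici_result`.
#' @param ... Unused.
#' @method glance ici_result
#' @export
glance.ici_result <- function(x, ...) {
  tibble(assembly = x$assembly_name, mean_ici = x$mean_ici,
         n_reads_scored = x$n_reads_scored)
}

#' Per-contig ECI scores as a tibble
#' @param x An `eci_result`.
#' @param ... Unused.
#' @method tidy eci_result
#' @export
tidy.eci_result <- function(x, ...) x$per_contig

#' One-row ECI summary
#' @param x An `eci_result`.
#' @param ... Unused.
#' @method glance eci_result
#' @export
glance.eci_result <- function(x, ...) {
  tibble(assembly = x$assembly_name, mean_eci = x$mean_eci,
         n_flagged = x$n_flagged, merge_threshold = x$merge_threshold)
}

#' Histogram of per-read ICI scores
#' @param object An `ici_result`.
#' @param binwidth Histogram bin width on the ICI scale.
#' @param ... Unused.
#' @method autoplot ici_result
#' @export
autoplot.ici_result <- function(object, binwidth = 2.5, ...) {
  ggplot2::ggplot(object$per_read, ggplot2::aes(x = .data$ici)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "Internal Consistency Index",
      y = "reads",
      title = sprintf("%s: mean ICI %.2f", object$assembly_name, object$mean_ici)
    )
}

#' Best-partner ECI scores per contig
#' @param object An `eci_result`.
#' @param ... Unused.
#' @method autoplot eci_result
#' @export
autoplot.eci_result <- function(object, ...) {
  ggplot2::ggplot(object$per_contig,
                  ggplot2::aes(x = stats::reorder(.data$contig_id, .data$eci),
                               y = .data$eci, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$merge_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "best-partner ECI",
                  title = sprintf("%s: %d contig(s) flagged",
                                  object$assembly_name, object$n_flagged))
}
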