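# The assembly container: contigs (consensus + member reads) and singletons,
# together forming the unigene set.

#' Construct an assembly of contigs and singletons
#'
#' A unigene set is the union of contigs (consensus sequences built from two
#' or more overlapping reads) and singletons (reads that clustered with
#' nothing). Validation enforces the clustering invariants: unique contig
#' ids, >= 2 unique members per contig, and no read claimed by two contigs
#' or by a contig and the singleton pool at once.
#'
#' @param contigs Tibble with columns `id`, `consensus` and `members`
#'   (list-column of member read ids).
#' @param singletons Character vector of singleton read ids.
#' @param name Label for the assembly (e.g. the assembler that produced it).
#' @return An object of class `qc_assembly`.
#' @export
assembly <- function(contigs, singletons = character(0), name = "assembly") {
  contigs <- as_tibble(contigs)
  stopifnot(all(c("id", "consensus", "members") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) abort("contig ids must be unique")
  if (nrow(contigs) > 0) {
    assert_dna(contigs$consensus, "contig consensus")
    if (any(nchar(contigs$consensus) == 0)) abort("contig consensus length must be >= 1")
    n_mem <- lengths(contigs$members)
    if (any(n_mem < 2)) {
      abort(sprintf("contig(s) with fewer than 2 members: %s",
                    paste(contigs$id[n_mem < 2], collapse = ", ")))
    }
    if (any(vapply(contigs$members, anyDuplicated, integer(1)) > 0)) {
      abort("contig members must be unique within a contig")
    }
  }
  all_members <- unlist(contigs$members, use.names = FALSE)
  dup <- all_members[duplicated(all_members)]
  if (length(dup) > 0) {
    abort(sprintf("read(s) assigned to more than one contig: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  both <- intersect(all_members, singletons)
  if (length(both) > 0) {
    abort(sprintf("read(s) both clustered and singleton: %s",
                  paste(both, collapse = ", ")))
  }
  structure(
    list(name = name, contigs = contigs, singletons = unique(singletons)),
    class = "qc_assembly"
  )
}

#' Assemble the contig table and a membership table into an assembly
#'
#' Convenience constructor for the common case where contig membership lives
#' in a separate `read_id -> contig_id` table (e.g. from [read_membership()]).
#'
#' @param consensi Tibble with `id` and `consensus` (or `seq`) columns.
#' @param membership Tibble with `read_id`, `contig_id`.
#' @param singletons Character vector of singleton read ids.
#' @inheritParams assembly
#' @export
assembly_from_membership <- function(consensi, membership, singletons = character(0),
                                     name = "assembly") {
  seq_col <- if ("consensus" %in% names(consensi)) "consensus" else "seq"
  unknown <- setdiff(membership$contig_id, consensi$id)
  if (length(unknown) > 0) {
    abort(sprintf("membership references unknown contig(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  members <- split(membership$read_id, membership$contig_id)
  contigs <- tibble(
    id = consensi$id,
    consensus = consensi[[seq_col]],
    members = unname(members[consensi$id])
  )
  contigs$members[vapply(contigs$members, is.null, logical(1))] <- list(character(0))
  keep <- lengths(contigs$members) >= 2
  assembly(contigs[keep, ], singletons, name = name)
}

#' @export
print.qc_assembly <- function(x, ...) {
  cat(sprintf(
    "<qc_assembly '%s'> %d contigs + %d singletons = %d unigenes\n",
    x$name, nrow(x$contigs), length(x$singletons), n_unigenes(x)
  ))
  invisible(x)
}

#' Number of unigenes (contigs + singletons) in an assembly
#' @param x A `qc_assembly`.
#' @export
n_unigenes <- function(x) nrow(x$contigs) + length(x$singletons)

#' Membership table of an assembly
#'
#' @param x A `qc_assembly`.
#' @return Tibble with `read_id`, `contig_id`, one row per clustered read.
#' @export
assembly_membership <- function(x) {
  tibble(
    read_id = unlist(x$contigs$members, use.names = FALSE),
    contig_id = rep(x$contigs$id, lengths(x$contigs$members))
  )
}
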