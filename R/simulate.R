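# Deterministic synthetic-data generators: random transcriptomes, 454-style
# reads (length ~554 bases, optional adapters, homopolymer over/undercall
# and substitution errors), assembly variants with known defects, planted
# tabular hit files and planted SSR panels. Every planted quantity is
# recorded so downstream modules can be validated without external data.

#' Generate a random transcriptome
#'
#' I.i.d. random sequences with a target GC content. Pairs sharing more
#' canonical 11-mers than `shared_kmer_ceiling` are resampled so that
#' unrelated transcripts stay alignment-quiet (the ECI null).
#'
#' @param n Number of transcripts.
#' @param len_range Length range in bases (default `c(300, 2000)`).
#' @param gc Target GC fraction (default 0.4).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param shared_kmer_ceiling Maximum canonical 11-mers any pair may share
#'   (default 5).
#' @return Tibble with columns `id`, `seq`.
#' @export
sim_transcriptome <- function(n, len_range = c(300, 2000), gc = 0.4, seed = NULL,
                              shared_kmer_ceiling = 5) {
  stopifnot(n >= 1, len_range[1] >= 12, len_range[1] <= len_range[2])
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    seqs <- vapply(lens, random_dna, character(1), gc = gc)
    ksets <- lapply(seqs, canonical_kmer_set, k = 11L)
    for (i in seq_len(n)) {
      for (try in 1:50) {
        shared <- if (i == 1) 0 else
          max(vapply(seq_len(i - 1),
                     function(j) length(intersect(ksets[[i]], ksets[[j]])),
                     numeric(1)))
        if (shared <= shared_kmer_ceiling) break
        seqs[i] <- random_dna(lens[i], gc = gc)
        ksets[[i]] <- canonical_kmer_set(seqs[i], k = 11L)
      }
    }
    tibble(id = sprintf("t%04d", seq_len(n)), seq = seqs)
  })
}

#' Simulate 454-style reads from a transcriptome
#'
#' Reads are substrings of transcripts (either strand), optionally flanked
#' by a 5' adapter and the reverse complement of a 3' adapter, with an
#' optional 454-style error model: per-homopolymer-run +/-1-base over- and
#' undercalls and i.i.d. substitutions. Provenance (source transcript, span
#' of the error-free insert, strand) is recorded for every read.
#'
#' @param transcripts Tibble with `id`, `seq` (e.g. [sim_transcriptome()]).
#' @param n_reads Number of reads to draw.
#' @param mean_len,sd_len Insert length distribution in bases (defaults 554
#'   and 100, echoing typical clean 454 read lengths); lengths are clamped
#'   to `[min_len, transcript length]`.
#' @param min_len Minimum insert length (default 40).
#' @param adapter Optional adapter sequence: attached verbatim at the 5'
#'   end and reverse-complemented at the 3' end of every read.
#' @param error_model `NULL` for error-free reads, or a list with any of
#'   `overcall_rate`, `undercall_rate` (per homopolymer run of length >= 2)
#'   and `subst_rate` (per base).
#' @param coverage_mode `"length_weighted"` samples source transcripts
#'   proportionally to length; `"even"` deals reads out round-robin so every
#'   transcript receives `n_reads / n_transcripts` reads.
#' @param seed Integer seed.
#' @return List with `reads` (read tibble) and `truth` (provenance tibble:
#'   `read_id, transcript_id, start, end` 0-based half-open on the
#'   transcript, `strand, insert_len`).
#' @export
sim_reads <- function(transcripts, n_reads, mean_len = 554, sd_len = 100,
                      min_len = 40, adapter = NULL, error_model = NULL,
                      coverage_mode = c("length_weighted", "even"), seed = NULL) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(n_reads >= 1)
  em <- utils::modifyList(
    list(overcall_rate = 0, undercall_rate = 0, subst_rate = 0),
    error_model %||% list()
  )
  with_seed(seed, {
    tlen <- nchar(transcripts$seq)
    src <- if (coverage_mode == "even") {
      rep_len(seq_len(nrow(transcripts)), n_reads)
    } else {
      sample(seq_len(nrow(transcripts)), n_reads, replace = TRUE, prob = tlen)
    }
    ins_len <- pmin(tlen[src], pmax(min_len, round(stats::rnorm(n_reads, mean_len, sd_len))))
    start <- vapply(seq_len(n_reads),
                    function(i) sample.int(tlen[src[i]] - ins_len[i] + 1L, 1L) - 1L,
                    integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- substr(transcripts$seq[src[i]], start[i] + 1L, start[i] + ins_len[i])
      if (strand[i] == "-") s <- revcomp(s)
      if (em$subst_rate > 0) s <- mutate_seq(s, em$subst_rate)
      if (em$overcall_rate > 0 || em$undercall_rate > 0) {
        s <- apply_homopolymer_errors(s, em$overcall_rate, em$undercall_rate)
      }
      if (!is.null(adapter)) {
        s <- paste0(normalize_seq(adapter), s, revcomp(normalize_seq(adapter)))
      }
      seqs[i] <- s
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    list(
      reads = tibble(id = ids, seq = seqs,
                     masked = rep(list(empty_intervals()), n_reads)),
      truth = tibble(read_id = ids, transcript_id = transcripts$id[src],
                     start = start, end = start + ins_len,
                     strand = strand, insert_len = ins_len)
    )
  })
}

# i.i.d. substitutions at rate p (each hit base becomes a different base)
mutate_seq <- function(seq, p) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < p)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[hit] <- vapply(ch[hit],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
  paste(ch, collapse = "")
}

# 454 homopolymer model: each mononucleotide run of length >= 2 gains one
# base with prob `overcall`, else loses one with prob `undercall`.
apply_homopolymer_errors <- function(seq, overcall, undercall) {
  r <- rle(strsplit(seq, "")[[1]])
  run <- r$lengths >= 2
  u <- stats::runif(length(r$lengths))
  r$lengths[run & u < overcall] <- r$lengths[run & u < overcall] + 1L
  under <- run & u >= overcall & u < overcall + undercall
  r$lengths[under] <- r$lengths[under] - 1L
  paste(inverse.rle(r), collapse = "")
}

#' Assembly variants with known defects
#'
#' Builds candidate assemblies from simulated reads and their provenance:
#' * `truth`: contigs are the source transcripts, reads assigned by
#'   provenance (transcripts with fewer than 2 reads contribute their reads
#'   as singletons);
#' * `split`: each transcript with >= 4 reads is emitted twice, as the
#'   full consensus plus its contained middle half - the redundant-contig
#'   defect in which one gene is represented by two contigs; by
#'   construction each such pair has ECI exactly 100;
#' * `mutated`: truth consensi with i.i.d. substitutions at
#'   `mutation_rate`;
#' * `shuffled`: truth contigs with reads randomly reassigned among them
#'   (negative control).
#'
#' @param transcripts Transcript tibble the reads were drawn from.
#' @param reads Read tibble from [sim_reads()].
#' @param truth Provenance tibble from [sim_reads()].
#' @param mutation_rate Substitution rate for the `mutated` variant
#'   (default 0.05).
#' @param seed Integer seed (drives the `mutated` and `shuffled` variants).
#' @return Named list of variants; each is a list with `assembly` (a
#'   [assembly()] object) and `membership` (tibble).
#' @export
sim_assembly_variants <- function(transcripts, reads, truth, mutation_rate = 0.05,
                                  seed = NULL) {
  counts <- table(truth$transcript_id)
  clustered <- names(counts)[counts >= 2]
  lone_reads <- truth$read_id[!truth$transcript_id %in% clustered]
  base_contigs <- tibble(
    id = clustered,
    consensus = transcripts$seq[match(clustered, transcripts$id)],
    members = unname(split(truth$read_id, truth$transcript_id)[clustered])
  )
  truth_asm <- assembly(base_contigs, singletons = lone_reads, name = "truth")
  truth_mem <- assembly_membership(truth_asm)

  with_seed(seed, {
    mut_contigs <- base_contigs
    mut_contigs$consensus <- vapply(mut_contigs$consensus, mutate_seq,
                                    character(1), p = mutation_rate)
    mutated_asm <- assembly(mut_contigs, singletons = lone_reads, name = "mutated")

    shuf_mem <- truth_mem
    shuf_mem$read_id <- sample(shuf_mem$read_id)
    shuf_asm <- assembly_from_membership(
      dplyr::rename(base_contigs[, c("id", "consensus")], seq = "consensus"),
      shuf_mem, singletons = lone_reads, name = "shuffled"
    )

    split_parts <- purrr::map(clustered, function(tid) {
      mem <- truth[truth$transcript_id == tid, ]
      cons <- transcripts$seq[match(tid, transcripts$id)]
      L <- nchar(cons)
      if (nrow(mem) < 4) {
        return(list(contigs = tibble(id = tid, consensus = cons,
                                     members = list(mem$read_id))))
      }
      lo <- floor(L / 4)            # middle half, 0-based half-open
      hi <- lo + floor(L / 2)
      mid <- (mem$start + mem$end) / 2
      to_b <- mid >= lo & mid < hi
      # guarantee >= 2 members on each side, moving reads closest to the
      # middle (deterministic: by |midpoint - centre|)
      ord <- order(abs(mid - L / 2))
      while (sum(to_b) < 2) {
        to_b[ord[which(!to_b[ord])[1]]] <- TRUE
      }
      while (sum(!to_b) < 2) {
        ridx <- rev(ord)
        to_b[ridx[which(to_b[ridx])[1]]] <- FALSE
      }
      list(contigs = tibble(
        id = paste0(tid, c(".a", ".b")),
        consensus = c(cons, substr(cons, lo + 1L, hi)),
        members = list(mem$read_id[!to_b], mem$read_id[to_b])
      ))
    })
    split_asm <- assembly(dplyr::bind_rows(purrr::map(split_parts, "contigs")),
                          singletons = lone_reads, name = "split")

    list(
      truth = list(assembly = truth_asm, membership = truth_mem),
      split = list(assembly = split_asm, membership = assembly_membership(split_asm)),
      mutated = list(assembly = mutated_asm, membership = assembly_membership(mutated_asm)),
      shuffled = list(assembly = shuf_asm, membership = assembly_membership(shuf_asm))
    )
  })
}

#' Generate a tabular hit file with planted subject coverage
#'
#' For every planted `(qid, sid, coverage_frac, evalue)` row, emits 1-3
#' non-overlapping HSPs whose merged subject coverage equals
#' `round(coverage_frac * slen)` residues exactly (within one residue of
#' the requested fraction).
#'
#' @param planted Tibble with columns `qid, sid, coverage_frac` (in
#'   `(0, 1]`) and `evalue`.
#' @param subjects Named integer vector (or `sid`/`slen` tibble) of subject
#'   lengths in residues.
#' @param pident Percent identity written on each HSP row (default 97).
#' @param seed Integer seed.
#' @return Hit tibble in the [read_tabular_hits()] 14-column layout.
#' @export
sim_hit_table <- function(planted, subjects, pident = 97, seed = NULL) {
  slen_of <- as_slen_lookup(subjects)
  stopifnot(all(planted$coverage_frac > 0), all(planted$coverage_frac <= 1))
  with_seed(seed, {
    rows <- purrr::pmap_dfr(planted, function(qid, sid, coverage_frac, evalue, ...) {
      sl <- slen_of[[sid]]
      if (is.null(sl)) abort(sprintf("unknown subject: %s", sid))
      covered <- round(coverage_frac * sl)
      if (covered < 1) {
        abort(sprintf("infeasible coverage %.3f of subject %s (%d residues)",
                      coverage_frac, sid, sl))
      }
      k_max <- min(3L, covered, sl - covered + 1L)
      k <- sample.int(k_max, 1L)
      seg <- tabulate(sample.int(k, covered - k, replace = TRUE), nbins = k) + 1L
      slack <- sl - covered - (k - 1L)
      gaps <- c(0L, tabulate(sample.int(k, slack, replace = TRUE), nbins = k)[-k] + 1L)
      sstart <- integer(k); send <- integer(k); pos <- 0L
      for (i in seq_len(k)) {
        pos <- pos + gaps[i]
        sstart[i] <- pos + 1L
        send[i] <- pos + seg[i]
        pos <- send[i]
      }
      qpos <- cumsum(c(1L, utils::head(seg, -1)))
      tibble(
        qid = qid, sid = sid, pident = pident, aln_len = seg,
        mismatches = as.integer(round((1 - pident / 100) * seg)), gapopens = 0L,
        qstart = qpos, qend = qpos + seg - 1L,
        sstart = sstart, send = send,
        evalue = evalue,
        bitscore = round(1.8 * seg - log10(evalue + 1e-300), 1),
        qlen = as.integer(sum(seg) + 20L), slen = as.integer(sl),
        sstrand = "+"
      )
    })
    rows
  })
}

#' Generate a panel of sequences with planted SSR loci
#'
#' Each sequence carries exactly one perfect SSR, with the motif class drawn
#' from `class_mix`, embedded in random flanks that are rejection-sampled
#' (with an internal scanner independent of [find_ssrs()]) so they neither
#' contain a qualifying repeat themselves nor extend or re-phase the planted
#' locus.
#'
#' @param n_loci Number of loci (= sequences).
#' @param class_mix Named class probabilities; the default mirrors the SSR
#'   class frequencies observed in the mussel transcriptome that motivated
#'   this package (tetra 35.68%, penta 30.75%, tri 16.3%, hexa 13.37%,
#'   di 3.98%).
#' @param min_units Minimum repeat units per class (as in [find_ssrs()]).
#' @param extra_units_max Extra units above the class minimum, drawn
#'   uniformly from `0:extra_units_max` (default 3).
#' @param flank Flank length in bases either side of the locus (default 40).
#' @param seed Integer seed.
#' @return List with `seqs` (tibble `id`, `seq`) and `loci` (planted loci in
#'   the [find_ssrs()] output layout).
#' @export
sim_ssr_panel <- function(n_loci,
                          class_mix = c(di = 0.0398, tri = 0.163, tetra = 0.3568,
                                        penta = 0.3075, hexa = 0.1337),
                          min_units = DEFAULT_MIN_UNITS,
                          extra_units_max = 3, flank = 40, seed = NULL) {
  class_mix <- class_mix / sum(class_mix)
  mlen_of <- stats::setNames(2:6, unname(SSR_CLASSES))
  with_seed(seed, {
    cls <- sample(names(class_mix), n_loci, replace = TRUE, prob = class_mix)
    rows <- purrr::map(seq_len(n_loci), function(i) {
      m <- mlen_of[[cls[i]]]
      units <- min_units[[cls[i]]] + sample.int(extra_units_max + 1L, 1L) - 1L
      repeat {
        motif <- random_dna(m, gc = 0.5)
        if (is_primitive(motif)) break
      }
      core <- strrep(motif, units)
      last <- substr(motif, m, m)
      first <- substr(motif, 1, 1)
      repeat {
        left <- random_dna(flank, gc = 0.5)
        right <- random_dna(flank, gc = 0.5)
        if (substr(left, flank, flank) == last) next
        if (substr(right, 1, 1) == first) next
        seq <- paste0(left, core, right)
        found <- scan_tandem_runs(seq, min_units)
        if (nrow(found) == 1 && found$start == flank + 1L &&
            found$end == flank + nchar(core) && found$motif == motif) break
      }
      list(
        seq = tibble(id = sprintf("s%05d", i), seq = seq),
        locus = tibble(seq_id = sprintf("s%05d", i),
                       start = flank + 1L, end = flank + nchar(core),
                       motif = motif, canonical_motif = canonical_motif(motif),
                       n_repeats = as.integer(units), class = cls[i])
      )
    })
    list(seqs = dplyr::bind_rows(purrr::map(rows, "seq")),
         loci = dplyr::bind_rows(purrr::map(rows, "locus")))
  })
}

# Plain positional scanner for perfect tandem runs (used only to vet
# simulated flanks; intentionally a different algorithm from find_ssrs):
# for every start and motif length, extend maximally, keep qualifying
# primitive runs, then resolve overlaps leftmost-first-then-longest.
scan_tandem_runs <- function(seq, min_units = DEFAULT_MIN_UNITS) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cand <- list()
  for (start in seq_len(n)) {
    for (m in 2:6) {
      if (start + 2 * m - 1 > n) next
      motif <- ch[start:(start + m - 1)]
      if (any(!motif %in% c("A", "C", "G", "T"))) next
      units <- 1L
      while (start + (units + 1L) * m - 1L <= n &&
             all(ch[(start + units * m):(start + (units + 1L) * m - 1L)] == motif)) {
        units <- units + 1L
      }
      mstr <- paste(motif, collapse = "")
      if (!is_primitive(mstr)) next
      if (units < min_units[[SSR_CLASSES[[as.character(m)]]]]) next
      cand[[length(cand) + 1L]] <-
        tibble(start = start, end = start + units * m - 1L, motif = mstr,
               n_repeats = units, class = SSR_CLASSES[[as.character(m)]])
    }
  }
  if (length(cand) == 0) {
    return(tibble(start = integer(), end = integer(), motif = character(),
                  n_repeats = integer(), class = character()))
  }
  cand <- dplyr::bind_rows(cand)
  # drop runs wholly inside a longer same-period run (non-maximal phases)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), ]
  kept <- cand[0, ]
  frontier <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > frontier) {
      kept <- rbind(kept, cand[i, ])
      frontier <- cand$end[i]
    }
  }
  kept
}
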