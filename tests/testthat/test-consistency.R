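# ICI/ECI metrics and assembly ranking.

make_asm <- function(consensi, members, singletons = character(0), name = "a") {
  assembly(tibble::tibble(
    id = names(consensi), consensus = unname(consensi),
    members = unname(members)
  ), singletons = singletons, name = name)
}

test_that("a read that is an exact substring of its consensus scores ICI 100", {
  set.seed(31)
  cons <- rand_dna(300)
  expect_equal(read_ici(substr(cons, 51, 150), cons), 100)
})

test_that("partial mapping and substitutions lower ICI by the expected amount", {
  set.seed(32)
  cons <- rand_dna(300)
  # 90 consensus bases + 10 unrelated tail bases: only 90 can align
  read <- paste0(substr(cons, 211, 300), strrep("T", 10))
  expect_equal(read_ici(read, cons), 90)

  # 100-base read with 5 interior substitutions: 95
  read <- substr(cons, 101, 200)
  for (pos in c(10, 30, 50, 70, 90)) {
    substr(read, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, pos, pos))[1]
  }
  expect_equal(read_ici(read, cons), 95)
  expect_error(read_ici("", cons), "empty")
})

test_that("ICI is monotone non-increasing in consensus substitutions", {
  set.seed(33)
  cons <- rand_dna(400)
  read <- substr(cons, 101, 300)
  mutated <- cons
  scores <- numeric(11)
  positions <- seq(110, 290, length.out = 10)
  scores[1] <- read_ici(read, mutated)
  for (k in 1:10) {
    p <- round(positions[k])
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), substr(mutated, p, p))[1]
    scores[k + 1] <- read_ici(read, mutated)
  }
  expect_equal(scores[1], 100)
  expect_true(all(diff(scores) <= 0))
})

test_that("assembly_ici scores clustered reads only and validates inputs", {
  set.seed(34)
  cons <- rand_dna(400)
  reads <- tibble::tibble(
    id = c("r1", "r2", "s1"),
    seq = c(substr(cons, 1, 150), substr(cons, 200, 380), rand_dna(100))
  )
  asm <- make_asm(c(c1 = cons), list(c("r1", "r2")), singletons = "s1")
  res <- assembly_ici(asm, reads)
  expect_s3_class(res, "ici_result")
  expect_equal(res$n_reads_scored, 2)         # singleton excluded
  expect_equal(res$mean_ici, 100)
  expect_named(glance(res), c("assembly", "mean_ici", "n_reads_scored"))
  expect_equal(nrow(tidy(res)), 2)

  expect_error(
    assembly_ici(asm, reads, membership = tibble::tibble(read_id = "zz", contig_id = "c1")),
    "unknown read"
  )
  empty <- assembly(tibble::tibble(id = character(), consensus = character(),
                                   members = list()), name = "none")
  expect_error(assembly_ici(empty, reads), "nothing to score")
})

test_that("pair ECI anchors: duplicate 100, containment 100, unrelated near 0", {
  set.seed(35)
  a <- rand_dna(500)
  expect_equal(pair_eci(a, a), 100)
  # contig equal to the last 60% of another: overlap covers all of it
  expect_equal(pair_eci(a, substr(a, 201, 500)), 100)
  # unrelated contigs from the k-mer-screened generator
  tx <- sim_transcriptome(8, len_range = c(450, 550), seed = 36)
  worst <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    worst <- max(worst, pair_eci(tx$seq[i], tx$seq[j]))
  }
  expect_lt(worst, 10)
})

test_that("assembly_eci flags redundant contigs and handles degenerate input", {
  set.seed(37)
  a <- rand_dna(400)
  dup <- make_asm(c(c1 = a, c2 = a),
                  list(c("r1", "r2"), c("r3", "r4")))
  res <- assembly_eci(dup)
  expect_equal(res$per_contig$eci, c(100, 100))
  expect_equal(res$n_flagged, 2L)

  tx <- sim_transcriptome(5, len_range = c(300, 500), seed = 38)
  distinct <- make_asm(stats::setNames(tx$seq, tx$id),
                       purrr::map(seq_len(5), ~ paste0("r", .x, c("a", "b"))))
  res <- assembly_eci(distinct)
  expect_equal(res$n_flagged, 0L)
  expect_true(all(res$per_contig$eci < 75))

  single <- make_asm(c(c1 = a), list(c("r1", "r2")))
  expect_warning(res <- assembly_eci(single), "fewer than 2")
  expect_equal(res$mean_eci, 0)
  expect_equal(res$n_flagged, 0L)
})

test_that("the 11-mer prefilter never changes reported scores here", {
  tx <- sim_transcriptome(6, len_range = c(300, 400), seed = 39)
  asm <- make_asm(stats::setNames(tx$seq, tx$id),
                  purrr::map(tx$id, ~ paste0(.x, c("/1", "/2"))))
  plain <- assembly_eci(asm)
  pref <- assembly_eci(asm, kmer_prefilter = TRUE)
  # scores that exist (alignable pairs) are identical; the prefilter may
  # only zero out sub-11-base chance alignments
  expect_true(all(pref$per_contig$eci %in% c(0, plain$per_contig$eci)))
  expect_equal(pref$n_flagged, plain$n_flagged)
})

test_that("evaluate_assemblies ranks by ICI, then annotation, then ECI", {
  tx <- sim_transcriptome(5, len_range = c(500, 700), seed = 40)
  sim <- sim_reads(tx, 25, mean_len = 300, coverage_mode = "even", seed = 41)
  vars <- sim_assembly_variants(tx, sim$reads, sim$truth,
                                mutation_rate = 0.05, seed = 42)
  cands <- list(
    truth = list(assembly = vars$truth$assembly, reads = sim$reads),
    mutated = list(assembly = vars$mutated$assembly, reads = sim$reads)
  )
  ev <- evaluate_assemblies(cands)
  expect_equal(ev$assembly[1], "truth")
  expect_equal(ev$rank, 1:2)
  expect_true(all(c("n_clustered", "n_contigs", "mean_contig_len", "n_unigenes",
                    "mean_unigene_len", "mean_ici", "mean_eci", "n_annotated")
                  %in% names(ev)))

  # single candidate is trivially first
  ev1 <- evaluate_assemblies(cands["truth"])
  expect_equal(ev1$rank, 1L)

  # permutation invariance of the ranked table
  ev_rev <- evaluate_assemblies(rev(cands))
  expect_equal(as.data.frame(ev), as.data.frame(ev_rev))

  # equal ICI and annotation: lower mean ECI wins
  a <- vars$truth$assembly
  dup_contigs <- dplyr::bind_rows(
    a$contigs,
    dplyr::mutate(a$contigs[1, ], id = "dup",
                  members = list(c("zz1", "zz2")))
  )
  dup_reads <- dplyr::bind_rows(
    sim$reads,
    tibble::tibble(id = c("zz1", "zz2"),
                   seq = rep(substr(a$contigs$consensus[1], 1, 200), 2),
                   masked = sim$reads$masked[1:2])
  )
  redundant <- assembly(dup_contigs, name = "redundant")
  ev2 <- evaluate_assemblies(list(
    truth = list(assembly = a, reads = sim$reads),
    redundant = list(assembly = redundant, reads = dup_reads)
  ))
  expect_equal(ev2$assembly, c("truth", "redundant"))
  expect_gt(ev2$mean_eci[2], ev2$mean_eci[1])
})
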