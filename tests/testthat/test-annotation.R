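# E-value filtering, best hits, subject coverage and full-length calling.

mk_hits <- function(qid, sid, sstart, send, evalue = 1e-20, bitscore = 100,
                    slen = NULL) {
  n <- max(length(qid), length(sid), length(sstart), length(send),
           length(evalue), length(bitscore))
  h <- tibble::tibble(
    qid = rep_len(qid, n), sid = rep_len(sid, n),
    pident = 97, aln_len = rep_len(send - sstart + 1L, n),
    mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = rep_len(send - sstart + 1L, n),
    sstart = rep_len(as.integer(sstart), n), send = rep_len(as.integer(send), n),
    evalue = rep_len(evalue, n), bitscore = rep_len(bitscore, n),
    sstrand = "+"
  )
  if (!is.null(slen)) h$slen <- rep_len(as.integer(slen), n)
  h
}

test_that("the e-value cutoff is inclusive and order-preserving", {
  h <- mk_hits("q", "s", 1, 10, evalue = c(1e-6, 1e-5, 1e-4))
  kept <- filter_hits(h)
  expect_equal(kept$evalue, c(1e-6, 1e-5))
  expect_equal(filter_hits(h[0, ]), h[0, ])
  all_pass <- mk_hits("q", "s", 1, 10, evalue = c(1e-8, 1e-9))
  expect_equal(filter_hits(all_pass), all_pass)
})

test_that("best hit takes highest bitscore, then lowest e-value, then sid", {
  h <- mk_hits("q1", c("sA", "sB"), 1, 10, bitscore = c(350, 200))
  expect_equal(best_hits(h)$sid, "sA")
  h <- mk_hits("q1", c("sA", "sB"), 1, 10, evalue = c(1e-20, 1e-50),
               bitscore = 100)
  expect_equal(best_hits(h)$sid, "sB")
  h <- mk_hits("q1", c("sB", "sA"), 1, 10)
  expect_equal(best_hits(h)$sid, "sA")
  single <- mk_hits("q1", "sZ", 1, 10)
  expect_equal(best_hits(single), single)
})

test_that("annotation summaries count distinct passing queries", {
  h <- mk_hits(c("q1", "q1", "q2", "q3", "q4"), "s", 1, 10,
               evalue = c(1e-8, 1e-7, 1e-8, 1e-8, 1e-3))
  s <- annotation_summary(h, 10, db_name = "nr")
  expect_equal(s$n_annotated, 3L)
  expect_equal(s$n_unannotated, 7L)
  expect_equal(s$pct_annotated, 30)
  expect_equal(annotation_summary(h[0, ], 10)$pct_annotated, 0)
  expect_error(annotation_summary(h, 2), "exceed")

  # doubling every record doubles counts and keeps the percentage
  h2 <- dplyr::bind_rows(h, dplyr::mutate(h, qid = paste0(qid, "_b")))
  s2 <- annotation_summary(h2, 20)
  expect_equal(s2$n_annotated, 2L * s$n_annotated)
  expect_equal(s2$pct_annotated, s$pct_annotated)
})

test_that("subject coverage merges HSP intervals of one pair", {
  expect_equal(subject_coverage(mk_hits("q", "s", 1, 100), 100), 1.0)
  expect_equal(subject_coverage(mk_hits("q", "s", c(1, 40), c(50, 95)), 100), 0.95)
  expect_equal(subject_coverage(mk_hits("q", "s", c(1, 61), c(40, 100)), 100), 0.80)
  expect_error(subject_coverage(mk_hits("q", "s", 1, 120), 100), "outside")
  expect_error(subject_coverage(mk_hits(c("q1", "q2"), "s", 1, 10), 100), "single")
})

test_that("subject coverage equals the per-residue bitmap oracle", {
  set.seed(61)
  for (i in 1:300) {
    slen <- sample(20:1000, 1)
    k <- sample(1:6, 1)
    sstart <- sample(slen, k, replace = TRUE)
    send <- pmin(slen, sstart + sample(0:200, k, replace = TRUE))
    h <- mk_hits("q", "s", sstart, send)
    expect_equal(subject_coverage(h, slen),
                 oracle_bitmap_coverage(sstart, send, slen))
  }
})

test_that("full-length calling uses the best single query, inclusively", {
  slen <- c(sA = 100L, sB = 200L)
  # exactly 90% single-query coverage counts
  h <- mk_hits("q1", "sA", 1, 90)
  fl <- count_full_length(h, slen)
  expect_equal(fl$n_full_length, 1L)
  expect_true(fl$records$is_full_length)

  # two queries at 50% and 60%: not full length by default, full length in
  # union mode (together they span the whole subject)
  h2 <- mk_hits(c("q1", "q2"), "sB", c(1, 81), c(100, 200))
  fl <- count_full_length(h2, slen)
  expect_equal(fl$n_full_length, 0L)
  expect_equal(max(fl$records$best_coverage_frac), 0.6)
  fl_union <- count_full_length(h2, slen, union_queries = TRUE)
  expect_equal(fl_union$n_full_length, 1L)

  # monotone non-increasing in the threshold
  set.seed(62)
  planted <- tibble::tibble(
    qid = paste0("q", 1:12), sid = paste0("s", 1:12),
    coverage_frac = seq(0.2, 0.98, length.out = 12), evalue = 1e-30
  )
  subs <- stats::setNames(sample(150:400, 12), planted$sid)
  h <- sim_hit_table(planted, subs, seed = 63)
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95),
                   function(t) count_full_length(h, subs, threshold = t)$n_full_length,
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(count_full_length(mk_hits("q", "sX", 1, 10), slen), "missing.*sX")
})

test_that("transcriptome coverage counts distinct passing ids", {
  h <- mk_hits(c("q1", "q2"), "s1", 1, 10)
  tc <- transcriptome_coverage(h)
  expect_equal(c(tc$n_queries_with_hit, tc$n_subjects_hit), c(2L, 1L))
  tc0 <- transcriptome_coverage(h[0, ])
  expect_equal(c(tc0$n_queries_with_hit, tc0$n_subjects_hit), c(0L, 0L))
  h8 <- mk_hits(paste0("q", 1:8), rep(c("sA", "sB", "sC"), length.out = 8), 1, 10)
  tc8 <- transcriptome_coverage(h8)
  expect_equal(c(tc8$n_queries_with_hit, tc8$n_subjects_hit), c(8L, 3L))
})

test_that("keyword tally matches case-insensitive family patterns", {
  ann <- tibble::tibble(
    qid = paste0("q", 1:6),
    description = c("Catalase", "superoxide dismutase Cu/Zn",
                    "cytochrome P450 4F22", "Cytochrome P450 2J6",
                    "heat shock protein 70", "putative CYTOCHROME P450")
  )
  fams <- list(CAT = "catalase", SOD = "superoxide dismutase",
               CYP = "cytochrome p450", GGT = "glutamyl")
  tally <- keyword_tally(ann, fams)
  expect_equal(stats::setNames(tally$n, tally$family),
               c(CAT = 1L, SOD = 1L, CYP = 3L, GGT = 0L))
})
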