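# Adapter masking and largest-unmasked-substring clipping.

one_read <- function(seq, id = "r1") {
  tibble::tibble(id = id, seq = seq,
                 masked = list(matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("start", "end")))))
}

test_that("exact adapter occurrences are masked, absent adapters are not", {
  r <- mask_adapters(one_read("AAAATTTTGGGGCCCC"), "AAAATTTT", min_match = 8)
  expect_equal(unname(r$masked[[1]][1, ]), c(0L, 8L))
  r2 <- mask_adapters(one_read("AAAATTTTGGGGCCCC"), "GAGAGAGAGA")
  expect_equal(nrow(r2$masked[[1]]), 0)
})

test_that("bounded-mismatch masking matches a sliding-window oracle", {
  # 1 mismatch in a 12-base adapter is within max_mismatch_frac = 0.1
  adapter <- "ACGTTGCAACGT"
  read_seq <- paste0("GGGG", "ACGTTGAAACGT", "GGGG")  # one substitution at pos 7
  r <- mask_adapters(one_read(read_seq), adapter, max_mismatch_frac = 0.1)
  expect_equal(unname(r$masked[[1]][1, ]), c(4L, 16L))

  # oracle: every full-or-partial window with mismatches <= floor(0.1 * ov)
  set.seed(7)
  for (trial in 1:25) {
    rs <- rand_dna(60)
    ad <- rand_dna(12)
    if (sample(2, 1) == 1) {  # plant a 1-mismatch copy
      pos <- sample(40, 1)
      copy <- ad
      substr(copy, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(ad, 5, 5))[1]
      rs <- paste0(substr(rs, 1, pos), copy, substr(rs, pos + 13, 60))
    }
    got <- mask_adapters(one_read(rs), ad)$masked[[1]]
    want <- local({
      probes <- c(ad, as.character(Biostrings::reverseComplement(Biostrings::DNAString(ad))))
      iv <- matrix(integer(0), ncol = 2)
      n <- nchar(rs)
      for (p in probes) {
        m <- nchar(p)
        for (off in -(m - 10):(n - 10)) {
          lo <- max(0, off); hi <- min(n, off + m); ov <- hi - lo
          if (ov < min(10, m)) next
          x <- substr(rs, lo + 1, hi)
          y <- substr(p, lo - off + 1, hi - off)
          mm <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
          if (mm <= floor(0.1 * ov)) iv <- rbind(iv, c(lo, hi))
        }
      }
      unigeneqc:::merge_intervals(iv)
    })
    expect_equal(unname(got), unname(want))
  }
})

test_that("clipping keeps the longest (5'-most on ties) unmasked run", {
  # no masks: read passes through without suffix
  cl <- clip_reads(one_read(strrep("ACGT", 10)))
  expect_equal(cl$id, "r1")
  expect_false(cl$clipped)

  # mask [0,10) on a 30-base read: bases [10,30) survive
  r <- one_read(paste0(strrep("A", 10), strrep("CGT", 20 %/% 3 + 1)))
  r$seq <- substr(r$seq, 1, 30)
  r$masked <- list(cbind(start = 0L, end = 10L))
  cl <- clip_reads(r, min_len = 10)
  expect_equal(cl$seq, substr(r$seq, 11, 30))
  expect_equal(cl$id, "r1/clip")

  # equal-length runs: the 5'-most wins
  r <- one_read(strrep("ACGTT", 10))  # 50 bases
  r$masked <- list(cbind(start = 20L, end = 30L))  # runs [0,20) and [30,50)
  cl <- clip_reads(r, min_len = 5)
  expect_equal(cl$seq, substr(r$seq, 1, 20))

  # fully masked read is removed
  r <- one_read(strrep("A", 30))
  r$masked <- list(cbind(start = 0L, end = 30L))
  expect_equal(nrow(clip_reads(r)), 0)
})

test_that("clipped output contains no masked base and clipping is idempotent", {
  set.seed(11)
  adapter <- rand_dna(20)
  for (trial in 1:20) {
    reads <- rand_reads_tbl(5, len_range = c(60, 150))
    # plant the adapter at a random position in some reads
    reads$seq <- vapply(reads$seq, function(s) {
      if (sample(2, 1) == 1) return(s)
      pos <- sample(nchar(s) - 20, 1)
      paste0(substr(s, 1, pos), adapter, substr(s, pos + 21, nchar(s)))
    }, character(1))
    res <- clip_batch(reads, adapter, min_len = 10)
    expect_false(any(grepl(adapter, res$reads$seq, fixed = TRUE)))
    res2 <- clip_batch(res$reads, adapter, min_len = 10)
    expect_equal(res2$reads$seq, res$reads$seq)
    expect_equal(res2$reads$id, res$reads$id)  # no second /clip suffix
  }
})

test_that("clip_batch report aggregates counts and planted inserts exactly", {
  # adapter-free reads pass through untouched
  set.seed(3)
  clean <- rand_reads_tbl(3, len_range = c(50, 80))
  res <- clip_batch(clean, "AAGCAGTGGTATCAACGCAGAGT")
  expect_equal(res$report$n_clean, 3)
  expect_equal(res$report$n_removed, 0)
  expect_equal(res$report$mean_len_after, res$report$mean_len_before)

  # error-free simulated reads with end adapters: every planted insert base
  # is recovered
  tx <- sim_transcriptome(4, len_range = c(400, 600), seed = 21)
  adapter <- "AAGCAGTGGTATCAACGCAGAGT"
  sim <- sim_reads(tx, 20, mean_len = 200, adapter = adapter,
                   coverage_mode = "even", seed = 22)
  res <- clip_batch(sim$reads, adapter)
  expect_equal(res$report$n_clean, 20)
  expect_equal(res$report$bases_clean, sum(sim$truth$insert_len))

  # a read that is pure adapter is removed
  allad <- dplyr::bind_rows(clean, one_read(strrep(adapter, 2), id = "bad"))
  res <- clip_batch(allad, adapter)
  expect_equal(res$report$n_input, 4)
  expect_equal(res$report$n_removed, 1)
  expect_equal(res$report$n_clean + res$report$n_removed, res$report$n_input)
  expect_lte(res$report$bases_clean, res$report$bases_input)
})
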