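# brute-force trimming oracle: scan every window, cut at the first failure
oracle_trim_len <- function(q, w, thr) {
  L <- length(q)
  if (L < w) return(L)
  for (s in 1:(L - w + 1)) {
    if (mean(q[s:(s + w - 1)]) < thr) return(s - 1L)
  }
  L
}

test_that("sliding-window trimming matches the brute-force window scan", {
  # frozen example: first failing window starts at base 4 (30,2,2,2 -> 9)
  q <- c(30, 30, 30, 30, 2, 2, 2, 2, rep(30, 4))
  expect_identical(oracle_trim_len(q, 4, 10), 3L)
  r <- sliding_window_trim(one_read(rand_dna(12), q), 4, 10)
  expect_identical(nchar(r$seq), 3L)
  expect_identical(r$qual[[1]], as.integer(q[1:3]))

  withr::local_seed(7)
  for (i in 1:50) {
    L <- sample(1:80, 1)
    q <- sample(2:40, L, replace = TRUE)
    w <- sample(1:6, 1)
    thr <- sample(5:35, 1)
    r <- sliding_window_trim(one_read(rand_dna(L), q), w, thr)
    expect_identical(nchar(r$seq), as.integer(oracle_trim_len(q, w, thr)))
    expect_lte(nchar(r$seq), L)  # never lengthens
  }
})

test_that("trimming edge cases: clean reads, zero threshold, short reads", {
  r <- one_read(rand_dna(250), 30L)
  expect_identical(sliding_window_trim(r, 4, 20)$seq, r$seq)
  expect_identical(sliding_window_trim(r, 4, 0)$seq, r$seq)
  short <- one_read("ACG", c(2L, 2L, 2L))
  expect_identical(sliding_window_trim(short, 4, 30)$seq, "ACG")
  empty <- read_set(character(0), character(0), list())
  expect_identical(length(sliding_window_trim(empty, 4, 10)), 0L)
})

test_that("length/quality filter applies mate-specific bounds and the 80% rule", {
  cfg <- pipeline_config()
  r199 <- one_read(rand_dna(199), 40L, mate = "R1")
  expect_false(filter_reads(r199, cfg)$keep)
  expect_identical(filter_reads(r199, cfg)$drops[["short"]], 1L)
  r199b <- one_read(rand_dna(199), 40L, mate = "R2")  # R2 minimum is 70
  expect_true(filter_reads(r199b, cfg)$keep)

  # exactly 80% of bases at/above Q20 is kept; 79% is dropped
  q80 <- c(rep(20L, 80), rep(19L, 20))
  q79 <- c(rep(20L, 79), rep(19L, 21))
  expect_true(filter_reads(one_read(rand_dna(100), q80, mate = "R2"),
                           cfg)$keep)
  f <- filter_reads(one_read(rand_dna(100), q79, mate = "R2"), cfg)
  expect_false(f$keep)
  expect_identical(f$drops[["low_quality"]], 1L)

  # filtering never modifies surviving sequences
  rs <- read_set(c("a", "b"), c(rand_dna(250), rand_dna(100)),
                 list(rep(40L, 250), rep(40L, 100)), "R1")
  out <- filter_reads(rs, cfg)
  expect_identical(out$reads$seq, rs$seq[1])
})

make_pair <- function(template, read_len = 200L, q1 = 35L, q2 = 30L,
                      id = "p1") {
  tl <- nchar(template)
  r1 <- substr(template, 1, min(read_len, tl))
  r2 <- rev_comp(substr(template, max(1, tl - read_len + 1), tl))
  list(r1 = one_read(r1, q1, id, "R1"), r2 = one_read(r2, q2, id, "R2"))
}

test_that("pair merging reconstructs templates and honours the thresholds", {
  cfg <- pipeline_config()
  withr::local_seed(11)
  # exact 100-base overlap: 200 + 200 - 300
  template <- rand_dna(300)
  p <- make_pair(template)
  m <- merge_pair(p$r1, p$r2, cfg)
  expect_identical(m$sequence, template)
  expect_identical(m$overlap_length, 100L)
  expect_identical(nchar(m$sequence), 200L + 200L - 100L)

  # a true overlap of 59 bases fails the 60-base minimum
  t59 <- rand_dna(341)  # 200 + 200 - 341 = 59
  p59 <- make_pair(t59)
  expect_null(merge_pair(p59$r1, p59$r2, cfg))

  # identity exactly 0.90 in the overlap still merges
  p10 <- make_pair(template)
  ov_in_r2 <- 101:200  # overlap occupies the first 100 bases of rc(r2)
  rc <- rev_comp(p10$r2$seq)
  ch <- strsplit(rc, "")[[1]]
  pos <- sample(1:100, 10)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  p10$r2 <- one_read(rev_comp(paste(ch, collapse = "")), 20L, "p1", "R2")
  m10 <- merge_pair(p10$r1, p10$r2, cfg)
  expect_identical(m10$overlap_length, 100L)
  # r1 quality (35) beats r2 (20) at every disagreement -> template restored
  expect_identical(m10$sequence, template)

  # 11 disagreements (identity 0.89) fail
  for (i in sample(setdiff(1:100, pos), 1))
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  p11 <- make_pair(template)
  p11$r2 <- one_read(rev_comp(paste(ch, collapse = "")), 20L, "p1", "R2")
  expect_null(merge_pair(p11$r1, p11$r2, cfg))
})

test_that("disagreement consensus takes the higher-quality base, ties to R1", {
  withr::local_seed(3)
  cfg <- pipeline_config(min_overlap = 10L)
  template <- rand_dna(60)
  r1s <- substr(template, 1, 40)
  rc2 <- substr(template, 21, 60)
  # disagreement at template position 30 (= r1 pos 30, rc2 pos 10)
  ch <- strsplit(rc2, "")[[1]]
  orig <- ch[10]
  ch[10] <- setdiff(c("A", "C", "G", "T"), orig)[1]
  alt <- ch[10]
  q1 <- rep(30L, 40); q2 <- rep(30L, 40)
  mk <- function(q1v, q2v) {
    q1[30] <- q1v
    q2r <- rev(q2); q2r[10] <- q2v
    merge_pair(one_read(r1s, q1, "x", "R1"),
               one_read(rev_comp(paste(ch, collapse = "")), rev(q2r),
                        "x", "R2"), cfg)
  }
  hi_r2 <- mk(10L, 35L)
  expect_identical(substr(hi_r2$sequence, 30, 30), alt)
  expect_identical(hi_r2$qualities[30], 35L)
  hi_r1 <- mk(35L, 10L)
  expect_identical(substr(hi_r1$sequence, 30, 30), orig)
  tie <- mk(25L, 25L)
  expect_identical(substr(tie$sequence, 30, 30), orig)  # tie -> R1
  expect_identical(tie$qualities[30], 25L)
})

test_that("error-free simulated pairs all re-merge to their template", {
  w <- small_world(seed = 21L, n_pairs = 150L, n_samples = 1L, n_cts = 3L,
                   error_rate_r1 = 0, error_rate_r2 = 0)
  r1 <- read_fastq(w$reads$samples$r1[1], "R1")
  r2 <- read_fastq(w$reads$samples$r2[1], "R2")
  mg <- merge_pairs(r1, r2, w$cfg)
  expect_true(all(mg$merged))
  tmpl <- setNames(w$reads$truth$template_sequence,
                   w$reads$truth$read_pair_id)
  expect_identical(mg$amplicons$seq, unname(tmpl[mg$amplicons$id]))
})
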