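# Independent repeat-scan oracle: Hamming distance at every offset via
# character vectors.
oracle_repeat_hits <- function(seq, motif, max_mm) {
  sv <- strsplit(seq, "")[[1]]; mv <- strsplit(motif, "")[[1]]
  m <- length(mv)
  hits <- integer(0)
  for (s in 0:(length(sv) - m)) {
    if (sum(sv[(s + 1):(s + m)] != mv) <= max_mm) hits <- c(hits, s)
  }
  hits
}

test_that("full repeat matches are found at constructed offsets", {
  cfg <- pipeline_config()
  withr::local_seed(41)
  R <- cfg$repeat_sequence
  leader <- rand_dna(60)
  s1 <- rand_dna(35)
  seq <- build_template(leader, R, s1)
  reps <- locate_repeats(seq, cfg)
  expect_identical(reps$start, c(60L, 60L + nchar(R) + 35L))
  expect_identical(reps$end - reps$start, rep(nchar(R), 2))
  expect_identical(reps$mismatches, c(0L, 0L))
  expect_false(any(reps$partial))
})

test_that("repeat matching tolerates exactly repeat_max_mismatch errors", {
  cfg <- pipeline_config()
  withr::local_seed(42)
  R <- cfg$repeat_sequence
  for (i in 1:10) {
    leader <- rand_dna(60)
    mid <- rand_dna(35)
    r_at <- mutate_k(R, cfg$repeat_max_mismatch)
    r_over <- mutate_k(R, cfg$repeat_max_mismatch + 1L)
    seq_ok <- paste0(leader, R, mid, r_at)
    seq_bad <- paste0(leader, R, mid, r_over)
    expect_identical(locate_repeats(seq_ok, cfg)$start,
                     oracle_repeat_hits(seq_ok, R, cfg$repeat_max_mismatch))
    expect_identical(nrow(locate_repeats(seq_ok, cfg)), 2L)
    hits_bad <- locate_repeats(seq_bad, cfg)
    expect_identical(sum(!hits_bad$partial), 1L)
  }
  expect_identical(nrow(locate_repeats(rand_dna(200), cfg)), 0L)
})

test_that("spacers are the in-bounds inter-repeat segments, leader first", {
  cfg <- pipeline_config()
  withr::local_seed(43)
  R <- cfg$repeat_sequence
  s1 <- rand_dna(35); s2 <- rand_dna(40)
  amp <- build_template(rand_dna(80), R, c(s1, s2))
  ex <- extract_spacers("a1", amp, cfg)
  expect_identical(ex$status, "ok")
  expect_identical(ex$spacers$sequence, c(s1, s2))
  expect_identical(ex$spacers$position_from_leader, 1:2)
  expect_identical(ex$spacers$source_amplicon, rep("a1", 2))
  expect_false(ex$rc_used)

  # a single repeat leaves nothing between repeats
  one <- paste0(rand_dna(80), R, rand_dna(50))
  ex1 <- extract_spacers("a2", one, cfg)
  expect_identical(ex1$status, "no_repeats")
  expect_identical(nrow(ex1$spacers), 0L)

  # 10-base segment is below spacer_min_len: dropped and flagged
  tooshort <- build_template(rand_dna(80), R, c(rand_dna(10), s2))
  ex2 <- extract_spacers("a3", tooshort, cfg)
  expect_identical(nrow(ex2$dropped), 1L)
  expect_identical(ex2$dropped$reason, "too_short")
  expect_identical(ex2$spacers$sequence, s2)

  expect_identical(extract_spacers("a4", rand_dna(150), cfg)$status,
                   "no_repeats")
})

test_that("reverse-complement rescue recovers flipped amplicons", {
  cfg <- pipeline_config()
  withr::local_seed(44)
  s1 <- rand_dna(33); s2 <- rand_dna(36)
  amp <- build_template(rand_dna(70), cfg$repeat_sequence, c(s1, s2))
  ex <- extract_spacers("flip", rev_comp(amp), cfg)
  expect_identical(ex$status, "ok")
  expect_true(ex$rc_used)
  expect_identical(ex$spacers$sequence, c(s1, s2))
})

test_that("a truncated 3' repeat is reported as a partial match", {
  cfg <- pipeline_config()
  withr::local_seed(45)
  R <- cfg$repeat_sequence
  s1 <- rand_dna(35)
  amp <- paste0(rand_dna(60), R, s1, substr(R, 1, 18))  # 18 >= 15 minimum
  reps <- locate_repeats(amp, cfg)
  expect_identical(nrow(reps), 2L)
  expect_true(reps$partial[2])
  expect_identical(reps$end[2] - reps$start[2], 18L)
})

test_that("extraction recovers planted spacers exactly on clean amplicons", {
  cfg <- pipeline_config()
  w <- small_world(seed = 46L, n_pairs = 60L, n_samples = 1L, n_cts = 3L,
                   error_rate_r1 = 0, error_rate_r2 = 0)
  truth <- w$reads$truth
  spacer_seq <- c(w$gen$catalog$spacer_seq, w$gen$novel_pool)
  for (i in seq_len(nrow(truth))) {
    ex <- extract_spacers(truth$read_pair_id[i],
                          truth$template_sequence[i], cfg)
    planted <- strsplit(truth$true_spacer_ids[i], ",")[[1]]
    expect_identical(ex$status, "ok")
    expect_identical(ex$spacers$sequence, unname(spacer_seq[planted]))
    # repeats and spacers tile the array region without unexplained gaps
    reps <- ex$repeats
    gaps <- reps$start[-1] - reps$end[-nrow(reps)]
    expect_true(all(gaps >= cfg$spacer_min_len & gaps <= cfg$spacer_max_len))
  }
})
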