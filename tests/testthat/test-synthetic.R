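test_that("generated catalogs are disjoint, well separated, deterministic", {
  cfg <- pipeline_config()
  sim <- simulation_config(n_reference_cts = 4L, repertoire_length = 5L,
                           rng_seed = 101L)
  gen <- generate_catalog(sim, cfg)
  expect_identical(length(gen$catalog$entries), 4L)
  expect_identical(unique(lengths(gen$catalog$entries)), 5L)
  validate_catalog(gen$catalog)
  # exhaustive pairwise separation over catalog + reserved novel pool
  seqs <- c(gen$catalog$spacer_seq, gen$novel_pool)
  for (i in seq_along(seqs)) {
    for (j in seq_len(i - 1L)) {
      if (nchar(seqs[i]) == nchar(seqs[j])) {
        d <- sum(strsplit(seqs[[i]], "")[[1]] != strsplit(seqs[[j]], "")[[1]])
        expect_gt(d, cfg$spacer_max_mismatch)
      }
    }
  }
  gen2 <- generate_catalog(sim, cfg)
  expect_identical(gen2, gen)

  empty <- generate_catalog(simulation_config(n_reference_cts = 0L,
                                              rng_seed = 1L), cfg)
  expect_identical(length(empty$catalog$entries), 0L)
})

test_that("compositions are normalized and honour degenerate settings", {
  cfg <- pipeline_config()
  sim <- simulation_config(n_reference_cts = 5L, n_samples = 4L,
                           rng_seed = 102L)
  gen <- generate_catalog(sim, cfg)
  comp <- simulate_composition(gen, sim)
  sums <- tapply(comp$proportion, comp$sample, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)

  all_origin <- simulation_config(
    n_reference_cts = 3L, n_samples = 2L, n_read_pairs = 120L,
    variant_fractions_dominant = c(origin = 1, new_plus = 0, proto = 0,
                                   others = 0),
    variant_fractions_rest = c(origin = 1, new_plus = 0, proto = 0,
                               others = 0),
    rng_seed = 103L)
  gen2 <- generate_catalog(all_origin, cfg)
  comp2 <- simulate_composition(gen2, all_origin)
  out <- synthesize_reads(gen2, comp2, all_origin, withr::local_tempdir(),
                          cfg)
  expect_setequal(unique(out$truth$true_variant), "origin")
})

test_that("read synthesis is deterministic and respects fixed spacer counts", {
  cfg <- pipeline_config()
  sim <- simulation_config(n_reference_cts = 3L, n_samples = 2L,
                           n_read_pairs = 80L,
                           spacer_count_probs = c(0, 1, 0, 0, 0),
                           rng_seed = 104L)
  gen <- generate_catalog(sim, cfg)
  comp <- simulate_composition(gen, sim)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  o1 <- synthesize_reads(gen, comp, sim, d1, cfg)
  o2 <- synthesize_reads(gen, comp, sim, d2, cfg)
  expect_true(all(lengths(strsplit(o1$truth$true_spacer_ids, ",")) == 2L))
  for (i in seq_len(nrow(o1$samples))) {
    expect_identical(readLines(o1$samples$r1[i]), readLines(o2$samples$r1[i]))
    expect_identical(readLines(o1$samples$r2[i]), readLines(o2$samples$r2[i]))
  }
  expect_identical(o1$truth, o2$truth)
})

test_that("zero-error pairs re-merge exactly and realized counts track the
           composition", {
  cfg <- pipeline_config()
  sim <- simulation_config(n_reference_cts = 4L, n_samples = 2L,
                           n_read_pairs = 3000L, error_rate_r1 = 0,
                           error_rate_r2 = 0, rng_seed = 105L)
  gen <- generate_catalog(sim, cfg)
  comp <- simulate_composition(gen, sim)
  out <- synthesize_reads(gen, comp, sim, withr::local_tempdir(), cfg)
  r1 <- read_fastq(out$samples$r1[1], "R1")
  r2 <- read_fastq(out$samples$r2[1], "R2")
  mg <- merge_pairs(r1, r2, cfg)
  expect_true(all(mg$merged))
  tmpl <- setNames(out$truth$template_sequence, out$truth$read_pair_id)
  expect_identical(mg$amplicons$seq, unname(tmpl[mg$amplicons$id]))

  # realized (CT, sample) counts within 3 multinomial SD of the composition
  expected <- tapply(comp$proportion, list(comp$sample, comp$ct), sum)
  for (s in rownames(expected)) {
    n_s <- sum(out$truth$sample_id == s)
    for (ct in colnames(expected)) {
      p <- expected[s, ct]
      got <- sum(out$truth$sample_id == s & out$truth$true_ct == ct) / n_s
      expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n_s) + 1e-9)
    }
  }
})

test_that("quality model exercises the configured thresholds", {
  cfg <- pipeline_config()
  sim <- simulation_config(n_reference_cts = 3L, n_samples = 1L,
                           n_read_pairs = 300L, rng_seed = 106L)
  gen <- generate_catalog(sim, cfg)
  comp <- simulate_composition(gen, sim)
  out <- synthesize_reads(gen, comp, sim, withr::local_tempdir(), cfg)
  r1 <- read_fastq(out$samples$r1[1], "R1")
  r2 <- read_fastq(out$samples$r2[1], "R2")
  m1 <- mean(unlist(r1$qual)); m2 <- mean(unlist(r2$qual))
  expect_gt(m1, m2)  # R2 chemistry is worse
  # 3' decay: final-quarter mean below first-quarter mean for R2
  tails <- vapply(r2$qual, function(q) mean(q[(length(q) * 3 %/% 4):length(q)]),
                  numeric(1))
  heads <- vapply(r2$qual, function(q) mean(q[seq_len(length(q) %/% 4)]),
                  numeric(1))
  expect_gt(mean(heads), mean(tails))
})
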