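test_that("catalog file round-trips and disjointness is enforced", {
  cat <- tiny_catalog()
  p <- withr::local_tempfile()
  write_catalog(cat, p)
  back <- read_catalog(p)
  expect_identical(back$entries, cat$entries)
  expect_identical(unname(back$provenance), unname(cat$provenance))
  expect_identical(back$spacer_seq, cat$spacer_seq)

  expect_error(ct_catalog(list(CT_A = 1:5, CT_B = c(5L, 7L))),
               "disjointness")
  expect_error(ct_catalog(list(CT_A = integer(0))), "non-empty")
})

test_that("CT assignment follows shared leader-end order", {
  cfg <- pipeline_config()
  cat <- ct_catalog(list(CT_A = 1:5, CT_B = 6:10))
  # prefix of CT_A
  a <- assign_ct(c(1L, 2L, 3L), cat, cfg)
  expect_identical(a$label, "CT_A")
  expect_identical(a$novel_count, 0L)
  expect_identical(a$matched_ids, c(1L, 2L, 3L))
  # single novel spacer is discarded
  expect_identical(assign_ct(99L, cat, cfg)$label, "discarded_novel_1or2")
  expect_identical(assign_ct(c(98L, 99L), cat, cfg)$label,
                   "discarded_novel_1or2")
  # a single catalog spacer is assigned to its CT
  expect_identical(assign_ct(2L, cat, cfg)$label, "CT_A")
  # three novel spacers qualify as a new-CT candidate
  expect_identical(assign_ct(c(97L, 98L, 99L), cat, cfg)$label,
                   "candidate_new")
  # scrambled order within one CT is ambiguous
  expect_identical(assign_ct(c(2L, 1L), cat, cfg)$label,
                   "unassigned_ambiguous")
  # spacers from two CTs are ambiguous, never majority-resolved
  expect_identical(assign_ct(c(1L, 2L, 6L), cat, cfg)$label,
                   "unassigned_ambiguous")
  # leading novel spacers before a consistent block still assign
  expect_identical(assign_ct(c(50L, 1L, 2L), cat, cfg)$label, "CT_A")
  # non-contiguous but order-consistent subsequence assigns (variant rules
  # judge contiguity later)
  expect_identical(assign_ct(c(1L, 3L, 5L), cat, cfg)$label, "CT_A")
})

test_that("dataset-wide singleton arrays are discarded with a fraction", {
  cat <- ct_catalog(list(CT_A = 1:5))
  arr <- arrays_df(list(c(1L, 2L), c(1L, 2L), c(2L, 3L), 9L),
                   weights = c(1, 1, 1, 1))
  arr <- assign_cts(arr, cat, pipeline_config())
  ds <- discard_singletons(arr)
  # c(1,2) seen twice (weight 2) is retained; the others are singletons
  expect_identical(ds$assignments$label[1:2], c("CT_A", "CT_A"))
  expect_identical(ds$assignments$label[3:4], rep("discarded_singleton", 2))
  expect_equal(ds$singleton_fraction, 0.5)
  expect_identical(ds$n_singletons, 2L)

  empty <- discard_singletons(arr[0, ])
  expect_identical(nrow(empty$assignments), 0L)
  expect_equal(empty$singleton_fraction, 0)
})

test_that("new CTs form by shared-ID groups with longest-array origins", {
  cat <- ct_catalog(list(CT_A = 1:5))
  cand <- arrays_df(list(c(10L, 11L, 12L), c(10L, 11L, 12L, 13L)),
                    weights = c(5, 2))
  out <- define_new_cts(cand, cat, "CT2")
  expect_identical(length(out$catalog$entries), 2L)
  expect_identical(out$catalog$entries$CT2, c(10L, 11L, 12L, 13L))
  expect_identical(unname(out$catalog$provenance["CT2"]), "new_this_run")
  expect_setequal(out$assignments$label, "CT2")

  # no shared IDs: two separate new CTs
  out2 <- define_new_cts(arrays_df(list(c(10L, 11L, 12L),
                                        c(20L, 21L, 22L))),
                         cat, "CT2")
  expect_identical(length(out2$catalog$entries), 3L)
  validate_catalog(out2$catalog)

  # a candidate bridging two groups is flagged, both groups unmodified
  cand3 <- arrays_df(list(c(10L, 11L, 12L, 13L), c(20L, 21L, 22L, 23L),
                          c(10L, 20L)),
                     weights = c(3, 3, 1))
  out3 <- define_new_cts(cand3, cat, "CT2")
  expect_identical(length(out3$catalog$entries), 3L)
  labs <- setNames(out3$assignments$label, out3$assignments$amplicon_id)
  expect_identical(unname(labs["amp03"]), "unassigned_ambiguous")
  expect_identical(sort(out3$catalog$entries$CT2), c(10L, 11L, 12L, 13L))
  expect_identical(sort(out3$catalog$entries$CT3), c(20L, 21L, 22L, 23L))

  # candidates must not contain catalog spacers
  expect_error(define_new_cts(arrays_df(list(c(1L, 10L))), cat, "CT2"),
               "catalog spacer")
})

test_that("every array receives exactly one label on simulated data", {
  w <- small_world(seed = 61L, n_pairs = 400L, n_samples = 2L, n_cts = 3L,
                   error_rate_r1 = 0, error_rate_r2 = 0)
  res <- run_pipeline(w$reads$samples, w$gen$catalog, w$cfg,
                      withr::local_tempdir())
  expect_false(anyNA(res$arrays$label))
  expect_identical(length(res$arrays$label), nrow(res$arrays))
  validate_catalog(res$catalog)
  # with the true catalog and zero error, every catalog-spacer array is
  # assigned to its true CT
  truth <- w$reads$truth
  nond <- res$arrays[!startsWith(res$arrays$label, "discarded"), ]
  rep_truth <- truth$true_ct[match(sub("^[^:]+:", "", nond$amplicon_id),
                                   truth$read_pair_id)]
  expect_identical(unname(nond$label), unname(rep_truth))
})
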