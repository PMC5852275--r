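# Shared fixture builders. Everything is generated in code; tests fix their
# own seeds.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

one_read <- function(seq, qual, id = "r1", mate = "R1") {
  if (length(qual) == 1L) qual <- rep(qual, nchar(seq))
  read_set(id, seq, list(as.integer(qual)), mate)
}

# template = leader + R + (spacer + R) x k, the simulated amplicon structure
build_template <- function(leader, rep_seq, spacers) {
  paste0(leader, rep_seq, paste0(spacers, rep_seq, collapse = ""))
}

# a small two-CT catalog with real sequences for dictionary seeding
tiny_catalog <- function(spacer_len = 35L, seed = 404L) {
  withr::with_seed(seed, {
    seqs <- vapply(1:10, function(i) rand_dna(spacer_len), "")
  })
  ct_catalog(list(CT_A = 1:5, CT_B = 6:10),
             spacer_seq = setNames(seqs, as.character(1:10)))
}

# mutate exactly k positions of a DNA string (guaranteed Hamming distance k)
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# arrays table in the shape arrays_from_amplicons() produces
arrays_df <- function(ids_list, weights = rep(1, length(ids_list)),
                      amp_ids = sprintf("amp%02d", seq_along(ids_list))) {
  out <- data.frame(amplicon_id = amp_ids, weight = weights)
  out$ids <- lapply(ids_list, as.integer)
  out
}

# small simulated world shared by several tests
small_world <- function(seed = 99L, n_pairs = 900L, n_samples = 3L,
                        n_cts = 4L, ...) {
  cfg <- pipeline_config()
  sim <- simulation_config(n_read_pairs = n_pairs, n_samples = n_samples,
                           n_reference_cts = n_cts, rng_seed = seed, ...)
  gen <- generate_catalog(sim, cfg)
  comp <- simulate_composition(gen, sim)
  out <- synthesize_reads(gen, comp, sim, withr::local_tempdir(
    .local_envir = parent.frame()), cfg)
  list(cfg = cfg, sim = sim, gen = gen, comp = comp, reads = out)
}
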