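# Seeded synthetic-data module: reference catalogs, seasonal compositions
# and paired-end FASTQ read sets with ground truth. The defaults describe a
# bloom-season population typed at the leader end of one CRISPR locus:
# 16 reference genotypes sampled at 7 timepoints, one dominant genotype at
# 32% pooled abundance split 0.50/0.45/0.004/0.046 over the
# origin/new_plus/proto/others variant classes, 300-base paired reads with
# substitution error 0.001 (R1) / 0.005 (R2) and weaker R2 qualities.

#' Simulation configuration
#'
#' @param n_reference_cts number of reference CTs in the generated catalog.
#' @param repertoire_length spacers per CT origin repertoire.
#' @param spacer_length_range min/max spacer length (bases).
#' @param leader_tail_length leader bases kept on the amplicon 5' end.
#' @param n_samples number of timepoints.
#' @param timepoint_labels sample labels (default `S01..`).
#' @param abundance_model `"dirichlet"` (per-sample Dirichlet around the
#'   base composition) or `"lognormal_walk"` (per-CT log-scale random walk).
#' @param dirichlet_concentration concentration of the Dirichlet model
#'   (larger = less temporal variation).
#' @param walk_sd log-scale step s.d. of the lognormal walk model.
#' @param dominant_fraction pooled target abundance of the dominant CT
#'   (the first catalog CT).
#' @param variant_fractions_dominant,variant_fractions_rest length-4 numeric
#'   vectors (origin, new_plus, proto, others) summing to 1.
#' @param proto_start_range 1-based origin positions (>= 2) from which a
#'   proto variant may start.
#' @param spacer_count_probs probabilities of 1..5 spacers per amplicon.
#' @param n_read_pairs total read pairs across all samples.
#' @param read_length bases per read.
#' @param error_rate_r1,error_rate_r2 per-base substitution probabilities
#'   (R2 at least R1; both in `[0, 0.2]`).
#' @param quality_r1,quality_r2 length-3 vectors `c(start, end, sd)`: mean
#'   Phred at the 5' end, at the 3' end (linear decay), and Gaussian jitter.
#' @param bottleneck optional list `list(after = i, survivors = k)`:
#'   between samples i and i+1 the composition is resampled from k founder
#'   CTs drawn by abundance (founder-effect scenario).
#' @param rng_seed integer seed; all generation is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_reference_cts = 16L,
                              repertoire_length = 10L,
                              spacer_length_range = c(32L, 40L),
                              leader_tail_length = 140L,
                              n_samples = 7L,
                              timepoint_labels = NULL,
                              abundance_model = c("dirichlet",
                                                  "lognormal_walk"),
                              dirichlet_concentration = 200,
                              walk_sd = 0.3,
                              dominant_fraction = 0.32,
                              variant_fractions_dominant =
                                c(origin = 0.50, new_plus = 0.45,
                                  proto = 0.004, others = 0.046),
                              variant_fractions_rest =
                                c(origin = 0.90, new_plus = 0.08,
                                  proto = 0.005, others = 0.015),
                              proto_start_range = c(2L, 3L),
                              spacer_count_probs =
                                c(62, 27, 4.5, 3, 1.5) / 98,
                              n_read_pairs = 20000L,
                              read_length = 300L,
                              error_rate_r1 = 0.001,
                              error_rate_r2 = 0.005,
                              quality_r1 = c(start = 36, end = 30, sd = 2),
                              quality_r2 = c(start = 33, end = 24, sd = 2),
                              bottleneck = NULL,
                              rng_seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (is.null(timepoint_labels))
    timepoint_labels <- sprintf("S%02d", seq_len(n_samples))
  stopifnot(length(timepoint_labels) == n_samples,
            error_rate_r1 >= 0, error_rate_r1 <= 0.2,
            error_rate_r2 >= error_rate_r1, error_rate_r2 <= 0.2,
            abs(sum(variant_fractions_dominant) - 1) < 1e-9,
            abs(sum(variant_fractions_rest) - 1) < 1e-9,
            all(proto_start_range >= 2),
            length(spacer_count_probs) == 5L,
            abs(sum(spacer_count_probs) - 1) < 1e-9,
            dominant_fraction >= 0, dominant_fraction <= 1)
  structure(list(n_reference_cts = as.integer(n_reference_cts),
                 repertoire_length = as.integer(repertoire_length),
                 spacer_length_range = as.integer(spacer_length_range),
                 leader_tail_length = as.integer(leader_tail_length),
                 n_samples = as.integer(n_samples),
                 timepoint_labels = timepoint_labels,
                 abundance_model = abundance_model,
                 dirichlet_concentration = dirichlet_concentration,
                 walk_sd = walk_sd,
                 dominant_fraction = dominant_fraction,
                 variant_fractions_dominant = variant_fractions_dominant,
                 variant_fractions_rest = variant_fractions_rest,
                 proto_start_range = as.integer(proto_start_range),
                 spacer_count_probs = spacer_count_probs,
                 n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 error_rate_r1 = error_rate_r1,
                 error_rate_r2 = error_rate_r2,
                 quality_r1 = quality_r1, quality_r2 = quality_r2,
                 bottleneck = bottleneck,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
        collapse = "")
}

#' Generate a reference catalog with disjoint, well-separated spacers
#'
#' Spacers are rejection-sampled so that every equal-length pair of
#' canonical spacers has Hamming distance strictly greater than
#' `spacer_max_mismatch` (different-length spacers are distinct identities
#' by construction). They are partitioned disjointly into
#' `n_reference_cts` repertoires of `repertoire_length` spacers; a reserved
#' novel pool (spacer IDs continuing after the catalog, one per CT plus
#' spares) supplies the new leader-end spacers of simulated `new_plus`
#' variants, so novelty is detectable only by dictionary lookup failure.
#' A single leader sequence is shared by all CTs (one locus, one organism).
#'
#' @param sim a [simulation_config].
#' @param cfg a [pipeline_config] (supplies `spacer_max_mismatch`).
#' @return A list: `catalog` (a `"ct_catalog"`), `novel_pool` (named
#'   character vector: reserved spacer ID -> sequence), `leader` (DNA
#'   string), `new_spacer_of` (named integer: CT label -> reserved novel
#'   spacer ID).
#' @export
generate_catalog <- function(sim, cfg = pipeline_config()) {
  set.seed(sim$rng_seed)
  n_ct <- sim$n_reference_cts
  n_catalog <- n_ct * sim$repertoire_length
  n_pool <- max(2L * n_ct, 2L)
  n_total <- n_catalog + n_pool
  seqs <- character(0)
  lens <- integer(0)
  tries <- 0L
  while (length(seqs) < n_total) {
    if ((tries <- tries + 1L) > 50L * n_total + 100L)
      stop("cannot satisfy the spacer distance constraint; ",
           "use longer spacers or fewer CTs")
    L <- sample(seq(sim$spacer_length_range[1L], sim$spacer_length_range[2L]),
                1L)
    cand <- random_dna(L)
    clash <- FALSE
    for (j in which(lens == L)) {
      if (cpp_hamming(seqs[j], cand) <= cfg$spacer_max_mismatch) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      seqs <- c(seqs, cand)
      lens <- c(lens, L)
    }
  }
  leader <- random_dna(max(sim$leader_tail_length, 1L))
  if (n_ct == 0L) {
    return(list(catalog = ct_catalog(list()),
                novel_pool = setNames(seqs[seq_len(n_pool)],
                                      as.character(seq_len(n_pool))),
                leader = leader,
                new_spacer_of = setNames(integer(0), character(0))))
  }
  labels <- paste0("CT", seq_len(n_ct))
  entries <- split(seq_len(n_catalog),
                   rep(seq_len(n_ct), each = sim$repertoire_length))
  names(entries) <- labels
  spacer_seq <- setNames(seqs[seq_len(n_catalog)],
                         as.character(seq_len(n_catalog)))
  pool_ids <- n_catalog + seq_len(n_pool)
  novel_pool <- setNames(seqs[pool_ids], as.character(pool_ids))
  new_spacer_of <- setNames(pool_ids[seq_len(n_ct)], labels)
  list(catalog = ct_catalog(entries, spacer_seq = spacer_seq),
       novel_pool = novel_pool,
       leader = leader,
       new_spacer_of = new_spacer_of)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  g / sum(g)
}

#' Simulate per-sample (CT, variant) compositions
#'
#' The base composition gives the dominant CT its target fraction and
#' splits the rest geometrically over the remaining CTs. Per-sample CT
#' proportions follow the configured abundance model; within-CT variant
#' proportions are the configured variant fractions. An optional bottleneck
#' resamples the composition from a few founder CTs mid-series.
#'
#' @param gen result of [generate_catalog].
#' @param sim a [simulation_config].
#' @return data.frame `sample`, `ct`, `variant`, `proportion` (proportions
#'   sum to 1 within each sample).
#' @export
simulate_composition <- function(gen, sim) {
  set.seed(sim$rng_seed + 1L)
  labels <- names(gen$catalog$entries)
  n_ct <- length(labels)
  if (n_ct == 0L)
    return(data.frame(sample = character(0), ct = character(0),
                      variant = character(0), proportion = numeric(0)))
  if (n_ct == 1L) {
    base <- 1
  } else {
    rest <- 0.7^seq_len(n_ct - 1L)
    base <- c(sim$dominant_fraction,
              (1 - sim$dominant_fraction) * rest / sum(rest))
  }
  props <- matrix(0, nrow = sim$n_samples, ncol = n_ct)
  if (sim$abundance_model == "dirichlet") {
    for (s in seq_len(sim$n_samples))
      props[s, ] <- rdirichlet1(sim$dirichlet_concentration * base)
  } else {
    logw <- log(base)
    for (s in seq_len(sim$n_samples)) {
      if (s > 1L) logw <- logw + rnorm(n_ct, sd = sim$walk_sd)
      props[s, ] <- exp(logw) / sum(exp(logw))
    }
  }
  if (!is.null(sim$bottleneck)) {
    after <- sim$bottleneck$after
    founders <- sample(seq_len(n_ct), min(sim$bottleneck$survivors, n_ct),
                       prob = props[after, ])
    for (s in seq(after + 1L, sim$n_samples)) {
      keep <- props[s, founders]
      props[s, ] <- 0
      props[s, founders] <- keep / sum(keep)
    }
  }
  vf <- rbind(sim$variant_fractions_dominant,
              matrix(rep(sim$variant_fractions_rest, max(n_ct - 1L, 0L)),
                     ncol = 4L, byrow = TRUE))
  variants <- c("origin", "new_plus", "proto", "others")
  out <- expand.grid(variant = variants, ct = labels,
                     sample = sim$timepoint_labels,
                     stringsAsFactors = FALSE)[, 3:1]
  out$proportion <- vapply(seq_len(nrow(out)), function(i) {
    s <- match(out$sample[i], sim$timepoint_labels)
    k <- match(out$ct[i], labels)
    v <- match(out$variant[i], variants)
    props[s, k] * vf[k, v]
  }, numeric(1))
  out
}

# draw an ordered spacer-ID array for one (CT, variant) amplicon
draw_array <- function(variant, repertoire, new_spacer, proto_start,
                       spacer_count_probs) {
  k <- sample(1:5, 1L, prob = spacer_count_probs)
  if (variant %in% c("new_plus", "others")) k <- max(k, 2L)
  k <- min(k, length(repertoire))
  switch(variant,
    origin = repertoire[seq_len(k)],
    new_plus = c(new_spacer, repertoire[seq_len(k - 1L)]),
    proto = {
      k <- min(k, length(repertoire) - 1L)
      j <- max(2L, min(proto_start, length(repertoire) - k + 1L))
      repertoire[seq(j, j + k - 1L)]
    },
    others = {
      # deletion of the 2nd origin spacer
      k <- min(k, length(repertoire) - 1L)
      repertoire[seq_len(k + 1L)][-2L]
    })
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1L]]
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

quality_profile <- function(n_bases, model) {
  mu <- seq(model[["start"]], model[["end"]], length.out = n_bases)
  q <- round(mu + rnorm(n_bases, sd = model[["sd"]]))
  pmin(pmax(q, 2L), 40L)
}

#' Synthesize paired-end FASTQ read sets with ground truth
#'
#' For each read pair a (CT, variant) is drawn from the sample composition,
#' an ordered spacer array is built by the variant rules, and the template
#' `leader + repeat + (spacer + repeat) x k` is sequenced as R1 (first
#' `read_length` bases) and R2 (reverse complement of the last
#' `read_length` bases) with per-mate substitution errors and a linear
#' 5'->3' quality decay. Output is byte-deterministic given the seed.
#'
#' @param gen result of [generate_catalog].
#' @param composition result of [simulate_composition].
#' @param sim a [simulation_config].
#' @param outdir directory for FASTQ and truth files (created).
#' @param cfg a [pipeline_config] (supplies `repeat_sequence`).
#' @return A list: `samples` (data.frame `sample_id`, `r1`, `r2` paths),
#'   `truth` (data.frame `read_pair_id`, `sample_id`, `true_ct`,
#'   `true_variant`, `true_spacer_ids`, `template_sequence`), `truth_path`.
#' @export
synthesize_reads <- function(gen, composition, sim, outdir,
                             cfg = pipeline_config()) {
  set.seed(sim$rng_seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rep_seq <- cfg$repeat_sequence
  spacer_seq <- c(gen$catalog$spacer_seq, gen$novel_pool)
  labels <- names(gen$catalog$entries)
  proto_start <- setNames(
    sample(seq(sim$proto_start_range[1L], sim$proto_start_range[2L]),
           length(labels), replace = TRUE), labels)
  per_sample <- rep(sim$n_read_pairs %/% sim$n_samples, sim$n_samples)
  extra <- sim$n_read_pairs - sum(per_sample)
  if (extra > 0) per_sample[seq_len(extra)] <- per_sample[seq_len(extra)] + 1L
  truth <- vector("list", sim$n_samples)
  paths <- data.frame(sample_id = sim$timepoint_labels,
                      r1 = file.path(outdir,
                                     paste0(sim$timepoint_labels,
                                            "_R1.fastq")),
                      r2 = file.path(outdir,
                                     paste0(sim$timepoint_labels,
                                            "_R2.fastq")))
  min_template <- cfg$min_overlap
  for (s in seq_len(sim$n_samples)) {
    lab <- sim$timepoint_labels[s]
    comp <- composition[composition$sample == lab, ]
    n <- per_sample[s]
    pick <- sample(seq_len(nrow(comp)), n, replace = TRUE,
                   prob = comp$proportion)
    ids_list <- vector("list", n)
    templates <- character(n)
    for (i in seq_len(n)) {
      ct <- comp$ct[pick[i]]
      variant <- comp$variant[pick[i]]
      arr <- draw_array(variant, gen$catalog$entries[[ct]],
                        gen$new_spacer_of[[ct]], proto_start[[ct]],
                        sim$spacer_count_probs)
      ids_list[[i]] <- arr
      templates[i] <- paste0(gen$leader, rep_seq,
                             paste0(spacer_seq[as.character(arr)], rep_seq,
                                    collapse = ""))
    }
    if (any(nchar(templates) < min_template))
      stop("template shorter than the minimum overlap requirement; ",
           "increase leader_tail_length or spacer lengths")
    tlen <- nchar(templates)
    r1_seq <- substr(templates, 1L, pmin(sim$read_length, tlen))
    r2_seq <- rev_comp(substr(templates,
                              pmax(1L, tlen - sim$read_length + 1L), tlen))
    r1_seq <- apply_substitutions(r1_seq, sim$error_rate_r1)
    r2_seq <- apply_substitutions(r2_seq, sim$error_rate_r2)
    r1_qual <- lapply(nchar(r1_seq), quality_profile, model = sim$quality_r1)
    r2_qual <- lapply(nchar(r2_seq), quality_profile, model = sim$quality_r2)
    pair_ids <- sprintf("%s_rp%06d", lab, seq_len(n))
    write_fastq(read_set(pair_ids, r1_seq, r1_qual, "R1"), paths$r1[s])
    write_fastq(read_set(pair_ids, r2_seq, r2_qual, "R2"), paths$r2[s])
    truth[[s]] <- data.frame(
      read_pair_id = pair_ids,
      sample_id = lab,
      true_ct = comp$ct[pick],
      true_variant = comp$variant[pick],
      true_spacer_ids = vapply(ids_list, array_key, ""),
      template_sequence = templates)
  }
  truth <- do.call(rbind, truth)
  truth_path <- file.path(outdir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(samples = paths, truth = truth, truth_path = truth_path)
}
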