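# End-to-end orchestration: FASTQ pairs -> trimming/filtering -> merging ->
# clustering -> spacer extraction -> pooled dictionary -> CT assignment ->
# new-CT definition -> variant classes -> profiles, diversity, trajectories.

#' Run the full leader-end typing pipeline
#'
#' Per sample: reads are sliding-window trimmed (mate-specific thresholds),
#' length/quality filtered, merged by best overlap, clustered greedily, and
#' the cluster representatives are screened for direct repeats and spacers.
#' Spacer occurrences from all samples are pooled into one mismatch-
#' tolerant dictionary seeded with the reference catalog; each
#' representative's ordered spacer-ID array is assigned to a CT,
#' dataset-wide singleton arrays are discarded, candidate arrays with
#' enough novel spacers found new CTs, and every assigned array receives a
#' leader-end variant class. Sample profiles, pooled dominance, diversity
#' statistics and trajectory tables are written to `outdir` together with a
#' run log recording every threshold used.
#'
#' @param samples data.frame with columns `sample_id`, `r1`, `r2` (FASTQ
#'   paths).
#' @param catalog a `"ct_catalog"` or path to a catalog file.
#' @param cfg a [pipeline_config].
#' @param outdir output directory (created).
#' @return Invisibly, a list with the run's tables: `config`, `attrition`,
#'   `clusters`, `extraction_status`, `dictionary`, `arrays` (with labels),
#'   `catalog` (updated with new CTs), `variant_calls`, `profiles`,
#'   `pooled`, `diversity`, `rarefaction`, `singleton_fraction`, `outdir`.
#' @export
run_pipeline <- function(samples, catalog, cfg = pipeline_config(), outdir) {
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  validate_catalog(catalog)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "clusters"), showWarnings = FALSE)
  attrition <- list()
  extractions <- list()
  weights <- numeric(0)
  amp_sample <- character(0)
  status_rows <- list()
  cluster_tables <- list()
  member_of <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    stage <- function(name, n_in, n_out, detail = "") {
      data.frame(sample = sid, stage = name, n_in = n_in, n_out = n_out,
                 dropped = n_in - n_out, detail = detail)
    }
    r1 <- tryCatch(read_fastq(samples$r1[s], "R1"),
                   error = function(e) stop("stage read_fastq failed for ",
                                            sid, ": ", conditionMessage(e)))
    r2 <- tryCatch(read_fastq(samples$r2[s], "R2"),
                   error = function(e) stop("stage read_fastq failed for ",
                                            sid, ": ", conditionMessage(e)))
    if (length(r1) != length(r2))
      stop("stage pairing failed for ", sid, ": R1/R2 read counts differ")
    n0 <- length(r1)
    att <- list(stage("input", n0, n0))
    r1 <- sliding_window_trim(r1, cfg$window_size, cfg$q_threshold_r1)
    r2 <- sliding_window_trim(r2, cfg$window_size, cfg$q_threshold_r2)
    att <- c(att, list(stage("trim", n0, n0)))
    f1 <- filter_reads(r1, cfg)
    f2 <- filter_reads(r2, cfg)
    keep <- f1$keep & f2$keep
    att <- c(att, list(stage(
      "filter", n0, sum(keep),
      sprintf("r1_short=%d;r1_lowq=%d;r2_short=%d;r2_lowq=%d",
              f1$drops[["short"]], f1$drops[["low_quality"]],
              f2$drops[["short"]], f2$drops[["low_quality"]]))))
    r1 <- r1[keep]; r2 <- r2[keep]
    mg <- merge_pairs(r1, r2, cfg)
    att <- c(att, list(stage("merge", sum(keep), sum(mg$merged),
                             sprintf("merge_failed=%d", mg$n_failed))))
    attrition[[sid]] <- do.call(rbind, att)
    amp <- mg$amplicons
    cl <- cluster_greedy(amp$id, amp$seq, cfg)
    ctab <- cluster_table(cl)
    ctab <- if (nrow(ctab)) {
      cbind(sample = sid, ctab)
    } else {
      data.frame(sample = character(0), cluster_id = integer(0),
                 representative_id = character(0), member_id = character(0))
    }
    cluster_tables[[sid]] <- ctab
    write.table(ctab, file.path(outdir, "clusters",
                                paste0(sid, "_clusters.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(cl)) {
      write_fasta(setNames(vapply(cl, `[[`, "", "representative_seq"),
                           paste0(sid, ":",
                                  vapply(cl, `[[`, "", "representative_id"),
                                  "|size=",
                                  vapply(cl, function(x)
                                    length(x$member_ids), 1L))),
                  file.path(outdir, "clusters",
                            paste0(sid, "_representatives.fasta")))
    }
    for (j in seq_along(cl)) {
      rep_id <- paste0(sid, ":", cl[[j]]$representative_id)
      ex <- extract_spacers(rep_id, cl[[j]]$representative_seq, cfg)
      extractions[[rep_id]] <- ex
      weights[rep_id] <- cl[[j]]$size
      amp_sample[rep_id] <- sid
      member_of[[rep_id]] <- cl[[j]]$member_ids
      status_rows[[rep_id]] <- data.frame(
        sample = sid, amplicon_id = rep_id, status = ex$status,
        weight = cl[[j]]$size, n_spacers = nrow(ex$spacers),
        n_dropped_segments = nrow(ex$dropped), rc_used = ex$rc_used)
    }
  }
  attrition <- do.call(rbind, c(attrition, list(make.row.names = FALSE)))
  extraction_status <- if (length(status_rows)) {
    do.call(rbind, c(status_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(sample = character(0), amplicon_id = character(0),
               status = character(0), weight = numeric(0),
               n_spacers = integer(0), n_dropped_segments = integer(0),
               rc_used = logical(0))
  }
  # pooled spacer dictionary, seeded with the reference catalog
  occ <- do.call(rbind, c(lapply(names(extractions), function(a) {
    sp <- extractions[[a]]$spacers
    if (!nrow(sp)) return(NULL)
    data.frame(amplicon_id = a, position = sp$position_from_leader,
               sequence = sp$sequence, weight = weights[[a]])
  }), list(make.row.names = FALSE)))
  if (!is.null(occ) && nrow(occ)) {
    write_fasta(setNames(occ$sequence,
                         paste0(occ$amplicon_id, "|pos=", occ$position)),
                file.path(outdir, "spacers.fasta"))
  }
  dict <- if (!is.null(occ) && nrow(occ)) {
    build_dictionary(occ$sequence, occ$weight, cfg, catalog)
  } else {
    build_dictionary(character(0), numeric(0), cfg, catalog)
  }
  arrays <- arrays_from_amplicons(extractions, dict$map, weights)
  arrays$sample <- amp_sample[arrays$amplicon_id]
  arrays <- assign_cts(arrays, catalog, cfg)
  ds <- discard_singletons(arrays)
  arrays <- ds$assignments
  # novel candidates found new CTs, numbered after the catalog
  cand <- arrays[arrays$label == "candidate_new", , drop = FALSE]
  suffixes <- suppressWarnings(
    as.integer(sub("^.*?([0-9]+)$", "\\1", names(catalog$entries))))
  next_num <- max(c(0L, suffixes), na.rm = TRUE) + 1L
  novel_seq <- setNames(dict$identities$sequence,
                        as.character(dict$identities$spacer_id))
  new_def <- define_new_cts(cand, catalog, paste0("CT", next_num),
                            spacer_seq = novel_seq)
  catalog_out <- new_def$catalog
  if (nrow(new_def$assignments)) {
    idx <- match(new_def$assignments$amplicon_id, arrays$amplicon_id)
    arrays$label[idx] <- new_def$assignments$label
  }
  calls <- classify_variants(arrays, catalog_out)
  calls$sample <- amp_sample[calls$amplicon_id]
  # per-sample profiles and pooled dominance
  profiles <- sample_profiles(arrays, catalog_out, cfg,
                              sample_ids = samples$sample_id)
  pooled <- pooled_summary(arrays, catalog_out, cfg)
  divers <- list(); rare <- list()
  for (sid in samples$sample_id) {
    w <- arrays[arrays$sample == sid &
                arrays$label %in% names(catalog_out$entries), ]
    if (!nrow(w)) next
    cts <- tapply(w$weight, w$label, sum)
    d <- diversity_stats(as.numeric(cts), cfg = cfg)
    divers[[sid]] <- data.frame(sample = sid, S_obs = d$S_obs, F1 = d$F1,
                                F2 = d$F2, chao1 = d$chao1,
                                shannon_H = d$shannon_H)
    rare[[sid]] <- cbind(sample = sid, d$rarefaction)
  }
  divers <- do.call(rbind, c(divers, list(make.row.names = FALSE)))
  rare <- do.call(rbind, c(rare, list(make.row.names = FALSE)))
  res <- list(config = cfg, attrition = attrition,
              clusters = cluster_tables,
              extraction_status = extraction_status,
              dictionary = dict$identities, arrays = arrays,
              catalog = catalog_out, variant_calls = calls,
              profiles = profiles, pooled = pooled,
              diversity = divers, rarefaction = rare,
              singleton_fraction = ds$singleton_fraction,
              outdir = outdir)
  write_run_outputs(res)
  invisible(res)
}

# pooled CT weights, fractions of total amplicon weight, dominance flags
pooled_summary <- function(arrays, catalog, cfg) {
  total <- sum(arrays$weight)
  assigned <- arrays[arrays$label %in% names(catalog$entries), ]
  cts <- if (nrow(assigned)) tapply(assigned$weight, assigned$label, sum)
         else setNames(numeric(0), character(0))
  out <- data.frame(ct = names(cts), weight = as.numeric(cts))
  out <- out[order(-out$weight, out$ct), , drop = FALSE]
  out$fraction_total <- if (total > 0) out$weight / total else 0
  out$fraction_assigned <- if (sum(out$weight) > 0) {
    out$weight / sum(out$weight)
  } else 0
  out$dominant <- out$fraction_total > cfg$dominance_threshold
  rownames(out) <- NULL
  attr(out, "total_weight") <- total
  attr(out, "assigned_weight") <- sum(out$weight)
  out
}

# per-sample CT weights and relative abundances; empty samples flagged
sample_profiles <- function(arrays, catalog, cfg, sample_ids) {
  rows <- lapply(sample_ids, function(sid) {
    sub <- arrays[arrays$sample == sid, , drop = FALSE]
    total <- sum(sub$weight)
    assigned <- sub[sub$label %in% names(catalog$entries), , drop = FALSE]
    if (!nrow(assigned)) {
      return(data.frame(sample = sid, ct = "unassigned",
                        weight = total, total_weight = total,
                        fraction_total = if (total > 0) 1 else 0,
                        dominant = FALSE, empty = total == 0))
    }
    cts <- tapply(assigned$weight, assigned$label, sum)
    other <- total - sum(cts)
    df <- data.frame(sample = sid,
                     ct = c(names(cts), "unassigned"),
                     weight = c(as.numeric(cts), other),
                     total_weight = total)
    df$fraction_total <- df$weight / total
    df$dominant <- df$fraction_total > cfg$dominance_threshold &
      df$ct != "unassigned"
    df$empty <- FALSE
    df
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

write_run_outputs <- function(res) {
  outdir <- res$outdir
  wt <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$attrition, "attrition.tsv")
  wt(res$extraction_status, "extraction_status.tsv")
  wt(res$dictionary, "dictionary.tsv")
  if (nrow(res$dictionary)) {
    write_fasta(setNames(res$dictionary$sequence,
                         paste0("spacer_", res$dictionary$spacer_id,
                                "|abundance=", res$dictionary$abundance)),
                file.path(outdir, "dictionary.fasta"))
  }
  arr <- res$arrays
  arr_flat <- data.frame(amplicon_id = arr$amplicon_id, sample = arr$sample,
                         weight = arr$weight,
                         ids = vapply(arr$ids, array_key, ""),
                         label = arr$label, novel_count = arr$novel_count)
  wt(arr_flat, "arrays.tsv")
  wt(res$variant_calls, "variant_calls.tsv")
  wt(res$profiles, "sample_profiles.tsv")
  wt(res$pooled, "pooled_cts.tsv")
  if (!is.null(res$diversity)) wt(res$diversity, "diversity.tsv")
  if (!is.null(res$rarefaction)) wt(res$rarefaction, "rarefaction.tsv")
  write_catalog(res$catalog, file.path(outdir, "catalog_out.txt"))
  log_path <- file.path(outdir, "run_log.txt")
  cfg <- res$config
  lines <- c("ctyper run log",
             paste0("config ", names(.ct_defaults), " = ",
                    vapply(names(.ct_defaults),
                           function(k) paste(format(cfg[[k]]), collapse = ","),
                           "")),
             sprintf("singleton_fraction = %.6g", res$singleton_fraction),
             sprintf("total_weight = %s",
                     format(attr(res$pooled, "total_weight"))),
             sprintf("assigned_weight = %s",
                     format(attr(res$pooled, "assigned_weight"))),
             sprintf("label_counts: %s",
                     paste(names(table(res$arrays$label)),
                           table(res$arrays$label), sep = "=",
                           collapse = " ")))
  writeLines(lines, log_path)
  invisible(res)
}

#' Figure-style report tables
#'
#' Builds plot-ready tables from a finished run: pooled CT fractions with
#' rare CTs binned (`fig1`), per-sample trajectories of the pooled-dominant
#' CTs (`fig2`), pooled variant fractions per CT (`fig3`), and the
#' per-sample variant trajectory of one chosen CT (`fig4`).
#'
#' @param run result of [run_pipeline].
#' @param ct CT label for the `fig4` table (default: the most abundant CT).
#' @return A list of data.frames: `fig1`, `fig2`, `fig3`, `fig4`.
#' @export
report_tables <- function(run, ct = NULL) {
  pooled <- run$pooled
  total <- attr(pooled, "total_weight")
  rare <- pooled[!pooled$dominant, , drop = FALSE]
  fig1 <- rbind(pooled[pooled$dominant, c("ct", "weight", "fraction_total")],
                if (nrow(rare)) data.frame(ct = "rare",
                                           weight = sum(rare$weight),
                                           fraction_total =
                                             sum(rare$fraction_total)),
                data.frame(ct = "unassigned",
                           weight = total - sum(pooled$weight),
                           fraction_total =
                             if (total > 0)
                               (total - sum(pooled$weight)) / total else 0))
  rownames(fig1) <- NULL
  dom <- pooled$ct[pooled$dominant]
  prof <- run$profiles
  fig2 <- prof[prof$ct %in% dom,
               c("sample", "ct", "weight", "fraction_total")]
  traj <- variant_trajectories(run$variant_calls)
  fig3 <- traj_pooled(run$variant_calls)
  if (is.null(ct)) ct <- if (nrow(pooled)) pooled$ct[1L] else NA_character_
  if (!ct %in% run$variant_calls$ct_label)
    stop("CT '", ct, "' not in this run; available: ",
         paste(sort(unique(run$variant_calls$ct_label)), collapse = ", "))
  fig4 <- traj[traj$ct_label == ct, , drop = FALSE]
  list(fig1 = fig1, fig2 = fig2, fig3 = fig3, fig4 = fig4)
}

# pooled (all samples) variant fractions per CT
traj_pooled <- function(calls) {
  calls$sample <- "pooled"
  variant_trajectories(calls)
}

#' Report tables from a finished run directory
#'
#' Rebuilds the [report_tables] output from the TSV files a previous
#' [run_pipeline] call wrote (`pooled_cts.tsv`, `sample_profiles.tsv`,
#' `variant_calls.tsv`).
#'
#' @param rundir the run's output directory.
#' @param ct CT label for the `fig4` table (default: most abundant).
#' @return A list of data.frames: `fig1`, `fig2`, `fig3`, `fig4`.
#' @export
report_from_dir <- function(rundir, ct = NULL) {
  rd <- function(f) read.table(file.path(rundir, f), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  pooled <- rd("pooled_cts.tsv")
  profiles <- rd("sample_profiles.tsv")
  calls <- rd("variant_calls.tsv")
  attr(pooled, "total_weight") <- sum(profiles$weight)
  run <- list(pooled = pooled, profiles = profiles, variant_calls = calls)
  report_tables(run, ct = ct)
}
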