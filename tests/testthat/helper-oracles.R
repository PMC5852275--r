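# Plain-R reference for the best ungapped alignment (independent of the
# C++ scan): enumerate every offset, maximize matches, tie -> longer
# overlap.
oracle_best_alignment <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- c(matches = -1, overlap = -1)
  for (d in (-(nb - 1)):(na - 1)) {
    lo <- max(0L, d); hi <- min(na, d + nb)
    ov <- hi - lo
    if (ov <= 0) next
    x <- av[(lo + 1):hi]; y <- bv[(lo - d + 1):(hi - d)]
    m <- sum(x == y & x != "N")
    if (m > best[["matches"]] ||
        (m == best[["matches"]] && ov > best[["overlap"]]))
      best <- c(matches = m, overlap = ov)
  }
  best
}

# reference greedy clustering applying the package's membership rule
# (identity on the best alignment, coverage over the longer sequence)
oracle_cluster <- function(ids, seqs, cfg) {
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]
  reps <- character(0); members <- list()
  for (i in seq_along(ids)) {
    hit <- 0
    for (j in seq_along(reps)) {
      b <- oracle_best_alignment(reps[j], seqs[i])
      identity <- b[["matches"]] / b[["overlap"]]
      coverage <- b[["overlap"]] / max(nchar(reps[j]), nchar(seqs[i]))
      if (identity >= cfg$cluster_identity - 1e-12 &&
          coverage >= cfg$cluster_coverage - 1e-12) {
        hit <- j
        break
      }
    }
    if (hit == 0) {
      reps <- c(reps, seqs[i])
      members <- c(members, list(character(0)))
      hit <- length(reps)
    }
    members[[hit]] <- c(members[[hit]], ids[i])
  }
  members
}

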