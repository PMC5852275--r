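# FASTQ handling and the in-memory read-set container. A read_set is a plain
# list of parallel fields: id (character), seq (character), qual (list of
# integer Phred vectors), mate ("R1"/"R2" per read). Biostrings does the
# actual FASTQ parsing/serialisation (Sanger Phred+33).

#' Construct a read set
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences (A,C,G,T,N).
#' @param qual list of integer vectors of per-base Phred scores (same
#'   lengths as `seq`).
#' @param mate `"R1"` or `"R2"`, recycled to the number of reads.
#' @return A list of class `"read_set"`.
#' @export
read_set <- function(id, seq, qual, mate = "R1") {
  n <- length(id)
  stopifnot(length(seq) == n, length(qual) == n)
  if (n > 0L && any(nchar(seq) != lengths(qual)))
    stop("sequence and quality lengths disagree")
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = qual, mate = rep_len(as.character(mate), n)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$seq[i], x$qual[i], x$mate[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set of", length(x), "reads (",
      paste(unique(x$mate), collapse = "/"), ")\n")
  invisible(x)
}

phred_to_string <- function(q) {
  vapply(q, function(z) {
    if (!length(z)) "" else rawToChar(as.raw(as.integer(z) + 33L))
  }, "")
}

string_to_phred <- function(s) {
  lapply(s, function(z) if (!nzchar(z)) integer(0) else utf8ToInt(z) - 33L)
}

#' Read / write FASTQ (Sanger Phred+33)
#'
#' @param path FASTQ file path.
#' @param mate mate label to attach to every read (`"R1"` or `"R2"`).
#' @return `read_fastq()`: a [read_set]; `write_fastq()`: `path`, invisibly.
#' @export
read_fastq <- function(path, mate = "R1") {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L)
    return(read_set(character(0), character(0), list(), mate))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- string_to_phred(as.character(S4Vectors::mcols(x)$qualities))
  read_set(names(x), as.character(x), qual, mate)
}

#' @rdname read_fastq
#' @param reads a [read_set].
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(phred_to_string(reads$qual))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read / write FASTA
#'
#' Thin wrappers returning/accepting a named character vector.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
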