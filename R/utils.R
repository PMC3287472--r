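`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# lower median: for an even number of values, the smaller of the two central ones
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Coerce a reference to a named character vector of contig sequences
#'
#' Accepts a FASTA path, a [Biostrings::DNAStringSet], or a named character
#' vector. FASTA record descriptions are truncated at the first whitespace,
#' matching the SAM convention for reference names.
#'
#' @param reference FASTA file path, `DNAStringSet`, or named character vector.
#' @return Named character vector, one element per contig.
#' @export
as_ref_seqs <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      if (length(reference) != 1L) {
        stop("a multi-contig character reference must be named")
      }
      names(reference) <- "ref"
    }
    return(toupper(reference))
  }
  stop("unsupported reference representation: ", class(reference)[1])
}

#' Generate a uniform-random genome sequence
#'
#' @param length Number of bases.
#' @param name Contig name.
#' @return Named character vector of length one.
#' @export
random_genome <- function(length, name = "ref") {
  stopifnot(length >= 1)
  out <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  names(out) <- name
  out
}

#' Read a FASTQ file into a named character vector
#'
#' Plain 4-line FASTQ, Phred+33; qualities are discarded. Read ids are taken
#' up to the first whitespace.
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1L, length(lines), by = 4L)]))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  names(seqs) <- ids
  seqs
}

#' Write reads as FASTQ
#'
#' @param seqs Named character vector (names become read ids).
#' @param path Output path.
#' @param qual Quality character used for every base (Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  n <- length(seqs)
  quals <- strrep(qual, nchar(seqs))
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", names(seqs))
  lines[seq(2L, by = 4L, length.out = n)] <- as.character(seqs)
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- quals
  writeLines(lines, path)
  invisible(path)
}

#' Write contig sequences as FASTA
#'
#' @param seqs Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
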