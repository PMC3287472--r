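# SAM text I/O and soft-clip extraction.
#
# Alignments travel through the pipeline as a plain data.frame with columns
#   qname, flag, rname, start (0-based leftmost aligned base), mapq, cigar,
#   seq, qual, strand ("+"/"-"), mapped, primary
# SAM's 1-based POS is converted at this boundary; everything downstream is
# 0-based, half-open.

.aln_columns <- c("qname", "flag", "rname", "start", "mapq", "cigar",
                  "seq", "qual", "strand", "mapped", "primary")

empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             start = integer(0), mapq = integer(0), cigar = character(0),
             seq = character(0), qual = character(0), strand = character(0),
             mapped = logical(0), primary = logical(0),
             stringsAsFactors = FALSE)
}

#' Read a SAM file into an alignment table
#'
#' Parses plain-text SAM (v1). Only the eleven mandatory fields are kept;
#' optional tags are ignored. Missing qualities (`"*"`) are tolerated.
#'
#' @param path Path to a SAM file.
#' @return A data.frame with one row per alignment record and columns
#'   `qname`, `flag`, `rname`, `start` (0-based), `mapq`, `cigar`, `seq`,
#'   `qual`, `strand`, `mapped`, `primary`. The SAM header lines are attached
#'   as attribute `"header"`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- empty_alignments()
    attr(out, "header") <- header
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("SAM record with fewer than 11 fields at line ",
         which(nf < 11L)[1], " of the alignment section")
  }
  col <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(col(2))
  pos1 <- as.integer(col(4))
  out <- data.frame(
    qname = col(1),
    flag = flag,
    rname = col(3),
    start = pos1 - 1L,
    mapq = as.integer(col(5)),
    cigar = col(6),
    seq = toupper(col(10)),
    qual = col(11),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapped = bitwAnd(flag, 4L) == 0L,
    primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    stringsAsFactors = FALSE
  )
  attr(out, "header") <- header
  out
}

#' Write an alignment table as SAM
#'
#' @param aln Alignment data.frame (see [read_sam()]).
#' @param path Output path.
#' @param ref_lengths Named integer vector of contig lengths for `@SQ` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref_lengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(ref_lengths)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                          as.integer(ref_lengths)))
  }
  qual <- aln$qual
  if (is.null(qual)) qual <- rep("*", nrow(aln))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$qname, aln$flag, aln$rname, aln$start + 1L, aln$mapq,
                  aln$cigar, aln$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert hard clips to soft clips using the original reads
#'
#' Some aligners store only the mapped part of a partially aligned read and
#' mark the trimmed tails as hard clips (`H`), which makes the clipped bases
#' unrecoverable from the SAM record alone. Given the original reads (e.g.
#' from the FASTQ the aligner consumed), every terminal `H` operation is
#' rewritten as `S` and the record's sequence is replaced by the full-length
#' original read, reverse-complemented first for reverse-strand records so it
#' matches SAM orientation. Records without `H` pass through unchanged, so
#' the operation is idempotent.
#'
#' @param aln Alignment data.frame (see [read_sam()]).
#' @param original_reads Named character vector mapping read id to the
#'   original full-length read sequence (as read off the sequencer).
#' @return The alignment table with hard clips softened.
#' @export
soften_hard_clips <- function(aln, original_reads) {
  has_h <- grepl("H", aln$cigar, fixed = TRUE)
  if (!any(has_h)) return(aln)
  for (i in which(has_h)) {
    ops <- parse_cigar(aln$cigar[i])
    hpos <- which(ops$op == "H")
    if (any(hpos != 1L & hpos != nrow(ops))) {
      stop("internal hard clip in CIGAR '", aln$cigar[i], "' for read ",
           aln$qname[i])
    }
    orig <- original_reads[aln$qname[i]]
    if (is.na(orig)) {
      stop("read ", aln$qname[i], " not found in the original read set")
    }
    orig <- toupper(unname(orig))
    if (aln$strand[i] == "-") orig <- revcomp(orig)
    ops$op[hpos] <- "S"
    # merge adjacent identical ops (e.g. 5H10S85M -> 15S85M)
    run <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
    ops <- data.frame(op = ops$op[!duplicated(run)],
                      len = as.integer(tapply(ops$len, run, sum)),
                      stringsAsFactors = FALSE)
    if (cigar_query_length(ops) != nchar(orig)) {
      stop("original read length (", nchar(orig),
           ") inconsistent with CIGAR '", cigar_to_string(ops),
           "' for read ", aln$qname[i])
    }
    aln$cigar[i] <- cigar_to_string(ops)
    aln$seq[i] <- orig
    aln$qual[i] <- "*"
  }
  aln
}

empty_clips <- function() {
  data.frame(read_id = character(0), ref = character(0), side = character(0),
             pos = integer(0), fragment = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Extract clipped reads from an alignment table
#'
#' Keeps primary mapped records with exactly one terminal soft-clip run and
#' turns each into a clipped read: the anchor's breakpoint position plus the
#' clipped fragment. Records clipped at both ends carry no usable directional
#' information and are dropped, as are records without any soft clip.
#'
#' The breakpoint of a `LEFT` clip is the record's start; for a `RIGHT` clip
#' it is the first reference position after the last aligned base (0-based,
#' half-open convention).
#'
#' @param aln Alignment data.frame (see [read_sam()]).
#' @param min_mapq Minimum mapping quality (default 0: no filtering).
#' @return A data.frame with columns `read_id`, `ref`, `side`
#'   (`"LEFT"`/`"RIGHT"`), `pos` (0-based breakpoint), `fragment` (clipped
#'   bases in SAM orientation) and `strand`. Skip counters are attached as
#'   attribute `"counts"`.
#' @export
extract_clipped_reads <- function(aln, min_mapq = 0) {
  counts <- c(n_records = nrow(aln), n_skipped_unusable = 0L,
              n_skipped_malformed = 0L, n_no_clip = 0L, n_both_ends = 0L,
              n_left = 0L, n_right = 0L)
  usable <- aln$mapped & aln$primary & aln$seq != "*" & aln$cigar != "*" &
    aln$mapq >= min_mapq
  counts["n_skipped_unusable"] <- sum(!usable)
  a <- aln[usable, , drop = FALSE]
  if (nrow(a) == 0L) {
    out <- empty_clips()
    attr(out, "counts") <- counts
    return(out)
  }
  runs <- cigar_runs(a$cigar)
  malformed <- attr(runs, "malformed")
  # hard clips consume no stored sequence; ignore them for clip geometry
  runs <- runs[runs$op != "H", , drop = FALSE]
  qlen <- ref_len <- left_s <- right_s <- integer(nrow(a))
  qc <- runs$op %in% .cigar_query_ops
  rc <- runs$op %in% .cigar_ref_ops
  add_by_rec <- function(recs, vals) {
    acc <- integer(nrow(a))
    if (length(recs)) {
      s <- rowsum(vals, recs, reorder = FALSE)
      acc[as.integer(rownames(s))] <- s[, 1]
    }
    acc
  }
  qlen <- add_by_rec(runs$rec[qc], runs$len[qc])
  ref_len <- add_by_rec(runs$rec[rc], runs$len[rc])
  first <- !duplicated(runs$rec)
  last <- !duplicated(runs$rec, fromLast = TRUE)
  lf <- first & runs$op == "S"
  rt <- last & runs$op == "S"
  left_s[runs$rec[lf]] <- runs$len[lf]
  right_s[runs$rec[rt]] <- runs$len[rt]
  only_clip <- first & last & runs$op == "S"  # CIGAR is a single S run

  malformed <- malformed | qlen != nchar(a$seq)
  counts["n_skipped_malformed"] <- sum(malformed)
  both <- !malformed & ((left_s > 0L & right_s > 0L) |
                          seq_len(nrow(a)) %in% runs$rec[only_clip])
  counts["n_both_ends"] <- sum(both)
  take_l <- !malformed & !both & left_s > 0L
  take_r <- !malformed & !both & right_s > 0L
  counts["n_left"] <- sum(take_l)
  counts["n_right"] <- sum(take_r)
  counts["n_no_clip"] <- sum(!malformed & !both & !take_l & !take_r)

  out <- rbind(
    data.frame(read_id = a$qname[take_l], ref = a$rname[take_l],
               side = rep("LEFT", sum(take_l)), pos = a$start[take_l],
               fragment = substring(a$seq[take_l], 1L, left_s[take_l]),
               strand = a$strand[take_l], stringsAsFactors = FALSE),
    data.frame(read_id = a$qname[take_r], ref = a$rname[take_r],
               side = rep("RIGHT", sum(take_r)),
               pos = a$start[take_r] + ref_len[take_r],
               fragment = substring(a$seq[take_r],
                                    qlen[take_r] - right_s[take_r] + 1L,
                                    qlen[take_r]),
               strand = a$strand[take_r], stringsAsFactors = FALSE)
  )
  attr(out, "counts") <- counts
  out
}
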