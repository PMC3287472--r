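# Deterministic seed-and-extend read mapper.
#
# This is a minimal mapper for simulated, (near-)error-free reads: it places
# each read by an exact 20-mer seed at either end, in either orientation,
# verifies the placement base-by-base, and soft-clips the non-matching tail.
# It exists so the pipeline's test data need no external aligner; real data
# should be mapped with any production aligner that emits soft clips.

#' Map reads to a genome with terminal soft-clipping
#'
#' Each read is anchored by an exact seed at its start and/or its end
#' (forward orientation first, then the reverse complement for still
#' unplaced reads). The full read is compared to the reference at each
#' implied position: if the total number of mismatches is at most
#' `max_mismatch` the read is reported end-to-end (`<n>M`); otherwise the
#' tail beyond the anchor's first mismatch is soft-clipped, and when both
#' ends anchor, the placement with the longer matched anchor wins (ties go
#' to the prefix anchor) — mirroring how production aligners keep the
#' longer partial alignment. Reads with no anchored placement are reported
#' unmapped.
#'
#' @param reads Named character vector of read sequences (names become
#'   `qname`s), or a `DNAStringSet`.
#' @param genome Reference genome (path, `DNAStringSet`, named character).
#' @param seed_len Exact seed length (default 20).
#' @param max_mismatch Mismatches tolerated in an end-to-end placement
#'   (default 4); reads exceeding it are soft-clipped at the first mismatch.
#' @param include_unmapped Keep unmapped reads in the output table
#'   (default FALSE).
#' @return An alignment data.frame in the same layout as [read_sam()].
#' @export
map_reads <- function(reads, genome, seed_len = 20L, max_mismatch = 4L,
                      include_unmapped = FALSE) {
  refs <- as_ref_seqs(genome)
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%07d", seq_along(reads))
  }
  n <- length(reads)
  qname <- names(reads)
  res_flag <- rep(NA_integer_, n)
  res_rname <- rep(NA_character_, n)
  res_start <- rep(NA_integer_, n)
  res_cigar <- rep(NA_character_, n)
  res_seq <- rep(NA_character_, n)
  rlen <- nchar(reads)
  rc_reads <- NULL  # computed lazily once

  # one anchored placement attempt for a batch of oriented sequences;
  # returns per-read start (1-based), cigar and anchor length (NA = failed)
  try_side <- function(sq, nn, g, gdna, L, side_suffix) {
    out <- list(st = rep(NA_integer_, length(sq)),
                cigar = rep(NA_character_, length(sq)),
                anchor = rep(NA_integer_, length(sq)))
    seeds <- if (side_suffix) {
      substring(sq, nn - seed_len + 1L, nn)
    } else {
      substring(sq, 1L, seed_len)
    }
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    mi <- Biostrings::matchPDict(pd, gdna)
    nh <- S4Vectors::elementNROWS(mi)
    hit <- which(nh > 0L)
    if (length(hit) == 0L) return(out)
    u <- unlist(Biostrings::startIndex(mi)[hit], use.names = FALSE)
    off <- cumsum(nh[hit])
    first <- u[off - nh[hit] + 1L]
    # implied 1-based start of the full read on this contig
    astart <- if (side_suffix) first - (nn[hit] - seed_len) else first
    ok <- astart >= 1L & astart + nn[hit] - 1L <= L
    hit <- hit[ok]
    astart <- astart[ok]
    if (length(hit) == 0L) return(out)
    sqh <- sq[hit]
    nnh <- nn[hit]
    seg <- substring(g, astart, astart + nnh - 1L)
    exact <- seg == sqh
    cig <- rep(NA_character_, length(hit))
    anchor <- rep(NA_integer_, length(hit))
    st <- astart
    cig[exact] <- paste0(nnh[exact], "M")
    anchor[exact] <- nnh[exact]
    for (k in which(!exact)) {
      mm <- which(charToRaw(sqh[k]) != charToRaw(seg[k]))
      if (length(mm) <= max_mismatch) {
        cig[k] <- paste0(nnh[k], "M")
        anchor[k] <- nnh[k]
      } else if (!side_suffix) {
        j <- mm[1] - 1L
        if (j >= seed_len && nnh[k] - j >= 1L) {
          cig[k] <- paste0(j, "M", nnh[k] - j, "S")
          anchor[k] <- j
        }
      } else {
        j <- mm[length(mm)]  # clip read bases 1..j
        if (nnh[k] - j >= seed_len && j >= 1L) {
          cig[k] <- paste0(j, "S", nnh[k] - j, "M")
          st[k] <- astart[k] + j
          anchor[k] <- nnh[k] - j
        }
      }
    }
    out$st[hit] <- st
    out$cigar[hit] <- cig
    out$anchor[hit] <- anchor
    out
  }

  for (contig in names(refs)) {
    g <- refs[[contig]]
    gdna <- Biostrings::DNAString(g)
    L <- nchar(g)
    for (orient_rev in c(FALSE, TRUE)) {
      unres <- which(is.na(res_flag) & rlen >= seed_len)
      if (length(unres) == 0L) break
      if (orient_rev && is.null(rc_reads)) rc_reads <- revcomp(reads)
      sq <- if (orient_rev) rc_reads[unres] else unname(reads[unres])
      nn <- rlen[unres]
      pre <- try_side(sq, nn, g, gdna, L, side_suffix = FALSE)
      suf <- try_side(sq, nn, g, gdna, L, side_suffix = TRUE)
      # longer matched anchor wins; ties go to the prefix anchor
      use_suf <- !is.na(suf$anchor) &
        (is.na(pre$anchor) | suf$anchor > pre$anchor)
      st <- ifelse(use_suf, suf$st, pre$st)
      cig <- ifelse(use_suf, suf$cigar, pre$cigar)
      got <- !is.na(cig)
      if (any(got)) {
        gi <- unres[got]
        res_flag[gi] <- if (orient_rev) 16L else 0L
        res_rname[gi] <- contig
        res_start[gi] <- st[got] - 1L  # 0-based
        res_cigar[gi] <- cig[got]
        res_seq[gi] <- sq[got]
      }
    }
  }

  mapped <- !is.na(res_flag)
  keep <- if (include_unmapped) rep(TRUE, n) else mapped
  flag <- res_flag
  flag[!mapped] <- 4L
  out <- data.frame(
    qname = qname[keep],
    flag = flag[keep],
    rname = ifelse(mapped, res_rname, "*")[keep],
    start = ifelse(mapped, res_start, -1L)[keep],
    mapq = ifelse(mapped, 60L, 0L)[keep],
    cigar = ifelse(mapped, res_cigar, "*")[keep],
    seq = ifelse(mapped, res_seq, unname(reads))[keep],
    qual = rep("*", sum(keep)),
    stringsAsFactors = FALSE
  )
  out$strand <- ifelse(bitwAnd(out$flag, 16L) > 0L, "-", "+")
  out$mapped <- bitwAnd(out$flag, 4L) == 0L
  out$primary <- rep(TRUE, nrow(out))
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}
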