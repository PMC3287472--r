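# Breakpoint normalization. When the sequences flanking an SV junction share
# bases (microhomology), several intervals produce byte-identical donor
# genomes and the breakpoints are genuinely ambiguous. Calls and simulated
# truth records are therefore both left-aligned: an interval is shifted one
# base left as long as applying the event at the shifted interval yields the
# same donor sequence. This mirrors the standard VCF left-alignment
# convention for indels.

# local donor sequence produced by applying one event; comparing these over
# a fixed reference region [lo, hi) is equivalent to comparing full donors
.local_donor <- function(g, lo, hi, s, e, type, copies) {
  seg <- substring(g, s + 1L, e)
  piece <- switch(type,
                  DEL = "",
                  INV = revcomp(seg),
                  DUP = strrep(seg, copies))
  paste0(substring(g, lo + 1L, s), piece, substring(g, e + 1L, hi))
}

#' Normalize a structural-variant interval
#'
#' Resolves breakpoint microhomology deterministically by moving the
#' interval towards a canonical, donor-equivalent representative:
#' deletions and tandem duplications are shifted left while the shifted
#' event produces a donor genome identical to the original (the VCF
#' left-alignment convention); inversions — whose ambiguity is palindromic
#' trimming, `[s, e)` versus `[s+1, e-1)` when the outer bases are
#' complementary — are shrunk while equivalence holds, matching the
#' maximal-anchor representation a split-read caller observes. Other types
#' pass through unchanged.
#'
#' @param g Reference contig sequence (single character string).
#' @param s,e Interval, 0-based half-open.
#' @param type SV type (`"DEL"`, `"INV"`, `"DUP"`; others returned as-is).
#' @param copies Tandem-duplication copy number (default 2; the result is
#'   insensitive to it in all but degenerate repeat structures).
#' @param max_shift Safety cap on the adjustment (default 200 bases).
#' @return Integer vector `c(start, end)` of the normalized interval.
#' @export
normalize_sv_interval <- function(g, s, e, type, copies = 2L,
                                  max_shift = 200L) {
  if (!type %in% c("DEL", "INV", "DUP") || e <= s) {
    return(c(as.integer(s), as.integer(e)))
  }
  if (is.na(copies) || copies < 2L) copies <- 2L
  shift <- 0L
  if (type == "INV") {
    while (e - s > 2L && shift < max_shift) {
      lo <- max(0L, s - 1L)
      hi <- min(nchar(g), e + 1L)
      d0 <- .local_donor(g, lo, hi, s, e, type, copies)
      d1 <- .local_donor(g, lo, hi, s + 1L, e - 1L, type, copies)
      if (d0 != d1) break
      s <- s + 1L
      e <- e - 1L
      shift <- shift + 1L
    }
  } else {
    while (s > 0L && shift < max_shift) {
      lo <- max(0L, s - 2L)
      hi <- min(nchar(g), e + 1L)
      d0 <- .local_donor(g, lo, hi, s, e, type, copies)
      d1 <- .local_donor(g, lo, hi, s - 1L, e - 1L, type, copies)
      if (d0 != d1) break
      s <- s - 1L
      e <- e - 1L
      shift <- shift + 1L
    }
  }
  c(as.integer(s), as.integer(e))
}

# left-align an insertion point by rotating the inserted sequence: inserting
# I at p equals inserting ref[p-1] + I[-len] at p-1 whenever the last base
# of I matches ref[p-1]
.leftalign_insertion <- function(g, p, ins, max_shift = 200L) {
  len <- nchar(ins)
  shift <- 0L
  while (p > 0L && shift < max_shift &&
         substring(ins, len, len) == substring(g, p, p)) {
    ins <- paste0(substring(g, p, p), substring(ins, 1L, len - 1L))
    p <- p - 1L
    shift <- shift + 1L
  }
  list(pos = as.integer(p), ins_seq = ins)
}

# vectorised over the rows of a calls/truth-like data.frame
.normalize_records <- function(records, refs, copies_col = NULL) {
  if (nrow(records) == 0L) return(records)
  for (i in seq_len(nrow(records))) {
    tp <- records$sv_type[i]
    g <- refs[[records$ref[i]]]
    if (tp == "INS" && !is.null(records$ins_seq) &&
        !is.na(records$ins_seq[i])) {
      la <- .leftalign_insertion(g, records$start[i], records$ins_seq[i])
      records$start[i] <- la$pos
      records$end[i] <- la$pos
      records$ins_seq[i] <- la$ins_seq
      next
    }
    if (!tp %in% c("DEL", "INV", "DUP")) next
    cp <- if (!is.null(copies_col)) records[[copies_col]][i] else 2L
    se <- normalize_sv_interval(g, records$start[i], records$end[i], tp,
                                copies = cp)
    records$start[i] <- se[1]
    records$end[i] <- se[2]
  }
  records
}
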