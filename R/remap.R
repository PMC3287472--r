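# Re-alignment of clipped fragments inside reference windows excised around
# breakpoint clusters. Restricting the search space to +/- 1000 bases around
# each cluster keeps short fragments from landing on spurious genome-wide
# matches.

#' Excise reference windows around breakpoint clusters
#'
#' One window per cluster, `[rep_pos - elongation, rep_pos + elongation)`,
#' clamped at contig boundaries. Windows carry their global offset so that
#' remap hits can be lifted back to genome coordinates.
#'
#' @param clusters Cluster data.frame from [cluster_breakpoints()].
#' @param reference Reference (path, `DNAStringSet`, or named character).
#' @param elongation Half-width of the window in bases (default 1000).
#' @return A data.frame with columns `cluster_id`, `ref`, `start`, `end`
#'   (0-based half-open, global) and `seq`.
#' @export
excise_windows <- function(clusters, reference, elongation = 1000) {
  refs <- as_ref_seqs(reference)
  missing <- setdiff(unique(clusters$ref), names(refs))
  if (length(missing)) {
    stop("contig not present in the reference: ", paste(missing, collapse = ", "))
  }
  ref_len <- nchar(refs)[clusters$ref]
  start <- pmax(0L, as.integer(clusters$rep_pos - elongation))
  end <- pmin(as.integer(ref_len), as.integer(clusters$rep_pos + elongation))
  data.frame(
    cluster_id = clusters$cluster_id,
    ref = clusters$ref,
    start = start,
    end = end,
    seq = substring(refs[clusters$ref], start + 1L, end),
    stringsAsFactors = FALSE
  )
}

#' Filter clipped fragments by length
#'
#' Only fragments longer than 10 bases (length >= `min_len`) carry enough
#' sequence to be re-aligned unambiguously.
#'
#' @param clips Clipped-read data.frame from [extract_clipped_reads()].
#' @param min_len Minimum fragment length kept (default 11).
#' @return The filtered data.frame.
#' @export
select_fragments <- function(clips, min_len = 11) {
  clips[nchar(clips$fragment) >= min_len, , drop = FALSE]
}

#' Re-align clipped fragments inside the excised windows
#'
#' Each fragment and its reverse complement are searched against every
#' window, in three stages of increasing cost: exact substring scan,
#' mismatch-tolerant full-length match, and Smith-Waterman local alignment
#' with unit mismatch/gap costs. The single best placement is kept
#' (score, then lowest global start, then forward orientation); a placement
#' is accepted only if it covers at least `min_cover` of the fragment with at
#' most `max(max_edit_base, max_edit_frac * length)` edits. Fragments with no
#' acceptable placement are reported as unmapped, which is itself informative
#' (insertions).
#'
#' @param frags Fragment data.frame: a clipped-read table (see
#'   [select_fragments()]) with an `anchor_cluster` column giving the id of
#'   the breakpoint cluster each fragment's read supports.
#' @param windows Window data.frame from [excise_windows()].
#' @param min_cover Minimum aligned fraction of the fragment (default 0.9).
#' @param max_edit_base Edit-distance floor (default 2).
#' @param max_edit_frac Edit-distance fraction of fragment length (default 0.1).
#' @param use_sw Whether to run the Smith-Waterman fallback (default TRUE).
#' @return A data.frame with one row per fragment: `read_id`,
#'   `anchor_cluster`, `anchor_side`, `mapped`, and for mapped fragments
#'   `target_ref`, `target_start`, `target_end` (0-based half-open, global),
#'   `orientation` (`"same"`/`"opposite"`), `score`, `edit_distance`.
#' @export
remap_fragments <- function(frags, windows, min_cover = 0.9,
                            max_edit_base = 2, max_edit_frac = 0.1,
                            use_sw = TRUE) {
  n <- nrow(frags)
  out <- data.frame(
    read_id = frags$read_id,
    anchor_cluster = frags$anchor_cluster,
    anchor_side = ifelse(frags$side == "LEFT", "L", "R"),
    mapped = logical(n),
    target_ref = NA_character_,
    target_start = NA_integer_,
    target_end = NA_integer_,
    orientation = NA_character_,
    score = NA_real_,
    edit_distance = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n == 0L || nrow(windows) == 0L) return(out)
  wseq <- windows$seq
  # exact placements are found in one scan over all windows concatenated
  # with N spacers (fragments contain no N, so no hit can cross a spacer)
  spacer <- strrep("N", 30L)
  big <- paste(wseq, collapse = spacer)
  wlen <- nchar(wseq)
  woff <- cumsum(c(0L, (wlen + 30L)[-length(wlen)]))  # 0-based start in big
  big_dna <- NULL  # built lazily for the inexact stages
  sw_mat <- NULL

  # keep only placements fully inside a single window and convert big-string
  # starts to per-window candidates
  window_hits <- function(st, len, ori, edits, score) {
    win <- findInterval(st, woff + 1L)
    ok <- win >= 1L & st > woff[win] & st + len - 1L <= woff[win] + wlen[win]
    if (!any(ok)) return(NULL)
    data.frame(win = win[ok], local_start = st[ok] - woff[win[ok]],
               len = len, orientation = ori, edits = as.integer(edits[ok]),
               score = score[ok], stringsAsFactors = FALSE)
  }

  sw_seed_len <- 11L
  big_kmers <- NULL  # all seed k-mers of the windows, built on first use
                     # (spacer-straddling k-mers contain N and never match)
  # windows holding an exact seed k-mer of the pattern: the only places a
  # local alignment could anchor (seed-and-extend)
  seed_windows <- function(pat) {
    fl <- nchar(pat)
    if (fl < sw_seed_len) return(seq_along(wseq))
    k <- sw_seed_len
    if (is.null(big_kmers)) {
      bs <- seq_len(nchar(big) - k + 1L)
      big_kmers <<- substring(big, bs, bs + k - 1L)
    }
    starts <- seq_len(fl - k + 1L)
    kmers <- substring(pat, starts, starts + k - 1L)
    st <- which(big_kmers %in% kmers)
    if (length(st) == 0L) return(integer(0))
    unique(findInterval(st, woff + 1L))
  }

  scan_exact <- function(pat, ori) {
    st <- gregexpr(pat, big, fixed = TRUE)[[1]]
    if (st[1] == -1L) return(NULL)
    st <- as.integer(st)
    fl <- nchar(pat)
    window_hits(st, fl, ori, rep(0L, length(st)), rep(as.numeric(fl),
                                                      length(st)))
  }

  place_fragment <- function(fr, rc) {
    fl <- nchar(fr)
    pats <- c(same = fr, opposite = rc)
    max_edit <- max(max_edit_base, floor(max_edit_frac * fl))
    cand <- rbind(scan_exact(pats[["same"]], "same"),
                  scan_exact(pats[["opposite"]], "opposite"))
    # stage 2: full-length match allowing mismatches (spacer Ns count as
    # mismatches, and spacer-overlapping hits are rejected anyway)
    if (is.null(cand)) {
      if (is.null(big_dna)) big_dna <<- Biostrings::DNAString(big)
      for (ori in names(pats)) {
        m <- Biostrings::matchPattern(pats[[ori]], big_dna,
                                      max.mismatch = max_edit,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        st <- Biostrings::start(m)
        ed <- Biostrings::neditStartingAt(Biostrings::DNAString(pats[[ori]]),
                                          big_dna, starting.at = st,
                                          with.indels = FALSE)
        cand <- rbind(cand, window_hits(st, fl, ori, ed, fl - 2 * ed))
      }
    }
    # stage 3: seed-and-extend local alignment with unit costs, run only
    # against windows holding an exact seed k-mer of the pattern
    if (is.null(cand) && use_sw && fl >= 2L) {
      if (is.null(sw_mat)) {
        sw_mat <<- Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE)
      }
      for (ori in names(pats)) {
        for (j in seed_windows(pats[[ori]])) {
          al <- Biostrings::pairwiseAlignment(
            pats[[ori]], wseq[j], type = "local",
            substitutionMatrix = sw_mat, gapOpening = 0, gapExtension = 1)
          p <- Biostrings::pattern(al)
          s <- Biostrings::subject(al)
          qcov <- Biostrings::end(p) - Biostrings::start(p) + 1L
          ni <- Biostrings::nindel(al)
          edits <- Biostrings::nmismatch(al) +
            Biostrings::insertion(ni)[1, "WidthSum"] +
            Biostrings::deletion(ni)[1, "WidthSum"]
          if (qcov / fl < min_cover || edits > max_edit) next
          cand <- rbind(cand, data.frame(
            win = j, local_start = Biostrings::start(s),
            len = Biostrings::end(s) - Biostrings::start(s) + 1L,
            orientation = ori, edits = as.integer(edits),
            score = as.numeric(Biostrings::score(al)),
            stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand$gstart <- windows$start[cand$win] + cand$local_start - 1L
    cand$gend <- cand$gstart + cand$len
    cand$gref <- windows$ref[cand$win]
    # the same placement seen through overlapping windows counts once
    cand <- cand[!duplicated(cand[, c("gref", "gstart", "gend",
                                      "orientation")]), , drop = FALSE]
    cand[order(-cand$score, cand$gstart,
               cand$orientation != "same"), , drop = FALSE][1, ]
  }

  # identical fragment sequences (frequent across tandem-duplication copies)
  # are placed once
  uniq <- unique(frags$fragment)
  uniq_rc <- revcomp(uniq)
  hits <- lapply(seq_along(uniq),
                 function(k) place_fragment(uniq[k], uniq_rc[k]))
  idx <- match(frags$fragment, uniq)
  for (i in seq_len(n)) {
    best <- hits[[idx[i]]]
    if (is.null(best)) next
    out$mapped[i] <- TRUE
    out$target_ref[i] <- best$gref
    out$target_start[i] <- best$gstart
    out$target_end[i] <- best$gend
    out$orientation[i] <- best$orientation
    out$score[i] <- best$score
    out$edit_distance[i] <- best$edits
  }
  out
}
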