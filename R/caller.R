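# Typed SV inference from remap geometry, call clustering, scoring,
# overlap resolution and filtering.
#
# Geometry, with b the anchor cluster's breakpoint and [m1, m2) the remap
# placement of the clipped fragment (all 0-based half-open):
#   * opposite orientation                      -> INV [min(b,m1), max(b,m2))
#   * R anchor, fragment resumes beyond b       -> DEL [b, m1)
#   * L anchor, fragment ends before b          -> DEL [m2, b)
#   * R anchor, fragment re-enters left of b    -> DUP [m1, b)
#   * L anchor, fragment re-enters right of b   -> DUP [b, m2)
#   * unmapped fragment + opposite-handed cluster at the same position -> INS
#   * mapped but inconsistent + opposite-handed cluster at the same
#     position                                  -> TRA (source = placement)
# A fragment whose placement simply continues the anchor (straddles b) is
# uninformative.

.sv_types <- c("DEL", "INV", "DUP", "INS", "TRA")

empty_evidence <- function() {
  data.frame(read_id = character(0), ref = character(0), sv_type = character(0),
             start = integer(0), end = integer(0), anchor_cluster = integer(0),
             anchor_side = character(0), opp_cluster = integer(0),
             tra_ref = character(0), tra_start = integer(0),
             tra_end = integer(0), stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(ref = character(0), start = integer(0), end = integer(0),
             sv_type = character(0), B_L = integer(0), B_R = integer(0),
             C_L = integer(0), C_R = integer(0), n_evidence = integer(0),
             score = numeric(0), tra_ref = character(0),
             tra_start = integer(0), tra_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Classify remapped fragments into typed SV evidence
#'
#' Applies the placement-geometry decision tree (see the package vignette)
#' to every remapped or unmapped fragment, producing one piece of typed
#' evidence per informative fragment.
#'
#' @param remap Remap table from [remap_fragments()].
#' @param clusters Cluster data.frame from [cluster_breakpoints()]`$clusters`.
#' @param same_pos_tol Maximum distance (bases) between an L- and an
#'   R-breakpoint cluster for them to count as "the same position" in the
#'   insertion/translocation rules (default 10).
#' @return Evidence data.frame with columns `read_id`, `ref`, `sv_type`,
#'   `start`, `end`, `anchor_cluster`, `anchor_side`, `opp_cluster`,
#'   `tra_ref`, `tra_start`, `tra_end`.
#' @export
classify_fragments <- function(remap, clusters, same_pos_tol = 10) {
  if (nrow(remap) == 0L) return(empty_evidence())
  # nearest opposite-handedness cluster within tolerance, per cluster
  opp_of <- rep(NA_integer_, nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    cand <- which(clusters$ref == clusters$ref[k] &
                    clusters$side != clusters$side[k] &
                    abs(clusters$rep_pos - clusters$rep_pos[k]) <= same_pos_tol)
    if (length(cand)) {
      d <- abs(clusters$rep_pos[cand] - clusters$rep_pos[k])
      cand <- cand[order(d, clusters$rep_pos[cand])]
      opp_of[k] <- clusters$cluster_id[cand[1]]
    }
  }
  idx <- match(remap$anchor_cluster, clusters$cluster_id)
  b <- clusters$rep_pos[idx]
  aref <- clusters$ref[idx]
  side <- remap$anchor_side
  opp <- opp_of[idx]
  has_opp <- !is.na(opp)
  n <- nrow(remap)
  m1 <- remap$target_start
  m2 <- remap$target_end
  mapped <- remap$mapped
  same_ref <- mapped & !is.na(remap$target_ref) & remap$target_ref == aref

  is_inv <- same_ref & remap$orientation == "opposite"
  fwd <- same_ref & !is_inv
  del_r <- fwd & side == "R" & m1 > b
  del_l <- fwd & side == "L" & m2 < b
  dup_r <- fwd & side == "R" & !del_r & m2 <= b
  dup_l <- fwd & side == "L" & !del_l & m1 >= b
  is_ins <- !mapped & has_opp
  is_tra <- mapped & !is_inv & !del_r & !del_l & !dup_r & !dup_l & has_opp

  type <- rep(NA_character_, n)
  type[is_inv] <- "INV"
  type[del_r | del_l] <- "DEL"
  type[dup_r | dup_l] <- "DUP"
  type[is_ins] <- "INS"
  type[is_tra] <- "TRA"

  s <- e <- rep(NA_integer_, n)
  s[is_inv] <- pmin(b, m1)[is_inv]
  e[is_inv] <- pmax(b, m2)[is_inv]
  s[del_r] <- b[del_r];  e[del_r] <- m1[del_r]
  s[del_l] <- m2[del_l]; e[del_l] <- b[del_l]
  s[dup_r] <- m1[dup_r]; e[dup_r] <- b[dup_r]
  s[dup_l] <- b[dup_l];  e[dup_l] <- m2[dup_l]
  # point events take the leftmost of the two coincident cluster positions:
  # with insert/flank homology the L and R clusters sit a few bases apart
  # and the leftmost representative is the canonical (left-aligned) point
  opp_rep <- clusters$rep_pos[match(opp, clusters$cluster_id)]
  pt <- is_ins | is_tra
  s[pt] <- pmin(b, opp_rep)[pt]
  e[pt] <- s[pt]

  oc <- rep(NA_integer_, n)
  oc[is_ins | is_tra] <- opp[is_ins | is_tra]
  tra_ref <- rep(NA_character_, n)
  tra_s <- tra_e <- rep(NA_integer_, n)
  tra_ref[is_tra] <- remap$target_ref[is_tra]
  tra_s[is_tra] <- m1[is_tra]
  tra_e[is_tra] <- m2[is_tra]

  keep <- !is.na(type)
  if (!any(keep)) return(empty_evidence())
  data.frame(
    read_id = remap$read_id[keep], ref = aref[keep], sv_type = type[keep],
    start = as.integer(s[keep]), end = as.integer(e[keep]),
    anchor_cluster = remap$anchor_cluster[keep], anchor_side = side[keep],
    opp_cluster = oc[keep], tra_ref = tra_ref[keep],
    tra_start = tra_s[keep], tra_end = tra_e[keep],
    stringsAsFactors = FALSE, row.names = NULL)
}

# single-linkage components under distance max(|ds|,|de|) <= tol; operates on
# unique (start,end) pairs so heavily duplicated evidence stays cheap
.link_intervals <- function(s, e, tol) {
  key <- paste(s, e)
  uk <- !duplicated(key)
  us <- s[uk]; ue <- e[uk]
  m <- length(us)
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (abs(us[i] - us[j]) <= tol && abs(ue[i] - ue[j]) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp_u <- vapply(seq_len(m), find, integer(1))
  comp_u <- match(comp_u, unique(comp_u))
  comp_u[match(key, key[uk])]
}

#' Aggregate typed evidence into SV calls
#'
#' Evidence of the same type on the same contig is merged single-linkage when
#' both interval endpoints agree within `call_tol` bases; merged endpoints are
#' the lower medians of member endpoints. Support counts follow breakpoint
#' handedness: `B_L`/`B_R` are the support of the L-/R-handed breakpoint
#' clusters involved in the call, `C_L`/`C_R` the member fragments anchored
#' on each handedness.
#'
#' @param evidence Evidence data.frame from [classify_fragments()].
#' @param clusters Cluster data.frame from [cluster_breakpoints()]`$clusters`.
#' @param call_tol Maximum per-endpoint difference for merging (default 10).
#' @return Unscored call data.frame (see [score_calls()]).
#' @export
aggregate_calls <- function(evidence, clusters, call_tol = 10) {
  if (nrow(evidence) == 0L) return(empty_calls())
  cl_side <- clusters$side[match(seq_len(max(clusters$cluster_id)),
                                 clusters$cluster_id)]
  cl_support <- clusters$support[match(seq_len(max(clusters$cluster_id)),
                                       clusters$cluster_id)]
  out <- list()
  for (grp in split(seq_len(nrow(evidence)),
                    paste(evidence$ref, evidence$sv_type))) {
    ev <- evidence[grp, , drop = FALSE]
    # coarse blocking on sorted starts bounds the pairwise stage
    ord <- order(ev$start, ev$end)
    ev <- ev[ord, , drop = FALSE]
    block <- cumsum(c(TRUE, diff(ev$start) > call_tol))
    for (bl in split(seq_len(nrow(ev)), block)) {
      sub <- ev[bl, , drop = FALSE]
      comp <- .link_intervals(sub$start, sub$end, call_tol)
      for (cp in split(seq_len(nrow(sub)), comp)) {
        mem <- sub[cp, , drop = FALSE]
        ids <- unique(c(mem$anchor_cluster,
                        mem$opp_cluster[!is.na(mem$opp_cluster)]))
        sides <- cl_side[ids]
        b_l <- sum(cl_support[ids[sides == "L"]])
        b_r <- sum(cl_support[ids[sides == "R"]])
        tra_ref <- NA_character_
        tra_s <- tra_e <- NA_integer_
        if (mem$sv_type[1] == "TRA") {
          tra_ref <- names(sort(table(mem$tra_ref), decreasing = TRUE))[1]
          sel <- mem$tra_ref == tra_ref
          tra_s <- as.integer(lower_median(mem$tra_start[sel]))
          tra_e <- as.integer(lower_median(mem$tra_end[sel]))
        }
        out[[length(out) + 1L]] <- data.frame(
          ref = mem$ref[1],
          start = as.integer(lower_median(mem$start)),
          end = as.integer(lower_median(mem$end)),
          sv_type = mem$sv_type[1],
          B_L = as.integer(b_l), B_R = as.integer(b_r),
          C_L = sum(mem$anchor_side == "L"),
          C_R = sum(mem$anchor_side == "R"),
          n_evidence = nrow(mem),
          score = NA_real_,
          tra_ref = tra_ref, tra_start = tra_s, tra_end = tra_e,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, out)
  calls[order(calls$ref, calls$start, calls$sv_type), , drop = FALSE]
}

#' Reliability score of an SV call
#'
#' `sqrt((B_L + C_L) * (B_R + C_R))`: increases with both clipped-read and
#' remapped-fragment support, is maximal for balanced left/right support at a
#' fixed total, and is exactly zero for one-sided calls
#' (`(n, 0, m, 0)` or `(0, n, 0, m)`).
#'
#' @param b_l,b_r Clipped-read support of the L-/R-handed breakpoint cluster.
#' @param c_l,c_r Remapped fragments anchored on the L/R side.
#' @return Non-negative numeric score (vectorised).
#' @export
score_sv <- function(b_l, b_r, c_l, c_r) {
  sqrt((b_l + c_l) * (b_r + c_r))
}

#' Attach reliability scores to calls
#'
#' @param calls Call data.frame from [aggregate_calls()].
#' @param score_fun Scoring strategy taking `(b_l, b_r, c_l, c_r)`;
#'   defaults to [score_sv()].
#' @return The calls with the `score` column filled in.
#' @export
score_calls <- function(calls, score_fun = score_sv) {
  calls$score <- score_fun(calls$B_L, calls$B_R, calls$C_L, calls$C_R)
  calls
}

#' Resolve overlapping same-type calls
#'
#' Among calls of the same type whose intervals intersect, only the
#' highest-scoring one survives (ties: larger total support, then smaller
#' start). Point events are treated as width-1 intervals for the overlap
#' test. Calls of different types never compete.
#'
#' @param calls Scored call data.frame.
#' @return The filtered calls.
#' @export
resolve_overlaps <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  keep <- logical(nrow(calls))
  for (grp in split(seq_len(nrow(calls)),
                    paste(calls$ref, calls$sv_type))) {
    sub <- calls[grp, , drop = FALSE]
    s <- sub$start
    e <- pmax(sub$end, sub$start + 1L)
    tot <- sub$B_L + sub$B_R + sub$C_L + sub$C_R
    ord <- order(-sub$score, -tot, sub$start)
    taken_s <- integer(0)
    taken_e <- integer(0)
    for (i in ord) {
      if (!any(s[i] < taken_e & e[i] > taken_s)) {
        keep[grp[i]] <- TRUE
        taken_s <- c(taken_s, s[i])
        taken_e <- c(taken_e, e[i])
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  out[order(out$ref, out$start, out$sv_type), , drop = FALSE]
}

#' Remove zero-score calls
#'
#' Calls supported from only one side score exactly zero and are dropped;
#' this is the method's noise control.
#'
#' @param calls Scored call data.frame.
#' @return Calls with positive score; the number removed is attached as
#'   attribute `"n_removed"`.
#' @export
filter_zero_score <- function(calls) {
  out <- calls[calls$score > 0, , drop = FALSE]
  attr(out, "n_removed") <- nrow(calls) - nrow(out)
  out
}

#' Call structural variants from an alignment table
#'
#' Runs the full pipeline: clipped-read extraction, breakpoint clustering,
#' window excision, fragment remapping, typed classification, call
#' aggregation, scoring, same-type overlap resolution and (by default)
#' zero-score filtering.
#'
#' @param aln Alignment data.frame (see [read_sam()] / [map_reads()]).
#' @param reference Reference genome (path, `DNAStringSet`, named character).
#' @param bp_tol Breakpoint clustering tolerance in bases (default 5).
#' @param min_frag_len Minimum clipped-fragment length remapped (default 11,
#'   i.e. fragments longer than 10 bases).
#' @param window_elong Window half-width around each cluster (default 1000).
#' @param call_tol Call clustering tolerance in bases (default 10).
#' @param same_pos_tol L/R same-position tolerance for INS/TRA (default 10).
#' @param min_mapq Minimum mapping quality of anchors (default 0).
#' @param zero_filter Drop zero-score calls (default TRUE).
#' @param original_reads Optional named character vector of original read
#'   sequences for hard-clip softening.
#' @param score_fun Scoring strategy, defaults to [score_sv()].
#' @return Call data.frame with columns `ref`, `start`, `end`, `sv_type`,
#'   `B_L`, `B_R`, `C_L`, `C_R`, `n_evidence`, `score`, `tra_ref`,
#'   `tra_start`, `tra_end` (coordinates 0-based half-open; INS/TRA are point
#'   events with `start == end`). Per-stage counts are attached as attribute
#'   `"manifest"`.
#' @export
call_svs <- function(aln, reference, bp_tol = 5, min_frag_len = 11,
                     window_elong = 1000, call_tol = 10, same_pos_tol = 10,
                     min_mapq = 0, zero_filter = TRUE, original_reads = NULL,
                     score_fun = score_sv) {
  reference <- as_ref_seqs(reference)
  if (!is.null(original_reads)) {
    aln <- soften_hard_clips(aln, original_reads)
  }
  clips <- extract_clipped_reads(aln, min_mapq = min_mapq)
  manifest <- list(n_records = nrow(aln),
                   clip_counts = as.list(attr(clips, "counts")),
                   n_clipped_reads = nrow(clips))
  bps <- collect_breakpoints(clips)
  bc <- cluster_breakpoints(bps, tolerance = bp_tol)
  manifest$n_breakpoints <- nrow(bps)
  manifest$n_clusters <- nrow(bc$clusters)
  frags <- clips
  frags$anchor_cluster <- bc$assignment
  frags <- select_fragments(frags, min_len = min_frag_len)
  manifest$n_fragments_selected <- nrow(frags)
  if (nrow(bc$clusters) == 0L || nrow(frags) == 0L) {
    calls <- empty_calls()
    manifest$n_fragments_remapped <- 0L
    manifest$n_evidence <- 0L
    manifest$n_calls_raw <- 0L
    manifest$n_calls_after_overlap <- 0L
    manifest$n_calls_final <- 0L
    attr(calls, "manifest") <- manifest
    return(calls)
  }
  windows <- excise_windows(bc$clusters, reference, elongation = window_elong)
  remap <- remap_fragments(frags, windows)
  manifest$n_fragments_remapped <- sum(remap$mapped)
  evidence <- classify_fragments(remap, bc$clusters,
                                 same_pos_tol = same_pos_tol)
  manifest$n_evidence <- nrow(evidence)
  calls <- aggregate_calls(evidence, bc$clusters, call_tol = call_tol)
  # breakpoint microhomology makes shifted intervals equivalent; normalize
  calls <- .normalize_records(calls, reference)
  calls <- score_calls(calls, score_fun = score_fun)
  manifest$n_calls_raw <- nrow(calls)
  calls <- resolve_overlaps(calls)
  manifest$n_calls_after_overlap <- nrow(calls)
  if (zero_filter) {
    calls <- filter_zero_score(calls)
    manifest$n_zero_score_removed <- attr(calls, "n_removed")
  }
  manifest$n_calls_final <- nrow(calls)
  rownames(calls) <- NULL
  attr(calls, "manifest") <- manifest
  calls
}
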