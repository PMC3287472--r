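# Breakpoint pooling and clustering.
#
# A LEFT-clipped read supports an L-breakpoint (clipped bases to the left of
# the aligned anchor); a RIGHT-clipped read supports an R-breakpoint. Nearby
# breakpoints of the same handedness on the same contig are chained into
# clusters whose support counts feed the reliability score.

#' Collect per-read breakpoints from clipped reads
#'
#' @param clips Clipped-read data.frame from [extract_clipped_reads()].
#' @return A data.frame with columns `ref`, `pos`, `side` (`"L"`/`"R"`) and
#'   `source_read_id`.
#' @export
collect_breakpoints <- function(clips) {
  data.frame(
    ref = clips$ref,
    pos = clips$pos,
    side = ifelse(clips$side == "LEFT", "L", "R"),
    source_read_id = clips$read_id,
    stringsAsFactors = FALSE
  )
}

#' Cluster breakpoints within a base tolerance
#'
#' Breakpoints are grouped per contig and handedness, sorted by position and
#' chained single-linkage: a gap larger than `tolerance` between consecutive
#' sorted positions starts a new cluster. The cluster representative is the
#' lower median of member positions, which keeps single-base resolution when
#' most members sit on the true junction and a minority are shifted by
#' coincidental reference matches past it.
#'
#' @param bps Breakpoint data.frame from [collect_breakpoints()].
#' @param tolerance Maximum gap (bases) between consecutive member positions
#'   (default 5).
#' @return A list with `clusters` (data.frame `cluster_id`, `ref`, `side`,
#'   `rep_pos`, `support`, sorted by contig then representative position) and
#'   `assignment` (integer cluster id for each input breakpoint row).
#' @export
cluster_breakpoints <- function(bps, tolerance = 5) {
  stopifnot(tolerance >= 0)
  n <- nrow(bps)
  if (n == 0L) {
    return(list(
      clusters = data.frame(cluster_id = integer(0), ref = character(0),
                            side = character(0), rep_pos = integer(0),
                            support = integer(0), stringsAsFactors = FALSE),
      assignment = integer(0)
    ))
  }
  ord <- order(bps$ref, bps$side, bps$pos)
  ref_o <- bps$ref[ord]
  side_o <- bps$side[ord]
  pos_o <- bps$pos[ord]
  new_grp <- c(TRUE, ref_o[-1] != ref_o[-n] | side_o[-1] != side_o[-n] |
                 pos_o[-1] - pos_o[-n] > tolerance)
  grp <- cumsum(new_grp)
  rep_pos <- as.integer(tapply(pos_o, grp, lower_median))
  ref_g <- ref_o[new_grp]
  side_g <- side_o[new_grp]
  support <- as.integer(tabulate(grp))
  # final ids sorted by (ref, rep_pos); ties broken by side then support
  cl_ord <- order(ref_g, rep_pos, side_g)
  id_map <- integer(length(cl_ord))
  id_map[cl_ord] <- seq_along(cl_ord)
  clusters <- data.frame(
    cluster_id = seq_along(cl_ord),
    ref = ref_g[cl_ord],
    side = side_g[cl_ord],
    rep_pos = rep_pos[cl_ord],
    support = support[cl_ord],
    stringsAsFactors = FALSE
  )
  assignment <- integer(n)
  assignment[ord] <- id_map[grp]
  list(clusters = clusters, assignment = assignment)
}
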