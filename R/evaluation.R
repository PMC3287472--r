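# Benchmarking a callset against simulated truth: discovery rate (mean over
# true SVs of the best overlap fraction achieved by any call; a
# sensitivity-like quantity) and true call rate (mean over calls of the best
# overlap fraction achieved by any true SV; specificity-like). Overlaps are
# computed between records of the same type on the same contig only.

#' Widen point events for evaluation
#'
#' Insertions (and translocation insertion points) carry only a single
#' reference coordinate, so their range for overlap purposes is taken as
#' `[p - flank, p + flank]` (half-open: `[p - flank, p + flank + 1)`),
#' clamped at zero. Interval events pass through unchanged.
#'
#' @param records Data.frame with `ref`, `start`, `end`, `sv_type`.
#' @param flank Widening flank in bases (default 100).
#' @return The records with point events widened and a logical `widened`
#'   column added.
#' @export
widen_insertions <- function(records, flank = 100) {
  stopifnot(flank >= 0)
  pt <- records$start == records$end
  records$widened <- pt
  records$start[pt] <- pmax(0L, as.integer(records$start[pt] - flank))
  records$end[pt] <- as.integer(records$end[pt] + flank + 1L)
  records
}

#' Overlap fraction of one record in another
#'
#' `|a intersect b| / |a|` when the two records have the same type and
#' contig; 0 otherwise.
#'
#' @param a,b One-row data.frames (or lists) with `ref`, `start`, `end`,
#'   `sv_type`.
#' @return A number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (a$sv_type != b$sv_type || a$ref != b$ref) return(0)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  width <- a$end - a$start
  if (width <= 0) return(0)
  ov / width
}

# best overlap fraction of each record in `x` against the set `y`
.best_fractions <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    sel <- y$sv_type == x$sv_type[i] & y$ref == x$ref[i]
    if (!any(sel)) return(0)
    ov <- pmax(0, pmin(y$end[sel], x$end[i]) - pmax(y$start[sel], x$start[i]))
    w <- x$end[i] - x$start[i]
    if (w <= 0) return(0)
    max(ov) / w
  }, numeric(1))
}

#' Discovery rate of a callset against truth
#'
#' Mean over truth records of the best overlap fraction achieved by any call
#' of the same type. Point events are widened by `flank` first.
#'
#' @param truth,calls Data.frames with `ref`, `start`, `end`, `sv_type`.
#' @param flank Point-event widening (default 100).
#' @return A number in `[0, 1]`, or `NA` when the truth set is empty.
#' @export
discovery_rate <- function(truth, calls, flank = 100) {
  if (nrow(truth) == 0L) return(NA_real_)
  if (nrow(calls) == 0L) return(0)
  tr <- widen_insertions(truth, flank)
  ca <- widen_insertions(calls, flank)
  mean(.best_fractions(tr, ca))
}

#' True call rate of a callset against truth
#'
#' Mean over calls of the best overlap fraction achieved by any truth record
#' of the same type; the dual of [discovery_rate()].
#'
#' @inheritParams discovery_rate
#' @return A number in `[0, 1]`, or `NA` when the callset is empty.
#' @export
true_call_rate <- function(truth, calls, flank = 100) {
  if (nrow(calls) == 0L) return(NA_real_)
  if (nrow(truth) == 0L) return(0)
  tr <- widen_insertions(truth, flank)
  ca <- widen_insertions(calls, flank)
  mean(.best_fractions(ca, tr))
}

#' Evaluate a callset against truth
#'
#' Overall and per-type discovery rate and true call rate. Undefined rates
#' (empty truth or empty callset for a type) are reported as `NA`, never as
#' 0/0.
#'
#' @inheritParams discovery_rate
#' @param per_type Include a per-type breakdown (default TRUE).
#' @return A list with `discovery_rate`, `true_call_rate`, `n_truth`,
#'   `n_calls`, and optionally `per_type` (data.frame with one row per SV
#'   type present in either set).
#' @export
evaluate_calls <- function(truth, calls, flank = 100, per_type = TRUE) {
  report <- list(
    discovery_rate = discovery_rate(truth, calls, flank),
    true_call_rate = true_call_rate(truth, calls, flank),
    n_truth = nrow(truth),
    n_calls = nrow(calls)
  )
  if (per_type) {
    types <- sort(unique(c(truth$sv_type, calls$sv_type)))
    report$per_type <- do.call(rbind, lapply(types, function(tp) {
      tr <- truth[truth$sv_type == tp, , drop = FALSE]
      ca <- calls[calls$sv_type == tp, , drop = FALSE]
      data.frame(sv_type = tp,
                 discovery_rate = discovery_rate(tr, ca, flank),
                 true_call_rate = true_call_rate(tr, ca, flank),
                 n_truth = nrow(tr), n_calls = nrow(ca),
                 stringsAsFactors = FALSE)
    }))
  }
  report
}
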