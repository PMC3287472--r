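mk_cl <- function(rep_pos, side, support = 5L, ref = "chr1") {
  data.frame(cluster_id = seq_along(rep_pos), ref = ref, side = side,
             rep_pos = rep_pos, support = support, stringsAsFactors = FALSE)
}

mk_hit <- function(cluster, side, m1 = NA, m2 = NA, orientation = "same",
                   mapped = TRUE, ref = "chr1", id = "f1") {
  data.frame(read_id = id, anchor_cluster = cluster, anchor_side = side,
             mapped = mapped, target_ref = ifelse(mapped, ref, NA),
             target_start = m1, target_end = m2,
             orientation = ifelse(mapped, orientation, NA),
             score = 10, edit_distance = 0L, stringsAsFactors = FALSE)
}

test_that("placement geometry maps to the expected SV types", {
  cl <- mk_cl(c(5000L, 6000L), c("R", "L"))
  # R anchor, fragment resumes beyond the breakpoint: deletion
  ev <- classify_fragments(mk_hit(1L, "R", 6000L, 6020L), cl)
  expect_equal(ev$sv_type, "DEL")
  expect_equal(c(ev$start, ev$end), c(5000L, 6000L))
  # L anchor, fragment ends at the opposite breakpoint: same deletion
  ev <- classify_fragments(mk_hit(2L, "L", 4980L, 5000L), cl)
  expect_equal(ev$sv_type, "DEL")
  expect_equal(c(ev$start, ev$end), c(5000L, 6000L))
  # R anchor at the right copy boundary, fragment re-enters on the left: DUP
  cl2 <- mk_cl(c(6000L, 5000L), c("R", "L"))
  ev <- classify_fragments(mk_hit(1L, "R", 5000L, 5030L), cl2)
  expect_equal(ev$sv_type, "DUP")
  expect_equal(c(ev$start, ev$end), c(5000L, 6000L))
  ev <- classify_fragments(mk_hit(2L, "L", 5970L, 6000L), cl2)
  expect_equal(ev$sv_type, "DUP")
  expect_equal(c(ev$start, ev$end), c(5000L, 6000L))
  # opposite orientation: inversion spanning anchor and placement
  ev <- classify_fragments(mk_hit(1L, "R", 5980L, 6000L,
                                  orientation = "opposite"), cl)
  expect_equal(ev$sv_type, "INV")
  expect_equal(c(ev$start, ev$end), c(5000L, 6000L))
})

test_that("unmapped fragments at coincident L/R clusters become insertions", {
  cl <- mk_cl(c(3000L, 3000L), c("L", "R"))
  ev <- classify_fragments(mk_hit(1L, "L", mapped = FALSE), cl)
  expect_equal(ev$sv_type, "INS")
  expect_equal(c(ev$start, ev$end), c(3000L, 3000L))
  expect_equal(ev$opp_cluster, 2L)
  # without an opposite cluster nearby the fragment is uninformative
  lone <- mk_cl(3000L, "L")
  expect_equal(nrow(classify_fragments(mk_hit(1L, "L", mapped = FALSE),
                                       lone)), 0L)
})

test_that("inconsistent placements near coincident clusters become TRA", {
  cl <- mk_cl(c(3000L, 3005L), c("L", "R"))
  # placement straddling the breakpoint fits no interval rule
  ev <- classify_fragments(mk_hit(1L, "L", 2990L, 3010L), cl)
  expect_equal(ev$sv_type, "TRA")
  expect_equal(ev$tra_start, 2990L)
  # different contig
  ev <- classify_fragments(mk_hit(1L, "L", 100L, 130L, ref = "chr9"), cl)
  expect_equal(ev$sv_type, "TRA")
  expect_equal(ev$tra_ref, "chr9")
  # straddle without an opposite cluster: uninformative
  lone <- mk_cl(3000L, "R")
  expect_equal(nrow(classify_fragments(mk_hit(1L, "R", 2990L, 3010L),
                                       lone)), 0L)
})

mk_ev <- function(start, end, type = "DEL", anchor = 1L, side = "R",
                  opp = NA_integer_, id = NULL) {
  n <- length(start)
  data.frame(read_id = id %||% sprintf("e%03d", seq_len(n)), ref = "chr1",
             sv_type = type, start = start, end = end,
             anchor_cluster = anchor, anchor_side = side, opp_cluster = opp,
             tra_ref = NA_character_, tra_start = NA_integer_,
             tra_end = NA_integer_, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("evidence merges by type with lower-median endpoints", {
  cl <- mk_cl(c(5000L, 6000L), c("R", "L"), support = c(7L, 3L))
  ev <- rbind(mk_ev(c(5000L, 5003L), c(6000L, 6002L)),
              mk_ev(5000L, 6000L, type = "DUP"))
  calls <- aggregate_calls(ev, cl)
  expect_equal(nrow(calls), 2L)  # types never merge
  del <- calls[calls$sv_type == "DEL", ]
  expect_equal(c(del$start, del$end), c(5000L, 6000L))
  expect_equal(del$n_evidence, 2L)
  # far-apart same-type evidence stays separate
  calls2 <- aggregate_calls(rbind(mk_ev(5000L, 6000L),
                                  mk_ev(5100L, 6100L)), cl)
  expect_equal(nrow(calls2), 2L)
})

test_that("support counts follow breakpoint handedness", {
  cl <- mk_cl(c(5000L, 6000L), c("R", "L"), support = c(7L, 3L))
  ev <- rbind(mk_ev(c(5000L, 5001L), c(6000L, 6001L), anchor = 1L, side = "R"),
              mk_ev(5000L, 6000L, anchor = 2L, side = "L", id = "x1"))
  call <- aggregate_calls(ev, cl)
  expect_equal(call$B_L, 3L)   # L-handed cluster support
  expect_equal(call$B_R, 7L)   # R-handed cluster support
  expect_equal(call$C_L, 1L)
  expect_equal(call$C_R, 2L)
  # the opposite-cluster link supplies B for unmapped-side-only insertions
  cl_ins <- mk_cl(c(3000L, 3000L), c("L", "R"), support = c(4L, 6L))
  ins <- mk_ev(3000L, 3000L, type = "INS", anchor = 1L, side = "L", opp = 2L)
  ic <- score_calls(aggregate_calls(ins, cl_ins))
  expect_equal(ic$B_L, 4L)
  expect_equal(ic$B_R, 6L)
  expect_gt(ic$score, 0)
})

test_that("the reliability score is zero-ruled, symmetric and balanced", {
  expect_equal(score_sv(5, 0, 3, 0), 0)
  expect_equal(score_sv(0, 5, 0, 3), 0)
  expect_equal(score_sv(0, 0, 0, 0), 0)
  expect_equal(score_sv(2, 2, 2, 2), 4)
  set.seed(51)
  for (i in 1:100) {
    x <- sample(0:10, 4, replace = TRUE)
    s <- score_sv(x[1], x[2], x[3], x[4])
    # symmetry under left/right exchange
    expect_equal(s, score_sv(x[2], x[1], x[4], x[3]))
    # monotone in every count
    for (j in 1:4) {
      y <- x
      y[j] <- y[j] + 1L
      expect_gte(score_sv(y[1], y[2], y[3], y[4]), s)
    }
  }
  # balance: fixed total is maximised at equal sides
  tot <- 10
  scores <- vapply(0:tot, function(l) score_sv(l, tot - l, 0, 0), numeric(1))
  expect_equal(which.max(scores) - 1L, tot %/% 2L)
})

test_that("overlapping same-type calls keep only the higher score", {
  calls <- data.frame(
    ref = "chr1", start = c(100L, 150L, 100L, 300L),
    end = c(200L, 250L, 200L, 400L),
    sv_type = c("DEL", "DEL", "INV", "DEL"),
    B_L = 1L, B_R = 1L, C_L = 1L, C_R = 1L, n_evidence = 1L,
    score = c(5, 3, 2, 1), tra_ref = NA_character_,
    tra_start = NA_integer_, tra_end = NA_integer_,
    stringsAsFactors = FALSE)
  out <- resolve_overlaps(calls)
  expect_equal(nrow(out), 3L)
  expect_false(any(out$sv_type == "DEL" & out$start == 150L))
  expect_true(any(out$sv_type == "INV"))          # other types untouched
  expect_true(any(out$start == 300L))             # disjoint kept
})

test_that("zero-score calls are removed with an audit count", {
  calls <- data.frame(ref = "chr1", start = c(1L, 10L), end = c(5L, 20L),
                      sv_type = "DEL", B_L = c(0L, 2L), B_R = c(3L, 2L),
                      C_L = c(0L, 2L), C_R = c(1L, 2L), n_evidence = 1L,
                      score = c(0, 4), tra_ref = NA_character_,
                      tra_start = NA_integer_, tra_end = NA_integer_,
                      stringsAsFactors = FALSE)
  out <- filter_zero_score(calls)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- filter_zero_score(calls[0, ])
  expect_equal(nrow(empty), 0L)
})
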