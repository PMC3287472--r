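make_aln <- function(qname, flag, rname, start0, cigar, seq) {
  data.frame(qname = qname, flag = flag, rname = rname, start = start0,
             mapq = 60L, cigar = cigar, seq = seq, qual = "*",
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapped = bitwAnd(flag, 4L) == 0L,
             primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
             stringsAsFactors = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("SAM files round-trip through write_sam/read_sam", {
  set.seed(21)
  aln <- make_aln(c("r1", "r2", "r3"), c(0L, 16L, 0L), "chr1",
                  c(999L, 4999L, 10L), c("31S69M", "69M31S", "100M"),
                  replicate(3, rand_seq(100)))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, path, ref_lengths = c(chr1 = 20000L))
  back <- read_sam(path)
  expect_equal(back[names(aln)], aln)
  expect_true(any(grepl("^@SQ", attr(back, "header"))))
})

test_that("hard clips are softened from the original reads", {
  orig <- rand_seq(100)
  aln <- make_aln("r1", 0L, "chr1", 1000L, "20H80M", substring(orig, 21, 100))
  out <- soften_hard_clips(aln, c(r1 = orig))
  expect_equal(out$cigar, "20S80M")
  expect_equal(out$seq, orig)
  # idempotent
  expect_equal(soften_hard_clips(out, c(r1 = orig)), out)
})

test_that("softening respects strand and validates input", {
  orig <- rand_seq(100)
  sam_seq <- revcomp(orig)  # stored in SAM orientation
  aln <- make_aln("r1", 16L, "chr1", 1000L, "80M20H", substring(sam_seq, 1, 80))
  out <- soften_hard_clips(aln, c(r1 = orig))
  expect_equal(out$seq, sam_seq)
  expect_equal(out$cigar, "80M20S")

  plain <- make_aln("r2", 0L, "chr1", 50L, "100M", rand_seq(100))
  expect_identical(soften_hard_clips(plain, c(r1 = orig)), plain)

  missing_aln <- make_aln("r9", 0L, "chr1", 0L, "20H80M", rand_seq(80))
  expect_error(soften_hard_clips(missing_aln, c(r1 = orig)), "not found")
  short <- make_aln("r1", 0L, "chr1", 0L, "20H90M", rand_seq(90))
  expect_error(soften_hard_clips(short, c(r1 = orig)), "inconsistent")
})

test_that("adjacent hard and soft clips merge into one clip after softening", {
  orig <- rand_seq(100)
  aln <- make_aln("r1", 0L, "chr1", 500L, "5H10S85M", substring(orig, 6, 100))
  out <- soften_hard_clips(aln, c(r1 = orig))
  expect_equal(out$cigar, "15S85M")
  clips <- extract_clipped_reads(out)
  expect_equal(clips$side, "LEFT")
  expect_equal(clips$fragment, substring(orig, 1, 15))
})

test_that("clipped reads carry the correct side, breakpoint and fragment", {
  s <- rand_seq(100)
  aln <- rbind(
    make_aln("left", 0L, "chr1", 1000L, "31S69M", s),
    make_aln("right", 0L, "chr1", 1000L, "69M31S", s),
    make_aln("both", 0L, "chr1", 2000L, "14S54M36S", rand_seq(104)),
    make_aln("none", 0L, "chr1", 3000L, "100M", s)
  )
  clips <- extract_clipped_reads(aln)
  expect_equal(nrow(clips), 2L)
  left <- clips[clips$read_id == "left", ]
  expect_equal(left$side, "LEFT")
  expect_equal(left$pos, 1000L)
  expect_equal(left$fragment, substring(s, 1, 31))
  right <- clips[clips$read_id == "right", ]
  expect_equal(right$side, "RIGHT")
  expect_equal(right$pos, 1069L)
  expect_equal(right$fragment, substring(s, 70, 100))
  counts <- attr(clips, "counts")
  expect_equal(unname(counts["n_both_ends"]), 1L)
  expect_equal(unname(counts["n_no_clip"]), 1L)
})

test_that("unmapped, secondary and malformed records are skipped with counts", {
  s <- rand_seq(50)
  aln <- rbind(
    make_aln("u", 4L, "*", -1L, "*", s),
    make_aln("sec", 256L, "chr1", 100L, "10S40M", s),
    make_aln("supp", 2048L, "chr1", 100L, "10S40M", s),
    make_aln("badlen", 0L, "chr1", 100L, "10S50M", s),  # 60 != 50
    make_aln("ok", 0L, "chr1", 100L, "10S40M", s)
  )
  clips <- extract_clipped_reads(aln)
  expect_equal(clips$read_id, "ok")
  counts <- attr(clips, "counts")
  expect_equal(unname(counts["n_skipped_unusable"]), 3L)
  expect_equal(unname(counts["n_skipped_malformed"]), 1L)
})

test_that("deletion/insertion ops shift the right-side breakpoint correctly", {
  # oracle: base-by-base walk over random clipped alignments
  set.seed(22)
  for (i in 1:300) {
    ml1 <- sample(20:60, 1)
    dl <- sample(1:10, 1)
    il <- sample(1:10, 1)
    ml2 <- sample(20:60, 1)
    sl <- sample(5:30, 1)
    left <- sample(c(TRUE, FALSE), 1)
    cg <- if (left) {
      sprintf("%dS%dM%dD%dM", sl, ml1, dl, ml2)
    } else {
      sprintf("%dM%dI%dM%dS", ml1, il, ml2, sl)
    }
    qlen <- cigar_query_length(parse_cigar(cg))
    start0 <- sample(0:5000, 1)
    aln <- make_aln("r", 0L, "chr1", start0, cg, rand_seq(qlen))
    clips <- extract_clipped_reads(aln)
    oracle <- bf_breakpoint(start0, cg)
    if (left) {
      expect_equal(clips$pos, oracle$left)
    } else {
      expect_equal(clips$pos, oracle$right)
    }
  }
})
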