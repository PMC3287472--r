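# independent reconstruction: apply truth records right-to-left by string
# surgery on the reference (deliberately different from the package builder)
bf_rebuild <- function(ref, truth) {
  g <- ref[[1]]
  truth <- truth[order(truth$start, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i]; e <- truth$end[i]
    left <- substring(g, 1, s)
    right <- substring(g, e + 1, nchar(g))
    mid <- switch(truth$sv_type[i],
                  DEL = "",
                  INV = revcomp(substring(g, s + 1, e)),
                  DUP = strrep(substring(g, s + 1, e), truth$copies[i]),
                  INS = truth$ins_seq[i])
    g <- paste0(left, mid, right)
  }
  g
}

test_that("implanting zero events is the identity", {
  set.seed(61)
  ref <- random_genome(5000)
  out <- implant_svs(ref, sim_config(n_svs = 0))
  expect_identical(unname(out$donor[[1]]), unname(ref[[1]]))
  expect_equal(nrow(out$truth), 0L)
})

test_that("event semantics change donor length as expected", {
  set.seed(62)
  ref <- random_genome(100000)
  del <- implant_svs(ref, sim_config(n_svs = 1, sv_types = "DEL",
                                     sv_len_mean = 500, seed = 1))
  expect_equal(nchar(del$donor[[1]]),
               100000 - (del$truth$end - del$truth$start))
  dup <- implant_svs(ref, sim_config(n_svs = 1, sv_types = "DUP",
                                     sv_len_mean = 500, dup_copies_mean = 3,
                                     dup_copies_sd = 1e-6, seed = 2))
  expect_equal(dup$truth$copies, 3L)
  seg_len <- dup$truth$end - dup$truth$start
  expect_equal(nchar(dup$donor[[1]]), 100000 + 2 * seg_len)
  seg <- substring(ref, dup$truth$start + 1, dup$truth$end)
  expect_true(grepl(strrep(seg, 3), dup$donor[[1]], fixed = TRUE))
  ins <- implant_svs(ref, sim_config(n_svs = 1, sv_types = "INS",
                                     sv_len_mean = 300, seed = 3))
  expect_equal(ins$truth$start, ins$truth$end)
  expect_equal(nchar(ins$donor[[1]]), 100000 + nchar(ins$truth$ins_seq))
})

test_that("truth records rebuild the donor for many seeds", {
  for (seed in 1:25) {
    set.seed(seed)
    ref <- random_genome(30000)
    cfg <- sim_config(n_svs = 3, sv_len_mean = 300, insert_mean = 200,
                      insert_sd = 20, read_len = 50, dup_copies_mean = 3,
                      dup_copies_sd = 1, seed = seed)
    out <- implant_svs(ref, cfg)
    expect_identical(unname(out$donor[[1]]), bf_rebuild(ref, out$truth))
    expect_identical(unname(apply_truth(ref, out$truth)[[1]]),
                     unname(out$donor[[1]]))
    # events stay separated
    tr <- out$truth[order(out$truth$start), ]
    if (nrow(tr) > 1) {
      expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] > 0))
    }
  }
})

test_that("a too-short reference fails with guidance", {
  set.seed(63)
  ref <- random_genome(2000)
  expect_error(implant_svs(ref, sim_config(n_svs = 10, sv_len_mean = 100)),
               "longer reference")
})

test_that("substitution counts follow the binomial model", {
  set.seed(64)
  g <- random_genome(1e6)
  expect_identical(add_snvs(g, 0)[[1]], g[[1]])
  mutated <- add_snvs(g, 1e-4)
  n <- attr(mutated, "n_snvs")
  d <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
              mutated[[1]], g[[1]])
  expect_equal(unname(d), n)
  # within 4 sd of the binomial expectation
  expect_lt(abs(n - 100), 4 * sqrt(1e6 * 1e-4))
  all_changed <- add_snvs(random_genome(500), 1)
  expect_equal(attr(all_changed, "n_snvs"), 500L)
})

test_that("read generation honours the coverage formula and pairing", {
  set.seed(65)
  donor <- random_genome(1e6)
  cfg <- sim_config(depth = 20, read_len = 100, seed = 9)
  reads <- generate_reads(donor, cfg)
  expect_equal(length(reads$ids), round(20 * 1e6 / (2 * 100)))
  expect_true(all(nchar(reads$seq1) == 100))
  expect_true(all(nchar(reads$seq2) == 100))
  # mate geometry: mate 2 reverse-complements the template tail
  i <- 1:50
  expect_equal(revcomp(reads$seq2[i]),
               substring(donor, reads$tstart[i] + reads$tlen[i] - 99,
                         reads$tstart[i] + reads$tlen[i]))
  expect_equal(reads$seq1[i],
               substring(donor, reads$tstart[i] + 1, reads$tstart[i] + 100))
  # template length distribution close to its mean
  se <- stats::sd(reads$tlen) / sqrt(length(reads$tlen))
  expect_lt(abs(mean(reads$tlen) - 400), 3 * se + 0.5)
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- random_genome(40000)
  cfg <- sim_config(n_svs = 2, sv_len_mean = 200, depth = 5, read_len = 50,
                    insert_mean = 150, insert_sd = 10, seed = 77)
  a <- simulate_dataset(ref, cfg)
  b <- simulate_dataset(ref, cfg)
  expect_identical(a$donor, b$donor)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
})

test_that("coverage lands near the configured depth", {
  set.seed(66)
  donor <- random_genome(1e6)
  cfg <- sim_config(depth = 10, read_len = 100, seed = 5)
  reads <- generate_reads(donor, cfg)
  total_bases <- 2 * 100 * length(reads$ids)
  expect_lt(abs(total_bases / 1e6 - 10) / 10, 0.05)
})
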