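# End-to-end simulation study runner shared by the acceptance tests. Results
# are cached per (seed, depth, read_len) so several test blocks can reuse the
# same runs within one session.

.study_cache <- new.env(parent = emptyenv())

run_study <- function(seed, depth = 40, read_len = 108, genome_len = 1e6,
                      n_svs = 20) {
  key <- paste(seed, depth, read_len, genome_len, n_svs, sep = "_")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  set.seed(seed)
  ref <- random_genome(genome_len, "chr1")
  cfg <- sim_config(n_svs = n_svs, sv_len_mean = 1000, sv_len_sd = 100,
                    snv_rate = 1e-4, depth = depth, read_len = read_len,
                    seed = seed + 1000)
  sim <- simulate_dataset(ref, cfg)
  reads <- c(sim$reads$seq1, sim$reads$seq2)
  names(reads) <- c(paste0(sim$reads$ids, ".1"), paste0(sim$reads$ids, ".2"))
  aln <- map_reads(reads, ref)
  calls <- call_svs(aln, ref)
  report <- evaluate_calls(sim$truth, calls)
  out <- list(truth = sim$truth, calls = calls, report = report)
  .study_cache[[key]] <- out
  out
}

# per-type rate averaged over several study runs (NA rates are skipped)
mean_rates <- function(runs, sv_type) {
  d <- vapply(runs, function(r) {
    pt <- r$report$per_type
    v <- pt$discovery_rate[pt$sv_type == sv_type]
    if (length(v) == 0L) NA_real_ else v
  }, numeric(1))
  t <- vapply(runs, function(r) {
    pt <- r$report$per_type
    v <- pt$true_call_rate[pt$sv_type == sv_type]
    if (length(v) == 0L) NA_real_ else v
  }, numeric(1))
  c(discovery = mean(d, na.rm = TRUE), true_call = mean(t, na.rm = TRUE))
}

# a single implanted event at fixed depth, through mapper and caller
run_single_event <- function(sv_type, seed, genome_len = 1e5, sv_len = 500,
                             depth = 30, read_len = 100) {
  set.seed(seed)
  ref <- random_genome(genome_len, "chr1")
  cfg <- sim_config(n_svs = 1, sv_types = sv_type, sv_len_mean = sv_len,
                    sv_len_sd = sv_len / 10, snv_rate = 0, depth = depth,
                    read_len = read_len, dup_copies_mean = 2,
                    dup_copies_sd = 1e-6, seed = seed + 500)
  sim <- simulate_dataset(ref, cfg)
  reads <- c(sim$reads$seq1, sim$reads$seq2)
  names(reads) <- c(paste0(sim$reads$ids, ".1"), paste0(sim$reads$ids, ".2"))
  aln <- map_reads(reads, ref)
  calls <- call_svs(aln, ref)
  list(truth = sim$truth, calls = calls)
}
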