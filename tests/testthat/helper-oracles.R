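# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: positions are computed by walking the
# alignment base by base, clusters by transitive closure over all pairs, and
# overlap rates from explicit integer position sets.

# breakpoint position + side by a base-by-base walk over the CIGAR
bf_breakpoint <- function(start0, cigar) {
  ops <- clipsv::parse_cigar(cigar)
  refpos <- start0
  left_clip <- NULL
  right_clip <- NULL
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op == "S") {
      if (i == 1L) left_clip <- refpos
      if (i == nrow(ops)) right_clip <- refpos
    }
    if (op %in% c("M", "D", "N", "=", "X")) {
      for (b in seq_len(len)) refpos <- refpos + 1L  # the walk, on purpose
    }
  }
  list(left = left_clip, right = right_clip)
}

# transitive closure of the "within tolerance" relation over all pairs
bf_cluster <- function(pos, tol) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= tol
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# overlap fraction via explicit integer position sets
bf_overlap_fraction <- function(a, b) {
  if (a$sv_type != b$sv_type || a$ref != b$ref) return(0)
  if (a$end <= a$start) return(0)
  pa <- seq(a$start, a$end - 1L)
  pb <- if (b$end > b$start) seq(b$start, b$end - 1L) else integer(0)
  length(intersect(pa, pb)) / length(pa)
}

bf_discovery_rate <- function(truth, calls) {
  mean(vapply(seq_len(nrow(truth)), function(i) {
    best <- 0
    for (j in seq_len(nrow(calls))) {
      best <- max(best, bf_overlap_fraction(truth[i, ], calls[j, ]))
    }
    best
  }, numeric(1)))
}

bf_true_call_rate <- function(truth, calls) {
  bf_discovery_rate(calls, truth)
}

# random interval records for the metric tests
random_records <- function(n, types = c("DEL", "INV", "DUP"), L = 1000) {
  s <- sample.int(L, n, replace = TRUE) - 1L
  w <- sample.int(100, n, replace = TRUE)
  data.frame(ref = "c1", start = s, end = s + w,
             sv_type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# random CIGAR strings over the full op alphabet
random_cigar <- function() {
  nops <- sample(1:6, 1)
  ops <- sample(c("M", "I", "D", "S", "N", "=", "X"), nops, replace = TRUE)
  paste0(sample(1:50, nops, replace = TRUE), ops, collapse = "")
}
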