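# Structural-variant and paired-end read simulator. Implants typed SVs and
# single-nucleotide alterations into a reference contig, then samples
# error-free paired-end reads from the resulting donor genome, providing
# ground truth for the evaluator.

#' Simulation configuration
#'
#' Defaults mirror the simulation study this package reproduces: 200 SVs of
#' types drawn uniformly from DEL/INS/INV/DUP, event lengths N(mean, mean/10),
#' a single-nucleotide alteration rate of 1/10000, tandem-duplication copy
#' numbers N(40, 20) truncated above 1, coverage depth 40, 108-base reads and
#' template (insert) lengths N(400, 50).
#'
#' @param n_svs Number of SV events.
#' @param sv_types Types to draw from (subset of `DEL`, `INS`, `INV`, `DUP`).
#' @param sv_len_mean,sv_len_sd Event length distribution (bases);
#'   `sv_len_sd` defaults to `sv_len_mean / 10`.
#' @param snv_rate Per-base substitution probability.
#' @param dup_copies_mean,dup_copies_sd Tandem-duplication copy-number
#'   distribution, rounded and redrawn until `> 1`.
#' @param depth Mean coverage of the donor genome.
#' @param read_len Read length (bases).
#' @param insert_mean,insert_sd Template-length distribution (bases).
#' @param seed Optional RNG seed; fixed seeds make every output reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_svs = 200, sv_types = c("DEL", "INS", "INV", "DUP"),
                       sv_len_mean = 1000, sv_len_sd = sv_len_mean / 10,
                       snv_rate = 1e-4, dup_copies_mean = 40,
                       dup_copies_sd = 20, depth = 40, read_len = 108,
                       insert_mean = 400, insert_sd = 50, seed = NULL) {
  stopifnot(n_svs >= 0, all(sv_types %in% c("DEL", "INS", "INV", "DUP")),
            sv_len_mean > 0, sv_len_sd > 0, snv_rate >= 0, snv_rate <= 1,
            dup_copies_mean > 0, dup_copies_sd > 0, depth > 0, read_len > 0,
            insert_mean > 0, insert_sd > 0, read_len < insert_mean)
  structure(list(
    n_svs = as.integer(n_svs), sv_types = sv_types,
    sv_len_mean = sv_len_mean, sv_len_sd = sv_len_sd, snv_rate = snv_rate,
    dup_copies_mean = dup_copies_mean, dup_copies_sd = dup_copies_sd,
    depth = depth, read_len = as.integer(read_len),
    insert_mean = insert_mean, insert_sd = insert_sd, seed = seed
  ), class = "sim_config")
}

empty_truth <- function() {
  data.frame(ref = character(0), start = integer(0), end = integer(0),
             sv_type = character(0), copies = integer(0),
             ins_seq = character(0), stringsAsFactors = FALSE)
}

#' Implant structural variants into a reference contig
#'
#' Event lengths are drawn from N(mean, sd) and rounded (minimum 1); types
#' uniformly from `config$sv_types`; positions uniformly, rejecting layouts
#' where consecutive events come closer than twice the mean insert length so
#' that truth intervals stay well separated. `DEL` removes the segment,
#' `INV` reverse-complements it, `DUP` repeats it `copies` times (drawn from
#' N(copies_mean, copies_sd), redrawn until `> 1`), and `INS` inserts a
#' uniform-random novel sequence at a point. Truth records are reported in
#' original reference coordinates (0-based half-open; INS has
#' `start == end`).
#'
#' @param reference Single-contig reference (path, `DNAStringSet`, or named
#'   character vector of length 1).
#' @param config A [sim_config()].
#' @return A list with `donor` (named character) and `truth` (data.frame
#'   with `ref`, `start`, `end`, `sv_type`, `copies`, `ins_seq`).
#' @export
implant_svs <- function(reference, config) {
  refs <- as_ref_seqs(reference)
  stopifnot(length(refs) == 1L)
  ref_name <- names(refs)
  g <- refs[[1]]
  L <- nchar(g)
  n <- config$n_svs
  if (n == 0L) {
    return(list(donor = refs, truth = empty_truth()))
  }
  gap <- 2L * as.integer(round(config$insert_mean))
  types <- sample(config$sv_types, n, replace = TRUE)
  lens <- pmax(1L, as.integer(round(stats::rnorm(n, config$sv_len_mean,
                                                 config$sv_len_sd))))
  span <- ifelse(types == "INS", 0L, lens)  # reference bases consumed
  if (sum(span) + (n + 1L) * gap >= L) {
    stop("reference too short to place ", n, " events with ", gap,
         "-base spacing; use a longer reference or fewer events")
  }
  placed <- FALSE
  for (try in seq_len(1000L)) {
    starts <- sort(floor(stats::runif(n, gap, L - gap - max(span))))
    ends <- starts + span
    if (n == 1L || all(starts[-1] - ends[-n] >= gap)) {
      placed <- TRUE
      break
    }
  }
  if (!placed) {
    stop("could not place ", n, " non-overlapping events after 1000 ",
         "attempts; use a longer reference or fewer events")
  }
  copies <- rep(NA_integer_, n)
  ins_seq <- rep(NA_character_, n)
  pieces <- character(2L * n + 1L)
  cur <- 0L  # 0-based position up to which the reference has been consumed
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substring(g, cur + 1L, starts[i])
    seg <- substring(g, starts[i] + 1L, ends[i])
    pieces[2L * i] <- switch(
      types[i],
      DEL = "",
      INV = revcomp(seg),
      DUP = {
        k <- 1L
        while (k <= 1L) {
          k <- as.integer(round(stats::rnorm(1, config$dup_copies_mean,
                                             config$dup_copies_sd)))
        }
        copies[i] <- k
        strrep(seg, k)
      },
      INS = {
        s <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                   collapse = "")
        ins_seq[i] <- s
        s
      }
    )
    cur <- ends[i]
  }
  pieces[2L * n + 1L] <- substring(g, cur + 1L, L)
  donor <- paste(pieces, collapse = "")
  names(donor) <- ref_name
  truth <- data.frame(ref = ref_name, start = as.integer(starts),
                      end = as.integer(ends), sv_type = types,
                      copies = copies, ins_seq = ins_seq,
                      stringsAsFactors = FALSE)
  # report breakpoints normalized (microhomology makes several intervals
  # produce the same donor; see normalize_sv_interval)
  truth <- .normalize_records(truth, refs, copies_col = "copies")
  list(donor = donor, truth = truth)
}

#' Rebuild a donor genome from a reference and truth records
#'
#' Applies the truth events to the reference; with the recorded inserted
#' sequences and copy numbers this reproduces the simulated donor exactly
#' (before single-nucleotide alterations).
#'
#' @param reference Single-contig reference.
#' @param truth Truth data.frame from [implant_svs()].
#' @return Named character vector: the reconstructed donor.
#' @export
apply_truth <- function(reference, truth) {
  refs <- as_ref_seqs(reference)
  stopifnot(length(refs) == 1L)
  g <- refs[[1]]
  truth <- truth[order(truth$start), , drop = FALSE]
  pieces <- character(2L * nrow(truth) + 1L)
  cur <- 0L
  for (i in seq_len(nrow(truth))) {
    pieces[2L * i - 1L] <- substring(g, cur + 1L, truth$start[i])
    seg <- substring(g, truth$start[i] + 1L, truth$end[i])
    pieces[2L * i] <- switch(
      truth$sv_type[i],
      DEL = "",
      INV = revcomp(seg),
      DUP = strrep(seg, truth$copies[i]),
      INS = truth$ins_seq[i]
    )
    cur <- truth$end[i]
  }
  pieces[2L * nrow(truth) + 1L] <- substring(g, cur + 1L, nchar(g))
  donor <- paste(pieces, collapse = "")
  names(donor) <- names(refs)
  donor
}

#' Add single-nucleotide alterations to a genome
#'
#' Each base is independently substituted with probability `rate` by a
#' uniformly chosen different base.
#'
#' @param donor Named character vector of contig sequences.
#' @param rate Per-base substitution probability.
#' @return The altered genome; substituted positions per contig are attached
#'   as attribute `"n_snvs"`.
#' @export
add_snvs <- function(donor, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n_snvs <- integer(length(donor))
  if (rate == 0) {
    attr(donor, "n_snvs") <- n_snvs
    return(donor)
  }
  bases <- c("A", "C", "G", "T")
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (ci in seq_along(donor)) {
    x <- strsplit(donor[[ci]], "", fixed = TRUE)[[1]]
    pos <- which(stats::runif(length(x)) < rate)
    if (length(pos)) {
      pick <- ceiling(stats::runif(length(pos)) * 3)
      x[pos] <- vapply(seq_along(pos), function(k) {
        cur <- x[pos[k]]
        if (cur %in% bases) alt[[cur]][pick[k]] else sample(bases, 1L)
      }, character(1))
      donor[[ci]] <- paste(x, collapse = "")
    }
    n_snvs[ci] <- length(pos)
  }
  attr(donor, "n_snvs") <- n_snvs
  donor
}

#' Generate error-free paired-end reads from a donor genome
#'
#' The number of pairs is `round(depth * donor_length / (2 * read_len))`.
#' Template starts are uniform; template lengths are N(insert_mean,
#' insert_sd), redrawn when shorter than the read length or overrunning the
#' contig. Mate 1 is the first `read_len` bases of the template (forward);
#' mate 2 is the reverse complement of the last `read_len` bases.
#'
#' @param donor Single-contig donor genome (named character vector).
#' @param config A [sim_config()].
#' @return A list with `ids` (pair ids), `seq1`, `seq2` (mate sequences) and
#'   `tstart` (0-based template start on the donor, for debugging only).
#' @export
generate_reads <- function(donor, config) {
  stopifnot(length(donor) == 1L)
  g <- donor[[1]]
  L <- nchar(g)
  rl <- config$read_len
  stopifnot(rl < L)
  n_pairs <- as.integer(round(config$depth * L / (2 * rl)))
  tl <- as.integer(round(stats::rnorm(n_pairs, config$insert_mean,
                                      config$insert_sd)))
  bad <- which(tl < rl | tl > L)
  while (length(bad)) {
    tl[bad] <- as.integer(round(stats::rnorm(length(bad), config$insert_mean,
                                             config$insert_sd)))
    bad <- bad[tl[bad] < rl | tl[bad] > L]
  }
  tstart <- floor(stats::runif(n_pairs) * (L - tl + 1))  # 0-based
  seq1 <- substring(g, tstart + 1L, tstart + rl)
  seq2 <- revcomp(substring(g, tstart + tl - rl + 1L, tstart + tl))
  ids <- sprintf("r%07d", seq_len(n_pairs))
  list(ids = ids, seq1 = seq1, seq2 = seq2, tstart = as.integer(tstart),
       tlen = tl)
}

#' Run the full simulation: implant SVs, add SNVs, generate reads
#'
#' @param reference Single-contig reference.
#' @param config A [sim_config()]; `config$seed`, when set, seeds the RNG so
#'   outputs are reproducible.
#' @return A list with `donor`, `truth`, `reads` (see [generate_reads()])
#'   and `config`.
#' @export
simulate_dataset <- function(reference, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  imp <- implant_svs(reference, config)
  donor <- add_snvs(imp$donor, config$snv_rate)
  reads <- generate_reads(donor, config)
  list(donor = donor, truth = imp$truth, reads = reads, config = config)
}
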