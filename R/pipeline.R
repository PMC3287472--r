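# File-level orchestration of the three subcommands: simulate, call,
# evaluate. Each run writes a JSON manifest recording parameters, seed and
# per-stage counts so results are reproducible and auditable.

#' Simulate a donor genome and paired-end reads, writing standard files
#'
#' Writes `<prefix>_donor.fa`, `<prefix>_1.fastq`, `<prefix>_2.fastq`,
#' `<prefix>_truth.tsv` and `<prefix>_manifest.json`.
#'
#' @param reference Single-contig reference (path, `DNAStringSet`, named
#'   character).
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(reference, config, out_prefix) {
  sim <- simulate_dataset(reference, config)
  write_fasta(sim$donor, paste0(out_prefix, "_donor.fa"))
  r1 <- sim$reads$seq1
  names(r1) <- paste0(sim$reads$ids, ".1")
  r2 <- sim$reads$seq2
  names(r2) <- paste0(sim$reads$ids, ".2")
  write_fastq(r1, paste0(out_prefix, "_1.fastq"))
  write_fastq(r2, paste0(out_prefix, "_2.fastq"))
  utils::write.table(sim$truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    subcommand = "simulate",
    config = unclass(config),
    donor_length = nchar(sim$donor[[1]]),
    n_truth = nrow(sim$truth),
    n_pairs = length(sim$reads$ids),
    n_snvs = as.integer(attr(sim$donor, "n_snvs"))
  )
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(sim)
}

#' Call SVs from a SAM file against a reference
#'
#' Thin file-level wrapper around [call_svs()]: reads the SAM, optionally
#' rehydrates hard clips from the original FASTQ, runs the caller, and
#' writes the calls as TSV (and optionally VCF) plus a JSON manifest.
#'
#' @param sam Path to a SAM file, or an alignment data.frame.
#' @param reference Reference genome (path, `DNAStringSet`, named character).
#' @param out_tsv Output TSV path.
#' @param out_vcf Optional output VCF path.
#' @param fastq Optional FASTQ path(s) with the original reads, used to
#'   convert hard clips to soft clips.
#' @param ... Further arguments passed to [call_svs()].
#' @return Invisibly, the call data.frame (manifest attached as attribute).
#' @export
run_call <- function(sam, reference, out_tsv, out_vcf = NULL, fastq = NULL,
                     ...) {
  aln <- if (is.data.frame(sam)) sam else read_sam(sam)
  refs <- as_ref_seqs(reference)
  known <- unique(aln$rname[aln$mapped])
  bad <- setdiff(known, c(names(refs), "*"))
  if (length(bad)) {
    stop("SAM refers to contigs absent from the reference: ",
         paste(bad, collapse = ", "))
  }
  original_reads <- NULL
  if (!is.null(fastq)) {
    original_reads <- unlist(lapply(fastq, read_fastq))
  }
  calls <- call_svs(aln, refs, original_reads = original_reads, ...)
  write_calls_tsv(calls, out_tsv)
  if (!is.null(out_vcf)) write_calls_vcf(calls, out_vcf, reference = refs)
  manifest <- c(list(subcommand = "call"), attr(calls, "manifest"))
  jsonlite::write_json(manifest, paste0(out_tsv, ".manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(calls)
}

#' Evaluate a callset against truth records
#'
#' @param truth Truth TSV path or data.frame (`ref`, `start`, `end`,
#'   `sv_type`).
#' @param calls Calls TSV path or data.frame.
#' @param flank Point-event widening in bases (default 100).
#' @param per_type Include the per-type breakdown (default TRUE).
#' @param out Optional JSON output path.
#' @return The [evaluate_calls()] report, invisibly when `out` is given.
#' @export
run_evaluate <- function(truth, calls, flank = 100, per_type = TRUE,
                         out = NULL) {
  tr <- if (is.data.frame(truth)) truth else read_calls_tsv(truth)
  ca <- if (is.data.frame(calls)) calls else read_calls_tsv(calls)
  report <- evaluate_calls(tr, ca, flank = flank, per_type = per_type)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, null = "null",
                         digits = NA, dataframe = "rows", na = "null")
    return(invisible(report))
  }
  report
}
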