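# Tabular and VCF output of SV calls. The TSV is the package's native
# format (0-based, half-open; also consumed by the evaluator); the VCF
# writer emits symbolic alleles for interoperability.

#' Write SV calls as TSV
#'
#' Columns: `ref`, `start`, `end` (0-based half-open; INS/TRA are point
#' events with `start == end`), `sv_type`, the four support counts, `score`
#' and the translocation source interval.
#'
#' @param calls Call data.frame from [call_svs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("ref", "start", "end", "sv_type", "B_L", "B_R", "C_L", "C_R",
            "score", "tra_ref", "tra_start", "tra_end")
  present <- intersect(cols, names(calls))
  utils::write.table(calls[, present, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SV calls (or truth records) from TSV
#'
#' @param path TSV path with at least `ref`, `start`, `end`, `sv_type`.
#' @return Call data.frame.
#' @export
read_calls_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write SV calls as VCF 4.2 with symbolic alleles
#'
#' Emits `<DEL>`, `<INV>`, `<DUP:TANDEM>`, `<INS>` and `<TRA>` records with
#' `SVTYPE`, `END`, the four support counts and the reliability score as
#' INFO fields. POS is converted to 1-based.
#'
#' @param calls Call data.frame from [call_svs()].
#' @param path Output path.
#' @param reference Optional reference for `##contig` header lines and REF
#'   bases; when absent, REF is written as `N`.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, reference = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clipsv",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=BL,Number=1,Type=Integer,Description=\"Clipped reads supporting the L-breakpoint\">",
    "##INFO=<ID=BR,Number=1,Type=Integer,Description=\"Clipped reads supporting the R-breakpoint\">",
    "##INFO=<ID=CL,Number=1,Type=Integer,Description=\"Remapped fragments anchored on the L side\">",
    "##INFO=<ID=CR,Number=1,Type=Integer,Description=\"Remapped fragments anchored on the R side\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Reliability score\">",
    "##INFO=<ID=TRASRC,Number=1,Type=String,Description=\"Translocation source interval (0-based half-open)\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=TRA,Description=\"Translocation\">"
  )
  refs <- NULL
  if (!is.null(reference)) {
    refs <- as_ref_seqs(reference)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(refs),
                          nchar(refs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  alt <- c(DEL = "<DEL>", INV = "<INV>", DUP = "<DUP:TANDEM>",
           INS = "<INS>", TRA = "<TRA>")[calls$sv_type]
  pos1 <- calls$start + 1L
  ref_base <- rep("N", nrow(calls))
  if (!is.null(refs)) {
    ok <- calls$ref %in% names(refs) & calls$start >= 0
    ref_base[ok] <- substring(refs[calls$ref[ok]], pos1[ok], pos1[ok])
  }
  info <- sprintf("SVTYPE=%s;END=%d;BL=%d;BR=%d;CL=%d;CR=%d;SCORE=%g",
                  calls$sv_type, calls$end, calls$B_L, calls$B_R,
                  calls$C_L, calls$C_R, calls$score)
  has_tra <- !is.na(calls$tra_ref)
  info[has_tra] <- paste0(info[has_tra],
                          sprintf(";TRASRC=%s:%d-%d", calls$tra_ref[has_tra],
                                  calls$tra_start[has_tra],
                                  calls$tra_end[has_tra]))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  calls$ref, pos1,
                  sprintf("sv%04d", seq_len(nrow(calls))),
                  ref_base, alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
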