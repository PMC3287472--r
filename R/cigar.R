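# CIGAR grammar: run-length encoded operations over M I D N S H P = X.
# Query-consuming ops: M I S = X.  Reference-consuming ops: M D N = X.

.cigar_query_ops <- c("M", "I", "S", "=", "X")
.cigar_ref_ops   <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' Splits a SAM CIGAR string into its ordered run-length operations. The
#' placeholder `"*"` yields a zero-row table.
#'
#' @param cigar A single CIGAR string, e.g. `"31S69M"`.
#' @return A data.frame with columns `op` (operation letter) and `len`
#'   (positive integer length), one row per operation in string order.
#' @examples
#' parse_cigar("31S69M")
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "*") {
    return(data.frame(op = character(0), len = integer(0),
                      stringsAsFactors = FALSE))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]?|[^0-9]+", cigar))[[1]]
  bad <- !grepl("^[0-9]+[MIDNSHP=X]$", toks)
  if (any(bad)) {
    stop("malformed CIGAR token '", toks[bad][1], "' in '", cigar, "'")
  }
  len <- as.integer(sub(".$", "", toks))
  if (any(len == 0L)) {
    stop("zero-length CIGAR operation '", toks[len == 0L][1],
         "' in '", cigar, "'")
  }
  data.frame(op = substr(toks, nchar(toks), nchar(toks)), len = len,
             stringsAsFactors = FALSE)
}

#' Serialise CIGAR operations back to a string
#'
#' @param ops A data.frame as returned by [parse_cigar()].
#' @return A CIGAR string (`"*"` for zero rows).
#' @export
cigar_to_string <- function(ops) {
  if (nrow(ops) == 0L) return("*")
  paste0(ops$len, ops$op, collapse = "")
}

#' Number of read bases consumed by a CIGAR
#'
#' @param ops A data.frame as returned by [parse_cigar()].
#' @return Integer count of query-consuming bases (M, I, S, =, X).
#' @export
cigar_query_length <- function(ops) {
  sum(ops$len[ops$op %in% .cigar_query_ops])
}

#' Number of reference bases consumed by a CIGAR
#'
#' @param ops A data.frame as returned by [parse_cigar()].
#' @return Integer count of reference-consuming bases (M, D, N, =, X).
#' @export
cigar_ref_length <- function(ops) {
  sum(ops$len[ops$op %in% .cigar_ref_ops])
}

# Vectorised bulk tokenizer. Returns a long data.frame (rec, op, len) where
# rec indexes the input vector; records whose tokens do not tile the string
# exactly are reported via the "malformed" attribute (logical per record).
# Used on hot paths where per-record parse_cigar() would be too slow.
cigar_runs <- function(cigars) {
  n <- length(cigars)
  if (n == 0L) {
    out <- data.frame(rec = integer(0), op = character(0), len = integer(0))
    attr(out, "malformed") <- logical(0)
    return(out)
  }
  nc <- nchar(cigars)
  big <- paste(cigars, collapse = "")
  m <- gregexpr("[0-9]+[MIDNSHP=X]", big)[[1]]
  if (m[1] == -1L) {
    out <- data.frame(rec = integer(0), op = character(0), len = integer(0))
    attr(out, "malformed") <- nc > 0L
    return(out)
  }
  tok <- regmatches(big, list(m))[[1]]
  starts <- as.integer(m)
  widths <- attr(m, "match.length")
  rec_end <- cumsum(nc)
  rec_start <- c(1L, rec_end[-n] + 1L)
  rec <- findInterval(starts, rec_start)
  # a token straddling two records would imply the first is malformed; such a
  # token can't be produced because record boundaries cut the digit run anyway
  covered <- rowsum(widths, rec, reorder = FALSE)
  cov <- integer(n)
  cov[as.integer(rownames(covered))] <- covered[, 1]
  malformed <- cov != nc & cigars != "*"
  out <- data.frame(
    rec = rec,
    op = substring(tok, widths, widths),
    len = as.integer(substring(tok, 1L, widths - 1L)),
    stringsAsFactors = FALSE
  )
  attr(out, "malformed") <- malformed
  out
}
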