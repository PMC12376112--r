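# CIGAR plumbing shared by the PAF reader, the simulator's exact-alignment
# emitter, and CIGAR-based variant extraction.

.CIG_Q <- c("M", "I", "=", "X")  # query-consuming ops
.CIG_T <- c("M", "D", "=", "X")  # target-consuming ops

#' Parse a CIGAR string
#'
#' @param cigar A single CIGAR string (e.g. `"100=1X10D"`).
#' @return A list with integer `len` and character `op` vectors, in order.
#' @export
parseCigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(list(len = integer(), op = character()))
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]]
  ops <- regmatches(cigar, gregexpr("[A-Za-z=]", cigar))[[1L]]
  if (length(lens) != length(ops) ||
      !identical(paste0(lens, ops, collapse = ""), cigar))
    stop("malformed CIGAR string: ", substr(cigar, 1, 50))
  list(len = as.integer(lens), op = ops)
}

#' Assemble a CIGAR string, merging adjacent identical ops
#'
#' @param len,op Parallel run-length and operation vectors.
#' @return A CIGAR string; zero-length runs are dropped.
#' @export
buildCigar <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (!length(op)) return("")
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  len <- vapply(split(len, grp), sum, numeric(1L))
  op <- op[!duplicated(grp)]
  paste0(format(len, scientific = FALSE, trim = TRUE), op, collapse = "")
}

#' Query- and target-consumed lengths of a CIGAR
#'
#' @param cig Parsed CIGAR (list from [parseCigar()]).
#' @return Named numeric vector with elements `query` and `target`.
#' @export
cigarSpans <- function(cig) {
  c(query = sum(cig$len[cig$op %in% .CIG_Q]),
    target = sum(cig$len[cig$op %in% .CIG_T]))
}
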