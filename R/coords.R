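# Coordinate conventions.
#
# External formats (VCF, GFF3) are 1-based, inclusive. All internal interval
# arithmetic (region lookup, codon mapping) is done on 0-based half-open
# intervals, which keeps length = end - start and removes +/-1 adjustments
# from codon arithmetic. The two converters below are inverses.

#' Convert a 1-based inclusive interval to 0-based half-open
#'
#' @param start,end Integer vectors, 1-based inclusive coordinates
#'   (`start <= end`).
#' @return A list with elements `start` and `end`, 0-based half-open.
#' @keywords internal
to_halfopen <- function(start, end) {
  stopifnot(all(start >= 1L), all(end >= start))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert a 0-based half-open interval to 1-based inclusive
#'
#' @param start,end Integer vectors, 0-based half-open (`start < end`).
#' @return A list with elements `start` and `end`, 1-based inclusive.
#' @keywords internal
from_halfopen <- function(start, end) {
  stopifnot(all(start >= 0L), all(end > start))
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

# TRUE where 1-based position `pos` falls in the 0-based half-open interval.
pos_in_halfopen <- function(pos, start0, end0) {
  p0 <- pos - 1L
  p0 >= start0 & p0 < end0
}
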