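#' @importFrom stats runif median quantile setNames
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Random i.i.d. nucleotide sequence with a specified GC fraction
#'
#' @param n sequence length in bp.
#' @param gc target GC fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @export
random_seq <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Point-mutate a sequence at a given per-base substitution rate
#'
#' Each base is replaced, independently with probability `rate`, by one of the
#' three other bases chosen uniformly. Non-ACGT characters are left untouched.
#'
#' @param seq character scalar.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return Mutated character scalar of identical length.
#' @export
mutate_seq <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nchar(seq) == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(s %in% DNA_BASES & runif(length(s)) < rate)
  if (length(idx)) {
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(s, collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar (IUPAC codes allowed).
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a sequence, ignoring non-ACGT characters
#' @param seq character scalar.
#' @return fraction in `[0, 1]`, `NaN` for sequences with no ACGT bases.
#' @export
gc_fraction <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  acgt <- s %in% DNA_BASES
  if (!any(acgt)) return(NaN)
  sum(s %in% c("G", "C")) / sum(acgt)
}

# 0-based half-open data.frame intervals -> IRanges
iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, width = end - start)

# IRanges -> 0-based half-open start/end data.frame
as_df0 <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Total bp of the union of 0-based half-open intervals
#' @param start,end integer vectors of interval bounds.
#' @return integer bp count.
#' @export
union_bp <- function(start, end) {
  if (length(start) == 0) return(0L)
  sum(BiocGenerics::width(IRanges::reduce(iranges0(start, end))))
}

#' Intersection bp of two 0-based half-open interval sets
#' @param a_start,a_end,b_start,b_end integer vectors of interval bounds.
#' @return integer bp count.
#' @export
intersect_bp <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0 || length(b_start) == 0) return(0L)
  a <- IRanges::reduce(iranges0(a_start, a_end))
  b <- IRanges::reduce(iranges0(b_start, b_end))
  sum(BiocGenerics::width(BiocGenerics::intersect(a, b)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
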