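# Structural element detection: terminal inverted repeats (TIRs) for MITE
# classification, and terminal telomere-repeat arrays. TIR search aligns a
# sequence against its own reverse complement (einverted-style scoring:
# match +3, mismatch -4, gap -12) and iterates with masking to enumerate
# non-redundant inverted-repeat pairs.

tir_substitution_matrix <- function(match = 3, mismatch = -4) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", "N"] <- mismatch  # masked positions can never contribute
  m
}

#' Find inverted repeats in a sequence
#'
#' Searches for pairs of subsequences where the upstream arm aligns to the
#' reverse complement of a downstream arm. Uses iterated best local alignment
#' of the sequence against its reverse complement with masking, so the
#' reported hits are maximal and non-redundant. Perfect palindromes are
#' reported as a single hit with loop length 0 (or 1 for odd spans).
#'
#' @param seq nucleotide character scalar.
#' @param min_arm minimum arm length bp.
#' @param max_loop maximum loop (spacer) length bp between the arms.
#' @param min_identity minimum arm identity fraction.
#' @param min_score minimum einverted-style alignment raw score to pursue.
#' @param max_hits cap on reported hits.
#' @return data.frame of TIR hits: `left_start`, `left_end`, `right_start`,
#'   `right_end` (0-based half-open), `arm_length`, `loop`, `identity`,
#'   `score`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 10, max_loop = 5000,
                                  min_identity = 0.8, min_score = 50,
                                  max_hits = 25) {
  stopifnot(min_arm >= 2, min_identity >= 0, min_identity <= 1)
  L <- nchar(seq)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), loop = integer(),
                      identity = numeric(), score = numeric())
  if (L < 2 * min_arm) return(empty)
  mat <- tir_substitution_matrix()
  s <- Biostrings::DNAString(toupper(seq))
  r <- Biostrings::reverseComplement(s)
  s_chr <- strsplit(as.character(s), "")[[1]]
  hits <- empty
  for (it in seq_len(max_hits)) {
    sm <- Biostrings::DNAString(paste(s_chr, collapse = ""))
    rm_ <- Biostrings::reverseComplement(sm)
    # N positions in the mask must stay N (reverseComplement keeps N)
    aln <- Biostrings::pairwiseAlignment(sm, rm_, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 12, gapExtension = 4)
    sc <- Biostrings::score(aln)
    if (sc < min_score) break
    p1 <- BiocGenerics::start(Biostrings::pattern(aln))
    p2 <- BiocGenerics::end(Biostrings::pattern(aln))
    s1 <- BiocGenerics::start(Biostrings::subject(aln))
    s2 <- BiocGenerics::end(Biostrings::subject(aln))
    # subject coords are on the reverse complement; map back to the sequence
    m1 <- L - s2 + 1L
    m2 <- L - s1 + 1L
    lo <- min(p1, m1); hi <- max(p2, m2)
    ident <- Biostrings::nmatch(aln) /
      max(Biostrings::nchar(aln), 1L)
    span <- hi - lo + 1L
    arm <- min(p2 - p1 + 1L, m2 - m1 + 1L)
    overlap <- m1 <= p2
    if (overlap) {
      # palindromic: split the span into two mirrored arms
      arm <- span %/% 2L
      left <- c(lo, lo + arm - 1L)
      right <- c(hi - arm + 1L, hi)
    } else {
      left <- c(p1, p2)
      right <- c(m1, m2)
    }
    loop <- right[1] - left[2] - 1L
    ok <- arm >= min_arm && ident >= min_identity && loop <= max_loop &&
      loop >= 0
    if (ok) {
      hits <- rbind(hits,
                    data.frame(left_start = left[1] - 1L, left_end = left[2],
                               right_start = right[1] - 1L,
                               right_end = right[2],
                               arm_length = as.integer(arm),
                               loop = as.integer(loop),
                               identity = ident, score = sc))
    }
    # mask both arms and continue
    s_chr[seq(left[1], left[2])] <- "N"
    s_chr[seq(right[1], right[2])] <- "N"
  }
  hits <- hits[order(hits$left_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify repeat families as MITEs by terminal-inverted-repeat structure
#'
#' A family is MITE-classified when its exemplar length lies within
#' `length_bounds`, the exemplar carries a qualifying TIR hit whose arms lie
#' within `terminal_slack` bp of the exemplar ends, and the family has at
#' least `min_copies` genomic copies. All copies of MITE-classified families
#' are emitted as calls.
#'
#' @param library a `repeat_library` from [cluster_into_families()].
#' @param copies repeat copies data.frame from [mask_repeats()] (used to
#'   emit per-copy calls); when `NULL` the library's candidate members are
#'   used.
#' @param length_bounds `c(min, max)` element length bp (default 80-800).
#' @param min_arm,max_loop,min_identity TIR thresholds
#'   (see [find_inverted_repeats()]).
#' @param terminal_slack max distance (bp) of a TIR arm from the exemplar end.
#' @param min_copies minimum copy number of a MITE family.
#' @return list with `families` (data.frame of per-family verdicts) and
#'   `calls` (data.frame of MITE copies: `contig`, `start`, `end`, `family`,
#'   `length`).
#' @export
call_mites <- function(library, copies = NULL, length_bounds = c(80, 800),
                       min_arm = 10, max_loop = 800, min_identity = 0.8,
                       terminal_slack = 30, min_copies = 2) {
  stopifnot(inherits(library, "repeat_library"))
  fams <- library$families
  verdicts <- data.frame(family = character(), exemplar_length = integer(),
                         in_bounds = logical(), has_tir = logical(),
                         n_copies = integer(), is_mite = logical())
  calls <- data.frame(contig = character(), start = integer(),
                      end = integer(), family = character(),
                      length = integer())
  for (f in fams) {
    len <- nchar(f$exemplar)
    in_bounds <- len >= length_bounds[1] && len <= length_bounds[2]
    fam_copies <- if (!is.null(copies)) {
      copies[copies$family == f$id, , drop = FALSE]
    } else f$copies
    n_cp <- nrow(fam_copies)
    has_tir <- FALSE
    if (in_bounds) {
      tir <- find_inverted_repeats(f$exemplar, min_arm = min_arm,
                                   max_loop = min(max_loop, len),
                                   min_identity = min_identity)
      if (nrow(tir)) {
        terminal <- tir$left_start <= terminal_slack &
          tir$right_end >= len - terminal_slack
        has_tir <- any(terminal)
      }
    }
    is_mite <- in_bounds && has_tir && n_cp >= min_copies
    verdicts <- rbind(verdicts,
                      data.frame(family = f$id, exemplar_length = len,
                                 in_bounds = in_bounds, has_tir = has_tir,
                                 n_copies = n_cp, is_mite = is_mite))
    if (is_mite && n_cp) {
      calls <- rbind(calls,
                     data.frame(contig = fam_copies$contig,
                                start = fam_copies$start,
                                end = fam_copies$end, family = f$id,
                                length = fam_copies$end - fam_copies$start))
    }
  }
  rownames(verdicts) <- NULL
  rownames(calls) <- NULL
  list(families = verdicts, calls = calls)
}

count_tandem <- function(s_chr, positions_start, motif_chr, mismatch_per3 = 1) {
  # count tandem motif copies at successive positions walking away from the
  # terminus; cumulative mismatch budget is mismatch_per3 per 3 complete
  # copies, and the innermost (interior-most) copies must be perfect so that
  # the array does not creep into flanking sequence
  m <- length(motif_chr)
  k <- 0L; cum_mm <- 0L
  mm_trace <- integer()
  repeat {
    st <- positions_start(k)
    if (is.na(st)) break
    seg <- s_chr[st:(st + m - 1L)]
    mm <- sum(seg != motif_chr)
    if (cum_mm + mm > mismatch_per3 * ((k + 1L) %/% 3L)) break
    cum_mm <- cum_mm + mm
    mm_trace <- c(mm_trace, mm)
    k <- k + 1L
  }
  while (k > 0L && mm_trace[k] > 0L) k <- k - 1L
  k
}

#' Detect terminal telomere repeat arrays
#'
#' Scans both ends of every contig for tandem arrays of the telomere motif:
#' the motif itself at the right (3') end and its reverse complement at the
#' left (5') end. An array must start within `max_offset` bp of the contig
#' terminus and contain at least `min_copies` tandem copies; the reported
#' copy count is maximal. Imperfect arrays are tolerated up to
#' `mismatch_per3` mismatches per three complete motif copies.
#'
#' @param genome genome sequences.
#' @param motif telomere repeat unit (default `TTAGGG`).
#' @param min_copies minimum tandem copy count.
#' @param max_offset maximum distance of the array from the contig terminus.
#' @param mismatch_per3 mismatch tolerance per 3 motif copies.
#' @return data.frame of hits: `contig`, `end` (`"left"`/`"right"`), `motif`,
#'   `copies`, `start`, `end_pos` (array interval, 0-based half-open),
#'   `offset` (bp from terminus).
#' @export
detect_telomeres <- function(genome, motif = "TTAGGG", min_copies = 4,
                             max_offset = 200, mismatch_per3 = 1) {
  stopifnot(nchar(motif) >= 4)
  g <- as_dss(genome)
  motif <- toupper(motif)
  m_chr <- strsplit(motif, "")[[1]]
  rc_chr <- strsplit(revcomp(motif), "")[[1]]
  m <- length(m_chr)
  out <- data.frame(contig = character(), end = character(),
                    motif = character(), copies = integer(),
                    start = integer(), end_pos = integer(),
                    offset = integer())
  for (ctg in names(g)) {
    s_chr <- strsplit(as.character(g[[ctg]]), "")[[1]]
    L <- length(s_chr)
    # right end: array of `motif` ending near position L
    best <- c(copies = 0L, offset = NA_integer_)
    for (o in 0:min(max_offset, L - m)) {
      pos <- function(k) {
        st <- L - o - (k + 1L) * m + 1L
        if (st < 1L) NA_integer_ else st
      }
      k <- count_tandem(s_chr, pos, m_chr, mismatch_per3)
      if (k > best["copies"]) best <- c(copies = k, offset = o)
    }
    if (best[["copies"]] >= min_copies) {
      k <- best[["copies"]]; o <- best[["offset"]]
      out <- rbind(out, data.frame(
        contig = ctg, end = "right", motif = motif, copies = k,
        start = L - o - k * m, end_pos = L - o, offset = o))
    }
    # left end: array of revcomp(motif) starting near position 1
    best <- c(copies = 0L, offset = NA_integer_)
    for (o in 0:min(max_offset, L - m)) {
      pos <- function(k) {
        st <- o + k * m + 1L
        if (st + m - 1L > L) NA_integer_ else st
      }
      k <- count_tandem(s_chr, pos, rc_chr, mismatch_per3)
      if (k > best["copies"]) best <- c(copies = k, offset = o)
    }
    if (best[["copies"]] >= min_copies) {
      k <- best[["copies"]]; o <- best[["offset"]]
      out <- rbind(out, data.frame(
        contig = ctg, end = "left", motif = motif, copies = k,
        start = o, end_pos = o + k * m, offset = o))
    }
  }
  rownames(out) <- NULL
  out
}

#' Distance from a feature to the nearest telomere array on its contig
#'
#' @param contig,start,end the feature's contig and 0-based half-open
#'   interval.
#' @param telomeres hits from [detect_telomeres()].
#' @param genome optional genome (for bounds validation).
#' @return bp gap to the nearest same-contig array boundary (0 when abutting
#'   or overlapping), or `NA` if the contig carries no array.
#' @export
distance_to_telomere <- function(contig, start, end, telomeres,
                                 genome = NULL) {
  if (!is.null(genome)) {
    g <- as_dss(genome)
    if (!contig %in% names(g) || start < 0 ||
        end > BiocGenerics::width(g)[match(contig, names(g))]) {
      stop("feature interval outside contig bounds: ", contig, ":", start,
           "-", end, call. = FALSE)
    }
  }
  th <- telomeres[telomeres$contig == contig, , drop = FALSE]
  if (nrow(th) == 0) return(NA_integer_)
  gaps <- pmax(0L, pmax(th$start - end, start - th$end_pos))
  min(gaps)
}
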