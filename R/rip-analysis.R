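# RIP-index profiling. Repeat-induced point mutation (RIP) converts CpA
# dinucleotides to TpA; a genomic region's RIP history is therefore visible
# in its dinucleotide composition. The index is computed in sliding windows
# (200 bp window, 20 bp step by default; partial windows at the contig end
# are not counted). The printed convention is ApT/TpA (low values = RIPped);
# the Margolin-style orientation TpA/ApT (high values = RIPped) is available
# behind a flag and is used internally for classification. Both dinucleotides
# are palindromic, so every window's index is strand-symmetric.

#' RIP-index sliding-window parameters
#'
#' @param window window size in bp (default 200).
#' @param step step size in bp (default 20).
#' @param orientation `"apT_over_tpA"` (the printed form; low = RIPped) or
#'   `"tpA_over_apT"` (high = RIPped).
#' @return list of class `rip_params`.
#' @export
rip_params <- function(window = 200, step = 20,
                       orientation = c("apT_over_tpA", "tpA_over_apT")) {
  orientation <- match.arg(orientation)
  stopifnot(window > 0, step > 0, step <= window)
  structure(list(window = as.integer(window), step = as.integer(step),
                 orientation = orientation), class = "rip_params")
}

# overlapping dinucleotide indicator vector: positions i where s[i]==a and
# s[i+1]==b (dinucleotides containing non-ACGT characters never match and are
# thereby skipped rather than imputed)
dinuc_indicator <- function(s, a, b) {
  n <- length(s)
  if (n < 2) return(logical(0))
  s[-n] == a & s[-1] == b
}

# window start offsets (0-based) for a sequence of length L
window_starts <- function(L, window, step) {
  if (L < window) return(integer(0))
  seq.int(0L, L - window, by = step)
}

#' Sliding-window RIP-index track of a sequence
#'
#' Counts overlapping ApT and TpA dinucleotides (case-insensitively; a
#' dinucleotide must lie entirely inside the window) in each full window and
#' reports the index in the requested orientation. Windows whose denominator
#' count is zero carry `NA` with `undefined = TRUE`. A sequence shorter than
#' one window yields an empty track. The number of windows is exactly
#' `floor((L - window) / step) + 1` for `L >= window`.
#'
#' @param seq nucleotide character scalar.
#' @param params a [rip_params()].
#' @param contig contig name recorded in the track.
#' @return data.frame of class `rip_track`: `contig`, `start`, `end` (0-based
#'   half-open), `apt`, `tpa`, `index`, `undefined`.
#' @export
rip_index_track <- function(seq, params = rip_params(), contig = "seq") {
  stopifnot(inherits(params, "rip_params"))
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(s)
  starts <- window_starts(L, params$window, params$step)
  if (length(starts) == 0) {
    tr <- data.frame(contig = character(), start = integer(), end = integer(),
                     apt = integer(), tpa = integer(), index = numeric(),
                     undefined = logical())
    attr(tr, "params") <- params
    class(tr) <- c("rip_track", "data.frame")
    return(tr)
  }
  # cumulative dinucleotide-start counts; window [w, w+window) contains
  # dinucleotide starts w .. w+window-2 (both bases inside the window)
  apt_cum <- c(0L, cumsum(dinuc_indicator(s, "A", "T")))
  tpa_cum <- c(0L, cumsum(dinuc_indicator(s, "T", "A")))
  lo <- starts + 1L                    # 1-based index into cum at position w
  hi <- starts + params$window         # position w+window-1 -> cum index
  apt <- apt_cum[pmin(hi, L)] - apt_cum[lo]
  tpa <- tpa_cum[pmin(hi, L)] - tpa_cum[lo]
  num <- if (params$orientation == "apT_over_tpA") apt else tpa
  den <- if (params$orientation == "apT_over_tpA") tpa else apt
  idx <- ifelse(den == 0, NA_real_, num / den)
  tr <- data.frame(contig = contig, start = starts,
                   end = starts + params$window, apt = apt, tpa = tpa,
                   index = idx, undefined = den == 0)
  attr(tr, "params") <- params
  class(tr) <- c("rip_track", "data.frame")
  tr
}

#' Sliding-window AT/GC composition track
#'
#' Per full window, the fractions of A/T bases, G/C bases and other (N or
#' ambiguity) characters; the three fractions sum to 1 exactly.
#'
#' @param seq nucleotide character scalar.
#' @param window window size bp.
#' @param step step size bp.
#' @param contig contig name recorded in the track.
#' @return data.frame: `contig`, `start`, `end`, `at`, `gc`, `other`.
#' @export
composition_track <- function(seq, window = 200, step = 20, contig = "seq") {
  stopifnot(window > 0, step > 0, step <= window)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(s)
  starts <- window_starts(L, window, step)
  if (length(starts) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), at = numeric(), gc = numeric(),
                      other = numeric()))
  }
  at_cum <- c(0, cumsum(s %in% c("A", "T")))
  gc_cum <- c(0, cumsum(s %in% c("G", "C")))
  lo <- starts + 1L
  hi <- starts + window
  at <- (at_cum[hi + 1L] - at_cum[lo]) / window
  gc <- (gc_cum[hi + 1L] - gc_cum[lo]) / window
  data.frame(contig = contig, start = starts, end = starts + window,
             at = at, gc = gc, other = 1 - at - gc)
}

#' Genome-wide background distribution of the RIP index
#'
#' Collects full windows lying entirely in non-repeat intergenic sequence and
#' returns their TpA/ApT index values and GC fractions; used as the null
#' distribution by [classify_ripped()].
#'
#' @param genome genome sequences.
#' @param genes gene models (may be empty).
#' @param masked repeat copies (may be empty).
#' @param params a [rip_params()] (orientation ignored; TpA/ApT used).
#' @return list with `index` (numeric vector), `gc` (numeric vector), and
#'   `median_gc`.
#' @export
rip_background <- function(genome, genes, masked, params = rip_params()) {
  g <- as_dss(genome)
  idx_vals <- numeric(); gc_vals <- numeric()
  p <- rip_params(params$window, params$step, "tpA_over_apT")
  for (ctg in names(g)) {
    s <- as.character(g[[ctg]])
    excl_start <- integer(); excl_end <- integer()
    gn <- genes[genes$contig == ctg, , drop = FALSE]
    if (nrow(gn)) { excl_start <- c(excl_start, gn$start)
                    excl_end <- c(excl_end, gn$end) }
    mk <- masked[masked$contig == ctg, , drop = FALSE]
    if (nrow(mk)) { excl_start <- c(excl_start, mk$start)
                    excl_end <- c(excl_end, mk$end) }
    tr <- rip_index_track(s, p, contig = ctg)
    cmp <- composition_track(s, p$window, p$step, contig = ctg)
    if (nrow(tr) == 0) next
    if (length(excl_start)) {
      excl <- IRanges::reduce(iranges0(excl_start, excl_end))
      win <- iranges0(tr$start, tr$end)
      ov <- IRanges::countOverlaps(win, excl)
      keep <- ov == 0
    } else keep <- rep(TRUE, nrow(tr))
    idx_vals <- c(idx_vals, tr$index[keep & !tr$undefined])
    gc_vals <- c(gc_vals, cmp$gc[keep])
  }
  list(index = idx_vals, gc = gc_vals,
       median_gc = median(gc_vals), params = p)
}

#' Classify repeat copies as RIP-affected
#'
#' A copy is flagged RIPped when (a) the median TpA/ApT index over its full
#' windows exceeds the `q` quantile of the background index distribution,
#' evaluated at the copy's scale (medians of consecutive background-window
#' blocks of the same window count, so a copy median is compared against the
#' null distribution of medians rather than of single noisy windows), and
#' (b) its GC fraction is below the background median GC. Copies shorter
#' than one window are reported `indeterminate`.
#'
#' @param copies repeat copies data.frame (`contig`, `start`, `end`).
#' @param genome genome sequences.
#' @param background from [rip_background()].
#' @param params a [rip_params()].
#' @param q background index quantile a RIPped copy must exceed.
#' @return `copies` with added columns `median_index`, `gc`, `index_high`,
#'   `gc_low`, `verdict` (`"ripped"`, `"not_ripped"`, `"indeterminate"`).
#' @export
classify_ripped <- function(copies, genome, background,
                            params = rip_params(), q = 0.95) {
  g <- as_dss(genome)
  p <- rip_params(params$window, params$step, "tpA_over_apT")
  bg_idx <- background$index[!is.na(background$index)]
  # null distribution of block medians at a given block size (cached)
  cutoff_cache <- new.env()
  cutoff_at <- function(w) {
    w <- max(1L, min(w, max(1L, length(bg_idx) %/% 20L)))
    key <- as.character(w)
    if (!is.null(cutoff_cache[[key]])) return(cutoff_cache[[key]])
    n_blocks <- length(bg_idx) %/% w
    meds <- vapply(seq_len(n_blocks), function(b)
      median(bg_idx[((b - 1L) * w + 1L):(b * w)]), 0)
    val <- quantile(meds, q, na.rm = TRUE, names = FALSE)
    cutoff_cache[[key]] <- val
    val
  }
  med_gc <- background$median_gc
  n <- nrow(copies)
  median_index <- numeric(n); gc <- numeric(n)
  index_high <- logical(n); gc_low <- logical(n)
  verdict <- character(n)
  for (k in seq_len(n)) {
    s <- as.character(Biostrings::subseq(g[[copies$contig[k]]],
                                         copies$start[k] + 1L,
                                         copies$end[k]))
    if (nchar(s) < p$window) {
      median_index[k] <- NA; gc[k] <- gc_fraction(s)
      index_high[k] <- NA; gc_low[k] <- NA
      verdict[k] <- "indeterminate"
      next
    }
    tr <- rip_index_track(s, p)
    median_index[k] <- median(tr$index, na.rm = TRUE)
    gc[k] <- gc_fraction(s)
    index_high[k] <- isTRUE(median_index[k] > cutoff_at(nrow(tr)))
    gc_low[k] <- gc[k] < med_gc
    verdict[k] <- if (index_high[k] && gc_low[k]) "ripped" else "not_ripped"
  }
  out <- copies
  out$median_index <- median_index
  out$gc <- gc
  out$index_high <- index_high
  out$gc_low <- gc_low
  out$verdict <- verdict
  out
}

#' Export a windowed track as bedGraph
#'
#' @param track a track data.frame with `contig`, `start`, `end` and a value
#'   column (0-based half-open, as bedGraph requires).
#' @param path output path.
#' @param value name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "index") {
  df <- track[!is.na(track[[value]]),
              c("contig", "start", "end", value)]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
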