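# De novo repeat-family discovery, cross-genome correspondence, masking and
# genome partition statistics. The approach mirrors classical self-BLASTN
# repeat-library construction: find all non-trivial local self-alignments,
# merge their footprints into multicopy candidate segments, single-linkage
# cluster the candidates into non-redundant families, then re-align the family
# exemplars to the genome to annotate (mask) all copies.

#' Local self-alignment of a genome
#'
#' Runs an all-against-all local alignment of the genome's contigs against
#' themselves (BLAST+; match +1 / mismatch -2 / gap open -5 / gap extend -2,
#' recorded in the `scoring` attribute) and drops the trivial full-length
#' self-identity hit of each contig. Coordinates in the returned hit table are
#' 1-based inclusive (outfmt-6 dialect), with `sstart > send` on minus-strand
#' hits. Rows are sorted deterministically so the result is invariant to the
#' input contig order.
#'
#' @param genome a [Biostrings::DNAStringSet], named character vector or
#'   FASTA path.
#' @param min_score minimum raw alignment score to report.
#' @return data.frame of alignment hits.
#' @export
self_align <- function(genome, min_score = 100) {
  g <- as_dss(genome)
  if (length(g) == 0) {
    return(run_blastn(Biostrings::DNAStringSet("ACGT"),
                      Biostrings::DNAStringSet("TTTT"))[0, ])
  }
  hits <- run_blastn(g, g, min_score = min_score)
  trivial <- hits$qseqid == hits$sseqid & hits$qstart == hits$sstart &
    hits$qend == hits$send
  hits <- hits[!trivial, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# hit footprints (query and subject sides) as a 0-based half-open data.frame
hit_footprints <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  }
  q <- data.frame(contig = hits$qseqid, start = hits$qstart - 1L,
                  end = hits$qend)
  s <- data.frame(contig = hits$sseqid,
                  start = pmin(hits$sstart, hits$send) - 1L,
                  end = pmax(hits$sstart, hits$send))
  rbind(q, s)
}

#' Merge self-alignment footprints into multicopy candidate segments
#'
#' Per contig, the union of all hit footprints (query and subject sides,
#' merging footprints separated by less than `merge_gap`) defines candidate
#' repeat segments; a segment is kept when it is at least `min_len` long and
#' supported by at least `min_copies - 1` hit footprints.
#'
#' @param hits hit table from [self_align()].
#' @param min_len minimum segment length in bp.
#' @param min_copies minimum genomic copy number implied (>= 2).
#' @param merge_gap merge footprints separated by less than this many bp.
#' @return data.frame of candidate intervals (`contig`, `start`, `end`,
#'   0-based half-open, plus `support`).
#' @export
call_multicopy_segments <- function(hits, min_len = 400, min_copies = 2,
                                    merge_gap = 50) {
  stopifnot(min_copies >= 2)
  fp <- hit_footprints(hits)
  if (nrow(fp) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  out <- lapply(split(fp, fp$contig), function(d) {
    ir <- iranges0(d$start, d$end)
    merged <- IRanges::reduce(ir, min.gapwidth = merge_gap)
    sup <- IRanges::countOverlaps(merged, ir)
    keep <- BiocGenerics::width(merged) >= min_len & sup >= min_copies - 1L
    cbind(data.frame(contig = rep(d$contig[1], sum(keep))),
          as_df0(merged[keep]), support = sup[keep])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Cluster multicopy candidate segments into non-redundant repeat families
#'
#' Builds a graph over candidate segments with an edge whenever an alignment
#' hit links them: a hit's query footprint must overlap one candidate and its
#' subject footprint the other, each by at least `overlap_frac` of the
#' footprint length. Families are the connected components (single linkage).
#' The exemplar of each family is the sequence of its longest member; family
#' ids are assigned deterministically by exemplar position.
#'
#' @param candidates from [call_multicopy_segments()].
#' @param hits from [self_align()].
#' @param genome the genome the hits were computed from.
#' @param overlap_frac minimum footprint overlap fraction for an edge.
#' @return An object of class `repeat_library`: list with `families` (list of
#'   `id`, `exemplar`, `copies` data.frame) and a `copies` convenience
#'   data.frame.
#' @export
cluster_into_families <- function(candidates, hits, genome,
                                  overlap_frac = 0.5) {
  g <- as_dss(genome)
  n <- nrow(candidates)
  if (n == 0) return(structure(list(families = list()),
                               class = "repeat_library"))
  cand_idx <- split(seq_len(n), candidates$contig)
  match_cands <- function(contig, start0, end0) {
    idx <- cand_idx[[contig]]
    if (is.null(idx)) return(integer())
    ov <- pmin(candidates$end[idx], end0) - pmax(candidates$start[idx], start0)
    idx[ov >= overlap_frac * (end0 - start0)]
  }
  edges <- integer()
  if (nrow(hits)) {
    for (k in seq_len(nrow(hits))) {
      a <- match_cands(hits$qseqid[k], hits$qstart[k] - 1L, hits$qend[k])
      b <- match_cands(hits$sseqid[k],
                       min(hits$sstart[k], hits$send[k]) - 1L,
                       max(hits$sstart[k], hits$send[k]))
      if (length(a) && length(b)) {
        eg <- expand.grid(a = a, b = b)
        eg <- eg[eg$a != eg$b, , drop = FALSE]
        if (nrow(eg)) edges <- c(edges, rbind(eg$a, eg$b))
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  fams <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < 2) next  # repeat families need >= 2 copies
    members <- candidates[idx, , drop = FALSE]
    widths <- members$end - members$start
    ex <- members[which.max(widths), ]
    exemplar <- as.character(Biostrings::subseq(g[[ex$contig]],
                                                ex$start + 1L, ex$end))
    fams[[length(fams) + 1L]] <-
      list(exemplar = exemplar, exemplar_contig = ex$contig,
           exemplar_start = ex$start, copies = members)
  }
  ord <- order(vapply(fams, `[[`, "", "exemplar_contig"),
               vapply(fams, `[[`, 0L, "exemplar_start"))
  fams <- fams[ord]
  for (i in seq_along(fams)) fams[[i]]$id <- sprintf("RF%03d", i)
  structure(list(families = fams), class = "repeat_library")
}

#' @export
print.repeat_library <- function(x, ...) {
  cat("repeat_library with", length(x$families), "families\n")
  for (f in x$families) {
    cat(sprintf("  %s: exemplar %d bp, %d copies\n", f$id, nchar(f$exemplar),
                nrow(f$copies)))
  }
  invisible(x)
}

#' Exemplar sequences of a repeat library as a DNAStringSet
#' @param library a `repeat_library`.
#' @return named [Biostrings::DNAStringSet].
#' @export
library_exemplars <- function(library) {
  stopifnot(inherits(library, "repeat_library"))
  Biostrings::DNAStringSet(setNames(
    vapply(library$families, `[[`, "", "exemplar"),
    vapply(library$families, `[[`, "", "id")))
}

#' Annotate (mask) all genomic copies of a repeat library
#'
#' Re-aligns every family exemplar to the genome and emits all placements
#' passing the identity/score cutoffs as repeat copies. Overlapping placements
#' from different families are resolved in favour of the higher alignment
#' score (a placement mostly covered by a better-scoring placement of another
#' family is dropped).
#'
#' @param genome genome to annotate.
#' @param library a `repeat_library` (or DNAStringSet of exemplars).
#' @param min_identity minimum percent identity of a placement.
#' @param min_score minimum raw alignment score.
#' @param min_length minimum placement length (bp); short segments of nested
#'   or truncated copies are kept by default.
#' @param max_overlap fraction of a placement allowed to overlap better
#'   placements of other families before it is dropped.
#' @return data.frame of repeat copies: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `family`, `pident`, `score`.
#' @export
mask_repeats <- function(genome, library, min_identity = 70, min_score = 100,
                         min_length = 50, max_overlap = 0.5) {
  g <- as_dss(genome)
  ex <- if (inherits(library, "repeat_library")) library_exemplars(library)
        else as_dss(library)
  if (length(ex) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), pident = numeric(),
                      score = numeric()))
  }
  hits <- run_blastn(ex, g, min_score = min_score)
  hits <- hits[hits$pident >= min_identity & hits$length >= min_length, ,
               drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), pident = numeric(),
                      score = numeric()))
  }
  pl <- data.frame(contig = hits$sseqid,
                   start = pmin(hits$sstart, hits$send) - 1L,
                   end = pmax(hits$sstart, hits$send),
                   strand = hits$strand, family = hits$qseqid,
                   pident = hits$pident, score = hits$score,
                   stringsAsFactors = FALSE)
  pl <- pl[order(-pl$score, pl$contig, pl$start, pl$family), ]
  kept <- vector("list", length(unique(pl$contig)))
  names(kept) <- unique(pl$contig)
  keep_row <- logical(nrow(pl))
  for (k in seq_len(nrow(pl))) {
    ctg <- pl$contig[k]
    prev <- kept[[ctg]]
    ov <- 0L
    if (!is.null(prev) && nrow(prev)) {
      other <- prev[prev$family != pl$family[k], , drop = FALSE]
      if (nrow(other)) {
        ov <- intersect_bp(pl$start[k], pl$end[k], other$start, other$end)
      }
    }
    if (ov <= max_overlap * (pl$end[k] - pl$start[k])) {
      keep_row[k] <- TRUE
      kept[[ctg]] <- rbind(prev, pl[k, c("start", "end", "family")])
    }
  }
  out <- pl[keep_row, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$family), ]
  rownames(out) <- NULL
  out
}

#' Cross-genome repeat-family correspondence
#'
#' Compares the exemplars of every pair of per-genome repeat libraries by
#' reciprocal local alignment; two families correspond when both directions
#' align with raw score at least `min_score`. Universal repeat numbers are the
#' connected components of the correspondence graph, numbered canonically
#' (invariant to genome input order).
#'
#' @param libraries named list of `repeat_library` objects (names are genome
#'   ids).
#' @param min_score reciprocal score threshold (default 100, in the recorded
#'   scoring scheme).
#' @return list with `assignment` (data.frame: `genome`, `family`,
#'   `universal`) and `pair_scores` (data.frame of per-pair reciprocal
#'   minimum scores).
#' @export
correspond_families <- function(libraries, min_score = 100) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  ex <- lapply(libraries, library_exemplars)
  nodes <- unlist(lapply(names(ex), function(g)
    if (length(ex[[g]])) paste0(g, "::", names(ex[[g]])) else character()))
  genomes <- names(ex)
  pair_scores <- data.frame(genomeA = character(), familyA = character(),
                            genomeB = character(), familyB = character(),
                            score = numeric())
  edges <- character()
  if (length(genomes) >= 2) {
    for (i in seq_along(genomes)[-length(genomes)]) {
      for (j in seq((i + 1), length(genomes))) {
        a <- genomes[i]; b <- genomes[j]
        if (length(ex[[a]]) == 0 || length(ex[[b]]) == 0) next
        ab <- run_blastn(ex[[a]], ex[[b]], min_score = min_score)
        ba <- run_blastn(ex[[b]], ex[[a]], min_score = min_score)
        if (nrow(ab) == 0 || nrow(ba) == 0) next
        fw <- stats::aggregate(score ~ qseqid + sseqid, ab, max)
        rv <- stats::aggregate(score ~ qseqid + sseqid, ba, max)
        key_fw <- paste(fw$qseqid, fw$sseqid)
        key_rv <- paste(rv$sseqid, rv$qseqid)
        common <- intersect(key_fw, key_rv)
        for (key in common) {
          fa <- fw$qseqid[key_fw == key]; fb <- fw$sseqid[key_fw == key]
          sc <- min(fw$score[key_fw == key], rv$score[key_rv == key])
          pair_scores <- rbind(pair_scores,
                               data.frame(genomeA = a, familyA = fa,
                                          genomeB = b, familyB = fb,
                                          score = sc))
          edges <- c(edges, paste0(a, "::", fa), paste0(b, "::", fb))
        }
      }
    }
  }
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(nodes))
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  # canonical numbering: components ordered by their smallest node label
  comp_min <- tapply(names(comp), comp, min)
  renum <- setNames(seq_along(sort(comp_min)), sort(comp_min))
  universal <- renum[comp_min[as.character(comp)]]
  assignment <- data.frame(
    genome = sub("::.*$", "", names(comp)),
    family = sub("^.*::", "", names(comp)),
    universal = as.integer(universal),
    stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$universal, assignment$genome,
                                 assignment$family), ]
  rownames(assignment) <- NULL
  list(assignment = assignment, pair_scores = pair_scores,
       min_score = min_score)
}

#' End-to-end repeat discovery on one genome
#'
#' Convenience wrapper: [self_align()] then [call_multicopy_segments()] then
#' [cluster_into_families()] then [mask_repeats()]. The default length floor
#' here is 100 bp (below [call_multicopy_segments()]'s 400 bp element
#' default) so that MITE-sized elements remain discoverable for downstream
#' TIR classification.
#'
#' @param genome genome sequences.
#' @param min_score self-alignment score threshold.
#' @param min_len,min_copies,merge_gap see [call_multicopy_segments()].
#' @param min_identity masking identity threshold (percent).
#' @return list with `hits`, `candidates`, `library`, `copies`.
#' @export
discover_repeats <- function(genome, min_score = 100, min_len = 100,
                             min_copies = 2, merge_gap = 50,
                             min_identity = 70) {
  g <- as_dss(genome)
  hits <- self_align(g, min_score = min_score)
  candidates <- call_multicopy_segments(hits, min_len = min_len,
                                        min_copies = min_copies,
                                        merge_gap = merge_gap)
  library <- cluster_into_families(candidates, hits, g)
  copies <- mask_repeats(g, library, min_identity = min_identity)
  list(hits = hits, candidates = candidates, library = library,
       copies = copies)
}

# N-gap intervals (0-based half-open) per contig
gap_intervals <- function(seq_chr) {
  r <- rle(strsplit(seq_chr, "", fixed = TRUE)[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Genome partition and GC statistics
#'
#' Assigns every non-gap base of the genome to exactly one of four categories
#' with precedence CDS > genic-non-CDS > intergenic-repeat >
#' intergenic-non-repeat, and computes per-category base counts, percentages
#' (of total non-gap length) and GC fractions. The four categories partition
#' the non-gap genome exactly, and the bp-weighted mean of the category GC
#' fractions equals the whole-genome GC.
#'
#' @param genome genome sequences.
#' @param genes gene model data.frame with `contig`, `start`, `end`,
#'   `cds_start`, `cds_end` (0-based half-open).
#' @param masked repeat copies data.frame from [mask_repeats()] (columns
#'   `contig`, `start`, `end`).
#' @return list with `summary` (one-row data.frame of totals, percentages and
#'   GC fractions) and `categories` (per-category bp and GC).
#' @export
partition_stats <- function(genome, genes, masked) {
  g <- as_dss(genome)
  lens <- setNames(BiocGenerics::width(g), names(g))
  if (nrow(genes)) {
    bad <- genes$end > lens[genes$contig] | genes$start < 0 |
      !(genes$contig %in% names(lens))
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      stop("gene interval outside contig bounds: ",
           paste(genes$gene_id[which(bad | is.na(bad))], collapse = ", "),
           call. = FALSE)
    }
  }
  cat_ranges <- list(cds = list(), genic_non_cds = list(), rpt_ig = list(),
                     non_rpt_ig = list())
  per_contig <- list()
  for (ctg in names(g)) {
    s <- as.character(g[[ctg]])
    L <- lens[[ctg]]
    gaps <- gap_intervals(s)
    non_gap <- BiocGenerics::setdiff(IRanges::IRanges(1L, L),
                                iranges0(gaps$start, gaps$end))
    gn <- genes[genes$contig == ctg, , drop = FALSE]
    cds <- if (nrow(gn)) IRanges::reduce(iranges0(gn$cds_start, gn$cds_end))
           else IRanges::IRanges()
    genic <- if (nrow(gn)) IRanges::reduce(iranges0(gn$start, gn$end))
             else IRanges::IRanges()
    mk <- masked[masked$contig == ctg, , drop = FALSE]
    rpt <- if (nrow(mk)) IRanges::reduce(iranges0(mk$start, mk$end))
           else IRanges::IRanges()
    cds_r <- BiocGenerics::intersect(cds, non_gap)
    genic_non_cds <- BiocGenerics::intersect(BiocGenerics::setdiff(genic, cds), non_gap)
    rpt_ig <- BiocGenerics::intersect(BiocGenerics::setdiff(rpt, genic), non_gap)
    non_rpt_ig <- BiocGenerics::setdiff(non_gap,
                                   BiocGenerics::union(genic, rpt))
    per_contig[[ctg]] <- list(cds = cds_r, genic_non_cds = genic_non_cds,
                              rpt_ig = rpt_ig, non_rpt_ig = non_rpt_ig,
                              non_gap = non_gap)
  }
  gc_of <- function(ranges_by_contig) {
    tot <- 0; gcc <- 0
    for (ctg in names(ranges_by_contig)) {
      ir <- ranges_by_contig[[ctg]]
      if (length(ir) == 0) next
      v <- Biostrings::extractAt(g[[ctg]], ir)
      gcc <- gcc + sum(Biostrings::letterFrequency(v, "GC"))
      tot <- tot + sum(Biostrings::letterFrequency(v, "ACGT"))
    }
    if (tot == 0) NA_real_ else gcc / tot
  }
  pull <- function(cat) lapply(per_contig, `[[`, cat)
  bp <- vapply(names(cat_ranges), function(cat)
    sum(vapply(pull(cat), function(ir) sum(BiocGenerics::width(ir)), 0)),
    0)
  gc <- vapply(names(cat_ranges), function(cat) gc_of(pull(cat)), 0)
  total_non_gap <- sum(vapply(per_contig, function(p)
    sum(BiocGenerics::width(p$non_gap)), 0))
  stopifnot(sum(bp) == total_non_gap)  # exact partition
  genome_gc <- gc_of(lapply(per_contig, `[[`, "non_gap"))
  categories <- data.frame(category = names(cat_ranges), bp = as.numeric(bp),
                           pct = 100 * as.numeric(bp) / total_non_gap,
                           gc = as.numeric(gc), stringsAsFactors = FALSE)
  genic_bp <- bp[["cds"]] + bp[["genic_non_cds"]]
  summary <- data.frame(
    total_bp = total_non_gap, genic_bp = genic_bp, cds_bp = bp[["cds"]],
    repeat_bp = bp[["rpt_ig"]], non_rpt_ig_bp = bp[["non_rpt_ig"]],
    pct_cds = 100 * bp[["cds"]] / total_non_gap,
    pct_rpt = 100 * bp[["rpt_ig"]] / total_non_gap,
    pct_non_rpt_ig = 100 * bp[["non_rpt_ig"]] / total_non_gap,
    genome_gc = genome_gc, cds_gc = gc[["cds"]],
    non_rpt_ig_gc = gc[["non_rpt_ig"]], rpt_gc = gc[["rpt_ig"]])
  list(summary = summary, categories = categories,
       total_non_gap = total_non_gap)
}
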