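# Ortholog-group refinement by recursive bipartition. An ortholog group (as
# produced by Markov-cluster-style grouping) may mix orthologs and ancient
# paralogs; each group is recursively divided in two by the deepest split of
# an average-linkage clustering of pairwise p-distances, and a division is
# accepted when its column-bootstrap support is at least `bootstrap_min`
# (default 0.75) and its split score at least `split_min` (default 0.5). The
# split score of a candidate bipartition is the number of taxa common to
# both subgroups divided by the number of taxa in the smaller subgroup; a
# high value indicates an ancient duplication, with many taxa represented on
# both sides.

#' Split score of a candidate bipartition
#'
#' `|taxa(A) intersect taxa(B)| / min(|taxa(A)|, |taxa(B)|)`.
#'
#' @param taxa_a,taxa_b character vectors (taxa of each subgroup; duplicates
#'   ignored).
#' @return fraction in `[0, 1]`.
#' @export
split_score <- function(taxa_a, taxa_b) {
  a <- unique(taxa_a); b <- unique(taxa_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("split_score: empty taxa set", call. = FALSE)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Construct an ortholog group
#'
#' @param id group id.
#' @param members data.frame with columns `genome`, `gene`, `seq`.
#' @return list of class `ortholog_group`.
#' @export
ortholog_group <- function(id, members) {
  stopifnot(is.data.frame(members),
            all(c("genome", "gene", "seq") %in% names(members)),
            nrow(members) >= 2, !anyDuplicated(members$gene))
  structure(list(id = id, members = members,
                 taxa = unique(members$genome)),
            class = "ortholog_group")
}

# Alignment engine contract: any function mapping a character vector of
# sequences to a character vector of equal-length rows. Equal-length input
# passes through; unequal lengths are aligned with mafft when available.
align_members <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1) return(seqs)
  if (!nzchar(Sys.which("mafft"))) {
    stop("members have unequal lengths and mafft is not on PATH; ",
         "supply pre-aligned sequences", call. = FALSE)
  }
  td <- tempfile("aln"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  inf <- file.path(td, "in.fa"); outf <- file.path(td, "out.fa")
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), inf)
  st <- system2("mafft", c("--auto", "--quiet", inf), stdout = outf,
                stderr = FALSE)
  if (st != 0) stop("mafft failed", call. = FALSE)
  x <- Biostrings::readBStringSet(outf)
  as.character(x)[order(as.integer(sub("^s", "", names(x))))]
}

# alignment (character vector, equal lengths) -> column character matrix
alignment_matrix <- function(aligned) {
  do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
}

# pairwise p-distance on alignment columns (gaps/ambiguity positions in a
# pair are ignored for that pair)
p_distance <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  ok <- mat %in% c(DNA_BASES, LETTERS)  # residues, not gaps
  dim(ok) <- dim(mat)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      d[i, j] <- d[j, i] <-
        if (nc == 0) 1 else sum(mat[i, use] != mat[j, use]) / nc
    }
  }
  d
}

# deepest-split bipartition of a distance matrix by average-linkage
# clustering; returns a logical vector (TRUE = side A) or NULL when the
# clustering cannot produce two non-empty sides
deepest_bipartition <- function(d) {
  n <- nrow(d)
  if (n < 2) return(NULL)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  side <- stats::cutree(hc, k = 2) == 1
  if (all(side) || !any(side)) return(NULL)
  side
}

# canonical string key of a bipartition for comparison across bootstraps
bipartition_key <- function(side, ids) {
  a <- sort(ids[side]); b <- sort(ids[!side])
  grp <- if (a[1] < b[1]) list(a, b) else list(b, a)
  paste(vapply(grp, paste, "", collapse = ","), collapse = "|")
}

#' Recursively refine an ortholog group
#'
#' Aligns the members, computes the p-distance matrix, proposes the
#' deepest-split bipartition of an average-linkage clustering, and scores it
#' by (a) bootstrap support: the fraction of `b` column-resampled replicates
#' reproducing the same member bipartition, and (b) the [split_score()] of
#' the two subgroups' taxa sets. The division is accepted iff bootstrap >=
#' `bootstrap_min` and split score >= `split_min`, in which case refinement
#' recurses into both subgroups. Groups of fewer than 3 members, or groups
#' whose clustering cannot be partitioned into exactly two subclusters, are
#' left as leaves.
#'
#' @param group an [ortholog_group()].
#' @param b bootstrap replicates (default 100).
#' @param bootstrap_min bootstrap acceptance threshold (default 0.75).
#' @param split_min split-score acceptance threshold (default 0.5).
#' @param seed RNG seed.
#' @return list of class `refinement_tree`: recursive nodes with `members`,
#'   and for internal nodes `decision` (`bootstrap`, `split_score`,
#'   `accepted`, thresholds) and `children`.
#' @export
refine_group <- function(group, b = 100, bootstrap_min = 0.75,
                         split_min = 0.5, seed = 1) {
  stopifnot(inherits(group, "ortholog_group"))
  withr::with_seed(seed, refine_node(group$members, b, bootstrap_min,
                                     split_min))
}

refine_node <- function(members, b, bootstrap_min, split_min) {
  leaf <- structure(list(members = members, decision = NULL,
                         children = NULL), class = "refinement_tree")
  if (nrow(members) < 3) return(leaf)
  aligned <- align_members(members$seq)
  mat <- alignment_matrix(aligned)
  d <- p_distance(mat)
  side <- deepest_bipartition(d)
  if (is.null(side)) return(leaf)  # cannot split into exactly two: leave
  key <- bipartition_key(side, members$gene)
  ncol_aln <- ncol(mat)
  support <- 0L
  for (r in seq_len(b)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    side_r <- deepest_bipartition(p_distance(mat[, cols, drop = FALSE]))
    if (!is.null(side_r) &&
        bipartition_key(side_r, members$gene) == key) {
      support <- support + 1L
    }
  }
  bootstrap <- support / b
  ss <- split_score(members$genome[side], members$genome[!side])
  accepted <- bootstrap >= bootstrap_min && ss >= split_min
  decision <- list(bootstrap = bootstrap, split_score = ss,
                   accepted = accepted, bootstrap_min = bootstrap_min,
                   split_min = split_min,
                   taxa_a = unique(members$genome[side]),
                   taxa_b = unique(members$genome[!side]))
  if (!accepted) {
    leaf$decision <- decision
    return(leaf)
  }
  structure(list(
    members = members, decision = decision,
    children = list(
      refine_node(members[side, , drop = FALSE], b, bootstrap_min,
                  split_min),
      refine_node(members[!side, , drop = FALSE], b, bootstrap_min,
                  split_min))), class = "refinement_tree")
}

#' Final subgroups (leaves) of a refinement tree
#'
#' @param tree a `refinement_tree`.
#' @return list of member data.frames; their gene sets partition the group.
#' @export
refinement_leaves <- function(tree) {
  if (is.null(tree$children)) return(list(tree$members))
  c(refinement_leaves(tree$children[[1]]),
    refinement_leaves(tree$children[[2]]))
}

#' Build ortholog groups by reciprocal best hits
#'
#' A simplified grouping stand-in for Markov-cluster orthology inference:
#' global pairwise alignment scores between every inter-genome protein pair,
#' reciprocal-best-hit edges, and single-linkage connected components as
#' groups. Singletons are not emitted. Deterministic; ties broken by gene id.
#'
#' @param protein_sets named list (genome id) of named character vectors
#'   (gene id -> amino-acid sequence).
#' @param min_score minimum alignment score for an RBH edge.
#' @return list of [ortholog_group()] objects.
#' @export
build_groups_rbh <- function(protein_sets, min_score = 0) {
  stopifnot(length(protein_sets) >= 2, !is.null(names(protein_sets)))
  genomes <- names(protein_sets)
  all_genes <- unlist(lapply(genomes, function(g)
    paste0(g, "::", names(protein_sets[[g]]))))
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  sub_mat <- get("BLOSUM62", envir = environment())
  edges <- character()
  for (i in seq_along(genomes)[-length(genomes)]) {
    for (j in seq((i + 1), length(genomes))) {
      a <- protein_sets[[genomes[i]]]
      bset <- protein_sets[[genomes[j]]]
      sc <- matrix(NA_real_, length(a), length(bset),
                   dimnames = list(names(a), names(bset)))
      for (x in seq_along(a)) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(rep(a[[x]], length(bset))),
          Biostrings::AAStringSet(unlist(bset)),
          substitutionMatrix = sub_mat, gapOpening = 10, gapExtension = 1,
          type = "global", scoreOnly = TRUE)
        sc[x, ] <- aln
      }
      best_ab <- colnames(sc)[apply(sc, 1, which.max)]
      best_ba <- rownames(sc)[apply(sc, 2, which.max)]
      for (x in seq_along(a)) {
        y <- best_ab[x]
        if (best_ba[match(y, colnames(sc))] == names(a)[x] &&
            sc[x, y] >= min_score) {
          edges <- c(edges, paste0(genomes[i], "::", names(a)[x]),
                     paste0(genomes[j], "::", y))
        }
      }
    }
  }
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(all_genes))
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  groups <- list()
  comp_ids <- split(names(comp), comp)
  comp_ids <- comp_ids[order(vapply(comp_ids, min, ""))]
  gi <- 0L
  for (ids in comp_ids) {
    if (length(ids) < 2) next
    gi <- gi + 1L
    gmem <- sub("::.*$", "", ids)
    gname <- sub("^.*::", "", ids)
    seqs <- vapply(seq_along(ids), function(k)
      protein_sets[[gmem[k]]][[gname[k]]], "")
    groups[[gi]] <- ortholog_group(
      sprintf("OG%04d", gi),
      data.frame(genome = gmem, gene = gname, seq = seqs,
                 stringsAsFactors = FALSE))
  }
  groups
}
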