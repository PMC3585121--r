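# Secondary-metabolism (SM) gene-cluster identification and delimitation.
# Signature genes (NRPS, PKS, DMATS-family prenyltransferase, terpene
# synthase/cyclase) are recognised by InterPro/Pfam domain annotations.
# Cluster boundaries follow the primary-metabolism ortholog rule: genes whose
# ortholog group spans all sequenced genomes are treated as probable primary
# metabolism, and the cluster extends from a signature gene until a run of
# such core genes is met on each side.

#' Signature-domain catalog for SM cluster detection
#'
#' Maps each signature class to its identifying domain IDs: NRPS
#' (IPR010071, IPR006163, IPR001242), PKS (IPR013968), DMATS-family aromatic
#' prenyltransferase (IPR017795, PF11991), terpene synthase/cyclase
#' (IPR008949).
#'
#' @return named list of uppercase domain-ID character vectors.
#' @export
signature_catalog <- function() {
  list(
    NRPS = c("IPR010071", "IPR006163", "IPR001242"),
    PKS = c("IPR013968"),
    DMATS = c("IPR017795", "PF11991"),
    TS = c("IPR008949"))
}

#' Find SM signature genes by domain annotation
#'
#' A gene matches a class when any of its domain IDs is in that class's
#' catalog set; a gene with domains from several classes is returned once
#' with all classes listed. Pseudogenes are matched but flagged.
#'
#' @param genes gene model data.frame with a `domains` column
#'   (comma-separated IDs, `NA` for none) and a `pseudogene` column.
#' @param catalog from [signature_catalog()].
#' @return data.frame: `gene_id`, `contig`, `start`, `end`, `classes`
#'   (comma-separated), `pseudogene`.
#' @export
find_signature_genes <- function(genes, catalog = signature_catalog()) {
  hits <- lapply(seq_len(nrow(genes)), function(k) {
    d <- genes$domains[k]
    if (is.na(d)) return(NULL)
    ids <- toupper(trimws(strsplit(d, ",")[[1]]))
    cls <- names(catalog)[vapply(catalog, function(set)
      any(ids %in% set), TRUE)]
    if (length(cls) == 0) return(NULL)
    data.frame(gene_id = genes$gene_id[k], contig = genes$contig[k],
               start = genes$start[k], end = genes$end[k],
               classes = paste(cls, collapse = ","),
               pseudogene = isTRUE(genes$pseudogene[k]))
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      classes = character(), pseudogene = logical())
  }
  rownames(out) <- NULL
  out
}

#' Core (probable primary-metabolism) ortholog groups
#'
#' Groups whose taxa span all input genomes.
#'
#' @param groups data.frame with columns `genome`, `gene_id`, `group_id`.
#' @param genomes character vector of all genome ids (defaults to those seen
#'   in `groups`).
#' @return character vector of core group ids.
#' @export
core_ortholog_set <- function(groups, genomes = unique(groups$genome)) {
  tab <- tapply(groups$genome, groups$group_id,
                function(g) length(unique(g)))
  names(tab)[tab == length(genomes)]
}

#' Delimit an SM cluster around a signature gene
#'
#' Walks left and right from the signature gene along the contig's gene
#' order, including genes whose ortholog group is not in the core set (genes
#' with no group are treated as accessory), and stops in a direction upon
#' encountering `stop_run` consecutive core genes. The first core gene on
#' each side is recorded as the flank. The boundary spans the first to last
#' included gene; with `include_flanking_repeats = TRUE` it is widened to
#' absorb repeat blocks contiguous (within `repeat_gap` bp) to the boundary.
#'
#' @param signature_gene_id id of the signature gene.
#' @param genes gene models of one genome (data.frame; must contain the
#'   signature gene); genes on the signature gene's contig are used in
#'   coordinate order.
#' @param core character vector of core ortholog-group ids.
#' @param stop_run number of consecutive core genes that terminate extension.
#' @param include_flanking_repeats widen the boundary over contiguous repeat
#'   blocks.
#' @param masked repeat copies (needed when `include_flanking_repeats`).
#' @param repeat_gap max gap (bp) for a repeat block to count as contiguous.
#' @return list of class `cluster_model`: `cluster_id`, `contig`, `members`
#'   (gene data.frame), `signature_gene`, `boundary` (`start`, `end`),
#'   `flank_left`, `flank_right`, `one_sided`.
#' @export
delimit_cluster <- function(signature_gene_id, genes, core, stop_run = 2,
                            include_flanking_repeats = FALSE, masked = NULL,
                            repeat_gap = 100) {
  stopifnot(stop_run >= 1)
  k <- match(signature_gene_id, genes$gene_id)
  if (is.na(k)) stop("signature gene not found: ", signature_gene_id,
                     call. = FALSE)
  ctg <- genes$contig[k]
  gn <- genes[genes$contig == ctg, , drop = FALSE]
  gn <- gn[order(gn$start), , drop = FALSE]
  i <- match(signature_gene_id, gn$gene_id)
  is_core <- !is.na(gn$ortholog_group) & gn$ortholog_group %in% core
  walk <- function(dir) {
    included <- integer()
    run <- 0L
    flank <- NA_integer_
    j <- i + dir
    while (j >= 1 && j <= nrow(gn)) {
      if (is_core[j]) {
        if (is.na(flank)) flank <- j
        run <- run + 1L
        if (run >= stop_run) break
      } else {
        run <- 0L
        flank <- NA_integer_
        included <- c(included, j)
      }
      j <- j + dir
    }
    list(included = included, flank = flank)
  }
  left <- walk(-1L)
  right <- walk(+1L)
  member_idx <- sort(c(left$included, i, right$included))
  members <- gn[member_idx, , drop = FALSE]
  boundary <- c(start = min(members$start), end = max(members$end))
  if (include_flanking_repeats && !is.null(masked)) {
    mk <- masked[masked$contig == ctg, , drop = FALSE]
    if (nrow(mk)) {
      mk <- mk[order(mk$start), ]
      repeat {
        grew <- FALSE
        touch_left <- mk$end >= boundary["start"] - repeat_gap &
          mk$start < boundary["start"]
        if (any(touch_left)) {
          boundary["start"] <- min(mk$start[touch_left])
          grew <- TRUE
        }
        touch_right <- mk$start <= boundary["end"] + repeat_gap &
          mk$end > boundary["end"]
        if (any(touch_right)) {
          boundary["end"] <- max(mk$end[touch_right])
          grew <- TRUE
        }
        if (!grew) break
      }
    }
  }
  one_sided <- (i == 1 && is.na(left$flank)) ||
    (i == nrow(gn) && is.na(right$flank))
  structure(list(
    cluster_id = paste0("cluster_", signature_gene_id),
    contig = ctg,
    members = members,
    signature_gene = signature_gene_id,
    boundary = boundary,
    flank_left = if (is.na(left$flank)) NA_character_ else
      gn$gene_id[left$flank],
    flank_right = if (is.na(right$flank)) NA_character_ else
      gn$gene_id[right$flank],
    one_sided = one_sided), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model %s on %s [%d, %d): %d members, signature %s\n",
              x$cluster_id, x$contig, x$boundary["start"], x$boundary["end"],
              nrow(x$members), x$signature_gene))
  invisible(x)
}

#' Repeat and CDS accounting within a cluster boundary
#'
#' Adds the repeat bp (union of masked intervals intersected with the
#' boundary), CDS bp (union of member CDS intervals intersected with the
#' boundary), and the base-10 log ratio repeat/CDS to a cluster model. The
#' ratio is flagged undefined when either count is zero.
#'
#' @param cluster a `cluster_model`.
#' @param masked repeat copies data.frame.
#' @param genes gene models of the genome (CDS intervals of all genes inside
#'   the boundary are counted, member or not).
#' @return the cluster with `repeat_bp`, `cds_bp`, `log_ratio`,
#'   `log_ratio_defined` added.
#' @export
cluster_repeat_cds_logratio <- function(cluster, masked, genes) {
  b <- cluster$boundary
  ctg <- cluster$contig
  mk <- masked[masked$contig == ctg, , drop = FALSE]
  rpt <- intersect_bp(mk$start, mk$end, b["start"], b["end"])
  gn <- genes[genes$contig == ctg, , drop = FALSE]
  cds <- intersect_bp(gn$cds_start, gn$cds_end, b["start"], b["end"])
  cluster$repeat_bp <- rpt
  cluster$cds_bp <- cds
  cluster$log_ratio_defined <- rpt > 0 && cds > 0
  cluster$log_ratio <- if (cluster$log_ratio_defined) log10(rpt / cds)
                       else NA_real_
  cluster
}

#' Functional status of a cluster
#'
#' A cluster is inactive iff all of its signature genes are pseudogenes (or
#' absent); a single intact signature gene makes it active.
#'
#' @param cluster a `cluster_model`.
#' @param signature_genes data.frame from [find_signature_genes()] restricted
#'   to this cluster's members (defaults to members carrying a signature
#'   domain per [signature_catalog()]).
#' @return the cluster with `functional_status` (`"active"`/`"inactive"`)
#'   added.
#' @export
assess_functional_status <- function(cluster, signature_genes = NULL) {
  if (is.null(signature_genes)) {
    signature_genes <- find_signature_genes(cluster$members)
  }
  sig <- signature_genes[signature_genes$gene_id %in%
                           cluster$members$gene_id, , drop = FALSE]
  cluster$functional_status <-
    if (nrow(sig) == 0 || all(sig$pseudogene)) "inactive" else "active"
  cluster
}

#' Core-periphery layout statistic of a cluster
#'
#' Quantifies the tendency of decoration (periphery) genes to sit at the
#' cluster edges and skeleton (core) genes at its centre. Genes are placed on
#' a rank scale; each gene's peripherality is its normalised absolute
#' distance from the cluster midpoint. The statistic is mean peripherality of
#' decoration genes minus that of skeleton genes (positive = decorations more
#' peripheral); significance is assessed by permutation of the role labels.
#' This statistic is this package's own formalisation of the
#' conserved-core / variable-periphery arrangement.
#'
#' @param roles character vector of `"skeleton"`/`"decoration"` labels in
#'   gene order along the cluster (other labels are ignored).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutation draw.
#' @return list: `statistic`, `p_value` (one-sided, decorations peripheral),
#'   `n_skeleton`, `n_decoration`, `defined`.
#' @export
core_periphery_layout <- function(roles, n_perm = 999, seed = 1) {
  keep <- roles %in% c("skeleton", "decoration")
  r <- roles[keep]
  n <- length(r)
  n_sk <- sum(r == "skeleton"); n_dec <- sum(r == "decoration")
  if (n_sk < 2 || n_dec < 2) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_skeleton = n_sk, n_decoration = n_dec, defined = FALSE))
  }
  pos <- seq_len(n)
  centre <- (n + 1) / 2
  periph <- abs(pos - centre) / (n - 1) * 2  # 0 at midpoint, 1 at the ends
  stat_of <- function(lab) {
    mean(periph[lab == "decoration"]) - mean(periph[lab == "skeleton"])
  }
  obs <- stat_of(r)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_of(sample(r)), 0)
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_skeleton = n_sk,
       n_decoration = n_dec, defined = TRUE)
}

#' Attach telomere linkage to a cluster
#'
#' A cluster is telomere-linked when a telomere array lies on its contig
#' within `max_distance` bp of the boundary.
#'
#' @param cluster a `cluster_model`.
#' @param telomeres from [detect_telomeres()].
#' @param max_distance linkage threshold in bp (default 100 kb).
#' @return cluster with `telomere_distance` (bp or `NA`) and
#'   `telomere_linked` added.
#' @export
cluster_telomere_linkage <- function(cluster, telomeres,
                                     max_distance = 100000) {
  d <- distance_to_telomere(cluster$contig, cluster$boundary[["start"]],
                            cluster$boundary[["end"]], telomeres)
  cluster$telomere_distance <- d
  cluster$telomere_linked <- !is.na(d) && d <= max_distance
  cluster
}
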