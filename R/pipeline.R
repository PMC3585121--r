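# End-to-end orchestration: repeats -> RIP -> structural elements -> SM
# clusters -> chemotype, per genome, with a manifest of every parameter so a
# rerun with the same configuration is bit-identical.

#' Pipeline configuration
#'
#' @param fasta path to the genome FASTA (or a DNAStringSet).
#' @param gff3 path to the gene-model GFF3 (or a gene data.frame).
#' @param genotype optional genotype data.frame or TSV path for chemotype
#'   prediction.
#' @param out_dir output directory (`NULL` for no file output).
#' @param seed RNG seed for the permutation-based layout statistic.
#' @param repeat_params,rip_params_,telomere_params,mite_params,cluster_params
#'   named lists overriding module defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, gff3, genotype = NULL, out_dir = NULL,
                            seed = 1, repeat_params = list(),
                            rip_params_ = list(), telomere_params = list(),
                            mite_params = list(), cluster_params = list()) {
  for (p in list(fasta, gff3)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(fasta = fasta, gff3 = gff3, genotype = genotype,
                 out_dir = out_dir, seed = as.integer(seed),
                 repeat_params = repeat_params, rip_params_ = rip_params_,
                 telomere_params = telomere_params,
                 mite_params = mite_params, cluster_params = cluster_params),
            class = "pipeline_config")
}

#' Run the full locus-architecture pipeline on one genome
#'
#' Stages, in dependency order: repeat discovery and masking; genome
#' partition/GC statistics; RIP-index background and per-copy RIP
#' classification; MITE and telomere detection; SM signature-gene detection
#' and cluster delimitation (with repeat/CDS accounting, functional status
#' and telomere linkage); optional chemotype prediction. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of class `genome_report` with elements `partition`,
#'   `repeat_library`, `repeat_copies`, `rip`, `mites`, `telomeres`,
#'   `clusters`, `chemotype`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genome <- stage("load_genome", as_dss(config$fasta))
  genes <- stage("load_genes", {
    if (is.data.frame(config$gff3)) config$gff3
    else read_gff3_genes(config$gff3)
  })

  rp <- utils::modifyList(list(min_score = 100, min_len = 100,
                               min_copies = 2, merge_gap = 50,
                               min_identity = 70), config$repeat_params)
  rep_res <- stage("repeats", discover_repeats(
    genome, min_score = rp$min_score, min_len = rp$min_len,
    min_copies = rp$min_copies, merge_gap = rp$merge_gap,
    min_identity = rp$min_identity))

  partition <- stage("partition_stats",
                     partition_stats(genome, genes, rep_res$copies))

  rpp <- utils::modifyList(list(window = 200, step = 20, q = 0.95),
                           config$rip_params_)
  params <- rip_params(rpp$window, rpp$step)
  rip <- stage("rip", {
    bg <- rip_background(genome, genes, rep_res$copies, params)
    verdicts <- classify_ripped(rep_res$copies, genome, bg, params,
                                q = rpp$q)
    list(background = bg, verdicts = verdicts)
  })

  tp <- utils::modifyList(list(motif = "TTAGGG", min_copies = 4,
                               max_offset = 200), config$telomere_params)
  telomeres <- stage("telomeres", detect_telomeres(
    genome, motif = tp$motif, min_copies = tp$min_copies,
    max_offset = tp$max_offset))

  mp <- utils::modifyList(list(length_bounds = c(80, 800), min_arm = 10,
                               min_identity = 0.8), config$mite_params)
  mites <- stage("mites", call_mites(
    rep_res$library, rep_res$copies, length_bounds = mp$length_bounds,
    min_arm = mp$min_arm, min_identity = mp$min_identity))

  cp <- utils::modifyList(list(stop_run = 2, telomere_max_distance = 100000,
                               include_flanking_repeats = FALSE),
                          config$cluster_params)
  clusters <- stage("clusters", {
    sig <- find_signature_genes(genes)
    groups <- data.frame(genome = "self", gene_id = genes$gene_id,
                         group_id = genes$ortholog_group)
    groups <- groups[!is.na(groups$group_id), ]
    core <- core_ortholog_set(groups)
    lapply(sig$gene_id, function(sg) {
      cl <- delimit_cluster(sg, genes, core, stop_run = cp$stop_run,
                            include_flanking_repeats =
                              cp$include_flanking_repeats,
                            masked = rep_res$copies)
      cl <- cluster_repeat_cds_logratio(cl, rep_res$copies, genes)
      cl <- assess_functional_status(cl)
      cluster_telomere_linkage(cl, telomeres,
                               max_distance = cp$telomere_max_distance)
    })
  })

  chemotype <- NULL
  if (!is.null(config$genotype)) {
    chemotype <- stage("chemotype", {
      rulesets <- load_rulesets()
      gt <- config$genotype
      if (is.character(gt)) {
        profs <- read_genotypes(gt, rulesets)
        lapply(profs, predict_chemotype, rulesets = rulesets)
      } else {
        prof <- genotype_profile("genome", gt, rulesets)
        list(predict_chemotype(prof, rulesets))
      }
    })
  }

  manifest <- list(
    seed = config$seed,
    n_contigs = length(genome),
    genome_bp = sum(BiocGenerics::width(genome)),
    n_genes = nrow(genes),
    scoring = BLAST_SCHEME,
    repeat_params = rp, rip_params = rpp, telomere_params = tp,
    mite_params = mp, cluster_params = cp,
    n_repeat_families = length(rep_res$library$families),
    n_repeat_copies = nrow(rep_res$copies),
    n_mite_calls = nrow(mites$calls),
    n_telomeres = nrow(telomeres),
    n_clusters = length(clusters))

  report <- structure(
    list(partition = partition, repeat_library = rep_res$library,
         repeat_copies = rep_res$copies, rip = rip, mites = mites,
         telomeres = telomeres, clusters = clusters, chemotype = chemotype,
         manifest = manifest), class = "genome_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a genome report to disk as JSON + TSV
#'
#' @param report a `genome_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$partition$summary, file.path(dir, "partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$repeat_copies, file.path(dir, "repeat_copies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$rip$verdicts, file.path(dir, "rip_verdicts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$telomeres, file.path(dir, "telomeres.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$mites$calls, file.path(dir, "mite_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl_tab <- cluster_table(report$clusters)
  write.table(cl_tab, file.path(dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Tabular summary of delimited clusters (repeat/CDS log-ratio table)
#'
#' @param clusters list of `cluster_model`s.
#' @return data.frame: one row per cluster with boundary, member count,
#'   repeat bp, CDS bp, log-ratio, functional status, telomere linkage.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(cluster_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), repeat_bp = integer(),
                      cds_bp = integer(), log_ratio = numeric(),
                      status = character(), telomere_distance = integer()))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, contig = cl$contig,
               start = cl$boundary[["start"]], end = cl$boundary[["end"]],
               n_members = nrow(cl$members),
               repeat_bp = cl$repeat_bp %||% NA,
               cds_bp = cl$cds_bp %||% NA,
               log_ratio = cl$log_ratio %||% NA,
               status = cl$functional_status %||% NA,
               telomere_distance = cl$telomere_distance %||% NA)
  }))
}

#' Layered track table (and optional figure) for a cluster locus map
#'
#' Produces the machine-readable equivalent of a locus map with tracks in
#' the order genes, repeats, MITEs, AT/GC composition; optionally renders a
#' ggplot2 figure. Telomere distance (kb) is annotated when the cluster is
#' telomere-linked.
#'
#' @param cluster a `cluster_model` (after accounting/linkage steps).
#' @param genome genome sequences (for the composition track).
#' @param masked repeat copies.
#' @param mites MITE calls data.frame.
#' @param window,step composition-track windowing within the boundary.
#' @param figure_path optional path for a PDF/PNG figure (requires ggplot2).
#' @param pad bp of context added on both sides of the boundary.
#' @return data.frame with columns `track` (`gene`, `repeat`, `mite`,
#'   `composition`), `name`, `start`, `end`, `value` (`NA` except for
#'   composition rows), `annotation`.
#' @export
render_locus_map <- function(cluster, genome, masked, mites,
                             window = 200, step = 200, figure_path = NULL,
                             pad = 2000) {
  g <- as_dss(genome)
  ctg <- cluster$contig
  L <- BiocGenerics::width(g)[match(ctg, names(g))]
  lo <- max(0L, cluster$boundary[["start"]] - pad)
  hi <- min(L, cluster$boundary[["end"]] + pad)
  rows <- list()
  m <- cluster$members
  rows$genes <- data.frame(track = "gene", name = m$gene_id,
                           start = m$start, end = m$end, value = NA_real_,
                           annotation = ifelse(m$pseudogene, "pseudogene",
                                               m$role))
  mk <- masked[masked$contig == ctg & masked$end > lo & masked$start < hi, ,
               drop = FALSE]
  rows$repeats <- if (nrow(mk)) {
    data.frame(track = "repeat", name = mk$family, start = mk$start,
               end = mk$end, value = NA_real_, annotation = "")
  }
  mt <- mites[mites$contig == ctg & mites$end > lo & mites$start < hi, ,
              drop = FALSE]
  rows$mites <- if (nrow(mt)) {
    data.frame(track = "mite", name = mt$family, start = mt$start,
               end = mt$end, value = NA_real_, annotation = "")
  }
  seg <- as.character(Biostrings::subseq(g[[ctg]], lo + 1L, hi))
  cmp <- composition_track(seg, window = window, step = step)
  rows$comp <- if (nrow(cmp)) {
    rbind(data.frame(track = "composition", name = "AT",
                     start = cmp$start + lo, end = cmp$end + lo,
                     value = cmp$at, annotation = ""),
          data.frame(track = "composition", name = "GC",
                     start = cmp$start + lo, end = cmp$end + lo,
                     value = cmp$gc, annotation = ""))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(tab) <- NULL
  if (isTRUE(cluster$telomere_linked)) {
    attr(tab, "telomere_kb") <- round(cluster$telomere_distance / 1000, 1)
  }
  if (!is.null(figure_path) && requireNamespace("ggplot2", quietly = TRUE)) {
    lev <- c(gene = 4, `repeat` = 3, mite = 2)
    feat <- tab[tab$track != "composition", ]
    comp <- tab[tab$track == "composition", ]
    pl <- ggplot2::ggplot() +
      ggplot2::geom_segment(
        data = feat,
        ggplot2::aes(x = start / 1000, xend = end / 1000,
                     y = lev[track], yend = lev[track], colour = track),
        linewidth = 4) +
      ggplot2::geom_line(
        data = comp,
        ggplot2::aes(x = (start + end) / 2000, y = value,
                     colour = name)) +
      ggplot2::labs(x = sprintf("%s (kb)", ctg), y = NULL,
                    title = cluster$cluster_id,
                    subtitle = if (isTRUE(cluster$telomere_linked))
                      sprintf("telomere at %.1f kb",
                              cluster$telomere_distance / 1000) else NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(figure_path, pl, width = 9, height = 4)
  }
  tab
}
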