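# Discovery of multicopy repeat families from genome self-alignment.
# These tests exercise the BLAST-backed alignment layer, the footprint
# merging, the single-linkage family clustering (against a brute-force
# union-find oracle), masking recall/precision on generator truth, and the
# exactness of the genome partition statistics.

test_that("self-alignment of a random contig yields no hits", {
  withr::with_seed(1, {
    g <- Biostrings::DNAStringSet(c(c1 = random_seq(10000, 0.5)))
    hits <- self_align(g, min_score = 100)
    expect_equal(nrow(hits), 0)
  })
})

test_that("an exact duplication self-aligns at full identity", {
  withr::with_seed(2, {
    dup <- random_seq(2000, 0.5)
    g <- Biostrings::DNAStringSet(c(c1 = paste0(
      random_seq(3000, 0.5), dup, random_seq(2500, 0.5), dup,
      random_seq(1500, 0.5))))
    hits <- self_align(g, min_score = 100)
    expect_gt(nrow(hits), 0)
    expect_true(any(hits$pident == 100 & hits$length >= 1990))
  })
})

test_that("hit tables are invariant to contig input order", {
  withr::with_seed(3, {
    dup <- random_seq(1500, 0.5)
    c1 <- paste0(random_seq(2000, 0.5), dup, random_seq(1000, 0.5))
    c2 <- paste0(random_seq(500, 0.5), dup, random_seq(3000, 0.5))
    h1 <- self_align(Biostrings::DNAStringSet(c(a = c1, b = c2)))
    h2 <- self_align(Biostrings::DNAStringSet(c(b = c2, a = c1)))
    expect_equal(h1, h2)
  })
})

test_that("multicopy segments recover planted copies and merge over gaps", {
  sim <- generate_genome(small_repeat_recipe(seed = 11))
  hits <- self_align(sim$genome)
  cands <- call_multicopy_segments(hits, min_len = 400, min_copies = 2)
  tr <- sim$truth$repeats
  # every planted copy reciprocally overlapped >= 90% by one candidate
  recovered <- vapply(seq_len(nrow(tr)), function(k) {
    same <- cands[cands$contig == tr$contig[k], ]
    if (nrow(same) == 0) return(FALSE)
    ov <- pmin(same$end, tr$end[k]) - pmax(same$start, tr$start[k])
    any(ov >= 0.9 * (tr$end[k] - tr$start[k]) &
          ov >= 0.9 * (same$end - same$start))
  }, TRUE)
  expect_gte(mean(recovered), 0.9)
  expect_equal(nrow(call_multicopy_segments(hits[0, ])), 0)
})

test_that("adjacent footprints closer than the merge gap become one segment", {
  # two copies of a bipartite element whose halves are separated by a short
  # spacer; footprints merge into a single candidate per locus
  withr::with_seed(4, {
    left <- random_seq(600, 0.5); right <- random_seq(600, 0.5)
    unit <- function() paste0(left, random_seq(30, 0.5), right)
    g <- Biostrings::DNAStringSet(c(c1 = paste0(
      random_seq(2000, 0.5), unit(), random_seq(2000, 0.5), unit(),
      random_seq(2000, 0.5))))
    hits <- self_align(g)
    cands <- call_multicopy_segments(hits, min_len = 400, merge_gap = 50)
    # brute-force interval union with the same gap rule
    fp <- rbind(
      data.frame(start = hits$qstart - 1L, end = hits$qend),
      data.frame(start = pmin(hits$sstart, hits$send) - 1L,
                 end = pmax(hits$sstart, hits$send)))
    fp <- fp[order(fp$start), ]
    merged <- fp[1, ]
    for (k in seq_len(nrow(fp))[-1]) {
      if (fp$start[k] < merged$end[nrow(merged)] + 50) {
        merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], fp$end[k])
      } else merged <- rbind(merged, fp[k, ])
    }
    merged <- merged[merged$end - merged$start >= 400, ]
    expect_equal(cands$start, merged$start)
    expect_equal(cands$end, merged$end)
    expect_equal(nrow(cands), 2)
  })
})

test_that("family clustering equals a brute-force union-find oracle", {
  sim <- generate_genome(small_repeat_recipe(seed = 17))
  hits <- self_align(sim$genome)
  cands <- call_multicopy_segments(hits)
  lib <- cluster_into_families(cands, hits, sim$genome)
  # oracle: label propagation over the same overlap edges
  nodes <- paste0("n", seq_len(nrow(cands)))
  match_c <- function(ctg, s, e) {
    idx <- which(cands$contig == ctg)
    ov <- pmin(cands$end[idx], e) - pmax(cands$start[idx], s)
    idx[ov >= 0.5 * (e - s)]
  }
  ea <- character(); eb <- character()
  for (k in seq_len(nrow(hits))) {
    a <- match_c(hits$qseqid[k], hits$qstart[k] - 1, hits$qend[k])
    b <- match_c(hits$sseqid[k], min(hits$sstart[k], hits$send[k]) - 1,
                 max(hits$sstart[k], hits$send[k]))
    for (x in a) for (y in b) if (x != y) {
      ea <- c(ea, nodes[x]); eb <- c(eb, nodes[y])
    }
  }
  lab <- brute_components(nodes, ea, eb)
  oracle_sizes <- sort(as.integer(table(lab)[table(lab) >= 2]))
  lib_sizes <- sort(vapply(lib$families, function(f) nrow(f$copies), 0L))
  expect_equal(lib_sizes, oracle_sizes)
  # two planted families with no cross-similarity -> exactly 2 families
  expect_equal(length(lib$families), 2)
  expect_setequal(lib_sizes, c(6L, 5L))
})

test_that("masking recovers planted repeat bp with high recall and precision", {
  sim <- generate_genome(small_repeat_recipe(seed = 23))
  res <- discover_repeats(sim$genome)
  tr <- sim$truth$repeats
  truth_bp <- union_bp(tr$start, tr$end)
  called_bp <- union_bp(res$copies$start, res$copies$end)
  tp <- intersect_bp(tr$start, tr$end, res$copies$start, res$copies$end)
  expect_gte(tp / truth_bp, 0.95)
  expect_gte(tp / called_bp, 0.95)
  # masking is a deterministic function of (genome, library)
  again <- mask_repeats(sim$genome, res$library)
  expect_equal(again, res$copies)
})

test_that("masking a repeat-free random genome marks almost nothing", {
  withr::with_seed(6, {
    g <- Biostrings::DNAStringSet(c(c1 = random_seq(100000, 0.45)))
    sim <- generate_genome(small_repeat_recipe(seed = 29, length = 200000))
    lib <- discover_repeats(sim$genome)$library
    copies <- mask_repeats(g, lib)
    masked_bp <- union_bp(copies$start, copies$end)
    expect_lt(masked_bp / 100000, 0.005)
  })
})

test_that("cross-genome correspondence groups shared families together", {
  simA <- generate_genome(small_repeat_recipe(seed = 11, length = 200000))
  resA <- discover_repeats(simA$genome)
  shared <- resA$library$families[[1]]$exemplar
  recB <- genome_recipe(
    seed = 31, contigs = data.frame(name = "c1", length = 150000),
    te_families = list(te_family("SH", exemplar = shared, copies = 4),
                       te_family("TEB", 1200, copies = 3)),
    genome_id = "synthB")
  simB <- generate_genome(recB)
  resB <- discover_repeats(simB$genome)
  co <- correspond_families(list(gA = resA$library, gB = resB$library))
  a <- co$assignment
  # the shared family carries one universal number in both genomes
  shared_ids <- unique(a$universal[paste(a$genome, a$family) %in%
    paste(co$pair_scores$genomeA, co$pair_scores$familyA)])
  expect_gte(nrow(co$pair_scores), 1)
  uA <- a$universal[a$genome == "gA" & a$family ==
                      co$pair_scores$familyA[1]]
  uB <- a$universal[a$genome == "gB" & a$family ==
                      co$pair_scores$familyB[1]]
  expect_equal(uA, uB)
  # families without cross-genome match keep distinct universal numbers
  expect_equal(anyDuplicated(a$universal[!duplicated(a$universal)]), 0)
  # invariance to genome input order
  co2 <- correspond_families(list(gB = resB$library, gA = resA$library))
  expect_equal(co$assignment,
               co2$assignment[order(co2$assignment$universal,
                                    co2$assignment$genome,
                                    co2$assignment$family), ],
               ignore_attr = TRUE)
  # component labels equal brute-force connected components
  nodes <- paste0(a$genome, "::", a$family)
  lab <- brute_components(
    nodes,
    paste0(co$pair_scores$genomeA, "::", co$pair_scores$familyA),
    paste0(co$pair_scores$genomeB, "::", co$pair_scores$familyB))
  expect_equal(length(unique(lab)), length(unique(a$universal)))
})

test_that("partition statistics are an exact partition with conserved GC", {
  # toy contig: 1000 bp with 400 bp CDS and 300 bp intergenic repeat
  withr::with_seed(7, {
    g <- Biostrings::DNAStringSet(c(c1 = random_seq(1000, 0.5)))
    genes <- data.frame(gene_id = "g1", contig = "c1", start = 0L,
                        end = 400L, cds_start = 0L, cds_end = 400L,
                        strand = "+", pseudogene = FALSE,
                        domains = NA, ortholog_group = NA, role = NA,
                        cluster_id = NA)
    masked <- data.frame(contig = "c1", start = 500L, end = 800L)
    st <- partition_stats(g, genes, masked)
    expect_equal(st$summary$pct_cds, 40)
    expect_equal(st$summary$pct_rpt, 30)
    expect_equal(st$summary$pct_non_rpt_ig, 30)
    # all-CDS contig
    genes2 <- genes; genes2$end <- 1000L; genes2$cds_end <- 1000L
    st2 <- partition_stats(g, genes2, masked[0, ])
    expect_equal(st2$summary$pct_cds, 100)
    expect_equal(st2$summary$pct_rpt, 0)
  })
  # on a full synthetic genome: categories sum exactly, weighted GC identity
  sim <- generate_genome(cluster_recipe(seed = 3))
  res <- discover_repeats(sim$genome)
  st <- partition_stats(sim$genome, sim$genes, res$copies)
  expect_equal(sum(st$categories$bp), st$total_non_gap)
  w <- st$categories
  expect_equal(sum(w$gc * w$bp, na.rm = TRUE) / st$total_non_gap,
               st$summary$genome_gc, tolerance = 1e-9)
  # gene interval outside the contig is a named validation error
  bad <- sim$genes
  bad$end[1] <- 10^9
  expect_error(partition_stats(sim$genome, bad, res$copies),
               bad$gene_id[1])
})
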