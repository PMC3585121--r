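mk_genes <- function(roles, groups, contig = "c1", gene_len = 1000,
                     gap = 200) {
  n <- length(roles)
  start <- (seq_len(n) - 1L) * (gene_len + gap)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), contig = contig,
    start = start, end = start + gene_len,
    cds_start = start + 100L, cds_end = start + gene_len - 100L,
    strand = "+", pseudogene = FALSE,
    domains = ifelse(roles == "signature", "IPR013968", NA),
    ortholog_group = groups, role = roles, cluster_id = NA,
    stringsAsFactors = FALSE)
}

test_that("signature genes are recognised by catalog domains", {
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    contig = "c1", start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    domains = c("IPR013968", NA, "IPR010071,IPR013968", "IPR000000"),
    pseudogene = c(FALSE, FALSE, TRUE, FALSE))
  sig <- find_signature_genes(genes)
  expect_equal(sig$gene_id, c("a", "c"))
  expect_equal(sig$classes[1], "PKS")
  # both classes listed once for a dual-domain gene
  expect_setequal(strsplit(sig$classes[2], ",")[[1]], c("NRPS", "PKS"))
  expect_true(sig$pseudogene[2])
})

test_that("delimitation follows the core-ortholog stop rule", {
  roles <- c("flanking-core", "flanking-core", "decoration", "decoration",
             "signature", "decoration", "flanking-core", "flanking-core")
  groups <- ifelse(roles == "flanking-core",
                   sprintf("COG%d", seq_along(roles)), NA)
  genes <- mk_genes(roles, groups)
  core <- groups[!is.na(groups)]
  cl <- delimit_cluster("g05", genes, core, stop_run = 2)
  expect_setequal(cl$members$gene_id, c("g03", "g04", "g05", "g06"))
  expect_equal(cl$flank_left, "g02")
  expect_equal(cl$flank_right, "g07")
  expect_false(cl$one_sided)
  # signature gene surrounded by core genes -> single-gene cluster
  roles2 <- c("flanking-core", "flanking-core", "signature",
              "flanking-core", "flanking-core")
  groups2 <- ifelse(roles2 == "flanking-core",
                    sprintf("COG%d", seq_along(roles2)), NA)
  genes2 <- mk_genes(roles2, groups2)
  cl2 <- delimit_cluster("g03", genes2, groups2[!is.na(groups2)])
  expect_equal(cl2$members$gene_id, "g03")
})

test_that("stop_run changes membership as the brute-force scan predicts", {
  # [SIG acc core acc core core]
  roles <- c("signature", "decoration", "flanking-core", "decoration",
             "flanking-core", "flanking-core")
  groups <- ifelse(roles == "flanking-core",
                   sprintf("COG%d", seq_along(roles)), NA)
  genes <- mk_genes(roles, groups)
  core <- groups[!is.na(groups)]
  for (sr in 1:2) {
    cl <- delimit_cluster("g01", genes, core, stop_run = sr)
    oracle <- brute_delimit(1, !is.na(groups), sr)
    expect_setequal(cl$members$gene_id, genes$gene_id[oracle])
  }
  # stop_run = 1 truncates at the single inserted core gene; 2 passes it
  m1 <- delimit_cluster("g01", genes, core, stop_run = 1)$members$gene_id
  m2 <- delimit_cluster("g01", genes, core, stop_run = 2)$members$gene_id
  expect_false(setequal(m1, m2))
})

test_that("delimitation matches the oracle over random layouts", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(6:16, 1)
      core_flag <- runif(n) < 0.45
      core_flag[sample(n, 1)] <- FALSE  # at least one accessory gene
      acc <- which(!core_flag)
      sig <- if (length(acc) == 1) acc else sample(acc, 1)
      roles <- ifelse(core_flag, "flanking-core", "decoration")
      roles[sig] <- "signature"
      groups <- ifelse(core_flag, sprintf("COG%d", seq_len(n)), NA)
      genes <- mk_genes(roles, groups)
      sr <- sample(1:3, 1)
      cl <- delimit_cluster(genes$gene_id[sig], genes,
                            groups[!is.na(groups)], stop_run = sr)
      oracle <- brute_delimit(sig, core_flag, sr)
      expect_setequal(cl$members$gene_id, genes$gene_id[oracle])
      # boundaries never cross the contig
      expect_gte(cl$boundary[["start"]], 0)
    }
  })
})

test_that("repeat/CDS accounting matches a brute-force intersection oracle", {
  # arithmetic contracts first
  cl <- structure(list(cluster_id = "x", contig = "c1",
                       boundary = c(start = 0L, end = 30000L)),
                  class = "cluster_model")
  masked <- data.frame(contig = "c1", start = 0L, end = 5000L)
  genes <- data.frame(contig = "c1", cds_start = 10000L, cds_end = 15000L)
  out <- cluster_repeat_cds_logratio(cl, masked, genes)
  expect_equal(out$log_ratio, 0)
  masked2 <- data.frame(contig = "c1", start = c(0L, 10000L),
                        end = c(5000L, 25000L))
  genes2 <- data.frame(contig = "c1", cds_start = 26000L, cds_end = 28000L)
  out2 <- cluster_repeat_cds_logratio(cl, masked2, genes2)
  expect_equal(out2$log_ratio, 1)
  # zero CDS -> undefined, flagged
  out3 <- cluster_repeat_cds_logratio(cl, masked, genes2[0, ])
  expect_false(out3$log_ratio_defined)
  # random clusters against a bit-vector oracle
  withr::with_seed(32, {
    for (rep in 1:20) {
      L <- 5000L
      b <- sort(sample(0:L, 2))
      cl <- structure(list(cluster_id = "r", contig = "c1",
                           boundary = c(start = b[1], end = b[2])),
                      class = "cluster_model")
      nm <- sample(1:6, 1); ng <- sample(1:6, 1)
      ms <- sort(sample(0:(L - 10), nm)); me <- pmin(L, ms + sample(5:500, nm))
      gs <- sort(sample(0:(L - 10), ng)); ge <- pmin(L, gs + sample(5:500, ng))
      masked <- data.frame(contig = "c1", start = ms, end = me)
      genes <- data.frame(contig = "c1", cds_start = gs, cds_end = ge)
      out <- cluster_repeat_cds_logratio(cl, masked, genes)
      expect_equal(out$repeat_bp,
                   brute_intersect_bp(ms, me, b[1], b[2], L))
      expect_equal(out$cds_bp,
                   brute_intersect_bp(gs, ge, b[1], b[2], L))
      # repeat bp and CDS bp each never exceed the boundary length
      expect_lte(out$repeat_bp, b[2] - b[1])
      expect_lte(out$cds_bp, b[2] - b[1])
    }
  })
})

test_that("functional status depends only on signature-gene integrity", {
  roles <- c("flanking-core", "signature", "decoration", "flanking-core",
             "flanking-core")
  groups <- ifelse(roles == "flanking-core",
                   sprintf("COG%d", seq_along(roles)), NA)
  genes <- mk_genes(roles, groups)
  core <- groups[!is.na(groups)]
  # intact signature, pseudogenised accessory -> active
  genes$pseudogene[3] <- TRUE
  cl <- assess_functional_status(delimit_cluster("g02", genes, core))
  expect_equal(cl$functional_status, "active")
  # pseudogene signature -> inactive
  genes$pseudogene[2] <- TRUE
  cl2 <- assess_functional_status(delimit_cluster("g02", genes, core))
  expect_equal(cl2$functional_status, "inactive")
  # two signature genes, one intact -> active
  genes3 <- genes
  genes3$domains[3] <- "IPR013968"
  genes3$pseudogene[3] <- FALSE
  cl3 <- assess_functional_status(delimit_cluster("g02", genes3, core))
  expect_equal(cl3$functional_status, "active")
})

test_that("the layout statistic is antisymmetric and extreme for edge decorations", {
  # decorations at both ends, skeletons centred: maximal statistic
  r <- c("decoration", "decoration", "skeleton", "skeleton", "skeleton",
         "skeleton", "decoration", "decoration")
  out <- core_periphery_layout(r, n_perm = 499, seed = 1)
  # exhaustive check: no permutation exceeds the observed statistic
  pos <- seq_along(r); centre <- (length(r) + 1) / 2
  periph <- abs(pos - centre) / (length(r) - 1) * 2
  combs <- utils::combn(length(r), sum(r == "decoration"))
  stats <- apply(combs, 2, function(dec)
    mean(periph[dec]) - mean(periph[-dec]))
  expect_equal(out$statistic, max(stats))
  expect_lte(out$p_value, 0.05)
  # alternating roles: statistic ~ 0
  r2 <- rep(c("skeleton", "decoration"), 4)
  out2 <- core_periphery_layout(r2, n_perm = 199, seed = 1)
  expect_lt(abs(out2$statistic), 0.2)
  # sign flips when labels are swapped
  r3 <- ifelse(r == "skeleton", "decoration", "skeleton")
  out3 <- core_periphery_layout(r3, n_perm = 199, seed = 1)
  expect_equal(out3$statistic, -out$statistic)
  # a missing role is undefined, flagged
  out4 <- core_periphery_layout(rep("skeleton", 5))
  expect_false(out4$defined)
})

test_that("planted cluster boundaries are recovered within one gene", {
  ok <- 0L; n_rep <- 12L
  for (sd in seq_len(n_rep)) {
    sim <- generate_genome(cluster_recipe(seed = 200 + sd))
    genes <- sim$genes
    groups <- data.frame(genome = "self", gene_id = genes$gene_id,
                         group_id = genes$ortholog_group)
    core <- core_ortholog_set(groups[!is.na(groups$group_id), ])
    sig <- find_signature_genes(genes)
    cl <- delimit_cluster(sig$gene_id[1], genes, core)
    truth <- sim$truth$clusters
    gn <- genes[genes$contig == truth$contig, ]
    gn <- gn[order(gn$start), ]
    # within +-1 gene: boundary endpoints within one gene position of truth
    lo_idx <- function(x) findInterval(x, gn$start)
    if (abs(lo_idx(cl$boundary[["start"]]) - lo_idx(truth$start)) <= 1 &&
        abs(lo_idx(cl$boundary[["end"]] - 1) - lo_idx(truth$end - 1)) <= 1) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.9)
})
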