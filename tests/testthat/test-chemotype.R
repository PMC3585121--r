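rulesets <- load_rulesets()
genotypes <- read_genotypes(
  system.file("extdata", "strain_genotypes.tsv", package = "alkaloci"),
  rulesets)

test_that("rule-set catalogs carry the documented gene sets and are acyclic", {
  expect_equal(length(rulesets$EAS$catalog), 14)
  expect_equal(length(rulesets$LOL$catalog), 11)
  expect_equal(length(rulesets$IDT$catalog), 11)
  expect_equal(rulesets$PER$catalog, "perA")
  expect_true(all(c("dmaW", "easF", "easE", "easC", "easO", "easP", "lpsA",
                    "lpsB", "lpsC", "easH") %in% rulesets$EAS$catalog))
  expect_true(all(c("lolN", "lolM", "lolP", "lolO") %in%
                    rulesets$LOL$catalog))
  expect_error(load_ruleset("XYZ"), "unknown pathway")
})

test_that("a genotype lacking only lpsA and easH makes EN and LAH but no ergopeptine", {
  p <- predict_chemotype(genotypes$Ngi, rulesets)$pathways$EAS
  expect_true(all(c("EN", "LAH") %in% p$producible))
  expect_false("ergopeptine" %in% p$producible)
  expect_setequal(p$blocked_at$ergopeptine, c("lpsA", "easH"))
})

test_that("a genotype lacking lpsC makes an ergopeptine but not EN or LAH", {
  p <- predict_chemotype(genotypes$Ef1, rulesets)$pathways$EAS
  expect_true("ergopeptine" %in% p$producible)
  expect_false("EN" %in% p$producible)
  expect_false("LAH" %in% p$producible)
  expect_equal(p$blocked_at$EN, "lpsC")
})

test_that("only the first four pathway genes accumulate chanoclavine-I", {
  for (g in c("Eel", "Ebe")) {
    p <- predict_chemotype(genotypes[[g]], rulesets)$pathways$EAS
    expect_equal(p$frontier, "CC")
  }
  gt <- genotype_profile("toy", data.frame(
    gene = c("dmaW", "easF", "easE", "easC"), status = "functional"),
    rulesets)
  expect_equal(predict_chemotype(gt, rulesets)$pathways$EAS$frontier, "CC")
})

test_that("an inactive lolO accumulates AcAP", {
  p <- predict_chemotype(genotypes$Ebe, rulesets)$pathways$LOL
  expect_equal(p$frontier, "AcAP")
  expect_equal(p$blocked_at$NANL, "lolO")
})

test_that("perA without its reductase domain yields no peramine", {
  expect_equal(
    predict_chemotype(genotypes$Ef2, rulesets)$pathways$PER$producible,
    character(0))
  expect_equal(
    predict_chemotype(genotypes$Ef1, rulesets)$pathways$PER$frontier, "PER")
})

test_that("removing a functional gene never adds a producible product", {
  for (pw in c("EAS", "LOL", "IDT", "PER")) {
    rs <- rulesets[pw]
    full <- genotype_profile("full", data.frame(
      gene = rulesets[[pw]]$catalog, status = "functional"), rs)
    base <- predict_chemotype(full, rs)$pathways[[pw]]$producible
    for (gene in rulesets[[pw]]$catalog) {
      st <- ifelse(rulesets[[pw]]$catalog == gene, "absent", "functional")
      gt <- genotype_profile("less", data.frame(
        gene = rulesets[[pw]]$catalog, status = st), rs)
      less <- predict_chemotype(gt, rs)$pathways[[pw]]$producible
      expect_true(all(less %in% base))
    }
  }
})

test_that("producibility is upward-closed along the dependency graph", {
  for (g in names(genotypes)) {
    pred <- predict_chemotype(genotypes[[g]], rulesets)
    for (pw in names(pred$pathways)) {
      prods <- rulesets[[pw]]$products
      parent <- setNames(vapply(prods, function(p)
        if (is.null(p$parent)) NA_character_ else p$parent, ""),
        vapply(prods, `[[`, "", "id"))
      for (pr in pred$pathways[[pw]]$producible) {
        pa <- parent[[pr]]
        if (!is.na(pa)) {
          expect_true(pa %in% pred$pathways[[pw]]$producible)
        }
      }
    }
  }
})

test_that("full catalogs give the whole product set; empty genotypes give none", {
  for (pw in c("EAS", "LOL", "IDT", "PER")) {
    all_ids <- vapply(rulesets[[pw]]$products, `[[`, "", "id")
    full <- genotype_profile("full", data.frame(
      gene = rulesets[[pw]]$catalog, status = "functional"), rulesets[pw])
    expect_setequal(
      predict_chemotype(full, rulesets[pw])$pathways[[pw]]$producible,
      all_ids)
    empty <- genotype_profile("none", data.frame(
      gene = rulesets[[pw]]$catalog, status = "absent"), rulesets[pw])
    expect_equal(
      predict_chemotype(empty, rulesets[pw])$pathways[[pw]]$producible,
      character(0))
  }
})

test_that("predictions are concordant with the observed alkaloid profiles", {
  exp_path <- system.file("extdata", "chemotype_expectations.tsv",
                          package = "alkaloci")
  expectations <- read.table(exp_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cc <- check_chemotype_concordance(genotypes, expectations, rulesets)
  expect_true(all(cc$consistent))
  # the non-expressed-cluster case is present and flagged
  expect_true(any(cc$expected_discordant))
})

test_that("ergopeptine multiplicity follows lpsA copy number", {
  expect_equal(ergopeptine_count(genotypes$Cpu, rulesets = rulesets), 2L)
  expect_equal(ergopeptine_count(genotypes$Ef1, rulesets = rulesets), 1L)
  expect_equal(ergopeptine_count(genotypes$Ngi, rulesets = rulesets), 0L)
})

test_that("unknown gene names are warned about and ignored", {
  expect_warning(
    gt <- genotype_profile("x", data.frame(gene = c("dmaW", "nope"),
                                           status = "functional"), rulesets),
    "nope")
  expect_equal(gt$unknown_genes, "nope")
  # ltm aliases map onto the idt catalog
  gt2 <- genotype_profile("y", data.frame(gene = c("ltmE", "ltmJ"),
                                          status = "functional"), rulesets)
  expect_setequal(names(gt2$status), c("idtE", "idtJ"))
})

test_that("the elymoclavine oxidase toggle relaxes the cloA requirement", {
  gt <- genotype_profile("cfu_like", data.frame(
    gene = c("dmaW", "easF", "easE", "easC", "easD", "easA", "easG"),
    status = "functional"), rulesets)
  default <- predict_chemotype(gt, rulesets)$pathways$EAS
  expect_equal(default$frontier, "agroclavine")
  rs2 <- load_rulesets(options = list(EAS = list(ec_oxidase = "unknown")))
  gt2 <- genotype_profile("cfu_like", data.frame(
    gene = c("dmaW", "easF", "easE", "easC", "easD", "easA", "easG"),
    status = "functional"), rs2)
  relaxed <- predict_chemotype(gt2, rs2)$pathways$EAS
  expect_true("EC" %in% relaxed$producible)
})
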