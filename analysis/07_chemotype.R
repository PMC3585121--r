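#!/usr/bin/env Rscript
# Genotype -> chemotype prediction for the 16 published strain genotypes:
# per-pathway producible products, accumulating end products, blocking
# genes, ergopeptine multiplicity from lpsA copy number, and the
# concordance check against the observed alkaloid profiles. Writes
# results/chemotype/.

suppressMessages(library(alkaloci))

out <- "results/chemotype"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rulesets <- load_rulesets()
genotypes <- read_genotypes(
  system.file("extdata", "strain_genotypes.tsv", package = "alkaloci"),
  rulesets)

rows <- list()
for (g in names(genotypes)) {
  pred <- predict_chemotype(genotypes[[g]], rulesets)
  for (pw in names(pred$pathways)) {
    fr <- pred$pathways[[pw]]$frontier
    rows[[paste(g, pw)]] <- data.frame(
      genome = g, pathway = pw,
      end_products = if (length(fr)) paste(fr, collapse = "+") else "none",
      producible = paste(pred$pathways[[pw]]$producible, collapse = ","))
  }
  cat(sprintf("%-4s EAS:%-18s IDT:%-10s LOL:%-6s PER:%s  ergopeptines:%d\n",
              g,
              paste(pred$pathways$EAS$frontier, collapse = "+"),
              paste(pred$pathways$IDT$frontier, collapse = "+"),
              paste(pred$pathways$LOL$frontier, collapse = "+"),
              paste(pred$pathways$PER$frontier, collapse = "+"),
              ergopeptine_count(genotypes[[g]], pred, rulesets)))
}
write.table(do.call(rbind, rows), file.path(out, "predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

expectations <- read.table(
  system.file("extdata", "chemotype_expectations.tsv", package = "alkaloci"),
  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
cc <- check_chemotype_concordance(genotypes, expectations, rulesets)
write.table(cc, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("concordance with observed profiles: %d/%d rows consistent\n",
            sum(cc$consistent), nrow(cc)))
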