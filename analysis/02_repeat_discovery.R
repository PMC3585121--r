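#!/usr/bin/env Rscript
# De novo repeat discovery on both synthetic genomes: self-alignment,
# family clustering, masking, genome partition/GC accounting, and the
# cross-genome repeat correspondence matrix. Compares the recovered copies
# against the generator truth and writes the partition table (cf. the
# genic/repeat content and GC accounting of real assemblies) and the
# universal repeat number assignment under results/repeats/.

suppressMessages(library(alkaloci))

gdir <- "results/genomes"
out <- "results/repeats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

libs <- list()
for (gid in c("synthA", "synthB")) {
  genome <- Biostrings::readDNAStringSet(file.path(gdir, gid, "genome.fasta"))
  genes <- read_gff3_genes(file.path(gdir, gid, "genes.gff3"))
  res <- discover_repeats(genome)
  libs[[gid]] <- res$library
  truth <- read.table(file.path(gdir, gid, "truth_repeats.tsv"),
                      header = TRUE, sep = "\t")
  tp <- intersect_bp(truth$start, truth$end, res$copies$start,
                     res$copies$end)
  cat(sprintf("%s: %d families, %d copies; bp recall %.3f, precision %.3f\n",
              gid, length(res$library$families), nrow(res$copies),
              tp / union_bp(truth$start, truth$end),
              tp / union_bp(res$copies$start, res$copies$end)))
  st <- partition_stats(genome, genes, res$copies)
  write.table(cbind(genome = gid, st$summary),
              file.path(out, paste0(gid, "_partition.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$copies, file.path(out, paste0(gid, "_copies.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(round(st$summary, 3))
}

co <- correspond_families(libs)
write.table(co$assignment, file.path(out, "correspondence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("universal repeat numbers:\n")
print(co$assignment)
shared <- co$assignment$universal[duplicated(co$assignment$universal)]
cat(sprintf("families shared across genomes: %d universal number(s)\n",
            length(unique(shared))))
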