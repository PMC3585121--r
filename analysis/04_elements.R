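#!/usr/bin/env Rscript
# Structural elements: MITE classification of the discovered repeat families
# (exemplar length bounds + terminal inverted repeats) and terminal telomere
# array detection, with distances from each SM signature gene to the nearest
# telomere. Writes results/elements/.

suppressMessages(library(alkaloci))

gdir <- "results/genomes"
out <- "results/elements"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (gid in c("synthA", "synthB")) {
  genome <- Biostrings::readDNAStringSet(file.path(gdir, gid, "genome.fasta"))
  genes <- read_gff3_genes(file.path(gdir, gid, "genes.gff3"))
  res <- discover_repeats(genome)
  mites <- call_mites(res$library, res$copies)
  write.table(mites$families, file.path(out, paste0(gid, "_mite_families.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mites$calls, file.path(out, paste0(gid, "_mite_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tel <- detect_telomeres(genome)
  write.table(tel, file.path(out, paste0(gid, "_telomeres.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(gid, ":", sum(mites$families$is_mite), "MITE families,",
      nrow(mites$calls), "MITE copies,", nrow(tel), "telomere arrays\n")
  sig <- find_signature_genes(genes)
  if (nrow(sig)) {
    sig$telomere_bp <- vapply(seq_len(nrow(sig)), function(k)
      as.numeric(distance_to_telomere(sig$contig[k], sig$start[k],
                                      sig$end[k], tel)), 0)
    cat("signature gene telomere distances (bp):\n")
    print(sig[, c("gene_id", "classes", "telomere_bp")])
  }
}
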