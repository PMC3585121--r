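#!/usr/bin/env Rscript
# Simulate the pair of synthetic epichloid-style genomes used throughout the
# analysis: genome A carries two transposon relic families (one RIP-mutated,
# with nested insertions), a MITE family, telomere arrays, and a PKS-anchored
# SM cluster pinned near a telomere; genome B shares one repeat family with A
# (planted from the same exemplar) so that cross-genome correspondence has a
# known answer. Writes FASTA/GFF3/truth tables under results/genomes/.

suppressMessages(library(alkaloci))

out <- "results/genomes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rec_a <- genome_recipe(
  seed = 101, genome_id = "synthA",
  contigs = data.frame(name = c("sc1", "sc2"), length = c(600000, 300000)),
  base_gc = 0.45, gene_density = 0.25,
  te_families = list(
    te_family("Tahi", 3000, copies = 8, sub_rate = 0.03, rip_rate = 0.4,
              nesting_prob = 0.3),
    te_family("Waru", 1200, copies = 6, sub_rate = 0.02)),
  mite_specs = list(mite_spec("m8", c(150, 350), tir_length = 25,
                              copies = 8)),
  telomeres = telomere_spec(ends = data.frame(
    contig = c("sc1", "sc2"), end = c("right", "right"))),
  clusters = list(cluster_spec(
    "EASlike", "sc1",
    roles = c("flanking-core", "flanking-core", "decoration", "skeleton",
              "skeleton", "signature", "skeleton", "decoration",
              "flanking-core", "flanking-core"),
    repeat_blocks = c(0, 0, 800, 0, 0, 800, 0, 0, 0),
    telomere_distance = 15000, signature_class = "NRPS")))
sim_a <- generate_genome(rec_a)
write_genome(sim_a, file.path(out, "synthA"))

shared <- sim_a$truth$exemplars$sequence[
  sim_a$truth$exemplars$family == "Waru"]
rec_b <- genome_recipe(
  seed = 202, genome_id = "synthB",
  contigs = data.frame(name = "sc1", length = 400000),
  base_gc = 0.45, gene_density = 0.25,
  te_families = list(
    te_family("WaruB", exemplar = shared, copies = 5, sub_rate = 0.03),
    te_family("Toru", 2000, copies = 5, sub_rate = 0.02, rip_rate = 0.3)),
  telomeres = telomere_spec(ends = data.frame(contig = "sc1",
                                              end = "left")),
  clusters = list(cluster_spec(
    "PKSlike", "sc1",
    roles = c("flanking-core", "flanking-core", "decoration", "signature",
              "skeleton", "decoration", "flanking-core", "flanking-core"),
    repeat_blocks = c(0, 0, 600, 0, 0, 0, 0),
    signature_class = "PKS", signature_pseudogene = TRUE)))
sim_b <- generate_genome(rec_b)
write_genome(sim_b, file.path(out, "synthB"))

for (s in list(sim_a, sim_b)) {
  cat(sprintf(
    "%s: %d contigs, %d bp, %d genes, %d planted repeat copies, %d MITEs, %d telomeres, %d clusters\n",
    s$recipe$genome_id, length(s$genome), sum(BiocGenerics::width(s$genome)),
    nrow(s$genes), nrow(s$truth$repeats), nrow(s$truth$mites),
    nrow(s$truth$telomeres), nrow(s$truth$clusters)))
}
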