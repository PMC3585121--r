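# Synthetic genomes with known ground truth.
#
# The generator emulates the structural features of epichloid (and related
# clavicipitaceous) genome assemblies that the downstream analyses assume:
# multicopy transposon relics (optionally nested into one another), RIP-mutated
# AT-rich repeat copies, MITEs with terminal inverted repeats, terminal
# telomere-repeat arrays, and clustered secondary-metabolism genes with a
# conserved-core / variable-periphery layout flanked by repeat blocks. All
# coordinates in the emitted truth tables are 0-based half-open; GFF3 output
# converts to 1-based inclusive.

#' Transposable-element family specification
#'
#' @param id family identifier (character).
#' @param length element length in bp.
#' @param copies number of genomic copies (>= 1).
#' @param sub_rate per-copy random substitution rate in `[0, 1]`.
#' @param rip_rate per-copy RIP mutation rate in `[0, 1]` (see [apply_rip()]).
#' @param nesting_prob probability that a copy (other than the first) is
#'   inserted inside a previously placed copy instead of the background.
#' @param exemplar optional explicit exemplar sequence; when supplied it
#'   overrides `length` and allows the same family to be planted in several
#'   genomes.
#' @return An object of class `te_family_spec`.
#' @export
te_family <- function(id, length = 3000, copies = 5, sub_rate = 0.02,
                      rip_rate = 0, nesting_prob = 0, exemplar = NULL) {
  stopifnot(copies >= 1, sub_rate >= 0, sub_rate <= 1,
            rip_rate >= 0, rip_rate <= 1,
            nesting_prob >= 0, nesting_prob <= 1)
  if (!is.null(exemplar)) length <- nchar(exemplar)
  stopifnot(length > 0)
  structure(list(id = id, length = length, copies = copies,
                 sub_rate = sub_rate, rip_rate = rip_rate,
                 nesting_prob = nesting_prob, exemplar = exemplar),
            class = "te_family_spec")
}

#' MITE family specification
#'
#' @param id family identifier.
#' @param length_range total element length bounds `c(min, max)` in bp.
#' @param tir_length terminal-inverted-repeat arm length in bp.
#' @param tir_identity identity fraction between the two TIR arms.
#' @param copies number of genomic copies.
#' @return An object of class `mite_spec`.
#' @export
mite_spec <- function(id, length_range = c(150, 400), tir_length = 25,
                      tir_identity = 1.0, copies = 5) {
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            2 * tir_length <= length_range[1],
            tir_identity >= 0, tir_identity <= 1, copies >= 1)
  structure(list(id = id, length_range = length_range,
                 tir_length = tir_length, tir_identity = tir_identity,
                 copies = copies),
            class = "mite_spec")
}

#' Telomere array specification
#'
#' @param motif telomere repeat unit (default the canonical `TTAGGG`).
#' @param copies tandem copy count, a single value or a `c(min, max)` range.
#' @param ends data.frame with columns `contig` and `end` (`"left"` or
#'   `"right"`) naming the contig termini that carry arrays. Left-end arrays
#'   are written as the reverse complement of the motif, as on a chromosome
#'   5' end.
#' @return An object of class `telomere_spec`.
#' @export
telomere_spec <- function(motif = "TTAGGG", copies = c(8, 15), ends) {
  stopifnot(nchar(motif) >= 4, all(copies >= 1),
            is.data.frame(ends), all(c("contig", "end") %in% names(ends)),
            all(ends$end %in% c("left", "right")))
  structure(list(motif = toupper(motif), copies = copies, ends = ends),
            class = "telomere_spec")
}

#' Secondary-metabolism cluster specification
#'
#' `roles` gives the ordered gene roles along the cluster. Exactly one
#' `"signature"` gene is required; `"skeleton"` genes stand for the conserved
#' early-pathway core, `"decoration"` genes for the variable periphery, and
#' `"flanking-core"` genes for the primary-metabolism orthologs that bound the
#' cluster on either side.
#'
#' @param id cluster identifier.
#' @param contig name of the contig carrying the cluster.
#' @param roles ordered character vector over
#'   `{"flanking-core", "skeleton", "decoration", "signature"}`.
#' @param repeat_blocks lengths (bp) of repeat blocks inserted between
#'   consecutive genes, recycled over the gaps; `0` means no block.
#' @param telomere_distance bp of background between the cluster segment and
#'   the right-end telomere array of its contig, or `NA` for unconstrained
#'   placement.
#' @param signature_class signature gene class, one of `"PKS"`, `"NRPS"`,
#'   `"DMATS"`, `"TS"`.
#' @param signature_pseudogene logical; plant the signature gene as a
#'   pseudogene (an inactivated cluster).
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(id, contig,
                         roles = c("flanking-core", "flanking-core",
                                   "decoration", "skeleton", "signature",
                                   "skeleton", "decoration",
                                   "flanking-core", "flanking-core"),
                         repeat_blocks = 0, telomere_distance = NA,
                         signature_class = "PKS",
                         signature_pseudogene = FALSE) {
  stopifnot(length(roles) >= 1,
            all(roles %in% c("flanking-core", "skeleton", "decoration",
                             "signature")),
            sum(roles == "signature") == 1,
            signature_class %in% c("PKS", "NRPS", "DMATS", "TS"))
  structure(list(id = id, contig = contig, roles = roles,
                 repeat_blocks = repeat_blocks,
                 telomere_distance = telomere_distance,
                 signature_class = signature_class,
                 signature_pseudogene = signature_pseudogene),
            class = "cluster_spec")
}

#' Genome recipe
#'
#' A complete, seed-deterministic description of a synthetic genome. The seed
#' fully determines the output of [generate_genome()].
#'
#' @param seed integer RNG seed.
#' @param contigs data.frame with columns `name` and `length` (bp).
#' @param base_gc background GC fraction.
#' @param gene_density background housekeeping genes per kb.
#' @param te_families list of [te_family()] specs.
#' @param mite_specs list of [mite_spec()] specs.
#' @param telomeres a [telomere_spec()] or `NULL`.
#' @param clusters list of [cluster_spec()] specs.
#' @param genome_id label used in gene and group identifiers.
#' @return An object of class `genome_recipe`.
#' @export
genome_recipe <- function(seed, contigs, base_gc = 0.45, gene_density = 0.25,
                          te_families = list(), mite_specs = list(),
                          telomeres = NULL, clusters = list(),
                          genome_id = "synthA") {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.data.frame(contigs), all(c("name", "length") %in% names(contigs)),
            all(contigs$length > 0), !anyDuplicated(contigs$name),
            base_gc >= 0, base_gc <= 1, gene_density >= 0)
  for (sp in te_families) stopifnot(inherits(sp, "te_family_spec"))
  for (sp in mite_specs) stopifnot(inherits(sp, "mite_spec"))
  for (sp in clusters) {
    stopifnot(inherits(sp, "cluster_spec"), sp$contig %in% contigs$name)
  }
  if (!is.null(telomeres)) {
    stopifnot(inherits(telomeres, "telomere_spec"),
              all(telomeres$ends$contig %in% contigs$name))
  }
  structure(list(seed = as.integer(seed), contigs = contigs, base_gc = base_gc,
                 gene_density = gene_density, te_families = te_families,
                 mite_specs = mite_specs, telomeres = telomeres,
                 clusters = clusters, genome_id = genome_id),
            class = "genome_recipe")
}

#' Apply RIP-style C-to-T transition mutations to a sequence
#'
#' Models repeat-induced point mutation in the dominant CpA/TpG dinucleotide
#' context: each C in a CpA context on the forward strand is mutated to T with
#' probability `rate`, and independently each C in a CpA context on the
#' reverse strand (seen on the forward strand as the G of TpG, mutated to A)
#' with the same probability. A single pass over the original sequence is
#' made; no other positions change and the length is preserved. Ambiguity
#' codes pass through unmodified.
#'
#' @param seq nucleotide character scalar.
#' @param rate per-site mutation probability in `[0, 1]`.
#' @return Mutated character scalar of identical length.
#' @export
apply_rip <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- nchar(seq)
  if (n < 2 || rate == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  ca <- which(s[-n] == "C" & s[-1] == "A")       # C of forward-strand CpA
  tg <- which(s[-n] == "T" & s[-1] == "G") + 1L  # G of TpG (revstrand CpA)
  ca <- ca[runif(length(ca)) < rate]
  tg <- tg[runif(length(tg)) < rate]
  s[ca] <- "T"
  s[tg] <- "A"
  paste(s, collapse = "")
}

# ---- internal feature machinery ---------------------------------------------

MIN_FEATURE_GAP <- 60L

empty_repeat_truth <- function() {
  data.frame(family = character(), copy_id = character(), start = integer(),
             end = integer(), strand = character(), rip_rate = numeric(),
             nested_in = character(), segment = integer(),
             stringsAsFactors = FALSE)
}

empty_gene_truth <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             cds_start = integer(), cds_end = integer(), strand = character(),
             pseudogene = logical(), domains = character(),
             ortholog_group = character(), role = character(),
             cluster_id = character(), stringsAsFactors = FALSE)
}

new_feature <- function(type, seq, repeats = empty_repeat_truth(),
                        mites = NULL, genes = empty_gene_truth(),
                        clusters = NULL) {
  list(type = type, seq = seq, len = nchar(seq), repeats = repeats,
       mites = mites %||% data.frame(family = character(), copy_id = character(),
                                     start = integer(), end = integer(),
                                     tir_length = integer(),
                                     stringsAsFactors = FALSE),
       genes = genes,
       clusters = clusters %||% data.frame(cluster_id = character(),
                                           start = integer(), end = integer(),
                                           signature_class = character(),
                                           stringsAsFactors = FALSE))
}

signature_domain_example <- c(PKS = "IPR013968", NRPS = "IPR010071",
                              DMATS = "IPR017795", TS = "IPR008949")

make_gene_feature <- function(gene_id, role, ortholog_group = NA_character_,
                              domains = NA_character_, pseudogene = FALSE,
                              cluster_id = NA_character_, gc = 0.55) {
  cds_len <- 3L * sample(300:800, 1L)  %/% 3L
  utr <- 100L
  seq <- paste0(random_seq(utr, gc - 0.05), random_seq(cds_len, gc),
                random_seq(utr, gc - 0.05))
  genes <- data.frame(gene_id = gene_id, start = 0L, end = nchar(seq),
                      cds_start = utr, cds_end = utr + cds_len,
                      strand = sample(c("+", "-"), 1L),
                      pseudogene = pseudogene, domains = domains,
                      ortholog_group = ortholog_group, role = role,
                      cluster_id = cluster_id, stringsAsFactors = FALSE)
  new_feature("gene", seq, genes = genes)
}

make_te_copy_feature <- function(spec, exemplar, copy_idx, base_gc) {
  seq <- mutate_seq(exemplar, spec$sub_rate)
  seq <- apply_rip(seq, spec$rip_rate)
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") seq <- revcomp(seq)
  copy_id <- sprintf("%s_c%02d", spec$id, copy_idx)
  rep_truth <- data.frame(family = spec$id, copy_id = copy_id, start = 0L,
                          end = nchar(seq), strand = strand,
                          rip_rate = spec$rip_rate, nested_in = NA_character_,
                          segment = 1L, stringsAsFactors = FALSE)
  new_feature("te", seq, repeats = rep_truth)
}

make_mite_copy_feature <- function(spec, exemplar, copy_idx) {
  seq <- mutate_seq(exemplar, 0.01)
  copy_id <- sprintf("%s_c%02d", spec$id, copy_idx)
  mites <- data.frame(family = spec$id, copy_id = copy_id, start = 0L,
                      end = nchar(seq), tir_length = spec$tir_length,
                      stringsAsFactors = FALSE)
  # MITEs are multicopy short repeats: record them in the repeat truth too
  reps <- data.frame(family = spec$id, copy_id = copy_id, start = 0L,
                     end = nchar(seq), strand = "+", rip_rate = 0,
                     nested_in = NA_character_, segment = 1L,
                     stringsAsFactors = FALSE)
  new_feature("mite", seq, repeats = reps, mites = mites)
}

make_mite_exemplar <- function(spec) {
  tir <- random_seq(spec$tir_length, 0.5)
  right <- revcomp(tir)
  n_mm <- round((1 - spec$tir_identity) * spec$tir_length)
  if (n_mm > 0) {
    s <- strsplit(right, "", fixed = TRUE)[[1]]
    idx <- sample(seq_along(s), n_mm)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    right <- paste(s, collapse = "")
  }
  total <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  loop <- random_seq(total - 2L * spec$tir_length, 0.35)
  paste0(tir, loop, right)
}

# Build a composite feature for a whole SM cluster segment.
make_cluster_feature <- function(spec, genome_id, block_exemplar,
                                 block_family_id, base_gc, core_counter) {
  pieces <- character()
  offset <- 0L
  genes <- empty_gene_truth()
  reps <- empty_repeat_truth()
  n_genes <- length(spec$roles)
  blocks <- rep_len(spec$repeat_blocks, max(n_genes - 1L, 0L))
  acc_i <- 0L
  block_i <- 0L
  for (i in seq_len(n_genes)) {
    role <- spec$roles[i]
    if (role == "flanking-core") {
      core_counter$n <- core_counter$n + 1L
      og <- sprintf("COG%04d", core_counter$n)
      gene_id <- sprintf("%s_%s_flank%d", genome_id, spec$id, core_counter$n)
      f <- make_gene_feature(gene_id, "flanking-core", ortholog_group = og,
                             cluster_id = spec$id)
    } else {
      acc_i <- acc_i + 1L
      gene_id <- sprintf("%s_%s_g%02d", genome_id, spec$id, acc_i)
      dom <- if (role == "signature")
        signature_domain_example[[spec$signature_class]] else NA_character_
      pg <- role == "signature" && spec$signature_pseudogene
      f <- make_gene_feature(gene_id, role, ortholog_group = NA_character_,
                             domains = dom, pseudogene = pg,
                             cluster_id = spec$id)
    }
    g <- f$genes
    g$start <- g$start + offset; g$end <- g$end + offset
    g$cds_start <- g$cds_start + offset; g$cds_end <- g$cds_end + offset
    genes <- rbind(genes, g)
    pieces <- c(pieces, f$seq)
    offset <- offset + f$len
    if (i < n_genes) {
      spacer <- random_seq(sample(150:400, 1L), base_gc)
      pieces <- c(pieces, spacer)
      offset <- offset + nchar(spacer)
      bl <- blocks[i]
      if (bl > 0) {
        block_i <- block_i + 1L
        bseq <- substr(block_exemplar, 1L,
                       min(bl, nchar(block_exemplar)))
        bseq <- apply_rip(mutate_seq(bseq, 0.02), 0.3)
        copy_id <- sprintf("%s_%s_blk%02d", genome_id, spec$id, block_i)
        reps <- rbind(reps, data.frame(family = block_family_id,
                                       copy_id = copy_id, start = offset,
                                       end = offset + nchar(bseq),
                                       strand = "+", rip_rate = 0.3,
                                       nested_in = NA_character_, segment = 1L,
                                       stringsAsFactors = FALSE))
        pieces <- c(pieces, bseq)
        offset <- offset + nchar(bseq)
        spacer <- random_seq(sample(150:400, 1L), base_gc)
        pieces <- c(pieces, spacer)
        offset <- offset + nchar(spacer)
      }
    }
  }
  member <- genes$role != "flanking-core"
  clusters <- data.frame(cluster_id = spec$id,
                         start = min(genes$start[member]),
                         end = max(genes$end[member]),
                         signature_class = spec$signature_class,
                         stringsAsFactors = FALSE)
  new_feature("cluster", paste(pieces, collapse = ""), repeats = reps,
              genes = genes, clusters = clusters)
}

# Insert `insert` feature into `host` at internal cut point; truth rows of the
# host that span the cut are split into two segments sharing the copy id.
insert_into_feature <- function(host, insert, cut) {
  shift_split <- function(df) {
    if (nrow(df) == 0) return(df)
    ins_len <- insert$len
    out <- df[0, ]
    for (k in seq_len(nrow(df))) {
      r <- df[k, ]
      if (r$end <= cut) {
        out <- rbind(out, r)
      } else if (r$start >= cut) {
        r$start <- r$start + ins_len; r$end <- r$end + ins_len
        out <- rbind(out, r)
      } else {
        r1 <- r; r1$end <- cut
        r2 <- r; r2$start <- cut + ins_len; r2$end <- r$end + ins_len
        if (!is.null(r$segment)) { r2$segment <- r$segment + 1L }
        out <- rbind(out, r1, r2)
      }
    }
    out
  }
  host_len <- host$len
  stopifnot(cut > 0, cut < host_len)
  host$repeats <- shift_split(host$repeats)
  host$mites <- shift_split(host$mites)
  ins_reps <- insert$repeats
  if (nrow(ins_reps)) {
    ins_reps$start <- ins_reps$start + cut
    ins_reps$end <- ins_reps$end + cut
    ins_reps$nested_in <- host$repeats$copy_id[1]
    host$repeats <- rbind(host$repeats, ins_reps)
  }
  ins_mites <- insert$mites
  if (nrow(ins_mites)) {
    ins_mites$start <- ins_mites$start + cut
    ins_mites$end <- ins_mites$end + cut
    host$mites <- rbind(host$mites, ins_mites)
  }
  host$seq <- paste0(substr(host$seq, 1, cut), insert$seq,
                     substr(host$seq, cut + 1, host_len))
  host$len <- nchar(host$seq)
  host
}

#' Generate a synthetic genome from a recipe
#'
#' Assembles each contig from i.i.d. background sequence with the recipe's
#' planted features spliced in at random non-overlapping positions:
#' transposon-family copies (substitution- and RIP-mutated, optionally nested
#' inside earlier copies), MITE copies, SM gene clusters with intergenic
#' repeat blocks, background housekeeping genes, and terminal telomere arrays.
#' Output is byte-deterministic given the recipe (including its seed).
#'
#' @param recipe a [genome_recipe()].
#' @return A list of class `synthetic_genome` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes` (data.frame of gene models,
#'   0-based half-open), `truth` (list of data.frames: `repeats`, `mites`,
#'   `telomeres`, `clusters`, `exemplars`), and `recipe`.
#' @export
generate_genome <- function(recipe) {
  stopifnot(inherits(recipe, "genome_recipe"))
  withr::with_seed(recipe$seed, generate_genome_impl(recipe))
}

generate_genome_impl <- function(recipe) {
  contigs <- recipe$contigs
  gid <- recipe$genome_id

  # family exemplars (shared across contigs)
  te_ex <- lapply(recipe$te_families, function(sp) {
    sp$exemplar %||% random_seq(sp$length, recipe$base_gc)
  })
  names(te_ex) <- vapply(recipe$te_families, `[[`, "", "id")
  mite_ex <- lapply(recipe$mite_specs, make_mite_exemplar)
  names(mite_ex) <- vapply(recipe$mite_specs, `[[`, "", "id")

  # distribute TE and MITE copies over contigs proportionally to length
  contig_prob <- contigs$length / sum(contigs$length)
  feat_by_contig <- setNames(vector("list", nrow(contigs)), contigs$name)
  for (fi in seq_along(recipe$te_families)) {
    sp <- recipe$te_families[[fi]]
    for (ci in seq_len(sp$copies)) {
      ctg <- sample(contigs$name, 1L, prob = contig_prob)
      f <- make_te_copy_feature(sp, te_ex[[sp$id]], ci, recipe$base_gc)
      f$nesting_prob <- sp$nesting_prob
      feat_by_contig[[ctg]] <- c(feat_by_contig[[ctg]], list(f))
    }
  }
  for (fi in seq_along(recipe$mite_specs)) {
    sp <- recipe$mite_specs[[fi]]
    for (ci in seq_len(sp$copies)) {
      ctg <- sample(contigs$name, 1L, prob = contig_prob)
      f <- make_mite_copy_feature(sp, mite_ex[[sp$id]], ci)
      feat_by_contig[[ctg]] <- c(feat_by_contig[[ctg]], list(f))
    }
  }

  # nested insertions: a nesting-prone TE copy moves inside an earlier TE copy
  for (ctg in contigs$name) {
    feats <- feat_by_contig[[ctg]]
    if (length(feats) < 2) next
    te_idx <- which(vapply(feats, function(f) f$type == "te", TRUE))
    drop <- integer()
    for (i in te_idx) {
      if (i == te_idx[1]) next
      npb <- feats[[i]]$nesting_prob %||% 0
      hosts <- setdiff(te_idx[te_idx < i], drop)
      hosts <- hosts[vapply(feats[hosts], function(f) f$len >= 120L, TRUE)]
      if (length(hosts) && runif(1) < npb) {
        h <- if (length(hosts) == 1) hosts else sample(hosts, 1L)
        cut <- sample(seq(50L, feats[[h]]$len - 50L), 1L)
        feats[[h]] <- insert_into_feature(feats[[h]], feats[[i]], cut)
        drop <- c(drop, i)
      }
    }
    if (length(drop)) feats <- feats[-drop]
    feat_by_contig[[ctg]] <- feats
  }

  # cluster features
  block_family <- if (length(recipe$te_families)) recipe$te_families[[1]]$id else NA
  core_counter <- new.env()
  core_counter$n <- 0L
  pinned <- setNames(vector("list", nrow(contigs)), contigs$name)
  for (sp in recipe$clusters) {
    f <- make_cluster_feature(sp, gid, te_ex[[block_family]] %||% "",
                              block_family, recipe$base_gc, core_counter)
    f$telomere_distance <- sp$telomere_distance
    if (!is.na(sp$telomere_distance)) {
      pinned[[sp$contig]] <- c(pinned[[sp$contig]], list(f))
    } else {
      feat_by_contig[[sp$contig]] <- c(feat_by_contig[[sp$contig]], list(f))
    }
  }

  # background housekeeping genes
  for (ci in seq_len(nrow(contigs))) {
    ctg <- contigs$name[ci]
    n_cluster_genes <- sum(vapply(feat_by_contig[[ctg]],
                                  function(f) nrow(f$genes), 0L)) +
      sum(vapply(pinned[[ctg]] %||% list(), function(f) nrow(f$genes), 0L))
    n_bg <- max(0L, round(recipe$gene_density * contigs$length[ci] / 1000) -
                  n_cluster_genes)
    for (k in seq_len(n_bg)) {
      core_counter$n <- core_counter$n + 1L
      og <- sprintf("COG%04d", core_counter$n)
      gene_id <- sprintf("%s_%s_hk%04d", gid, ctg, k)
      feat_by_contig[[ctg]] <- c(feat_by_contig[[ctg]],
                                 list(make_gene_feature(gene_id, "core",
                                                        ortholog_group = og)))
    }
  }

  # telomere features
  tel_feats <- list()
  if (!is.null(recipe$telomeres)) {
    ts <- recipe$telomeres
    for (k in seq_len(nrow(ts$ends))) {
      ctg <- ts$ends$contig[k]; side <- ts$ends$end[k]
      ncp <- if (length(ts$copies) == 2)
        sample(ts$copies[1]:ts$copies[2], 1L) else ts$copies[1]
      unit <- if (side == "right") ts$motif else revcomp(ts$motif)
      tel_feats[[paste(ctg, side)]] <-
        list(contig = ctg, end = side, motif = ts$motif, copies = ncp,
             seq = strrep(unit, ncp))
    }
  }

  # assemble contigs
  seqs <- character(nrow(contigs))
  repeats <- empty_repeat_truth(); repeats$contig <- character()
  mites <- data.frame(); genes <- data.frame(); clusters <- data.frame()
  telomeres <- data.frame()
  for (ci in seq_len(nrow(contigs))) {
    ctg <- contigs$name[ci]; L <- contigs$length[ci]
    feats <- feat_by_contig[[ctg]] %||% list()
    if (length(feats)) feats <- feats[sample(length(feats))]
    feats <- c(feats, pinned[[ctg]] %||% list())  # pinned clusters go last
    tl <- tel_feats[[paste(ctg, "left")]]
    tr <- tel_feats[[paste(ctg, "right")]]
    tel_len <- (if (!is.null(tl)) nchar(tl$seq) else 0L) +
      (if (!is.null(tr)) nchar(tr$seq) else 0L)
    feat_len <- sum(vapply(feats, `[[`, 0L, "len"))
    pin_gap <- 0L
    n_pin <- length(pinned[[ctg]] %||% list())
    if (n_pin > 0) {
      pin_gap <- sum(vapply(pinned[[ctg]], function(f)
        as.integer(f$telomere_distance), 0L))
    }
    bg_total <- L - feat_len - tel_len - pin_gap
    n_gaps <- length(feats) - n_pin + 1L
    # planted features are discrete: separate them by at least MIN_FEATURE_GAP
    # of background so that adjacent elements never read as one element
    bg_free <- bg_total - n_gaps * MIN_FEATURE_GAP
    if (bg_free < 0) {
      stop("packing error: planted features (", feat_len + tel_len + pin_gap,
           " bp plus ", n_gaps * MIN_FEATURE_GAP, " bp minimum spacing) ",
           "exceed contig ", ctg, " length (", L, " bp)",
           call. = FALSE)
    }
    cuts <- sort(sample.int(bg_free + 1L, n_gaps - 1L, replace = TRUE) - 1L)
    gap_lens <- diff(c(0L, cuts, bg_free)) + MIN_FEATURE_GAP
    pieces <- character(); pos <- 0L
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    if (!is.null(tl)) {
      telomeres <- rbind(telomeres,
                         data.frame(contig = ctg, end = "left",
                                    motif = tl$motif, copies = tl$copies,
                                    start = pos, end_pos = pos + nchar(tl$seq),
                                    stringsAsFactors = FALSE))
      add_piece(tl$seq)
    }
    gi <- 1L
    pin_seen <- FALSE
    for (k in seq_along(feats)) {
      f <- feats[[k]]
      is_pinned <- k > length(feats) - n_pin
      if (!is_pinned || !pin_seen) {
        add_piece(random_seq(gap_lens[gi], recipe$base_gc)); gi <- gi + 1L
      }
      if (is_pinned) pin_seen <- TRUE
      off <- pos
      if (nrow(f$repeats)) {
        r <- f$repeats; r$start <- r$start + off; r$end <- r$end + off
        r$contig <- ctg
        repeats <- rbind(repeats, r)
      }
      if (nrow(f$mites)) {
        m <- f$mites; m$start <- m$start + off; m$end <- m$end + off
        m$contig <- ctg
        mites <- rbind(mites, m)
      }
      if (nrow(f$genes)) {
        g <- f$genes
        g$start <- g$start + off; g$end <- g$end + off
        g$cds_start <- g$cds_start + off; g$cds_end <- g$cds_end + off
        g$contig <- ctg
        genes <- rbind(genes, g)
      }
      if (nrow(f$clusters)) {
        cl <- f$clusters; cl$start <- cl$start + off; cl$end <- cl$end + off
        cl$contig <- ctg
        cl$telomere_distance <- f$telomere_distance %||% NA
        clusters <- rbind(clusters, cl)
      }
      add_piece(f$seq)
      if (is_pinned) add_piece(random_seq(as.integer(f$telomere_distance),
                                          recipe$base_gc))
    }
    if (n_pin == 0) add_piece(random_seq(gap_lens[gi], recipe$base_gc))
    if (!is.null(tr)) {
      telomeres <- rbind(telomeres,
                         data.frame(contig = ctg, end = "right",
                                    motif = tr$motif, copies = tr$copies,
                                    start = pos, end_pos = pos + nchar(tr$seq),
                                    stringsAsFactors = FALSE))
      add_piece(tr$seq)
    }
    seqs[ci] <- paste(pieces, collapse = "")
    stopifnot(nchar(seqs[ci]) == L)
  }

  genome <- Biostrings::DNAStringSet(setNames(seqs, contigs$name))
  exemplars <- data.frame(
    family = c(names(te_ex), names(mite_ex)),
    kind = c(rep("te", length(te_ex)), rep("mite", length(mite_ex))),
    sequence = c(unlist(te_ex) %||% character(),
                 unlist(mite_ex) %||% character()),
    stringsAsFactors = FALSE)
  if (nrow(genes)) {
    genes <- genes[order(genes$contig, genes$start), ]
    rownames(genes) <- NULL
  }
  structure(list(genome = genome, genes = genes,
                 truth = list(repeats = repeats, mites = mites,
                              telomeres = telomeres, clusters = clusters,
                              exemplars = exemplars),
                 recipe = recipe),
            class = "synthetic_genome")
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.fasta`, `genes.gff3` (1-based inclusive, with `pseudogene`,
#' `Dbxref` and `ortholog_group` attributes), per-feature truth tables as TSV
#' (0-based half-open coordinates), and a JSON echo of the recipe.
#'
#' @param sim a `synthetic_genome` from [generate_genome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  for (nm in names(sim$truth)) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rec <- sim$recipe
  rec$contigs <- as.list(rec$contigs)
  jsonlite::write_json(rec, file.path(dir, "recipe.json"),
                       auto_unbox = TRUE, force = TRUE, null = "null")
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' Converts the package's internal 0-based half-open gene table to 1-based
#' inclusive GFF3 with `gene` and `CDS` features.
#'
#' @param genes gene model data.frame (see [generate_genome()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    attrs <- sprintf("ID=%s", g$gene_id)
    if (isTRUE(g$pseudogene)) attrs <- paste0(attrs, ";pseudogene=true")
    if (!is.na(g$domains)) {
      attrs <- paste0(attrs, ";Dbxref=",
                      paste0("InterPro:", strsplit(g$domains, ",")[[1]],
                             collapse = ","))
    }
    if (!is.na(g$ortholog_group))
      attrs <- paste0(attrs, ";ortholog_group=", g$ortholog_group)
    if (!is.na(g$role)) attrs <- paste0(attrs, ";role=", g$role)
    writeLines(paste(g$contig, "alkaloci", "gene", g$start + 1L, g$end,
                     ".", g$strand, ".", attrs, sep = "\t"), con)
    writeLines(paste(g$contig, "alkaloci", "CDS", g$cds_start + 1L, g$cds_end,
                     ".", g$strand, "0",
                     sprintf("ID=%s.cds;Parent=%s", g$gene_id, g$gene_id),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file written by [write_gff3()] (or compatible)
#'
#' Expects `gene` features with `ID` attributes and child `CDS` features with
#' `Parent` attributes; recognises `pseudogene=true`, InterPro `Dbxref`
#' entries, and `ortholog_group`/`role` attributes. Coordinates are converted
#' to the package's internal 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @return gene model data.frame.
#' @export
read_gff3_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) == 9L]
  m <- do.call(rbind, f)
  attr_get <- function(a, key) {
    hit <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))
    vapply(hit, function(h) if (length(h)) h[3] else NA_character_, "")
  }
  type <- m[, 3]
  gene_rows <- which(type == "gene")
  cds_rows <- which(type == "CDS")
  ids <- attr_get(m[gene_rows, 9], "ID")
  parents <- attr_get(m[cds_rows, 9], "Parent")
  cds_start <- as.integer(m[cds_rows, 4]) - 1L
  cds_end <- as.integer(m[cds_rows, 5])
  doms <- attr_get(m[gene_rows, 9], "Dbxref")
  doms <- ifelse(is.na(doms), NA,
                 vapply(strsplit(doms, ","), function(d)
                   paste(sub("^InterPro:", "", d), collapse = ","), ""))
  genes <- data.frame(
    gene_id = ids,
    contig = m[gene_rows, 1],
    start = as.integer(m[gene_rows, 4]) - 1L,
    end = as.integer(m[gene_rows, 5]),
    cds_start = cds_start[match(ids, parents)],
    cds_end = cds_end[match(ids, parents)],
    strand = m[gene_rows, 7],
    pseudogene = !is.na(attr_get(m[gene_rows, 9], "pseudogene")),
    domains = doms,
    ortholog_group = attr_get(m[gene_rows, 9], "ortholog_group"),
    role = attr_get(m[gene_rows, 9], "role"),
    cluster_id = NA_character_,
    stringsAsFactors = FALSE)
  genes[order(genes$contig, genes$start), ]
}

# ---- sequence-evolution simulators for orthology tests ----------------------

#' Simulate per-genome protein sets with one-to-one orthologs
#'
#' @param n_genomes number of genomes.
#' @param n_genes number of ancestor genes.
#' @param len protein length (aa).
#' @param divergence per-site substitution probability per genome lineage.
#' @param seed RNG seed.
#' @return Named list (genome id) of named character vectors (gene id ->
#'   amino-acid sequence).
#' @export
simulate_protein_sets <- function(n_genomes = 2, n_genes = 10, len = 120,
                                  divergence = 0.05, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    anc <- replicate(n_genes, paste(sample(aa, len, TRUE), collapse = ""))
    out <- list()
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("G%02d", g)
      seqs <- vapply(anc, function(s) {
        x <- strsplit(s, "")[[1]]
        idx <- which(runif(len) < divergence)
        if (length(idx))
          x[idx] <- vapply(x[idx], function(b) sample(setdiff(aa, b), 1L), "")
        paste(x, collapse = "")
      }, "")
      names(seqs) <- sprintf("%s_gene%03d", gid, seq_len(n_genes))
      out[[gid]] <- seqs
    }
    out
  })
}

#' Simulate an ortholog group containing two ancient paralog clades
#'
#' Models a gene duplication before speciation: two deeply diverged ancestral
#' paralogs, each inherited (with shallow within-clade divergence) by every
#' taxon, so the true bipartition has split score 1.
#'
#' @param n_taxa number of taxa (each contributes one member per clade).
#' @param len sequence length (nt).
#' @param clade_divergence per-site divergence between the two paralogs.
#' @param within_divergence per-site divergence within each clade.
#' @param seed RNG seed.
#' @return List with `members` (data.frame: `genome`, `gene`, `seq`) and
#'   `truth` (list of the two clade gene-id vectors).
#' @export
simulate_duplication_group <- function(n_taxa = 4, len = 300,
                                       clade_divergence = 0.4,
                                       within_divergence = 0.03, seed = 1) {
  withr::with_seed(seed, {
    anc <- random_seq(len, 0.5)
    par2 <- mutate_seq(anc, clade_divergence)
    mk <- function(base, clade) {
      data.frame(
        genome = sprintf("T%02d", seq_len(n_taxa)),
        gene = sprintf("T%02d_%s", seq_len(n_taxa), clade),
        seq = vapply(seq_len(n_taxa),
                     function(i) mutate_seq(base, within_divergence), ""),
        stringsAsFactors = FALSE)
    }
    a <- mk(anc, "cladeA"); b <- mk(par2, "cladeB")
    list(members = rbind(a, b), truth = list(A = a$gene, B = b$gene))
  })
}
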