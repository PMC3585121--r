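# Shared fixture builders. Everything is generated in code at test time.

small_repeat_recipe <- function(seed = 11, length = 300000) {
  genome_recipe(
    seed = seed,
    contigs = data.frame(name = "c1", length = length),
    te_families = list(
      te_family("TE1", 2000, copies = 6, sub_rate = 0.03, rip_rate = 0.2),
      te_family("TE2", 900, copies = 5, sub_rate = 0.02)),
    gene_density = 0.2)
}

cluster_recipe <- function(seed = 42) {
  genome_recipe(
    seed = seed,
    contigs = data.frame(name = c("sc1", "sc2"),
                         length = c(250000, 120000)),
    te_families = list(
      te_family("TE1", 2500, copies = 6, rip_rate = 0.3),
      te_family("TE2", 900, copies = 4)),
    mite_specs = list(mite_spec("M1", copies = 5)),
    telomeres = telomere_spec(ends = data.frame(contig = "sc1",
                                                end = "right")),
    clusters = list(cluster_spec(
      "CL1", "sc1", repeat_blocks = c(0, 0, 600, 0, 600, 0, 0, 0),
      telomere_distance = 8000)))
}

# brute-force union of 0-based half-open intervals via a bit vector
brute_union_bp <- function(start, end, L) {
  v <- logical(L)
  for (k in seq_along(start)) {
    if (end[k] > start[k]) v[(start[k] + 1):end[k]] <- TRUE
  }
  sum(v)
}

brute_intersect_bp <- function(a_start, a_end, b_start, b_end, L) {
  va <- logical(L); vb <- logical(L)
  for (k in seq_along(a_start)) va[(a_start[k] + 1):a_end[k]] <- TRUE
  for (k in seq_along(b_start)) vb[(b_start[k] + 1):b_end[k]] <- TRUE
  sum(va & vb)
}

# brute-force connected components by label propagation
brute_components <- function(nodes, edge_a, edge_b) {
  lab <- stats::setNames(nodes, nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(edge_a)) {
      m <- min(lab[[edge_a[k]]], lab[[edge_b[k]]])
      if (lab[[edge_a[k]]] != m || lab[[edge_b[k]]] != m) {
        lab[edge_a[k]] <- m; lab[edge_b[k]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# independent left/right extension scan mirroring the cluster-delimitation
# contract (accessory genes extend; stop_run consecutive core genes stop)
brute_delimit <- function(sig_idx, core_flags, stop_run) {
  n <- length(core_flags)
  members <- sig_idx
  for (dir in c(-1, 1)) {
    run <- 0
    j <- sig_idx + dir
    while (j >= 1 && j <= n) {
      if (core_flags[j]) {
        run <- run + 1
        if (run >= stop_run) break
      } else {
        run <- 0
        members <- c(members, j)
      }
      j <- j + dir
    }
  }
  sort(members)
}
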