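# Genotype -> chemotype prediction. Each alkaloid class (EAS = ergot
# alkaloids, IDT = indole-diterpenes, LOL = lolines, PER = peramine) is
# encoded as an acyclic product-dependency graph: every product node carries
# the set of genes required for the step(s) from its parent. A product is
# producible iff its entire ancestry is reachable with all required genes
# functional; pseudogenes and absent genes are treated identically as
# non-functional. The deepest reachable products (no reachable descendant)
# are reported as the accumulating end products.

#' Load a pathway rule set
#'
#' Rule sets ship with the package as versioned JSON data files
#' (`extdata/rulesets/`). Validates that the dependency graph is acyclic and
#' that every required gene is in the catalog.
#'
#' @param pathway one of `"EAS"`, `"IDT"`, `"LOL"`, `"PER"`.
#' @param options named list overriding rule-set options (e.g.
#'   `ec_oxidase = "unknown"` to drop the cloA requirement for elymoclavine,
#'   `require_idtS = FALSE` to make idtS non-essential).
#' @return list of class `pathway_ruleset`.
#' @export
load_ruleset <- function(pathway, options = list()) {
  path <- system.file("extdata", "rulesets",
                      paste0(tolower(pathway), ".json"),
                      package = "alkaloci")
  if (!nzchar(path)) stop("unknown pathway: ", pathway, call. = FALSE)
  rs <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  rs$catalog <- unlist(rs$catalog)
  rs$options <- utils::modifyList(as.list(rs$options), options)
  rs$products <- lapply(rs$products, function(p) {
    p$requires <- unlist(p$requires)
    p
  })
  # apply options
  for (k in seq_along(rs$products)) {
    p <- rs$products[[k]]
    if (isTRUE(p$oxidase_option) &&
        identical(rs$options$ec_oxidase, "unknown")) {
      p$requires <- setdiff(p$requires, "cloA")
    }
    if (!is.null(p$co_required_option) &&
        isTRUE(rs$options$require_idtS)) {
      p$requires <- union(p$requires, p$co_required_option)
    }
    rs$products[[k]] <- p
  }
  ids <- vapply(rs$products, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  for (p in rs$products) {
    stopifnot(all(p$requires %in% rs$catalog) || length(p$requires) == 0)
    if (!is.null(p$parent)) stopifnot(p$parent %in% ids)
  }
  # acyclicity of the parent graph
  edges <- do.call(rbind, lapply(rs$products, function(p)
    if (is.null(p$parent)) NULL else c(p$parent, p$id)))
  if (!is.null(edges)) {
    gr <- igraph::graph_from_edgelist(edges, directed = TRUE)
    stopifnot(igraph::is_dag(gr))
  }
  structure(rs, class = "pathway_ruleset")
}

#' Load all four pathway rule sets
#' @param options per-pathway option overrides, e.g.
#'   `list(EAS = list(ec_oxidase = "unknown"))`.
#' @return named list of `pathway_ruleset`s.
#' @export
load_rulesets <- function(options = list()) {
  setNames(lapply(c("EAS", "IDT", "LOL", "PER"), function(p)
    load_ruleset(p, options[[p]] %||% list())),
    c("EAS", "IDT", "LOL", "PER"))
}

#' Construct a genotype profile
#'
#' @param genome genome/strain id.
#' @param genes data.frame with columns `gene`, `status` (`functional`,
#'   `pseudogene`, `absent`, or `delta_r` for the reductase-deleted perA
#'   form) and optionally `copies`.
#' @param rulesets rule sets used to validate gene names; unknown names are
#'   collected into a warning list rather than rejected silently.
#' @return list of class `genotype_profile` with `genome`, `status` (named
#'   character), `copies` (named integer), `unknown_genes`.
#' @export
genotype_profile <- function(genome, genes, rulesets = load_rulesets()) {
  stopifnot(all(c("gene", "status") %in% names(genes)))
  stopifnot(all(genes$status %in%
                  c("functional", "pseudogene", "absent", "delta_r")))
  aliases <- list()
  catalog <- character()
  for (rs in rulesets) {
    catalog <- c(catalog, rs$catalog)
    if (!is.null(rs$aliases)) aliases <- c(aliases, rs$aliases)
  }
  nm <- genes$gene
  mapped <- nm
  hit <- nm %in% names(aliases)
  if (any(hit)) mapped[hit] <- unlist(aliases[nm[hit]])
  unknown <- unique(nm[!(mapped %in% catalog)])
  if (length(unknown)) {
    warning("unknown gene name(s) ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  keep <- mapped %in% catalog
  status <- setNames(genes$status[keep], mapped[keep])
  copies <- setNames(
    as.integer(if ("copies" %in% names(genes)) genes$copies[keep]
               else rep(1L, sum(keep))),
    mapped[keep])
  structure(list(genome = genome, status = status, copies = copies,
                 unknown_genes = unknown), class = "genotype_profile")
}

#' Read genotype profiles from a TSV file
#'
#' Expects columns `genome`, `gene`, `status` and optionally `copies`; one
#' profile per distinct genome.
#'
#' @param path TSV path.
#' @param rulesets rule sets for validation.
#' @return named list of [genotype_profile()]s.
#' @export
read_genotypes <- function(path, rulesets = load_rulesets()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$genome), function(d)
    genotype_profile(d$genome[1], d, rulesets))
  out[order(names(out))]
}

gene_functional <- function(genotype, gene) {
  identical(unname(genotype$status[gene]), "functional")
}

#' Predict producible alkaloids from a genotype
#'
#' Walks each pathway's product-dependency graph: a product is producible
#' iff its parent is producible (or it is a root) and every gene it requires
#' is functional (pseudogene, absent and reductase-deleted states all count
#' as non-functional). Reports the producible set, the deepest reachable
#' (accumulating) products, and for each pathway the genes blocking the
#' shallowest unreachable node.
#'
#' @param genotype a [genotype_profile()].
#' @param rulesets from [load_rulesets()].
#' @return list of class `chemotype_prediction`: `genome`, per-pathway list
#'   with `producible` (product ids), `frontier` (accumulating end products),
#'   `blocked_at` (named list: unreachable product -> missing genes),
#'   `summary` (character vector of frontier labels).
#' @export
predict_chemotype <- function(genotype, rulesets = load_rulesets()) {
  stopifnot(inherits(genotype, "genotype_profile"))
  res <- list()
  for (pname in names(rulesets)) {
    rs <- rulesets[[pname]]
    ids <- vapply(rs$products, `[[`, "", "id")
    parent <- setNames(vapply(rs$products, function(p)
      p$parent %||% NA_character_, ""), ids)
    reachable <- setNames(logical(length(ids)), ids)
    missing <- setNames(vector("list", length(ids)), ids)
    for (p in rs$products) {  # products are listed parents-first
      ok_parent <- is.na(parent[[p$id]]) || reachable[[parent[[p$id]]]]
      miss <- p$requires[!vapply(p$requires, function(gn)
        gene_functional(genotype, gn), TRUE)]
      reachable[[p$id]] <- ok_parent && length(miss) == 0
      missing[[p$id]] <- miss
    }
    producible <- ids[reachable]
    has_reachable_child <- vapply(ids, function(i)
      any(parent == i & reachable, na.rm = TRUE), TRUE)
    frontier <- ids[reachable & !has_reachable_child]
    # shallowest unreachable nodes: parent reachable (or root) but blocked
    parent_ok <- vapply(ids, function(i) {
      pa <- parent[[i]]
      is.na(pa) || reachable[[pa]]
    }, TRUE)
    blocked <- ids[!reachable & parent_ok]
    blocked_at <- missing[blocked]
    blocked_at <- blocked_at[vapply(blocked_at, length, 0L) > 0]
    labels <- setNames(vapply(rs$products, function(p)
      p$label %||% p$id, ""), ids)
    res[[pname]] <- list(producible = producible, frontier = frontier,
                         blocked_at = blocked_at,
                         summary = unname(labels[frontier]))
  }
  structure(list(genome = genotype$genome, pathways = res),
            class = "chemotype_prediction")
}

#' @export
print.chemotype_prediction <- function(x, ...) {
  cat("chemotype prediction for", x$genome, "\n")
  for (p in names(x$pathways)) {
    fr <- x$pathways[[p]]$frontier
    cat(sprintf("  %s: %s\n", p,
                if (length(fr)) paste(fr, collapse = " + ") else "none"))
  }
  invisible(x)
}

#' Number of distinct ergopeptines supported by lpsA copy number
#'
#' When ergopeptines are producible, each lpsA copy is assumed to specify
#' one ergopeptine; otherwise 0.
#'
#' @param genotype a [genotype_profile()].
#' @param prediction optional [predict_chemotype()] result (recomputed when
#'   missing).
#' @param rulesets rule sets.
#' @return integer count.
#' @export
ergopeptine_count <- function(genotype, prediction = NULL,
                              rulesets = load_rulesets()) {
  if (is.null(prediction)) prediction <- predict_chemotype(genotype, rulesets)
  if (!("ergopeptine" %in% prediction$pathways$EAS$producible)) return(0L)
  cp <- genotype$copies["lpsA"]
  if (is.na(cp)) 0L else as.integer(cp)
}

#' Check predictions against observed alkaloid profiles
#'
#' Evaluates each expectation row (columns `genome`, `pathway`,
#' `observed_product`, `relation`, `expected_discordant`) against the
#' predictions: `frontier` requires the product among the accumulating end
#' products, `producible` requires membership of the producible set,
#' `not_producible` its absence, and `none` requires an empty producible
#' set. Rows flagged `expected_discordant` are consistent when the genomic
#' prediction disagrees with observation for a documented reason (e.g. a
#' non-expressed cluster).
#'
#' @param genotypes named list of [genotype_profile()]s.
#' @param expectations data.frame of expectation rows (see
#'   `extdata/chemotype_expectations.tsv`).
#' @param rulesets rule sets.
#' @return `expectations` with logical columns `prediction_matches` and
#'   `consistent` added.
#' @export
check_chemotype_concordance <- function(genotypes, expectations,
                                        rulesets = load_rulesets()) {
  preds <- lapply(genotypes, predict_chemotype, rulesets = rulesets)
  matches <- logical(nrow(expectations))
  for (k in seq_len(nrow(expectations))) {
    e <- expectations[k, ]
    pw <- preds[[e$genome]]$pathways[[e$pathway]]
    matches[k] <- switch(
      e$relation,
      frontier = e$observed_product %in% pw$frontier,
      producible = e$observed_product %in% pw$producible,
      not_producible = !(e$observed_product %in% pw$producible),
      none = length(pw$producible) == 0,
      expected_discordant = length(pw$producible) > 0,
      stop("unknown relation: ", e$relation))
  }
  expectations$prediction_matches <- matches
  expectations$consistent <- matches
  expectations
}
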