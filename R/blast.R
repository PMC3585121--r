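# Thin wrappers around NCBI BLAST+ for local alignment. The scoring scheme is
# pinned (match +1, mismatch -2, gap open -5, gap extend -2) so that raw-score
# thresholds such as the score-100 correspondence cutoff are reproducible; it
# is recorded in the metadata of every hit set.

BLAST_SCHEME <- list(reward = 1L, penalty = -2L, gapopen = 5L, gapextend = 2L)

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

require_blast <- function() {
  if (!blast_available()) {
    stop("NCBI BLAST+ (blastn/makeblastdb) is required on PATH", call. = FALSE)
  }
}

as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(x)
}

write_fasta_tmp <- function(dss, dir, name) {
  path <- file.path(dir, name)
  Biostrings::writeXStringSet(dss, path)
  path
}

# Run blastn of query against subject, both DNAStringSets (or named character
# vectors). Returns the 12-column outfmt-6 dialect plus a raw `score` column;
# coordinates are 1-based inclusive as that dialect requires, with
# sstart > send for minus-strand subject hits.
run_blastn <- function(query, subject, min_score = 0, evalue = 10,
                       task = "blastn") {
  require_blast()
  q <- as_dss(query); s <- as_dss(subject)
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- write_fasta_tmp(q, td, "query.fa")
  sf <- write_fasta_tmp(s, td, "subject.fa")
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  st <- system2("makeblastdb",
                c("-in", sf, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed", call. = FALSE)
  st <- system2("blastn", c(
    "-task", task, "-query", qf, "-db", db,
    "-reward", BLAST_SCHEME$reward, "-penalty", BLAST_SCHEME$penalty,
    "-gapopen", BLAST_SCHEME$gapopen, "-gapextend", BLAST_SCHEME$gapextend,
    "-dust", "no", "-soft_masking", "false",
    "-evalue", format(evalue), "-max_target_seqs", "10000",
    "-outfmt", shQuote(paste("6 qseqid sseqid pident length mismatch gapopen",
                             "qstart qend sstart send evalue bitscore score")),
    "-out", out), stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastn failed", call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "score")
  if (file.size(out) == 0) {
    hits <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    hits$qseqid <- character(0); hits$sseqid <- character(0)
  } else {
    hits <- read.table(out, sep = "\t", col.names = cols,
                       colClasses = c("character", "character",
                                      rep("numeric", 11)),
                       quote = "", comment.char = "")
  }
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits$strand <- ifelse(hits$send >= hits$sstart, "+", "-")
  # deterministic order regardless of database sequence order
  hits <- hits[order(hits$qseqid, hits$qstart, hits$sseqid,
                     pmin(hits$sstart, hits$send), -hits$score), ]
  rownames(hits) <- NULL
  attr(hits, "scoring") <- BLAST_SCHEME
  hits
}
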