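test_that("a planted MITE's terminal inverted repeats are found once", {
  withr::with_seed(21, {
    tir <- random_seq(25, 0.5)
    mite <- paste0(tir, random_seq(150, 0.35), revcomp(tir))
    h <- find_inverted_repeats(mite, min_arm = 10)
    expect_equal(nrow(h), 1)
    expect_equal(h$identity, 1.0)
    # arms sit at the planted positions (local alignment may extend a few
    # bp into chance-complementary flanking sequence)
    expect_lte(abs(h$left_start - 0), 4)
    expect_lte(abs(h$right_end - 200), 4)
    expect_gte(h$arm_length, 25)
    expect_lte(h$arm_length, 31)
  })
})

test_that("a perfect palindrome is one hit spanning it with loop 0", {
  withr::with_seed(22, {
    half <- random_seq(30, 0.5)
    pal <- paste0(half, revcomp(half))
    h <- find_inverted_repeats(pal, min_arm = 10)
    expect_equal(nrow(h), 1)
    expect_equal(h$left_start, 0)
    expect_equal(h$right_end, 60)
    expect_equal(h$loop, 0)
    expect_equal(h$arm_length, 30)
  })
})

test_that("random sequence essentially never yields long high-identity TIRs", {
  hits <- vapply(1:20, function(sd) {
    withr::with_seed(sd, {
      nrow(find_inverted_repeats(random_seq(5000, 0.5), min_arm = 20,
                                 min_identity = 0.9, min_score = 55))
    })
  }, 0L)
  expect_true(all(hits <= 1))
  expect_lte(mean(hits), 0.25)
})

test_that("inverted-repeat hits mirror under reverse complement", {
  withr::with_seed(23, {
    tir <- random_seq(20, 0.5)
    s <- paste0(random_seq(40, 0.5), tir, random_seq(100, 0.4),
                revcomp(tir), random_seq(60, 0.5))
    L <- nchar(s)
    h1 <- find_inverted_repeats(s, min_arm = 12)
    h2 <- find_inverted_repeats(revcomp(s), min_arm = 12)
    expect_equal(nrow(h1), 1)
    expect_equal(nrow(h2), 1)
    expect_equal(h2$left_start, L - h1$right_end)
    expect_equal(h2$right_end, L - h1$left_start)
  })
})

test_that("MITE families are classified by structure, size and copy number", {
  rec <- genome_recipe(
    seed = 33, contigs = data.frame(name = "c1", length = 400000),
    te_families = list(te_family("LTRrelic", 2500, copies = 5,
                                 sub_rate = 0.02)),
    mite_specs = list(mite_spec("M1", c(200, 300), tir_length = 30,
                                copies = 6),
                      mite_spec("M2", c(300, 450), tir_length = 25,
                                copies = 5)),
    gene_density = 0.1)
  sim <- generate_genome(rec)
  res <- discover_repeats(sim$genome, min_len = 150)
  mites <- call_mites(res$library, res$copies)
  v <- mites$families
  # map discovered families to planted ones by exemplar length
  planted_mite <- v$exemplar_length <= 800
  expect_true(all(v$is_mite[planted_mite]))
  expect_true(all(!v$is_mite[!planted_mite]))
  expect_true(all(mites$calls$length >= 80 & mites$calls$length <= 800))
  # recall of planted MITE copies
  tm <- sim$truth$mites
  hit <- vapply(seq_len(nrow(tm)), function(k) {
    any(mites$calls$contig == tm$contig[k] &
          pmin(mites$calls$end, tm$end[k]) -
            pmax(mites$calls$start, tm$start[k]) >=
            0.8 * (tm$end[k] - tm$start[k]))
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("telomere arrays are recovered exactly at both ends", {
  for (sd in c(1, 7, 19)) {
    rec <- genome_recipe(
      seed = sd, contigs = data.frame(name = c("t1", "t2"),
                                      length = c(60000, 40000)),
      telomeres = telomere_spec(copies = c(5, 14),
                                ends = data.frame(
                                  contig = c("t1", "t1", "t2"),
                                  end = c("left", "right", "right"))))
    sim <- generate_genome(rec)
    hits <- detect_telomeres(sim$genome)
    tt <- sim$truth$telomeres
    expect_equal(nrow(hits), nrow(tt))
    key <- function(d) paste(d$contig, d$end, d$copies, d$start)
    expect_setequal(key(hits), key(tt))
  }
})

test_that("interior motif arrays and bare contigs yield no telomere hits", {
  withr::with_seed(41, {
    g <- Biostrings::DNAStringSet(c(
      mid = paste0(random_seq(5000, 0.45), strrep("TTAGGG", 10),
                   random_seq(5000, 0.45)),
      none = random_seq(8000, 0.45)))
    expect_equal(nrow(detect_telomeres(g)), 0)
  })
})

test_that("a left-end reverse-complement array is detected", {
  withr::with_seed(42, {
    g <- Biostrings::DNAStringSet(c(
      c1 = paste0(strrep("CCCTAA", 8), random_seq(5000, 0.45))))
    h <- detect_telomeres(g)
    expect_equal(nrow(h), 1)
    expect_equal(h$end, "left")
    expect_equal(h$copies, 8)
    expect_equal(h$start, 0)
  })
})

test_that("distance to telomere follows the boundary-gap contract", {
  hits <- data.frame(contig = "c1", end = "right", motif = "TTAGGG",
                     copies = 10, start = 10000L, end_pos = 10060L,
                     offset = 0L)
  expect_equal(distance_to_telomere("c1", 5000, 9999, hits), 1)
  expect_equal(distance_to_telomere("c1", 5000, 10000, hits), 0)
  expect_true(is.na(distance_to_telomere("c2", 0, 100, hits)))
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 10060)))
  expect_error(distance_to_telomere("c1", 0, 99999, hits, g), "outside")
})
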