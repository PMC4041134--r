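# Genome index, perfect-match lookup, known-miRNA matching, category
# cascade and the summary tally.

make_genome <- function(n = 5000, seed = 5) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

test_that("exact lookup finds planted substrings on both strands and nothing else", {
  g <- make_genome()
  idx <- genome_index(g)
  sub <- substr(g[["chr1"]], 1001, 1022)
  h <- genome_lookup(idx, sub)
  expect_true(any(h$chrom == "chr1" & h$start == 1001 & h$strand == "+"))
  hrc <- genome_lookup(idx, revcomp(sub))
  expect_true(any(hrc$start == 1001 & hrc$strand == "-"))
  # single substitution at a position absent elsewhere: no hits, and the
  # naive both-strand scan agrees
  mut <- sub
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(sub, 11, 11))[1]
  expect_equal(nrow(genome_lookup(idx, mut)), nrow(oracle_exact_hits(g, mut)))
})

test_that("lookup agrees with the naive scan oracle on random tags", {
  g <- make_genome(20000, seed = 6)
  idx <- genome_index(g)
  set.seed(7)
  tags <- character(0)
  for (i in 1:25) {
    st <- sample(1:19950, 1)
    tags <- c(tags, substr(g[["chr1"]], st, st + sample(18:25, 1)))
  }
  tags <- c(tags, revcomp(tags[1:5]),
            vapply(1:10, function(i) paste(sample(c("A", "C", "G", "T"), 20,
                                                  TRUE), collapse = ""), ""))
  got <- genome_lookup(idx, tags)
  for (tg in unique(tags)) {
    want <- oracle_exact_hits(g, tg)
    sub <- got[got$tag == tg, c("chrom", "start", "end", "strand")]
    want <- want[order(want$chrom, want$start, want$strand), ]
    sub <- sub[order(sub$chrom, sub$start, sub$strand), ]
    rownames(want) <- rownames(sub) <- NULL
    expect_equal(sub, want, info = tg)
  }
})

test_that("genome_index validates chromosome names", {
  expect_error(genome_index(c("ACGT", "GGCC")), "named")
  expect_error(genome_index(c(a = "ACGT", a = "GGCC")), "duplicate")
})

test_that("known-miRNA matching is perfect-match only, with tie audit", {
  db <- c(miR1 = "ACGTACGTACGTACGTACGTA", miR2 = "TTTTCCCCGGGGAAAACCCCG",
          miR3 = "ACGTACGTACGTACGTACGTA") # duplicate of miR1
  m <- match_known_mirna(c("ACGTACGTACGTACGTACGTA"), db)
  expect_equal(m$mirna_id, "miR1")
  expect_equal(m$all_ids, "miR1,miR3")
  # one extra terminal base: no match (isomiRs excluded)
  m2 <- match_known_mirna(c("ACGTACGTACGTACGTACGTAA",
                            "CGTACGTACGTACGTACGTA"), db)
  expect_true(all(is.na(m2$mirna_id)))
  # U/T normalization
  m3 <- match_known_mirna("ACGUACGUACGUACGUACGUA", db)
  expect_equal(m3$mirna_id, "miR1")
  expect_error(match_known_mirna("ACGT", character(0)), "empty")
})

test_that("the category cascade assigns exactly one category by priority", {
  set.seed(11)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  mir <- "TCGGACCAGGCTTCATTCCCC"
  rrna_seq <- substr(bg, 501, 650)
  g <- c(chr1 = paste0(substr(bg, 1, 200), mir, substr(bg, 221, 3000)))
  idx <- genome_index(g)
  ann <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(150, 501, 1001, 1001), c(400, 650, 1100, 1100)),
    strand = c("+", "+", "+", "+"),
    type = c("exon", "rRNA", "tRNA", "exon"))
  tags <- data.frame(
    sequence = c(mir,                          # mature match inside an exon
                 substr(g[["chr1"]], 520, 541), # rRNA sense
                 revcomp(substr(g[["chr1"]], 520, 541)), # rRNA antisense
                 substr(g[["chr1"]], 1010, 1031), # tRNA beats exon
                 revcomp(substr(g[["chr1"]], 1010, 1031)), # exon antisense
                 substr(g[["chr1"]], 2000, 2021), # mapped, unannotated
                 "GGGTTTAAACCCGGGTTTAAA"),       # unmapped, unannotated
    count = c(10L, 5L, 4L, 3L, 2L, 6L, 1L),
    stringsAsFactors = FALSE)
  cl <- classify_tags(tags, idx, ann, mature_db = c(planted = mir))
  expect_equal(cl$category,
               c("miRNA", "rRNA",
                 "unannotated", # antisense to rRNA: no other feature there
                 "tRNA", "exon_antisense", "unannotated", "unannotated"))
  expect_equal(cl$mapped, c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # partition invariant: every tag in exactly one category
  expect_equal(sum(table(cl$category)), nrow(tags))
})

test_that("strand-aware rRNA assignment does not leak to the antisense tag", {
  set.seed(12)
  g <- make_genome(2000, seed = 12)
  idx <- genome_index(g)
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 500),
                                strand = "+", type = "rRNA")
  anti <- revcomp(substr(g[["chr1"]], 350, 371))
  cl <- classify_tags(data.frame(sequence = anti, count = 1L), idx, ann, NULL)
  expect_false(cl$category == "rRNA")
  expect_equal(cl$category, "unannotated")
})

test_that("tally percentages follow the two-decimal printed convention", {
  # printed-table arithmetic on published count/total pairs
  expect_equal(format_percentage(5003869, 21668361), "23.09%")
  expect_equal(format_percentage(5618205, 21530509), "26.09%")
  expect_equal(format_percentage(16586059, 21668361), "76.55%")
  expect_equal(format_percentage(16889709, 21530509), "78.45%")
  expect_equal(format_percentage(1005187, 21668361), "4.64%")
  expect_equal(format_percentage(10112207, 21668361), "46.67%")
  expect_equal(format_percentage(3776597, 4505507), "83.82%")

  cl <- data.frame(sequence = c("A", "B", "C"), count = c(70L, 20L, 10L),
                   category = c("miRNA", "rRNA", "unannotated"),
                   mapped = c(TRUE, TRUE, FALSE))
  tl <- tally_categories(cl)
  expect_equal(tl$total_pct[tl$category == "miRNA"], 70)
  expect_equal(tl$unique_pct[tl$category == "miRNA"], 33.33)
  expect_equal(tl$total_count[tl$category == "mapped_to_genome"], 90L)
  # category partition: totals sum to the library total
  cats <- setdiff(tl$category, "mapped_to_genome")
  expect_equal(sum(tl$total_count[tl$category %in% cats]), 100L)
  expect_error(tally_categories(cl[0, ]), "zero|empty")
})
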