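# Hairpin duplex derivation and the criterion evaluator.

test_that("derive_duplex reads a perfect stem correctly", {
  # 22-bp fully complementary mature/star with an 8-nt loop:
  # mature 1..22, loop 23..30, star 31..52
  db <- paste0(strrep("(", 22), strrep(".", 8), strrep(")", 22))
  dx <- derive_duplex(db, 1, 22)
  expect_equal(dx$paired_bases, 22L)
  expect_equal(dx$max_bulge, 0L)
  expect_equal(dx$asymmetry, 0L)
  expect_equal(dx$spacing, 8L)
  expect_equal(dx$star_start, 31L)
  expect_equal(dx$star_end, 52L) # 2-nt overhang clipped at the sequence end
})

test_that("derive_duplex measures interior bulges and asymmetry", {
  # stem of 10 + bulge of 3 on the 5' (mature) side + stem of 9
  db <- paste0(strrep("(", 10), "...", strrep("(", 9),
               "....",
               strrep(")", 19))
  mat_len <- 22L # covers both stem segments and the bulge
  dx <- derive_duplex(db, 1, mat_len)
  expect_equal(dx$max_bulge, 3L)
  expect_equal(dx$asymmetry, 3L)
  expect_equal(dx$paired_bases, 19L)
})

test_that("a mature arm sitting on the loop has no duplex", {
  db <- paste0(strrep("(", 10), strrep(".", 20), strrep(")", 10))
  dx <- derive_duplex(db, 12, 18) # entirely inside the loop
  expect_equal(dx$paired_bases, 0L)
  expect_true(is.na(dx$star_start))
  expect_error(derive_duplex(db, 30, 30), "outside")
})

test_that("evaluate_candidate enforces every threshold and lists failures", {
  prm <- novel_params()
  base <- list(mature_len = 22L, mfe = -30, paired_bases = 20L,
               max_bulge = 1L, asymmetry = 1L, spacing = 10L,
               n_genome_copies = 1L)
  expect_true(evaluate_candidate(base, prm)$pass)

  v <- evaluate_candidate(modifyList(base, list(mfe = -17.5)), prm)
  expect_false(v$pass)
  expect_true("free_energy" %in% v$reasons)

  v <- evaluate_candidate(modifyList(base, list(paired_bases = 15L)), prm)
  expect_true("min_duplex_pairs" %in% v$reasons)

  v <- evaluate_candidate(modifyList(base, list(mature_len = 17L)), prm)
  expect_true("mature_length" %in% v$reasons)
  v <- evaluate_candidate(modifyList(base, list(mature_len = 26L)), prm)
  expect_true("mature_length" %in% v$reasons)

  v <- evaluate_candidate(modifyList(base, list(max_bulge = 5L)), prm)
  expect_true("max_bulge" %in% v$reasons)
  v <- evaluate_candidate(modifyList(base, list(asymmetry = 5L)), prm)
  expect_true("asymmetry" %in% v$reasons)
  v <- evaluate_candidate(modifyList(base, list(spacing = 301L)), prm)
  expect_true("spacing" %in% v$reasons)
  v <- evaluate_candidate(modifyList(base, list(n_genome_copies = 21L)), prm)
  expect_true("genome_copies" %in% v$reasons)

  # several violations are all reported
  v <- evaluate_candidate(modifyList(base, list(mfe = -10, paired_bases = 3L)),
                          prm)
  expect_setequal(v$reasons, c("free_energy", "min_duplex_pairs"))
})

test_that("evaluator agrees with the independent brute-force checker", {
  prm <- novel_params()
  set.seed(31)
  n_checked <- 0
  for (i in 1:1000) {
    cand <- random_candidate()
    dx <- derive_duplex(cand$structure, cand$mature_start, cand$mature_len)
    got <- evaluate_candidate(list(mature_len = cand$mature_len,
                                   mfe = cand$mfe,
                                   paired_bases = dx$paired_bases,
                                   max_bulge = dx$max_bulge,
                                   asymmetry = dx$asymmetry,
                                   spacing = dx$spacing,
                                   n_genome_copies = cand$n_genome_copies),
                              prm)
    want <- oracle_evaluate(cand$structure, cand$mature_start, cand$mature_len,
                            cand$mfe, cand$n_genome_copies, prm)
    expect_equal(sort(got$reasons), want,
                 info = paste(cand$structure, cand$mature_start,
                              cand$mature_len))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 1000)
})

test_that("tightening any single threshold never grows the PASS set", {
  set.seed(32)
  cands <- replicate(300, {
    c0 <- random_candidate()
    dx <- derive_duplex(c0$structure, c0$mature_start, c0$mature_len)
    list(mature_len = c0$mature_len, mfe = c0$mfe,
         paired_bases = dx$paired_bases, max_bulge = dx$max_bulge,
         asymmetry = dx$asymmetry, spacing = dx$spacing,
         n_genome_copies = c0$n_genome_copies)
  }, simplify = FALSE)
  passes <- function(prm) {
    vapply(cands, function(cd) evaluate_candidate(cd, prm)$pass, logical(1))
  }
  base <- novel_params()
  p0 <- passes(base)
  tighter <- list(novel_params(max_free_energy = -25),
                  novel_params(min_duplex_pairs = 18),
                  novel_params(max_bulge = 2),
                  novel_params(max_asymmetry = 2),
                  novel_params(max_spacing = 50),
                  novel_params(max_genome_copies = 2),
                  novel_params(min_mirna_len = 20, max_mirna_len = 23))
  for (prm in tighter) {
    expect_true(all(passes(prm) <= p0))
  }
})

test_that("candidate windows respect copy-number limits and chromosome bounds", {
  set.seed(33)
  unit <- "ACGGATTCAGGACTTACAGCTTAG"
  tagseq <- substr(unit, 1, 20)
  # plant the same 20-mer 21 times -> excluded at max_genome_copies = 20
  g <- c(chr1 = paste(c(rep(paste0(unit, paste(sample(c("A", "C", "G", "T"),
                                                      30, TRUE), collapse = "")),
                            21),
                        paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                              collapse = "")), collapse = ""))
  idx <- genome_index(g)
  prm <- novel_params()
  loci <- extract_candidate_loci(data.frame(sequence = tagseq, count = 5L),
                                 idx, prm)
  expect_equal(nrow(loci), 0L)

  # a tag at the chromosome start is clipped, not an error
  g2 <- c(chr1 = paste0(tagseq, paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                                      collapse = "")))
  idx2 <- genome_index(g2)
  loci2 <- extract_candidate_loci(data.frame(sequence = tagseq, count = 1L),
                                  idx2, prm)
  expect_true(all(loci2$win_start >= 1L))
  expect_true(all(loci2$win_end <= 820L))
  up <- loci2[loci2$side == "up" & loci2$strand == "+", ]
  expect_equal(up$win_start, 1L)
})

test_that("predict_novel recovers a designed hairpin and merges stacked tags", {
  set.seed(34)
  mature <- "TGGCATTCACCGCGTGAGTTA"
  d <- design_precursor(mature, seed = 9)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  g <- c(chr1 = paste0(flank5, d$precursor, flank3))
  idx <- genome_index(g)
  res <- predict_novel(data.frame(sequence = mature, count = 10L), NULL, idx)
  expect_equal(nrow(res$mirnas), 1L)
  expect_equal(res$mirnas$mature, mature)
  expect_equal(res$mirnas$count_a, 10L)
  expect_lte(res$mirnas$mfe, -18)
  # locus covers the planted precursor
  expect_lte(res$mirnas$start, 401 + 5)
  expect_gte(res$mirnas$end, 400 + nchar(d$precursor) - 5)

  # two stacked tags from the same arm collapse to a single call whose
  # mature is the more abundant tag
  shifted <- substr(paste0(d$precursor, flank3), 2, 22)
  res2 <- predict_novel(data.frame(sequence = c(mature, shifted),
                                   count = c(7L, 3L)), NULL, idx)
  expect_equal(nrow(res2$mirnas), 1L)
  expect_equal(res2$mirnas$mature, mature)
  expect_equal(res2$mirnas$count_a, 7L)
})
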