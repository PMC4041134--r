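# Synthetic experiment generator: designed precursors, genome/truth
# construction, library simulation, truth round-trip.

small_spec <- function(seed = 3, ...) {
  # reduced scale for unit tests; the default spec is exercised in the
  # acceptance suite
  synthetic_spec(genome_length = 30000L, n_mirnas = 6L, n_de_up = 2L,
                 n_de_down = 1L, de_fold_changes = c(4, 4, 0.25),
                 depth_control = 20000L, depth_treatment = 20000L,
                 n_decoys = 4L, seed = seed, ...)
}

test_that("designed precursors pass the hairpin evaluator with margin", {
  set.seed(61)
  prm <- novel_params()
  for (i in 1:5) {
    mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE,
                           prob = c(0.3, 0.2, 0.25, 0.25)), collapse = "")
    d <- tryCatch(design_precursor(mature, prm, seed = i),
                  error = function(e) NULL)
    if (is.null(d)) next # a pathological random mature may be undesignable
    v <- evaluate_candidate(list(mature_len = 22L, mfe = d$mfe,
                                 paired_bases = d$duplex$paired_bases,
                                 max_bulge = d$duplex$max_bulge,
                                 asymmetry = d$duplex$asymmetry,
                                 spacing = d$duplex$spacing,
                                 n_genome_copies = 1L), prm)
    expect_true(v$pass, info = mature)
    expect_lte(d$mfe, prm$max_free_energy - 5)
    expect_gte(d$duplex$paired_bases, prm$min_duplex_pairs + 2L)
  }
})

test_that("a homopolymer mature cannot be designed into a stable hairpin", {
  expect_error(design_precursor(strrep("A", 22), seed = 1), "attempts|stable")
})

test_that("design_precursor is deterministic and validates input", {
  m <- "TGGCATTCACCGCGTGAGTTA"
  d1 <- design_precursor(m, seed = 4)
  d2 <- design_precursor(m, seed = 4)
  expect_identical(d1$precursor, d2$precursor)
  expect_error(design_precursor("ACGT", seed = 1), "18-25")
  expect_error(design_precursor(strrep("ACGT", 8), seed = 1), "18-25")
})

test_that("build_genome plants loci that honor the recorded truth", {
  sg <- build_genome(small_spec())
  truth <- sg$truth
  expect_equal(sum(truth$kind == "miRNA"), 6L)
  expect_equal(sum(truth$kind == "decoy"), 4L)
  g <- sg$genome[["chr1"]]
  mi <- truth[truth$kind == "miRNA", ]
  for (i in seq_len(nrow(mi))) {
    # the planted precursor sits at the recorded locus on the recorded strand
    win <- substr(g, mi$start[i], mi$end[i])
    if (mi$strand[i] == "-") win <- revcomp(win)
    expect_true(grepl(mi$mature[i], win, fixed = TRUE))
    # exact brute-force copy count matches the truth
    hits <- oracle_exact_hits(sg$genome, mi$mature[i])
    expect_equal(nrow(hits), mi$n_genome_copies[i])
  }
  # loci do not overlap
  ord <- truth[order(truth$start), ]
  expect_true(all(diff(ord$start) > 0))
  expect_true(all(utils::head(ord$end, -1) < utils::tail(ord$start, -1)))
  # non-DE rows carry fold change exactly 1
  expect_true(all(mi$fold_change[!mi$is_de] == 1))
  # determinism: same spec, same genome bytes
  sg2 <- build_genome(small_spec())
  expect_identical(sg2$genome, sg$genome)
  expect_identical(sg2$truth, sg$truth)
})

test_that("simulate_library conserves depth and is deterministic", {
  sg <- build_genome(small_spec())
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_library(sg, "control", f1)
  expect_equal(length(readLines(f1)) / 4, sg$spec$depth_control)
  simulate_library(sg, "control", f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted read counts track expectations (Poisson-scale bounds)", {
  sg <- build_genome(small_spec(seed = 8))
  lib <- simulate_library(sg, "control")
  mi <- sg$truth[sg$truth$kind == "miRNA", ]
  cls <- lib$class
  for (i in seq_len(nrow(mi))) {
    n_i <- sum(cls == paste0("mirna:", mi$id[i]))
    mu <- mi$expected_count_control[i]
    expect_lte(abs(n_i - mu), 4 * sqrt(mu) + 1, label = mi$id[i])
  }
  # junk classes follow their configured fractions (binomial 4-sigma)
  for (j in names(sg$spec$junk_fractions)) {
    njunk <- sum(cls == j)
    mu <- sg$spec$depth_control * sg$spec$junk_fractions[[j]]
    expect_lte(abs(njunk - mu), 4 * sqrt(mu * (1 - sg$spec$junk_fractions[[j]]))
               + 1)
  }
  # control and treatment expected counts agree for non-DE loci
  expect_equal(mi$expected_count_control[!mi$is_de] *
                 sg$spec$depth_treatment / sg$spec$depth_control,
               mi$expected_count_treatment[!mi$is_de])
})

test_that("cleaning the simulated library recovers the junk tallies", {
  sg <- build_genome(small_spec(seed = 9))
  f <- withr::local_tempfile(fileext = ".fastq")
  lib <- simulate_library(sg, "control", f)
  cs <- clean_library(f, sg$spec$adaptor3, sg$spec$adaptor5)
  truth_n <- table(lib$class)
  for (j in c("poly_A", "no_insert", "too_short", "low_quality",
              "no_3prime_adaptor")) {
    got <- cs$filter_stats[[j]]
    want <- as.integer(truth_n[j])
    # small cross-class leakage is possible (e.g. a random tail containing
    # the adaptor by chance); tolerate a few reads
    expect_lte(abs(got - want), max(5, 0.02 * want), label = j)
  }
  expect_equal(cs$total_clean + sum(cs$filter_stats), sg$spec$depth_control)
})

test_that("truth tables round-trip losslessly through TSV", {
  sg <- build_genome(small_spec())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sg$truth, f)
  back <- read_truth(f)
  expect_equal(back, sg$truth)
  # empty truth: header-only file, empty read-back
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sg$truth[0, ], f2)
  back2 <- read_truth(f2)
  expect_equal(nrow(back2), 0L)
  expect_equal(names(back2), names(sg$truth))
})

test_that("simulate_experiment writes a complete consistent bundle", {
  out <- withr::local_tempdir()
  ex <- simulate_experiment(small_spec(seed = 10), out)
  expect_true(all(file.exists(unlist(ex$paths))))
  idx <- genome_index(ex$paths$genome)
  ann <- read_annotation(ex$paths$gff)
  expect_equal(length(ann), 10L) # 6 precursors + 4 decoys
  # GFF coordinates point at the planted loci
  truth <- read_truth(ex$paths$truth)
  expect_setequal(GenomicRanges::start(ann), truth$start)
  # every planted mature occurs in the genome
  mdb <- read_mature_db(ex$paths$mature)
  hits <- genome_lookup(idx, mdb$sequence)
  expect_setequal(mdb$sequence, unique(hits$tag))
})
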