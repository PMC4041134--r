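# Complementarity penalty scoring and the transcript scanner.

rc <- function(x) revcomp(x)

test_that("duplex penalties follow the scoring table", {
  mir <- "TGGCATTCACCGCGTGAGTTA" # 21 nt
  # perfect reverse complement: zero penalty, no flags
  sc <- score_duplex_penalty(mir, rc(mir))
  expect_equal(sc$penalty, 0)
  expect_length(sc$flags, 0)
  expect_true(all(sc$pairs == "match"))

  # single G:U wobble at miRNA position 5 (inside the doubled 2-13 zone):
  # 0.5 * 2 = 1.0. miRNA position 5 faces window position n-5+1.
  stopifnot(substr(mir, 5, 5) == "A")
  mir_gu <- mir
  substr(mir_gu, 5, 5) <- "T" # T:A -> wobble needs G:T or T:G; use target side
  win <- rc(mir)
  pos <- nchar(mir) - 5 + 1
  substr(win, pos, pos) <- "G" # miRNA A..., target G? A:G is a mismatch
  # instead put a wobble: miRNA T faces G
  sc2 <- score_duplex_penalty(mir_gu, rc(mir_gu))
  expect_equal(sc2$penalty, 0) # still perfect after substitution on both sides
  win2 <- rc(mir_gu)
  p5 <- nchar(mir_gu) - 5 + 1
  substr(win2, p5, p5) <- "G" # target base facing miRNA position 5: T:G wobble
  sc3 <- score_duplex_penalty(mir_gu, win2)
  expect_equal(sc3$penalty, 1.0)
  expect_length(sc3$flags, 0)

  # single mismatch at position 15, outside the doubled zone: 1.0, no flags
  win3 <- rc(mir)
  p15 <- nchar(mir) - 15 + 1
  old <- substr(win3, p15, p15)
  repl <- setdiff(c("A", "C", "G", "T"), c(old, "G", "T"))[1]
  substr(win3, p15, p15) <- repl
  sc4 <- score_duplex_penalty(mir, win3)
  expect_equal(sc4$penalty, 1.0)
  expect_length(sc4$flags, 0)
})

test_that("positional constraint flags fire at the cleavage site and seed", {
  mir <- "TGGCATTCACCGCGTGAGTTA"
  win <- rc(mir)
  # mismatch at position 10 (cleavage site): penalty 2, flagged
  p10 <- nchar(mir) - 10 + 1
  substr(win, p10, p10) <- setdiff(c("A", "C", "G", "T"),
                                   c(substr(win, p10, p10), "G", "T",
                                     chartr("ACGT", "TGCA",
                                            substr(mir, 10, 10))))[1]
  sc <- score_duplex_penalty(mir, win)
  expect_true("cleavage_site_mismatch" %in% sc$flags)

  # two mismatches in positions 2-12: seed flag
  win2 <- rc(mir)
  for (p in c(3, 7)) {
    tp <- nchar(mir) - p + 1
    comp <- chartr("ACGT", "TGCA", substr(mir, p, p))
    substr(win2, tp, tp) <- setdiff(c("A", "C", "G", "T"),
                                    c(comp, "G", "T"))[1]
  }
  sc2 <- score_duplex_penalty(mir, win2)
  expect_true("seed_mismatches" %in% sc2$flags)
  expect_error(score_duplex_penalty(mir, substr(rc(mir), 1, 5)), "lengths")
  expect_error(score_duplex_penalty("ACGTX" , "ACGTA"), "alphabet")
})

test_that("adding a mismatch never decreases the penalty", {
  set.seed(41)
  mir <- "TGGCATTCACCGCGTGAGTTA"
  for (i in 1:50) {
    win <- rc(mir)
    pos <- sample(nchar(win), sample(0:4, 1))
    for (p in pos) substr(win, p, p) <- sample(c("A", "C", "G", "T"), 1)
    base <- score_duplex_penalty(mir, win)$penalty
    # corrupt one currently-matching position
    sc <- score_duplex_penalty(mir, win)
    matches <- which(sc$pairs == "match")
    if (!length(matches)) next
    mpos <- sample(matches, 1)
    tpos <- nchar(mir) - mpos + 1
    comp <- chartr("ACGT", "TGCA", substr(mir, mpos, mpos))
    win2 <- win
    substr(win2, tpos, tpos) <- setdiff(c("A", "C", "G", "T"), comp)[1]
    expect_gte(score_duplex_penalty(mir, win2)$penalty, base)
  }
})

test_that("scan_transcripts finds planted sites and matches the oracle", {
  set.seed(42)
  mir <- "TGGCATTCACCGCGTGAGTTA"
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  perfect <- rc(mir)
  weak <- perfect
  substr(weak, 3, 3) <- "A" # one corruption
  tx <- c(t1 = paste0(bg(300), perfect, bg(200), weak, bg(100)))
  sites <- scan_transcripts(mir, tx, max_penalty = 4)
  expect_gte(nrow(sites), 2L)
  expect_equal(sites$start[1], 301)
  expect_equal(sites$penalty[1], 0)
  expect_true(all(diff(sites$penalty) >= 0)) # sorted by penalty

  # exhaustive oracle equivalence, including a random 2-kb transcript
  tx2 <- c(tx, t2 = bg(2000))
  for (id in names(tx2)) {
    got <- scan_transcripts(mir, tx2[id], max_penalty = 6)
    want <- oracle_scan(mir, tx2[[id]], 6)
    expect_equal(nrow(got), nrow(want))
    got <- got[order(got$start), ]
    want <- want[order(want$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$penalty, want$penalty)
  }

  # random transcript at penalty 0: almost surely nothing, oracle agrees
  got0 <- scan_transcripts(mir, c(t = bg(1000)), max_penalty = 0)
  expect_equal(nrow(got0), nrow(oracle_scan(mir, bg(1000), 0)))

  # empty input
  expect_equal(nrow(scan_transcripts(mir, character(0))), 0L)
})

test_that("strict mode drops flagged sites", {
  mir <- "TGGCATTCACCGCGTGAGTTA"
  win <- rc(mir)
  p10 <- nchar(mir) - 10 + 1
  comp <- chartr("ACGT", "TGCA", substr(mir, 10, 10))
  substr(win, p10, p10) <- setdiff(c("A", "C", "G", "T"), c(comp, "G", "T"))[1]
  tx <- c(t1 = paste0("ACGTACGT", win, "ACGTACGT"))
  lax <- scan_transcripts(mir, tx, max_penalty = 4, enforce_flags = FALSE)
  strict <- scan_transcripts(mir, tx, max_penalty = 4, enforce_flags = TRUE)
  expect_equal(nrow(lax), 1L)
  expect_equal(nrow(strict), 0L)
})
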