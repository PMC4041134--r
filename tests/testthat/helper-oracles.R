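# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code.

# --- exact two-library test -------------------------------------------------

# term-by-term direct summation of the conditional tail probabilities using
# the multiplicative recurrence t_{k+1} = t_k * (x+k+1)/(k+1) * q, with
# q = (N2/N1)/(1+N2/N1); no lgamma, no logsumexp.
oracle_ac_tails <- function(x, y, N1, N2) {
  r <- N2 / N1
  q <- r / (1 + r)
  t0 <- (1 / (1 + r))^(x + 1)
  if (y == 0) {
    return(list(C = min(t0, 1), D = 1))
  }
  k <- seq_len(y)
  terms <- t0 * cumprod((x + k) / k * q) # t_k = p(k|x), k = 1..y
  C <- t0 + sum(terms)
  # D includes the observed count: D = 1 - sum_{k <= y-1}
  D <- 1 - (C - terms[y])
  if (D < 0.5) {
    # small upper tails: sum upward directly to dodge cancellation
    t <- terms[y]
    D <- t
    kk <- y
    while (t > D * 1e-18 && kk < y + 100000) {
      t <- t * (x + kk + 1) / (kk + 1) * q
      D <- D + t
      kk <- kk + 1
    }
  }
  list(C = min(C, 1), D = max(min(D, 1), 0))
}

oracle_ac_pvalue <- function(x, y, N1, N2) {
  tl <- oracle_ac_tails(x, y, N1, N2)
  min(1, 2 * min(tl$C, tl$D))
}

# --- exact substring matching ----------------------------------------------

# naive O(n*m) scan over both strands of a named character-vector genome
oracle_exact_hits <- function(genome, tag) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  for (ch in names(genome)) {
    s <- genome[[ch]]
    w <- nchar(tag)
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") tag else srnamir::revcomp(tag)
      from <- 1L
      repeat {
        hit <- regexpr(probe, substr(s, from, nchar(s)), fixed = TRUE)
        if (hit < 0L) break
        st <- from + as.integer(hit) - 1L
        out <- rbind(out, data.frame(chrom = ch, start = st,
                                     end = st + w - 1L, strand = strand,
                                     stringsAsFactors = FALSE))
        from <- st + 1L
      }
    }
  }
  out
}

# --- hairpin criteria -------------------------------------------------------

# recompute every criterion directly from the structure string, with an
# independent pairing parse (position stack walked with a while loop) and
# run-length logic written out by hand
oracle_evaluate <- function(structure, mature_start, mature_len, mfe,
                            n_genome_copies, params) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      pt[i] <- stack[length(stack)]
      pt[stack[length(stack)]] <- i
      stack <- stack[-length(stack)]
    }
    i <- i + 1L
  }
  m1 <- mature_start
  m2 <- mature_start + mature_len - 1L
  partners <- pt[m1:m2]
  ok_out <- partners != 0L & !(partners >= m1 & partners <= m2)
  fails <- character(0)
  if (mature_len < params$min_mirna_len || mature_len > params$max_mirna_len) {
    fails <- c(fails, "mature_length")
  }
  if (is.na(mfe) || mfe > params$max_free_energy) fails <- c(fails, "free_energy")
  if (!is.na(n_genome_copies) && n_genome_copies > params$max_genome_copies) {
    fails <- c(fails, "genome_copies")
  }
  if (!any(ok_out)) {
    fails <- c(fails, "min_duplex_pairs", "spacing", "max_bulge", "asymmetry")
    return(sort(unique(fails)))
  }
  pp <- sort(partners[ok_out])
  # densest partner cluster (split at gaps > 10), as the duplex definition
  groups <- list()
  cur <- pp[1]
  for (v in pp[-1]) {
    if (v - cur[length(cur)] > 10L) {
      groups[[length(groups) + 1L]] <- cur
      cur <- v
    } else cur <- c(cur, v)
  }
  groups[[length(groups) + 1L]] <- cur
  sizes <- vapply(groups, length, integer(1))
  cl <- groups[[which.max(sizes)]]
  s1 <- min(cl)
  s2 <- min(max(cl) + 2L, length(ch))
  paired <- partners >= s1 & partners <= s2
  if (sum(paired) < params$min_duplex_pairs) fails <- c(fails, "min_duplex_pairs")
  spacing <- if (s1 > m2) s1 - m2 - 1L else max(m1 - s2 - 1L, 0L)
  if (spacing > params$max_spacing) fails <- c(fails, "spacing")
  runs_of_unpaired <- function(flags) {
    idx <- which(flags)
    if (length(idx) < 2L) return(integer(0))
    runs <- integer(0)
    cur <- 0L
    for (j in idx[1]:idx[length(idx)]) {
      if (!flags[j]) cur <- cur + 1L
      else {
        if (cur > 0L) runs <- c(runs, cur)
        cur <- 0L
      }
    }
    runs
  }
  m_runs <- runs_of_unpaired(paired)
  spaired <- pt[s1:s2] >= m1 & pt[s1:s2] <= m2
  s_runs <- runs_of_unpaired(spaired)
  if (max(c(m_runs, s_runs, 0L)) > params$max_bulge) fails <- c(fails, "max_bulge")
  if (abs(sum(m_runs) - sum(s_runs)) > params$max_asymmetry) {
    fails <- c(fails, "asymmetry")
  }
  sort(unique(fails))
}

# --- target scanning --------------------------------------------------------

# exhaustive window scorer written against the scoring table definition,
# position by position
oracle_scan <- function(mirna, tx_seq, max_penalty) {
  n <- nchar(mirna)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  hits <- list()
  for (st in seq_len(max(nchar(tx_seq) - n + 1L, 0L))) {
    win <- substr(tx_seq, st, st + n - 1L)
    t <- rev(strsplit(win, "")[[1]])
    pen <- 0
    for (i in seq_len(n)) {
      mult <- if (i >= 2 && i <= 13) 2 else 1
      if (comp[[m[i]]] == t[i]) {
        # Watson-Crick
      } else if ((m[i] == "G" && t[i] == "T") || (m[i] == "T" && t[i] == "G")) {
        pen <- pen + 0.5 * mult
      } else {
        pen <- pen + 1 * mult
      }
    }
    if (pen <= max_penalty) {
      hits[[length(hits) + 1L]] <- data.frame(start = st, penalty = pen)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), penalty = numeric()))
  }
  do.call(rbind, hits)
}

# --- small FASTQ construction ----------------------------------------------

write_test_fastq <- function(path, seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  writeLines(c(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# random hairpin-ish candidate structures for the evaluator cross-check:
# a stem with random bulges on either side, a loop, and a mature placement
random_candidate <- function() {
  stem <- sample(10:25, 1)
  loop <- sample(3:20, 1)
  left <- character(0)
  right <- character(0)
  for (i in seq_len(stem)) {
    left <- c(left, "(")
    right <- c(")", right)
    if (stats::runif(1) < 0.25) {
      side <- sample(c("l", "r", "b"), 1)
      blen <- sample(1:6, 1)
      if (side %in% c("l", "b")) left <- c(left, rep(".", blen))
      if (side %in% c("r", "b")) right <- c(rep(".", sample(1:6, 1)), right)
    }
  }
  db <- paste(c(rep(".", sample(0:8, 1)), left, rep(".", loop), right,
                rep(".", sample(0:8, 1))), collapse = "")
  n <- nchar(db)
  mlen <- sample(16:27, 1)
  mstart <- sample(seq_len(max(n - mlen, 1)), 1)
  list(structure = db, mature_start = mstart,
       mature_len = min(mlen, n - mstart + 1L),
       mfe = -stats::runif(1, 5, 40),
       n_genome_copies = sample(c(1L, 1L, 1L, 5L, 25L), 1))
}
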