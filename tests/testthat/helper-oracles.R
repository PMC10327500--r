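# Independent naive oracles: character-level sliding windows and direct
# formula evaluation, sharing no code with the package internals.

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Brute-force canonical word list: enumerate all 4^k words, collapse
# each onto the smaller of {w, revcomp(w)}.
naive_canonical_words <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  all_words <- apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste,
                     collapse = "")
  canon <- vapply(all_words,
                  function(w) min(w, naive_revcomp(w)), character(1))
  sort(unique(unname(canon)))
}

# Occurrences of each canonical class on both strands, N windows skipped.
naive_canonical_counts <- function(s, k) {
  words <- naive_canonical_words(k)
  counts <- setNames(rep(0, length(words)), words)
  for (strand in c(s, naive_revcomp(s))) {
    ch <- strsplit(strand, "")[[1]]
    n <- length(ch)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- paste(ch[i:(i + k - 1)], collapse = "")
      if (!grepl("N", w, fixed = TRUE)) {
        cw <- min(w, naive_revcomp(w))
        counts[cw] <- counts[cw] + 1
      }
    }
  }
  counts
}

# Direct evaluation of the rho formula from both-strand class counts and
# both-strand mononucleotide frequencies.
naive_rho <- function(s, k) {
  counts <- naive_canonical_counts(s, k)
  total <- sum(counts)
  ch <- strsplit(s, "")[[1]]
  ch <- ch[ch != "N"]
  nb <- table(factor(ch, levels = c("A", "C", "G", "T")))
  n <- sum(nb)
  p <- c(A = unname(nb["A"] + nb["T"]) / (2 * n),
         C = unname(nb["C"] + nb["G"]) / (2 * n),
         G = unname(nb["C"] + nb["G"]) / (2 * n),
         T = unname(nb["A"] + nb["T"]) / (2 * n))
  vapply(names(counts), function(w) {
    members <- unique(c(w, naive_revcomp(w)))
    fexp <- sum(vapply(members, function(m) {
      prod(p[strsplit(m, "")[[1]]])
    }, numeric(1)))
    fobs <- counts[[w]] / total
    if (fexp == 0) 0 else fobs / fexp
  }, numeric(1))
}

# Random ACGT(N) string.
random_seq <- function(n, p_n = 0, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (p_n > 0) probs <- c(probs * (1 - p_n), p_n)
  letters <- if (p_n > 0) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(letters, n, replace = TRUE, prob = probs), collapse = "")
}

# Bare signature object for tests that need prescribed coordinates.
fake_signature <- function(id, values, k = 3L) {
  structure(list(source_id = id, k = as.integer(k),
                 values = values, bases_used = NA_real_),
            class = "kmer_signature")
}

# Bare score result with prescribed numbers.
fake_score <- function(plasmid_id, chrom_id, d2, df = 32L, pvalue = NULL,
                       k = 3L, L = 5000L, n_segments = 200L) {
  structure(list(plasmid_id = plasmid_id, chrom_id = chrom_id,
                 k = as.integer(k), L = as.integer(L),
                 n_segments = as.integer(n_segments), df = as.integer(df),
                 d2 = d2,
                 pvalue = if (is.null(pvalue)) d2_pvalue(d2, df) else pvalue),
            class = "score_result")
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
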