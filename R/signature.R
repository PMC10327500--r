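#' Canonical k-mer space
#'
#' Because words are counted on both strands, a word and its reverse
#' complement always receive identical statistics; keeping both would
#' duplicate coordinates and make the segment covariance singular.  The
#' feature space is therefore collapsed to canonical words: the
#' lexicographically smaller member of each \{w, revcomp(w)\} pair.  The
#' dimension is 10 for k = 2, 32 for k = 3, and 136 for k = 4 (pairs of
#' size two, plus self-complementary palindromes at even k).
#'
#' @param k Word length; 2, 3, and 4 are the supported defaults.
#' @return An object of class `kmer_space` with fields `k`, `words`
#'   (sorted canonical words), and `dim`.
#' @examples
#' canonical_space(3)$dim   # 32
#' @export
canonical_space <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k == as.integer(k), k >= 1, k <= 8)
  k <- as.integer(k)
  all_words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc_all <- rc_words(all_words)
  canon <- sort(unique(ifelse(all_words <= rc_all, all_words, rc_all)),
                method = "radix")
  rc_canon <- rc_words(canon)
  i1 <- match(canon, all_words)
  i2 <- match(rc_canon, all_words)
  palindrome <- i1 == i2
  # count multiplier: both-strand occurrences of the whole RC class are
  # 2*(fwd[c] + fwd[rc(c)]) for pairs and 2*fwd[c] for palindromes;
  # fwd[i1] + fwd[i2] already doubles palindromes, so pairs get the 2.
  count_mult <- ifelse(palindrome, 1, 2)
  # expected class frequency is (class size) * prod p(base); prod p is
  # strand-symmetric, so the class size is 1 (palindrome) or 2 (pair).
  class_size <- ifelse(palindrome, 1, 2)
  base_comp <- t(vapply(strsplit(canon, ""), function(ch) {
    c(A = sum(ch == "A"), C = sum(ch == "C"),
      G = sum(ch == "G"), T = sum(ch == "T"))
  }, numeric(4)))
  rownames(base_comp) <- canon
  structure(list(k = k, words = canon, dim = length(canon),
                 i1 = i1, i2 = i2, palindrome = palindrome,
                 count_mult = count_mult, class_size = class_size,
                 base_comp = base_comp),
            class = "kmer_space")
}

# Reverse complement of a character vector of ACGT words.
rc_words <- function(words) {
  vapply(strsplit(chartr("ACGT", "TGCA", words), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("<kmer_space> k=%d, %d canonical words\n", x$k, x$dim))
  invisible(x)
}

as_space <- function(k_or_space) {
  if (inherits(k_or_space, "kmer_space")) k_or_space else canonical_space(k_or_space)
}

#' Both-strand canonical k-mer counts
#'
#' Counts, for every canonical word, the occurrences of its
#' reverse-complement class on both strands of the sequence: class
#' \{c, revcomp(c)\} is counted as `2 * (fwd(c) + fwd(revcomp(c)))`, and a
#' palindromic class as `2 * fwd(c)` (one occurrence per strand).  Windows
#' containing `N` are skipped, so the counts always sum to twice the
#' number of N-free windows.  A sequence shorter than `k` yields all
#' zeros.
#'
#' @param seq A `seq_record` (or plain ACGTN string).
#' @param space A `kmer_space`, or an integer `k`.
#' @return Named integer vector of counts over the canonical words.
#' @export
count_kmers_both_strands <- function(seq, space = 3L) {
  space <- as_space(space)
  bases <- record_bases(seq)
  fwd <- forward_counts(Biostrings::DNAStringSet(bases), space$k)
  counts <- (fwd[, space$i1, drop = FALSE] + fwd[, space$i2, drop = FALSE])
  counts <- counts[1, ] * space$count_mult
  names(counts) <- space$words
  storage.mode(counts) <- "integer"
  counts
}

record_bases <- function(seq) {
  if (inherits(seq, "seq_record")) return(seq$bases)
  if (is.character(seq) && length(seq) == 1L) return(normalize_bases(seq))
  ph_stop("ph_input_error", "expected a seq_record or a single string")
}

record_id <- function(seq) {
  if (inherits(seq, "seq_record")) seq$id else "seq"
}

# Forward-strand word counts for a DNAStringSet; windows containing any
# letter outside ACGT contribute to no word.  Guards width > length.
forward_counts <- function(dss, k) {
  if (all(Biostrings::width(dss) < k)) {
    nw <- 4^k
    m <- matrix(0L, nrow = length(dss), ncol = nw)
    colnames(m) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    return(m)
  }
  Biostrings::oligonucleotideFrequency(dss, width = k)
}

# Rho signatures for a set of sequences, vectorized across rows.
# Returns list(values = n x d matrix, windows = n N-free window counts).
rho_matrix <- function(dss, space) {
  fwd <- forward_counts(dss, space$k)
  counts <- fwd[, space$i1, drop = FALSE] + fwd[, space$i2, drop = FALSE]
  counts <- sweep(counts, 2L, space$count_mult, "*")
  total <- rowSums(counts)                     # = 2 * N-free windows
  af <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  af <- af[, c("A", "C", "G", "T"), drop = FALSE]
  nb <- rowSums(af)
  nb[nb == 0] <- NA_real_
  # both-strand mononucleotide frequencies: p(A)=p(T), p(C)=p(G)
  pat <- (af[, "A"] + af[, "T"]) / (2 * nb)
  pcg <- (af[, "C"] + af[, "G"]) / (2 * nb)
  logp <- log(cbind(A = pat, C = pcg, G = pcg, T = pat))
  logp[!is.finite(logp)] <- -1e10              # absent base: expected freq 0
  fexp <- exp(logp %*% t(space$base_comp))
  fexp <- sweep(fexp, 2L, space$class_size, "*")
  fobs <- counts / ifelse(total > 0, total, 1)
  rho <- fobs / fexp
  rho[fexp == 0 | !is.finite(rho)] <- 0        # 0/0 convention: rho = 0
  rho[total == 0, ] <- 0
  colnames(rho) <- space$words
  list(values = rho, windows = total / 2)
}

#' Rho-normalized k-mer signature
#'
#' The genomic signature of a sequence: for each canonical word class,
#' the ratio of its observed both-strand frequency to the frequency
#' expected from the sequence's base composition alone (a zero-order,
#' mononucleotide product background).  Values near 1 mean the word is as
#' common as base composition predicts; the departures are what carry the
#' host lineage signal.  Both-strand counting makes the signature exactly
#' invariant under reverse complementation.
#'
#' @param seq A `seq_record` (or ACGTN string).
#' @param space A `kmer_space`, or an integer `k` (default 3).
#' @return An object of class `kmer_signature` with fields `source_id`,
#'   `k`, `values` (named numeric, one per canonical word), and
#'   `bases_used` (number of N-free windows counted on one strand).
#' @export
rho_signature <- function(seq, space = 3L) {
  space <- as_space(space)
  rm <- rho_matrix(Biostrings::DNAStringSet(record_bases(seq)), space)
  if (rm$windows[1] == 0) {
    ph_stop("ph_degenerate_error",
            "sequence '%s' has no N-free window of length %d",
            record_id(seq), space$k)
  }
  new_signature(record_id(seq), space$k, rm$values[1, ], rm$windows[1])
}

new_signature <- function(source_id, k, values, bases_used = NA_real_) {
  structure(list(source_id = source_id, k = as.integer(k),
                 values = values, bases_used = bases_used),
            class = "kmer_signature")
}

#' @export
print.kmer_signature <- function(x, ...) {
  cat(sprintf("<kmer_signature> %s: k=%d, d=%d, windows=%s\n",
              x$source_id, x$k, length(x$values),
              format(x$bases_used, big.mark = ",")))
  invisible(x)
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` positions are excluded from
#' both numerator and denominator.
#'
#' @param seq A `seq_record` (or ACGTN string).
#' @return Fraction in \[0, 1\].
#' @examples
#' gc_content("ACGN")   # 2/3
#' @export
gc_content <- function(seq) {
  af <- Biostrings::alphabetFrequency(
    Biostrings::DNAString(record_bases(seq)), baseOnly = TRUE)
  n <- sum(af[c("A", "C", "G", "T")])
  if (n == 0) {
    ph_stop("ph_degenerate_error",
            "sequence '%s' has no unambiguous base", record_id(seq))
  }
  unname((af["G"] + af["C"]) / n)
}

#' Write / read signature tables
#'
#' Tab-separated with columns `source_id`, `k`, `bases_used`, then one
#' column per canonical word in space order, at full double precision.
#'
#' @param signatures List of `kmer_signature` objects (all with the same
#'   `k`).
#' @param path Output (input) TSV path.
#' @return `write_signatures()` returns `path` invisibly;
#'   `read_signatures()` returns a list of `kmer_signature` objects.
#' @export
write_signatures <- function(signatures, path) {
  signatures <- check_signature_set(signatures, require_unique = FALSE)
  words <- names(signatures[[1]]$values)
  rows <- vapply(signatures, function(s) {
    paste(c(s$source_id, s$k, format(s$bases_used, digits = 17),
            format(s$values, digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("source_id", "k", "bases_used", words), collapse = "\t"),
               rows), path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) {
    ph_stop("ph_input_error", "signature table not found: '%s'", path)
  }
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  words <- setdiff(colnames(tab), c("source_id", "k", "bases_used"))
  lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, words])
    names(vals) <- words
    new_signature(tab$source_id[i], tab$k[i], vals, tab$bases_used[i])
  })
}

check_signature_set <- function(signatures, require_unique = TRUE) {
  if (inherits(signatures, "kmer_signature")) signatures <- list(signatures)
  if (!is.list(signatures) || length(signatures) == 0L ||
      !all(vapply(signatures, inherits, logical(1), "kmer_signature"))) {
    ph_stop("ph_input_error", "expected a non-empty list of kmer_signature objects")
  }
  ks <- vapply(signatures, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) {
    ph_stop("ph_input_error", "signatures mix word sizes: %s",
            paste(unique(ks), collapse = ", "))
  }
  ids <- vapply(signatures, `[[`, character(1), "source_id")
  if (require_unique && anyDuplicated(ids)) {
    ph_stop("ph_input_error", "duplicate signature ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  signatures
}
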