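#' Construct a sequence record
#'
#' A `seq_record` holds one nucleotide sequence (plasmid, chromosome, or
#' chromosomal segment) as an uppercase string over the alphabet
#' \{A, C, G, T, N\}.  Lowercase letters are uppercased and every IUPAC
#' ambiguity code (and any other non-ACGT character) is mapped to `N`;
#' downstream k-mer counting skips windows containing `N`.
#'
#' @param id Unique identifier (first whitespace-delimited token of a
#'   FASTA header).
#' @param bases Nucleotide string; normalized on construction.
#' @param description Free-text remainder of the FASTA header.
#' @return An object of class `seq_record` with fields `id`,
#'   `description`, `bases`, and `length`.
#' @examples
#' r <- seq_record("p1", "acgtRySW")
#' r$bases   # "ACGTNNNN"
#' @export
seq_record <- function(id, bases, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(bases), length(bases) == 1L)
  bases <- normalize_bases(bases)
  structure(list(id = id,
                 description = description,
                 bases = bases,
                 length = nchar(bases)),
            class = "seq_record")
}

normalize_bases <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%s bp)%s\n", x$id,
              format(x$length, big.mark = ","),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Read a FASTA file into sequence records
#'
#' Reads a (possibly gzip-compressed) FASTA file and returns one
#' [seq_record()] per entry, in file order.  Sequences are normalized to
#' uppercase ACGTN (see [seq_record()]).
#'
#' @param path Path to a FASTA file (`.gz` accepted).
#' @return List of `seq_record` objects in file order.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    ph_stop("ph_input_error", "FASTA file not found: '%s'", as.character(path)[1])
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    ph_stop("ph_format_error", "cannot parse FASTA '%s': %s",
                            path, conditionMessage(e))
                  })
  if (length(set) == 0L) {
    ph_stop("ph_format_error", "no FASTA records in '%s'", path)
  }
  headers <- names(set)
  if (is.null(headers)) headers <- rep("", length(set))
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    ph_stop("ph_format_error", "FASTA record '%s' in '%s' has an empty sequence",
            ids[which(empty)[1]], path)
  }
  unname(Map(seq_record, ids, seqs, descs))
}

#' Write sequence records to a FASTA file
#'
#' @param records List of `seq_record` objects.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_seq_records(records)
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "bases"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path),
                              width = width)
  invisible(path)
}

as_seq_records <- function(records) {
  if (inherits(records, "seq_record")) return(list(records))
  if (!is.list(records) || !all(vapply(records, inherits, logical(1), "seq_record"))) {
    ph_stop("ph_input_error", "expected a seq_record or a list of seq_record objects")
  }
  records
}

#' Select the largest replicon of a genome
#'
#' Multi-replicon genomes are reduced to their largest chromosome before
#' signature modelling; the segment-signature distribution is fitted on a
#' single replicon.  Length ties are broken by the lexicographically
#' smallest id, so the choice is deterministic and permutation-invariant.
#'
#' @param records Non-empty list of `seq_record` objects.
#' @return The selected `seq_record`.
#' @export
select_largest_replicon <- function(records) {
  records <- as_seq_records(records)
  if (length(records) == 0L) {
    ph_stop("ph_input_error", "cannot select a replicon from an empty collection")
  }
  lens <- vapply(records, `[[`, numeric(1), "length")
  ids <- vapply(records, `[[`, character(1), "id")
  top <- which(lens == max(lens))
  records[[top[order(ids[top], method = "radix")[1]]]]
}

#' Check that a replicon is long enough for segment modelling
#'
#' Fitting the segment-signature covariance needs more segments than the
#' signature dimension, so very short replicons must be excluded (their
#' covariance matrix would be singular).  The minimal usable length for a
#' given word size and segment length is [min_chromosome_length()].
#'
#' @param record A `seq_record`.
#' @param min_length Minimum acceptable length in bases.
#' @return `record`, invisibly, if it passes.
#' @export
validate_for_analysis <- function(record, min_length) {
  stopifnot(inherits(record, "seq_record"),
            is.numeric(min_length), length(min_length) == 1L, min_length >= 0)
  if (record$length < min_length) {
    ph_stop("ph_exclusion_error",
            "replicon '%s' excluded: length %d b is below the minimum %d b",
            record$id, record$length, as.integer(min_length))
  }
  invisible(record)
}

#' Minimal chromosome length for segment-model fitting
#'
#' The segment model needs at least `d + 2` complete segments, where `d`
#' is the canonical k-mer dimension, so that the sample covariance of the
#' segment signatures is invertible with a margin of two.
#'
#' @param k Word size (2, 3, or 4).
#' @param L Segment length in bases (default 5000).
#' @return Minimal usable chromosome length in bases: `(d + 2) * L`.
#' @examples
#' min_chromosome_length(3)   # 170000
#' @export
min_chromosome_length <- function(k, L = 5000L) {
  (canonical_space(k)$dim + 2L) * as.integer(L)
}
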