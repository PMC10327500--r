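#' Rank candidate hosts for one plasmid
#'
#' Orders the pairwise scores of a single plasmid by ascending
#' Mahalanobis D2 (ties broken by chromosome id) and flags evolutionary
#' host candidates: chromosomes whose chi-square P-value is strictly
#' greater than the threshold (default 0.6).
#'
#' @param scores List of `score_result` objects (or an equivalent data
#'   frame), all for the same plasmid and word size.
#' @param threshold Candidate P-value threshold in \[0, 1\]; strict
#'   inequality.
#' @return A `prediction_table`: a data frame with columns `plasmid_id`,
#'   `chrom_id`, `rank`, `k`, `L`, `n_segments`, `df`, `d2`, `pvalue`,
#'   `is_candidate`, sorted by ascending `d2`, with attributes
#'   `plasmid_id`, `threshold`, `max_pvalue`, and `median_d2`.
#' @export
rank_hosts <- function(scores, threshold = 0.6) {
  df <- scores_to_df(scores)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (is.null(df) || nrow(df) == 0L) {
    ph_stop("ph_input_error", "no scores supplied")
  }
  if (length(unique(df$plasmid_id)) != 1L) {
    ph_stop("ph_input_error", "scores mix plasmids: %s",
            paste(unique(df$plasmid_id), collapse = ", "))
  }
  if (length(unique(df$k)) != 1L) {
    ph_stop("ph_input_error", "scores mix word sizes")
  }
  ord <- order(df$d2, df$chrom_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$is_candidate <- df$pvalue > threshold
  rownames(df) <- NULL
  df <- df[, c("plasmid_id", "chrom_id", "rank", "k", "L", "n_segments",
               "df", "d2", "pvalue", "is_candidate")]
  structure(df,
            plasmid_id = df$plasmid_id[1],
            threshold = threshold,
            max_pvalue = max(df$pvalue),
            median_d2 = median(df$d2),
            class = c("prediction_table", "data.frame"))
}

scores_to_df <- function(scores) {
  if (is.data.frame(scores)) return(scores)
  if (inherits(scores, "score_result")) scores <- list(scores)
  if (!is.list(scores) ||
      !all(vapply(scores, inherits, logical(1), "score_result"))) {
    ph_stop("ph_input_error", "expected score_result objects or a data frame")
  }
  do.call(rbind, lapply(scores, function(s) {
    data.frame(plasmid_id = s$plasmid_id, chrom_id = s$chrom_id,
               k = s$k, L = s$L, n_segments = s$n_segments, df = s$df,
               d2 = s$d2, pvalue = s$pvalue, stringsAsFactors = FALSE)
  }))
}

#' Evolutionary host candidates of a prediction table
#'
#' Rows whose P-value strictly exceeds the threshold.  A P-value above
#' 0.6 marks the chromosome as an evolutionary host candidate: the
#' plasmid's signature is statistically compatible with the chromosome's
#' segment-signature distribution.
#'
#' @param table A `prediction_table` from [rank_hosts()].
#' @param threshold Candidate threshold (default: the table's own,
#'   normally 0.6).
#' @return The candidate subset of the table's rows (a data frame).
#' @export
classify_candidates <- function(table, threshold = attr(table, "threshold")) {
  stopifnot(inherits(table, "prediction_table"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  out <- as.data.frame(table)[table$pvalue > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction table to TSV
#'
#' Deterministic bytes for a fixed table: columns `plasmid_id`,
#' `chrom_id`, `rank`, `n_segments`, `df`, `d2`, `pvalue`,
#' `is_candidate`; floats formatted `%.6g`; logicals as `true`/`false`.
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  stopifnot(inherits(table, "prediction_table"))
  header <- paste(c("plasmid_id", "chrom_id", "rank", "n_segments", "df",
                    "d2", "pvalue", "is_candidate"), collapse = "\t")
  rows <- sprintf("%s\t%s\t%d\t%d\t%d\t%.6g\t%.6g\t%s",
                  table$plasmid_id, table$chrom_id, table$rank,
                  table$n_segments, table$df, table$d2, table$pvalue,
                  ifelse(table$is_candidate, "true", "false"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) ph_stop("ph_io_error",
                                              "cannot write '%s': %s",
                                              path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Score many plasmids against many hosts
#'
#' Fits each host chromosome's segment model once, computes each plasmid
#' signature once, scores every pair, and returns one ranked
#' [rank_hosts()] table per plasmid.  Hosts too short for model fitting
#' are excluded with a warning naming them (never silently).
#'
#' @param plasmids,hosts Lists of `seq_record` objects (a single record
#'   is accepted).
#' @param k Word size (default 3).
#' @param L Segment length (default 5000).
#' @param threshold Candidate P-value threshold (default 0.6).
#' @param cov_denominator See [fit_segment_model()].
#' @return Named list of `prediction_table` objects, one per plasmid.
#' @export
predict_hosts <- function(plasmids, hosts, k = 3L, L = 5000L,
                          threshold = 0.6,
                          cov_denominator = c("n-1", "n")) {
  plasmids <- as_seq_records(plasmids)
  hosts <- as_seq_records(hosts)
  cov_denominator <- match.arg(cov_denominator)
  excluded <- character(0)
  models <- list()
  for (h in hosts) {
    m <- tryCatch(fit_segment_model(h, k = k, L = L,
                                    cov_denominator = cov_denominator),
                  ph_exclusion_error = function(e) e)
    if (inherits(m, "condition")) {
      excluded <- c(excluded, h$id)
    } else {
      models[[h$id]] <- m
    }
  }
  if (length(excluded) > 0L) {
    warning(sprintf("excluded %d host(s) too short for k=%d, L=%d: %s",
                    length(excluded), as.integer(k), as.integer(L),
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  if (length(models) == 0L) {
    ph_stop("ph_input_error", "no usable host chromosomes remain")
  }
  tables <- lapply(plasmids, function(p) {
    sig <- rho_signature(p, k)
    rank_hosts(lapply(models, score_signature, sig = sig),
               threshold = threshold)
  })
  names(tables) <- vapply(plasmids, `[[`, character(1), "id")
  tables
}

#' Summarize a set of prediction tables
#'
#' One row per plasmid: number of hosts scored, maximum P-value, median
#' D2, and number of candidate hosts — the summaries used to judge
#' whether any evolutionary host candidate exists for a plasmid.
#'
#' @param tables List of `prediction_table` objects.
#' @return Data frame with columns `plasmid_id`, `n_hosts`,
#'   `max_pvalue`, `median_d2`, `n_candidates`.
#' @export
summarize_predictions <- function(tables) {
  if (inherits(tables, "prediction_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "prediction_table")))
  do.call(rbind, lapply(tables, function(t) {
    data.frame(plasmid_id = attr(t, "plasmid_id"),
               n_hosts = nrow(t),
               max_pvalue = attr(t, "max_pvalue"),
               median_d2 = attr(t, "median_d2"),
               n_candidates = sum(t$is_candidate),
               stringsAsFactors = FALSE)
  }))
}
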