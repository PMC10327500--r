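#' Build a compositional taxon model
#'
#' A seeded Markov generative model standing in for one bacterial
#' lineage.  Each context's transition row is a convex combination of
#' the GC-matched i.i.d. distribution and a seeded random perturbation,
#' scaled by `divergence`; the perturbation is constrained so every row
#' keeps `P(G) + P(C) = gc_target`, which pins the stationary GC content
#' to the target exactly while `divergence` controls how distinctive the
#' short-word transition structure is.
#'
#' @param taxon_id Identifier for the taxon.
#' @param gc_target Target GC fraction in \[0.2, 0.8\] (real host
#'   chromosomes span roughly 0.35-0.68).
#' @param divergence Scalar in \[0, 1\]: 0 gives the i.i.d. model, larger
#'   values give a more idiosyncratic transition structure.
#' @param order Markov order (default 2: rich enough to shape 3-mer
#'   signatures, cheap to simulate).
#' @param seed Integer seed; the model is a pure function of its
#'   arguments.
#' @return An object of class `taxon_model` with fields `taxon_id`,
#'   `order`, `trans` (4^order x 4 row-stochastic matrix), `gc_target`,
#'   `divergence`, `seed`.
#' @export
make_taxon_model <- function(taxon_id, gc_target, divergence = 0.3,
                             order = 2L, seed = 1L) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L,
            is.numeric(divergence), length(divergence) == 1L,
            divergence >= 0, divergence <= 1,
            is.numeric(order), length(order) == 1L, order >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(gc_target) || length(gc_target) != 1L ||
      gc_target < 0.2 || gc_target > 0.8) {
    ph_stop("ph_input_error", "gc_target must be in [0.2, 0.8], got %s",
            format(gc_target))
  }
  order <- as.integer(order)
  ncontext <- 4L^order
  base <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
            G = gc_target / 2, T = (1 - gc_target) / 2)
  trans <- with_seed(seed, {
    t(vapply(seq_len(ncontext), function(i) {
      w <- stats::rgamma(4, shape = 1)
      # renormalize within the AT and GC pools so row GC == gc_target
      pert <- c((1 - gc_target) * w[1] / (w[1] + w[4]),
                gc_target * w[2] / (w[2] + w[3]),
                gc_target * w[3] / (w[2] + w[3]),
                (1 - gc_target) * w[4] / (w[1] + w[4]))
      (1 - divergence) * base + divergence * pert
    }, numeric(4)))
  })
  colnames(trans) <- c("A", "C", "G", "T")
  rownames(trans) <- if (order == 0L) "" else {
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), order)
  }
  structure(list(taxon_id = taxon_id, order = order, trans = trans,
                 gc_target = gc_target, divergence = divergence,
                 seed = as.integer(seed)),
            class = "taxon_model")
}

#' @export
print.taxon_model <- function(x, ...) {
  cat(sprintf("<taxon_model> %s: order %d, GC %.3f, divergence %.2f, seed %d\n",
              x$taxon_id, x$order, x$gc_target, x$divergence, x$seed))
  invisible(x)
}

#' Simulate a sequence from a taxon model
#'
#' Generates a Markov chain of the model's order; the first `order`
#' bases are drawn i.i.d. from the model's average base distribution.
#' Deterministic for fixed (model, length, seed).
#'
#' @param model A `taxon_model`.
#' @param length Sequence length in bases (at least `order + 1`).
#' @param seed Integer seed.
#' @param id Identifier for the resulting record (default
#'   `"{taxon_id}_sim"`).
#' @return A `seq_record`.
#' @export
simulate_sequence <- function(model, length, seed = 1L,
                              id = paste0(model$taxon_id, "_sim")) {
  stopifnot(inherits(model, "taxon_model"),
            is.numeric(length), length(length) == 1L,
            length >= model$order + 1)
  init <- colMeans(model$trans)
  bases <- with_seed(seed, {
    simulate_markov_cpp(model$trans, model$order, as.integer(length), init)
  })
  seq_record(id, bases)
}

#' Simulate a host-recovery benchmark
#'
#' Builds a complete, seeded benchmark: one chromosome per synthetic
#' taxon (GC targets evenly spaced across `gc_range`, distinct seeded
#' transition structure), one "narrow" plasmid per taxon drawn from that
#' taxon's model, and optionally "broad" plasmids whose halves come from
#' two compositionally adjacent taxa (a 50/50 mixture).  A truth table
#' maps every plasmid to its generating taxon (or pair).  The whole
#' benchmark is a pure function of its parameters and `seed`.
#'
#' @param n_taxa Number of taxa (at least 2; default 10).
#' @param chrom_length Chromosome length in bases (default 1e6); must be
#'   at least [min_chromosome_length()] for the chosen `k`, `L`.
#' @param plasmid_length Plasmid length in bases (default 5e4).
#' @param k Word size the benchmark targets (default 3).
#' @param L Segment length (default 5000).
#' @param divergence Between-taxon transition divergence (default 0.3).
#' @param gc_range GC span of the taxa (default `c(0.35, 0.68)`).
#' @param n_broad Number of 50/50 mixture plasmids (default 0).
#' @param order Markov order (default 2).
#' @param seed Master seed; all per-taxon seeds derive from it.
#' @return An object of class `host_benchmark`: `hosts` (list of
#'   `seq_record`, id = taxon id), `plasmids` (list of `seq_record`),
#'   `truth` (data frame `plasmid_id`, `taxon_id`, `taxon_id2`,
#'   `mixture`), `models`, `params`.
#' @export
simulate_benchmark <- function(n_taxa = 10L, chrom_length = 1e6,
                               plasmid_length = 5e4, k = 3L, L = 5000L,
                               divergence = 0.3,
                               gc_range = c(0.35, 0.68),
                               n_broad = 0L, order = 2L, seed = 1L) {
  stopifnot(n_taxa >= 2, n_broad >= 0)
  minlen <- min_chromosome_length(k, L)
  if (chrom_length < minlen) {
    ph_stop("ph_exclusion_error",
            "chrom_length %d is below the minimum %d for k=%d, L=%d",
            as.integer(chrom_length), minlen, as.integer(k), as.integer(L))
  }
  n_taxa <- as.integer(n_taxa)
  n_broad <- as.integer(n_broad)
  gc_targets <- seq(gc_range[1], gc_range[2], length.out = n_taxa)
  sub <- with_seed(seed, sample.int(2^31 - 2, 3L * n_taxa + 2L * n_broad))
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  models <- lapply(seq_len(n_taxa), function(i) {
    make_taxon_model(taxa[i], gc_targets[i], divergence = divergence,
                     order = order, seed = sub[i])
  })
  names(models) <- taxa
  hosts <- lapply(seq_len(n_taxa), function(i) {
    simulate_sequence(models[[i]], chrom_length, seed = sub[n_taxa + i],
                      id = taxa[i])
  })
  plasmids <- lapply(seq_len(n_taxa), function(i) {
    simulate_sequence(models[[i]], plasmid_length,
                      seed = sub[2L * n_taxa + i],
                      id = sprintf("plasmid%02d", i))
  })
  truth <- data.frame(plasmid_id = sprintf("plasmid%02d", seq_len(n_taxa)),
                      taxon_id = taxa, taxon_id2 = NA_character_,
                      mixture = 1, stringsAsFactors = FALSE)
  if (n_broad > 0L) {
    # adjacent-GC pairs: mixtures between compositionally distant taxa
    # resemble neither parent, so adjacent pairing is the regime where
    # parent recovery is meaningful
    pair_start <- with_seed(sub[3L * n_taxa + 1L],
                            sample.int(n_taxa - 1L, n_broad,
                                       replace = n_broad > n_taxa - 1L))
    half <- as.integer(plasmid_length) %/% 2L
    for (b in seq_len(n_broad)) {
      i <- pair_start[b]; j <- i + 1L
      s <- sub[3L * n_taxa + n_broad + b]
      h1 <- simulate_sequence(models[[i]], half, seed = s)
      h2 <- simulate_sequence(models[[j]], plasmid_length - half, seed = s + 1L)
      pid <- sprintf("broad%02d", b)
      plasmids <- c(plasmids, list(seq_record(pid, paste0(h1$bases, h2$bases))))
      truth <- rbind(truth, data.frame(plasmid_id = pid, taxon_id = taxa[i],
                                       taxon_id2 = taxa[j], mixture = 0.5,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(hosts = hosts, plasmids = plasmids, truth = truth,
                 models = models,
                 params = list(n_taxa = n_taxa,
                               chrom_length = as.integer(chrom_length),
                               plasmid_length = as.integer(plasmid_length),
                               k = as.integer(k), L = as.integer(L),
                               divergence = divergence,
                               gc_range = gc_range, n_broad = n_broad,
                               order = as.integer(order),
                               seed = as.integer(seed))),
            class = "host_benchmark")
}

#' @export
print.host_benchmark <- function(x, ...) {
  cat(sprintf("<host_benchmark> %d taxa, %d plasmids, seed %d\n",
              x$params$n_taxa, length(x$plasmids), x$params$seed))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Writes `hosts.fasta`, `plasmids.fasta`, `truth.tsv`, and
#' `params.json` into a directory.
#'
#' @param benchmark A `host_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "host_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(benchmark$hosts, file.path(dir, "hosts.fasta"))
  write_fasta(benchmark$plasmids, file.path(dir, "plasmids.fasta"))
  write.table(benchmark$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(benchmark$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Evaluate host-recovery predictions against benchmark truth
#'
#' Summarizes how well ranked predictions recover the generating taxa:
#' rank-1 accuracy and mean true-host rank over the single-taxon
#' ("narrow") plasmids, candidate precision/recall at the tables'
#' P-value threshold over all plasmids, and, when mixture plasmids are
#' present, the fraction whose two parents occupy the top two ranks.
#'
#' @param tables List of `prediction_table` objects (chromosome ids must
#'   be the benchmark taxon ids).
#' @param truth The benchmark `truth` data frame (or a `host_benchmark`).
#' @return One-row data frame: `n_narrow`, `rank1_accuracy`,
#'   `mean_true_rank`, `candidate_precision`, `candidate_recall`,
#'   `n_broad`, `broad_top2_rate`.
#' @export
evaluate_recovery <- function(tables, truth) {
  if (inherits(truth, "host_benchmark")) truth <- truth$truth
  if (inherits(tables, "prediction_table")) tables <- list(tables)
  if (length(tables) == 0L) {
    ph_stop("ph_input_error", "no prediction tables supplied")
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "prediction_table")))
  pids <- vapply(tables, attr, character(1), "plasmid_id")
  missing <- setdiff(pids, truth$plasmid_id)
  if (length(missing) > 0L) {
    ph_stop("ph_input_error", "plasmid(s) absent from truth: %s",
            paste(missing, collapse = ", "))
  }
  tp <- 0L; n_cand <- 0L; n_rel <- 0L
  ranks <- numeric(0); top2 <- logical(0)
  for (t in tables) {
    row <- truth[truth$plasmid_id == attr(t, "plasmid_id"), ]
    parents <- stats::na.omit(c(row$taxon_id, row$taxon_id2))
    cand <- t$chrom_id[t$is_candidate]
    tp <- tp + sum(cand %in% parents)
    n_cand <- n_cand + length(cand)
    n_rel <- n_rel + sum(parents %in% t$chrom_id)
    if (is.na(row$taxon_id2)) {
      ranks <- c(ranks, t$rank[match(row$taxon_id, t$chrom_id)])
    } else {
      top2 <- c(top2, setequal(t$chrom_id[t$rank <= 2L], parents))
    }
  }
  data.frame(n_narrow = length(ranks),
             rank1_accuracy = if (length(ranks)) mean(ranks == 1) else NA_real_,
             mean_true_rank = if (length(ranks)) mean(ranks) else NA_real_,
             candidate_precision = if (n_cand) tp / n_cand else NA_real_,
             candidate_recall = if (n_rel) tp / n_rel else NA_real_,
             n_broad = length(top2),
             broad_top2_rate = if (length(top2)) mean(top2) else NA_real_)
}
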