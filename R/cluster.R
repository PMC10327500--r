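#' Pairwise Euclidean dissimilarity of signatures
#'
#' The dissimilarity used to cluster plasmid signatures:
#' `sqrt(sum_c (rho_i(c) - rho_j(c))^2)` over the canonical words.
#'
#' @param signatures List of `kmer_signature` objects with identical `k`
#'   and unique ids (at least two).
#' @return An object of class `signature_dist`: `ids` plus a symmetric
#'   nonnegative `values` matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(signatures) {
  signatures <- check_signature_set(signatures)
  if (length(signatures) < 2L) {
    ph_stop("ph_input_error", "need at least two signatures")
  }
  ids <- vapply(signatures, `[[`, character(1), "source_id")
  X <- do.call(rbind, lapply(signatures, `[[`, "values"))
  rownames(X) <- ids
  values <- as.matrix(dist(X, method = "euclidean"))
  structure(list(ids = ids, values = values), class = "signature_dist")
}

#' @export
print.signature_dist <- function(x, ...) {
  cat(sprintf("<signature_dist> %d sequences\n", length(x$ids)))
  invisible(x)
}

#' Write a distance matrix to TSV
#'
#' @param dm A `signature_dist`.
#' @param path Output path; square matrix with row and column ids.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "signature_dist"))
  write.table(format(dm$values, digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Hierarchical grouping of signatures
#'
#' Agglomerative clustering of a signature dissimilarity matrix.  The
#' default linkage is average (UPGMA); single, complete and Ward are
#' available for matching other conventions.  The partition is
#' deterministic for a given matrix and invariant to input order.
#'
#' @param dm A `signature_dist` from [pairwise_euclidean()].
#' @param n_groups Number of groups to cut the tree into (between 1 and
#'   the number of ids).
#' @param linkage One of `"average"`, `"single"`, `"complete"`,
#'   `"ward"`.
#' @return An object of class `signature_clustering`: `labels` (named
#'   integer group per id), `tree` (an `hclust`), `newick` (the tree in
#'   Newick format), `n_groups`, `linkage`.
#' @export
hierarchical_groups <- function(dm, n_groups,
                                linkage = c("average", "single",
                                            "complete", "ward")) {
  stopifnot(inherits(dm, "signature_dist"),
            is.numeric(n_groups), length(n_groups) == 1L)
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L || n_groups > length(dm$ids)) {
    ph_stop("ph_input_error",
            "n_groups must be between 1 and %d", length(dm$ids))
  }
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(as.dist(dm$values), method = method)
  labels <- cutree(tree, k = n_groups)
  structure(list(labels = labels, tree = tree,
                 newick = ape::write.tree(ape::as.phylo(tree)),
                 n_groups = n_groups, linkage = linkage),
            class = "signature_clustering")
}

#' @export
print.signature_clustering <- function(x, ...) {
  cat(sprintf("<signature_clustering> %d ids in %d groups (%s linkage)\n",
              length(x$labels), x$n_groups, x$linkage))
  invisible(x)
}

#' Write cluster results
#'
#' Writes the group labels as a two-column TSV (`id`, `group`) and,
#' optionally, the linkage tree in Newick format.
#'
#' @param clustering A `signature_clustering`.
#' @param labels_path Output TSV path for the labels.
#' @param newick_path Optional output path for the Newick tree.
#' @return `labels_path`, invisibly.
#' @export
write_cluster_labels <- function(clustering, labels_path,
                                 newick_path = NULL) {
  stopifnot(inherits(clustering, "signature_clustering"))
  writeLines(c("id\tgroup",
               sprintf("%s\t%d", names(clustering$labels),
                       clustering$labels)),
             labels_path)
  if (!is.null(newick_path)) writeLines(clustering$newick, newick_path)
  invisible(labels_path)
}
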