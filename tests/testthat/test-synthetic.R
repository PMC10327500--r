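test_that("taxon models are valid, seeded, and GC-pinned", {
  m <- make_taxon_model("t1", 0.55, divergence = 0.4, seed = 801)
  expect_equal(dim(m$trans), c(16, 4))
  expect_true(all(m$trans >= 0))
  expect_true(all(abs(rowSums(m$trans) - 1) < 1e-12))
  # every row keeps P(G) + P(C) at the GC target
  expect_true(all(abs(m$trans[, "C"] + m$trans[, "G"] - 0.55) < 1e-12))
  m2 <- make_taxon_model("t1", 0.55, divergence = 0.4, seed = 801)
  expect_identical(m$trans, m2$trans)
  m3 <- make_taxon_model("t1", 0.55, divergence = 0.4, seed = 802)
  expect_false(identical(m$trans, m3$trans))
  expect_error(make_taxon_model("t", 0.1, 0.3), class = "ph_input_error")
  expect_error(make_taxon_model("t", 0.9, 0.3), class = "ph_input_error")
})

test_that("divergence zero reduces to the i.i.d. model", {
  m <- make_taxon_model("iid", 0.5, divergence = 0, seed = 803)
  expect_true(all(abs(m$trans - 0.25) < 1e-12))
  s <- simulate_sequence(m, 1e6, seed = 804)
  expect_true(all(abs(rho_signature(s, 3)$values - 1) < 0.05))
})

test_that("simulated sequences hit the GC target", {
  m <- make_taxon_model("hi", 0.64, divergence = 0.3, seed = 805)
  s <- simulate_sequence(m, 1e6, seed = 806)
  gc <- gc_content(s)
  expect_gte(gc, 0.62)
  expect_lte(gc, 0.66)
})

test_that("simulation is seeded, alphabet-clean, and length-exact", {
  m <- make_taxon_model("t", 0.5, 0.3, seed = 807)
  s10 <- simulate_sequence(m, 10, seed = 808)
  expect_equal(s10$length, 10L)
  expect_true(grepl("^[ACGT]+$", s10$bases))
  a <- simulate_sequence(m, 1000, seed = 809)
  b <- simulate_sequence(m, 1000, seed = 809)
  c_ <- simulate_sequence(m, 1000, seed = 810)
  expect_identical(a$bases, b$bases)
  expect_gt(sum(strsplit(a$bases, "")[[1]] != strsplit(c_$bases, "")[[1]]), 0)
  expect_error(simulate_sequence(m, 2, seed = 1))   # below order + 1
})

test_that("empirical transition frequencies match the model within 0.01", {
  m <- make_taxon_model("t", 0.45, divergence = 0.5, seed = 811)
  s <- simulate_sequence(m, 1e6, seed = 812)
  tri <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s$bases))
  ctx <- substr(names(tri), 1, 2)
  nxt <- substr(names(tri), 3, 3)
  for (context in rownames(m$trans)) {
    n_ctx <- sum(tri[ctx == context])
    for (b in colnames(m$trans)) {
      emp <- tri[paste0(context, b)] / n_ctx
      expect_lt(abs(emp - m$trans[context, b]), 0.01)
    }
  }
})

test_that("simulate_sequence does not disturb the caller's RNG stream", {
  set.seed(813)
  before <- stats::runif(1)
  set.seed(813)
  m <- make_taxon_model("t", 0.5, 0.3, seed = 814)
  invisible(simulate_sequence(m, 1000, seed = 815))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("benchmarks are complete, labelled, and byte-deterministic", {
  b <- simulate_benchmark(n_taxa = 3, chrom_length = 2e5, plasmid_length = 2e4,
                          n_broad = 2, seed = 42)
  expect_length(b$hosts, 3)
  expect_length(b$plasmids, 5)
  expect_equal(nrow(b$truth), 5)
  expect_equal(anyDuplicated(b$truth$plasmid_id), 0L)
  expect_equal(b$truth$mixture, c(1, 1, 1, 0.5, 0.5))
  # mixture parents are compositionally adjacent taxa
  broad <- b$truth[b$truth$mixture == 0.5, ]
  idx <- function(x) as.integer(sub("taxon", "", x))
  expect_true(all(idx(broad$taxon_id2) == idx(broad$taxon_id) + 1L))

  b2 <- simulate_benchmark(n_taxa = 3, chrom_length = 2e5, plasmid_length = 2e4,
                           n_broad = 2, seed = 42)
  expect_identical(lapply(b$hosts, `[[`, "bases"),
                   lapply(b2$hosts, `[[`, "bases"))
  expect_identical(lapply(b$plasmids, `[[`, "bases"),
                   lapply(b2$plasmids, `[[`, "bases"))

  dir <- tempfile()
  write_benchmark(b, dir)
  expect_true(all(file.exists(file.path(dir, c("hosts.fasta", "plasmids.fasta",
                                               "truth.tsv", "params.json")))))
  hosts_back <- read_fasta(file.path(dir, "hosts.fasta"))
  expect_equal(vapply(hosts_back, `[[`, "", "bases"),
               vapply(b$hosts, `[[`, "", "bases"))
  params <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(params$n_taxa, 3)
  expect_equal(params$seed, 42)

  expect_error(simulate_benchmark(n_taxa = 2, chrom_length = 1e5, seed = 1),
               class = "ph_exclusion_error")
})

test_that("recovery evaluation scores perfect and degenerate inputs correctly", {
  truth <- data.frame(plasmid_id = c("p1", "p2"), taxon_id = c("t1", "t2"),
                      taxon_id2 = NA_character_, mixture = 1,
                      stringsAsFactors = FALSE)
  perfect <- list(
    rank_hosts(list(fake_score("p1", "t1", 5, pvalue = 0.9),
                    fake_score("p1", "t2", 500, pvalue = 0))),
    rank_hosts(list(fake_score("p2", "t2", 4, pvalue = 0.8),
                    fake_score("p2", "t1", 400, pvalue = 0))))
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$rank1_accuracy, 1.0)
  expect_equal(ev$mean_true_rank, 1.0)
  expect_equal(ev$candidate_precision, 1.0)
  expect_equal(ev$candidate_recall, 1.0)

  expect_error(evaluate_recovery(list(), truth), class = "ph_input_error")
  stranger <- list(rank_hosts(list(fake_score("pX", "t1", 5))))
  expect_error(evaluate_recovery(stranger, truth), class = "ph_input_error")
})

test_that("random rankings give chance-level rank-1 accuracy", {
  n_taxa <- 10
  taxa <- sprintf("t%02d", 1:n_taxa)
  set.seed(816)
  hits <- replicate(2000, {
    sample(taxa, 1) == taxa[1]
  })
  expect_lt(abs(mean(hits) - 1 / n_taxa), 0.03)

  # the same chance level through the evaluator itself
  truth <- data.frame(plasmid_id = "p1", taxon_id = taxa[1],
                      taxon_id2 = NA_character_, mixture = 1,
                      stringsAsFactors = FALSE)
  accs <- replicate(300, {
    d2 <- sample(seq(10, 100, length.out = n_taxa))
    tab <- rank_hosts(lapply(1:n_taxa, function(i) {
      fake_score("p1", taxa[i], d2[i])
    }))
    evaluate_recovery(list(tab), truth)$rank1_accuracy
  })
  expect_lt(abs(mean(accs) - 1 / n_taxa), 0.05)
})

test_that("taxon separation grows with divergence and recovery never drops", {
  med_cross <- numeric(0)
  accs <- numeric(0)
  for (dv in c(0.1, 0.3, 0.6)) {
    cross <- numeric(0)
    acc <- numeric(0)
    for (seed in 1:2) {
      b <- simulate_benchmark(n_taxa = 4, chrom_length = 4e5,
                              plasmid_length = 2e4, divergence = dv,
                              seed = seed)
      tabs <- predict_hosts(b$plasmids, b$hosts, k = 3)
      for (t in tabs) {
        own <- b$truth$taxon_id[b$truth$plasmid_id == attr(t, "plasmid_id")]
        cross <- c(cross, t$d2[t$chrom_id != own])
      }
      acc <- c(acc, evaluate_recovery(tabs, b)$rank1_accuracy)
    }
    med_cross <- c(med_cross, median(cross))
    accs <- c(accs, mean(acc))
  }
  expect_true(all(diff(med_cross) > 0))
  expect_true(all(diff(accs) >= 0))
})

test_that("mixture plasmids rank their two parents on top", {
  rates <- vapply(1:6, function(seed) {
    b <- simulate_benchmark(n_taxa = 6, chrom_length = 4e5,
                            plasmid_length = 3e4, n_broad = 2, seed = seed)
    tabs <- predict_hosts(b$plasmids, b$hosts, k = 3)
    evaluate_recovery(tabs, b)$broad_top2_rate
  }, numeric(1))
  expect_gte(mean(rates), 0.8)
})
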