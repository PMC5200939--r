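test_that("degenerate parameters give an exact V+D+J join", {
  db <- toy_db()
  set.seed(1)
  r <- simulate_rearrangement(db, trim_mean = 0, max_n_insert = 0L,
                              productive_only = FALSE)
  segs <- db$segments
  v <- segs$sequence[segs$segment_id == r$v_call]
  j <- segs$sequence[segs$segment_id == r$j_call]
  d_seqs <- segs$sequence[segs$gene_type == "D"]
  hit <- vapply(d_seqs, function(d) identical(r$sequence, paste0(v, d, j)), TRUE)
  expect_true(any(hit))
})

test_that("productive-only rearrangements are in frame with no stop codon", {
  db <- toy_db()
  set.seed(2)
  for (i in 1:50) {
    r <- simulate_rearrangement(db)
    expect_true(r$productive)
    expect_equal((r$j_anchor - r$v_anchor) %% 3L, 0L)
    expect_equal(nchar(r$cdr3_nt) %% 3L, 0L)
    expect_false(grepl("*", r$cdr3_aa, fixed = TRUE))
    expect_equal(translate_nt(r$cdr3_nt), r$cdr3_aa)
  }
})

test_that("rearrangement and repertoire draws are seed-deterministic", {
  db <- toy_db()
  set.seed(9); a <- simulate_rearrangement(db)
  set.seed(9); b <- simulate_rearrangement(db)
  expect_identical(a, b)
  m <- repertoire_model(100, "even_lognormal", lognormal_sigma = 1, seed = 42)
  expect_identical(simulate_repertoire(m, db), simulate_repertoire(m, db))
})

test_that("clone frequencies follow the abundance model", {
  db <- toy_db()
  # zero dispersion: exactly uniform
  m0 <- repertoire_model(50, "even_lognormal", lognormal_sigma = 0, seed = 1)
  f0 <- simulate_clone_frequencies(m0)
  expect_equal(f0, rep(1 / 50, 50))

  # HEC-dominated regime: expanded block floored at 1%, summing to its mass
  m1 <- repertoire_model(500, "hec_dominated", n_expanded = 22,
                         expanded_mass = 0.77, lognormal_sigma = 1, seed = 2)
  set.seed(2); f1 <- simulate_clone_frequencies(m1)
  expect_equal(sum(f1), 1, tolerance = 1e-9)
  expect_equal(sum(f1[1:22]), 0.77, tolerance = 1e-9)
  expect_true(all(f1[1:22] >= 0.01))
  expect_equal(sum(f1[1:22] >= 0.01), 22L)

  # infeasible configuration is rejected up front
  expect_error(repertoire_model(500, "hec_dominated", n_expanded = 80,
                                expanded_mass = 0.5), "infeasible")
})

test_that("truth-table frequencies always sum to one", {
  db <- toy_db()
  set.seed(3)
  for (mode in c("even_lognormal", "hec_dominated")) {
    m <- repertoire_model(200, mode, n_expanded = 10, expanded_mass = 0.4,
                          lognormal_sigma = 1.5)
    truth <- simulate_repertoire(m, db)
    expect_equal(sum(truth$frequency), 1, tolerance = 1e-9)
    expect_equal(nrow(truth), 200L)
    expect_false(any(duplicated(paste(truth$cdr3_nt, truth$v_family,
                                      truth$j_family))))
  }
})

test_that("sampled HEC count matches the planted number of expanded clones", {
  db <- toy_db()
  m <- repertoire_model(1000, "hec_dominated", n_expanded = 22,
                        expanded_mass = 0.77, lognormal_sigma = 1, seed = 11)
  truth <- simulate_repertoire(m, db)
  counts <- sample_read_counts(truth, 2e5)
  freqs <- counts / sum(counts)
  expect_equal(sum(freqs >= 0.01), 22L)
  expect_true(all(which(freqs >= 0.01) <= 22))
})

test_that("observed read shares converge to truth without bias or error", {
  db <- toy_db()
  m <- repertoire_model(100, "even_lognormal", lognormal_sigma = 1, seed = 4)
  truth <- simulate_repertoire(m, db)
  set.seed(4)
  sim <- simulate_reads(truth, sequencing_model(2e5, error_rate = 0))
  obs <- sim$counts$count / sum(sim$counts$count)
  expect_lt(max(abs(obs - truth$frequency)), 0.01)
  expect_equal(sum(sim$counts$count), 2e5)
  expect_error(sample_read_counts(truth, 0), "positive")
})

test_that("paired mates overlap as configured and reconstruct the fragment", {
  db <- toy_db()
  m <- repertoire_model(60, "even_lognormal", lognormal_sigma = 1, seed = 5)
  truth <- simulate_repertoire(m, db)
  set.seed(5)
  sim <- simulate_reads(truth, sequencing_model(200, read_length = 100,
                                                error_rate = 0, paired = TRUE,
                                                overlap = 30))
  frag <- truth$sequence[match(sub("_r.*$", "", sim$reads$read_id),
                               truth$clone_id)]
  n1 <- nchar(sim$reads$sequence1); n2 <- nchar(sim$reads$sequence2)
  expect_equal(n1 + n2 - 30L, nchar(frag))
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads$sequence2)))
  rebuilt <- paste0(sim$reads$sequence1, substr(rc2, 31L, n2))
  expect_identical(rebuilt, frag)
})

test_that("simulated junction lengths follow the enumerated generative law", {
  db <- toy_db()
  set.seed(6)
  draws <- tcrep:::draw_rearrangements(db, 5000L)
  pmf <- junction_length_pmf(db)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  fit <- chisq_vs_pmf(nchar(draws$cdr3_nt), pmf)
  expect_gt(fit$p.value, 0.01)
})

test_that("FASTQ output round-trips through the reader", {
  db <- toy_db()
  m <- repertoire_model(30, "even_lognormal", lognormal_sigma = 1, seed = 7)
  truth <- simulate_repertoire(m, db)
  fq <- tempfile(fileext = ".fastq")
  set.seed(7)
  sim <- simulate_reads(truth, sequencing_model(100), fastq_out = fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$read_id, sim$reads$read_id)
})
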