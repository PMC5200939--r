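test_that("perfect 30-base overlaps merge with exact arithmetic", {
  set.seed(99)
  frag <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")                                   # aperiodic
  r1 <- tibble::tibble(read_id = "p1", sequence = substr(frag, 1, 75),
                       quality = strrep("I", 75))
  r2 <- tibble::tibble(read_id = "p1",
                       sequence = as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(substr(frag, 46, 120)))),
                       quality = strrep("I", 75))
  out <- merge_pairs(r1, r2, min_overlap = 10)
  expect_equal(nchar(out$sequence), 75 + 75 - 30)
  expect_identical(out$sequence, frag)
  expect_equal(attr(out, "report")$n_merged, 1L)
})

test_that("pairs without sufficient overlap are counted and dropped", {
  r1 <- tibble::tibble(read_id = "p1", sequence = strrep("ACGT", 10),
                       quality = strrep("I", 40))
  r2 <- tibble::tibble(read_id = "p1", sequence = strrep("GGCA", 10),
                       quality = strrep("I", 40))
  out <- merge_pairs(r1, r2, min_overlap = 20, max_mismatch_rate = 0.1)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "report")$n_dropped, 1L)
  expect_error(merge_pairs(r1, r2[c(1, 1), ]), "pairing error")
})

test_that("overlap mismatches resolve to the higher-quality base", {
  # fragment with one planted disagreement inside a 30-base overlap
  left <- paste0(strrep("ACGTG", 9), "AAAAACCCCCGGGGGTTTTTACGTACGTAC")
  n <- nchar(left)                                 # 75
  ov1 <- substr(left, n - 29, n)
  ov2 <- ov1; substr(ov2, 5, 5) <- "T"             # mate2 disagrees at one base
  r1 <- tibble::tibble(read_id = "p", sequence = left, quality = strrep("I", n))
  mate2_fwd <- paste0(ov2, strrep("CATG", 10))
  r2 <- tibble::tibble(read_id = "p",
                       sequence = as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(mate2_fwd))),
                       quality = strrep("+", nchar(mate2_fwd)))  # Q10
  out <- merge_pairs(r1, r2, min_overlap = 15)
  # quality 40 on mate 1 beats quality 10 on mate 2
  expect_equal(substr(out$sequence, n - 29 + 4, n - 29 + 4),
               substr(ov1, 5, 5))

  # now give mate 2 the higher quality: its base must win
  r1lo <- r1; r1lo$quality <- strrep("+", n)
  r2hi <- r2; r2hi$quality <- strrep("I", nchar(mate2_fwd))
  out2 <- merge_pairs(r1lo, r2hi, min_overlap = 15)
  expect_equal(substr(out2$sequence, n - 29 + 4, n - 29 + 4), "T")
})

test_that("a read equal to V plus J is called exactly with identity 100", {
  db <- toy_db()
  read <- paste0(toy_segment("TRBV9*01"), toy_segment("TRBJ1-5*01"))
  ann <- annotate_reads(read, db)
  expect_equal(ann$v_call, "TRBV9*01")
  expect_equal(ann$j_call, "TRBJ1-5*01")
  expect_equal(ann$v_identity, 100)
  expect_equal(ann$j_identity, 100)
  expect_true(ann$pass_filter)
})

test_that("random reads fall below the identity threshold", {
  db <- toy_db()
  set.seed(1234)
  rnd <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""), "")
  ann <- annotate_reads(rnd, db)
  expect_true(all(ann$v_identity < 70))
  expect_false(any(ann$pass_filter))

  # a read too short to align is marked unalignable, not errored
  short <- annotate_reads("ACGTACGT", db)
  expect_true(is.na(short$v_call))
  expect_false(short$pass_filter)
})

test_that("equal-scoring alleles break ties to the smallest segment id", {
  db <- toy_db()
  segs <- db$segments
  dup <- segs[segs$segment_id == "TRBV9*01", ]
  dup$segment_id <- "TRBV9*02"
  db2 <- germline_db(dplyr::bind_rows(segs, dup))
  read <- paste0(toy_segment("TRBV9*01"), toy_segment("TRBJ1-5*01"))
  ann <- annotate_reads(read, db2)
  expect_equal(ann$v_call, "TRBV9*01")
})

test_that("identity filtering keeps the inclusive 70 percent boundary", {
  mk <- function(v, j) tibble::tibble(read_id = "r", v_identity = v,
                                      j_identity = j, productive = TRUE,
                                      cdr3_nt = "AAA")
  expect_equal(attr(filter_by_identity(mk(100, 100)), "report")$kept, 1L)
  expect_equal(attr(filter_by_identity(mk(69.9, 100)), "report")$kept, 0L)
  expect_equal(attr(filter_by_identity(mk(70, 70)), "report")$kept, 1L)
})

test_that("raising the identity threshold never adds reads", {
  db <- toy_db()
  m <- repertoire_model(150, "even_lognormal", lognormal_sigma = 1, seed = 8)
  truth <- simulate_repertoire(m, db)
  set.seed(8)
  sim <- simulate_reads(truth, sequencing_model(600, error_rate = 0.02))
  ann <- annotate_reads(sim$reads, db)
  prev <- ann$read_id
  for (th in c(70, 80, 90, 99)) {
    kept <- filter_by_identity(ann, th)$read_id
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("the worked dominant clone yields CDR3 ATAGLAGETQY", {
  db <- toy_db()
  read <- paste0(toy_segment("TRBV15*01"), "GCAGGACTGGCAGGG",
                 toy_segment("TRBJ2-5*01"))
  ann <- annotate_reads(read, db)
  expect_equal(ann$v_family, "TRBV15")
  expect_equal(ann$j_family, "TRBJ2-5")
  expect_equal(ann$cdr3_aa, "ATAGLAGETQY")
  expect_true(ann$productive)

  # CDR3 extraction ignores bases outside the anchor span
  padded <- paste0("GATTACAGATTACAGATTACA", read, "TTTTGGGGCCCC")
  expect_equal(annotate_reads(padded, db)$cdr3_aa, "ATAGLAGETQY")
})

test_that("stop codons and frameshifts are called unproductive", {
  db <- toy_db()
  # internal TAA stop inside an in-frame junction
  stop_read <- paste0(toy_segment("TRBV15*01"), "TAAGGACTGGCAGGG",
                      toy_segment("TRBJ2-5*01"))
  ann <- annotate_reads(stop_read, db)
  expect_false(ann$productive)
  expect_true(grepl("*", ann$cdr3_aa, fixed = TRUE))

  # anchor-to-anchor span of 3k+1 bases
  shift_read <- paste0(toy_segment("TRBV15*01"), "GCAGGACTGGCAGGGA",
                       toy_segment("TRBJ2-5*01"))
  ann2 <- annotate_reads(shift_read, db)
  expect_false(ann2$productive)
  expect_true(is.na(ann2$cdr3_aa))

  # low-level extractor agrees on the frame rule
  ext <- extract_cdr3("AAATGTACGTAGTTCAAA", v_anchor = 3L, j_anchor = 12L)
  expect_equal(ext$cdr3_nt, "ACGTAG")
  expect_false(ext$productive)            # TAG stop
})

test_that("annotation recovers truth for nearly all error-free reads", {
  db <- toy_db()
  m <- repertoire_model(500, "even_lognormal", lognormal_sigma = 1, seed = 21)
  truth <- simulate_repertoire(m, db)
  set.seed(21)
  sim <- simulate_reads(truth, sequencing_model(1e4, error_rate = 0))
  ann <- annotate_reads(sim$reads, db)
  truth_key <- paste(truth$v_family, truth$j_family, truth$cdr3_aa)
  read_truth <- truth_key[match(sub("_r.*$", "", ann$read_id), truth$clone_id)]
  read_ann <- paste(ann$v_family, ann$j_family, ann$cdr3_aa)
  expect_gte(mean(read_ann == read_truth, na.rm = FALSE), 0.99)
})
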