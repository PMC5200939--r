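two_family_sample <- function() {
  repertoire_sample(tibble::tibble(
    cdr3_nt = c("AAA", "CCC"), cdr3_aa = c("K", "P"),
    v_family = c("TRBV15", "TRBV9"), j_family = c("TRBJ2-5", "TRBJ1-1"),
    count = c(60L, 40L)), sample_id = "u1", group = "T1D", subset = "CD4")
}

test_that("usage profiles are read-weighted and zero-filled", {
  db <- toy_db()
  s <- make_sample(1, v_family = "TRBV15", j_family = "TRBJ2-5")
  u <- usage_profile(s, db)
  expect_equal(unname(u$v_usage[db$v_families == "TRBV15"]), 1)
  expect_equal(sum(u$v_usage), 1)
  expect_equal(sum(u$v_usage > 0), 1L)             # one-hot
  expect_length(u$v_usage, length(db$v_families))
  expect_length(u$j_usage, length(db$j_families))

  u2 <- usage_profile(two_family_sample(), db)
  expect_equal(unname(u2$v_usage[c("TRBV15", "TRBV9")]), c(0.6, 0.4),
               ignore_attr = TRUE)
})

test_that("uniform segment choice gives near-uniform usage within multinomial bands", {
  db <- toy_db()
  set.seed(41)
  draws <- tcrep:::draw_rearrangements(db, 3000L)
  s <- repertoire_sample(tibble::tibble(
    cdr3_nt = sprintf("N%05d", seq_len(nrow(draws))), cdr3_aa = "X",
    v_family = draws$v_family, j_family = draws$j_family, count = 1L),
    sample_id = "unif")
  u <- usage_profile(s, db, weight = "clone")
  # oracle: per-family multinomial CI, Bonferroni-corrected across the 17
  # family statistics so the joint band holds at the 1% level
  z <- qnorm(1 - 0.01 / (2 * (length(db$v_families) + length(db$j_families))))
  p <- 1 / length(db$v_families)
  band <- z * sqrt(p * (1 - p) / nrow(draws))
  expect_true(all(abs(u$v_usage - p) < band))
  pj <- 1 / length(db$j_families)
  bandj <- z * sqrt(pj * (1 - pj) / nrow(draws))
  expect_true(all(abs(u$j_usage - pj) < bandj))
})

test_that("usage correlations match hand-computed Pearson values", {
  mk <- function(id, v) structure(list(sample_id = id, v_usage = v,
                                       j_usage = v), class = "usage_profile")
  a <- mk("a", c(0.5, 0.3, 0.2)); b <- mk("b", c(0.2, 0.3, 0.5))
  r <- usage_correlation(list(a, a), "v")
  expect_equal(unname(r[1, 2]), 1)
  # hand Pearson: deviations (1/6, -1/30, -2/15) vs their reverse give
  # cov = -13/300 against common variance 14/300, so r = -13/14
  r2 <- usage_correlation(list(a, b), "v")
  expect_equal(unname(r2[1, 2]), -13 / 14, tolerance = 1e-9)
  expect_equal(r2, t(r2))
  expect_equal(unname(diag(r2)), c(1, 1))

  # one-hot vs uniform-ish is well-posed; a constant vector is NA, not 0
  onehot <- mk("c", c(1, 0, 0)); flat <- mk("d", c(1, 1, 1) / 3)
  r3 <- usage_correlation(list(onehot, flat, a), "v")
  expect_true(is.na(r3["c", "d"]))
  expect_false(is.na(r3["c", "a"]))
})

test_that("usage correlation matrices are symmetric and positive semidefinite", {
  db <- toy_db()
  set.seed(42)
  profs <- lapply(1:8, function(i) {
    f <- rgamma(length(db$v_families), 1); f <- f / sum(f)
    structure(list(sample_id = paste0("s", i), v_usage = f,
                   j_usage = f[seq_along(db$j_families)] /
                     sum(f[seq_along(db$j_families)])),
              class = "usage_profile")
  })
  r <- usage_correlation(profs, "v")
  expect_equal(r, t(r))
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("VJ matrices normalize to one and marginalize to the usage vectors", {
  db <- toy_db()
  s <- make_sample(1, v_family = "TRBV15", j_family = "TRBJ2-5")
  vj <- vj_matrix(s, db)
  expect_equal(sum(vj$matrix), 1)
  expect_equal(vj$matrix["TRBV15", "TRBJ2-5"], 1)
  expect_equal(vj$dominant$v_family, "TRBV15")
  expect_equal(vj$dominant$j_family, "TRBJ2-5")

  s2 <- two_family_sample()
  vj2 <- vj_matrix(s2, db)
  u2 <- usage_profile(s2, db)
  expect_equal(rowSums(vj2$matrix), u2$v_usage)
  expect_equal(colSums(vj2$matrix), u2$j_usage)
  # unobserved combinations are zero, not missing
  expect_equal(vj2$matrix["TRBV15", "TRBJ1-1"], 0)
  expect_false(anyNA(vj2$matrix))
})

test_that("spectratypes are read-weighted length histograms", {
  s <- make_sample(c(0.5, 0.3, 0.2), aas = c("AAAAAAAAAAAA", "CCCCCCCCCCCC",
                                             "GGGGGGGGGGGG"))
  sp <- spectratype(s)
  expect_equal(sp$length, 12L)
  expect_equal(sp$fraction, 1)

  s2 <- make_sample(c(0.7, 0.3), aas = c("AAAA", "CCCCCCCC"))
  sp2 <- spectratype(s2)
  expect_equal(sp2$fraction[sp2$length == 4L], 0.7)
  expect_equal(sum(sp2$fraction), 1)
})

test_that("expanded clones dominate the spectratype in the HEC regime", {
  db <- toy_db()
  m <- repertoire_model(400, "hec_dominated", n_expanded = 22,
                        expanded_mass = 0.77, lognormal_sigma = 1, seed = 43)
  truth <- simulate_repertoire(m, db)
  s <- repertoire_sample(tibble::tibble(
    cdr3_nt = truth$cdr3_nt, cdr3_aa = truth$cdr3_aa,
    v_family = truth$v_family, j_family = truth$j_family,
    count = pmax(1L, round(truth$frequency * 1e6))), sample_id = "hec")
  sp <- spectratype(s)
  exp_lens <- unique(nchar(truth$cdr3_aa[truth$expanded]))
  mass <- sum(sp$fraction[sp$length %in% exp_lens])
  expect_gte(mass, 0.769)
})
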