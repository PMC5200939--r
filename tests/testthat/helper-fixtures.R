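# Shared fixtures and independent oracles, built in code at test time.

toy_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- builtin_toy_reference()
    db
  }
})

toy_segment <- function(id) {
  segs <- toy_db()$segments
  segs$sequence[segs$segment_id == id]
}

# A repertoire_sample built directly from frequencies (counts scaled to a
# nominal depth), bypassing read simulation.
make_sample <- function(freqs, sample_id = "s1", group = "control",
                        subset = "CD4", aas = NULL, v_family = "TRBV15",
                        j_family = "TRBJ2-5", depth = 1e6) {
  n <- length(freqs)
  if (is.null(aas)) aas <- sprintf("CASS%04d", seq_len(n))
  repertoire_sample(
    tibble::tibble(cdr3_nt = sprintf("NT%04d", seq_len(n)), cdr3_aa = aas,
                   v_family = rep_len(v_family, n),
                   j_family = rep_len(j_family, n),
                   count = pmax(1L, round(freqs * depth)),
                   frequency = freqs),
    sample_id = sample_id, group = group, subset = subset)
}

# ---- independent oracle: exact junction-length law of the simulator ----
# Enumerates the pmf of the CDR3 nucleotide length (bases strictly between
# the anchors) from the generative parameters by direct convolution:
# uniform segment choice, geometric trimming collapsed at its cap, uniform
# N-insertion lengths. Implemented from the model definition, not from the
# simulator code.

geom_capped_pmf <- function(mean, cap) {
  p <- 1 / (1 + mean)
  pr <- p * (1 - p)^(0:cap)
  pr[cap + 1L] <- (1 - p)^cap
  pr
}

pmf_convolve <- function(a, b) {
  # a, b: numeric vectors over support 0..(len-1)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

pmf_mix <- function(pmfs) {
  len <- max(vapply(pmfs, length, 1L))
  acc <- numeric(len)
  for (p in pmfs) acc[seq_along(p)] <- acc[seq_along(p)] + p / length(pmfs)
  acc
}

junction_length_pmf <- function(db, trim_mean = 2, max_n_insert = 10L) {
  segs <- db$segments
  v_pmfs <- lapply(which(segs$gene_type == "V"), function(i) {
    cap <- nchar(segs$sequence[i]) - (segs$anchor_pos[i] + 3L)
    tr <- geom_capped_pmf(trim_mean, cap)
    rev(tr)                              # contrib = cap - trim, support 0..cap
  })
  j_pmfs <- lapply(which(segs$gene_type == "J"), function(i) {
    cap <- segs$anchor_pos[i]
    rev(geom_capped_pmf(trim_mean, cap)) # contrib = anchor - trim
  })
  d_pmfs <- lapply(which(segs$gene_type == "D"), function(i) {
    dlen <- nchar(segs$sequence[i])
    t5 <- geom_capped_pmf(trim_mean, dlen)
    contrib <- numeric(dlen + 1L)        # support 0..dlen
    for (a in 0:dlen) {
      t3 <- geom_capped_pmf(trim_mean, dlen - a)
      for (b in 0:(dlen - a))
        contrib[dlen - a - b + 1L] <- contrib[dlen - a - b + 1L] + t5[a + 1L] * t3[b + 1L]
    }
    contrib
  })
  n_pmf <- rep(1 / (max_n_insert + 1L), max_n_insert + 1L)
  out <- pmf_convolve(pmf_mix(v_pmfs), n_pmf)
  out <- pmf_convolve(out, pmf_mix(d_pmfs))
  out <- pmf_convolve(out, n_pmf)
  pmf_convolve(out, pmf_mix(j_pmfs))
}

# chi-square goodness of fit of observed integer lengths against a pmf over
# support 0..(length(pmf)-1), pooling cells with small expected counts
chisq_vs_pmf <- function(lengths, pmf, min_expected = 5) {
  n <- length(lengths)
  obs <- tabulate(lengths + 1L, nbins = length(pmf))
  keep <- pmf * n >= min_expected
  obs_p <- c(obs[keep], sum(obs[!keep]))
  exp_p <- c(pmf[keep], sum(pmf[!keep]))
  if (exp_p[length(exp_p)] == 0) { obs_p <- obs_p[-length(obs_p)]; exp_p <- exp_p[-length(exp_p)] }
  suppressWarnings(stats::chisq.test(obs_p, p = exp_p / sum(exp_p)))
}

# frequency-level entropy of one simulated cohort arm
arm_entropies <- function(n_samples, model) {
  vapply(seq_len(n_samples), function(i)
    shannon_entropy_normalized(simulate_clone_frequencies(model)), 1)
}
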