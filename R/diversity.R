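#' Normalized Shannon entropy of clone frequencies
#'
#' Computes `H = -sum(p * log p) / log n`, with `n` the number of observed
#' clones: 1 is a maximally even repertoire, 0 a single clone (the `n = 1`
#' case returns 0 by convention). The log base cancels in the normalization;
#' natural log is used internally. Frequencies must be positive and are
#' renormalized when their sum is within `1e-6` of 1.
#'
#' @param frequencies positive clone frequencies.
#' @return normalized entropy in \[0, 1\].
#' @export
shannon_entropy_normalized <- function(frequencies) {
  p <- as.numeric(frequencies)
  if (length(p) == 0L) stop("at least one frequency required")
  if (any(!is.finite(p)) || any(p <= 0))
    stop("frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-6)
    stop("frequencies must sum to 1 (within 1e-6)")
  p <- p / sum(p)
  n <- length(p)
  if (n == 1L) return(0)
  -sum(p * log(p)) / log(n)
}

#' Call highly- and lowly-expanded clones
#'
#' A clonotype is a highly-expanded clone (HEC) when its within-sample
#' frequency is at or above `threshold` (inclusive; the conventional cutoff
#' is 1% of reads). The partition into HECs and LECs is exhaustive and
#' disjoint.
#'
#' @param sample a `repertoire_sample`.
#' @param threshold HEC frequency cutoff, in (0, 1).
#' @return list with `hec` and `lec`, each a clonotype tibble.
#' @export
call_hecs <- function(sample, threshold = 0.01) {
  check_fraction(threshold, "threshold", open = TRUE)
  tab <- as_tibble(sample)
  is_hec <- tab$frequency >= threshold
  list(hec = tab[is_hec, ], lec = tab[!is_hec, ])
}

#' Per-sample diversity report
#'
#' Bundles clone richness, normalized Shannon entropy, the HEC count and the
#' HEC ratio (total read fraction held by HECs) for one sample. Entropy is
#' computed on nucleotide-level clonotype frequencies by default (the finest
#' observed partition); set `level = "aa"` for amino-acid-level sensitivity
#' analysis.
#'
#' @param sample a `repertoire_sample`.
#' @param threshold HEC cutoff, see [call_hecs()].
#' @param level `"nt"` or `"aa"` clonotype resolution for the entropy.
#' @return one-row tibble: `sample_id`, `group`, `subset`, `n_clones`,
#'   `entropy`, `hec_count`, `hec_ratio`.
#' @export
diversity_report <- function(sample, threshold = 0.01, level = c("nt", "aa")) {
  level <- match.arg(level)
  tab <- as_tibble(sample)
  if (nrow(tab) == 0L) stop("empty sample")
  m <- sample_meta(sample)
  freqs <- if (level == "aa") aggregate_by_aa(sample)$frequency else tab$frequency
  hecs <- call_hecs(sample, threshold)
  tibble(sample_id = m$sample_id %||% NA_character_,
         group = m$group %||% NA_character_,
         subset = m$subset %||% NA_character_,
         n_clones = nrow(tab),
         entropy = shannon_entropy_normalized(freqs),
         hec_count = nrow(hecs$hec),
         hec_ratio = sum(hecs$hec$frequency))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diversity reports for a cohort
#'
#' @param samples list of `repertoire_sample` objects.
#' @param ... passed to [diversity_report()].
#' @return tibble with one row per sample.
#' @export
cohort_diversity <- function(samples, ...) {
  bind_rows(lapply(samples, diversity_report, ...))
}
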