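#' Cycle-series container
#'
#' Read counts for the same clones amplified from one template at two or more
#' PCR cycle numbers — the input to amplification-bias estimation.
#'
#' @param counts integer matrix, clones x cycle points.
#' @param cycles increasing integer vector of cycle numbers, one per column.
#' @param v_family optional V family per clone (for usage-stability checks).
#' @return a `cycle_series` list.
#' @export
cycle_series <- function(counts, cycles, v_family = NULL) {
  counts <- as.matrix(counts)
  if (length(cycles) < 2L) stop("need at least two cycle points")
  if (ncol(counts) != length(cycles))
    stop("one count column per cycle point required")
  if (!is.null(v_family) && length(v_family) != nrow(counts))
    stop("v_family must have one entry per clone")
  structure(list(counts = counts, cycles = as.integer(cycles),
                 v_family = v_family),
            class = "cycle_series")
}

cycle_col <- function(series, cycle) {
  i <- match(cycle, series$cycles)
  if (is.na(i)) stop("cycle ", cycle, " not present in series")
  series$counts[, i]
}

#' Estimate PCR amplification bias from a cycle series
#'
#' Quantifies the per-clone variation in amplification between a low- and a
#' high-cycle sequencing of the same template. Each clone's expected
#' high-cycle count is its low-cycle count scaled by the depth ratio; the
#' fold variation is `v = max(obs/exp, exp/obs)`. Clones are binned by
#' low-cycle count into log-spaced bins (merged so each holds at least
#' `min_per_bin` clones) and the accumulated bias `k` is the intercept-only
#' least-squares level of the bin means — i.e. their mean — with a linear
#' regression on log10 count reported as a diagnostic. The per-cycle bias is
#' `k^(1/(c2-c1))`. Multinomial sampling noise is not subtracted, so `k`
#' upper-bounds pure amplification bias at low counts.
#'
#' @param series a [cycle_series()].
#' @param c1,c2 the two cycle numbers to compare (`c2 > c1`).
#' @param n_bins target number of log-spaced bins.
#' @param min_per_bin minimum clones per bin after merging.
#' @return list with `c1`, `c2`, `k` (accumulated fold bias, >= 1),
#'   `per_cycle_bias` (= `k^(1/(c2-c1))`), `n_clones`, `bins` (tibble of bin
#'   centers, sizes and mean fold variation), and `diagnostics` (slope,
#'   intercept, residual SD of bin mean vs log10 count).
#' @export
estimate_bias <- function(series, c1, c2, n_bins = 12L, min_per_bin = 20L) {
  stopifnot(inherits(series, "cycle_series"))
  if (c2 <= c1) stop("c2 must exceed c1")
  x1 <- cycle_col(series, c1); x2 <- cycle_col(series, c2)
  shared <- x1 > 0 & x2 > 0
  if (sum(shared) < 100L)
    stop("insufficient data: fewer than 100 clones observed at both cycle points")
  x1 <- as.numeric(x1[shared]); x2 <- as.numeric(x2[shared])
  expected <- x1 * sum(x2) / sum(x1)
  v <- pmax(x2 / expected, expected / x2)

  breaks <- exp(seq(log(min(x1)), log(max(x1)), length.out = n_bins + 1L))
  breaks[1] <- breaks[1] - 1e-9; breaks[n_bins + 1L] <- breaks[n_bins + 1L] + 1e-9
  bin <- cut(x1, breaks, labels = FALSE)
  # merge sparse bins left-to-right so each holds >= min_per_bin clones
  sizes <- tabulate(bin, nbins = n_bins)
  relab <- integer(n_bins); cur <- 1L; acc <- 0L
  for (i in seq_len(n_bins)) {
    relab[i] <- cur
    acc <- acc + sizes[i]
    if (acc >= min_per_bin && i < n_bins) { cur <- cur + 1L; acc <- 0L }
  }
  if (acc < min_per_bin && cur > 1L) relab[relab == cur] <- cur - 1L
  bin <- relab[bin]

  bins <- tibble(center = as.numeric(tapply(x1, bin, function(z) exp(mean(log(z))))),
                 n = as.integer(tapply(x1, bin, length)),
                 mean_v = as.numeric(tapply(v, bin, mean)))
  k <- mean(bins$mean_v)                      # intercept-only least squares
  diag_fit <- if (nrow(bins) >= 2) {
    fit <- stats::lm(mean_v ~ log10(center), data = bins)
    list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
         residual_sd = stats::sigma(fit))
  } else list(slope = NA_real_, intercept = bins$mean_v[1], residual_sd = NA_real_)

  list(c1 = c1, c2 = c2, k = k, per_cycle_bias = k^(1 / (c2 - c1)),
       n_clones = length(x1), bins = bins, diagnostics = diag_fit)
}

#' V-family usage stability across cycle numbers
#'
#' Mean absolute relative deviation of V gene-family usage between two cycle
#' points, over the `top_n` families by high-cycle usage — a check that
#' primer efficiencies are balanced at the family level.
#'
#' @param series a [cycle_series()] with `v_family` set.
#' @param c1,c2 cycle numbers to compare.
#' @param top_n families considered (by usage at `c2`); if fewer families are
#'   observed, all are used with a warning.
#' @return list with `deviation` (mean over families of `|u1 - u2| / u2`) and
#'   `usage` (tibble of per-family usage at both points).
#' @export
vgene_usage_stability <- function(series, c1, c2, top_n = 20L) {
  stopifnot(inherits(series, "cycle_series"))
  if (is.null(series$v_family)) stop("series lacks per-clone V families")
  x1 <- cycle_col(series, c1); x2 <- cycle_col(series, c2)
  u1 <- tapply(x1, series$v_family, sum) / sum(x1)
  u2 <- tapply(x2, series$v_family, sum) / sum(x2)
  fams <- names(sort(u2, decreasing = TRUE))
  fams <- fams[u2[fams] > 0]
  if (length(fams) < top_n) {
    warning("only ", length(fams), " observed V families; using all")
    top_n <- length(fams)
  }
  fams <- fams[seq_len(top_n)]
  dev <- abs(u1[fams] - u2[fams]) / u2[fams]
  list(deviation = mean(dev),
       usage = tibble(v_family = fams, usage_c1 = as.numeric(u1[fams]),
                      usage_c2 = as.numeric(u2[fams]),
                      rel_dev = as.numeric(dev)))
}
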