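#' V/J family usage profile of a sample
#'
#' Read-weighted gene-family frequencies over the fixed, cohort-wide family
#' ordering of the germline reference (unobserved families are zero-filled so
#' profiles are comparable across samples). Reads are the weighting unit;
#' set `weight = "clone"` to weight every clonotype equally instead.
#'
#' @param sample a `repertoire_sample`.
#' @param db the [germline_db()] fixing the family ordering.
#' @param weight `"read"` (default) or `"clone"`.
#' @return a `usage_profile`: list with `sample_id`, `v_usage` and `j_usage`
#'   (named fraction vectors, each summing to 1).
#' @export
usage_profile <- function(sample, db, weight = c("read", "clone")) {
  weight <- match.arg(weight)
  tab <- as_tibble(sample)
  w <- if (weight == "read") tab$count else rep(1, nrow(tab))
  usage_of <- function(fam, levels) {
    u <- tapply(w, factor(fam, levels = levels), sum, default = 0)
    u <- as.numeric(u) / sum(w)
    names(u) <- levels
    u
  }
  structure(list(sample_id = attr(sample, "sample_id"),
                 v_usage = usage_of(tab$v_family, db$v_families),
                 j_usage = usage_of(tab$j_family, db$j_families)),
            class = "usage_profile")
}

#' Pairwise Pearson correlation of usage profiles
#'
#' Pearson correlation of the V (or J) family-usage vectors of every sample
#' pair, as used to compare gene-usage structure across individuals. The
#' matrix is symmetric with unit diagonal; a zero-variance usage vector makes
#' its correlations undefined and they are reported as `NA`, not 0.
#'
#' @param profiles list of [usage_profile()] objects with identical family
#'   ordering.
#' @param gene `"v"` or `"j"`.
#' @return symmetric matrix of Pearson r, dimnames = sample ids.
#' @export
usage_correlation <- function(profiles, gene = c("v", "j")) {
  gene <- match.arg(gene)
  if (length(profiles) < 2L) stop("need at least two usage profiles")
  vecs <- vapply(profiles, function(p) p[[paste0(gene, "_usage")]],
                 numeric(length(profiles[[1]][[paste0(gene, "_usage")]])))
  ids <- vapply(profiles, function(p) p$sample_id %||% "", "")
  r <- suppressWarnings(cor(vecs, method = "pearson"))
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  r
}

#' V x J combination matrix of a sample
#'
#' Read-fraction per (V family, J family) cell; rows/columns follow the
#' reference family ordering and empty combinations are 0. Row and column
#' sums equal the [usage_profile()] vectors exactly.
#'
#' @inheritParams usage_profile
#' @return list with `sample_id`, `matrix` (V families x J families, entries
#'   summing to 1) and `dominant` (one-row tibble naming the largest cell and
#'   its read fraction).
#' @export
vj_matrix <- function(sample, db) {
  tab <- as_tibble(sample)
  m <- matrix(0, length(db$v_families), length(db$j_families),
              dimnames = list(db$v_families, db$j_families))
  agg <- tab %>%
    group_by(.data$v_family, .data$j_family) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  m[cbind(match(agg$v_family, db$v_families),
          match(agg$j_family, db$j_families))] <- agg$count
  m <- m / sum(m)
  top <- arrayInd(which.max(m), dim(m))
  list(sample_id = attr(sample, "sample_id"), matrix = m,
       dominant = tibble(v_family = db$v_families[top[1]],
                         j_family = db$j_families[top[2]],
                         fraction = m[top]))
}

#' CDR3 length spectratype
#'
#' Read-weighted histogram of CDR3 amino-acid lengths (anchors excluded),
#' the classic skew indicator for repertoires.
#'
#' @inheritParams usage_profile
#' @return tibble with `length` (aa) and `fraction` (sums to 1).
#' @export
spectratype <- function(sample, weight = c("read", "clone")) {
  weight <- match.arg(weight)
  tab <- as_tibble(sample)
  w <- if (weight == "read") tab$count else rep(1, nrow(tab))
  len <- nchar(tab$cdr3_aa)
  h <- tapply(w, factor(len, levels = sort(unique(len))), sum, default = 0)
  tibble(length = as.integer(names(h)), fraction = as.numeric(h) / sum(w))
}
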