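#' Build a clonotype table from annotated reads
#'
#' Collapses annotated reads into clonotypes keyed by
#' `(cdr3_nt, v_family, j_family)`. Only productive, filter-passing reads
#' enter; frequencies are normalized over those reads (the "total number of
#' CDR3 sequences" denominator — unproductive reads have no CDR3 to count).
#'
#' @param reads tibble from [annotate_reads()], or any tibble with columns
#'   `cdr3_nt`, `cdr3_aa`, `v_family`, `j_family`, `productive`,
#'   `pass_filter` and optionally `count` (per-row read multiplicity,
#'   default 1).
#' @param sample_id,group,subset sample metadata; `group` is typically one of
#'   `"T1D"`, `"T2D"`, `"control"`, and `subset` `"CD4"` or `"CD8"`.
#' @return a `repertoire_sample`: tibble of clonotypes (`cdr3_nt`, `cdr3_aa`,
#'   `v_family`, `j_family`, `count`, `frequency`) sorted by descending count
#'   (ties: `cdr3_nt` lexicographic), with `sample_id`, `group`, `subset`
#'   attributes.
#' @export
build_clonotypes <- function(reads, sample_id = "sample1", group = "control",
                             subset = "CD4") {
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  keep <- reads$productive & reads$pass_filter & !is.na(reads$cdr3_nt)
  reads <- reads[keep, ]
  if (nrow(reads) == 0L)
    stop("empty sample: no productive, filter-passing reads")
  tab <- reads %>%
    group_by(.data$cdr3_nt, .data$cdr3_aa, .data$v_family, .data$j_family) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  tab$frequency <- tab$count / sum(tab$count)
  tab <- tab[order(-tab$count, tab$cdr3_nt), ]
  repertoire_sample(tab, sample_id = sample_id, group = group, subset = subset)
}

#' Construct a repertoire sample from a clonotype table
#'
#' @param clonotypes tibble with `cdr3_nt`, `cdr3_aa`, `v_family`,
#'   `j_family`, `count` (`frequency` is recomputed if absent).
#' @inheritParams build_clonotypes
#' @return a `repertoire_sample` tibble.
#' @export
repertoire_sample <- function(clonotypes, sample_id, group = "control",
                              subset = "CD4") {
  clonotypes <- as_tibble(clonotypes)
  req <- c("cdr3_nt", "cdr3_aa", "v_family", "j_family", "count")
  if (!all(req %in% names(clonotypes)))
    stop("clonotype table must have columns: ", paste(req, collapse = ", "))
  if (any(clonotypes$count < 1)) stop("clonotype counts must be >= 1")
  if (!"frequency" %in% names(clonotypes))
    clonotypes$frequency <- clonotypes$count / sum(clonotypes$count)
  clonotypes <- clonotypes[order(-clonotypes$count, clonotypes$cdr3_nt), ]
  structure(clonotypes, class = c("repertoire_sample", class(clonotypes)),
            sample_id = sample_id, group = group, subset = subset)
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf("<repertoire_sample> %s (%s, %s): %d clonotypes, %d reads\n",
              attr(x, "sample_id"), attr(x, "group"), attr(x, "subset"),
              nrow(x), sum(x$count)))
  NextMethod()
}

sample_meta <- function(sample) {
  list(sample_id = attr(sample, "sample_id"), group = attr(sample, "group"),
       subset = attr(sample, "subset"))
}

#' Aggregate a clonotype table to amino-acid level
#'
#' Sums counts and frequencies over nucleotide clonotypes sharing a CDR3
#' amino-acid sequence — the unit at which clones are compared across
#' samples.
#'
#' @param sample a `repertoire_sample`.
#' @return tibble with `cdr3_aa`, `count`, `frequency`.
#' @export
aggregate_by_aa <- function(sample) {
  tab <- as_tibble(sample)[, c("cdr3_aa", "count", "frequency")]
  if (nrow(tab) == 0L) return(tibble(cdr3_aa = character(), count = integer(),
                                     frequency = numeric()))
  tab %>%
    group_by(.data$cdr3_aa) %>%
    summarise(count = sum(.data$count), frequency = sum(.data$frequency),
              .groups = "drop") %>%
    arrange(desc(.data$count), .data$cdr3_aa)
}

#' Read and write clonotype tables
#'
#' Tab-separated with header columns `sample_id`, `group`, `subset`,
#' `cdr3_nt`, `cdr3_aa`, `v_family`, `j_family`, `count`, `frequency`.
#' Multiple samples may share one file; `read_clonotypes` returns a list of
#' `repertoire_sample` objects keyed by sample id.
#'
#' @param samples a `repertoire_sample` or list of them.
#' @param path file path.
#' @return `write_clonotypes`: the path, invisibly; `read_clonotypes`: a
#'   named list of `repertoire_sample` objects.
#' @export
write_clonotypes <- function(samples, path) {
  if (inherits(samples, "repertoire_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    m <- sample_meta(s)
    cbind(tibble(sample_id = m$sample_id, group = m$group, subset = m$subset),
          as_tibble(s)[, c("cdr3_nt", "cdr3_aa", "v_family", "j_family",
                           "count", "frequency")])
  })
  write_tsv_plain(bind_rows(rows), path)
}

#' @rdname write_clonotypes
#' @export
read_clonotypes <- function(path) {
  tab <- read_tsv_plain(path)
  out <- lapply(split(tab, tab$sample_id), function(d)
    repertoire_sample(d[, c("cdr3_nt", "cdr3_aa", "v_family", "j_family",
                            "count", "frequency")],
                      sample_id = d$sample_id[1], group = d$group[1],
                      subset = d$subset[1]))
  out[unique(tab$sample_id)]
}
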