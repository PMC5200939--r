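#' Cross-sample shared-clone matrix
#'
#' For every CDR3 amino-acid sequence that is a highly-expanded clone in at
#' least one case-group sample, records its per-sample status — `HEC`
#' (frequency at or above the threshold), `LEC` (present below it) or
#' `absent` — and classifies it: `type1` clones are expanded in cases but
#' also present (expanded or not) in at least one non-case sample; `type2`
#' clones are found only in case samples. Sharing is at amino-acid level
#' only; V/J identity is not required for a cross-sample match.
#'
#' @param cohort list of `repertoire_sample` objects with unique sample ids.
#' @param case_group group label of the case arm (e.g. `"T1D"`).
#' @param threshold HEC frequency cutoff.
#' @return tibble of shared-clone records ranked by descending `n_case_hec`
#'   (ties: `cdr3_aa` lexicographic): `cdr3_aa`, `n_case_hec`, `hec_type`,
#'   then one `status_<sample_id>` column per sample. Attributes `sample_ids`,
#'   `case_ids` carry the cohort layout.
#' @export
share_matrix <- function(cohort, case_group, threshold = 0.01) {
  ids <- vapply(cohort, function(s) attr(s, "sample_id"), "")
  if (anyDuplicated(ids)) stop("cohort error: duplicate sample_id")
  groups <- vapply(cohort, function(s) attr(s, "group"), "")
  is_case <- groups == case_group
  if (!any(is_case)) stop("no samples in case group '", case_group, "'")

  aa_tabs <- lapply(cohort, aggregate_by_aa)
  status_of <- function(tab, aa) {
    f <- tab$frequency[match(aa, tab$cdr3_aa)]
    ifelse(is.na(f), "absent", ifelse(f >= threshold, "HEC", "LEC"))
  }
  case_hec_aa <- sort(unique(unlist(lapply(aa_tabs[is_case], function(tab)
    tab$cdr3_aa[tab$frequency >= threshold]))))
  if (length(case_hec_aa) == 0L)
    return(structure(tibble(cdr3_aa = character(), n_case_hec = integer(),
                            hec_type = character()),
                     sample_ids = ids, case_ids = ids[is_case]))

  status <- vapply(aa_tabs, status_of, character(length(case_hec_aa)),
                   aa = case_hec_aa)
  status <- matrix(status, nrow = length(case_hec_aa),
                   dimnames = list(NULL, ids))
  n_case_hec <- rowSums(status[, is_case, drop = FALSE] == "HEC")
  present_noncase <- if (any(!is_case))
    rowSums(status[, !is_case, drop = FALSE] != "absent") > 0 else
    rep(FALSE, length(case_hec_aa))

  out <- tibble(cdr3_aa = case_hec_aa,
                n_case_hec = as.integer(n_case_hec),
                hec_type = ifelse(present_noncase, "type1", "type2"))
  out <- cbind(out, setNames(as.data.frame(status, stringsAsFactors = FALSE),
                             paste0("status_", ids)))
  out <- as_tibble(out)[order(-n_case_hec, case_hec_aa), ]
  structure(out, sample_ids = ids, case_ids = ids[is_case])
}

#' Summarise a shared-clone matrix
#'
#' @param records a [share_matrix()] result.
#' @return list: `n_case_hec_total` (clones expanded in at least one case
#'   sample), `type1_fraction`, `type2_fraction`, `n_hec_all_case` (expanded
#'   in every case sample), `n_hec_over_half` (expanded in strictly more than
#'   half of the case samples).
#' @export
sharing_summary <- function(records) {
  n_case <- length(attr(records, "case_ids"))
  total <- nrow(records)
  list(n_case_hec_total = total,
       type1_fraction = if (total) mean(records$hec_type == "type1") else NA_real_,
       type2_fraction = if (total) mean(records$hec_type == "type2") else NA_real_,
       n_hec_all_case = sum(records$n_case_hec == n_case),
       n_hec_over_half = sum(records$n_case_hec > n_case / 2))
}

#' Write a shared-clone matrix
#'
#' @param records a [share_matrix()] result.
#' @param path tab-separated output path.
#' @export
write_share_matrix <- function(records, path) write_tsv_plain(records, path)
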