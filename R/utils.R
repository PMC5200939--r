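#' @importFrom dplyr %>% arrange mutate summarise group_by ungroup filter select
#'   bind_rows left_join desc n across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rnorm rgeom rmultinom rgamma runif median sd cor pt setNames
#' @importFrom Rcpp sourceCpp
#' @useDynLib tcrep, .registration = TRUE
NULL

STOP_AA <- "*"

#' Translate nucleotide sequences to amino acids
#'
#' Standard-code translation of in-frame nucleotide strings. Sequences whose
#' length is not a multiple of 3 are an error; ambiguous codons translate to
#' `X`, stop codons to `*`.
#'
#' @param nt character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt))
  out <- character(length(nt))
  nz <- nchar(nt) > 0L
  if (any(nchar(nt) %% 3L != 0L))
    stop("sequence length must be a multiple of 3 for translation")
  if (any(nz)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[nz]),
                                if.fuzzy.codon = "X", no.init.codon = TRUE)
    out[nz] <- unname(as.character(aa))
  }
  out
}

reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}

has_stop <- function(aa) grepl("*", aa, fixed = TRUE)

#' Natural ordering of TRB family names
#'
#' Orders locus family names (e.g. `TRBV2`, `TRBV12-3`, `TRBJ2-5`) by their
#' numeric group and subgroup so usage tables align across samples.
#'
#' @param families character vector of family names.
#' @return the input, sorted in locus nomenclature order.
#' @export
sort_families <- function(families) {
  families <- unique(families)
  m <- regmatches(families, regexec("^([A-Z]+)(\\d+)(?:-(\\d+))?", families))
  prefix <- vapply(m, function(x) if (length(x) >= 2) x[2] else "", "")
  g1 <- vapply(m, function(x) if (length(x) >= 3 && nzchar(x[3])) as.integer(x[3]) else NA_integer_, 1L)
  g2 <- vapply(m, function(x) if (length(x) >= 4 && nzchar(x[4])) as.integer(x[4]) else 0L, 1L)
  families[order(prefix, g1, g2, families)]
}

# Segment id -> family: strip the allele designation after "*".
segment_family <- function(segment_id) sub("\\*.*$", "", segment_id)

check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  bad <- if (open) any(x <= lo | x >= hi) else any(x < lo | x > hi)
  if (!is.numeric(x) || anyNA(x) || bad)
    stop(sprintf("`%s` must lie in %s%g, %g%s", name,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]"))
  invisible(x)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE))
}
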