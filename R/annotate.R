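#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (Phred+33).
#' @return tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

as_read_tbl <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_fastq(x))
  x <- as_tibble(x)
  stopifnot(all(c("read_id", "sequence") %in% names(x)))
  if (!"quality" %in% names(x)) x$quality <- strrep("I", nchar(x$sequence))
  x
}

#' Merge overlapping paired-end reads
#'
#' A simple quality-aware overlap merger: mate 2 is reverse complemented,
#' every candidate overlap of at least `min_overlap` bases is scored
#' (`matches - 2 * mismatches`), and the best-scoring overlap whose mismatch
#' rate does not exceed `max_mismatch_rate` is used (ties go to the longer
#' overlap). At overlap mismatches the base with the higher Phred quality
#' wins; unmergeable pairs are counted and dropped.
#'
#' @param fastq1,fastq2 FASTQ paths, or tibbles with `read_id`, `sequence`,
#'   `quality` (mate order must correspond).
#' @param min_overlap minimum overlap length, bases.
#' @param max_mismatch_rate maximum fraction of mismatching overlap columns.
#' @return tibble of merged reads (`read_id`, `sequence`, `quality`) with an
#'   attached `report` attribute: list of `n_pairs`, `n_merged`, `n_dropped`.
#' @export
merge_pairs <- function(fastq1, fastq2, min_overlap = 10L, max_mismatch_rate = 0.25) {
  r1 <- as_read_tbl(fastq1); r2 <- as_read_tbl(fastq2)
  if (nrow(r1) != nrow(r2)) stop("pairing error: mate files differ in length")

  s2 <- reverse_complement(r2$sequence)
  q2 <- vapply(strsplit(r2$quality, "", fixed = TRUE),
               function(q) paste(rev(q), collapse = ""), "")

  out_seq <- character(nrow(r1)); out_qual <- character(nrow(r1))
  merged <- logical(nrow(r1))
  for (i in seq_len(nrow(r1))) {
    a <- strsplit(r1$sequence[i], "", fixed = TRUE)[[1]]
    b <- strsplit(s2[i], "", fixed = TRUE)[[1]]
    qa <- utf8ToInt(r1$quality[i]) - 33L
    qb <- utf8ToInt(q2[i]) - 33L
    n1 <- length(a); n2 <- length(b)
    best_o <- NA_integer_; best_score <- -Inf
    for (o in seq.int(min_overlap, min(n1, n2))) {
      mism <- sum(a[(n1 - o + 1L):n1] != b[seq_len(o)])
      if (mism / o > max_mismatch_rate) next
      score <- o - 2L * mism
      if (score > best_score || (score == best_score && o > best_o)) {
        best_score <- score; best_o <- o
      }
    }
    if (is.na(best_o)) next
    o <- best_o
    ia <- (n1 - o + 1L):n1; ib <- seq_len(o)
    cons <- a[ia]; consq <- pmax(qa[ia], qb[ib])
    take_b <- (a[ia] != b[ib]) & (qb[ib] > qa[ia])
    cons[take_b] <- b[ib][take_b]
    merged[i] <- TRUE
    out_seq[i] <- paste(c(a[seq_len(n1 - o)], cons, b[(o + 1L):n2][seq_len(max(0L, n2 - o))]),
                        collapse = "")
    out_qual[i] <- intToUtf8(c(qa[seq_len(n1 - o)], consq, qb[(o + 1L):n2][seq_len(max(0L, n2 - o))]) + 33L)
  }
  out <- tibble(read_id = r1$read_id[merged],
                sequence = out_seq[merged], quality = out_qual[merged])
  attr(out, "report") <- list(n_pairs = nrow(r1), n_merged = sum(merged),
                              n_dropped = sum(!merged))
  out
}

align_segment_set <- function(reads, segs, match = 1, mismatch = -1, gap = 2,
                              anchor_side = c("v", "j")) {
  # best segment per read: maximal glocal score (segment fully aligned within
  # the read region), ties broken by lexicographically smallest segment_id
  anchor_side <- match.arg(anchor_side)
  segs <- segs[order(segs$segment_id), ]
  scores <- matrix(-Inf, length(reads), nrow(segs))
  alns <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    alns[[k]] <- .glocal_align_batch(reads, segs$sequence[k],
                                     match, mismatch, gap, -1L)
    scores[, k] <- alns[[k]]$score
  }
  best <- max.col(round(scores, 9), ties.method = "first")  # first = smallest id
  pick <- function(field) vapply(seq_along(reads), function(i)
    alns[[best[i]]][[field]][i], numeric(1))

  # Anchor codons are located with a second alignment against only the
  # conserved part of the segment (V: start..anchor codon; J: anchor
  # codon..end) -- the bases beyond it are the ones junctional trimming
  # removes, and letting them fight for alignment can shift gaps into the
  # anchor codon itself.
  anchor <- rep(NA_integer_, length(reads))
  for (k in unique(best)) {
    if (is.na(segs$anchor_pos[k])) next
    idx <- which(best == k)
    if (anchor_side == "v") {
      sub <- substr(segs$sequence[k], 1L, segs$anchor_pos[k] + 3L)
      a0 <- segs$anchor_pos[k]
    } else {
      sub <- substr(segs$sequence[k], segs$anchor_pos[k] + 1L,
                    nchar(segs$sequence[k]))
      a0 <- 0L
    }
    r2 <- .glocal_align_batch(reads[idx], sub, match, mismatch, gap, a0)
    anchor[idx] <- ifelse(r2$anchor_read < 0L, NA_integer_, r2$anchor_read)
  }
  tibble(call = segs$segment_id[best],
         identity = 100 * pick("matches") / pick("cols"),
         anchor_read = anchor,
         match_end = as.integer(pick("p_end")),
         score = scores[cbind(seq_along(reads), best)])
}

#' Align reads to germline V and J segments
#'
#' The in-package stand-in for a full V(D)J aligner: each read is aligned
#' against every V segment with a glocal alignment (the segment aligned
#' end-to-end within the best-matching read region; match +1, mismatch -1,
#' linear gap -2), then the read suffix 3' of the V match is aligned against
#' every J segment the same way. Identity is `matches / aligned columns * 100`
#' over the glocal alignment; score ties break to the lexicographically
#' smallest segment id. D segments are not assigned.
#'
#' @param reads character vector of read sequences.
#' @param db a [germline_db()].
#' @param match,mismatch,gap alignment scores (gap is a positive penalty).
#' @param min_read_length reads shorter than this are marked unalignable.
#' @return tibble with `v_call`, `j_call`, `v_identity`, `j_identity`,
#'   `v_anchor`, `j_anchor` (0-based read offsets of the anchor codons, `NA`
#'   when not covered).
#' @export
align_to_germline <- function(reads, db, match = 1, mismatch = -1, gap = 2,
                              min_read_length = 30L) {
  stopifnot(inherits(db, "germline_db"), is.character(reads))
  n <- length(reads)
  out <- tibble(v_call = NA_character_, j_call = NA_character_,
                v_identity = NA_real_, j_identity = NA_real_,
                v_anchor = NA_integer_, j_anchor = NA_integer_, .rows = n)
  ok <- !is.na(reads) & nchar(reads) >= min_read_length
  if (!any(ok)) return(out)

  vs <- db_segments(db, "V"); js <- db_segments(db, "J")
  v <- align_segment_set(reads[ok], vs, match, mismatch, gap, anchor_side = "v")
  out$v_call[ok] <- v$call
  out$v_identity[ok] <- v$identity
  out$v_anchor[ok] <- v$anchor_read

  suffix_start <- v$match_end + 1L
  suffix <- substr(reads[ok], suffix_start, nchar(reads[ok]))
  long_enough <- nchar(suffix) >= 6L
  if (any(long_enough)) {
    j <- align_segment_set(suffix[long_enough], js, match, mismatch, gap,
                           anchor_side = "j")
    oki <- which(ok)[long_enough]
    out$j_call[oki] <- j$call
    out$j_identity[oki] <- j$identity
    out$j_anchor[oki] <- j$anchor_read + (suffix_start[long_enough] - 1L)
  }
  out
}

#' Extract the CDR3 between conserved anchors
#'
#' Returns the nucleotides strictly between the conserved cysteine codon of
#' the V segment and the conserved phenylalanine codon of the J segment
#' (anchor codons excluded, matching how repertoire clones are convention-
#' ally printed), its translation, and the productivity call: the
#' anchor-to-anchor span must be a multiple of 3 and the CDR3 must carry no
#' stop codon.
#'
#' @param read read sequence (character scalar or vector).
#' @param v_anchor,j_anchor 0-based read offsets of the anchor codons (as
#'   returned by [align_to_germline()]); `NA` means the anchor was not
#'   covered and the CDR3 is undefined.
#' @return tibble with `cdr3_nt`, `cdr3_aa`, `productive`.
#' @export
extract_cdr3 <- function(read, v_anchor, j_anchor) {
  n <- length(read)
  cdr3_nt <- rep(NA_character_, n); cdr3_aa <- rep(NA_character_, n)
  productive <- logical(n)
  ok <- !is.na(v_anchor) & !is.na(j_anchor) & (j_anchor > v_anchor + 3L)
  if (any(ok)) {
    nt <- substr(read[ok], v_anchor[ok] + 4L, j_anchor[ok])
    in_frame <- (j_anchor[ok] - v_anchor[ok]) %% 3L == 0L
    aa <- rep(NA_character_, sum(ok))
    aa[in_frame] <- translate_nt(nt[in_frame])
    cdr3_nt[ok] <- nt
    cdr3_aa[ok] <- aa
    productive[ok] <- in_frame & !is.na(aa) & !has_stop(ifelse(is.na(aa), "", aa))
  }
  tibble(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive)
}

#' Annotate reads against a germline reference
#'
#' Runs [align_to_germline()] and [extract_cdr3()] over a set of reads
#' (dereplicating identical sequences first), applies the germline-identity
#' filter, and returns one AIRR-style rearrangement row per read.
#'
#' @param reads character vector of sequences, or a tibble with `read_id` and
#'   `sequence` (e.g. from [read_fastq()] or [merge_pairs()]).
#' @param db a [germline_db()].
#' @param identity_threshold minimum percent identity to germline for both the
#'   V and the J alignment; reads at or above the threshold pass (boundary
#'   inclusive).
#' @param ... passed to [align_to_germline()].
#' @return tibble with `read_id`, `sequence`, `v_call`, `j_call`, `v_family`,
#'   `j_family`, `v_identity`, `j_identity`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `pass_filter`.
#' @export
annotate_reads <- function(reads, db, identity_threshold = 70, ...) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%07d", seq_along(reads)),
                    sequence = reads)
  }
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))

  uniq <- unique(reads$sequence)
  aln <- align_to_germline(uniq, db, ...)
  cdr3 <- extract_cdr3(uniq, aln$v_anchor, aln$j_anchor)
  per_seq <- tibble(
    sequence = uniq,
    v_call = aln$v_call, j_call = aln$j_call,
    v_family = segment_family(aln$v_call), j_family = segment_family(aln$j_call),
    v_identity = aln$v_identity, j_identity = aln$j_identity,
    cdr3_nt = cdr3$cdr3_nt, cdr3_aa = cdr3$cdr3_aa,
    productive = cdr3$productive
  )
  per_seq$pass_filter <- !is.na(per_seq$v_identity) & !is.na(per_seq$j_identity) &
    pmin(per_seq$v_identity, per_seq$j_identity) >= identity_threshold
  out <- left_join(reads[, c("read_id", "sequence")], per_seq, by = "sequence")
  out
}

#' Filter annotated reads by germline identity
#'
#' Keeps reads whose V and J identities are both at or above `threshold`
#' percent (inclusive: exactly 70 passes at the default, since the exclusion
#' rule "identity below 70% is excluded" is read literally).
#'
#' @param annotated tibble from [annotate_reads()].
#' @param threshold percent identity cutoff.
#' @return the passing rows, with a `report` attribute carrying `kept` and
#'   `excluded` counts.
#' @export
filter_by_identity <- function(annotated, threshold = 70) {
  keep <- !is.na(annotated$v_identity) & !is.na(annotated$j_identity) &
    pmin(annotated$v_identity, annotated$j_identity) >= threshold
  out <- annotated[keep, ]
  out$pass_filter <- TRUE
  attr(out, "report") <- list(kept = sum(keep), excluded = sum(!keep))
  out
}

#' Write an AIRR-style rearrangement table
#'
#' @param annotated tibble from [annotate_reads()].
#' @param path output path (tab-separated).
#' @export
write_rearrangements <- function(annotated, path) {
  cols <- c("read_id", "v_call", "j_call", "v_identity", "j_identity",
            "cdr3_nt", "cdr3_aa", "productive", "pass_filter")
  write_tsv_plain(annotated[, intersect(cols, names(annotated))], path)
}
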