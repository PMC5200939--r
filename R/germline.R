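#' Germline reference databases
#'
#' A `germline_db` bundles the TRBV/TRBD/TRBJ reference segments used for
#' annotation together with the CDR3 anchor metadata that IMGT numbering
#' provides: the first base of the conserved cysteine codon for V segments and
#' of the conserved phenylalanine (of the F-G-X-G motif) for J segments.
#' Anchor positions are supplied as explicit metadata rather than rediscovered
#' by motif scanning, mirroring how curated references ship precomputed
#' numbering.
#'
#' @param segments a data frame with columns `segment_id`, `gene_type`
#'   (`"V"`, `"D"` or `"J"`), `sequence` and `anchor_pos` (0-based offset of
#'   the anchor codon; `NA` for D segments).
#' @param j_anchor_aa permitted J anchor residues; `"F"` by IMGT convention,
#'   with `c("F", "W")` allowing the J-TRP variant.
#' @return an object of class `germline_db`: a list with elements `segments`
#'   (tibble, with a derived `family` column), `v_families` and `j_families`
#'   (family names in locus nomenclature order).
#' @export
germline_db <- function(segments, j_anchor_aa = "F") {
  segments <- as_tibble(segments)
  req <- c("segment_id", "gene_type", "sequence", "anchor_pos")
  if (!all(req %in% names(segments)))
    stop("`segments` must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(segments$segment_id))
    stop("duplicate segment_id in germline reference")
  if (!all(segments$gene_type %in% c("V", "D", "J")))
    stop("gene_type must be V, D or J")
  if (!all(grepl("^[ACGTN]+$", segments$sequence)))
    stop("segment sequences may contain only A/C/G/T/N")

  segments$family <- segment_family(segments$segment_id)
  segments$anchor_pos <- as.integer(segments$anchor_pos)

  vj <- segments[segments$gene_type %in% c("V", "J"), ]
  if (anyNA(vj$anchor_pos))
    stop("reference-integrity error: V/J segment(s) missing anchor_pos: ",
         paste(vj$segment_id[is.na(vj$anchor_pos)], collapse = ", "))
  if (nrow(vj)) {
    codons <- substr(vj$sequence, vj$anchor_pos + 1L, vj$anchor_pos + 3L)
    if (any(nchar(codons) < 3L))
      stop("anchor codon out of range for segment ",
           paste(vj$segment_id[nchar(codons) < 3L], collapse = ", "))
    aa <- translate_nt(codons)
    ok <- ifelse(vj$gene_type == "V", aa == "C", aa %in% j_anchor_aa)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("validation error: anchor codon of ", vj$segment_id[i],
           " translates to ", aa[i], ", expected ",
           if (vj$gene_type[i] == "V") "C" else paste(j_anchor_aa, collapse = "/"))
    }
  }

  structure(list(
    segments   = segments,
    v_families = sort_families(segments$family[segments$gene_type == "V"]),
    j_families = sort_families(segments$family[segments$gene_type == "J"])
  ), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat("<germline_db> ", sum(x$segments$gene_type == "V"), " V / ",
      sum(x$segments$gene_type == "D"), " D / ",
      sum(x$segments$gene_type == "J"), " J segments; ",
      length(x$v_families), " V families, ",
      length(x$j_families), " J families\n", sep = "")
  invisible(x)
}

db_segments <- function(db, type) db$segments[db$segments$gene_type == type, ]

#' Load a germline reference from FASTA plus an anchor table
#'
#' @param fasta_path path to a FASTA file of germline segments; record names
#'   are segment ids (e.g. `TRBV15*01`).
#' @param anchor_table path to a tab-separated table with columns
#'   `segment_id`, `gene_type`, `anchor_pos` (0-based; `NA` for D segments).
#' @param j_anchor_aa see [germline_db()].
#' @return a validated [germline_db()].
#' @export
load_germline <- function(fasta_path, anchor_table, j_anchor_aa = "F") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  anchors <- read_tsv_plain(anchor_table)
  if (!all(c("segment_id", "gene_type", "anchor_pos") %in% names(anchors)))
    stop("anchor table must have columns segment_id, gene_type, anchor_pos")
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(anchors$segment_id[anchors$gene_type %in% c("V", "J")], ids)
  if (length(missing))
    stop("anchor table lists segments absent from FASTA: ",
         paste(missing, collapse = ", "))
  no_anchor <- setdiff(ids, anchors$segment_id)
  if (length(no_anchor))
    stop("reference-integrity error: no anchor-table entry for: ",
         paste(no_anchor, collapse = ", "))
  segs <- tibble(segment_id = ids, sequence = unname(as.character(seqs))) %>%
    left_join(anchors, by = "segment_id")
  germline_db(segs, j_anchor_aa = j_anchor_aa)
}

#' Write a germline reference to FASTA plus an anchor table
#'
#' Inverse of [load_germline()]; the pair round-trips a database exactly.
#'
#' @param db a [germline_db()].
#' @param fasta_path,anchor_table output paths.
#' @return invisibly, the two paths.
#' @export
write_germline <- function(db, fasta_path, anchor_table) {
  seqs <- Biostrings::DNAStringSet(db$segments$sequence)
  names(seqs) <- db$segments$segment_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv_plain(db$segments[, c("segment_id", "gene_type", "anchor_pos")],
                  anchor_table)
  invisible(c(fasta_path, anchor_table))
}

#' Built-in toy germline reference
#'
#' A small, fully synthetic TRB reference shipped with the package: 10 V
#' families (including `TRBV15`), 2 D segments and 7 J families (including
#' `TRBJ2-5`, whose 5' region encodes ...E-T-Q-Y ahead of the conserved Phe).
#' Sequences were generated once from a fixed seed with canonical anchor
#' motifs (V segments end with the conserved `TGT` cysteine codon plus two
#' retained codons; J segments carry 12 nt ahead of the `TTC` anchor).
#' They are *not* real IMGT sequences; the reference exists so that every
#' simulation, annotation and worked clone example runs without any download.
#'
#' @return a [germline_db()].
#' @export
builtin_toy_reference <- function() {
  v <- c(
    `TRBV2*01`    = "TTAACGCGACTACTAAAATCACCGACGTTTATATGCATGTGAGCAGACTGTGCCAGC",
    `TRBV5-1*01`  = "TATTTCGCAAATCCGGACACCGTGATCGCCTACATCGGCGGGTCGGCATGTGCCAGC",
    `TRBV6-1*01`  = "GCATTGTTATTGCAAGGGCATCAACTTCGGTAAAAGATGAATACGATATGTGCCAGT",
    `TRBV7-2*01`  = "GATTACAGGCATCAGAGGTCAAAGCAGGCTTCTGGATAAGTAAGAAAGTGTGCCAGC",
    `TRBV9*01`    = "CGTGGCAGTGTGGCGTGTGACTGACTAGTGACGCCACTCGGACACGGCTGTGCCTCC",
    `TRBV12-3*01` = "GGTGTATTTTTGAAGTATCGCTGAGAATCGTGACGCCCCAAGCAAAGATGTGCCAGT",
    `TRBV15*01`   = "TCACGACTTGTCGGTTCGAAAATCTCACCTGCCGCTTCGCCATCACCTTGTGCCACA",
    `TRBV20-1*01` = "CGTAAACGTTTGAAATCGCGCGCCCGTGCTTTTTTGATACCCCAGGTTTGTAGTGCT",
    `TRBV28*01`   = "CCTGCAGGCGGACAGGTATTCCGTTTAGACCCTCTTTGATCCTGAATCTGTGCCAGC",
    `TRBV30*01`   = "GCCTGGCGGAAACTCTGTCAAAGCGAGTCCATAACGTCGGCCTCCCATTGTGCCTGG")
  d <- c(
    `TRBD1*01` = "GGGACAGGGGGC",
    `TRBD2*01` = "GGGACTAGCGGGAGG")
  j <- c(
    `TRBJ1-1*01` = "AACACTGAAGCTTTCGGGAATGGTACTCGACTGACCGTAGTCGGCTAC",
    `TRBJ1-2*01` = "AACTATGGCTACTTCGGGTCAGGTCAAGTTCGACCAATGCACGATTAG",
    `TRBJ1-5*01` = "AGCAATCAGCCCTTCGGGCCAGGTATTCAAGCTACGGAGCATCTTAGC",
    `TRBJ2-1*01` = "TACAATGAGCAGTTCGGGTGCGGTCTGAAAGTTCCTACAAGCGTGCAC",
    `TRBJ2-3*01` = "AGCACAGATACGTTCGGGGCAGGTACCAACTCTGATCGAAGTTACTGG",
    `TRBJ2-5*01` = "GAGACCCAGTACTTCGGGCCAGGCACGCGGCTCCTGGTGCTCGAGTCA",
    `TRBJ2-7*01` = "AGCTACGAGCAGTTCGGGCCGGGTACGCGACTGACTGTTACCGAAGAC")

  segs <- tibble(
    segment_id = c(names(v), names(d), names(j)),
    gene_type  = rep(c("V", "D", "J"), c(length(v), length(d), length(j))),
    sequence   = c(unname(v), unname(d), unname(j)),
    anchor_pos = c(rep(48L, length(v)), rep(NA_integer_, length(d)),
                   rep(12L, length(j)))
  )
  germline_db(segs)
}
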