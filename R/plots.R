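need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot a CDR3 length spectratype
#'
#' @param spec tibble from [spectratype()].
#' @return a ggplot object.
#' @export
plot_spectratype <- function(spec) {
  need_ggplot()
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "CDR3 length (aa)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Plot a V x J combination matrix as a bubble chart
#'
#' Sphere area tracks the read fraction of each VJ combination, with V
#' families on the x axis and J families on the y axis.
#'
#' @param vj result of [vj_matrix()].
#' @return a ggplot object.
#' @export
plot_vj_matrix <- function(vj) {
  need_ggplot()
  d <- as.data.frame.table(vj$matrix, stringsAsFactors = FALSE,
                           responseName = "fraction")
  names(d)[1:2] <- c("v_family", "j_family")
  d$v_family <- factor(d$v_family, levels = rownames(vj$matrix))
  d$j_family <- factor(d$j_family, levels = colnames(vj$matrix))
  ggplot2::ggplot(d[d$fraction > 0, ],
                  ggplot2::aes(x = .data$v_family, y = .data$j_family,
                               size = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(x = NULL, y = NULL, size = "read fraction",
                  title = vj$sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a shared-clone status heatmap
#'
#' Rows are shared CDR3 amino-acid sequences (ranked as in [share_matrix()]),
#' columns samples; cells show HEC / LEC / absent status.
#'
#' @param records result of [share_matrix()].
#' @param top_n number of top-ranked clones to display.
#' @return a ggplot object.
#' @export
plot_share_matrix <- function(records, top_n = 30L) {
  need_ggplot()
  recs <- utils::head(records, top_n)
  status_cols <- grep("^status_", names(recs), value = TRUE)
  d <- tidyr::pivot_longer(recs[, c("cdr3_aa", status_cols)],
                           dplyr::all_of(status_cols),
                           names_to = "sample", values_to = "status")
  d$sample <- sub("^status_", "", d$sample)
  d$cdr3_aa <- factor(d$cdr3_aa, levels = rev(recs$cdr3_aa))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$cdr3_aa,
                                  fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(HEC = "darkorange", LEC = "seagreen",
                                          absent = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
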