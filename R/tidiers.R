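# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a community composition
#'
#' @param x A `composition_table`.
#' @param ... Unused.
#' @return Plain tibble of the reported taxa with `rank` as a column.
#' @export
tidy.composition_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$rank <- attr(x, "rank")
  out
}

#' One-row summary of a community composition
#'
#' @param x A `composition_table`.
#' @param ... Unused.
#' @return Tibble with rank, taxon count, classified/unclassified peptide
#'   counts, and the decoy retained-alignment rate.
#' @export
glance.composition_table <- function(x, ...) {
  tibble::tibble(
    rank = attr(x, "rank"), freq_cut = attr(x, "freq_cut"),
    n_taxa = sum(x$taxon != "other"),
    n_classified = attr(x, "n_classified"),
    n_unclassified = attr(x, "n_unclassified"),
    decoy_match_rate = attr(x, "decoy_match_rate")
  )
}

#' Tidy a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.coverage_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Stacked-bar plot of a community composition
#'
#' @param object A `composition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$fraction,
                                  fill = stats::reorder(.data$taxon,
                                                        -.data$fraction))) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "fraction of classified peptides",
                  fill = attr(object, "rank")) +
    ggplot2::theme_minimal()
}

#' Faceted coverage-report plot
#'
#' One stacked bar per peptide set (DN_only, DN_all, DB_only, DB_all),
#' faceted by rank.
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$fraction,
                                  fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~rank) +
    ggplot2::labs(x = NULL, y = "fraction of classified peptides") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Spectral-quality plots
#'
#' Stacked bar of the alignment-quality categories, split by database-search
#' status when available.
#'
#' @param qc Tibble from [classify_alignment_quality()] (optionally with a
#'   `db_status` column).
#' @return A ggplot object.
#' @export
plot_spectral_qc <- function(qc) {
  has_db <- !is.null(qc$db_status) && !all(qc$db_status == "unknown")
  p <- ggplot2::ggplot(qc, ggplot2::aes(x = .data$category))
  p <- if (has_db) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$db_status))
  } else {
    p + ggplot2::geom_bar(fill = "steelblue")
  }
  p + ggplot2::labs(x = NULL, y = "peptides") + ggplot2::theme_minimal()
}

#' Score versus mass-error scatter plot
#'
#' @param records De novo records with `score` and `ppm_error`.
#' @return A ggplot object.
#' @export
plot_score_ppm <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ppm_error,
                                        y = .data$score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "precursor mass error (ppm)", y = "de novo score") +
    ggplot2::theme_minimal()
}
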