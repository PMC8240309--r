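# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result
#'
#' One row per representative ORF with its classification and triplet.
#'
#' @param x An `orfgraph_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy orfgraph_result
#' @export
tidy.orfgraph_result <- function(x, ...) {
  tb <- x$representatives
  if (nrow(tb) == 0) return(tibble::tibble())
  tibble::tibble(
    orf_id = tb$orf_id, cluster = tb$cluster, query_id = tb$query_id,
    nt_len = tb$nt_len, aa_len = nchar(tb$aa_seq),
    verdict = tb$verdict, best_hit = tb$best_hit,
    best_identity = tb$best_identity,
    likelihood = tb$likelihood, coverage = tb$coverage,
    single_contig = tb$single_contig,
    path = vapply(tb$path, path_string, ""))
}

#' Glance at a pipeline result
#'
#' @param x An `orfgraph_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @method glance orfgraph_result
#' @export
glance.orfgraph_result <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
}

#' Tidy a position model
#'
#' @param x A `position_model`.
#' @param ... Unused.
#' @return A tibble with one row per trained distance.
#' @method tidy position_model
#' @export
tidy.position_model <- function(x, ...) {
  tibble::tibble(
    model_id = rep(names(x$distances), lengths(x$distances)),
    distance = unlist(x$distances, use.names = FALSE))
}

#' Plot per-stage candidate counts
#'
#' @param object An `orfgraph_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orfgraph_result
#' @export
autoplot.orfgraph_result <- function(object, ...) {
  df <- object$counts
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "count", title = "Pipeline stage counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the start-distance histograms of a position model
#'
#' @param object A `position_model`.
#' @param ... Unused.
#' @return A ggplot faceted by model.
#' @method autoplot position_model
#' @export
autoplot.position_model <- function(object, ...) {
  df <- tidy.position_model(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = object$binSize, fill = "grey40") +
    ggplot2::facet_wrap(~model_id, scales = "free_y") +
    ggplot2::labs(x = "distance from gene start (nt)", y = "alignments") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
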