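#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the significant patterns of a mining result
#'
#' @param x an `mm_result`.
#' @param ... unused.
#' @return a tibble with one row per significant closed pattern.
#' @method tidy mm_result
#' @export
tidy.mm_result <- function(x, ...) {
  x$significant[, c("p", "p_min", "support", "interaction", "genes",
                    "encodings", "intervals")]
}

#' One-row summary of a mining run
#'
#' @param x an `mm_result`.
#' @param ... unused.
#' @return a one-row tibble with the run-level quantities.
#' @method glance mm_result
#' @export
glance.mm_result <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    method = x$method,
    delta_final = x$delta_final,
    n_significant = nrow(x$significant),
    n_testable = x$counters$testable,
    n_processed = x$counters$processed,
    n_pruned = x$counters$pruned,
    min_p_testable = x$min_p_testable,
    delta_bonferroni = x$alpha / max(x$counters$processed, 1L)
  )
}

#' Plot the significant meta-markers of a mining run
#'
#' Shows each significant closed pattern's association strength
#' (`-log10 p`) against its gene interaction, with the final significance
#' threshold as a horizontal line.
#'
#' @param object an `mm_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mm_result
#' @export
autoplot.mm_result <- function(object, ...) {
  sig <- object$significant
  thr <- -log10(object$delta_final)
  if (nrow(sig) == 0) {
    df <- tibble::tibble(x = factor(character(0)), y = numeric(0))
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
             ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
             ggplot2::labs(x = "gene interaction",
                           y = expression(-log[10](p)),
                           title = "No significant meta-markers") +
             ggplot2::theme_minimal())
  }
  df <- tibble::tibble(
    genes = factor(sig$genes, levels = unique(sig$genes)),
    neglogp = -log10(pmax(sig$p, 1e-300)),
    encodings = sig$encodings)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genes, y = .data$neglogp,
                                   colour = .data$encodings)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "gene interaction", y = expression(-log[10](p)),
                  colour = "encodings") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 .data
NULL
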