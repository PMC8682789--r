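#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline run into its candidate table
#'
#' @param x An `attrace_run`.
#' @param ... Unused.
#' @return The candidate tibble (evidence renderings dropped).
#' @method tidy attrace_run
#' @export
tidy.attrace_run <- function(x, ...) {
  select(as_tibble(x$candidates), -"evidence_alignments")
}

#' One-row summary of a pipeline run
#'
#' @param x An `attrace_run`.
#' @param ... Unused.
#' @return One-row tibble of per-stage record counts plus the mode.
#' @method glance attrace_run
#' @export
glance.attrace_run <- function(x, ...) {
  mutate(x$counts, mode = x$mode)
}

#' @method tidy attrace_fc
#' @export
tidy.attrace_fc <- function(x, ...) as_tibble(x)

#' Candidate map along the reference
#'
#' Draws each retained candidate as a segment spanning attL to attR on its
#' reference sequence, labelled with size and evidence counts.
#'
#' @param object An `attrace_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attrace_candidates
#' @export
autoplot.attrace_candidates <- function(object, ...) {
  df <- as_tibble(object)
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no candidates") +
             ggplot2::theme_void())
  }
  df$label <- sprintf("%s (%.1f kb, SR %d/%d)", df$prophage, df$size / 1000,
                      df$SR_attB, df$SR_attP)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$attL_start, xend = .data$attR_end,
                                       y = .data$prophage, yend = .data$prophage),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$attL_start, y = .data$prophage),
                        shape = "|", size = 5) +
    ggplot2::geom_point(ggplot2::aes(x = .data$attR_end, y = .data$prophage),
                        shape = "|", size = 5) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$attL_start + .data$attR_end) / 2,
                                    y = .data$prophage, label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::facet_wrap(~contig, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "reference position (bp)", y = NULL,
                  title = "Candidate excisable prophages") +
    ggplot2::theme_minimal()
}

#' Fold-change bar chart
#'
#' @param object An `attrace_fc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attrace_fc
#' @export
autoplot.attrace_fc <- function(object, ...) {
  df <- as_tibble(object)
  df$flag <- ifelse(df$zero_substituted_treated | df$zero_substituted_control,
                    "zero substituted", "observed")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$evidence_class,
                                   y = .data$fold_change, fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fold-change (treated / control)",
                  title = "Excision-activity fold-change") +
    ggplot2::theme_minimal()
}
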