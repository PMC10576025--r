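# ggplot2 figures for the result types: balance plots, filter logos,
# position-bias profiles and training curves.

#' Balance plot for one exon
#'
#' Stacked inclusion vs skipping strength bars with the basal-strength bar.
#'
#' @param object A [balance_summary()].
#' @param min_bar Hide bars smaller than this strength.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.balance_summary <- function(object, min_bar = 0.05, ...) {
  bars <- object$bars |>
    filter(.data$total >= min_bar) |>
    bind_rows(tibble(filter = "B", scm = "basal", side = object$B_side,
                     total = abs(object$B))) |>
    group_by(.data$side) |>
    arrange(dplyr::desc(.data$total), .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$total), ymin = .data$ymax - .data$total) |>
    ungroup()
  ggplot2::ggplot(bars) +
    ggplot2::geom_rect(ggplot2::aes(xmin = as.numeric(factor(.data$side,
                                                             c("inclusion", "skipping"))) - 0.35,
                                    xmax = as.numeric(factor(.data$side,
                                                             c("inclusion", "skipping"))) + 0.35,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$side),
                       colour = "white", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(x = as.numeric(factor(.data$side,
                                                          c("inclusion", "skipping"))),
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$filter),
                       size = 2.6, colour = "white") +
    ggplot2::scale_x_continuous(breaks = c(1, 2),
                                labels = c("inclusion", "skipping"),
                                limits = c(0.5, 2.5)) +
    ggplot2::scale_fill_manual(values = c(inclusion = "#2166ac",
                                          skipping = "#b2182b"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "total strength",
                  title = sprintf("Δ strength %.2f → predicted PSI %.2f",
                                  object$delta, object$psi_hat)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a filter logo matrix
#'
#' @param object A [filter_logo()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_logo <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("nucleotide", "position", "value")
  df$position <- as.integer(factor(df$position, levels = unique(df$position)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$nucleotide,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "position in filter window", y = NULL,
                  fill = if (attr(object, "mode") == "sample")
                    "log2 enrichment" else "frequency") +
    ggplot2::theme_minimal()
}

#' Position-bias profiles of a model's filters
#'
#' @param model A `splice_model`.
#' @param scms SCM subset to show.
#' @return A ggplot object.
#' @export
plot_position_bias <- function(model, scms = SCM_NAMES) {
  df <- purrr::map(scms, function(nm) {
    b <- model$scms[[nm]]$beta
    tibble(scm = nm,
           filter = rep(seq_len(ncol(b)), each = nrow(b)),
           position = rep(seq_len(nrow(b)), ncol(b)),
           bias = as.numeric(b))
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$bias,
                                   group = .data$filter,
                                   colour = factor(.data$filter))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~scm, scales = "free") +
    ggplot2::labs(colour = "filter") +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param model A fitted `splice_model` (with a `history` tibble).
#' @return A ggplot object.
#' @export
plot_training <- function(model) {
  if (is.null(model$history)) abort("model has no training history")
  df <- model$history |>
    mutate(step = row_number()) |>
    tidyr::pivot_longer(c("loss", "kl", "heldout_kl"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "epoch (cumulative)", y = "nats") +
    ggplot2::theme_minimal()
}
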