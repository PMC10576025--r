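# broom-style methods for fitted models.

argmax_kmer <- function(alpha_f) {
  # additive per-position scoring: the best k-mer is the per-position argmax
  paste(SEQ_LEVELS[apply(alpha_f, 1, which.max)], collapse = "")
}

#' Tidy a fitted splicing balance model
#'
#' One row per filter: its SCM, side, width, best-matching k-mer (sequence
#' filters; per-position argmax of the additive kernel score), kernel
#' norm, and mean position bias.
#'
#' @param x A `splice_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.splice_model <- function(x, ...) {
  purrr::map(SCM_NAMES, function(nm) {
    a <- x$scms[[nm]]$alpha
    b <- x$scms[[nm]]$beta
    k <- dim(a)[3]
    tibble(filter = sprintf("%s:%d", nm, seq_len(k)),
           scm = nm,
           side = ifelse(grepl("^incl", nm), "inclusion", "skipping"),
           width = dim(a)[1],
           best_kmer = if (grepl("seq", nm)) {
             vapply(seq_len(k), function(f) argmax_kmer(a[, 1:4, f]),
                    character(1))
           } else NA_character_,
           kernel_norm = vapply(seq_len(k), function(f) sqrt(sum(a[, , f]^2)),
                                numeric(1)),
           mean_bias = colMeans(b))
  }) |> bind_rows()
}

#' Model-level summary
#'
#' @param x A `splice_model`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, tuner type, basal strength,
#'   parameter count, last training losses.
#' @exportS3Method generics::glance
glance.splice_model <- function(x, ...) {
  n_par <- sum(vapply(x$scms, function(s) length(s$alpha) + length(s$beta),
                      numeric(1))) + 1 +
    sum(lengths(x$tuner[setdiff(names(x$tuner), "type")]))
  last <- if (!is.null(x$history)) utils::tail(x$history, 1) else NULL
  tibble(d = x$d,
         n_filters_seq = dim(x$scms$incl_seq$alpha)[3],
         n_filters_struct = dim(x$scms$incl_struct$alpha)[3],
         tuner = x$tuner$type, stage = x$stage, basal = x$B,
         n_parameters = n_par,
         final_loss = if (is.null(last)) NA_real_ else last$loss,
         final_heldout_kl = if (is.null(last)) NA_real_ else last$heldout_kl)
}

#' Augment a dataset with model predictions
#'
#' @param x A `splice_model`.
#' @param data Dataset tibble.
#' @param ... Unused.
#' @return `data` with prediction columns (see [predict.splice_model()]).
#' @exportS3Method generics::augment
augment.splice_model <- function(x, data, ...) {
  predict(x, data)
}
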