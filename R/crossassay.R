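# Applying a trained model to assays with other exon lengths: Lanczos
# resampling of the position-bias matrices and a per-assay scalar basal
# correction.

lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  core <- abs(x) < a & x != 0
  out[x == 0] <- 1
  out[core] <- a * sin(pi * x[core]) * sin(pi * x[core] / a) /
    (pi^2 * x[core]^2)
  out
}

#' Lanczos resampling of a position-bias matrix
#'
#' Resamples each filter's bias column from `nrow(beta)` to
#' `new_row_count` positions with the Lanczos kernel (windowed sinc,
#' window parameter `a`) under a proportional endpoint-to-endpoint
#' position mapping; out-of-range source indices are clamped to the
#' edges. At the native length the kernel is exact (identity).
#'
#' @param beta Numeric matrix (positions x filters) or column vector.
#' @param new_row_count Target number of positions (>= 1).
#' @param a Lanczos window parameter (default 3).
#' @return Resampled matrix `new_row_count x k`.
#' @export
resample_position_bias <- function(beta, new_row_count, a = 3) {
  beta <- as.matrix(beta)
  old <- nrow(beta)
  if (new_row_count < 1) abort("new_row_count must be >= 1")
  if (new_row_count == 1L && old > 1L) {
    warn("resampling to a single position: returning column means")
    return(matrix(colMeans(beta), 1L, ncol(beta)))
  }
  if (old == 1L) return(matrix(beta, new_row_count, ncol(beta), byrow = TRUE))
  out <- matrix(0, new_row_count, ncol(beta))
  for (j in seq_len(new_row_count)) {
    t <- (j - 1) * (old - 1) / (new_row_count - 1)  # 0-based source position
    lo <- floor(t) - a + 1
    hi <- floor(t) + a
    src <- lo:hi
    wts <- lanczos_kernel(t - src, a = a)
    src <- pmin(pmax(src, 0), old - 1)  # clamp edges
    out[j, ] <- colSums(beta[src + 1, , drop = FALSE] * wts) / sum(wts)
  }
  out
}

#' Adapt a model to another assay's exon length
#'
#' Resamples every SCM's position-bias matrix to the row count implied by
#' the new window length (`exon_length + 2 * flank - w + 1`) and returns a
#' model operating on that window. The per-assay basal correction is
#' fitted separately with [fit_assay_correction()].
#'
#' @param model A trained `splice_model`.
#' @param exon_length Variable exon length of the target assay.
#' @param flank Flank width on each side (default 10).
#' @param a Lanczos window parameter.
#' @return A `splice_model` with resampled position biases and updated `d`.
#' @export
adapt_model <- function(model, exon_length, flank = 10, a = 3) {
  d_new <- as.integer(exon_length + 2L * flank)
  out <- model
  out$d <- d_new
  for (nm in SCM_NAMES) {
    w <- dim(model$scms[[nm]]$alpha)[1]
    out$scms[[nm]]$beta <- resample_position_bias(model$scms[[nm]]$beta,
                                                  d_new - w + 1L, a = a)
  }
  out$adapted_from <- model$d
  out
}

#' Filter external-assay exons against the wild-type sequence
#'
#' Keeps records whose sequence has the wild-type length (no indels) and
#' matches the wild type at the first and last three nucleotides.
#'
#' @param records Tibble with an `exon_seq` column.
#' @param wt_sequence The assay's wild-type exon sequence.
#' @return Filtered tibble.
#' @export
filter_external_exons <- function(records, wt_sequence) {
  records <- as_tibble(records)
  wt <- rna_normalize(wt_sequence)
  L <- nchar(wt)
  seqs <- rna_normalize(records$exon_seq)
  keep <- nchar(seqs) == L &
    substr(seqs, 1L, 3L) == substr(wt, 1L, 3L) &
    substr(seqs, L - 2L, L) == substr(wt, L - 2L, L)
  records[keep, , drop = FALSE]
}

#' Fit the per-assay basal correction
#'
#' Finds the scalar shift of the basal strength minimizing the mean
#' Bernoulli KL between measured and predicted PSI on the assay, all
#' other parameters frozen (golden-section search on a bounded interval).
#'
#' @param model A (possibly adapted) `splice_model`.
#' @param data Assay dataset tibble (`sequence`, `structure`, `wobble`,
#'   `psi`).
#' @param interval Search interval for the correction (default c(-10, 10)).
#' @param tol Search tolerance (default 1e-4).
#' @return List with `delta_b`, `loss` (mean KL at the optimum), and
#'   `loss0` (mean KL with no correction).
#' @export
fit_assay_correction <- function(model, data, interval = c(-10, 10),
                                 tol = 1e-4) {
  data <- as_tibble(data)
  pred <- predict(model, data)
  delta <- pred$.delta
  link <- function(dlt) {
    if (model$tuner$type == "prime") {
      tuner_prime(dlt, model$tuner$nu, model$tuner$eta)
    } else tuner_full(dlt, model$tuner)
  }
  obj <- function(db) mean(bernoulli_kl(data$psi, link(delta + db)))
  opt <- optimize(obj, interval = interval, tol = tol)
  if (!is.finite(opt$objective)) {
    abort("basal-correction fit failed: non-finite loss",
          class = "splicebalance_fitting_failure")
  }
  loss0 <- obj(0)
  db <- if (opt$objective <= loss0) opt$minimum else 0
  list(delta_b = db, loss = min(opt$objective, loss0), loss0 = loss0)
}
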