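# Staged training: Bernoulli-KL loss, activity (l1) and smoothness (l2 of
# first differences) regularizers, Adam, and the three-stage schedule
# (sequence SCMs with the affine-sigmoid link; + structure SCMs; + full
# tuner). Sparsity-aware hyperparameter selection via grid search.

#' Training configuration
#'
#' @param n_filters_seq,n_filters_struct Filters per sequence / structure
#'   SCM.
#' @param tuner_hidden Hidden width of the full tuner.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs_stage1,epochs_stage2,epochs_stage3 Epochs per stage.
#' @param lambda_act Activity-regularization weight (l1 of all strengths).
#' @param lambda_smooth Smoothness-regularization weight (squared l2 of
#'   position-bias first differences).
#' @param eps_clip Predicted-PSI clipping bound inside the KL loss.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param init_sd,beta_init Initialization of kernels / position biases.
#' @param verbose Print per-epoch loss lines.
#' @param log_path Optional path for a JSON-lines training log.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_filters_seq = 20, n_filters_struct = 8,
                         tuner_hidden = 10, lr = 1e-2, batch_size = 128,
                         epochs_stage1 = 200, epochs_stage2 = 40,
                         epochs_stage3 = 15,
                         lambda_act = 1e-4, lambda_smooth = 1e-3,
                         eps_clip = 1e-6, seed = 1,
                         init_sd = 0.05, beta_init = -4,
                         verbose = FALSE, log_path = NULL) {
  if (lambda_act < 0 || lambda_smooth < 0) abort("regularization weights must be >= 0")
  if (eps_clip <= 0 || eps_clip > 0.01) abort("eps_clip must be in (0, 0.01]")
  structure(as.list(environment()), class = "train_config")
}

#' Bernoulli Kullback-Leibler divergence
#'
#' `KL(p || q) = p log(p/q) + (1-p) log((1-p)/(1-q))`, with `0 log 0 = 0`
#' and `q` clipped to `[eps, 1 - eps]`. This is the per-record training
#' loss (measured || predicted), averaged over records.
#'
#' @param p Measured PSI in `[0, 1]`.
#' @param q Predicted PSI.
#' @param eps Clipping bound for `q`.
#' @return Non-negative numeric vector.
#' @export
bernoulli_kl <- function(p, q, eps = 1e-6) {
  stopifnot_scalar_prob(p, "p")
  q <- pmin(pmax(q, eps), 1 - eps)
  t1 <- ifelse(p > 0, p * log(p / q), 0)
  t2 <- ifelse(p < 1, (1 - p) * log((1 - p) / (1 - q)), 0)
  t1 + t2
}

#' Activity penalty: l1 norm of all strengths
#'
#' Strengths are post-softplus and hence positive, so the l1 norm equals
#' their plain sum.
#'
#' @param strength_maps A strength matrix, a list of strength matrices, or
#'   a list of [scm_forward()] results.
#' @return Non-negative scalar.
#' @export
activity_penalty <- function(strength_maps) {
  if (is.numeric(strength_maps)) return(sum(abs(strength_maps)))
  sum(vapply(strength_maps, function(m) {
    if (is.list(m) && !is.null(m$strengths)) sum(abs(m$strengths)) else sum(abs(m))
  }, numeric(1)))
}

#' Smoothness penalty on position biases
#'
#' Squared l2 norm of the discrete derivative (first differences along the
#' position dimension) of each position-bias column, summed over filters
#' and SCMs. Invariant under adding a constant to a column.
#'
#' @param betas A position-bias matrix, list of matrices, or a
#'   `splice_model` (all active SCMs).
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(betas) {
  if (inherits(betas, "splice_model")) {
    nms <- if (betas$use_struct) SCM_NAMES else c("incl_seq", "skip_seq")
    betas <- lapply(betas$scms[nms], `[[`, "beta")
  }
  if (is.matrix(betas)) betas <- list(betas)
  sum(vapply(betas, function(b) sum(apply(b, 2, function(col) sum(diff(col)^2))),
             numeric(1)))
}

# ---- parameter packing ------------------------------------------------

stage_slots <- function(model, stage) {
  scms <- if (stage == 1L) c("incl_seq", "skip_seq") else SCM_NAMES
  slots <- c(t(outer(scms, c("alpha", "beta"), paste, sep = ".")), "B")
  if (model$tuner$type == "prime") {
    c(slots, "tuner.nu", "tuner.eta")
  } else {
    c(slots, paste0("tuner.", c("W1", "b1", "W2", "b2", "w3", "b3", "r")))
  }
}

get_slot <- function(model, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (parts[1] == "B") model$B
  else if (parts[1] == "tuner") model$tuner[[parts[2]]]
  else model$scms[[parts[1]]][[parts[2]]]
}

set_slot <- function(model, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (parts[1] == "B") model$B <- value
  else if (parts[1] == "tuner") model$tuner[[parts[2]]][] <- value
  else model$scms[[parts[1]]][[parts[2]]][] <- value
  model
}

grad_slot <- function(grads, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (parts[1] == "B") grads$B
  else if (parts[1] == "tuner") grads$tuner[[parts[2]]]
  else if (parts[2] == "alpha") grads$alpha[[match(parts[1], SCM_NAMES)]]
  else grads$beta[[match(parts[1], SCM_NAMES)]]
}

pack <- function(model, slots) {
  unlist(lapply(slots, function(k) as.numeric(get_slot(model, k))),
         use.names = FALSE)
}

pack_grads <- function(grads, slots) {
  unlist(lapply(slots, function(k) as.numeric(grad_slot(grads, k))),
         use.names = FALSE)
}

unpack <- function(model, slots, theta) {
  off <- 0L
  for (k in slots) {
    len <- length(get_slot(model, k))
    model <- set_slot(model, k, theta[(off + 1L):(off + len)])
    off <- off + len
  }
  model
}

# ---- optimizer --------------------------------------------------------

run_adam <- function(model, enc, psi, slots, config, epochs, stage,
                     valid_enc = NULL, valid_psi = NULL) {
  n <- nrow(enc$seqm)
  theta <- pack(model, slots)
  m_t <- numeric(length(theta))
  v_t <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- list()
  n_batches <- max(1L, ceiling(n / config$batch_size))
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    ep <- c(loss = 0, kl = 0, activity = 0, smoothness = 0)
    for (bi in seq_len(n_batches)) {
      rows <- ord[seq.int((bi - 1L) * config$batch_size + 1L,
                          min(bi * config$batch_size, n))]
      res <- cpp_loss_grad(enc$seqm, enc$structm, enc$wobm, rows, psi,
                           model$scms, model$B, model$tuner,
                           model$use_struct,
                           config$lambda_act, config$lambda_smooth,
                           config$eps_clip, TRUE)
      if (!is.finite(res$loss)) {
        abort(sprintf("training diverged (non-finite loss) at stage %d, epoch %d",
                      stage, epoch), class = "splicebalance_training_failure")
      }
      g <- pack_grads(res$grads, slots)
      t <- t + 1L
      m_t <- b1 * m_t + (1 - b1) * g
      v_t <- b2 * v_t + (1 - b2) * g^2
      mhat <- m_t / (1 - b1^t)
      vhat <- v_t / (1 - b2^t)
      theta <- theta - config$lr * mhat / (sqrt(vhat) + eps)
      model <- unpack(model, slots, theta)
      w <- length(rows) / n
      ep <- ep + w * c(res$loss, res$kl, res$activity, res$smoothness)
    }
    heldout_kl <- NA_real_
    if (!is.null(valid_enc)) {
      pred <- cpp_model_eval(valid_enc$seqm, valid_enc$structm,
                             valid_enc$wobm, model$scms, model$B,
                             model$tuner, model$use_struct)
      heldout_kl <- mean(bernoulli_kl(valid_psi, pred$psi, config$eps_clip))
    }
    row <- tibble(stage = stage, epoch = epoch, loss = ep[["loss"]],
                  kl = ep[["kl"]], activity = ep[["activity"]],
                  smoothness = ep[["smoothness"]], heldout_kl = heldout_kl)
    history[[epoch]] <- row
    if (isTRUE(config$verbose)) {
      cat(sprintf("stage %d epoch %3d  loss %.5f  kl %.5f  heldout %.5f\n",
                  stage, epoch, ep[["loss"]], ep[["kl"]], heldout_kl))
    }
    if (!is.null(config$log_path)) {
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = config$log_path, append = TRUE)
    }
  }
  model$history <- bind_rows(model$history, bind_rows(history))
  model
}

split_data <- function(data) {
  data <- as_tibble(data)
  if ("split" %in% names(data)) {
    list(train = filter(data, .data$split == "train"),
         valid = filter(data, .data$split == "test"))
  } else {
    list(train = data, valid = NULL)
  }
}

# ---- staged training --------------------------------------------------

#' Stage 1: sequence SCMs with the affine-sigmoid link
#'
#' Trains a simplified model — only the two sequence SCMs, combined as
#' `sigmoid(nu * (f_incl_seq - f_skip_seq + B) + eta)` — so that short
#' sequence motifs are absorbed by the sequence filters before the more
#' expressive structure filters are introduced.
#'
#' @param data Dataset tibble (`sequence`, `structure`, `wobble`, `psi`;
#'   rows with `split == "train"` are used when a `split` column exists,
#'   and `split == "test"` rows provide held-out KL logging).
#' @param config A [train_config()].
#' @return A partially trained `splice_model` (structure SCMs present but
#'   inactive).
#' @export
train_stage1 <- function(data, config = train_config()) {
  parts <- split_data(data)
  set.seed(config$seed)
  model <- splice_model(d = nchar(parts$train$sequence[1]),
                        n_filters_seq = config$n_filters_seq,
                        n_filters_struct = config$n_filters_struct,
                        tuner = "prime", tuner_hidden = config$tuner_hidden,
                        init_sd = config$init_sd, beta_init = config$beta_init)
  model$use_struct <- FALSE
  enc <- encode_dataset(parts$train, d = model$d)
  valid_enc <- if (!is.null(parts$valid) && nrow(parts$valid) > 0) {
    encode_dataset(parts$valid, d = model$d)
  }
  model <- run_adam(model, enc, parts$train$psi, stage_slots(model, 1L),
                    config, config$epochs_stage1, 1L,
                    valid_enc, parts$valid$psi)
  model$stage <- 1L
  model
}

#' Stage 2: add the structure SCMs
#'
#' Activates the two structure SCMs (warm-starting the sequence SCMs from
#' stage 1) and trains all four SCMs, still under the affine-sigmoid link.
#'
#' @param model The stage-1 model.
#' @inheritParams train_stage1
#' @return The stage-2 `splice_model`.
#' @export
train_stage2 <- function(model, data, config = train_config()) {
  if (model$stage < 1L) abort("stage 2 requires a stage-1 model")
  parts <- split_data(data)
  set.seed(config$seed + 1L)
  model$use_struct <- TRUE
  enc <- encode_dataset(parts$train, d = model$d)
  valid_enc <- if (!is.null(parts$valid) && nrow(parts$valid) > 0) {
    encode_dataset(parts$valid, d = model$d)
  }
  model <- run_adam(model, enc, parts$train$psi, stage_slots(model, 2L),
                    config, config$epochs_stage2, 2L,
                    valid_enc, parts$valid$psi)
  model$stage <- 2L
  model
}

#' Stage 3: promote the link to the full tuner
#'
#' Replaces the affine-sigmoid link with the residual-MLP tuner,
#' initialized to reproduce it exactly (residual weight = nu, output bias
#' = eta, output weights zero), and fine-tunes everything.
#'
#' @param model The stage-2 model.
#' @inheritParams train_stage1
#' @return The final `splice_model`.
#' @export
train_stage3 <- function(model, data, config = train_config()) {
  if (model$stage < 2L) abort("stage 3 requires a stage-2 model")
  parts <- split_data(data)
  set.seed(config$seed + 2L)
  if (model$tuner$type == "prime") {
    model$tuner <- new_tuner_full(nu = model$tuner$nu, eta = model$tuner$eta,
                                  hidden = config$tuner_hidden)
  }
  enc <- encode_dataset(parts$train, d = model$d)
  valid_enc <- if (!is.null(parts$valid) && nrow(parts$valid) > 0) {
    encode_dataset(parts$valid, d = model$d)
  }
  model <- run_adam(model, enc, parts$train$psi, stage_slots(model, 3L),
                    config, config$epochs_stage3, 3L,
                    valid_enc, parts$valid$psi)
  model$stage <- 3L
  model
}

#' Fit the splicing balance model with the staged schedule
#'
#' Runs the requested training stages in order. Single-threaded and fully
#' reproducible given `config$seed`.
#'
#' @param data Dataset tibble (see [train_stage1()]).
#' @param config A [train_config()].
#' @param stages Integer subset of `1:3` (contiguous, starting at 1 unless
#'   `model` is supplied).
#' @param model Optional partially trained model to resume from.
#' @return A `splice_model` with a `history` tibble of per-epoch losses.
#' @export
fit_splice_model <- function(data, config = train_config(), stages = 1:3,
                             model = NULL) {
  stages <- sort(unique(as.integer(stages)))
  for (s in stages) {
    model <- switch(as.character(s),
                    "1" = train_stage1(data, config),
                    "2" = train_stage2(model, data, config),
                    "3" = train_stage3(model, data, config),
                    abort("stages must be in 1:3"))
  }
  model
}

# ---- sparsity & grid search ------------------------------------------

#' Sparsity of activations
#'
#' For each exon, strengths from all active SCMs are re-added greedily in
#' decreasing magnitude (starting from the basal strength alone) until the
#' KL divergence between the measured PSI and the PSI predicted from the
#' truncated delta drops below `kl_threshold`; the metric is the mean
#' number of strengths needed. Exons that never reach the threshold count
#' all their activations.
#'
#' @param model A trained `splice_model`.
#' @param data Dataset tibble with a `psi` column.
#' @param kl_threshold KL threshold in nats (default 0.05).
#' @param max_records Subsample cap (the metric is a mean; `NULL` = all).
#' @return Mean activation count (scalar).
#' @export
sparsity_metric <- function(model, data, kl_threshold = 0.05,
                            max_records = 500) {
  data <- as_tibble(data)
  if (!is.null(max_records) && nrow(data) > max_records) {
    data <- data[seq_len(max_records), ]
  }
  enc <- encode_dataset(data, d = model$d)
  tuner_eval <- function(delta) {
    if (model$tuner$type == "prime") {
      tuner_prime(delta, model$tuner$nu, model$tuner$eta)
    } else tuner_full(delta, model$tuner)
  }
  counts <- vapply(seq_len(nrow(data)), function(i) {
    maps <- cpp_strength_maps(enc$seqm[i, ], enc$structm[i, ], enc$wobm[i, ],
                              model$scms, model$use_struct)
    signed <- unlist(lapply(SCM_NAMES, function(nm) {
      if (is.null(maps[[nm]])) return(numeric(0))
      sgn <- if (grepl("^incl", nm)) 1 else -1
      sgn * as.numeric(maps[[nm]]$strengths)
    }))
    ord <- order(abs(signed), decreasing = TRUE)
    delta <- model$B
    p <- data$psi[i]
    if (bernoulli_kl(p, tuner_eval(delta)) < kl_threshold) return(0)
    for (j in seq_along(ord)) {
      delta <- delta + signed[ord[j]]
      if (bernoulli_kl(p, tuner_eval(delta)) < kl_threshold) return(j)
    }
    length(signed)
  }, numeric(1))
  mean(counts)
}

#' Sparsity-aware hyperparameter grid search
#'
#' Trains one model per (lambda_act, lambda_smooth) grid point and scores
#' it by held-out KL and the sparsity metric. Among points meeting both
#' cutoffs, the one with the highest smoothness regularization wins (ties:
#' highest activity regularization, then grid order). If no point passes,
#' the best-KL point is returned with a warning.
#'
#' @param data Dataset tibble with a `split` column.
#' @param lambda_act_grid,lambda_smooth_grid Non-empty numeric grids.
#' @param config Base [train_config()].
#' @param stages Training stages used for each grid point.
#' @param kl_cutoff Maximum admissible held-out KL (nats).
#' @param sparsity_cutoff Maximum admissible mean activation count.
#' @param kl_threshold KL threshold inside [sparsity_metric()].
#' @return The chosen `train_config`, with the scored grid attached as
#'   attribute `"grid"`.
#' @export
grid_search <- function(data, lambda_act_grid = c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                        lambda_smooth_grid = c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                        config = train_config(), stages = 1:2,
                        kl_cutoff = 0.05, sparsity_cutoff = 5,
                        kl_threshold = 0.05) {
  if (length(lambda_act_grid) == 0 || length(lambda_smooth_grid) == 0) {
    abort("hyperparameter grids must be non-empty")
  }
  grid <- tidyr::expand_grid(lambda_act = lambda_act_grid,
                             lambda_smooth = lambda_smooth_grid)
  parts <- split_data(data)
  if (is.null(parts$valid) || nrow(parts$valid) == 0) {
    abort("grid_search needs a dataset with a train/test split")
  }
  scored <- purrr::pmap(grid, function(lambda_act, lambda_smooth) {
    cfg <- config
    cfg$lambda_act <- lambda_act
    cfg$lambda_smooth <- lambda_smooth
    fit <- fit_splice_model(data, cfg, stages = stages)
    pred <- predict(fit, parts$valid)
    tibble(lambda_act = lambda_act, lambda_smooth = lambda_smooth,
           heldout_kl = mean(bernoulli_kl(parts$valid$psi, pred$.psi_hat)),
           sparsity = sparsity_metric(fit, parts$valid,
                                      kl_threshold = kl_threshold))
  }) |> bind_rows()
  passing <- scored |>
    filter(.data$heldout_kl <= kl_cutoff, .data$sparsity <= sparsity_cutoff)
  if (nrow(passing) > 0) {
    chosen <- passing |>
      arrange(dplyr::desc(.data$lambda_smooth), dplyr::desc(.data$lambda_act)) |>
      dplyr::slice(1)
  } else {
    warn("no grid point met the accuracy and sparsity cutoffs; returning the best-KL point")
    chosen <- scored |> arrange(.data$heldout_kl) |> dplyr::slice(1)
  }
  out <- config
  out$lambda_act <- chosen$lambda_act
  out$lambda_smooth <- chosen$lambda_smooth
  attr(out, "grid") <- scored
  out
}
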