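# Loss functions, regularizers, staged schedule contracts, sparsity and
# grid search.

test_that("Bernoulli KL matches its closed forms", {
  expect_equal(bernoulli_kl(0.5, 0.5), 0)
  expect_equal(bernoulli_kl(1.0, 0.5), log(2), tolerance = 1e-10)
  p <- 0.3; q <- 0.7
  expect_equal(bernoulli_kl(p, q),
               p * log(p / q) + (1 - p) * log((1 - p) / (1 - q)),
               tolerance = 1e-12)
  expect_equal(round(bernoulli_kl(0.3, 0.7), 4), 0.3389)
  # non-negativity with equality iff p == q, on a grid
  grid <- seq(0.05, 0.95, by = 0.15)
  for (p in grid) for (q in grid) {
    kl <- bernoulli_kl(p, q)
    if (p == q) expect_equal(kl, 0) else expect_gt(kl, 0)
  }
  # 0 log 0 convention at the endpoints
  expect_equal(bernoulli_kl(0, 0.5), log(2), tolerance = 1e-10)
  expect_true(is.finite(bernoulli_kl(1, 1)))
})

test_that("activity penalty is the plain sum of positive strengths", {
  maps <- list(matrix(log(2), 85, 20), matrix(log(2), 85, 20))
  expect_equal(activity_penalty(maps), 2 * 1700 * log(2), tolerance = 1e-9)
  set.seed(41)
  m <- matrix(abs(rnorm(30)), 6, 5)
  expect_equal(activity_penalty(list(m)), sum(m))
  # accepts scm_forward output
  x <- encode_input("ACGUAA", "......")$x_seq
  sf <- scm_forward(x, list(alpha = array(0.1, dim = c(2, 4, 2)),
                            beta = matrix(0, 5, 2)))
  expect_equal(activity_penalty(list(sf)), sum(sf$strengths))
})

test_that("smoothness penalty is the squared l2 norm of first differences", {
  expect_equal(smoothness_penalty(matrix(3.7, 10, 2)), 0)
  expect_equal(smoothness_penalty(matrix(c(0, 1, 3), 3, 1)), 5.0)
  b <- matrix(rnorm(20), 10, 2)
  expect_equal(smoothness_penalty(b + 100), smoothness_penalty(b),
               tolerance = 1e-8)
})

test_that("loss decomposition is reproducible from the logged components", {
  dat <- make_tiny_dataset(n = 16, d = 40, seed = 43)
  model <- make_tiny_model(d = 40, seed = 47)
  sb <- asNamespace("splicebalance")
  enc <- sb$encode_dataset(dat)
  res <- sb$cpp_loss_grad(enc$seqm, enc$structm, enc$wobm, 1:16, dat$psi,
                          model$scms, model$B, model$tuner, TRUE,
                          2e-3, 5e-2, 1e-6, FALSE)
  expect_equal(res$loss, res$kl + 2e-3 * res$activity + 5e-2 * res$smoothness,
               tolerance = 1e-12)
  # components agree with the R-side implementations
  pred <- predict(model, dat)
  expect_equal(res$kl, mean(bernoulli_kl(dat$psi, pred$.psi_hat)),
               tolerance = 1e-8)
  expect_equal(res$smoothness, smoothness_penalty(model), tolerance = 1e-8)
  act <- mean(vapply(seq_len(nrow(dat)), function(i) {
    maps <- sb$record_strength_maps(dat[i, ], model)
    sum(vapply(SCM_NAMES, function(nm) sum(maps[[nm]]$strengths), numeric(1)))
  }, numeric(1)))
  expect_equal(res$activity, act, tolerance = 1e-8)
})

test_that("compiled gradients match numerical differentiation", {
  dat <- make_tiny_dataset(n = 6, d = 40, seed = 53)
  model <- make_tiny_model(d = 40, seed = 59)
  sb <- asNamespace("splicebalance")
  enc <- sb$encode_dataset(dat)
  lossfn <- function(m) {
    sb$cpp_loss_grad(enc$seqm, enc$structm, enc$wobm, 1:6, dat$psi,
                     m$scms, m$B, m$tuner, TRUE, 1e-3, 1e-2, 1e-6, FALSE)$loss
  }
  res <- sb$cpp_loss_grad(enc$seqm, enc$structm, enc$wobm, 1:6, dat$psi,
                          model$scms, model$B, model$tuner, TRUE,
                          1e-3, 1e-2, 1e-6, TRUE)
  h <- 1e-6
  bump <- function(path, i, eps) {
    m <- model
    if (path == "B") m$B <- m$B + eps
    else if (path == "nu") m$tuner$nu <- m$tuner$nu + eps
    else {
      parts <- strsplit(path, "\\$")[[1]]
      m$scms[[parts[1]]][[parts[2]]][i] <- m$scms[[parts[1]]][[parts[2]]][i] + eps
    }
    m
  }
  checks <- list(
    list("incl_seq$alpha", 5, res$grads$alpha[[1]][5]),
    list("skip_struct$alpha", 100, res$grads$alpha[[4]][100]),
    list("incl_struct$beta", 7, res$grads$beta[[2]][7]),
    list("B", NA, res$grads$B),
    list("nu", NA, res$grads$tuner$nu))
  for (ck in checks) {
    num <- (lossfn(bump(ck[[1]], ck[[2]], h)) -
              lossfn(bump(ck[[1]], ck[[2]], -h))) / (2 * h)
    expect_equal(ck[[3]], num, tolerance = 1e-4)
  }
})

# one small synthetic dataset shared by the schedule tests
sched_data <- local({
  flat <- rep(1, 85)
  rule <- splice_rule(
    tibble::tibble(kmer = c("GAAGAA", "UAGGGU"),
                   side = c("inclusion", "skipping"),
                   strength = c(3, 3), profile = list(flat, flat)),
    stem = list(min_stem_len = 5, max_stem_len = 7, strength = 2),
    gpoor = NULL)
  assay <- build_synthetic_assay(rule, n_exons = 1200, depth = 400, seed = 61,
                                 p_motif = 0.45, p_stem = 0.3)
  ds <- preprocess_assay(assay$records,
                         structures = assay$truth[, c("barcode", "structure")],
                         seed = 62)
  dplyr::left_join(ds, assay$truth[, c("barcode", "true_psi")], by = "barcode")
})

sched_env <- new.env()

sched_cfg <- train_config(n_filters_seq = 4, n_filters_struct = 4,
                          epochs_stage1 = 60, epochs_stage2 = 25,
                          epochs_stage3 = 10, lr = 1e-2, seed = 63)

test_that("stage 1 learns a planted motif rule and is seed-reproducible", {
  m1 <- train_stage1(sched_data, sched_cfg)
  te <- dplyr::filter(sched_data, split == "test")
  pred <- predict(m1, te)
  kl_model <- mean(bernoulli_kl(te$psi, pred$.psi_hat))
  kl_const <- mean(bernoulli_kl(te$psi, mean(sched_data$psi)))
  expect_lt(kl_model, kl_const)
  # determinism: same config twice gives the identical final loss
  m1b <- train_stage1(sched_data, sched_cfg)
  expect_identical(utils::tail(m1$history$loss, 1),
                   utils::tail(m1b$history$loss, 1))
  expect_identical(predict(m1b, te)$.psi_hat, pred$.psi_hat)
  assign("m1_cache", m1, envir = sched_env)
})

test_that("stage 2 warm-starts from stage 1 and captures the stem feature", {
  m1 <- get("m1_cache", envir = sched_env)
  m2 <- train_stage2(m1, sched_data, sched_cfg)
  te <- dplyr::filter(sched_data, split == "test")
  kl1 <- mean(bernoulli_kl(te$psi, predict(m1, te)$.psi_hat))
  kl2 <- mean(bernoulli_kl(te$psi, predict(m2, te)$.psi_hat))
  # planted stems carry real signal: structure SCMs must improve held-out KL
  expect_lt(kl2, kl1)
  # warm start: a zero-epoch stage 2 leaves the sequence SCMs untouched
  cfg0 <- sched_cfg
  cfg0$epochs_stage2 <- 0
  m2_init <- train_stage2(m1, sched_data, cfg0)
  expect_identical(m2_init$scms$incl_seq$alpha, m1$scms$incl_seq$alpha)
  expect_identical(m2_init$scms$skip_seq$beta, m1$scms$skip_seq$beta)
  expect_true(m2_init$use_struct)
  assign("m2_cache", m2, envir = sched_env)
})

test_that("stage 3 starts exactly at the stage-2 predictions and does not regress", {
  m2 <- get("m2_cache", envir = sched_env)
  te <- dplyr::filter(sched_data, split == "test")
  # promotion alone (before any stage-3 training) reproduces stage 2
  set.seed(sched_cfg$seed + 2L)
  promoted <- m2
  promoted$tuner <- splicebalance:::new_tuner_full(
    nu = m2$tuner$nu, eta = m2$tuner$eta, hidden = sched_cfg$tuner_hidden)
  expect_equal(predict(promoted, te)$.psi_hat, predict(m2, te)$.psi_hat,
               tolerance = 1e-4)
  m3 <- train_stage3(m2, sched_data, sched_cfg)
  kl2 <- mean(bernoulli_kl(te$psi, predict(m2, te)$.psi_hat))
  kl3 <- mean(bernoulli_kl(te$psi, predict(m3, te)$.psi_hat))
  expect_lt(kl3, kl2 + 0.02)
  # tuner audit: non-decreasing over the observed delta range
  d <- seq(min(predict(m3, te)$.delta), max(predict(m3, te)$.delta),
           length.out = 60)
  expect_true(all(diff(tuner_full(d, m3$tuner)) > -1e-6))
})

test_that("a heavy activity penalty drives strengths toward the minimum", {
  cfg_reg <- sched_cfg
  cfg_reg$lambda_act <- 10
  cfg_reg$epochs_stage1 <- 30
  m_reg <- train_stage1(sched_data, cfg_reg)
  cfg_free <- sched_cfg
  cfg_free$lambda_act <- 0
  cfg_free$epochs_stage1 <- 30
  m_free <- train_stage1(sched_data, cfg_free)
  act_of <- function(m) {
    pred <- predict(m, sched_data[1:50, ])
    mean(pred$.f_incl_seq + pred$.f_skip_seq)
  }
  expect_lt(act_of(m_reg), act_of(m_free) / 5)
})

test_that("the sparsity metric counts dominant activations and is monotone", {
  m2 <- get("m2_cache", envir = sched_env)
  te <- dplyr::filter(sched_data, split == "test")[1:40, ]
  s_inf <- sparsity_metric(m2, te, kl_threshold = Inf)
  expect_equal(s_inf, 0)
  s_mid <- sparsity_metric(m2, te, kl_threshold = 0.05)
  s_loose <- sparsity_metric(m2, te, kl_threshold = 0.2)
  expect_gte(s_mid, s_loose)
  expect_gt(s_mid, 0)
})

test_that("grid search prefers the smoothest passing configuration", {
  te <- dplyr::filter(sched_data, split == "test")
  cfg <- sched_cfg
  cfg$epochs_stage1 <- 25
  # generous cutoffs so several points pass; the smoothest must win
  res <- grid_search(sched_data, lambda_act_grid = c(0, 1e-4),
                     lambda_smooth_grid = c(1e-4, 1e-2),
                     config = cfg, stages = 1,
                     kl_cutoff = 10, sparsity_cutoff = Inf)
  expect_equal(res$lambda_smooth, 1e-2)
  expect_equal(res$lambda_act, 1e-4)
  expect_identical(nrow(attr(res, "grid")), 4L)
  # impossible cutoffs exercise the fallback path
  expect_warning(
    res2 <- grid_search(sched_data, lambda_act_grid = 0,
                        lambda_smooth_grid = 0, config = cfg, stages = 1,
                        kl_cutoff = -1, sparsity_cutoff = 0),
    "no grid point")
  expect_equal(res2$lambda_smooth, 0)
})
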