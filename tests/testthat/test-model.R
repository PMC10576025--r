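# Encoding, convolution, SCM forward, tuner, full model forward, and the
# model container round trip.

test_that("encode_input builds correct one-hot channels", {
  s <- "ACGUA"
  db <- "(...)"
  enc <- encode_input(s, db)
  expect_equal(unname(enc$x_seq[1, ]), c(1, 0, 0, 0))   # A
  expect_equal(unname(enc$x_seq[2, ]), c(0, 1, 0, 0))   # C
  expect_equal(unname(enc$x_struct[2, ]), c(0, 1, 0))   # "."
  expect_equal(unname(enc$x_struct[1, ]), c(1, 0, 0))   # "("
  expect_equal(unname(enc$x_struct[5, ]), c(0, 0, 1))   # ")"
  expect_true(all(rowSums(enc$x_seq) == 1))
  expect_true(all(rowSums(enc$x_struct) == 1))
  # A-U closing pair is not a wobble
  expect_equal(sum(enc$x_wobble), 0)
  expect_identical(decode_input(enc),
                   list(sequence = s, structure = db, wobble = "00000"))
  expect_error(encode_input("ACGX", "...."), "invalid")
})

test_that("convolution matches the printed formula and a brute-force loop", {
  # d=3 over "ACG", w=2, k=1, kernel hits A at offset 1 and C at offset 2
  x <- encode_input("ACG", "...")$x_seq
  alpha <- array(0, dim = c(2, 4, 1))
  alpha[1, 1, 1] <- 1  # A at first kernel position
  alpha[2, 2, 1] <- 1  # C at second
  z <- scm_convolve(x, alpha)
  expect_equal(as.numeric(z), c(2, 0))
  expect_equal(scm_convolve(x, array(0, dim = c(2, 4, 1))),
               matrix(0, 2, 1))
  # output row counts at the published filter widths
  expect_identical(nrow(scm_convolve(matrix(0, 90, 4),
                                     array(0, dim = c(6, 4, 3)))), 85L)
  expect_identical(nrow(scm_convolve(matrix(0, 90, 8),
                                     array(0, dim = c(30, 8, 2)))), 61L)
  expect_error(scm_convolve(matrix(0, 4, 4), array(0, dim = c(6, 4, 1))),
               "width")
})

test_that("scm_forward applies position bias and softplus then sums", {
  x <- encode_input("ACG", "...")$x_seq
  alpha <- array(0, dim = c(2, 4, 1))
  alpha[1, 1, 1] <- 1
  alpha[2, 2, 1] <- 1
  out <- scm_forward(x, list(alpha = alpha, beta = matrix(0, 2, 1)))
  expect_equal(out$strengths[1, 1], log(1 + exp(2)), tolerance = 1e-6)
  expect_equal(out$strengths[2, 1], log(2), tolerance = 1e-6)
  expect_equal(out$total, log(1 + exp(2)) + log(2), tolerance = 1e-6)
  expect_true(all(out$strengths > 0))
})

test_that("scm_forward agrees with the brute-force oracle on random instances", {
  set.seed(17)
  max_dev <- 0
  for (i in 1:200) {
    d <- sample(8:12, 1)
    w <- sample(2:4, 1)
    c <- sample(c(4L, 8L), 1)
    k <- sample(1:3, 1)
    x <- matrix(rnorm(d * c), d, c)
    alpha <- array(rnorm(w * c * k), dim = c(w, c, k))
    beta <- matrix(rnorm((d - w + 1) * k), d - w + 1, k)
    got <- scm_forward(x, list(alpha = alpha, beta = beta))
    want <- oracle_scm_forward(x, alpha, beta)
    max_dev <- max(max_dev, max(abs(got$strengths - want$strengths)),
                   abs(got$total - want$total))
  }
  expect_lt(max_dev, 1e-6)
})

test_that("compiled fast path agrees with the R reference forward", {
  dat <- make_tiny_dataset(n = 6, d = 45, seed = 19)
  model <- make_tiny_model(d = 45, seed = 23)
  pred <- predict(model, dat)
  for (i in seq_len(nrow(dat))) {
    enc <- encode_input(dat$sequence[i], dat$structure[i], dat$wobble[i])
    ref <- model_forward(enc, model)
    expect_equal(ref$delta, pred$.delta[i], tolerance = 1e-10)
    expect_equal(ref$psi_hat, pred$.psi_hat[i], tolerance = 1e-10)
    expect_equal(unname(ref$totals),
                 unname(unlist(pred[i, c(".f_incl_seq", ".f_incl_struct",
                                         ".f_skip_seq", ".f_skip_struct")])),
                 tolerance = 1e-10)
  }
})

test_that("tuner behaves at its fixed points and the full tuner reduces", {
  expect_equal(tuner_prime(0, 1, 0), 0.5)
  expect_equal(tuner_prime(1, 2, -1), 1 / (1 + exp(-1)), tolerance = 1e-10)
  # sigmoid symmetry: outputs at t and -t - 2*eta/nu sum to one
  t <- 0.7; nu <- 1.5; eta <- 0.4
  expect_equal(tuner_prime(t, nu, eta) + tuner_prime(-t - 2 * eta / nu, nu, eta),
               1, tolerance = 1e-12)
  # full tuner with zero MLP output weights = prime
  tun <- splicebalance:::new_tuner_full(nu = 1.3, eta = -0.2, hidden = 6)
  d <- seq(-3, 3, by = 0.5)
  expect_equal(tuner_full(d, tun), tuner_prime(d, 1.3, -0.2), tolerance = 1e-12)
  expect_true(all(tuner_full(d, tun) > 0 & tuner_full(d, tun) < 1))
})

test_that("model forward is antisymmetric in the side assignment", {
  dat <- make_tiny_dataset(n = 4, d = 40, seed = 29)
  model <- make_tiny_model(d = 40, seed = 31)
  model$B <- 0
  pred <- predict(model, dat)
  swapped <- model
  swapped$scms <- model$scms[c("skip_seq", "skip_struct",
                               "incl_seq", "incl_struct")]
  names(swapped$scms) <- c("incl_seq", "incl_struct",
                           "skip_seq", "skip_struct")
  pred2 <- predict(swapped, dat)
  expect_equal(pred2$.delta, -pred$.delta, tolerance = 1e-10)
  # zero model predicts 0.5 by symmetry
  zero <- make_tiny_model(d = 40, seed = 1)
  for (nm in names(zero$scms)) {
    zero$scms[[nm]]$alpha[] <- 0
    zero$scms[[nm]]$beta[] <- 0
  }
  zero$B <- 0
  predz <- predict(zero, dat)
  expect_equal(predz$.delta, rep(0, nrow(dat)), tolerance = 1e-12)
  expect_equal(predz$.psi_hat, rep(0.5, nrow(dat)), tolerance = 1e-12)
})

test_that("the default architecture matches the published dimensions", {
  model <- splice_model()
  expect_identical(model$d, 90L)
  expect_identical(dim(model$scms$incl_seq$alpha), c(6L, 4L, 20L))
  expect_identical(dim(model$scms$skip_seq$alpha), c(6L, 4L, 20L))
  expect_identical(dim(model$scms$incl_struct$alpha), c(30L, 8L, 8L))
  expect_identical(dim(model$scms$skip_struct$alpha), c(30L, 8L, 8L))
  expect_identical(dim(model$scms$incl_seq$beta), c(85L, 20L))
  expect_identical(dim(model$scms$incl_struct$beta), c(61L, 8L))
})

test_that("the model container round-trips bit-exactly", {
  model <- make_tiny_model(d = 40, seed = 37)
  model$B <- pi
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  for (nm in names(model$scms)) {
    expect_identical(back$scms[[nm]]$alpha, model$scms[[nm]]$alpha)
    expect_identical(back$scms[[nm]]$beta, model$scms[[nm]]$beta)
  }
  expect_identical(back$B, model$B)
  expect_identical(back$d, model$d)
  expect_identical(back$tuner$nu, model$tuner$nu)
  # full tuner too
  model$tuner <- splicebalance:::new_tuner_full(nu = 0.8, eta = 0.1, hidden = 5)
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$tuner$W2, model$tuner$W2)
  # truncated file refuses cleanly
  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), path)
  expect_error(load_model(path), "cannot parse")
})
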