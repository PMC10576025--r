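# Balance summaries, clustering, logos, relevance, stability, mutant
# design and the artifact rule-out comparison.

interp_data <- make_tiny_dataset(n = 30, d = 60, seed = 71)
interp_model <- make_tiny_model(d = 60, k_seq = 4, k_struct = 2, seed = 73)

test_that("balance summaries reconstruct delta exactly", {
  set.seed(79)
  dat <- make_tiny_dataset(n = 100, d = 60, seed = 79)
  model <- interp_model
  model$B <- 0.37
  pred <- predict(model, dat)
  worst <- 0
  for (i in seq_len(nrow(dat))) {
    bs <- balance_summary(dat[i, ], model)
    signed <- sum(ifelse(bs$bars$side == "inclusion", 1, -1) * bs$bars$total) +
      model$B
    worst <- max(worst, abs(signed - pred$.delta[i]),
                 abs(bs$delta - pred$.delta[i]),
                 abs(bs$psi_hat - pred$.psi_hat[i]))
  }
  expect_lt(worst, 1e-9)
})

test_that("an all-zero model yields softplus(0) bars and PSI one half", {
  model <- make_tiny_model(d = 60, k_seq = 2, k_struct = 2, seed = 83)
  for (nm in names(model$scms)) {
    model$scms[[nm]]$alpha[] <- 0
    model$scms[[nm]]$beta[] <- 0
  }
  model$B <- 0
  bs <- balance_summary(interp_data[1, ], model)
  expect_equal(bs$psi_hat, 0.5)
  p_seq <- 60 - 6 + 1
  p_struct <- 60 - 30 + 1
  expect_equal(bs$bars$total[bs$bars$scm == "incl_seq"],
               rep(p_seq * log(2), 2), tolerance = 1e-9)
  expect_equal(bs$bars$total[bs$bars$scm == "skip_struct"],
               rep(p_struct * log(2), 2), tolerance = 1e-9)
})

test_that("a planted dominant skipping motif drives the largest bar", {
  # filter 1 of skip_seq recognizes UAGGGU strongly
  model <- make_tiny_model(d = 60, k_seq = 2, k_struct = 2, seed = 89)
  kmer <- strsplit("UAGGGU", "")[[1]]
  model$scms$skip_seq$alpha[] <- 0
  for (i in 1:6) {
    model$scms$skip_seq$alpha[i, match(kmer[i], c("A", "C", "G", "U")), 1] <- 3
  }
  model$scms$skip_seq$beta[, 1] <- -12  # fires only on a near-perfect match
  rec <- tibble::tibble(
    sequence = paste0(strrep("A", 20), "UAGGGU", strrep("A", 34)),
    structure = strrep(".", 60), wobble = strrep("0", 60))
  bs <- balance_summary(rec, model)
  expect_identical(bs$bars$filter[which.max(bs$bars$total)], "skip_seq:1")
  expect_identical(bs$bars$side[which.max(bs$bars$total)], "skipping")
  expect_lt(bs$psi_hat, 0.5)
})

test_that("identical filters cluster together; distinct ones apart", {
  model <- make_tiny_model(d = 60, k_seq = 3, k_struct = 2, seed = 97)
  # make incl_seq filter 2 a copy of filter 1
  model$scms$incl_seq$alpha[, , 2] <- model$scms$incl_seq$alpha[, , 1]
  model$scms$incl_seq$beta[, 2] <- model$scms$incl_seq$beta[, 1]
  cl <- cluster_filters(model, interp_data, threshold = 0.1)
  c1 <- cl$cluster[cl$filter == "incl_seq:1"]
  c2 <- cl$cluster[cl$filter == "incl_seq:2"]
  expect_identical(c1, c2)
  expect_identical(sum(cl$representative[cl$cluster == c1]), 1L)
  # clusters partition the sequence filters
  expect_identical(nrow(cl), 6L)
  # cluster count is non-increasing in the threshold
  n_cl <- vapply(c(0.05, 0.3, 0.8, 1.5),
                 function(h) length(unique(
                   cluster_filters(model, interp_data, threshold = h)$cluster)),
                 numeric(1))
  expect_true(all(diff(n_cl) <= 0))
  # a dead filter lands in its own singleton cluster
  model$scms$incl_seq$alpha[, , 3] <- 0
  model$scms$incl_seq$beta[, 3] <- -50
  cl2 <- cluster_filters(model, interp_data, threshold = 0.1)
  expect_identical(sum(cl2$cluster == cl2$cluster[cl2$filter == "incl_seq:3"]), 1L)
})

test_that("clusters can be merged manually with a re-chosen representative", {
  cl <- cluster_filters(interp_model, interp_data, threshold = 0.1)
  merged <- merge_clusters(cl, c("incl_seq:1", "incl_seq:2", "skip_seq:1"))
  ids <- merged$cluster[merged$filter %in% c("incl_seq:1", "incl_seq:2",
                                             "skip_seq:1")]
  expect_identical(length(unique(ids)), 1L)
  expect_identical(sum(merged$representative[merged$cluster == ids[1]]), 1L)
  expect_error(merge_clusters(cl, "no_such:9"), "unknown")
})

test_that("enumerate logos recover a planted consensus k-mer", {
  model <- make_tiny_model(d = 60, k_seq = 2, k_struct = 2, seed = 101)
  kmer <- strsplit("GAAGAA", "")[[1]]
  model$scms$incl_seq$alpha[, , 1] <- 0
  for (i in 1:6) {
    model$scms$incl_seq$alpha[i, match(kmer[i], c("A", "C", "G", "U")), 1] <- 2
  }
  model$scms$incl_seq$beta[, 1] <- -9  # at most one mismatch activates
  logo <- filter_logo(model, "incl_seq:1")
  expect_identical(dim(unclass(logo)), c(4L, 6L))
  expect_identical(attr(logo, "mode"), "enumerate")
  # 1 perfect + 18 single-mismatch 6-mers score above 0
  expect_identical(attr(logo, "n_selected"), 19L)
  consensus <- rownames(logo)[apply(logo, 2, which.max)]
  expect_identical(paste(consensus, collapse = ""), "GAAGAA")
  # all-equal kernel columns give a uniform logo over all 4096 k-mers
  model$scms$incl_seq$alpha[, , 2] <- 1
  model$scms$incl_seq$beta[, 2] <- 0
  logo_u <- filter_logo(model, "incl_seq:2")
  expect_identical(attr(logo_u, "n_selected"), 4096L)
  expect_true(all(abs(logo_u - 0.25) < 1e-12))
  # a filter that never activates warns and returns an empty logo
  model$scms$incl_seq$beta[, 2] <- -100
  expect_warning(logo_e <- filter_logo(model, "incl_seq:2"), "no 6-mer")
  expect_true(all(logo_e == 0))
})

test_that("sample-mode logos depict enrichment for a structure filter", {
  model <- make_tiny_model(d = 60, k_seq = 2, k_struct = 2, seed = 103)
  model$scms$skip_struct$beta[, 1] <- 0  # let the filter activate somewhere
  logo <- filter_logo(model, "skip_struct:1", data = interp_data)
  expect_gt(attr(logo, "n_selected"), 0)
  expect_identical(dim(unclass(logo)), c(4L, 30L))
  expect_identical(attr(logo, "mode"), "sample")
})

test_that("relevance conserves each filter's total strength", {
  model <- interp_model
  for (flt in c("incl_seq:2", "skip_struct:1")) {
    ref <- splicebalance:::parse_filter_ref(flt)
    for (i in 1:20) {
      rec <- interp_data[i, ]
      rel <- nucleotide_relevance(rec, model, flt)
      maps <- splicebalance:::record_strength_maps(rec, model)
      total <- sum(maps[[ref$scm]]$strengths[, ref$index])
      expect_equal(sum(rel$relevance), total, tolerance = 1e-3)
    }
  }
})

test_that("relevance localizes inside the matching window", {
  model <- make_tiny_model(d = 60, k_seq = 2, k_struct = 2, seed = 107)
  kmer <- strsplit("GAAGAA", "")[[1]]
  model$scms$incl_seq$alpha[, , 1] <- 0
  for (i in 1:6) {
    model$scms$incl_seq$alpha[i, match(kmer[i], c("A", "C", "G", "U")), 1] <- 2
  }
  model$scms$incl_seq$beta[, 1] <- -11.9  # only the exact match fires
  rec <- tibble::tibble(
    sequence = paste0(strrep("C", 30), "GAAGAA", strrep("C", 24)),
    structure = strrep(".", 60), wobble = strrep("0", 60))
  rel <- nucleotide_relevance(rec, model, "incl_seq:1")
  inside <- rel$relevance[31:36]
  outside <- rel$relevance[-(31:36)]
  expect_gt(sum(inside), 0.99 * sum(rel$relevance))
  expect_lt(max(abs(outside)), 1e-2)
})

test_that("filters match themselves across duplicated models and not noise", {
  rep1 <- seed_stability(list(interp_model, interp_model), interp_data)
  expect_true(all(rep1$correlation > 1 - 1e-12))
  other <- make_tiny_model(d = 60, k_seq = 4, k_struct = 2, seed = 211)
  rep2 <- seed_stability(list(interp_model, other), interp_data)
  expect_lt(median(rep2$correlation), 0.9)
})

test_that("artifact check distinguishes bona fide skipping from dropout", {
  set.seed(113)
  n <- 120
  flag <- rep(c(TRUE, FALSE), each = n / 2)
  depth <- 200
  # bona fide: the feature shifts PSI down at constant depth
  psi <- ifelse(flag, 0.25, 0.6)
  incl <- rbinom(n, depth, psi)
  bona <- tibble::tibble(n_inclusion = incl, n_skipping = depth - incl)
  expect_identical(artifact_check(bona, flag)$verdict, "bona fide")
  # artifact: inclusion reads drop out, skipping unchanged
  incl0 <- rbinom(n, depth, 0.6)
  skip0 <- depth - incl0
  art <- tibble::tibble(
    n_inclusion = ifelse(flag, rbinom(n, incl0, 0.4), incl0),
    n_skipping = skip0)
  expect_identical(artifact_check(art, flag)$verdict, "artifact-like")
  # identical groups are inconclusive
  same <- tibble::tibble(n_inclusion = incl0, n_skipping = skip0)
  expect_identical(artifact_check(same, flag)$verdict, "inconclusive")
  # tiny groups are inconclusive regardless
  expect_identical(artifact_check(bona[1:12, ], flag[1:12])$verdict,
                   "inconclusive")
})
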