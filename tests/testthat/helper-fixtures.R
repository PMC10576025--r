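# Shared fixtures and independent oracles, all built in code.

# tiny deterministic dataset of folded random windows
make_tiny_dataset <- function(n = 8, d = 40, seed = 101) {
  seqs <- generate_exon(length = d, n = n, seed = seed)
  structs <- fold_toy(seqs)
  wob <- vapply(seq_len(n), function(i) {
    paste(wobble_vector(seqs[i], structs[i]), collapse = "")
  }, character(1))
  set.seed(seed + 1)
  tibble::tibble(sequence = seqs, structure = structs, wobble = wob,
                 psi = runif(n))
}

make_tiny_model <- function(d = 40, k_seq = 3, k_struct = 2, seed = 5) {
  splice_model(d = d, n_filters_seq = k_seq, n_filters_struct = k_struct,
               seed = seed)
}

# brute-force Nussinov oracle: exhaustive recursion over pairings
oracle_max_pairs <- function(seq, min_loop = 3) {
  pairs_ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (paste0(chars[i], chars[k]) %in% pairs_ok) {
        cand <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

count_pairs <- function(db) sum(strsplit(db, "")[[1]] == "(")

# brute-force SCM forward oracle: index-by-index double loop
oracle_scm_forward <- function(x, alpha, beta) {
  d <- nrow(x); w <- dim(alpha)[1]; k <- dim(alpha)[3]
  P <- d - w + 1L
  total <- 0
  strengths <- matrix(0, P, k)
  for (f in seq_len(k)) {
    for (p in seq_len(P)) {
      z <- 0
      for (i in seq_len(w)) {
        for (ch in seq_len(dim(alpha)[2])) {
          z <- z + x[p + i - 1L, ch] * alpha[i, ch, f]
        }
      }
      strengths[p, f] <- log(1 + exp(z + beta[p, f]))
      total <- total + strengths[p, f]
    }
  }
  list(strengths = strengths, total = total)
}

encoded_struct_input <- function(enc) {
  cbind(enc$x_seq, enc$x_struct, enc$x_wobble)
}

# a small preprocessed synthetic dataset joined with its ground truth
make_small_assay_dataset <- function(n = 400, depth = 300, seed = 77) {
  assay <- build_synthetic_assay(n_exons = n, depth = depth, seed = seed)
  ds <- preprocess_assay(
    assay$records,
    structures = assay$truth[, c("barcode", "structure")],
    seed = seed)
  dplyr::left_join(ds, assay$truth[, c("barcode", "true_delta", "true_psi",
                                       "active_features")],
                   by = "barcode")
}
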