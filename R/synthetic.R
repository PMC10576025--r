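# Synthetic reporter assay with planted, additive splicing rules.
#
# The generator emulates the structure of a massively parallel splicing
# reporter assay: random 70-nt exons inside fixed 10-nt flanks, a known
# additive rule mapping sequence/structure features to a delta strength,
# a sigmoidal link from delta strength to PSI, and binomial read sampling
# per barcode. Because the rule is known, every downstream stage
# (preprocessing, training, interpretation) can be benchmarked by
# parameter recovery.

#' Construct a ground-truth splicing rule
#'
#' A rule is a set of planted features with additive, position-dependent
#' strengths: short sequence motifs assigned to the inclusion or skipping
#' side, a stem-loop structure feature, and a G-poor window feature (both
#' on the skipping side, mirroring the feature classes such models
#' recover), plus the sigmoidal link from delta strength to PSI.
#'
#' @param motifs Tibble with columns `kmer` (6-letter RNA string), `side`
#'   (`"inclusion"` or `"skipping"`), `strength` (non-negative), and
#'   `profile` (list column of position multipliers over window starts).
#' @param stem List with `min_stem_len`, `max_stem_len`, `strength`, and
#'   `min_gc_fraction`. A helix run whose length falls in
#'   `[min_stem_len, max_stem_len]` and whose pairs are at least
#'   `min_gc_fraction` G-C contributes `strength` to the skipping side,
#'   once per run (the feature emulates short GC-rich stem loops).
#' @param gpoor List with `window_len`, `max_g_count`, `strength`. Fires
#'   (once) if any window of `window_len` nucleotides contains at most
#'   `max_g_count` Gs.
#' @param nu,eta Link parameters: PSI = sigmoid(nu * delta + eta), `nu > 0`.
#' @return An object of class `splice_rule`.
#' @export
splice_rule <- function(motifs, stem = NULL, gpoor = NULL, nu = 1, eta = 0) {
  motifs <- as_tibble(motifs)
  stopifnot(all(c("kmer", "side", "strength") %in% names(motifs)))
  motifs$kmer <- rna_normalize(motifs$kmer)
  if (!all(nchar(motifs$kmer) == 6L)) abort("rule motifs must be 6-mers")
  if (!all(motifs$side %in% c("inclusion", "skipping"))) {
    abort("motif side must be 'inclusion' or 'skipping'")
  }
  if (any(motifs$strength < 0)) abort("motif strengths must be non-negative")
  if (is.null(motifs$profile)) {
    motifs$profile <- lapply(seq_len(nrow(motifs)), function(i) rep(1, 85))
  }
  if (!is.null(stem) && stem$strength < 0) abort("stem strength must be non-negative")
  if (!is.null(gpoor) && gpoor$strength < 0) abort("gpoor strength must be non-negative")
  if (!is.numeric(nu) || nu <= 0) abort("link slope `nu` must be > 0")
  structure(list(motifs = motifs, stem = stem, gpoor = gpoor,
                 nu = nu, eta = eta),
            class = "splice_rule")
}

#' Default planted rule
#'
#' Three inclusion and three skipping 6-mers with piecewise-linear position
#' profiles, one stem-loop feature and one G-poor feature — small enough
#' for desk-scale parameter-recovery experiments.
#'
#' @param n_starts Number of valid 6-mer window starts (85 for the default
#'   90-nt window).
#' @return A `splice_rule`.
#' @export
default_splice_rule <- function(n_starts = 85) {
  ramp_up <- seq(0.5, 1.5, length.out = n_starts)
  ramp_down <- seq(1.5, 0.5, length.out = n_starts)
  flat <- rep(1, n_starts)
  peak <- c(seq(0.5, 1.5, length.out = ceiling(n_starts / 2)),
            seq(1.5, 0.5, length.out = n_starts - ceiling(n_starts / 2) + 1)[-1])
  motifs <- tibble(
    kmer = c("GAAGAA", "CAUCGC", "ACCUGA", "UAGGGU", "UCUUCU", "GUGGAC"),
    side = c("inclusion", "inclusion", "inclusion",
             "skipping", "skipping", "skipping"),
    strength = c(2.5, 2.0, 1.5, 2.5, 2.0, 1.5),
    profile = list(flat, ramp_up, ramp_down, flat, ramp_down, peak)
  )
  splice_rule(motifs,
              stem = list(min_stem_len = 5, max_stem_len = 7, strength = 1.5,
                          min_gc_fraction = 0.8),
              gpoor = list(window_len = 30, max_g_count = 2, strength = 1.0),
              nu = 1, eta = 0)
}

#' Generate random exon sequences
#'
#' Uniform i.i.d. letters over A,C,G,U.
#'
#' @param length Exon length in nucleotides (default 70).
#' @param n Number of exons.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of RNA strings.
#' @export
generate_exon <- function(length = 70, n = 1, seed = NULL) {
  if (length < 1) abort("exon length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(SEQ_LEVELS, n * length, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Plant a GC-rich stem loop into a sequence
#'
#' Writes a hairpin — two reverse-complementary GC-rich arms separated by a
#' loop — into `seq` starting at position `at` (1-based), and returns the
#' modified sequence together with a dot-bracket string marking exactly the
#' planted pairs.
#'
#' @param seq RNA string.
#' @param stem_len Arm length (5-7 is the intended regime).
#' @param loop_len Loop length, at least 3.
#' @param at 1-based start of the upstream arm.
#' @param gc_fraction Probability of drawing G/C for each arm position.
#' @return List with `sequence` and `structure`.
#' @export
plant_stem_loop <- function(seq, stem_len, loop_len, at, gc_fraction = 0.9) {
  seq <- rna_normalize(seq)
  if (loop_len < 3) abort("loop_len must be >= 3")
  span <- 2L * stem_len + loop_len
  if (at < 1 || at + span - 1L > nchar(seq)) {
    abort("stem loop does not fit: at + 2*stem_len + loop_len exceeds sequence")
  }
  arm5 <- ifelse(runif(stem_len) < gc_fraction,
                 sample(c("G", "C"), stem_len, replace = TRUE),
                 sample(c("A", "U"), stem_len, replace = TRUE))
  arm3 <- rev(chartr("ACGU", "UGCA", arm5))
  loop <- sample(SEQ_LEVELS, loop_len, replace = TRUE)
  insert <- paste(c(arm5, loop, arm3), collapse = "")
  substr(seq, at, at + span - 1L) <- insert
  db <- rep(".", nchar(seq))
  db[at:(at + stem_len - 1L)] <- "("
  db[(at + stem_len + loop_len):(at + span - 1L)] <- ")"
  list(sequence = seq, structure = paste(db, collapse = ""))
}

#' Toy RNA folder (maximum base pairing)
#'
#' Nussinov-style maximum-pairing fold with a minimum hairpin loop of
#' `min_loop` and deterministic tie-breaking (the 5'-most partner is
#' preferred). Allowed pairs: AU, UA, GC, CG, GU, UG. This is a synthetic
#' stand-in for a thermodynamic folding tool and makes no parity claim
#' with one; for real assays, supply externally predicted structures.
#'
#' @param seq Character vector of RNA strings.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return Character vector of dot-bracket strings.
#' @export
fold_toy <- function(seq, min_loop = 3) {
  seq <- rna_normalize(seq)
  vapply(seq, cpp_fold_nussinov, character(1), min_loop = min_loop,
         USE.NAMES = FALSE)
}

stem_fires <- function(chars, partner, stem) {
  # number of helix runs with length in [min, max] and a GC-rich pair set
  runs <- helix_run_list(partner)
  min_gc <- if (is.null(stem$min_gc_fraction)) 0 else stem$min_gc_fraction
  n_fire <- 0L
  for (run in runs) {
    len <- length(run)
    if (len < stem$min_stem_len || len > stem$max_stem_len) next
    gc <- mean(chars[run] %in% c("G", "C") & chars[partner[run]] %in% c("G", "C"))
    if (gc >= min_gc) n_fire <- n_fire + 1L
  }
  n_fire
}

gpoor_fires <- function(seq, window_len, max_g_count) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < window_len) return(FALSE)
  gs <- cumsum(chars == "G")
  counts <- gs[window_len:n] - c(0, gs)[1:(n - window_len + 1)]
  any(counts <= max_g_count)
}

#' True delta strength of an exon under a planted rule
#'
#' Scans `sequence` for every planted motif occurrence (overlapping
#' occurrences included), weighting each by `strength *
#' profile[start position]`, evaluates the stem and G-poor predicates on
#' `structure`/`sequence`, and returns the inclusion-minus-skipping total
#' together with a per-feature breakdown that sums to it.
#'
#' @param sequence RNA string (typically the 90-nt window).
#' @param structure Dot-bracket string, same length.
#' @param rule A [splice_rule()].
#' @return List with `delta` and `breakdown` (tibble: feature, side, value,
#'   signed).
#' @export
true_delta_strength <- function(sequence, structure, rule) {
  sequence <- rna_normalize(sequence)
  if (nchar(sequence) != nchar(structure)) {
    abort("sequence and structure lengths differ")
  }
  feats <- list()
  n_starts <- nchar(sequence) - 6L + 1L
  for (i in seq_len(nrow(rule$motifs))) {
    kmer <- rule$motifs$kmer[i]
    hits <- gregexpr(paste0("(?=", kmer, ")"), sequence, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    prof <- rule$motifs$profile[[i]]
    if (length(prof) != n_starts) {
      prof <- stats::approx(seq(0, 1, length.out = length(prof)), prof,
                            xout = seq(0, 1, length.out = n_starts))$y
    }
    for (h in as.integer(hits)) {
      if (h > n_starts) next
      feats[[length(feats) + 1L]] <- list(
        feature = sprintf("motif:%s@%d", kmer, h),
        side = rule$motifs$side[i],
        value = rule$motifs$strength[i] * prof[h])
    }
  }
  if (!is.null(rule$stem)) {
    n_fire <- stem_fires(strsplit(sequence, "")[[1]], pair_table(structure),
                         rule$stem)
    if (n_fire > 0) {
      for (j in seq_len(n_fire)) {
        feats[[length(feats) + 1L]] <- list(feature = sprintf("stem:%d", j),
                                            side = "skipping",
                                            value = rule$stem$strength)
      }
    }
  }
  if (!is.null(rule$gpoor) &&
      gpoor_fires(sequence, rule$gpoor$window_len, rule$gpoor$max_g_count)) {
    feats[[length(feats) + 1L]] <- list(feature = "gpoor", side = "skipping",
                                        value = rule$gpoor$strength)
  }
  if (length(feats) == 0L) {
    breakdown <- tibble(feature = character(0), side = character(0),
                        value = numeric(0), signed = numeric(0))
  } else {
    breakdown <- tibble(
      feature = vapply(feats, `[[`, character(1), "feature"),
      side = vapply(feats, `[[`, character(1), "side"),
      value = vapply(feats, `[[`, numeric(1), "value"))
    breakdown$signed <- ifelse(breakdown$side == "inclusion", 1, -1) * breakdown$value
  }
  list(delta = sum(breakdown$signed), breakdown = breakdown)
}

#' Sigmoidal link from delta strength to PSI
#'
#' @param delta Numeric vector of delta strengths.
#' @param nu Link slope, must be positive.
#' @param eta Link offset.
#' @return PSI values in `[0, 1]`, strictly increasing in `delta`.
#' @export
psi_from_delta <- function(delta, nu = 1, eta = 0) {
  if (!is.numeric(nu) || nu <= 0) abort("link slope `nu` must be > 0")
  sigmoid(nu * delta + eta)
}

#' Binomial read sampling for one barcode
#'
#' @param psi True inclusion probability in `[0, 1]`.
#' @param depth Total informative reads.
#' @return Tibble with `n_inclusion` and `n_skipping` (vectorized).
#' @export
sample_counts <- function(psi, depth) {
  stopifnot_scalar_prob(psi, "psi")
  if (any(depth < 0)) abort("depth must be >= 0")
  n <- max(length(psi), length(depth))
  n_incl <- rbinom(n, size = depth, prob = psi)
  tibble(n_inclusion = n_incl, n_skipping = depth - n_incl)
}

random_barcodes <- function(n, length = 20) {
  repeat {
    bc <- apply(matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
                       nrow = n), 1, paste, collapse = "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate a synthetic splicing reporter assay
#'
#' Draws random 70-nt exons, plants rule motifs and stem loops, folds each
#' 90-nt window with the toy folder, computes the true delta strength and
#' PSI under `rule`, and samples per-barcode read counts binomially.
#' Fully reproducible from `seed`.
#'
#' @param rule A [splice_rule()]; defaults to [default_splice_rule()].
#' @param n_exons Number of barcoded exons.
#' @param depth Reads per barcode per replicate (constant by default), or a
#'   function `function(n)` drawing depths.
#' @param seed Integer seed.
#' @param p_motif Per-exon, per-motif planting probability.
#' @param p_stem Per-exon probability of planting a GC-rich stem loop.
#' @param other_rate Fraction of reads assigned to non-inclusion,
#'   non-skipping outcomes (intron retention etc.), pooled as `n_other`.
#' @param replicates Number of replicate count tables to emit.
#' @param exon_length Variable exon length (default 70).
#' @return An object of class `synthetic_assay`: a list with `records`
#'   (tibble: barcode, exon_seq, n_inclusion, n_skipping, n_other,
#'   replicate), `truth` (tibble: barcode, sequence, structure, wobble,
#'   true_delta, true_psi, active_features), the `rule` and the `seed`.
#' @export
build_synthetic_assay <- function(rule = default_splice_rule(),
                                  n_exons, depth = 200, seed = 1,
                                  p_motif = 0.25, p_stem = 0.15,
                                  other_rate = 0.02, replicates = 1,
                                  exon_length = 70) {
  if (n_exons < 1) abort("n_exons must be >= 1")
  set.seed(seed)
  flanks <- splice_flanks()

  exons <- generate_exon(length = exon_length, n = n_exons)
  n_motifs <- nrow(rule$motifs)

  # starts where a span-long feature fits without touching occupied bases
  free_starts <- function(occupied, span) {
    n_start <- length(occupied) - span + 1L
    if (n_start < 1L) return(integer(0))
    occ <- c(0L, cumsum(occupied))
    which(occ[seq_len(n_start) + span] - occ[seq_len(n_start)] == 0L)
  }

  # plant motifs and stems without overlap
  for (e in seq_len(n_exons)) {
    occupied <- rep(FALSE, exon_length)
    s <- exons[e]
    for (i in seq_len(n_motifs)) {
      if (runif(1) >= p_motif) next
      starts <- free_starts(occupied, 6L)
      if (length(starts) == 0L) next
      at <- if (length(starts) == 1L) starts else sample(starts, 1)
      substr(s, at, at + 5L) <- rule$motifs$kmer[i]
      occupied[at:(at + 5L)] <- TRUE
    }
    if (!is.null(rule$stem) && runif(1) < p_stem) {
      stem_len <- sample(rule$stem$min_stem_len:rule$stem$max_stem_len, 1)
      loop_len <- sample(3:6, 1)
      span <- 2L * stem_len + loop_len
      starts <- free_starts(occupied, span)
      if (length(starts) > 0L) {
        at <- if (length(starts) == 1L) starts else sample(starts, 1)
        s <- plant_stem_loop(s, stem_len, loop_len, at)$sequence
        occupied[at:(at + span - 1L)] <- TRUE
      }
    }
    exons[e] <- s
  }

  windows <- paste0(flanks[["flank5"]], exons, flanks[["flank3"]])
  structures <- fold_toy(windows)

  truth_list <- lapply(seq_len(n_exons), function(e) {
    td <- true_delta_strength(windows[e], structures[e], rule)
    feats <- if (nrow(td$breakdown)) {
      paste(sprintf("%s=%+.4g", td$breakdown$feature, td$breakdown$signed),
            collapse = ";")
    } else ""
    list(delta = td$delta, feats = feats)
  })
  true_delta <- vapply(truth_list, `[[`, numeric(1), "delta")
  active_features <- vapply(truth_list, `[[`, character(1), "feats")
  true_psi <- psi_from_delta(true_delta, rule$nu, rule$eta)

  wobble <- vapply(seq_len(n_exons), function(e) {
    paste(wobble_vector(windows[e], structures[e]), collapse = "")
  }, character(1))

  barcodes <- random_barcodes(n_exons)

  draw_depth <- if (is.function(depth)) depth else function(n) rep(depth, n)
  records <- lapply(seq_len(replicates), function(rep_i) {
    dep <- draw_depth(n_exons)
    n_other <- rbinom(n_exons, size = dep, prob = other_rate)
    rem <- dep - n_other
    n_incl <- rbinom(n_exons, size = rem, prob = true_psi)
    tibble(barcode = barcodes, exon_seq = exons,
           n_inclusion = n_incl, n_skipping = rem - n_incl,
           n_other = n_other, replicate = rep_i)
  })
  records <- bind_rows(records)

  truth <- tibble(barcode = barcodes, sequence = windows,
                  structure = structures, wobble = wobble,
                  true_delta = true_delta, true_psi = true_psi,
                  active_features = active_features)

  structure(list(records = records, truth = truth, rule = rule, seed = seed),
            class = "synthetic_assay")
}

#' @export
print.synthetic_assay <- function(x, ...) {
  cat(sprintf("<synthetic_assay> %d exons x %d replicate(s), seed %d\n",
              nrow(x$truth), max(x$records$replicate), x$seed))
  cat(sprintf("  planted motifs: %s\n",
              paste(x$rule$motifs$kmer, collapse = ", ")))
  invisible(x)
}
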