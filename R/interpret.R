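# Interpretation: balance summaries, filter clustering and logos,
# per-nucleotide relevance (LRP), seed-stability reports, mutant design,
# and the sequencing-artifact rule-out comparison.

parse_filter_ref <- function(filter) {
  if (is.list(filter)) return(filter)
  parts <- strsplit(filter, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% SCM_NAMES) {
    abort("filter reference must look like 'skip_struct:2'")
  }
  list(scm = parts[1], index = as.integer(parts[2]))
}

record_strength_maps <- function(record, model) {
  enc <- encode_dataset(record, d = model$d)
  cpp_strength_maps(enc$seqm[1, ], enc$structm[1, ], enc$wobm[1, ],
                    model$scms, model$use_struct)
}

filter_totals_tbl <- function(maps, model) {
  active <- if (model$use_struct) SCM_NAMES else c("incl_seq", "skip_seq")
  purrr::map(active, function(nm) {
    tot <- colSums(maps[[nm]]$strengths)
    tibble(filter = sprintf("%s:%d", nm, seq_along(tot)),
           scm = nm,
           side = ifelse(grepl("^incl", nm), "inclusion", "skipping"),
           total = tot)
  }) |> bind_rows()
}

#' Balance summary of one prediction
#'
#' Decomposes a single exon's prediction into per-filter total strengths
#' (each filter's strength-map column summed over positions) on the
#' inclusion and skipping sides, plus the basal strength B. The signed
#' bar sum reproduces the model's delta strength exactly, and the tuner
#' maps it to the predicted PSI.
#'
#' @param record One-row tibble with `sequence`, `structure`, `wobble`.
#' @param model A trained `splice_model`.
#' @return A `balance_summary`: list with `bars` (tibble: filter, scm,
#'   side, total), `B`, `delta`, `psi_hat`.
#' @export
balance_summary <- function(record, model) {
  record <- as_tibble(record)
  if (nrow(record) != 1L) abort("balance_summary takes a single record")
  maps <- record_strength_maps(record, model)
  bars <- filter_totals_tbl(maps, model)
  delta <- sum(ifelse(bars$side == "inclusion", 1, -1) * bars$total) + model$B
  psi_hat <- if (model$tuner$type == "prime") {
    tuner_prime(delta, model$tuner$nu, model$tuner$eta)
  } else {
    tuner_full(delta, model$tuner)
  }
  structure(list(bars = bars, B = model$B,
                 B_side = if (model$B >= 0) "inclusion" else "skipping",
                 delta = delta, psi_hat = psi_hat,
                 sequence = record$sequence[1]),
            class = "balance_summary")
}

#' @export
print.balance_summary <- function(x, ...) {
  cat(sprintf("<balance_summary> delta strength %.3f -> predicted PSI %.3f (basal B %.3f)\n",
              x$delta, x$psi_hat, x$B))
  top <- x$bars |> arrange(dplyr::desc(.data$total)) |> head(5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-16s %-9s %8.3f\n", top$filter[i], top$side[i], top$total[i]))
  }
  invisible(x)
}

per_record_filter_totals <- function(model, data, scms = NULL) {
  # matrix: records x filters (named scm:index)
  data <- as_tibble(data)
  enc <- encode_dataset(data, d = model$d)
  active <- if (model$use_struct) SCM_NAMES else c("incl_seq", "skip_seq")
  if (!is.null(scms)) active <- intersect(active, scms)
  rows <- lapply(seq_len(nrow(data)), function(i) {
    maps <- cpp_strength_maps(enc$seqm[i, ], enc$structm[i, ], enc$wobm[i, ],
                              model$scms, model$use_struct)
    unlist(lapply(active, function(nm) {
      tot <- colSums(maps[[nm]]$strengths)
      setNames(tot, sprintf("%s:%d", nm, seq_along(tot)))
    }))
  })
  do.call(rbind, rows)
}

#' Cluster sequence filters by their activation profiles
#'
#' Represents each sequence filter by the vector of its total strength on
#' every exon in `data`, applies agglomerative hierarchical clustering on
#' correlation distance, and marks the strongest member (largest mean
#' strength) of each cluster as its representative. Filters with constant
#' (zero-variance) strength vectors are assigned singleton clusters.
#'
#' @param model A trained `splice_model`.
#' @param data Dataset tibble.
#' @param threshold Tree-cut height on `1 - correlation` (default 0.3).
#' @param linkage Linkage method (default `"average"`).
#' @return Tibble: `filter`, `side`, `cluster`, `mean_strength`,
#'   `representative`.
#' @export
cluster_filters <- function(model, data, threshold = 0.3, linkage = "average") {
  strengths <- per_record_filter_totals(model, data,
                                        scms = c("incl_seq", "skip_seq"))
  if (ncol(strengths) < 2L) abort("need at least two filters to cluster")
  sds <- apply(strengths, 2, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  cl <- rep(NA_integer_, ncol(strengths))
  if (sum(!degenerate) >= 2L) {
    cm <- suppressWarnings(cor(strengths[, !degenerate, drop = FALSE]))
    dmat <- 1 - cm
    dmat[!is.finite(dmat)] <- 2
    hc <- hclust(as.dist(dmat), method = linkage)
    cl[!degenerate] <- cutree(hc, h = threshold)
  } else if (sum(!degenerate) == 1L) {
    cl[!degenerate] <- 1L
  }
  n_real <- max(c(0L, cl), na.rm = TRUE)
  cl[degenerate] <- n_real + seq_len(sum(degenerate))
  out <- tibble(filter = colnames(strengths),
                side = ifelse(grepl("^incl", colnames(strengths)),
                              "inclusion", "skipping"),
                cluster = cl,
                mean_strength = colMeans(strengths))
  out |>
    group_by(.data$cluster) |>
    mutate(representative = .data$mean_strength == max(.data$mean_strength) &
             !duplicated(.data$mean_strength == max(.data$mean_strength))) |>
    ungroup()
}

#' Manually merge filter clusters
#'
#' Related filters that the automatic clustering keeps apart (e.g.
#' stem-loop filters differing only in loop length) can be forced into
#' one cluster; the representative is re-chosen by mean strength.
#'
#' @param clusters A [cluster_filters()] result.
#' @param filters Character vector of filter ids to merge.
#' @return The updated cluster tibble.
#' @export
merge_clusters <- function(clusters, filters) {
  if (!all(filters %in% clusters$filter)) {
    abort("unknown filter id in `filters`")
  }
  target <- min(clusters$cluster[clusters$filter %in% filters])
  clusters$cluster[clusters$filter %in% filters] <- target
  clusters |>
    group_by(.data$cluster) |>
    mutate(representative = .data$mean_strength == max(.data$mean_strength) &
             !duplicated(.data$mean_strength == max(.data$mean_strength))) |>
    ungroup()
}

all_kmers_int <- function(w = 6L) {
  # 4^w x w matrix of 0-based base codes, A,C,G,U order
  as.matrix(do.call(tidyr::expand_grid,
                    setNames(rep(list(0:3), w), paste0("p", seq_len(w)))))
}

#' Sequence logo of a filter
#'
#' For a (short) sequence filter, mode `"enumerate"` scores every 6-mer
#' by its kernel match plus the best position bias and returns the
#' position-frequency matrix of the 6-mers with positive position-adjusted
#' pre-activation. For a (long) structure filter, mode `"sample"`
#' evaluates the filter on dataset windows and returns the
#' enrichment-depletion matrix (log2 ratio) of activating versus
#' background window sequences.
#'
#' @param model A trained `splice_model`.
#' @param filter Filter reference, e.g. `"incl_seq:3"` or `"skip_struct:1"`.
#' @param mode `"enumerate"` or `"sample"` (defaults by SCM kind).
#' @param data Dataset tibble (required for `"sample"`).
#' @param n_sample Max records scanned in `"sample"` mode.
#' @param pseudocount Added to frequencies before the log ratio.
#' @return A `filter_logo` matrix (4 x width, rows A,C,G,U), with
#'   attributes `mode` and `n_selected`.
#' @export
filter_logo <- function(model, filter, mode = NULL, data = NULL,
                        n_sample = 500, pseudocount = 0.01) {
  ref <- parse_filter_ref(filter)
  is_struct <- grepl("struct", ref$scm)
  if (is.null(mode)) mode <- if (is_struct) "sample" else "enumerate"
  alpha <- model$scms[[ref$scm]]$alpha
  beta <- model$scms[[ref$scm]]$beta
  w <- dim(alpha)[1]
  if (mode == "enumerate") {
    if (is_struct) abort("enumerate mode is for 6-nt sequence filters")
    kmers <- all_kmers_int(w)
    scores <- numeric(nrow(kmers))
    for (i in seq_len(w)) scores <- scores + alpha[i, , ref$index][kmers[, i] + 1L]
    adj <- scores + max(beta[, ref$index])
    sel <- adj > 0
    pfm <- matrix(0, 4, w, dimnames = list(SEQ_LEVELS, NULL))
    if (!any(sel)) {
      warn(sprintf("filter %s activates on no %d-mer; empty logo", filter, w))
    } else {
      for (i in seq_len(w)) {
        tab <- tabulate(kmers[sel, i] + 1L, nbins = 4)
        pfm[, i] <- tab / sum(tab)
      }
    }
    structure(pfm, mode = "enumerate", n_selected = sum(sel),
              class = c("filter_logo", "matrix"))
  } else {
    if (is.null(data)) abort("sample mode needs a dataset")
    data <- as_tibble(data)
    if (nrow(data) > n_sample) data <- data[seq_len(n_sample), ]
    enc <- encode_dataset(data, d = model$d)
    act <- character(0)
    bg <- character(0)
    for (i in seq_len(nrow(data))) {
      maps <- cpp_strength_maps(enc$seqm[i, ], enc$structm[i, ], enc$wobm[i, ],
                                model$scms, model$use_struct)
      pre <- maps[[ref$scm]]$pre[, ref$index]
      pos <- which(pre > 0)
      subs <- substring(data$sequence[i], seq_along(pre), seq_along(pre) + w - 1L)
      act <- c(act, subs[pos])
      bg <- c(bg, subs)
    }
    if (length(act) == 0L) {
      warn(sprintf("filter %s activates nowhere in the sampled data; empty logo", filter))
      return(structure(matrix(0, 4, w, dimnames = list(SEQ_LEVELS, NULL)),
                       mode = "sample", n_selected = 0L,
                       class = c("filter_logo", "matrix")))
    }
    freq <- function(x) {
      m <- seq_to_int(x)
      out <- matrix(0, 4, w, dimnames = list(SEQ_LEVELS, NULL))
      for (i in seq_len(w)) out[, i] <- tabulate(m[, i] + 1L, nbins = 4) / nrow(m)
      out
    }
    logo <- log2((freq(act) + pseudocount) / (freq(bg) + pseudocount))
    structure(logo, mode = "sample", n_selected = length(act),
              class = c("filter_logo", "matrix"))
  }
}

#' Per-nucleotide relevance of a filter's strength
#'
#' Layer-wise relevance propagation (epsilon-stabilized proportionality
#' rule): each window's post-softplus strength is redistributed onto the
#' window's input positions in proportion to their additive contribution
#' to the raw strength; the position-bias share is split evenly across the
#' window. Contributions sum to the filter's total strength up to the
#' epsilon stabilizer.
#'
#' @param record One-row dataset tibble.
#' @param model A trained `splice_model`.
#' @param filter Filter reference, e.g. `"skip_struct:1"`.
#' @param eps Stabilizer added to each denominator (default 1e-6).
#' @return Tibble: `position`, `nucleotide`, `relevance`.
#' @export
nucleotide_relevance <- function(record, model, filter, eps = 1e-6) {
  ref <- parse_filter_ref(filter)
  record <- as_tibble(record)
  if (nrow(record) != 1L) abort("nucleotide_relevance takes a single record")
  enc <- encode_dataset(record, d = model$d)
  maps <- record_strength_maps(record, model)
  alpha <- model$scms[[ref$scm]]$alpha
  beta <- model$scms[[ref$scm]]$beta
  w <- dim(alpha)[1]
  is_struct <- grepl("struct", ref$scm)
  s <- enc$seqm[1, ]; st <- enc$structm[1, ]; wo <- enc$wobm[1, ]
  strengths <- maps[[ref$scm]]$strengths[, ref$index]
  pre <- maps[[ref$scm]]$pre[, ref$index]
  rel <- numeric(model$d)
  for (p in seq_along(strengths)) {
    denom <- pre[p] + eps * ifelse(pre[p] >= 0, 1, -1)
    share <- strengths[p] / denom
    for (i in seq_len(w)) {
      pos <- p + i - 1L
      contrib <- alpha[i, s[pos] + 1L, ref$index]
      if (is_struct) {
        contrib <- contrib + alpha[i, 4L + st[pos] + 1L, ref$index] +
          wo[pos] * alpha[i, 8L, ref$index]
      }
      rel[pos] <- rel[pos] + share * contrib
    }
    # position-bias share, split evenly over the window
    rel[(p):(p + w - 1L)] <- rel[(p):(p + w - 1L)] +
      share * beta[p, ref$index] / w
  }
  tibble(position = seq_len(model$d),
         nucleotide = strsplit(rna_normalize(record$sequence[1]), "")[[1]],
         relevance = rel)
}

#' Filter stability across training runs
#'
#' Matches the filters of independently trained models (different seeds or
#' splits) by greedy bipartite matching on the correlation of their
#' per-exon total-strength vectors, using the first model as reference.
#'
#' @param models List of at least two trained `splice_model`s.
#' @param data Dataset tibble the strength vectors are evaluated on.
#' @param scms SCM subset to match (default sequence SCMs).
#' @return Tibble: `model` (index of the compared model), `filter_ref`,
#'   `filter_other`, `correlation`.
#' @export
seed_stability <- function(models, data,
                           scms = c("incl_seq", "skip_seq")) {
  if (length(models) < 2L) abort("need at least two models")
  mats <- lapply(models, per_record_filter_totals, data = data, scms = scms)
  ref <- mats[[1]]
  out <- list()
  for (m in seq_along(mats)[-1]) {
    other <- mats[[m]]
    cm <- suppressWarnings(cor(ref, other))
    cm[!is.finite(cm)] <- -Inf
    pairs <- list()
    while (any(is.finite(cm)) && nrow(cm) > 0 && ncol(cm) > 0) {
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <- tibble(
        model = m, filter_ref = rownames(cm)[idx[1]],
        filter_other = colnames(cm)[idx[2]],
        correlation = cm[idx[1], idx[2]])
      cm <- cm[-idx[1], -idx[2], drop = FALSE]
    }
    out[[length(out) + 1L]] <- bind_rows(pairs)
  }
  bind_rows(out)
}

eval_variant_totals <- function(sequence, model, refold, structure = NULL) {
  if (refold || is.null(structure)) structure <- fold_toy(sequence)
  wob <- paste(wobble_vector(sequence, structure), collapse = "")
  rec <- tibble(sequence = sequence, structure = structure, wobble = wob)
  maps <- record_strength_maps(rec, model)
  list(record = rec, totals = filter_totals_tbl(maps, model),
       pred = predict(model, rec))
}

qualifying_runs <- function(partner, min_len = 3L) {
  helix_run_list(partner, min_len = min_len)
}

empty_mutants <- function(reason) {
  out <- tibble(variant = character(0), sequence = character(0),
                structure = character(0), target_strength = numeric(0),
                target_change = numeric(0), max_other_change = numeric(0),
                psi_hat = numeric(0), accepted = logical(0))
  attr(out, "reason") <- reason
  out
}

#' Design validation mutants for a structure feature
#'
#' Stem mode: for a record with a single stem (helix run), proposes the
#' two single stem-disrupting mismatch mutants (upstream arm, downstream
#' arm) and the compensatory double mutant that swaps both partners,
#' restoring complementarity. G-poor mode: proposes one C-to-G mutation at
#' the center of the (single) window activating the target filter. Every
#' proposal is annotated with the predicted change of the target filter's
#' strength and the largest absolute change over all other filters;
#' proposals whose other-filter change exceeds `max_other_change` times
#' the largest single-mutant target change are rejected. Substitutions
#' only — record length never changes.
#'
#' @param record One-row dataset tibble.
#' @param model A trained `splice_model`.
#' @param target `"stem"` or `"gpoor"`.
#' @param target_filter Filter reference, e.g. `"skip_struct:1"`.
#' @param max_other_change Tolerated off-target change, as a fraction of
#'   the largest single-mutant target-strength change (default 0.1).
#' @param min_stem_len Minimum helix-run length treated as a stem.
#' @param refold Recompute structures of mutants with [fold_toy()]
#'   (synthetic-data path; supply pre-folded structures otherwise).
#' @return Tibble of proposals (variant, sequence, structure,
#'   target_strength, target_change, max_other_change, psi_hat, accepted);
#'   empty with attribute `"reason"` when no eligible site exists.
#' @export
design_mutants <- function(record, model, target = c("stem", "gpoor"),
                           target_filter, max_other_change = 0.1,
                           min_stem_len = 3L, refold = TRUE) {
  target <- match.arg(target)
  ref <- parse_filter_ref(target_filter)
  record <- as_tibble(record)
  if (nrow(record) != 1L) abort("design_mutants takes a single record")
  seq0 <- rna_normalize(record$sequence[1])
  orig <- eval_variant_totals(seq0, model, refold = FALSE,
                              structure = record$structure[1])
  target_id <- sprintf("%s:%d", ref$scm, ref$index)

  mutate_at <- function(s, pos, base) {
    substr(s, pos, pos) <- base
    s
  }

  if (target == "stem") {
    runs <- qualifying_runs(pair_table(record$structure[1]), min_stem_len)
    if (length(runs) != 1L) {
      return(empty_mutants(sprintf("expected exactly one stem, found %d",
                                   length(runs))))
    }
    partner <- pair_table(record$structure[1])
    run <- runs[[1]]
    i_mid <- run[ceiling(length(run) / 2)]
    j_mid <- partner[i_mid]
    b_i <- substr(seq0, i_mid, i_mid)
    b_j <- substr(seq0, j_mid, j_mid)
    variants <- tibble(
      variant = c("upstream_mutant", "downstream_mutant", "double_compensatory"),
      sequence = c(mutate_at(seq0, i_mid, b_j),
                   mutate_at(seq0, j_mid, b_i),
                   mutate_at(mutate_at(seq0, i_mid, b_j), j_mid, b_i)))
  } else {
    maps <- record_strength_maps(record, model)
    pre <- maps[[ref$scm]]$pre[, ref$index]
    act <- which(pre > 0)
    if (length(act) == 0L) return(empty_mutants("target filter never activates"))
    if (any(diff(act) > 1L)) {
      return(empty_mutants("target filter activates in more than one region"))
    }
    w <- dim(model$scms[[ref$scm]]$alpha)[1]
    p_star <- act[ceiling(length(act) / 2)]
    center <- p_star + floor(w / 2)
    win <- seq(p_star, min(p_star + w - 1L, nchar(seq0)))
    cs <- win[substring(seq0, win, win) == "C"]
    if (length(cs) == 0L) return(empty_mutants("no C inside the activated window"))
    pos <- cs[which.min(abs(cs - center))]
    variants <- tibble(variant = "c_to_g_mutant",
                       sequence = mutate_at(seq0, pos, "G"))
  }

  evals <- purrr::map(variants$sequence, eval_variant_totals, model = model,
                      refold = refold,
                      structure = if (refold) NULL else record$structure[1])
  get_target <- function(tot) tot$total[tot$filter == target_id]
  t0 <- get_target(orig$totals)
  rows <- purrr::imap(evals, function(ev, i) {
    d_all <- ev$totals$total - orig$totals$total
    other <- max(abs(d_all[ev$totals$filter != target_id]))
    tibble(variant = variants$variant[i],
           sequence = ev$record$sequence,
           structure = ev$record$structure,
           target_strength = get_target(ev$totals),
           target_change = get_target(ev$totals) - t0,
           max_other_change = other,
           psi_hat = ev$pred$.psi_hat)
  }) |> bind_rows()
  scale <- max(abs(rows$target_change))
  rows$accepted <- rows$max_other_change <= max_other_change * scale
  orig_row <- tibble(variant = "original", sequence = seq0,
                     structure = orig$record$structure,
                     target_strength = t0, target_change = 0,
                     max_other_change = 0, psi_hat = orig$pred$.psi_hat,
                     accepted = TRUE)
  bind_rows(orig_row, rows)
}

#' Rule out sequencing artifacts for a candidate skipping feature
#'
#' A bona fide exon-skipping feature should reduce inclusion reads while
#' increasing skipping reads; an enzymatic/sequencing artifact (feature
#' impairing reactivity of the included product) reduces inclusion reads
#' while leaving skipping reads unchanged. Compares the raw count
#' distributions between feature-positive and feature-negative records
#' with rank-based (Wilcoxon) tests.
#'
#' @param records Tibble with `n_inclusion`, `n_skipping`.
#' @param feature_flag Logical vector (or name of a logical column in
#'   `records`) marking feature-positive records.
#' @param alpha Significance level (default 0.05).
#' @param min_group Minimum records per group (default 10); smaller groups
#'   yield an `"inconclusive"` verdict.
#' @return One-row tibble: group sizes, shift p-values and directions for
#'   both counts, and `verdict` (`"bona fide"`, `"artifact-like"`,
#'   `"inconclusive"`).
#' @export
artifact_check <- function(records, feature_flag, alpha = 0.05,
                           min_group = 10) {
  records <- as_tibble(records)
  if (is.character(feature_flag) && length(feature_flag) == 1L) {
    feature_flag <- records[[feature_flag]]
  }
  flag <- as.logical(feature_flag)
  n_pos <- sum(flag); n_neg <- sum(!flag)
  shift <- function(x) {
    if (n_pos < min_group || n_neg < min_group) {
      return(list(p = NA_real_, dir = "unknown"))
    }
    p <- suppressWarnings(wilcox.test(x[flag], x[!flag])$p.value)
    d <- median(x[flag]) - median(x[!flag])
    list(p = p, dir = if (p >= alpha) "unchanged" else if (d < 0) "down" else "up")
  }
  incl <- shift(records$n_inclusion)
  skip <- shift(records$n_skipping)
  verdict <- if (n_pos < min_group || n_neg < min_group) {
    "inconclusive"
  } else if (incl$dir == "down" && skip$dir == "up") {
    "bona fide"
  } else if (incl$dir == "down" && skip$dir == "unchanged") {
    "artifact-like"
  } else {
    "inconclusive"
  }
  tibble(n_positive = n_pos, n_negative = n_neg,
         p_inclusion = incl$p, dir_inclusion = incl$dir,
         p_skipping = skip$p, dir_skipping = skip$dir,
         verdict = verdict)
}
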